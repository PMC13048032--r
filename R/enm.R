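# Elastic network models and normal modes.
#
# Two variants share the contact-based spring energy
#   V = (K/2) sum_contacts [ rhat_ij . (dr_i' - dr_j') ]^2 :
#
# * Cartesian (ANM): degrees of freedom are the 3L Cartesian coordinates of
#   the C-alpha atoms; springs act on C-alpha pair distances of contacting
#   residues; 6 rigid-body modes removed; 3L-6 modes.
# * Torsional (TNM): degrees of freedom are the backbone phi/psi torsions
#   (first residue's phi and last residue's psi excluded: 2L-2 for a single
#   chain); all heavy atoms move through the torsion->Cartesian Jacobian;
#   springs act on the closest-heavy-atom pair of each contact; a quadratic
#   torsional penalty kappa_psi * K * sum_a (dtheta_a)^2 regularizes the
#   spectrum; rigid-body motion is removed by mass-weighted Eckart projection.
#
# Masses are normalized so the total mass is 1; modes satisfy the
# mass-weighted orthonormality sum_i m_i v^a_i v^b_i = delta_ab, so the
# mass-weighted mean-square deformation of a response is directly the sum of
# squared mode amplitudes.

#' Elastic-network parameters
#'
#' @param K Overall force constant (arbitrary units; thermal amplitudes scale
#'   as 1/K).
#' @param kappa_psi Torsional penalty coefficient (default 0.2), applied to
#'   all retained phi/psi torsions.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Object of class \code{enm_parameters}.
#' @export
enm_parameters <- function(K = 1, kappa_psi = 0.2, cutoff = 4.5) {
  stopifnot(K > 0, kappa_psi >= 0)
  structure(list(K = K, kappa_psi = kappa_psi, cutoff = cutoff),
            class = "enm_parameters")
}

# mass-orthonormalized rigid-body basis (3N x 6) for coordinates xyz (N x 3)
# and per-atom masses m (sum 1); columns orthonormal in the m-metric.
.rigid_basis <- function(xyz, m) {
  n <- nrow(xyz)
  com <- colSums(xyz * m)
  xc <- sweep(xyz, 2, com)
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  B[, 4] <- as.vector(t(cbind(0, -xc[, 3], xc[, 2])))
  B[, 5] <- as.vector(t(cbind(xc[, 3], 0, -xc[, 1])))
  B[, 6] <- as.vector(t(cbind(-xc[, 2], xc[, 1], 0)))
  mm <- rep(m, each = 3)
  # Gram-Schmidt in the mass metric
  for (k in 1:6) {
    for (l in seq_len(k - 1))
      B[, k] <- B[, k] - sum(mm * B[, k] * B[, l]) * B[, l]
    nk <- sqrt(sum(mm * B[, k]^2))
    if (nk < 1e-12) stop("degenerate rigid-body basis")
    B[, k] <- B[, k] / nk
  }
  B
}

.mode_basis <- function(omega, modes, masses, variant, atoms_res) {
  o <- order(omega)
  structure(list(omega = omega[o], modes = modes[, o, drop = FALSE],
                 masses = masses, n_dof = length(omega), variant = variant,
                 atoms_res = atoms_res),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode_basis (%s): %d modes, omega in [%.3g, %.3g]\n",
              x$variant, x$n_dof, min(x$omega), max(x$omega)))
  invisible(x)
}

#' Cartesian (ANM) normal modes over C-alpha atoms
#'
#' @param s A \code{protein_structure}.
#' @param cm An enm-flavor \code{contact_map} of \code{s}.
#' @param p \code{enm_parameters}.
#' @return A \code{mode_basis} with 3L-6 modes; mode vectors span the
#'   C-alpha coordinates (atoms_res maps coordinate blocks to residues).
#' @export
build_cartesian_enm <- function(s, cm, p = enm_parameters()) {
  if (inherits(cm, "contact_map") && cm$flavor != "enm")
    stop("ANM requires the enm-flavor contact map")
  L <- s$n
  ca_rows <- which(s$atoms$name == "CA")
  if (length(ca_rows) != L) stop("structure must have one CA per residue")
  xyz <- as.matrix(s$atoms[ca_rows, c("x", "y", "z")])
  m <- s$atoms$mass[ca_rows]
  # residue masses: total heavy-atom mass per residue, normalized to sum 1
  m <- as.vector(rowsum(s$atoms$mass, s$atoms$res))
  m <- m / sum(m)
  H <- matrix(0, 3 * L, 3 * L)
  pr <- cm$pairs
  for (q in seq_len(nrow(pr))) {
    i <- pr$i[q]; j <- pr$j[q]
    v <- xyz[i, ] - xyz[j, ]
    d <- sqrt(sum(v^2))
    if (d < 1e-9) next
    blk <- p$K * tcrossprod(v / d)
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  msq <- rep(sqrt(m), each = 3)
  Hw <- H / tcrossprod(msq)
  ee <- eigen(Hw, symmetric = TRUE)
  ev <- rev(ee$values)
  vec <- ee$vectors[, rev(seq_len(3 * L)), drop = FALSE]
  tolz <- max(ev) * 1e-9
  nzero <- sum(ev < tolz)
  if (nzero > 6)
    stop("disconnected elastic network: ", nzero, " near-zero modes")
  keep <- (nzero + 1):(3 * L)
  omega <- sqrt(ev[keep])
  modes <- vec[, keep, drop = FALSE] / msq  # mass-orthonormal Cartesian modes
  .mode_basis(omega, modes, m, "cartesian", seq_len(L))
}

# torsion axes for the TNM: returns list with axis point, unit vector and
# 0/1 membership vector of moved atoms for each retained phi/psi torsion.
.torsion_axes <- function(s) {
  a <- s$atoms
  L <- s$n
  idx <- function(res, name) {
    k <- which(a$res == res & a$name == name)
    if (length(k) != 1) stop("missing backbone atom ", name, " in residue ", res)
    k[1]
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n_at <- nrow(a)
  axes <- list()
  for (i in seq_len(L)) {
    iN <- idx(i, "N"); iCA <- idx(i, "CA"); iC <- idx(i, "C")
    # phi_i: rotation about N_i -> CA_i; moves side chain + C/O of i and all
    # residues after i (excluded for i = 1)
    if (i > 1) {
      moved <- (a$res > i) | (a$res == i & !(a$name %in% c("N", "CA")))
      axes[[length(axes) + 1]] <- list(
        p = xyz[iN, ], u = xyz[iCA, ] - xyz[iN, ], moved = moved,
        label = sprintf("phi_%d", i))
    }
    # psi_i: rotation about CA_i -> C_i; moves O of i and residues after i
    # (excluded for i = L)
    if (i < L) {
      moved <- (a$res > i) | (a$res == i & a$name == "O")
      axes[[length(axes) + 1]] <- list(
        p = xyz[iCA, ], u = xyz[iC, ] - xyz[iCA, ], moved = moved,
        label = sprintf("psi_%d", i))
    }
  }
  for (k in seq_along(axes)) {
    u <- axes[[k]]$u
    axes[[k]]$u <- u / sqrt(sum(u^2))
  }
  axes
}

# raw torsional Jacobian (3N x n_dof): column a holds d r_j / d theta_a
.torsion_jacobian <- function(s, axes) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  n_at <- nrow(xyz)
  J <- matrix(0, 3 * n_at, length(axes))
  for (k in seq_along(axes)) {
    ax <- axes[[k]]
    w <- which(ax$moved)
    if (length(w) == 0) next
    rel <- sweep(xyz[w, , drop = FALSE], 2, ax$p)
    disp <- cbind(ax$u[2] * rel[, 3] - ax$u[3] * rel[, 2],
                  ax$u[3] * rel[, 1] - ax$u[1] * rel[, 3],
                  ax$u[1] * rel[, 2] - ax$u[2] * rel[, 1])
    rows <- rep(3 * (w - 1), each = 3) + 1:3
    J[rows, k] <- as.vector(t(disp))
  }
  J
}

#' Torsional (TNM) normal modes over backbone phi/psi angles
#'
#' @inheritParams build_cartesian_enm
#' @return A \code{mode_basis} with 2L-2 modes; mode vectors are Cartesian
#'   displacement fields over all heavy atoms, mass-orthonormal. The
#'   torsional amplitudes of each mode are stored as attribute
#'   \code{"theta"}, the Eckart-projected Jacobian as attribute
#'   \code{"jacobian"}.
#' @export
build_torsional_enm <- function(s, cm, p = enm_parameters()) {
  if (inherits(cm, "contact_map") && cm$flavor != "enm")
    stop("TNM requires the enm-flavor contact map")
  L <- s$n
  m <- s$atoms$mass / sum(s$atoms$mass)
  mm <- rep(m, each = 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  axes <- .torsion_axes(s)
  J <- .torsion_jacobian(s, axes)
  B <- .rigid_basis(xyz, m)
  # Eckart: remove rigid-body content of each torsional direction
  J <- J - B %*% (t(B * mm) %*% J)
  Tm <- t(J * mm) %*% J
  # spring potential on closest-heavy-atom pairs
  nd <- ncol(J)
  V <- matrix(0, nd, nd)
  pr <- cm$pairs
  if (nrow(pr) > 0) {
    G <- matrix(0, nrow(pr), nd)
    for (q in seq_len(nrow(pr))) {
      v <- c(pr$vx[q], pr$vy[q], pr$vz[q])
      d <- pr$dist[q]
      if (d < 1e-9) next
      u <- v / d
      ri <- 3 * (pr$ai[q] - 1) + 1:3
      rj <- 3 * (pr$aj[q] - 1) + 1:3
      G[q, ] <- u %*% J[ri, , drop = FALSE] - u %*% J[rj, , drop = FALSE]
    }
    V <- p$K * crossprod(G)
  }
  V <- V + 2 * p$kappa_psi * p$K * diag(nd)
  # generalized eigenproblem V theta = omega^2 T theta via T^(-1/2)
  eT <- eigen(Tm, symmetric = TRUE)
  if (min(eT$values) < max(eT$values) * 1e-12)
    stop("degenerate torsional kinetic matrix (chain break or collinear axes?)")
  Tisq <- eT$vectors %*% (t(eT$vectors) / sqrt(eT$values))
  Cm <- t(Tisq) %*% V %*% Tisq
  Cm <- (Cm + t(Cm)) / 2
  ee <- eigen(Cm, symmetric = TRUE)
  ord <- rev(seq_len(nd))
  om2 <- ee$values[ord]
  theta <- Tisq %*% ee$vectors[, ord, drop = FALSE]
  if (min(om2) <= 0)
    stop("non-positive torsional spectrum; increase kappa_psi")
  modes <- J %*% theta
  mb <- .mode_basis(sqrt(om2), modes, m, "torsional", s$atoms$res)
  o <- order(sqrt(om2))
  attr(mb, "theta") <- theta[, o, drop = FALSE]
  attr(mb, "jacobian") <- J
  attr(mb, "axes") <- axes
  mb
}

#' Thermal mean-square displacement of a mode basis
#'
#' MSD of the null (no-mutation) model: sum over modes of 1/omega^2, i.e. the
#' mass-weighted mean-square thermal fluctuation in units where k_B T = 1.
#'
#' @param mb A \code{mode_basis}.
#' @return Scalar.
#' @export
thermal_msd <- function(mb) sum(1 / mb$omega^2)
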