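# Synthetic fixtures: ideal-geometry backbones (helix / helix bundle /
# random compact), decoy contact-map libraries standing in for PDB contact
# statistics, and MSAs sampled from site-specific stationary models, either
# i.i.d. or along a tree.
#
# All generators are deterministic given the seed.

# NeRF atom placement: position D given A-B-C, bond length r (C-D), bond
# angle theta (B-C-D, degrees) and torsion phi (A-B-C-D, degrees).
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build an all-backbone (N, CA, C, O, CB; no CB for glycine) chain from
# per-residue (phi, psi) torsions with ideal bond geometry.
.backbone_from_torsions <- function(seq, phi, psi) {
  L <- length(seq)
  stopifnot(length(phi) == L, length(psi) == L)
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231; bCA_CB <- 1.53
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7
  aCA_C_O <- 120.5; aN_CA_CB <- 110.5
  atoms <- vector("list", L)
  # seed first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(bN_CA, 0, 0)
  th <- aN_CA_C * pi / 180
  C <- CA + bCA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      prev <- atoms[[i - 1]]
      N <- .nerf(prev$N, prev$CA, prev$C, bC_N, aCA_C_N, psi[i - 1])
      CA <- .nerf(prev$CA, prev$C, N, bN_CA, aC_N_CA, 180)  # omega trans
      C <- .nerf(prev$C, N, CA, bCA_C, aN_CA_C, phi[i])
    }
    O <- .nerf(N, CA, C, bC_O, aCA_C_O, psi[i] + 180)
    res <- list(N = N, CA = CA, C = C, O = O)
    if (seq[i] != "G")
      res$CB <- .nerf(C, N, CA, bCA_CB, aN_CA_CB, -122.5)
    atoms[[i]] <- res
  }
  rows <- list()
  for (i in seq_len(L)) {
    r <- atoms[[i]]
    nm <- c("N", "CA", "C", "O", if (!is.null(r$CB)) "CB")
    el <- c("N", "C", "C", "O", if (!is.null(r$CB)) "C")
    xyz <- do.call(rbind, r[nm])
    rows[[i]] <- data.frame(res = i, name = nm, elem = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  do.call(rbind, rows)
}

# ---- helix-bundle construction ---------------------------------------------
# Packed antiparallel helices built as an explicit C-alpha trace (helical
# segments on a grid of axes joined by outward-bowed arc loops resampled at
# ~3.8 A spacing), lightly relaxed to remove steric clashes, then dressed
# with backbone atoms (N, C, O, CB) from local frames. The result is not a
# physically ideal backbone, but it has realistic contact-number ranges
# (roughly 2-12 for L ~ 50), which is what downstream trend tests exercise.

.bezier3 <- function(A, mid, B, tt)
  outer((1 - tt)^2, A) + outer(2 * tt * (1 - tt), mid) + outer(tt^2, B)

# interior loop points between A and B, spaced ~3.8 A along an arc bowed in
# direction `out` (unit, xy-plane)
.loop_points <- function(A, B, out, zsig) {
  for (bow in seq(4.5, 8, by = 0.5)) {
    mid <- (A + B) / 2 + out * bow + c(0, 0, zsig * 1.5)
    dense <- .bezier3(A, mid, B, seq(0, 1, length.out = 400))
    cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
    m <- round(max(cum) / 3.8) - 1
    if (m >= 2) {
      sp <- max(cum) / (m + 1)
      return(dense[vapply(seq_len(m) * sp,
                          function(s) which.min(abs(cum - s)), 1L), ,
                   drop = FALSE])
    }
  }
  .bezier3(A, (A + B) / 2 + out * 8, B, c(1 / 3, 2 / 3))
}

.bundle_ca_trace <- function(L, n_helix = 4, sep = 9.5, jitter = 0) {
  loop_est <- 4
  nh_res <- max(4, floor((L - (n_helix - 1) * loop_est) / n_helix))
  grid <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0)[1:n_helix],
                c(0, 0, 1, 1, 2, 2, 3, 3)[1:n_helix]) * sep
  if (jitter > 0)
    grid <- grid + matrix(stats::rnorm(length(grid), 0, jitter), ncol = 2)
  cen <- colMeans(grid)
  ca <- NULL
  dirz <- 1
  for (k in seq_len(n_helix)) {
    if (!is.null(ca) && nrow(ca) >= L) break
    nk <- if (k == n_helix) max(4, L - nrow(ca)) else nh_res
    if (!is.null(ca)) nk <- min(nk, max(4, L - nrow(ca)))
    t <- seq_len(nk) - 1
    ph <- if (jitter > 0) stats::runif(1, 0, 2 * pi) else (k - 1) * 1.7
    z0 <- if (dirz > 0) 0 else (nk - 1) * 1.5
    h <- cbind(grid[k, 1] + 2.3 * cos(1.745 * t + ph),
               grid[k, 2] + 2.3 * sin(1.745 * t + ph),
               z0 + dirz * 1.5 * t)
    if (!is.null(ca)) {
      A <- ca[nrow(ca), ]; B <- h[1, ]
      out <- c((A[1:2] + B[1:2]) / 2 - cen, 0)
      out <- out / max(sqrt(sum(out^2)), 1e-6)
      ca <- rbind(ca, .loop_points(A, B, out, dirz))
    }
    ca <- rbind(ca, h)
    dirz <- -dirz
  }
  ca[seq_len(min(L, nrow(ca))), , drop = FALSE]
}

# soft steric relaxation of a C-alpha trace: push apart non-local pairs below
# dmin while projecting consecutive spacings back to their original values
.relax_ca <- function(ca, nit = 60, dmin = 4.6) {
  L <- nrow(ca)
  bond <- sqrt(rowSums(diff(ca)^2))
  for (it in seq_len(nit)) {
    D <- as.matrix(stats::dist(ca))
    F <- matrix(0, L, 3)
    moved <- FALSE
    for (i in seq_len(L - 3)) {
      close <- which(D[i, (i + 3):L] < dmin) + i + 2
      for (j in close) {
        v <- ca[i, ] - ca[j, ]
        push <- 0.12 * (dmin - D[i, j]) * v / max(D[i, j], 0.1)
        F[i, ] <- F[i, ] + push
        F[j, ] <- F[j, ] - push
        moved <- TRUE
      }
    }
    if (!moved) break
    ca <- ca + F
    for (i in seq_len(L - 1)) {
      v <- ca[i + 1, ] - ca[i, ]
      d <- sqrt(sum(v^2))
      corr <- 0.5 * (d - bond[i]) * v / d
      ca[i, ] <- ca[i, ] + corr
      ca[i + 1, ] <- ca[i + 1, ] - corr
    }
  }
  ca
}

# dress a C-alpha trace with N, C, O (and CB except glycine) using local
# frames; peptide geometry is approximate but bonded topology is exact.
.backbone_from_ca <- function(ca, seq) {
  L <- nrow(ca)
  d <- diff(ca)
  dn <- d / sqrt(rowSums(d^2))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  p <- matrix(0, L - 1, 3)
  for (i in seq_len(L - 1)) {
    nb <- if (i < L - 1) dn[i + 1, ] else dn[i - 1, ]
    cr <- cross3(dn[i, ], nb)
    if (sqrt(sum(cr^2)) < 1e-3) {
      ref <- if (abs(dn[i, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      cr <- cross3(dn[i, ], ref)
    }
    p[i, ] <- cr / sqrt(sum(cr^2))
  }
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    segN <- max(i - 1, 1); segC <- min(i, L - 1)
    N <- if (i == 1) ca[1, ] - (1.183 * dn[segC, ] - 0.84 * p[segC, ])
         else ca[i, ] - 1.183 * dn[segN, ] + 0.84 * p[segN, ]
    C <- ca[i, ] + 1.26 * dn[segC, ] + 0.84 * p[segC, ]
    b1 <- N - ca[i, ]; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- C - ca[i, ]; b2 <- b2 / sqrt(sum(b2^2))
    cr <- cross3(b1, b2)
    nextN <- if (i < L) ca[i + 1, ] - 1.183 * dn[segC, ] + 0.84 * p[segC, ]
             else ca[i, ] + 2.5 * dn[segC, ]
    od <- (C - ca[i, ]) / 1.52 + (C - nextN) / 1.33
    O <- C + 1.23 * od / sqrt(sum(od^2))
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xyz <- rbind(N, ca[i, ], C, O)
    if (seq[i] != "G") {
      cb <- 1.2 * cr - 0.55 * (b1 + b2)
      xyz <- rbind(xyz, ca[i, ] + 1.53 * cb / sqrt(sum(cb^2)))
      nm <- c(nm, "CB"); el <- c(el, "C")
    }
    rows[[i]] <- data.frame(res = i, name = nm, elem = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  do.call(rbind, rows)
}

#' Generate a synthetic backbone structure
#'
#' Ideal-geometry backbones (N, CA, C, O and CB except glycine) built from
#' torsion angles: a straight alpha-helix, a compact helix bundle
#' (helix segments joined by turns, giving contact numbers from ~1 up to
#' >= 8), or a random-compact variant of the bundle with randomized segment
#' lengths.
#'
#' @param L Number of residues (>= 4).
#' @param geometry "helix", "helix_bundle" or "random_compact".
#' @param seq Optional residue sequence (default: deterministic pseudo-random
#'   sequence over the 20 amino acids).
#' @param seed Integer seed; same spec gives identical coordinates.
#' @param n_helix Number of helical segments for the bundle geometries.
#' @return A \code{protein_structure}.
#' @export
make_backbone <- function(L, geometry = c("helix", "helix_bundle",
                                          "random_compact"),
                          seq = NULL, seed = 1, n_helix = 4) {
  geometry <- match.arg(geometry)
  stopifnot(L >= 4)
  set.seed(seed)
  if (is.null(seq)) seq <- sample(aa_alphabet(), L, replace = TRUE)
  stopifnot(length(seq) == L)
  if (geometry == "helix") {
    atoms <- .backbone_from_torsions(seq, rep(-57, L), rep(-47, L))
  } else {
    jitter <- if (geometry == "random_compact") 1.2 else 0
    nh <- if (geometry == "random_compact") sample(3:5, 1) else n_helix
    ca <- .relax_ca(.bundle_ca_trace(L, n_helix = nh, jitter = jitter))
    seq <- seq[seq_len(nrow(ca))]
    atoms <- .backbone_from_ca(ca, seq)
  }
  protein_structure(seq, atoms, chain = "A")
}

#' Generate a decoy contact-map library
#'
#' Stability-flavor contact maps of randomized compact backbones, standing in
#' for the contact statistics of a nonredundant structure set.
#'
#' @param n Number of decoys (>= 2).
#' @param L Residue count of each decoy.
#' @param seed Integer seed.
#' @return List of \code{contact_map} objects (flavor "stability").
#' @export
make_decoy_library <- function(n, L, seed = 1) {
  stopifnot(n >= 2)
  lapply(seq_len(n), function(k) {
    s <- make_backbone(L, "random_compact", seed = seed * 1000 + k)
    build_contact_map(s, "stability")
  })
}

#' Design a foldable sequence for a synthetic structure
#'
#' Greedy minimization of the folding free energy Delta G over sites (a few
#' sweeps of per-site argmin of Delta Delta G), with a composition penalty
#' that discourages homopolymeric solutions. Used to make fixtures that pass
#' the stability filters the way native sequences do.
#'
#' @param s A \code{protein_structure} (its sequence is the start point).
#' @param cs \code{contact_statistics}.
#' @param sp \code{stability_parameters}.
#' @param sweeps Number of optimization sweeps.
#' @param comp_penalty Weight of the composition penalty (k_BT per unit of
#'   amino-acid fraction).
#' @param seed Seed for the site ordering.
#' @return Character vector: the designed sequence.
#' @export
design_sequence <- function(s, cs, sp = stability_parameters(), sweeps = 3,
                            comp_penalty = 3, seed = 1) {
  set.seed(seed)
  cmS <- build_contact_map(s, "stability")
  seqd <- s$seq
  aa <- aa_alphabet()
  for (sw in seq_len(sweeps)) {
    ca <- stability_cache(seqd, cmS, cs, sp)
    for (i in sample(seq_along(seqd))) {
      cnt <- table(factor(seqd, levels = aa)) / length(seqd)
      dd <- vapply(aa, function(a) delta_delta_g(ca, i, a), 0) +
        comp_penalty * as.vector(cnt)
      best <- aa[which.min(dd)]
      if (best != seqd[i]) {
        seqd[i] <- best
        ca <- stability_cache(seqd, cmS, cs, sp)
      }
    }
  }
  seqd
}

#' Sample an MSA from site-specific stationary models
#'
#' In i.i.d. mode each column draws \code{n_seq} letters independently from
#' its stationary distribution. In tree mode the root state of each site is
#' drawn from the stationary distribution and evolved along each branch with
#' the transition probabilities exp(t Q_i) of the site's rate matrix.
#'
#' @param P L x 20 matrix of site stationary distributions (rows sum to 1).
#' @param n_seq Number of sequences (ignored in tree mode: one per leaf).
#' @param tree Optional \code{ape::phylo} tree with branch lengths.
#' @param models Optional \code{site_models} object (required in tree mode).
#' @param seed Integer seed.
#' @return Character MSA matrix (sequences x sites).
#' @export
sample_msa <- function(P, n_seq = 100, tree = NULL, models = NULL, seed = 1) {
  set.seed(seed)
  aa <- aa_alphabet()
  L <- nrow(P)
  if (is.null(tree)) {
    m <- vapply(seq_len(L), function(i)
      sample(aa, n_seq, replace = TRUE, prob = P[i, ]), character(n_seq))
    rownames(m) <- sprintf("seq%03d", seq_len(n_seq))
    return(m)
  }
  if (is.null(models)) stop("tree mode requires a site_models object")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(0L, nnode, L)
  for (i in seq_len(L))
    states[root, i] <- sample.int(20, 1, prob = P[i, ])
  # preorder traversal
  eo <- rev(seq_len(nrow(tree$edge)))
  for (e in eo) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t_b <- tree$edge.length[e]
    for (i in seq_len(L)) {
      Pt <- site_transition_matrix(models, i, t_b)
      states[child, i] <- sample.int(20, 1, prob = Pt[states[par, i], ])
    }
  }
  m <- matrix(aa[states[seq_len(ntip), , drop = FALSE]], ntip, L)
  rownames(m) <- tree$tip.label
  m
}
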