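# Mutation response: a point mutation is represented as a perturbing force
# along the native contacts of the mutated site, and the structural
# deformation is the linear response of the elastic network.
#
# For mutation (a, m, b) the force on each contacting residue k is directed
# along the closest-heavy-atom vector r_m' - r_k', with kernel
# 1/|r|^(1+g), and magnitude combining the changes of amino-acid size,
# contact energy and optimal contact distance:
#   F_k = K R0^g [ W_size (s(b)-s(a)) + W_stab (U(b,A_k)-U(a,A_k))
#                  + W_dist (d(b,A_k)-d(a,A_k)) ] * r_mk / |r_mk|^(1+g)
# and the force on the mutated residue is minus the sum of its contacts'
# forces (reaction), so the total force vanishes.
#
# Distances entering the kernel are floored at 2.5 A (van-der-Waals contact):
# synthetic fixtures can contain closer approaches than curated crystal
# structures, and the kernel must not blow up there.

.KERNEL_FLOOR <- 2.5

# per-contact mutation geometry of site m: for each contact of m, the kernel
# vector w = (r_m' - r_k')/max(d, floor)^(1+g), the neighbour residue k and
# the two atoms involved.
.site_contact_geometry <- function(cm, m, g) {
  pr <- cm$pairs
  sel <- which(pr$i == m | pr$j == m)
  if (length(sel) == 0)
    return(data.frame(k = integer(), atom_m = integer(), atom_k = integer(),
                      wx = numeric(), wy = numeric(), wz = numeric()))
  out <- lapply(sel, function(q) {
    swap <- pr$j[q] == m
    v <- c(pr$vx[q], pr$vy[q], pr$vz[q])
    if (swap) v <- -v
    d <- max(pr$dist[q], .KERNEL_FLOOR)
    w <- v / d^(1 + g)
    data.frame(k = if (swap) pr$i[q] else pr$j[q],
               atom_m = if (swap) pr$aj[q] else pr$ai[q],
               atom_k = if (swap) pr$ai[q] else pr$aj[q],
               wx = w[1], wy = w[2], wz = w[3])
  })
  do.call(rbind, out)
}

# scalar force coefficients for mutation a -> b against neighbour residues aa_k
.force_coefficients <- function(mp, a, b, aa_k) {
  mp$K * mp$R0^mp$g *
    (mp$W_size * (mp$size_table[b] - mp$size_table[a]) +
     mp$W_stab * (mp$U[b, aa_k] - mp$U[a, aa_k]) +
     mp$W_dist * (mp$d[b, aa_k] - mp$d[a, aa_k]))
}

#' Mutation force for a specific point mutation
#'
#' @param s A \code{protein_structure}.
#' @param cm The enm-flavor \code{contact_map}.
#' @param mp \code{mutation_parameters}.
#' @param m Mutated site (1-based).
#' @param a,b Wild-type and mutant amino acids (one-letter).
#' @param wt Wild-type sequence (default \code{s$seq}).
#' @return Object of class \code{mutation_force}: the Cartesian force over
#'   all heavy atoms (3 N_atoms vector) plus bookkeeping.
#' @export
mutation_force <- function(s, cm, mp, m, a, b, wt = s$seq) {
  if (!(b %in% aa_alphabet()) || !(a %in% aa_alphabet()))
    stop("amino acids must be one of the 20 standard codes")
  n_at <- nrow(s$atoms)
  F <- numeric(3 * n_at)
  geo <- .site_contact_geometry(cm, m, mp$g)
  if (nrow(geo) > 0 && a != b) {
    co <- .force_coefficients(mp, a, b, wt[geo$k])
    for (q in seq_len(nrow(geo))) {
      f <- co[q] * c(geo$wx[q], geo$wy[q], geo$wz[q])
      rk <- 3 * (geo$atom_k[q] - 1) + 1:3
      rm <- 3 * (geo$atom_m[q] - 1) + 1:3
      F[rk] <- F[rk] + f
      F[rm] <- F[rm] - f      # reaction at the mutated residue
    }
  }
  structure(list(site = m, from = a, to = b, force = F, n_atoms = n_at,
                 atoms_res = s$atoms$res),
            class = "mutation_force")
}

# project a heavy-atom force onto a mode basis; for the Cartesian (C-alpha)
# variant the per-residue net force is applied at the residue's coordinates.
.project_force <- function(F, atoms_res, mb) {
  if (mb$variant == "torsional") {
    drop(crossprod(mb$modes, F))
  } else {
    L <- length(mb$masses)
    Fm <- matrix(F, ncol = 3, byrow = TRUE)
    Fres <- rowsum(Fm, atoms_res)
    drop(crossprod(mb$modes, as.vector(t(Fres))))
  }
}

#' Predict the structural deformation caused by a mutation force
#'
#' Linear response in the normal-mode basis: the deformation along mode alpha
#' is F'_alpha / omega_alpha^2 where F'_alpha is the force projection. The
#' RMSD is the mass-weighted root-mean-square of the deformation (total mass
#' normalized to 1) and DE is the harmonic energy of the deformation,
#' (Delta r, H Delta r) = sum_alpha (F'_alpha / omega_alpha)^2.
#'
#' @param mf A \code{mutation_force}.
#' @param mb A \code{mode_basis} built on the same structure.
#' @return List with \code{rmsd}, \code{de} and the projections \code{fprime}.
#' @export
predict_deformation <- function(mf, mb) {
  if (mb$variant == "torsional" && length(mf$force) != nrow(mb$modes))
    stop("force and mode basis have mismatched dimensions")
  fp <- .project_force(mf$force, mf$atoms_res, mb)
  list(rmsd = sqrt(sum((fp / mb$omega^2)^2)),
       de = sum((fp / mb$omega)^2),
       fprime = fp)
}

#' Decompose the total predicted MSD of a mutant structure
#'
#' Three terms: the deformation produced by the mutation force, the null
#' model of mutation-independent conformational variability (thermal
#' fluctuation profile), and a cross term of undetermined sign sigma_p:
#' MSD = MSD_mut + MSD_nomut + 2 sigma_p sqrt(sum (F'_a/omega^3)^2).
#'
#' @param mf A \code{mutation_force}.
#' @param mb A \code{mode_basis}.
#' @param sigma_p +1 or -1.
#' @return Object of class \code{deformation_prediction} with fields
#'   \code{msd_mut}, \code{msd_nomut}, \code{msd_cross_magnitude},
#'   \code{sigma_p}, \code{total}.
#' @export
total_msd_model <- function(mf, mb, sigma_p = 1) {
  stopifnot(sigma_p %in% c(-1, 1))
  fp <- .project_force(mf$force, mf$atoms_res, mb)
  msd_mut <- sum((fp / mb$omega^2)^2)
  msd_nomut <- thermal_msd(mb)
  cross <- 2 * sqrt(sum((fp / mb$omega^3)^2))
  structure(list(msd_mut = msd_mut, msd_nomut = msd_nomut,
                 msd_cross_magnitude = cross, sigma_p = sigma_p,
                 total = msd_mut + msd_nomut + sigma_p * cross),
            class = "deformation_prediction")
}

#' Fit the cross-term sign from an observed MSD
#'
#' sigma_p is +1 if the observed MSD exceeds the mutation-plus-null
#' expectation, otherwise -1 (+1 at exact equality).
#'
#' @param observed_msd Observed mean-square deviation.
#' @param dp A \code{deformation_prediction}.
#' @return +1 or -1.
#' @export
fit_sigma_p <- function(observed_msd, dp) {
  if (observed_msd >= dp$msd_mut + dp$msd_nomut) 1 else -1
}

#' Filter conformational changes that look functional
#'
#' Projects an observed deformation on the normal modes and compares its
#' harmonic energy with the null expectation at the same total MSD (null
#' mode weights proportional to 1/omega^2). Changes whose energy barrier is
#' less than half the null expectation load low-frequency modes anomalously
#' and are flagged as likely functional (discard); zero change keeps by
#' convention (ratio 1).
#'
#' @param mb A \code{mode_basis}.
#' @param dr Observed Cartesian deformation (heavy atoms for the torsional
#'   variant, C-alpha for the Cartesian one).
#' @param threshold Ratio below which the pair is discarded (default 0.5).
#' @return List with \code{keep} (logical) and \code{ratio}.
#' @export
functional_change_filter <- function(mb, dr, threshold = 0.5) {
  mm <- rep(mb$masses, each = 3)
  ca <- drop(crossprod(mb$modes, mm * dr))
  msd <- sum(ca^2)
  if (msd < 1e-30) return(list(keep = TRUE, ratio = 1))
  e_obs <- sum(mb$omega^2 * ca^2)
  e_null <- mb$n_dof * msd / sum(1 / mb$omega^2)
  ratio <- e_obs / e_null
  list(keep = ratio >= threshold, ratio = ratio)
}

#' Predicted RMSD and DE for every point mutation
#'
#' Builds the L x 20 tables of predicted RMSD and harmonic energy change.
#' The wild-type entry of each site is the average deformation of mutations
#' to the wild-type amino acid from the 19 others, weighted by their
#' stationary weights exp(lambda_str * phi) with phi = -RMSD (or -DE):
#' with lambda_str = 0 the plain arithmetic mean.
#'
#' @param s A \code{protein_structure}.
#' @param cm The enm-flavor \code{contact_map}.
#' @param mb A \code{mode_basis} of \code{s}.
#' @param mp \code{mutation_parameters}.
#' @param wt Wild-type sequence.
#' @param lambda_str Selection parameter used for the wild-type-entry
#'   weights.
#' @return Object of class \code{mutation_effect_table}: list with
#'   \code{rmsd}, \code{de} (L x 20 matrices, columns in [aa_alphabet()]
#'   order) and \code{wild_type}.
#' @export
build_effect_table <- function(s, cm, mb, mp, wt = s$seq, lambda_str = 0) {
  aa <- aa_alphabet()
  L <- s$n
  rmsd <- matrix(0, L, 20, dimnames = list(NULL, aa))
  de <- matrix(0, L, 20, dimnames = list(NULL, aa))
  iw2 <- 1 / mb$omega^2
  iw1 <- 1 / mb$omega
  for (m in seq_len(L)) {
    geo <- .site_contact_geometry(cm, m, mp$g)
    if (nrow(geo) > 0) {
      # mode projections of each contact's unit geometry force
      Pq <- matrix(0, mb$n_dof, nrow(geo))
      for (q in seq_len(nrow(geo))) {
        F <- numeric(3 * nrow(s$atoms))
        w <- c(geo$wx[q], geo$wy[q], geo$wz[q])
        F[3 * (geo$atom_k[q] - 1) + 1:3] <- w
        F[3 * (geo$atom_m[q] - 1) + 1:3] <- -w
        Pq[, q] <- .project_force(F, s$atoms$res, mb)
      }
      a <- wt[m]
      for (b in aa) {
        if (b == a) next
        co <- .force_coefficients(mp, a, b, wt[geo$k])
        fp <- drop(Pq %*% co)
        rmsd[m, b] <- sqrt(sum((fp * iw2)^2))
        de[m, b] <- sum((fp * iw1)^2)
      }
    }
    # wild-type entry: stationary-weighted average of the 19 mutations
    others <- setdiff(aa, wt[m])
    for (tab in c("rmsd", "de")) {
      v <- get(tab)[m, others]
      w <- exp(lambda_str * (-v) - max(lambda_str * (-v)))
      val <- sum(v * w) / sum(w)
      if (tab == "rmsd") rmsd[m, wt[m]] <- val else de[m, wt[m]] <- val
    }
  }
  structure(list(rmsd = rmsd, de = de, wild_type = wt),
            class = "mutation_effect_table")
}

#' Write an effect table as TSV
#'
#' One row per site: index, wild-type amino acid, then the 20 predicted
#' values in alphabet order.
#'
#' @param et A \code{mutation_effect_table}.
#' @param path Output file.
#' @param what "rmsd" or "de".
#' @export
write_effect_table <- function(et, path, what = c("rmsd", "de")) {
  what <- match.arg(what)
  M <- et[[what]]
  df <- data.frame(site = seq_len(nrow(M)), wt = et$wild_type,
                   round(M, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the mutation-force weights on observed deformations
#'
#' Maximizes the Pearson correlation between the mutation-only predicted
#' RMSD and observed RMSDs over the three component weights (the correlation
#' is invariant to the overall scale of W, so the result is reported with
#' unit Euclidean norm). Deterministic Nelder-Mead on log-ratio coordinates.
#'
#' @param training_pairs List of entries, each a list with elements
#'   \code{s}, \code{cm}, \code{mb}, \code{m}, \code{a}, \code{b},
#'   \code{observed} (observed RMSD).
#' @param mp Base \code{mutation_parameters} (tables, g, R0 held fixed).
#' @return List with \code{W} (named, unit norm), \code{correlation}.
#' @export
fit_weights <- function(training_pairs, mp = mutation_parameters()) {
  stopifnot(length(training_pairs) >= 3)
  obs <- vapply(training_pairs, function(p) p$observed, 0)
  if (stats::sd(obs) < 1e-12) stop("degenerate training set: constant observed RMSD")
  # per-pair basis: predicted rmsd(W) = || B W || with B = (F'_c / omega^2)
  basis <- lapply(training_pairs, function(p) {
    geo <- .site_contact_geometry(p$cm, p$m, mp$g)
    B <- matrix(0, p$mb$n_dof, 3)
    if (nrow(geo) == 0) return(B)
    wtk <- p$s$seq[geo$k]
    comp <- cbind(size = mp$size_table[p$b] - mp$size_table[p$a],
                  stab = mp$U[p$b, wtk] - mp$U[p$a, wtk],
                  dist = mp$d[p$b, wtk] - mp$d[p$a, wtk])
    for (q in seq_len(nrow(geo))) {
      F <- numeric(3 * nrow(p$s$atoms))
      w <- c(geo$wx[q], geo$wy[q], geo$wz[q])
      F[3 * (geo$atom_k[q] - 1) + 1:3] <- w
      F[3 * (geo$atom_m[q] - 1) + 1:3] <- -w
      pq <- .project_force(F, p$s$atoms$res, p$mb) / p$mb$omega^2
      B <- B + outer(pq, comp[q, ])
    }
    mp$K * mp$R0^mp$g * B
  })
  pred <- function(W) vapply(basis, function(B) sqrt(sum((B %*% W)^2)), 0)
  obj <- function(par) {
    W <- c(1, exp(par))
    p <- pred(W)
    if (stats::sd(p) < 1e-14) return(1)
    -stats::cor(p, obs)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  W <- c(1, exp(fit$par))
  W <- W / sqrt(sum(W^2))
  names(W) <- c("W_size", "W_stab", "W_dist")
  list(W = W, correlation = -fit$value)
}
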