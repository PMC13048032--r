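# Contact-based folding stability.
#
# The native free energy is the sum of contact energies over the stability
# contact map. The unfolded state is purely entropic, G_U = -L S_U. The
# misfolded ensemble of compact alternative conformations is described by the
# random energy model (REM): G_misf = <E> - var(E)/2 - L S_C, with the
# energy moments over a decoy library of compact contact matrices. The mean
# uses the reduced parameterization <C_ij> = a(L) f(|i-j|); the variance is
# assembled from three moment classes (same-pair, shared-site via contact
# numbers, pair-vs-total), precomputed per chain length, or computed exactly
# from the decoy energies (variance = "empirical").
#
# Delta G = G_nat - G_nonnative with
# G_nonnative = -log(exp(-G_misf) + exp(-G_U)).

#' Native contact energy of a sequence on a structure
#'
#' E(C, A) = sum over contacts i<j of U(A_i, A_j).
#'
#' @param seq Character vector (length L).
#' @param cm Stability-flavor \code{contact_map} (or bare 0/1 matrix).
#' @param U 20x20 contact energy table.
#' @return Scalar energy (k_BT units).
#' @export
native_energy <- function(seq, cm, U) {
  C <- if (inherits(cm, "contact_map")) cm$C else cm
  if (length(seq) != nrow(C)) stop("sequence / contact map length mismatch")
  if (!all(seq %in% aa_alphabet())) stop("sequence outside the 20-letter alphabet")
  idx <- which(upper.tri(C) & C == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  sum(U[cbind(seq[idx[, 1]], seq[idx[, 2]])])
}

#' Build contact statistics from a decoy library
#'
#' Estimates the contact probability versus sequence separation f(|i-j|),
#' the length scale a(L) reproducing the library's mean contact count, and
#' caches, per queried chain length L, the second-moment summaries of the
#' contacts (from leading L x L submatrices of the library maps): the
#' contact-number covariance matrix and the contact-vs-total covariance.
#'
#' @param structure_library List of \code{contact_map} objects or 0/1
#'   matrices (>= 2 entries).
#' @param min_seqsep Minimum sequence separation of counted contacts.
#' @return Object of class \code{contact_statistics}.
#' @export
build_contact_statistics <- function(structure_library, min_seqsep = 3) {
  if (length(structure_library) < 2)
    stop("decoy library needs at least 2 contact maps")
  mats <- lapply(structure_library, function(x)
    if (inherits(x, "contact_map")) x$C else as.matrix(x))
  lens <- vapply(mats, nrow, 1L)
  # pooled f(s): contact probability at each sequence separation
  smax <- max(lens) - 1L
  hits <- tot <- numeric(smax)
  ncont <- numeric(length(mats))
  for (k in seq_along(mats)) {
    C <- mats[[k]]
    Lk <- nrow(C)
    for (s in min_seqsep:(Lk - 1)) {
      d <- C[cbind(seq_len(Lk - s), seq_len(Lk - s) + s)]
      hits[s] <- hits[s] + sum(d)
      tot[s] <- tot[s] + length(d)
    }
    ncont[k] <- sum(C[upper.tri(C)])
  }
  f <- ifelse(tot > 0, hits / pmax(tot, 1), 0)
  # contacts per residue, fitted through the origin: N_c(L) ~ c L
  cfit <- sum(ncont * lens) / sum(lens^2)
  structure(list(f = f, c_per_res = cfit, maps = mats, lens = lens,
                 min_seqsep = min_seqsep, cache = new.env(parent = emptyenv())),
            class = "contact_statistics")
}

#' @export
print.contact_statistics <- function(x, ...) {
  cat(sprintf("contact_statistics: %d decoys, lengths %d-%d, %.2f contacts/residue\n",
              length(x$maps), min(x$lens), max(x$lens), x$c_per_res))
  invisible(x)
}

# length-L moment summaries (cached): P = a(L) f(|i-j|), empirical mean
# submatrix, contact-number covariance, contact-vs-total covariance, and the
# decoy submatrices themselves for the empirical-variance path.
.stats_for_length <- function(cs, L) {
  key <- as.character(L)
  if (!is.null(cs$cache[[key]])) return(cs$cache[[key]])
  use <- which(cs$lens >= L)
  if (length(use) < 2)
    stop("no contact statistics available for length ", L,
         " (library max ", max(cs$lens), ")")
  subs <- lapply(cs$maps[use], function(C) C[seq_len(L), seq_len(L)])
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  fmat <- matrix(0, L, L)
  ok <- sep >= cs$min_seqsep & sep <= length(cs$f)
  fmat[ok] <- cs$f[sep[ok]]
  target <- cs$c_per_res * L
  sf <- sum(fmat[upper.tri(fmat)])
  a_L <- if (sf > 0) min(target / sf, 1 / max(cs$f, 1e-12)) else 0
  P <- pmin(a_L * fmat, 1)
  diag(P) <- 0
  nmat <- vapply(subs, rowSums, numeric(L))        # L x ndec contact numbers
  Nc <- vapply(subs, function(C) sum(C[upper.tri(C)]), 0)
  covn <- stats::cov(t(nmat)) * (length(use) - 1) / length(use)
  Cbar <- Reduce(`+`, subs) / length(subs)
  CNc <- Reduce(`+`, Map(function(C, n) C * n, subs, Nc)) / length(subs)
  covCN <- CNc - Cbar * mean(Nc)
  st <- list(P = P, a_L = a_L, covn = covn, covCN = covCN, subs = subs,
             Cbar = Cbar)
  cs$cache[[key]] <- st
  st
}

# variance of the decoy-ensemble energy for pair-energy matrix Um (L x L
# symmetric, zero diagonal)
.misfold_moments <- function(st, Um, variance = c("moments", "empirical")) {
  variance <- match.arg(variance)
  P <- st$P
  ut <- upper.tri(P)
  if (variance == "empirical") {
    # fully empirical moments over the decoy energies
    Ed <- vapply(st$subs, function(C) sum(C[ut] * Um[ut]), 0)
    return(list(mean = mean(Ed),
                var = stats::var(Ed) * (length(Ed) - 1) / length(Ed),
                Ed = Ed))
  }
  meanE <- sum(P[ut] * Um[ut])
  # variance pieces use the empirical mean contact matrix of the library
  # (a(L) f(|i-j|) parameterizes the mean energy only), so a degenerate
  # library with identical maps gives exactly zero variance
  Cb <- st$Cbar
  rP <- rowSums(Cb)
  SU <- rowSums(Cb * Um)
  Ubar <- ifelse(rP > 0, SU / rP, 0)
  sumP <- sum(Cb[ut])
  Uglob <- if (sumP > 0) sum(Cb[ut] * Um[ut]) / sumP else 0
  T1 <- sum((Cb[ut] - Cb[ut]^2) * Um[ut]^2)
  cvU <- st$covn %*% Ubar
  T2 <- 0.5 * (sum(Ubar * cvU) - sum(diag(st$covn) * Ubar^2))
  T3 <- sum(st$covCN[ut] * Um[ut]) * Uglob
  list(mean = meanE, var = max(T1 + T2 + T3, 0))
}

#' Misfolded-ensemble free energy (REM)
#'
#' G_misf = <E> - var(E)/2 - L S_C above the REM freezing point; below it
#' (var > 2 L S_C) the free energy is clamped at the frozen value
#' <E> - sqrt(2 L S_C var(E)) - the standard REM ground-state estimate -
#' and the \code{frozen} flag is set.
#'
#' @param seq Sequence (length L).
#' @param cs \code{contact_statistics} covering length L.
#' @param U 20x20 contact energy table.
#' @param S_C Compact-conformation entropy per residue.
#' @param variance "moments" (three-term precomputed assembly, the default)
#'   or "empirical" (exact variance over the decoy energies).
#' @return List with \code{g_misf}, \code{frozen}, \code{mean}, \code{var}.
#' @export
misfold_free_energy <- function(seq, cs, U, S_C,
                                variance = c("moments", "empirical")) {
  variance <- match.arg(variance)
  L <- length(seq)
  st <- .stats_for_length(cs, L)
  Um <- U[seq, seq]
  diag(Um) <- 0
  mo <- .misfold_moments(st, Um, variance)
  if (mo$var <= 2 * L * S_C) {
    list(g_misf = mo$mean - mo$var / 2 - L * S_C, frozen = FALSE,
         mean = mo$mean, var = mo$var)
  } else {
    list(g_misf = mo$mean - sqrt(2 * L * S_C * mo$var), frozen = TRUE,
         mean = mo$mean, var = mo$var)
  }
}

.logsumexp2 <- function(a, b) {
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Folding free energy of a sequence on a structure
#'
#' Delta G = G_nat - G_nonnative, G_nonnative being the Boltzmann combination
#' of the unfolded and misfolded channels. With \code{sp$use_misfold = FALSE}
#' the misfolded channel is disabled and Delta G = G_nat + L S_U exactly.
#'
#' @param seq Sequence.
#' @param cm Stability-flavor contact map of the native structure.
#' @param cs \code{contact_statistics}.
#' @param sp \code{stability_parameters}.
#' @param variance Variance path for the REM (see [misfold_free_energy()]).
#' @return Object of class \code{stability_result} with \code{g_nat},
#'   \code{g_unf}, \code{g_misf}, \code{delta_g}, \code{frozen}.
#' @export
delta_g <- function(seq, cm, cs, sp, variance = c("moments", "empirical")) {
  variance <- match.arg(variance)
  L <- length(seq)
  g_nat <- native_energy(seq, cm, sp$U)
  g_unf <- -L * sp$S_U
  if (!sp$use_misfold) {
    return(structure(list(g_nat = g_nat, g_unf = g_unf, g_misf = Inf,
                          delta_g = g_nat - g_unf, frozen = FALSE),
                     class = "stability_result"))
  }
  mf <- misfold_free_energy(seq, cs, sp$U, sp$S_C, variance)
  g_nonnat <- -.logsumexp2(-mf$g_misf, -g_unf)
  structure(list(g_nat = g_nat, g_unf = g_unf, g_misf = mf$g_misf,
                 delta_g = g_nat - g_nonnat, frozen = mf$frozen),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: G_nat %.3f, G_unf %.3f, G_misf %.3f, DG %.3f%s\n",
              x$g_nat, x$g_unf, x$g_misf, x$delta_g,
              if (x$frozen) " (REM frozen)" else ""))
  invisible(x)
}

#' Precomputed terms for fast mutational Delta Delta G
#'
#' Caches the wild-type sums so that [delta_delta_g()] only touches the terms
#' involving the mutated site: native contact sums, the misfold mean, the
#' three variance pieces and (for the empirical path) the per-decoy energies.
#'
#' @inheritParams delta_g
#' @return Object of class \code{stability_cache}.
#' @export
stability_cache <- function(seq, cm, cs, sp, variance = c("moments", "empirical")) {
  variance <- match.arg(variance)
  L <- length(seq)
  st <- .stats_for_length(cs, L)
  C <- if (inherits(cm, "contact_map")) cm$C else cm
  Um <- sp$U[seq, seq]
  diag(Um) <- 0
  wt <- delta_g(seq, cm, cs, sp, variance)
  structure(list(seq = seq, C = C, st = st, sp = sp, Um = Um,
                 variance = variance, wt = wt, L = L),
            class = "stability_cache")
}

#' Change in folding free energy upon point mutation
#'
#' Delta Delta G = Delta G(mutant) - Delta G(wild type), computed by
#' updating only the cached sums that involve the mutated site (native row,
#' misfold mean/variance rows, decoy-energy increments), then recombining
#' the free-energy channels. Agrees with a full recomputation to numerical
#' precision.
#'
#' @param cache A \code{stability_cache} of the wild type.
#' @param i Mutated site.
#' @param a Mutant amino acid.
#' @return Scalar Delta Delta G (k_BT units).
#' @export
delta_delta_g <- function(cache, i, a) {
  seq <- cache$seq
  if (a == seq[i]) return(0)
  sp <- cache$sp
  L <- cache$L
  dU <- sp$U[a, seq] - sp$U[seq[i], seq]
  dU[i] <- 0
  g_nat_mut <- cache$wt$g_nat + sum(cache$C[i, ] * dU)
  g_unf <- -L * sp$S_U
  if (!sp$use_misfold) {
    dg_mut <- g_nat_mut - g_unf
    return(dg_mut - cache$wt$delta_g)
  }
  st <- cache$st
  P <- st$P
  Um2 <- cache$Um
  Um2[i, ] <- Um2[i, ] + dU
  Um2[, i] <- Um2[, i] + dU
  Um2[i, i] <- 0
  if (cache$variance == "empirical") {
    mo <- .misfold_moments(st, Um2, "empirical")
  } else {
    mo <- .misfold_moments(st, Um2, "moments")
  }
  meanE <- mo$mean
  varE <- mo$var
  S_C <- sp$S_C
  g_misf <- if (varE <= 2 * L * S_C) meanE - varE / 2 - L * S_C
            else meanE - sqrt(2 * L * S_C * varE)
  g_nonnat <- -.logsumexp2(-g_misf, -g_unf)
  (g_nat_mut - g_nonnat) - cache$wt$delta_g
}
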