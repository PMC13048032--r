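# Site-specific exchangeability matrices and rate matrices.
#
# Q_i(a,b) = E_i(a,b) P_i(b). The exchangeability options are
#   * HB / noHB: multiply a global exchangeability by the Halpern-Bruno
#     fixation factor of the site's fitness differences, or not;
#   * FL / noFL: rescale the global exchangeability so the site-averaged
#     flux of every amino-acid pair matches the empirical model's flux, or
#     use the empirical exchangeability directly;
#   * rate0 / rate1: normalize the per-site substitution rate to one, or
#     keep a per-site scale factor restoring the model-predicted rate.

.paml_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load an empirical amino-acid substitution model
#'
#' Builtin models ("JTT", "LG", "WAG") are taken from phangorn's model data
#' at run time; alternatively a PAML-dialect .dat file (190 lower-triangle
#' exchangeabilities in row-major order followed by 20 frequencies, amino
#' acids in PAML order) is parsed.
#'
#' @param model Builtin name or path to a .dat file.
#' @return Object of class \code{empirical_model}: list with \code{name},
#'   \code{E} (20x20 symmetric, alphabet order), \code{P} (frequencies,
#'   sum 1).
#' @export
load_empirical <- function(model = c("WAG", "LG", "JTT")) {
  aa <- aa_alphabet()
  if (file.exists(model[1])) {
    nums <- scan(model[1], what = numeric(), quiet = TRUE,
                 comment.char = "#")
    if (length(nums) < 210)
      stop("PAML .dat file must contain 190 exchangeabilities + 20 frequencies")
    E <- matrix(0, 20, 20, dimnames = list(.paml_order, .paml_order))
    k <- 1
    for (i in 2:20) for (j in 1:(i - 1)) {
      E[i, j] <- nums[k]; k <- k + 1
    }
    E <- E + t(E)
    P <- nums[191:210]
    names(P) <- .paml_order
    name <- basename(model[1])
  } else {
    name <- match.arg(model)
    tmp <- get(paste0(".", name), environment(phangorn::pml))
    bf <- tmp$bf
    ord <- toupper(names(bf))
    E <- matrix(0, 20, 20, dimnames = list(ord, ord))
    E[lower.tri(E)] <- tmp$Q           # phangorn stores column-major
    E <- E + t(E)
    P <- bf
    names(P) <- ord
  }
  E <- E[aa, aa]
  P <- P[aa] / sum(P[aa])
  if (max(abs(E - t(E))) > 1e-10) stop("asymmetric exchangeability matrix")
  if (any(E < 0) || any(P < 0)) stop("negative entries in empirical model")
  structure(list(name = name, E = E, P = P), class = "empirical_model")
}

#' Write an empirical model as a PAML-dialect .dat file
#'
#' @param em An \code{empirical_model}.
#' @param path Output file.
#' @export
write_empirical <- function(em, path) {
  E <- em$E[.paml_order, .paml_order]
  P <- em$P[.paml_order]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 2:20)
    writeLines(paste(format(E[i, 1:(i - 1)], digits = 12), collapse = " "), con)
  writeLines("", con)
  writeLines(paste(format(P, digits = 12), collapse = " "), con)
  invisible(path)
}

# Halpern-Bruno fixation factor matrix for one site: given the combined
# log-fitness vector lphi (Lambda * phi) and normalizer Z, the symmetric
# factor  Z (lphi_b - lphi_a) / (e^{lphi_b} - e^{lphi_a}),
# with the analytic limit Z e^{-lphi_a} at lphi_a = lphi_b.
.hb_factor <- function(lphi, Z) {
  d <- outer(lphi, lphi, function(a, b) b - a)
  ea <- outer(lphi, lphi, function(a, b) a)
  r <- ifelse(abs(d) < 1e-9, 1 / (1 + d / 2), d / expm1(d))
  Z * exp(-ea) * r
}

#' Per-site Halpern-Bruno exchangeabilities
#'
#' E_i(a,b) = E_glob(a,b) * Lambda(phi_b - phi_a) /
#' [(1/Z_i)(e^{Lambda phi_b} - e^{Lambda phi_a})], with the equal-fitness
#' limit handled analytically.
#'
#' @param E_glob Global 20x20 exchangeability.
#' @param lphi L x 20 matrix of combined log-fitness (Lambda * phi summed
#'   over channels).
#' @param Z Per-site normalizers (as returned by
#'   [stationary_distribution()]).
#' @return List of per-site 20x20 symmetric matrices.
#' @export
hb_exchangeability <- function(E_glob, lphi, Z) {
  lapply(seq_len(nrow(lphi)), function(i) E_glob * .hb_factor(lphi[i, ], Z[i]))
}

#' Flux-matched global exchangeability
#'
#' Sets E_glob so that the model's site-averaged flux of every amino-acid
#' pair, mean_i P_i(a) P_i(b) E_i(a,b), equals the empirical flux
#' P_emp(a) P_emp(b) E_emp(a,b).
#'
#' @param emp An \code{empirical_model}.
#' @param lphi L x 20 combined log-fitness matrix.
#' @param Z Per-site normalizers.
#' @param p_glob Global frequencies of the profile model.
#' @param hb Logical: is the Halpern-Bruno factor part of E_i?
#' @return 20x20 symmetric E_glob.
#' @export
flux_match <- function(emp, lphi, Z, p_glob, hb = TRUE) {
  L <- nrow(lphi)
  D <- matrix(0, 20, 20)
  for (i in seq_len(L)) {
    eab <- outer(exp(lphi[i, ]), exp(lphi[i, ]))
    if (hb) {
      # site flux: p_a p_b e^{la+lb} hbfac / Z_i^2, hbfac carries one Z_i
      D <- D + eab * .hb_factor(lphi[i, ], Z[i]) / Z[i]^2
    } else {
      D <- D + eab / Z[i]^2
    }
  }
  D <- D / L
  if (any(D[upper.tri(D)] <= 0))
    stop("vanishing site-averaged flux denominator")
  num <- outer(emp$P, emp$P) * emp$E
  E_glob <- num / (D * outer(p_glob, p_glob))
  diag(E_glob) <- 0
  dimnames(E_glob) <- dimnames(emp$E)
  E_glob
}

#' Assemble site-specific substitution models
#'
#' Builds the per-site exchangeabilities and rate matrices for one of the
#' eight HB/noHB x FL/noFL x rate0/rate1 option combinations.
#'
#' @param P L x 20 stationary site distributions (floored).
#' @param lphi L x 20 combined log-fitness matrix (zeros for the GLOB
#'   model).
#' @param Z Per-site normalizers.
#' @param p_glob Global frequencies.
#' @param emp An \code{empirical_model}.
#' @param hb,fl,rate1 Logical option switches.
#' @return Object of class \code{site_models}: list with \code{E} (list of
#'   per-site normalized exchangeabilities), \code{Q} (per-site generators,
#'   rows sum to 0, rate 1), \code{scale} (per-site rate multipliers; all 1
#'   under rate0), \code{rate_pred} (the model-predicted rates), \code{P},
#'   \code{options}, \code{emp_name}.
#' @export
assemble_site_models <- function(P, lphi, Z, p_glob, emp,
                                 hb = TRUE, fl = TRUE, rate1 = TRUE) {
  L <- nrow(P)
  E_glob <- if (fl) flux_match(emp, lphi, Z, p_glob, hb = hb) else emp$E
  E_list <- if (hb) hb_exchangeability(E_glob, lphi, Z)
            else rep(list(E_glob), L)
  rate <- numeric(L)
  Qn <- vector("list", L)
  En <- vector("list", L)
  for (i in seq_len(L)) {
    Ei <- E_list[[i]]
    diag(Ei) <- 0
    M <- outer(P[i, ], P[i, ]) * Ei
    rate[i] <- sum(M)
    if (rate[i] <= 0) stop("zero substitution rate at site ", i)
    En[[i]] <- Ei / rate[i]
    Qi <- En[[i]] * rep(P[i, ], each = 20)
    diag(Qi) <- -rowSums(Qi)
    Qn[[i]] <- Qi
  }
  structure(list(E = En, Q = Qn,
                 scale = if (rate1) rate else rep(1, L),
                 rate_pred = rate, P = P,
                 options = c(hb = hb, fl = fl, rate1 = rate1),
                 emp_name = emp$name,
                 .cache = new.env(parent = emptyenv())),
            class = "site_models")
}

#' @export
print.site_models <- function(x, ...) {
  o <- x$options
  cat(sprintf("site_models: %d sites, %s%s%s, empirical %s\n",
              length(x$Q), if (o["hb"]) "HB" else "noHB",
              if (o["fl"]) "+FL" else "+noFL",
              if (o["rate1"]) "+rate1" else "+rate0", x$emp_name))
  invisible(x)
}

# symmetrized eigendecomposition of the site's effective generator
# (scale_i * Q_i), cached; reversibility wrt P_i makes the spectrum real.
.site_eigen <- function(models, i) {
  key <- as.character(i)
  cache <- models$.cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  Q <- models$Q[[i]] * models$scale[i]
  p <- models$P[i, ]
  sq <- sqrt(p)
  S <- Q * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  out <- list(values = ee$values,
              right = ee$vectors / sq,
              left = t(ee$vectors * sq))
  cache[[key]] <- out
  out
}

#' Transition probability matrix of one site model
#'
#' exp(t * scale_i * Q_i) via the symmetrized eigendecomposition.
#'
#' @param models A \code{site_models}.
#' @param i Site index.
#' @param t Branch length (expected substitutions at rate 1).
#' @return 20x20 stochastic matrix.
#' @export
site_transition_matrix <- function(models, i, t) {
  ed <- .site_eigen(models, i)
  Pt <- ed$right %*% (exp(t * ed$values) * ed$left)
  Pt[Pt < 0] <- 0
  Pt / rowSums(Pt)
}

#' Aligned pair counts of an MSA
#'
#' Counts substitutions between a reference sequence and every other
#' sequence, per site and pooled. Pairs involving a gap are skipped.
#'
#' @param msa Character MSA matrix.
#' @param ref Reference row name or index (default: first row).
#' @return Object of class \code{pair_counts}: list with \code{pooled}
#'   (20x20), \code{per_site} (20 x 20 x L), \code{N_a} (occurrences in the
#'   counted pairs), \code{per_site_N}.
#' @export
pair_counts <- function(msa, ref = 1) {
  aa <- aa_alphabet()
  if (is.character(ref)) ref <- match(ref, rownames(msa))
  L <- ncol(msa)
  per <- array(0, c(20, 20, L), dimnames = list(aa, aa, NULL))
  for (s in setdiff(seq_len(nrow(msa)), ref)) {
    x <- msa[ref, ]; y <- msa[s, ]
    ok <- x %in% aa & y %in% aa
    if (!any(ok)) next
    ix <- match(x[ok], aa); iy <- match(y[ok], aa); iw <- which(ok)
    for (k in seq_along(iw))
      per[ix[k], iy[k], iw[k]] <- per[ix[k], iy[k], iw[k]] + 1
  }
  # symmetrize (unordered pairs); N(a) = row sums (one root state per pair)
  for (i in seq_len(L)) per[, , i] <- (per[, , i] + t(per[, , i])) / 2
  pooled <- apply(per, c(1, 2), sum)
  structure(list(pooled = pooled, per_site = per, L = L),
            class = "pair_counts")
}

#' Approximate pair likelihood without a tree
#'
#' Short-branch approximation of the likelihood of aligned pair counts under
#' exchangeability E and frequencies P, evaluated at the closed-form optimal
#' divergence time
#' t_opt = sum_a (N(a) - N(a,a)) / (-sum_a N(a,a) P(a) E(a,a)), with
#' E(a,a) = -sum_{b != a} E(a,b) P(b).
#'
#' @param N 20x20 symmetric pair-count matrix.
#' @param E 20x20 exchangeability.
#' @param P Frequency 20-vector.
#' @return List with \code{loglik} and \code{t_opt}.
#' @export
approx_loglik <- function(N, E, P) {
  if (sum(N) == 0) stop("empty pair counts")
  Na <- rowSums(N)             # one root state per aligned pair
  off <- N
  diag(off) <- 0
  Noff <- sum(off)
  E0 <- E
  diag(E0) <- 0
  Eaa <- -drop(E0 %*% P)       # E(a,a) = -sum_{b != a} E(a,b) P(b)
  base <- sum(Na[Na > 0] * log(P[Na > 0]))
  if (Noff == 0) return(list(loglik = base, t_opt = 0))
  denom <- sum(diag(N) * P * Eaa)
  if (denom > 0) stop("non-negative diagonal rate; degenerate counts")
  # no identical pairs: the short-branch optimum diverges; cap the
  # divergence time at t = 5 (a saturated pair) instead of failing
  t_opt <- if (denom == 0) 5 else -Noff / denom
  ll <- sum(off[off > 0] * log(E0[off > 0])) + base +
    log(t_opt) * Noff + t_opt * denom
  list(loglik = ll, t_opt = t_opt)
}

#' Approximate likelihood of site-specific models
#'
#' Sums [approx_loglik()] over sites with each site's exchangeability
#' (including the rate1 scale) and stationary distribution.
#'
#' @param counts A \code{pair_counts}.
#' @param models A \code{site_models}.
#' @return Total approximate log-likelihood.
#' @export
site_approx_loglik <- function(counts, models) {
  L <- counts$L
  tot <- 0
  for (i in seq_len(L)) {
    N <- counts$per_site[, , i]
    if (sum(N) == 0) next
    Ei <- models$E[[i]] * models$scale[i]
    tot <- tot + approx_loglik(N, Ei, models$P[i, ])$loglik
  }
  tot
}

#' Rank candidate models by approximate likelihood
#'
#' @param counts A \code{pair_counts} (pooled counts are used).
#' @param candidates Named list of \code{empirical_model}s (default the
#'   three builtins in the fixed tie-break order JTT, LG, WAG).
#' @return Data frame ranked by decreasing log-likelihood; ties keep the
#'   fixed order.
#' @export
select_best <- function(counts, candidates = NULL) {
  if (is.null(candidates)) {
    nm <- c("JTT", "LG", "WAG")
    candidates <- lapply(nm, load_empirical)
    names(candidates) <- nm
  }
  ll <- vapply(candidates, function(m)
    approx_loglik(counts$pooled, m$E, m$P)$loglik, 0)
  ord <- order(-ll)  # stable: ties keep input order
  data.frame(model = names(candidates)[ord], loglik = ll[ord],
             row.names = NULL)
}
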