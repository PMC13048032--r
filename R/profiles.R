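# Site-specific stationary amino-acid distributions.
#
# Every model is of the Boltzmann form
#   P_i(a) = P_glob(a) exp( sum_m Lambda_m phi_m,i(a) ) / Z_i
# with site-independence across sites. Fitness matrices phi come from the
# stability channel (mean-field or wild-type Delta Delta G) and/or from the
# structural channel (predicted RMSD or harmonic energy DE of mutations).
# Global frequencies are fitted so the model's summed frequencies match the
# MSA; the selection parameters Lambda are fitted by minimizing the symmetric
# KL divergence to the MSA site frequencies with a ridge penalty R Lambda^2,
# R chosen by the maximum specific-heat criterion C_V = dKL/dR.

# floor-and-renormalize a frequency vector: floored entries sit exactly at
# eps, the rest are scaled to keep the sum at 1
.floor_renorm <- function(p, eps) {
  for (it in 1:25) {
    low <- p <= eps + 1e-15
    if (all(low)) return(rep(1 / length(p), length(p)))
    target <- 1 - eps * sum(low)
    p[low] <- eps
    p[!low] <- p[!low] * target / sum(p[!low])
    if (all(p >= eps - 1e-15)) break
  }
  p
}

#' Observed site frequencies of an MSA
#'
#' Per-column amino-acid frequencies with gaps excluded from the counts,
#' floored at \code{eps} and renormalized.
#'
#' @param msa Character MSA matrix (sequences x columns).
#' @param eps Frequency floor (default 0.001).
#' @return Object of class \code{msa_profile}: list with \code{f} (L x 20),
#'   \code{n_seq}, \code{eps}.
#' @export
msa_profile <- function(msa, eps = 0.001) {
  aa <- aa_alphabet()
  L <- ncol(msa)
  f <- matrix(0, L, 20, dimnames = list(NULL, aa))
  for (i in seq_len(L)) {
    x <- msa[, i]
    x <- x[x %in% aa]
    if (length(x) == 0) {
      f[i, ] <- 1 / 20
    } else {
      tb <- table(factor(x, levels = aa))
      f[i, ] <- .floor_renorm(as.vector(tb) / length(x), eps)
    }
  }
  structure(list(f = f, n_seq = nrow(msa), eps = eps), class = "msa_profile")
}

#' Stationary site distributions from fitness matrices
#'
#' @param phi List of L x 20 fitness matrices (possibly length 1).
#' @param lambda Numeric vector of selection parameters, one per matrix.
#' @param p_glob Global frequencies (20-vector summing to 1).
#' @param eps Frequency floor; frequencies are floored then renormalized
#'   (floored entries sit exactly at eps).
#' @return List with \code{P} (L x 20, rows sum to 1, min >= eps), \code{Z}
#'   (pre-floor normalizers), \code{P_raw} (pre-floor distribution).
#' @export
stationary_distribution <- function(phi, lambda, p_glob, eps = 0.001) {
  if (is.matrix(phi)) phi <- list(phi)
  stopifnot(length(phi) == length(lambda))
  L <- nrow(phi[[1]])
  S <- matrix(0, L, 20)
  for (m in seq_along(phi)) S <- S + lambda[m] * phi[[m]]
  shift <- apply(S, 1, max)
  W <- exp(S - shift) * rep(p_glob, each = L)
  Z <- rowSums(W)
  P_raw <- W / Z
  # unshifted normalizer (enters the Halpern-Bruno fixation factors)
  Zi <- Z * exp(shift)
  P <- t(apply(P_raw, 1, .floor_renorm, eps = eps))
  colnames(P) <- colnames(P_raw) <- aa_alphabet()
  list(P = P, Z = Zi, P_raw = P_raw)
}

#' Fit global frequencies to an MSA
#'
#' Iterates the self-consistency p_glob(a) * sum_i exp(Lambda phi_i(a))/Z_i =
#' sum_i f_i(a) (the +F analogue): the model's frequency of each amino acid
#' summed over sites matches the MSA.
#'
#' @param phi List of fitness matrices.
#' @param lambda Selection parameters.
#' @param f L x 20 observed site frequencies (floored).
#' @param tol Per-amino-acid tolerance on the site-averaged residual.
#' @param max_iter Iteration cap.
#' @return List with \code{p_glob}, \code{converged}, \code{residual}.
#' @export
fit_global_frequencies <- function(phi, lambda, f, tol = 1e-8,
                                   max_iter = 1000) {
  if (is.matrix(phi)) phi <- list(phi)
  L <- nrow(f)
  Fa <- colSums(f)
  S <- matrix(0, L, 20)
  for (m in seq_along(phi)) S <- S + lambda[m] * phi[[m]]
  S <- S - apply(S, 1, max)   # per-site shift cancels in P_i
  E <- exp(S)
  p <- Fa / sum(Fa)
  for (it in seq_len(max_iter)) {
    Z <- drop(E %*% p)
    Sa <- colSums(E / Z)       # sum_i exp(L phi_i(a)) / Z_i
    resid <- max(abs(p * Sa - Fa)) / L
    if (resid < tol) return(list(p_glob = p, converged = TRUE, residual = resid))
    p_new <- Fa / Sa
    p_new <- p_new / sum(p_new)
    p <- 0.5 * p + 0.5 * p_new
  }
  list(p_glob = p, converged = FALSE, residual = resid)
}

# symmetric KL divergence between model and MSA, averaged over sites
.kl_symm <- function(P, f) {
  mean(rowSums(f * log(f / P) + P * log(P / f)))
}

# mean log-likelihood of the observed site frequencies under the model
.ll_score <- function(P, f) mean(rowSums(f * log(P)))

# evaluate the fitting criterion at given lambda: refit p_glob, build the
# floored distribution, return list(score, kl, ll, p_glob, P).
# Fitness entries that are functions of lambda (the structural channel's
# wild-type entries) are resolved first.
.profile_objective <- function(phi, lambda, f, eps, criterion = "KL", R = 0) {
  phi <- .resolve_phi(phi, lambda)
  gf <- fit_global_frequencies(phi, lambda, f)
  sd <- stationary_distribution(phi, lambda, gf$p_glob, eps)
  kl <- .kl_symm(sd$P, f)
  ll <- .ll_score(sd$P, f)
  base <- if (criterion == "KL") kl else -ll
  list(score = base + R * sum(lambda^2), kl = kl, ll = ll,
       p_glob = gf$p_glob, P = sd$P, Z = sd$Z)
}

#' Fit the selection parameter(s) of a profile model
#'
#' One-dimensional models: coarse grid on [0, lambda_max] followed by
#' quadratic (Brent) refinement of the penalized criterion, with the global
#' frequencies refitted at every evaluation. Two-parameter models: coarse
#' 2-D grid then cyclic coordinate-wise refinement.
#'
#' @param phi List of fitness matrices (length 1 or 2).
#' @param msa An \code{msa_profile} (or bare L x 20 frequency matrix).
#' @param criterion "KL" (symmetric KL, default) or "LL".
#' @param R Ridge (Tykhonov) regularization weight on Lambda^2.
#' @param lambda_max Upper bound of the search.
#' @param n_grid Coarse grid size per dimension.
#' @param eps Frequency floor.
#' @return List with \code{lambda}, \code{score}, \code{kl}, \code{ll},
#'   \code{p_glob}, \code{P}.
#' @export
fit_lambda <- function(phi, msa, criterion = c("KL", "LL"), R = 0,
                       lambda_max = 10, n_grid = 9, eps = 0.001) {
  criterion <- match.arg(criterion)
  if (is.matrix(phi)) phi <- list(phi)
  f <- if (inherits(msa, "msa_profile")) msa$f else msa
  obj1 <- function(l, lam_other = NULL, pos = 1) {
    lam <- if (is.null(lam_other)) l else {
      v <- lam_other; v[pos] <- l; v
    }
    .profile_objective(phi, lam, f, eps, criterion, R)$score
  }
  if (length(phi) == 1) {
    grid <- seq(0, lambda_max, length.out = n_grid)
    sc <- vapply(grid, obj1, 0)
    k <- which.min(sc)
    lo <- grid[max(k - 1, 1)]; hi <- grid[min(k + 1, n_grid)]
    opt <- stats::optimize(obj1, c(lo, hi), tol = 1e-5)
    cand <- if (opt$objective < sc[k]) opt$minimum else grid[k]
    lam <- cand
  } else {
    g <- seq(0, lambda_max, length.out = max(5, n_grid %/% 2 + 2))
    sc <- outer(g, g, Vectorize(function(a, b) obj1(c(a, b))))
    k <- arrayInd(which.min(sc), dim(sc))
    lam <- c(g[k[1]], g[k[2]])
    for (cyc in 1:3) {
      for (pos in 1:2) {
        lo <- max(0, lam[pos] - diff(range(g)) / (length(g) - 1))
        hi <- min(lambda_max, lam[pos] + diff(range(g)) / (length(g) - 1))
        opt <- stats::optimize(function(l) obj1(l, lam, pos), c(lo, hi),
                               tol = 1e-4)
        if (opt$objective <= obj1(lam[pos], lam, pos)) lam[pos] <- opt$minimum
      }
    }
  }
  out <- .profile_objective(phi, lam, f, eps, criterion, R)
  c(list(lambda = lam), out)
}

#' Regularization path with the specific-heat criterion
#'
#' Samples a log-spaced grid of ridge weights R, fits Lambda at each,
#' computes the specific heat C_V = dKL/dR by central finite differences and
#' selects the R with maximal C_V, refined by quadratic interpolation in
#' log R; Lambda is then refit at the chosen R.
#'
#' @inheritParams fit_lambda
#' @param R_grid Ridge grid (log-spaced by default).
#' @return Object of class \code{regularization_path}: list with
#'   \code{R_grid}, \code{lambda_at_R}, \code{kl_at_R}, \code{cv_at_R},
#'   \code{chosen_R}, \code{chosen_lambda}, \code{fit} (the refit at
#'   chosen_R).
#' @export
regularization_path <- function(phi, msa, criterion = c("KL", "LL"),
                                R_grid = 10^seq(-3, 0.8, length.out = 8),
                                lambda_max = 10, eps = 0.001) {
  criterion <- match.arg(criterion)
  if (is.matrix(phi)) phi <- list(phi)
  fits <- lapply(R_grid, function(R)
    fit_lambda(phi, msa, criterion, R = R, lambda_max = lambda_max, eps = eps))
  kl <- vapply(fits, function(x) x$kl, 0)
  lam <- t(vapply(fits, function(x) as.numeric(x$lambda),
                  numeric(length(fits[[1]]$lambda))))
  n <- length(R_grid)
  cv <- rep(NA_real_, n)
  for (k in 2:(n - 1))
    cv[k] <- (kl[k + 1] - kl[k - 1]) / (R_grid[k + 1] - R_grid[k - 1])
  cv[1] <- (kl[2] - kl[1]) / (R_grid[2] - R_grid[1])
  cv[n] <- (kl[n] - kl[n - 1]) / (R_grid[n] - R_grid[n - 1])
  k <- which.max(cv)
  boundary <- k == 1 || k == n
  if (boundary)
    warning("specific heat maximal at the boundary of the R grid")
  chosen_R <- R_grid[k]
  if (!boundary) {
    # quadratic refinement in log R through the three points around the max
    x <- log(R_grid[(k - 1):(k + 1)])
    y <- cv[(k - 1):(k + 1)]
    den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
    B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / den
    if (A < 0) {
      xs <- -B / (2 * A)
      if (xs > x[1] && xs < x[3]) chosen_R <- exp(xs)
    }
  }
  fit <- fit_lambda(phi, msa, criterion, R = chosen_R,
                    lambda_max = lambda_max, eps = eps)
  structure(list(R_grid = R_grid, lambda_at_R = lam, kl_at_R = kl,
                 cv_at_R = cv, chosen_R = chosen_R,
                 chosen_lambda = fit$lambda, fit = fit),
            class = "regularization_path")
}

#' @export
print.regularization_path <- function(x, ...) {
  cat(sprintf("regularization_path: chosen R = %.4g, Lambda = %s\n",
              x$chosen_R, paste(signif(x$chosen_lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Mean-field stability fitness
#'
#' Self-consistent stability fitness: phi_i(a) = -<Delta G | A_i = a> under
#' the product distribution of the other sites. The native channel uses the
#' exponential (Boltzmann) average per contact; the misfold mean is updated
#' per (site, amino acid) while the misfold variance and REM freezing are
#' evaluated once per sweep at the average composition. The computation runs
#' at Lambda = 1 and the selection parameter is fitted afterwards.
#'
#' @param seq Wild-type sequence (starting composition).
#' @param cm Stability-flavor contact map.
#' @param cs \code{contact_statistics}.
#' @param sp \code{stability_parameters}.
#' @param p_glob Global frequencies used inside the self-consistency.
#' @param lambda Selection parameter of the internal computation (default 1).
#' @param tol Convergence tolerance on max frequency change.
#' @param max_iter Sweep cap.
#' @param damping Mixing factor for the frequency update.
#' @return List with \code{phi} (L x 20, zero-centred at the wild type),
#'   \code{P}, \code{iterations}, \code{converged}.
#' @export
mf_fitness <- function(seq, cm, cs, sp, p_glob = rep(1 / 20, 20),
                       lambda = 1, tol = 1e-6, max_iter = 500,
                       damping = 0.5) {
  aa <- aa_alphabet()
  L <- length(seq)
  C <- if (inherits(cm, "contact_map")) cm$C else cm
  U <- sp$U
  st <- if (sp$use_misfold) .stats_for_length(cs, L) else NULL
  g_unf <- -L * sp$S_U
  # start from the wild-type point distribution softened towards p_glob
  P <- matrix(rep(p_glob, each = L), L, 20, dimnames = list(NULL, aa))
  wtidx <- cbind(seq_len(L), match(seq, aa))
  P <- P * 0.5
  P[wtidx] <- P[wtidx] + 0.5
  Mexp <- exp(-lambda * U)
  phi <- matrix(0, L, 20, dimnames = list(NULL, aa))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # exponential-average contact energies: u_exp[a, k]
    W <- Mexp %*% t(P)                    # 20 x L
    u_exp <- -log(pmax(W, 1e-300)) / lambda
    Enat <- u_exp %*% C                   # 20 x L: E_nat(a, i) = sum_k C_ik u_exp[a,k]
    if (sp$use_misfold) {
      Ulin <- U %*% t(P)                  # 20 x L: <U(a, A_k)>_{P_k}
      Upair <- t(P %*% U) %*% t(P)        # L x L effective pair energies
      Upair <- (Upair + t(Upair)) / 2
      diag(Upair) <- 0
      mo <- .misfold_moments(st, Upair, "moments")
      rowP <- st$P
      common <- mo$mean
      rowTerm <- rowSums(rowP * Upair)    # sum_j P_ij Upair[i,j] per i
      S_C <- sp$S_C
      varE <- mo$var
      for (i in seq_len(L)) {
        meanE_ia <- common - rowTerm[i] + drop(Ulin %*% rowP[i, ])
        g_misf <- if (varE <= 2 * L * S_C) meanE_ia - varE / 2 - L * S_C
                  else meanE_ia - sqrt(2 * L * S_C * varE)
        g_nonnat <- -vapply(g_misf, function(g) .logsumexp2(-g, -g_unf), 0)
        phi[i, ] <- -(Enat[, i] - g_nonnat)
      }
    } else {
      phi <- -t(Enat) + g_unf   # -Delta G with the unfolded channel only
    }
    sdist <- stationary_distribution(phi, lambda, p_glob, eps = 0)
    P_new <- (1 - damping) * sdist$P_raw + damping * P
    delta <- max(abs(P_new - P))
    P <- P_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("mean-field iteration did not converge: residual ", signif(delta, 3))
  # centre phi at the wild type (only differences within a site matter)
  phi <- phi - phi[wtidx]
  list(phi = phi, P = P, iterations = it, converged = converged)
}

#' Wild-type stability fitness
#'
#' phi_i(a) = -Delta Delta G of the point mutation wild-type -> a; zero at
#' the wild-type amino acid.
#'
#' @inheritParams mf_fitness
#' @param variance Variance path for the REM.
#' @return L x 20 fitness matrix.
#' @export
wt_fitness <- function(seq, cm, cs, sp, variance = c("moments", "empirical")) {
  variance <- match.arg(variance)
  aa <- aa_alphabet()
  cache <- stability_cache(seq, cm, cs, sp, variance)
  phi <- matrix(0, length(seq), 20, dimnames = list(NULL, aa))
  for (i in seq_along(seq))
    for (a in aa)
      phi[i, a] <- -delta_delta_g(cache, i, a)
  phi
}

#' Structural fitness from a mutation effect table
#'
#' phi = -RMSD or -DE, with the wild-type entries already filled by the
#' stationary-weighted average in [build_effect_table()].
#'
#' @param effects A \code{mutation_effect_table}.
#' @param kind "RMSD" or "DE".
#' @return L x 20 fitness matrix.
#' @export
str_fitness <- function(effects, kind = c("RMSD", "DE")) {
  kind <- match.arg(kind)
  -(if (kind == "RMSD") effects$rmsd else effects$de)
}

#' Site entropy and substitution rate
#'
#' S_i = -sum_a P_i(a) log P_i(a); R_i = sum_{a != b} P_i(a) P_i(b) E_i(a,b).
#'
#' @param P L x 20 stationary distributions.
#' @param E Either one 20x20 exchangeability matrix (used at all sites) or a
#'   list of per-site matrices.
#' @return List with \code{S} and \code{R} (L-vectors).
#' @export
entropy_and_rate <- function(P, E) {
  L <- nrow(P)
  S <- -rowSums(P * log(P))
  R <- numeric(L)
  for (i in seq_len(L)) {
    Ei <- if (is.list(E)) E[[i]] else E
    M <- outer(P[i, ], P[i, ]) * Ei
    R[i] <- sum(M) - sum(diag(M))
  }
  list(S = S, R = R)
}
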