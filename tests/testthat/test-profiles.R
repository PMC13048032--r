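test_that("stationary distributions are normalized, floored and reduce to GLOB", {
  phi <- toy_phi(30, seed = 3)
  set.seed(4)
  pg <- runif(20); pg <- pg / sum(pg)
  sd1 <- stationary_distribution(phi, 0.8, pg)
  expect_lt(max(abs(rowSums(sd1$P) - 1)), 1e-10)
  expect_gte(min(sd1$P), 0.001)
  # both selection parameters at zero: every site equals p_glob
  sd0 <- stationary_distribution(list(phi, toy_phi(30, 5)), c(0, 0), pg)
  expect_lt(max(abs(sweep(sd0$P_raw, 2, pg))), 1e-12)
  # an impossibly unfit amino acid sits exactly at the floor
  phiX <- phi; phiX[3, 5] <- -1000
  expect_equal(unname(stationary_distribution(phiX, 1, pg)$P[3, 5]), 0.001)
  # Z matches the direct normalizer
  Zref <- rowSums(exp(0.8 * phi) * rep(pg, each = 30))
  expect_equal(sd1$Z, Zref, tolerance = 1e-12)
})

test_that("global frequencies satisfy the matching condition", {
  phi <- toy_phi(25, seed = 6)
  set.seed(7)
  f <- matrix(rgamma(25 * 20, 1), 25, 20); f <- f / rowSums(f)
  # lambda = 0: column means
  g0 <- fit_global_frequencies(phi, 0, f)
  expect_equal(g0$p_glob, colSums(f) / sum(f), tolerance = 1e-10,
               ignore_attr = TRUE)
  # fixed point satisfies the residual by direct substitution
  g1 <- fit_global_frequencies(phi, 0.7, f)
  expect_true(g1$converged)
  E <- exp(0.7 * phi)
  Z <- drop(E %*% g1$p_glob)
  expect_lt(max(abs(g1$p_glob * colSums(E / Z) - colSums(f))) / 25, 1e-8)
  # permuting sites leaves p_glob unchanged
  perm <- sample(25)
  g2 <- fit_global_frequencies(phi[perm, ], 0.7, f[perm, ])
  expect_equal(g2$p_glob, g1$p_glob, tolerance = 1e-10)
})

test_that("the selection parameter is recovered from model-sampled columns", {
  phi <- toy_phi(30, seed = 3)
  set.seed(4)
  pg <- runif(20); pg <- pg / sum(pg)
  P <- stationary_distribution(phi, 0.5, pg)$P
  msa <- sample_msa(P, n_seq = 500, seed = 7)
  fit <- fit_lambda(phi, msa_profile(msa), "KL", R = 0, lambda_max = 3)
  expect_lt(abs(fit$lambda - 0.5), 0.1)
  # huge ridge drives lambda to zero
  fitR <- fit_lambda(phi, msa_profile(msa), "KL", R = 1e6, lambda_max = 3)
  expect_lt(fitR$lambda, 1e-3)
  # MSA identical to p_glob: no selection
  fg <- matrix(rep(pg, each = 30), 30, 20)
  expect_lt(fit_lambda(phi, fg, "KL", R = 0, lambda_max = 3)$lambda, 1e-3)
})

test_that("selection can only improve the fitted criterion at R = 0", {
  phi <- toy_phi(20, seed = 9)
  set.seed(10)
  P <- stationary_distribution(phi, 0.8, rep(1 / 20, 20))$P
  mp <- msa_profile(sample_msa(P, n_seq = 150, seed = 11))
  fit <- fit_lambda(phi, mp, "KL", R = 0, lambda_max = 5)
  pg0 <- colSums(mp$f) / sum(mp$f)
  P0 <- t(apply(matrix(rep(pg0, each = 20), 20, 20), 1,
                sscpe:::.floor_renorm, eps = 0.001))
  expect_lte(fit$kl, sscpe:::.kl_symm(P0, mp$f) + 1e-10)
})

test_that("the specific-heat criterion picks a stable interior ridge", {
  phi <- toy_phi(25, seed = 13)
  set.seed(14)
  P <- stationary_distribution(phi, 0.6, rep(1 / 20, 20))$P
  mp <- msa_profile(sample_msa(P, n_seq = 200, seed = 15))
  rp <- regularization_path(phi, mp, lambda_max = 3,
                            R_grid = 10^seq(-3, 0.8, length.out = 8))
  expect_true(all(rp$cv_at_R > -1e-10, na.rm = TRUE))
  expect_true(all(diff(rp$kl_at_R) > -1e-8))
  # refining the grid moves the chosen R by at most one coarse step
  rp2 <- regularization_path(phi, mp, lambda_max = 3,
                             R_grid = 10^seq(-3, 0.8, length.out = 15))
  step <- diff(log10(rp$R_grid))[1]
  expect_lt(abs(log10(rp2$chosen_R) - log10(rp$chosen_R)), 2 * step + 1e-9)
})

test_that("mean-field fitness satisfies the self-consistency on a two-site toy", {
  # two sites, one contact, no misfold channel: the fixed point must satisfy
  # e^{phi_1(a)} = sum_b P_2(b) e^{-U(a,b)} up to a per-site constant
  sp <- stability_parameters(use_misfold = FALSE)
  C <- matrix(0, 2, 2); C[1, 2] <- C[2, 1] <- 1
  seq2 <- c("A", "L")
  mf <- mf_fitness(seq2, C, fx_bundle$cs, sp, lambda = 1)
  expect_true(mf$converged)
  M <- exp(-sp$U)
  for (i in 1:2) {
    target <- log(drop(M %*% mf$P[3 - i, ]))
    resid <- (mf$phi[i, ] - target) - mean(mf$phi[i, ] - target)
    expect_lt(max(abs(resid)), 1e-4)
  }
  # re-running from the converged state changes nothing
  mf2 <- mf_fitness(seq2, C, fx_bundle$cs, sp, lambda = 1)
  expect_equal(mf2$phi, mf$phi, tolerance = 1e-8)
})

test_that("an isolated site under the mean field keeps the global distribution", {
  sp <- stability_parameters(use_misfold = FALSE)
  C <- matrix(0, 3, 3)   # no contacts at all
  mf <- mf_fitness(c("A", "L", "G"), C, fx_bundle$cs, sp, lambda = 1)
  expect_lt(max(abs(sweep(mf$P, 2, 1 / 20))), 1e-5)
})

test_that("wild-type fitness equals minus Delta Delta G", {
  s <- fx_bundle$s
  phi <- wt_fitness(s$seq, fx_bundle$cms, fx_bundle$cs, fx_bundle$sp)
  wtidx <- cbind(seq_len(s$n), match(s$seq, aa_alphabet()))
  expect_true(all(phi[wtidx] == 0))
  ca <- stability_cache(s$seq, fx_bundle$cms, fx_bundle$cs, fx_bundle$sp)
  set.seed(3)
  for (k in 1:5) {
    i <- sample(s$n, 1); a <- sample(aa_alphabet(), 1)
    expect_equal(unname(phi[i, a]), -delta_delta_g(ca, i, a), tolerance = 1e-12)
  }
  # destabilizing mutations have negative fitness
  expect_lt(min(phi), 0)
})

test_that("structural fitness is minus the deformation with monotone frequencies", {
  s <- fx_helix$s
  et <- build_effect_table(s, fx_helix$cm, fx_helix$tnm, mutation_parameters())
  phiR <- str_fitness(et, "RMSD")
  expect_equal(phiR, -et$rmsd)
  expect_equal(str_fitness(et, "DE"), -et$de)
  # larger deformation => smaller stationary frequency at Lambda > 0
  P <- stationary_distribution(phiR, 1, rep(1 / 20, 20))$P_raw
  i <- which.max(contact_counts(fx_helix$cm))
  ord <- order(et$rmsd[i, ])
  expect_true(all(diff(P[i, ord]) <= 1e-12))
})

test_that("entropy and rate identities hold", {
  L <- 6
  P <- matrix(1 / 20, L, 20)
  E1 <- matrix(1, 20, 20); diag(E1) <- 0
  er <- entropy_and_rate(P, E1)
  expect_equal(er$S, rep(log(20), L))
  expect_equal(er$R, 1 - rowSums(P^2), tolerance = 1e-12)
  # near-delta distribution: entropy below 0.05
  Pd <- matrix(0.001, 1, 20); Pd[1] <- 1 - 0.019
  er2 <- entropy_and_rate(Pd, E1)
  expect_lt(er2$S, 0.16)
  expect_equal(er2$R[1], 1 - sum(Pd^2), tolerance = 1e-12)
})
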