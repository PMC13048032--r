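test_that("builtin empirical models load validated and round-trip as PAML files", {
  for (nm in c("JTT", "LG", "WAG")) {
    em <- load_empirical(nm)
    expect_equal(sum(em$P), 1, tolerance = 1e-10)
    expect_equal(em$E, t(em$E))
    expect_true(all(em$E >= 0) && all(em$P > 0))
  }
  em <- load_empirical("WAG")
  f <- withr::local_tempfile(fileext = ".dat")
  write_empirical(em, f)
  em2 <- load_empirical(f)
  expect_equal(em2$E, em$E, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(em2$P), unname(em$P), tolerance = 1e-12)
})

test_that("Halpern-Bruno factors are symmetric with the analytic equal-fitness limit", {
  L <- 15
  phi <- toy_phi(L, seed = 21, sd = 0.8)
  emp <- load_empirical("WAG")
  lam <- 0.7
  sd1 <- stationary_distribution(phi, lam, emp$P)
  hb <- hb_exchangeability(emp$E, lam * phi, sd1$Z)
  expect_lt(max(vapply(hb, function(M) max(abs(M - t(M))), 0)), 1e-10)
  # equal fitness: factor = Z e^{-lphi}
  phic <- matrix(1.3, L, 20)
  sdc <- stationary_distribution(phic, lam, emp$P)
  hbc <- hb_exchangeability(emp$E, lam * phic, sdc$Z)
  expect_equal(hbc[[1]], emp$E * sdc$Z[1] * exp(-lam * 1.3), tolerance = 1e-10)
  # lambda -> 0: factor -> Z -> 1, E_i -> E_glob
  sd0 <- stationary_distribution(phi, 0, emp$P)
  hb0 <- hb_exchangeability(emp$E, 0 * phi, sd0$Z)
  expect_equal(hb0[[3]], emp$E, tolerance = 1e-10)
})

test_that("flux matching reproduces the empirical fluxes site-averaged", {
  L <- 15
  phi <- toy_phi(L, seed = 22, sd = 0.8)
  emp <- load_empirical("LG")
  lam <- 0.6
  sd1 <- stationary_distribution(phi, lam, emp$P)
  lphi <- lam * phi
  off <- upper.tri(emp$E)
  empF <- (outer(emp$P, emp$P) * emp$E)[off]
  for (hbopt in c(TRUE, FALSE)) {
    Eg <- flux_match(emp, lphi, sd1$Z, emp$P, hb = hbopt)
    FL <- matrix(0, 20, 20)
    for (i in seq_len(L)) {
      Pi <- sd1$P_raw[i, ]
      Ei <- if (hbopt) Eg * sscpe:::.hb_factor(lphi[i, ], sd1$Z[i]) else Eg
      FL <- FL + outer(Pi, Pi) * Ei
    }
    expect_lt(max(abs(FL[off] / L - empF)), 1e-8)
  }
  # lambda = 0 with p_glob = P_emp reduces to the empirical matrix
  Eg0 <- flux_match(emp, 0 * phi, stationary_distribution(phi, 0, emp$P)$Z,
                    emp$P, hb = FALSE)
  expect_lt(max(abs(Eg0[off] - emp$E[off])), 1e-10)
  # linearity: scaling the empirical exchangeability scales the fluxes
  emp2 <- emp; emp2$E <- 3 * emp$E
  Eg3 <- flux_match(emp2, lphi, sd1$Z, emp$P, hb = FALSE)
  Eg1 <- flux_match(emp, lphi, sd1$Z, emp$P, hb = FALSE)
  expect_equal(Eg3[off], 3 * Eg1[off], tolerance = 1e-10)
})

test_that("assembled site models satisfy the generator contracts", {
  L <- 12
  phi <- toy_phi(L, seed = 23, sd = 1)
  emp <- load_empirical("WAG")
  sd1 <- stationary_distribution(phi, 0.8, emp$P)
  for (hb in c(TRUE, FALSE)) for (fl in c(TRUE, FALSE)) {
    sm <- assemble_site_models(sd1$P, 0.8 * phi, sd1$Z, emp$P, emp,
                               hb = hb, fl = fl, rate1 = TRUE)
    for (i in c(1, 7)) {
      Pi <- sm$P[i, ]
      M <- outer(Pi, Pi) * sm$E[[i]]
      expect_equal(sum(M) - sum(diag(M)), 1, tolerance = 1e-10)  # rate0 norm
      Qi <- sm$Q[[i]]
      expect_lt(max(abs(rowSums(Qi))), 1e-12)
      expect_lt(max(abs(Pi * Qi - t(Pi * Qi))), 1e-10)   # detailed balance
      expect_lt(max(abs(Pi %*% Qi)), 1e-10)              # stationarity
      Pt <- site_transition_matrix(sm, i, 500)
      expect_lt(max(abs(rowSums(Pt) - 1)), 1e-9)
      expect_lt(max(abs(sweep(Pt, 2, Pi))), 1e-6)        # long-time limit
    }
    # rate1 scale restores the model-predicted rate
    er <- entropy_and_rate(sm$P, lapply(seq_len(L), function(i)
      sm$E[[i]] * sm$scale[i]))
    expect_equal(er$R, sm$rate_pred, tolerance = 1e-10)
  }
  # plain empirical reduction: noHB+noFL with the empirical distribution
  Pe <- matrix(rep(emp$P, each = L), L, 20, dimnames = list(NULL, aa_alphabet()))
  sme <- assemble_site_models(Pe, 0 * phi, rep(1, L), emp$P, emp,
                              hb = FALSE, fl = FALSE, rate1 = FALSE)
  rate_emp <- sum(outer(emp$P, emp$P) * emp$E) - sum(diag(outer(emp$P, emp$P) * emp$E))
  expect_equal(sme$E[[1]], emp$E / rate_emp, tolerance = 1e-12)
})

test_that("approximate pair likelihood matches hand computation", {
  aa <- aa_alphabet()
  emp <- load_empirical("WAG")
  # identical pair: only the frequency term survives
  N <- matrix(0, 20, 20, dimnames = list(aa, aa))
  N["A", "A"] <- 5; N["C", "C"] <- 3
  al <- approx_loglik(N, emp$E, emp$P)
  expect_equal(al$loglik, 5 * log(emp$P["A"]) + 3 * log(emp$P["C"]),
               ignore_attr = TRUE)
  expect_equal(al$t_opt, 0)
  # two-state analog: hand-computed optimum and value
  N2 <- matrix(0, 20, 20, dimnames = list(aa, aa))
  N2["A", "A"] <- 8; N2["A", "C"] <- 2
  E <- emp$E; P <- emp$P
  E0 <- E; diag(E0) <- 0
  Eaa <- -drop(E0 %*% P)
  t_hand <- -2 / (8 * P["A"] * Eaa["A"])
  ll_hand <- 2 * log(E["A", "C"]) + 10 * log(P["A"]) +
    2 * log(t_hand) + t_hand * 8 * P["A"] * Eaa["A"]
  # N(a) by row: A appears 10 times as the root state
  al2 <- approx_loglik(N2, E, P)
  expect_equal(al2$t_opt, unname(t_hand))
  expect_equal(al2$loglik, unname(ll_hand), tolerance = 1e-12)
  # moving substitutions to smaller-E pairs lowers the likelihood
  worst <- which(E0 == min(E0[E0 > 0]), arr.ind = TRUE)[1, ]
  N3 <- matrix(0, 20, 20, dimnames = list(aa, aa))
  N3["A", "A"] <- 8
  N3[worst[1], worst[2]] <- 2
  N3[worst[1], worst[1]] <- N3[worst[1], worst[1]] + 0  # keep diagonal mass
  al3 <- approx_loglik(N3, E, P)
  expect_lt(al3$loglik - sum(rowSums(N3) * log(P)),
            al2$loglik - sum(rowSums(N2) * log(P)))
})

test_that("model selection ranks the generating empirical model first", {
  emp <- load_empirical("WAG")
  L <- 40
  wins <- 0
  for (sd in 1:8) {
    Pe <- matrix(rep(emp$P, each = L), L, 20)
    sm <- assemble_site_models(Pe, matrix(0, L, 20), rep(1, L), emp$P, emp,
                               hb = FALSE, fl = FALSE, rate1 = FALSE)
    tr <- ape::rtree(6)
    tr$edge.length <- tr$edge.length * 0.4
    msa <- sample_msa(Pe, tree = tr, models = sm, seed = 300 + sd)
    rk <- select_best(pair_counts(msa))
    if (rk$model[1] == "WAG") wins <- wins + 1
  }
  expect_gte(wins, 6)
  # single candidate returns itself; duplicated candidate keeps fixed order
  pc <- pair_counts(sample_msa(matrix(rep(emp$P, each = 10), 10, 20),
                               n_seq = 10, seed = 1))
  one <- select_best(pc, list(WAG = emp))
  expect_equal(one$model, "WAG")
  two <- select_best(pc, list(first = emp, second = emp))
  expect_equal(two$model[1], "first")
})
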