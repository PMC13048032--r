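test_that("degenerate mutations produce zero force", {
  s <- fx_bundle$s
  mp <- fx_bundle$mp
  expect_equal(max(abs(mutation_force(s, fx_bundle$cme, mp, 5, "A", "A")$force)), 0)
  # a site with no contacts: 3 isolated CA residues
  iso <- protein_structure(
    c("A", "L", "G"),
    data.frame(res = 1:3, name = "CA", elem = "C",
               x = c(0, 10, 20), y = 0, z = 0))
  cmi <- build_contact_map(iso, "enm")
  expect_equal(max(abs(mutation_force(iso, cmi, mp, 2, "L", "W")$force)), 0)
})

test_that("the total mutation force vanishes (reaction at the mutated site)", {
  s <- fx_bundle$s
  for (m in c(3, 17, 30)) {
    mf <- mutation_force(s, fx_bundle$cme, fx_bundle$mp, m, s$seq[m], "W")
    net <- colSums(matrix(mf$force, ncol = 3, byrow = TRUE))
    expect_lt(max(abs(net)), 1e-10)
  }
})

test_that("DE from the mode sum equals the Hessian pseudo-inverse quadratic form", {
  s <- make_backbone(8, "helix", seed = 5)
  cm <- build_contact_map(s, "enm")
  anm <- build_cartesian_enm(s, cm)
  or <- anm_hessian_pinv(s, cm)
  mp <- mutation_parameters()
  for (m in c(2, 4, 7)) {
    mf <- mutation_force(s, cm, mp, m, s$seq[m], "F")
    Fca <- force_to_ca(mf$force, s$atoms$res)
    de_oracle <- drop(Fca %*% or$pinv_mass %*% Fca)
    de_modes <- predict_deformation(mf, anm)$de
    expect_equal(de_modes, de_oracle, tolerance = 1e-6)
  }
})

test_that("predicted RMSD is invariant to the force constant K", {
  s <- fx_helix$s
  cm <- fx_helix$cm
  m <- 6
  pd1 <- predict_deformation(
    mutation_force(s, cm, mutation_parameters(K = 1), m, s$seq[m], "W"),
    fx_helix$tnm)
  tnm10 <- build_torsional_enm(s, cm, enm_parameters(K = 10))
  pd10 <- predict_deformation(
    mutation_force(s, cm, mutation_parameters(K = 10), m, s$seq[m], "W"),
    tnm10)
  expect_equal(pd10$rmsd, pd1$rmsd, tolerance = 1e-8)
  # DE carries one power of K (energy scale of the network)
  expect_equal(pd10$de, 10 * pd1$de, tolerance = 1e-8)
})

test_that("total MSD decomposes per the three-term model", {
  s <- fx_helix$s
  mf <- mutation_force(s, fx_helix$cm, mutation_parameters(), 4, s$seq[4], "W")
  dp <- total_msd_model(mf, fx_helix$tnm, sigma_p = 1)
  dm <- total_msd_model(mf, fx_helix$tnm, sigma_p = -1)
  expect_equal(dp$total, dp$msd_mut + dp$msd_nomut + dp$msd_cross_magnitude)
  expect_equal(dp$total - dm$total, 2 * dp$msd_cross_magnitude)
  expect_equal(dp$msd_nomut, thermal_msd(fx_helix$tnm))
  # zero force: total reduces to the null model
  mf0 <- mutation_force(s, fx_helix$cm, mutation_parameters(), 4,
                        s$seq[4], s$seq[4])
  expect_equal(total_msd_model(mf0, fx_helix$tnm)$total,
               thermal_msd(fx_helix$tnm))
})

test_that("sigma_p is fitted by comparing observed and null-plus-mutation MSD", {
  s <- fx_helix$s
  mf <- mutation_force(s, fx_helix$cm, mutation_parameters(), 4, s$seq[4], "W")
  dp <- total_msd_model(mf, fx_helix$tnm)
  base <- dp$msd_mut + dp$msd_nomut
  expect_equal(fit_sigma_p(base + 1, dp), 1)
  expect_equal(fit_sigma_p(base - 1, dp), -1)
  expect_equal(fit_sigma_p(base, dp), 1)   # documented tie-break
})

test_that("the functional-change filter compares barriers against the null profile", {
  mb <- fx_helix$tnm
  # change along the null profile (c_alpha^2 proportional to 1/omega^2)
  dr_null <- mb$modes %*% (1 / mb$omega)
  expect_equal(functional_change_filter(mb, dr_null)$ratio, 1, tolerance = 1e-8)
  expect_true(functional_change_filter(mb, rep(0, nrow(mb$modes)))$keep)
  # all weight on the softest mode of a stiff spectrum: barrier anomaly
  dr_soft <- mb$modes[, 1]
  fc <- functional_change_filter(mb, dr_soft)
  # closed form: all weight on mode 1 gives E = omega_1^2, null expectation
  # at the same MSD is n_dof / sum(1/omega^2)
  ratio_closed <- mb$omega[1]^2 / (mb$n_dof / sum(1 / mb$omega^2))
  expect_equal(fc$ratio, ratio_closed, tolerance = 1e-8)
  expect_false(fc$keep)
})

test_that("wild-type entries of the effect table follow the stationary-weighted average", {
  s <- fx_helix$s
  et0 <- build_effect_table(s, fx_helix$cm, fx_helix$tnm,
                            mutation_parameters(), lambda_str = 0)
  aa <- aa_alphabet()
  for (i in c(2, 8)) {
    others <- setdiff(aa, s$seq[i])
    expect_equal(unname(et0$rmsd[i, s$seq[i]]), mean(et0$rmsd[i, others]))
  }
  # strong negative selection parameter concentrates weight on the largest
  # deformation
  etn <- build_effect_table(s, fx_helix$cm, fx_helix$tnm,
                            mutation_parameters(), lambda_str = -10)
  i <- 5
  others <- setdiff(aa, s$seq[i])
  v <- etn$rmsd[i, others]
  w <- exp(-10 * (-v)); w <- w / sum(w)
  expect_equal(unname(etn$rmsd[i, s$seq[i]]), sum(v * w), tolerance = 1e-10)
  expect_gt(unname(etn$rmsd[i, s$seq[i]]), unname(et0$rmsd[i, s$seq[i]]))
  # matrices are non-negative with rmsd positive wherever contacts exist
  expect_true(all(et0$rmsd >= 0) && all(et0$de >= 0))
})

test_that("deformation is invariant under global rotation", {
  s <- fx_helix$s
  m <- 7
  pd1 <- predict_deformation(
    mutation_force(s, fx_helix$cm, mutation_parameters(), m, s$seq[m], "D"),
    fx_helix$tnm)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  cm2 <- build_contact_map(s2, "enm")
  pd2 <- predict_deformation(
    mutation_force(s2, cm2, mutation_parameters(), m, s$seq[m], "D"),
    build_torsional_enm(s2, cm2))
  expect_equal(pd2$rmsd, pd1$rmsd, tolerance = 1e-8)
  expect_equal(pd2$de, pd1$de, tolerance = 1e-6)
})

test_that("fit_weights recovers the generating direction on noiseless data", {
  s <- fx_bundle$s
  cm <- fx_bundle$cme
  mb <- fx_bundle$tnm
  Wtrue <- c(3, 2, 15)
  set.seed(42)
  muts <- data.frame(m = sample(s$n, 25, replace = TRUE),
                     b = sample(aa_alphabet(), 25, replace = TRUE))
  pairs <- lapply(seq_len(nrow(muts)), function(k) {
    m <- muts$m[k]; b <- muts$b[k]
    mpw <- mutation_parameters(W_size = Wtrue[1], W_stab = Wtrue[2],
                               W_dist = Wtrue[3])
    obs <- predict_deformation(mutation_force(s, cm, mpw, m, s$seq[m], b), mb)$rmsd
    list(s = s, cm = cm, mb = mb, m = m, a = s$seq[m], b = b, observed = obs)
  })
  pairs <- pairs[vapply(pairs, function(p) p$observed > 0, TRUE)]
  fit <- fit_weights(pairs)
  expect_equal(fit$correlation, 1, tolerance = 1e-6)
  expect_equal(unname(fit$W), Wtrue / sqrt(sum(Wtrue^2)), tolerance = 0.05)
  # permuted observations: correlation collapses
  perm <- pairs
  obs <- vapply(pairs, `[[`, 0, "observed")
  set.seed(1)
  obs_p <- sample(obs)
  for (k in seq_along(perm)) perm[[k]]$observed <- obs_p[k]
  expect_lt(fit_weights(perm)$correlation, 0.6)
  # degenerate observations are refused
  for (k in seq_along(perm)) perm[[k]]$observed <- 1
  expect_error(fit_weights(perm), "degenerate")
})
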