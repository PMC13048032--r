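# shared toy model set for the likelihood tests
phy_fx <- local({
  emp <- load_empirical("WAG")
  L <- 10
  phi <- toy_phi(L, seed = 31, sd = 0.5)
  sd1 <- stationary_distribution(phi, 0.6, emp$P)
  sm <- assemble_site_models(sd1$P, 0.6 * phi, sd1$Z, emp$P, emp,
                             hb = TRUE, fl = FALSE, rate1 = FALSE)
  set.seed(32)
  tr <- ape::rtree(5)
  tr$tip.label <- paste0("t", 1:5)
  msa <- sample_msa(sd1$P, tree = tr, models = sm, seed = 33)
  list(emp = emp, sm = sm, tr = tr, msa = msa, P = sd1$P)
})

test_that("pruning likelihood has the zero-branch and exhaustive-sum limits", {
  sm <- phy_fx$sm
  L <- nrow(sm$P)
  # identical sequences at t = 0
  t2 <- ape::read.tree(text = "(A:0,B:0);")
  m2 <- rbind(A = phy_fx$msa[1, ], B = phy_fx$msa[1, ])
  ll <- pruning_loglik(t2, m2, sm)
  expect_equal(ll, sum(log(sm$P[cbind(seq_len(L),
                                      match(phy_fx$msa[1, ], aa_alphabet()))])),
               tolerance = 1e-12)
  # 3-leaf single-site exhaustive summation over internal states
  t3 <- ape::read.tree(text = "((A:0.3,B:0.5):0.2,C:0.7);")
  m1 <- matrix(c("A", "W", "L"), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  smi <- phy_fx$sm
  llp <- pruning_loglik(t3, m1, smi, site_map = 1)
  P1 <- smi$P[1, ]
  PA <- site_transition_matrix(smi, 1, 0.3)
  PB <- site_transition_matrix(smi, 1, 0.5)
  PAB <- site_transition_matrix(smi, 1, 0.2)
  PC <- site_transition_matrix(smi, 1, 0.7)
  aa <- aa_alphabet()
  ia <- match("A", aa); ib <- match("W", aa); ic <- match("L", aa)
  tot <- 0
  for (x in 1:20) for (y in 1:20)
    tot <- tot + P1[x] * PC[x, ic] * PAB[x, y] * PA[y, ia] * PB[y, ib]
  expect_equal(llp, unname(log(tot)), tolerance = 1e-12)
  # gaps are missing data: an all-gap taxon contributes nothing
  m2g <- rbind(A = phy_fx$msa[1, ], B = rep("-", L))
  llg <- pruning_loglik(ape::read.tree(text = "(A:0.1,B:0.4);"), m2g, sm)
  expect_equal(llg, ll, tolerance = 1e-10)
})

test_that("pruning likelihood is invariant under re-rooting", {
  ll <- pruning_loglik(phy_fx$tr, phy_fx$msa, phy_fx$sm)
  for (og in c(1, 3)) {
    tr2 <- ape::root(phy_fx$tr, outgroup = phy_fx$tr$tip.label[og],
                     resolve.root = TRUE)
    expect_equal(pruning_loglik(tr2, phy_fx$msa, phy_fx$sm), ll,
                 tolerance = 1e-10)
  }
})

test_that("pruning agrees with an independent likelihood engine on a global model", {
  emp <- phy_fx$emp
  L <- ncol(phy_fx$msa)
  Pe <- matrix(rep(emp$P, each = L), L, 20)
  smG <- assemble_site_models(Pe, matrix(0, L, 20), rep(1, L), emp$P, emp,
                              hb = FALSE, fl = FALSE, rate1 = FALSE)
  llG <- pruning_loglik(phy_fx$tr, phy_fx$msa, smG)
  fitp <- phangorn::pml(phy_fx$tr, phangorn::phyDat(phy_fx$msa, type = "AA"),
                        model = "WAG")
  expect_equal(llG, fitp$logLik, tolerance = 1e-6)
})

test_that("mu is the least-squares slope of loglik on branch sum", {
  expect_equal(fit_mu(c(-10, -8), c(1, 2)), 2)
  set.seed(41)
  bs <- runif(50, 0.5, 3)
  ll <- -30 + 4.2 * bs
  expect_equal(fit_mu(ll, bs), 4.2, tolerance = 1e-10)
  lln <- ll + rnorm(50, 0, 0.3)
  se <- 0.3 / (sd(bs) * sqrt(49))
  expect_lt(abs(fit_mu(lln, bs) - 4.2), 3 * se)
  expect_error(fit_mu(c(-1, -2), c(1, 1)), "identical")
})

test_that("RegMLaME reduces to -loglik at mu = 0 and is linear in length", {
  ts0 <- regmlame(phy_fx$tr, phy_fx$msa, phy_fx$sm, mu = 0)
  expect_identical(ts0$regmlame, -ts0$loglik)
  ts1 <- regmlame(phy_fx$tr, phy_fx$msa, phy_fx$sm, mu = 2.5)
  expect_equal(ts1$regmlame, -ts0$loglik + 2.5 * sum(phy_fx$tr$edge.length))
  # monotone non-decreasing in mu at fixed tree
  mus <- c(0, 0.5, 1, 2)
  vals <- vapply(mus, function(m)
    regmlame(phy_fx$tr, phy_fx$msa, phy_fx$sm, mu = m)$regmlame, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("branch-length optimization matches the closed-form equal-rate distance", {
  # equal-exchangeability model: p_same(t) = 1/20 + 19/20 exp(-c t), c = 20/19
  aa <- aa_alphabet()
  L <- 60
  E1 <- matrix(1, 20, 20, dimnames = list(aa, aa)); diag(E1) <- 0
  emp1 <- structure(list(name = "flat", E = E1, P = rep(1 / 20, 20)),
                    class = "empirical_model")
  Pu <- matrix(1 / 20, L, 20)
  smF <- assemble_site_models(Pu, matrix(0, L, 20), rep(1, L), rep(1 / 20, 20),
                              emp1, hb = FALSE, fl = FALSE, rate1 = FALSE)
  set.seed(55)
  x <- sample(aa, L, replace = TRUE)
  y <- x
  flip <- sample(L, 12)
  y[flip] <- vapply(x[flip], function(a) sample(setdiff(aa, a), 1), "")
  msa2 <- rbind(A = x, B = y)
  t2 <- ape::read.tree(text = "(A:0.2,B:0.2);")
  opt <- optimize_branch_lengths(t2, msa2, smF, site_map = rep(1, L))
  cc <- 20 / 19
  p_same_hat <- mean(x == y)
  t_closed <- -log((p_same_hat - 1 / 20) * 20 / 19) / cc
  expect_equal(sum(opt$edge.length), t_closed, tolerance = 1e-4)
  # a dominating penalty drives branches to zero
  opt0 <- optimize_branch_lengths(t2, msa2, smF, mu = 1e6,
                                  site_map = rep(1, L))
  expect_lt(sum(opt0$edge.length), 1e-4)
})

test_that("K score contracts: identity, pure scaling, grid-search optimum", {
  set.seed(61)
  r1 <- ape::rtree(8)
  expect_equal(k_score(r1, r1)$k, 0)
  expect_equal(k_score(r1, r1)$scale, 1)
  r2 <- r1; r2$edge.length <- 0.5 * r1$edge.length
  ks <- k_score(r1, r2)
  expect_equal(ks$k, 0, tolerance = 1e-12)
  expect_equal(ks$scale, 0.5)
  # random perturbation: fitted scale beats a dense grid search
  r3 <- r1; r3$edge.length <- r1$edge.length * runif(length(r1$edge.length), 0.3, 1.4)
  bf <- sscpe:::.branch_frame(r1, r3)
  sse <- function(s) sum((bf$t_comp - s * bf$t_ref)^2)
  grid <- seq(0, 3, by = 1e-4)
  expect_lte(sse(k_score(r1, r3)$scale), min(vapply(grid, sse, 0)) + 1e-10)
})

test_that("K2 recovers a constructed two-class scaling exactly", {
  set.seed(62)
  r1 <- ape::unroot(ape::rtree(10))
  bt <- sscpe:::.branch_table(r1)
  # scale terminal branches by 1.0 and internal ones by 0.2
  r2 <- r1
  po <- ape::reorder.phylo(r1, "postorder")
  ntip <- length(r1$tip.label)
  internal <- po$edge[, 2] > ntip
  r2 <- po
  r2$edge.length[internal] <- 0.2 * po$edge.length[internal]
  k2 <- k2_score(po, r2)
  expect_equal(k2$k2, 0, tolerance = 1e-10)
  expect_equal(sort(c(k2$scale_slow, k2$scale_fast)), c(0.2, 1),
               tolerance = 1e-10)
  expect_gt(k2$k, 0)
  # identical trees: all three scores vanish (degenerate split warns)
  expect_warning(k2i <- k2_score(po, po), "falling back")
  expect_equal(k2i$k2, 0)
  expect_equal(k2i$rf_norm, 0)
})

test_that("K2 never exceeds K on random tree pairs", {
  for (i in 1:100) {
    set.seed(700 + i)
    a <- ape::rtree(7)
    b <- ape::rtree(7)
    b$tip.label <- sample(a$tip.label)
    x <- k2_score(a, b)
    expect_lte(x$k2, x$k + 1e-12)
  }
})

test_that("normalized RF agrees with exhaustive bipartition enumeration", {
  enum_rf <- function(a, b) {
    splits <- function(tr) {
      tr <- ape::unroot(tr)
      n <- length(tr$tip.label)
      labs <- sort(tr$tip.label)
      out <- character(0)
      pp <- ape::prop.part(tr)
      for (k in seq_along(pp)) {
        side <- sort(attr(pp, "labels")[pp[[k]]])
        if (labs[1] %in% side) side <- sort(setdiff(labs, side))
        if (length(side) >= 2 && length(side) <= n - 2)
          out <- c(out, paste(side, collapse = "|"))
      }
      unique(out)
    }
    sa <- splits(a); sb <- splits(b)
    (length(setdiff(sa, sb)) + length(setdiff(sb, sa))) /
      (2 * (length(a$tip.label) - 3))
  }
  for (i in 1:20) {
    set.seed(900 + i)
    a <- ape::rtree(6)
    b <- ape::rtree(6)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_normalized(a, b), enum_rf(a, b))
    expect_equal(rf_normalized(a, b), rf_normalized(b, a))  # symmetry
    expect_equal(rf_normalized(a, b),
                 phangorn::RF.dist(ape::unroot(a), ape::unroot(b),
                                   normalize = TRUE))
  }
  expect_error(rf_normalized(ape::rtree(3), ape::rtree(3)), "4 leaves")
})
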