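# Shared fixtures, built once per test run. Sizes are kept small so the
# whole suite stays fast; the helix exercises ideal geometry, the bundle
# exercises a realistic contact-number range.

fx_helix <- local({
  s <- make_backbone(12, "helix", seed = 101)
  cm <- build_contact_map(s, "enm")
  list(s = s, cm = cm,
       tnm = build_torsional_enm(s, cm),
       anm = build_cartesian_enm(s, cm))
})

fx_bundle <- local({
  s <- make_backbone(40, "helix_bundle", seed = 202)
  cs <- build_contact_statistics(make_decoy_library(12, 40, seed = 11))
  sp <- stability_parameters()
  s$seq <- design_sequence(s, cs, sp, sweeps = 2, seed = 3)
  cme <- build_contact_map(s, "enm")
  cms <- build_contact_map(s, "stability")
  list(s = s, cme = cme, cms = cms, cs = cs, sp = sp,
       mp = mutation_parameters(),
       tnm = build_torsional_enm(s, cme))
})

# explicit mass-weighted pseudo-inverse of an ANM Hessian: the independent
# linear-response oracle (inverts the Hessian directly, not through the
# package's mode loop)
anm_hessian_pinv <- function(s, cm, K = 1) {
  L <- s$n
  xyz <- as.matrix(s$atoms[s$atoms$name == "CA", c("x", "y", "z")])
  m <- as.vector(rowsum(s$atoms$mass, s$atoms$res))
  m <- m / sum(m)
  H <- matrix(0, 3 * L, 3 * L)
  for (q in seq_len(nrow(cm$pairs))) {
    i <- cm$pairs$i[q]; j <- cm$pairs$j[q]
    v <- xyz[i, ] - xyz[j, ]
    blk <- K * tcrossprod(v / sqrt(sum(v^2)))
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    H[ii, ii] <- H[ii, ii] + blk; H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk; H[jj, ii] <- H[jj, ii] - blk
  }
  msq <- rep(sqrt(m), each = 3)
  Hw <- H / tcrossprod(msq)
  ee <- eigen(Hw, symmetric = TRUE)
  keep <- seq_len(3 * L - 6)
  Hwp <- ee$vectors[, keep] %*% (t(ee$vectors[, keep]) / ee$values[keep])
  list(pinv_mass = Hwp / tcrossprod(msq), H = H, masses = m)
}

# aggregate a heavy-atom force field to per-residue C-alpha coordinates
force_to_ca <- function(F, atoms_res) {
  as.vector(t(rowsum(matrix(F, ncol = 3, byrow = TRUE), atoms_res)))
}

# deterministic random fitness/frequency toy of given size
toy_phi <- function(L, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(L * 20, 0, sd), L, 20, dimnames = list(NULL, aa_alphabet()))
}

# a small end-to-end fit shared by the pipeline tests (and the acceptance
# contracts): MSA sampled from a known combined model on a designed bundle
pipe_fx <- local({
  s <- fx_bundle$s
  cs <- fx_bundle$cs
  sp <- fx_bundle$sp
  phiW <- wt_fitness(s$seq, fx_bundle$cms, cs, sp)
  et <- build_effect_table(s, fx_bundle$cme, fx_bundle$tnm, fx_bundle$mp)
  # generate with the same lambda-dependent wild-type-entry convention the
  # fitted structural channel uses, so the fit is a clean recovery problem
  phiS <- sscpe:::.str_phi_fun(et, "RMSD")(0.5)
  P <- stationary_distribution(list(phiW, phiS), c(2, 0.5),
                               rep(1 / 20, 20))$P
  msa <- sample_msa(P, n_seq = 30, seed = 77)
  rownames(msa)[1] <- "ref"
  msa[1, ] <- s$seq
  fit <- sscpe(msa, s, model = "RMSDWT", decoys = cs, sp = sp, R = 0,
               lambda_max = 6, seed = 9)
  list(s = s, msa = msa, P_true = P, fit = fit, phiW = phiW, et = et)
})

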