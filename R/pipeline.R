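# End-to-end orchestration: match structures to MSA sequences, apply the
# stability filters, average fitness over multiple structures, fit the
# profile model, and assemble the site-specific substitution models.

.SSCPE_MODELS <- c("GLOB", "MF", "WT", "DE", "RMSD",
                   "DEMF", "DEWT", "RMSDMF", "RMSDWT")

# which channels a model uses: stability in {none,MF,WT}, structure in
# {none,DE,RMSD}
.model_channels <- function(model) {
  switch(model,
    GLOB = list(stab = "none", str = "none"),
    MF = list(stab = "MF", str = "none"),
    WT = list(stab = "WT", str = "none"),
    DE = list(stab = "none", str = "DE"),
    RMSD = list(stab = "none", str = "RMSD"),
    DEMF = list(stab = "MF", str = "DE"),
    DEWT = list(stab = "WT", str = "DE"),
    RMSDMF = list(stab = "MF", str = "RMSD"),
    RMSDWT = list(stab = "WT", str = "RMSD"),
    stop("unknown model ", model))
}

#' Match a structure sequence to an MSA
#'
#' Globally aligns the structure's sequence against every (degapped) MSA
#' sequence, keeps the best match, and accepts it if the sequence identity
#' over aligned non-gap positions is at least \code{min_identity}.
#'
#' @param s A \code{protein_structure}.
#' @param msa Character MSA matrix.
#' @param min_identity Acceptance threshold (default 0.5).
#' @param gap_opening,gap_extension Alignment gap penalties.
#' @return List with \code{accepted}, \code{best_row}, \code{identity} and
#'   \code{column_map} (structure site -> MSA column; NA where unaligned).
#' @export
match_structure_to_msa <- function(s, msa, min_identity = 0.5,
                                   gap_opening = 10, gap_extension = 0.5) {
  sseq <- paste(s$seq, collapse = "")
  best <- list(identity = -1)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  for (r in seq_len(nrow(msa))) {
    dg <- .degap(msa[r, ])
    if (length(dg) == 0) next
    al <- Biostrings::pairwiseAlignment(
      sseq, paste(dg, collapse = ""), type = "global",
      substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    both <- ap != "-" & as_ != "-"
    ident <- if (any(both)) mean(ap[both] == as_[both]) else 0
    if (ident > best$identity)
      best <- list(identity = ident, row = r, ap = ap, as_ = as_)
  }
  if (best$identity < min_identity)
    return(list(accepted = FALSE, best_row = best$row,
                identity = best$identity, column_map = NULL))
  # structure position -> degapped-subject position -> MSA column
  cols_of_row <- which(msa[best$row, ] != "-")
  cmap <- rep(NA_integer_, s$n)
  p <- q <- 0
  for (k in seq_along(best$ap)) {
    if (best$ap[k] != "-") p <- p + 1
    if (best$as_[k] != "-") q <- q + 1
    if (best$ap[k] != "-" && best$as_[k] != "-")
      cmap[p] <- cols_of_row[q]
  }
  list(accepted = TRUE, best_row = best$row, identity = best$identity,
       column_map = cmap)
}

# thread MSA sequence r onto structure sites: gaps and unaligned structure
# positions keep the structure's native residue
.threaded_sequence <- function(s, msa, r, column_map) {
  out <- s$seq
  ok <- !is.na(column_map)
  ch <- msa[r, column_map[ok]]
  std <- ch %in% aa_alphabet()
  out[which(ok)[std]] <- ch[std]
  out
}

#' Structure retention filter
#'
#' A structure is retained if its own sequence is predicted stable
#' (Delta G < 0) and it stabilizes enough MSA sequences:
#' sum_s f_ps >= min(4.5, 0.45 n_seq), with f_ps = 1/(1 + exp(Delta G)).
#'
#' @param delta_g_own Delta G of the structure's own sequence.
#' @param f_ps Vector of stabilities of every MSA sequence on the structure.
#' @param n_seq Number of sequences in the MSA.
#' @return Logical.
#' @export
filter_structures <- function(delta_g_own, f_ps, n_seq) {
  delta_g_own < 0 && sum(f_ps) >= min(4.5, 0.45 * n_seq)
}

#' Sequence retention filter and empty-column removal
#'
#' Drops MSA sequences whose stability score sum_p f_sp is below 0.9, then
#' removes columns left without any residue, recording the old-to-new column
#' map.
#'
#' @param msa Character MSA matrix.
#' @param score Per-sequence stability score sum_p f_sp.
#' @param threshold Retention threshold (default 0.9).
#' @return List with \code{msa}, \code{kept_seqs}, \code{column_map}
#'   (old index -> new index, NA for dropped columns).
#' @export
filter_sequences <- function(msa, score, threshold = 0.9) {
  keep <- score >= threshold
  if (!any(keep)) stop("no sequence passes the stability filter")
  m2 <- msa[keep, , drop = FALSE]
  nonempty <- apply(m2, 2, function(x) any(x %in% aa_alphabet()))
  column_map <- rep(NA_integer_, ncol(msa))
  column_map[nonempty] <- seq_len(sum(nonempty))
  list(msa = m2[, nonempty, drop = FALSE],
       kept_seqs = which(keep), column_map = column_map)
}

#' Weighted combination of per-structure fitness matrices
#'
#' phi_i(a) = sum_p w_p phi^p_i(a) / sum_p w_p over the structures covering
#' column i; columns covered by no structure get phi = 0 (described by the
#' global frequencies alone).
#'
#' @param phi_list List of L x 20 matrices with NA rows at uncovered
#'   columns.
#' @param weights Per-structure weights (proportional to sum_s f_sp).
#' @return L x 20 matrix.
#' @export
combine_structure_fitness <- function(phi_list, weights) {
  stopifnot(length(phi_list) == length(weights))
  L <- nrow(phi_list[[1]])
  num <- matrix(0, L, 20)
  den <- matrix(0, L, 20)
  for (p in seq_along(phi_list)) {
    M <- phi_list[[p]]
    cov <- !is.na(M[, 1])
    num[cov, ] <- num[cov, ] + weights[p] * M[cov, ]
    den[cov, ] <- den[cov, ] + weights[p]
  }
  out <- ifelse(den > 0, num / pmax(den, 1e-300), 0)
  colnames(out) <- aa_alphabet()
  out
}

# structural-channel fitness as a function of lambda: the 19 mutant entries
# are fixed, the wild-type entry is the stationary-weighted average
.str_phi_fun <- function(et, kind) {
  base <- -(if (kind == "RMSD") et$rmsd else et$de)
  wt <- et$wild_type
  aa <- aa_alphabet()
  wtj <- match(wt, aa)
  function(lambda) {
    out <- base
    for (i in seq_len(nrow(base))) {
      v <- base[i, -wtj[i]]
      w <- exp(lambda * v - max(lambda * v))
      out[i, wtj[i]] <- sum(v * w) / sum(w)
    }
    # centre at the wild type so Lambda acts on differences only
    out - out[cbind(seq_len(nrow(out)), wtj)]
  }
}

#' Fit a site-specific profile model to an MSA with structures
#'
#' The main fitting function. Matches each structure to the alignment,
#' applies the retention filters, computes the per-structure fitness
#' matrices of the requested model (stability channel: mean-field MF or
#' wild-type WT; structural channel: predicted mutation RMSD or harmonic
#' energy DE), combines them across structures, fits the selection
#' parameter(s) by ridge-regularized symmetric-KL minimization with the
#' specific-heat choice of the ridge weight, and assembles the site-specific
#' substitution models.
#'
#' @param msa Character MSA matrix or path to an aligned FASTA file.
#' @param structures A \code{protein_structure}, list of them, or PDB path(s).
#' @param model One of GLOB, MF, WT, DE, RMSD, DEMF, DEWT, RMSDMF, RMSDWT.
#' @param empirical "auto" (choose by approximate likelihood) or one of
#'   "JTT", "LG", "WAG", or an \code{empirical_model}.
#' @param hb,fl,rate1 Exchangeability options (defaults HB+FL+rate1).
#' @param decoys A \code{contact_statistics} object, a list of contact maps,
#'   or NULL to generate a seeded synthetic decoy library.
#' @param sp,mp,ep Stability, mutation and elastic-network parameters.
#' @param eps Frequency floor.
#' @param criterion "KL" or "LL".
#' @param R Ridge weight; NULL (default) selects it by the specific-heat
#'   criterion.
#' @param lambda_max Upper bound of the selection-parameter search.
#' @param min_identity Structure-to-MSA identity threshold.
#' @param seed Seed for the generated decoy library.
#' @param verbose Log filter decisions.
#' @return Object of class \code{sscpe}.
#' @export
sscpe <- function(msa, structures, model = "RMSDWT",
                  empirical = "auto", hb = TRUE, fl = TRUE, rate1 = TRUE,
                  decoys = NULL, sp = stability_parameters(),
                  mp = mutation_parameters(), ep = enm_parameters(),
                  eps = 0.001, criterion = "KL", R = NULL, lambda_max = 10,
                  min_identity = 0.5, seed = 1, verbose = FALSE) {
  cl <- match.call()
  model <- match.arg(model, .SSCPE_MODELS)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(msa) && !is.matrix(msa)) msa <- read_fasta_msa(msa)
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  structures <- lapply(structures, function(x)
    if (is.character(x)) load_structure(x) else x)
  ch <- .model_channels(model)
  # decoy statistics
  cs <- if (inherits(decoys, "contact_statistics")) decoys
        else if (is.list(decoys) && length(decoys)) build_contact_statistics(decoys)
        else {
          Lmax <- max(vapply(structures, function(s) s$n, 1L))
          build_contact_statistics(make_decoy_library(16, Lmax, seed = seed))
        }
  n_seq <- nrow(msa)
  # --- structure matching and filters -----------------------------------
  matches <- lapply(structures, match_structure_to_msa, msa = msa,
                    min_identity = min_identity)
  keep1 <- vapply(matches, `[[`, TRUE, "accepted")
  for (p in which(!keep1))
    say("structure %d rejected: best identity %.2f < %.2f",
        p, matches[[p]]$identity, min_identity)
  structures <- structures[keep1]
  matches <- matches[keep1]
  if (length(structures) == 0) stop("no structure matches the MSA")
  fps <- matrix(0, length(structures), n_seq)   # f_ps per structure x sequence
  dg_own <- numeric(length(structures))
  cms <- lapply(structures, build_contact_map, flavor = "stability",
                cutoff = ep$cutoff)
  for (p in seq_along(structures)) {
    s <- structures[[p]]
    dg_own[p] <- delta_g(s$seq, cms[[p]], cs, sp)$delta_g
    for (r in seq_len(n_seq)) {
      thr <- .threaded_sequence(s, msa, r, matches[[p]]$column_map)
      fps[p, r] <- 1 / (1 + exp(delta_g(thr, cms[[p]], cs, sp)$delta_g))
    }
  }
  keep2 <- vapply(seq_along(structures), function(p)
    filter_structures(dg_own[p], fps[p, ], n_seq), TRUE)
  for (p in which(!keep2))
    say("structure %d rejected: Delta G %.2f, sum f %.2f", p, dg_own[p],
        sum(fps[p, ]))
  if (!any(keep2))
    stop("every structure was rejected by the stability/coverage filter ",
         "(Delta G >= 0 or too few stabilized sequences)")
  structures <- structures[keep2]
  matches <- matches[keep2]
  cms <- cms[keep2]
  fps <- fps[keep2, , drop = FALSE]
  # sequence filter + column relabeling
  seq_score <- colSums(fps)
  fs <- filter_sequences(msa, seq_score)
  say("kept %d/%d sequences, %d/%d columns", length(fs$kept_seqs), n_seq,
      ncol(fs$msa), ncol(msa))
  msa_f <- fs$msa
  Lcol <- ncol(msa_f)
  w_p <- rowSums(fps)
  w_p <- w_p / sum(w_p)
  # remap structure column maps through the filtered columns
  cmaps <- lapply(matches, function(m) fs$column_map[m$column_map])
  # --- per-structure fitness channels ------------------------------------
  stab_list <- str_list <- list()
  et_list <- vector("list", length(structures))
  ncont_col <- rep(NA_real_, Lcol)
  for (p in seq_along(structures)) {
    s <- structures[[p]]
    cmap <- cmaps[[p]]
    cov <- !is.na(cmap)
    nc <- contact_counts(cms[[p]])
    ncont_col[cmap[cov]] <- nc[cov]
    if (ch$stab != "none") {
      phi_s <- if (ch$stab == "WT") wt_fitness(s$seq, cms[[p]], cs, sp)
               else mf_fitness(s$seq, cms[[p]], cs, sp)$phi
      M <- matrix(NA_real_, Lcol, 20)
      M[cmap[cov], ] <- phi_s[cov, ]
      stab_list[[length(stab_list) + 1]] <- M
    }
    if (ch$str != "none") {
      cme <- build_contact_map(s, "enm", cutoff = ep$cutoff)
      mb <- build_torsional_enm(s, cme, ep)
      et_list[[p]] <- build_effect_table(s, cme, mb, mp)
    }
  }
  phi <- list()
  phi_names <- character(0)
  if (ch$stab != "none") {
    phi <- c(phi, list(combine_structure_fitness(stab_list, w_p)))
    phi_names <- c(phi_names, "stab")
  }
  if (ch$str != "none") {
    # structural channel: weighted combination evaluated per lambda
    funs <- list()
    for (p in seq_along(structures)) {
      fn <- .str_phi_fun(et_list[[p]], ch$str)
      cmap <- cmaps[[p]]
      cov <- which(!is.na(cmap))
      funs[[p]] <- list(fn = fn, rows = cov, cols = cmap[cov])
    }
    str_fun <- function(lambda) {
      mats <- lapply(seq_along(structures), function(p) {
        M <- matrix(NA_real_, Lcol, 20)
        full <- funs[[p]]$fn(lambda)
        M[funs[[p]]$cols, ] <- full[funs[[p]]$rows, ]
        M
      })
      combine_structure_fitness(mats, w_p)
    }
    phi <- c(phi, list(str_fun))
    phi_names <- c(phi_names, "str")
  }
  # --- profile fit --------------------------------------------------------
  prof <- msa_profile(msa_f, eps)
  if (model == "GLOB") {
    p_glob <- colSums(prof$f) / sum(prof$f)
    P <- matrix(rep(p_glob, each = Lcol), Lcol, 20,
                dimnames = list(NULL, aa_alphabet()))
    P <- t(apply(P, 1, .floor_renorm, eps = eps))
    fitres <- list(lambda = numeric(0), p_glob = p_glob, P = P,
                   kl = .kl_symm(P, prof$f), ll = .ll_score(P, prof$f))
    reg <- NULL
  } else {
    if (is.null(R)) {
      reg <- regularization_path(phi, prof, criterion = criterion,
                                 lambda_max = lambda_max, eps = eps)
      fitres <- reg$fit
    } else {
      reg <- NULL
      fitres <- fit_lambda(phi, prof, criterion = criterion, R = R,
                           lambda_max = lambda_max, eps = eps)
    }
    lam <- fitres$lambda
    phi_res <- .resolve_phi(phi, lam)
    sdist <- stationary_distribution(phi_res, lam, fitres$p_glob, eps)
    fitres$P <- sdist$P
  }
  # the exchangeability machinery works on the effective log-fitness of the
  # floored stationary distribution (phi~ = log(P_i/p_glob), Z = 1): the
  # Halpern-Bruno factors then stay finite once the frequency floor is
  # applied, and detailed balance holds against the distribution actually
  # used in the phylogenetic models
  lphi <- log(sweep(fitres$P, 2, fitres$p_glob, "/"))
  Z <- rep(1, Lcol)
  names(fitres$lambda) <- phi_names
  # --- empirical model and site models -----------------------------------
  ref_row <- matches[[which.max(w_p)]]$best_row
  ref_new <- match(ref_row, fs$kept_seqs)
  if (is.na(ref_new)) ref_new <- 1
  counts <- pair_counts(msa_f, ref = ref_new)
  if (inherits(empirical, "empirical_model")) {
    emp <- empirical
    emp_rank <- NULL
  } else if (identical(empirical, "auto")) {
    emp_rank <- select_best(counts)
    emp <- load_empirical(emp_rank$model[1])
  } else {
    emp <- load_empirical(empirical)
    emp_rank <- NULL
  }
  models <- assemble_site_models(fitres$P, lphi, Z, fitres$p_glob, emp,
                                 hb = hb, fl = fl, rate1 = rate1)
  # approximate likelihood of all eight option combinations
  opts <- expand.grid(hb = c(TRUE, FALSE), fl = c(TRUE, FALSE),
                      rate1 = c(TRUE, FALSE))
  summary_tab <- do.call(rbind, lapply(seq_len(nrow(opts)), function(k) {
    mk <- assemble_site_models(fitres$P, lphi, Z, fitres$p_glob, emp,
                               hb = opts$hb[k], fl = opts$fl[k],
                               rate1 = opts$rate1[k])
    data.frame(model = model, empirical = emp$name,
               hb = opts$hb[k], fl = opts$fl[k], rate1 = opts$rate1[k],
               approx_loglik = site_approx_loglik(counts, mk))
  }))
  summary_tab <- summary_tab[order(-summary_tab$approx_loglik), ]
  rownames(summary_tab) <- NULL
  er <- entropy_and_rate(fitres$P, lapply(seq_along(models$Q), function(i)
    models$E[[i]] * models$scale[i]))
  structure(list(call = cl, model = model,
                 msa = msa_f, msa_profile = prof,
                 column_map = fs$column_map, kept_seqs = fs$kept_seqs,
                 structures = structures, structure_maps = cmaps,
                 weights = w_p, f_ps = fps, delta_g_own = dg_own[keep2],
                 phi = phi, lambda = fitres$lambda,
                 p_glob = fitres$p_glob, P = fitres$P, Z = Z, lphi = lphi,
                 kl = fitres$kl, ll = fitres$ll, reg = reg,
                 empirical = emp, empirical_rank = emp_rank,
                 models = models, summary = summary_tab,
                 entropy = er$S, rates = er$R, contacts = ncont_col,
                 eps = eps, seed = seed),
            class = "sscpe")
}

# resolve fitness entries that are functions of lambda
.resolve_phi <- function(phi, lambda) {
  lapply(seq_along(phi), function(m)
    if (is.function(phi[[m]])) phi[[m]](lambda[m]) else phi[[m]])
}

#' Export per-site partition models
#'
#' Writes the fitted site models in a documented, deterministic text layout
#' consumable by external ML engines after conversion: a frequencies file
#' (site, rate scale, 20 stationary frequencies) and an exchangeability file
#' (global matrix, or per-site lower triangles under HB).
#'
#' @param models A \code{site_models}.
#' @param out_dir Output directory (created if needed).
#' @param name File-name stem.
#' @return Invisible vector of written paths.
#' @export
export_partitions <- function(models, out_dir, name = "sscpe") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aa <- aa_alphabet()
  L <- length(models$Q)
  fq <- file.path(out_dir, paste0(name, ".partition_frequencies.tsv"))
  df <- data.frame(site = seq_len(L),
                   scale = sprintf("%.10g", models$scale),
                   matrix(sprintf("%.10g", models$P), L, 20,
                          dimnames = list(NULL, aa)),
                   check.names = FALSE)
  utils::write.table(df, fq, sep = "\t", quote = FALSE, row.names = FALSE)
  fe <- file.path(out_dir, paste0(name, ".partition_exchangeabilities.tsv"))
  lt <- lower.tri(matrix(0, 20, 20))
  if (models$options["hb"]) {
    M <- t(vapply(models$E, function(E) E[lt], numeric(190)))
    df2 <- data.frame(site = seq_len(L),
                      matrix(sprintf("%.10g", M), L, 190), check.names = FALSE)
    utils::write.table(df2, fe, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(apply(matrix(sprintf("%.10g", models$E[[1]]), 20, 20), 1,
                     paste, collapse = "\t"), fe)
  }
  invisible(c(fq, fe))
}

#' Write the fitted amino-acid profiles
#'
#' One row per structured MSA column with the 20 stationary frequencies;
#' the header records the model's global frequencies.
#'
#' @param object A fitted \code{sscpe} object.
#' @param name Output stem; the file is
#'   \code{<name>.SSCPE.<MODEL>.AA_profiles.txt}.
#' @param dir Output directory.
#' @return Invisible path.
#' @export
write_profiles <- function(object, name, dir = ".") {
  path <- file.path(dir, sprintf("%s.SSCPE.%s.AA_profiles.txt",
                                 name, object$model))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# P_glob\t",
                    paste(sprintf("%.6f", object$p_glob), collapse = "\t")), con)
  writeLines(paste(c("column", aa_alphabet()), collapse = "\t"), con)
  for (i in seq_len(nrow(object$P)))
    writeLines(paste(c(i, sprintf("%.6f", object$P[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Write the site-specific rate profile
#'
#' Per-site substitution rates for the four exchangeability variants
#' (HB/noHB x FL/noFL).
#'
#' @inheritParams write_profiles
#' @return Invisible path.
#' @export
write_rate_profile <- function(object, name, dir = ".") {
  path <- file.path(dir, sprintf("%s.SSCPE.%s.rate_profile.dat",
                                 name, object$model))
  variants <- expand.grid(hb = c(TRUE, FALSE), fl = c(TRUE, FALSE))
  rates <- vapply(seq_len(nrow(variants)), function(k) {
    mk <- assemble_site_models(object$P, object$lphi, object$Z,
                               object$p_glob, object$empirical,
                               hb = variants$hb[k], fl = variants$fl[k],
                               rate1 = TRUE)
    mk$rate_pred
  }, numeric(nrow(object$P)))
  colnames(rates) <- sprintf("%s_%s",
                             ifelse(variants$hb, "HB", "noHB"),
                             ifelse(variants$fl, "FL", "noFL"))
  df <- data.frame(column = seq_len(nrow(object$P)), round(rates, 6),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the model summary table
#'
#' Approximate log-likelihood of the eight exchangeability option
#' combinations.
#'
#' @inheritParams write_profiles
#' @return Invisible path.
#' @export
write_summary <- function(object, name, dir = ".") {
  path <- file.path(dir, sprintf("%s.SSCPE.summary.dat", name))
  utils::write.table(object$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
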