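# Desk-scale phylogenetics under per-site substitution models: Felsenstein
# pruning likelihood, branch-length optimization, the regularized
# ML-and-minimum-evolution (RegMLaME) score, and branch-length tree
# comparison (K, K2, normalized Robinson-Foulds).

# map alignment characters to indices in the alphabet; gaps/unknowns -> NA
.aa_index_matrix <- function(msa) {
  aa <- aa_alphabet()
  m <- matrix(match(msa, aa), nrow(msa), ncol(msa))
  dimnames(m) <- dimnames(msa)
  m
}

#' Felsenstein pruning log-likelihood under site-specific models
#'
#' Computes the log-likelihood of an alignment on a tree, each site evolving
#' under its own reversible rate matrix (the site's stationary distribution
#' is used at the root; the result is root-invariant). Gaps and unknown
#' characters are treated as missing data.
#'
#' @param tree An \code{ape::phylo} tree with branch lengths; tip labels
#'   must be row names of \code{msa}.
#' @param msa Character MSA matrix.
#' @param models A \code{site_models} object.
#' @param site_map Integer vector mapping alignment columns to entries of
#'   \code{models} (default 1:L); sites sharing a model are batched.
#' @return Scalar log-likelihood.
#' @export
pruning_loglik <- function(tree, msa, models, site_map = NULL) {
  if (is.null(site_map)) site_map <- seq_len(ncol(msa))
  stopifnot(length(site_map) == ncol(msa))
  if (!all(tree$tip.label %in% rownames(msa)))
    stop("tree tips missing from the alignment: ",
         paste(setdiff(tree$tip.label, rownames(msa)), collapse = ","))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  X <- .aa_index_matrix(msa[tree$tip.label, , drop = FALSE])
  total <- 0
  for (mid in unique(site_map)) {
    sites <- which(site_map == mid)
    ns <- length(sites)
    ed <- .site_eigen(models, mid)
    rootP <- models$P[mid, ]
    # partial likelihood per node: ns x 20
    part <- vector("list", nnode)
    logscale <- numeric(ns)
    for (tip in seq_len(ntip)) {
      Lk <- matrix(0, ns, 20)
      st <- X[tip, sites]
      miss <- is.na(st)
      Lk[cbind(which(!miss), st[!miss])] <- 1
      Lk[miss, ] <- 1
      part[[tip]] <- Lk
    }
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      tb <- tree$edge.length[e]
      Pt <- ed$right %*% (exp(tb * ed$values) * ed$left)
      Pt[Pt < 0] <- 0
      M <- part[[child]] %*% t(Pt)
      if (is.null(part[[par]])) part[[par]] <- M
      else part[[par]] <- part[[par]] * M
      # rescale to avoid underflow
      mx <- apply(part[[par]], 1, max)
      bad <- mx < 1e-200
      mx[bad] <- 1
      part[[par]] <- part[[par]] / mx
      logscale <- logscale + log(mx)
    }
    root <- ntip + 1L
    lik <- drop(part[[root]] %*% rootP)
    total <- total + sum(log(lik) + logscale)
  }
  total
}

#' Fit the likelihood-vs-tree-length slope mu
#'
#' Least-squares slope of log-likelihood against the sum of branch lengths
#' over a collection of trees; used as the regularization weight of the
#' RegMLaME score.
#'
#' @param loglik Numeric vector of tree log-likelihoods.
#' @param branch_sum Numeric vector of branch-length sums.
#' @return Scalar slope.
#' @export
fit_mu <- function(loglik, branch_sum) {
  stopifnot(length(loglik) == length(branch_sum), length(loglik) >= 2)
  if (stats::sd(branch_sum) < 1e-14)
    stop("identical branch sums: slope undefined")
  unname(stats::coef(stats::lm(loglik ~ branch_sum))[2])
}

#' Regularized ML-and-minimum-evolution tree score
#'
#' RegMLaME = -loglik + mu * sum of branch lengths. With mu = 0 this is the
#' negative log-likelihood; larger mu penalizes longer trees (equivalently,
#' the maximum-posterior score under an exponential branch-length prior).
#'
#' @inheritParams pruning_loglik
#' @param mu Regularization weight (>= 0).
#' @return Object of class \code{tree_score}: list with \code{loglik},
#'   \code{branch_sum}, \code{mu}, \code{regmlame}.
#' @export
regmlame <- function(tree, msa, models, mu = 0, site_map = NULL) {
  ll <- pruning_loglik(tree, msa, models, site_map)
  bs <- sum(tree$edge.length)
  structure(list(loglik = ll, branch_sum = bs, mu = mu,
                 regmlame = -ll + mu * bs),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("tree_score: loglik %.4f, branch sum %.4f, mu %.3g, RegMLaME %.4f\n",
              x$loglik, x$branch_sum, x$mu, x$regmlame))
  invisible(x)
}

#' Optimize branch lengths of a fixed topology
#'
#' Cyclic one-dimensional (Brent) optimization of each branch length of
#' -loglik + mu * sum(t), keeping the topology fixed. mu = 0 gives ML branch
#' lengths; mu > 0 the RegMLaME-optimal ones.
#'
#' @inheritParams regmlame
#' @param t_max Upper branch-length bound.
#' @param tol Convergence tolerance on the score.
#' @param max_cycles Maximum sweeps over all branches.
#' @return The tree with optimized \code{edge.length} (attribute
#'   \code{"score"} holds the final \code{tree_score}).
#' @export
optimize_branch_lengths <- function(tree, msa, models, mu = 0,
                                    site_map = NULL, t_max = 10,
                                    tol = 1e-8, max_cycles = 50) {
  obj <- function(tr) -pruning_loglik(tr, msa, models, site_map) +
    mu * sum(tr$edge.length)
  cur <- obj(tree)
  for (cyc in seq_len(max_cycles)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tr <- tree
        tr$edge.length[e] <- t
        obj(tr)
      }
      op <- stats::optimize(f, c(0, t_max), tol = 1e-8)
      if (op$objective < cur) {
        tree$edge.length[e] <- op$minimum
        cur <- op$objective
      }
    }
    if (prev - cur < tol) break
  }
  if (cyc == max_cycles && prev - cur >= tol)
    warning("branch-length optimization did not converge; residual ",
            signif(prev - cur, 3))
  attr(tree, "score") <- structure(
    list(loglik = -(cur - mu * sum(tree$edge.length)),
         branch_sum = sum(tree$edge.length), mu = mu, regmlame = cur),
    class = "tree_score")
  tree
}

# branch table of an unrooted tree: one row per branch with a canonical
# bipartition key (terminal branches keyed by tip label); lengths of
# duplicate keys (the two root edges of a rooted binary tree) are summed.
.branch_table <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + po$Nnode)
  for (tip in seq_len(ntip)) desc[[tip]] <- po$tip.label[tip]
  keys <- character(0)
  lengths <- numeric(0)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    dd <- if (child <= ntip) desc[[child]]
          else desc[[child]]
    desc[[par]] <- c(desc[[par]], dd)
    if (child <= ntip) {
      key <- paste0("tip:", po$tip.label[child])
    } else {
      side <- sort(dd)
      if (labs[1] %in% side) side <- setdiff(labs, side)
      if (length(side) <= 1) next   # trivial split: skip (terminal covers it)
      key <- paste(side, collapse = "|")
    }
    keys <- c(keys, key)
    lengths <- c(lengths, po$edge.length[e])
  }
  stats::aggregate(list(length = lengths), list(key = keys), sum)
}

# rows of the joint branch frame: matched branches plus unmatched ones
# represented with a zero length on the missing side
.branch_frame <- function(reference, comparison) {
  tr <- .branch_table(reference)
  tc <- .branch_table(comparison)
  all_keys <- union(tr$key, tc$key)
  data.frame(key = all_keys,
             t_ref = tr$length[match(all_keys, tr$key)],
             t_comp = tc$length[match(all_keys, tc$key)]) |>
    transform(t_ref = ifelse(is.na(t_ref), 0, t_ref),
              t_comp = ifelse(is.na(t_comp), 0, t_comp))
}

#' One-parameter branch-length comparison (K score)
#'
#' Matches branches of the two trees by bipartition, fits a single scale s
#' minimizing sum (t_comp - s t_ref)^2 (unmatched branches enter with zero
#' length on the missing side, i.e. as unscalable error mass), and returns
#' the root-mean-square error normalized by the sum of squared reference
#' branch lengths.
#'
#' @param reference,comparison \code{ape::phylo} trees on the same leaf set.
#' @return List with \code{k}, \code{scale}, \code{n_matched}.
#' @export
k_score <- function(reference, comparison) {
  if (!setequal(reference$tip.label, comparison$tip.label))
    stop("trees must share the same leaf set")
  bf <- .branch_frame(reference, comparison)
  denom <- sum(bf$t_ref^2)
  if (denom == 0) stop("reference tree has zero branch lengths")
  s <- sum(bf$t_ref * bf$t_comp) / denom
  sse <- sum((bf$t_comp - s * bf$t_ref)^2)
  list(k = sqrt(sse / denom), scale = s,
       n_matched = sum(bf$t_ref > 0 & bf$t_comp > 0))
}

#' Two-parameter branch-length comparison (K2 score)
#'
#' Extends the K score with two scale factors and a two-class partition of
#' the branches (slow, function-conserving versus fast, function-changing).
#' Classes may be supplied per branch or fitted by alternating
#' assignment/least-squares seeded from the single-scale residual split; the
#' single-scale solution is always a candidate, so K2 <= K.
#'
#' @inheritParams k_score
#' @param classes Optional: named vector (by bipartition key) or integer
#'   vector of 1/2 class labels for the branch frame rows.
#' @return Object of class \code{tree_comparison}: list with \code{k2},
#'   \code{k}, \code{scale_1param}, \code{scale_slow}, \code{scale_fast},
#'   \code{branch_class}, \code{rf_norm}.
#' @export
k2_score <- function(reference, comparison, classes = NULL) {
  ks <- k_score(reference, comparison)
  bf <- .branch_frame(reference, comparison)
  denom <- sum(bf$t_ref^2)
  fit2 <- function(cl) {
    s <- numeric(2)
    for (c2 in 1:2) {
      w <- cl == c2
      s[c2] <- if (sum(bf$t_ref[w]^2) > 0)
        sum(bf$t_ref[w] * bf$t_comp[w]) / sum(bf$t_ref[w]^2) else 0
    }
    sse <- sum((bf$t_comp - s[cl] * bf$t_ref)^2)
    list(s = s, sse = sse)
  }
  if (is.null(classes)) {
    resid <- bf$t_comp - ks$scale * bf$t_ref
    cl <- ifelse(resid > 0, 2L, 1L)
    if (length(unique(cl)) < 2) {
      warning("degenerate residual split; falling back to the K score")
      cl <- rep(1L, nrow(bf))
    }
    best <- fit2(cl)
    for (it in 1:50) {
      r1 <- (bf$t_comp - best$s[1] * bf$t_ref)^2
      r2 <- (bf$t_comp - best$s[2] * bf$t_ref)^2
      cl_new <- ifelse(r2 < r1, 2L, 1L)
      if (all(cl_new == cl)) break
      cl <- cl_new
      if (length(unique(cl)) < 2) break
      best <- fit2(cl)
    }
  } else {
    cl <- if (is.null(names(classes))) as.integer(classes)
          else as.integer(classes[bf$key])
    if (anyNA(cl)) stop("classes must cover every branch key")
    best <- fit2(cl)
  }
  # the single-scale solution is always admissible
  sse1 <- sum((bf$t_comp - ks$scale * bf$t_ref)^2)
  if (best$sse > sse1) {
    best <- list(s = c(ks$scale, ks$scale), sse = sse1)
    cl <- rep(1L, nrow(bf))
  }
  sl <- sort(best$s)
  structure(list(k2 = sqrt(best$sse / denom), k = ks$k,
                 scale_1param = ks$scale,
                 scale_slow = sl[1], scale_fast = sl[2],
                 branch_class = stats::setNames(cl, bf$key),
                 rf_norm = tryCatch(rf_normalized(reference, comparison),
                                    error = function(e) NA_real_)),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("tree_comparison: K %.4f, K2 %.4f, scales %.3f/%.3f, RF %.3f\n",
              x$k, x$k2, x$scale_slow, x$scale_fast, x$rf_norm))
  invisible(x)
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions divided by
#' 2 (n - 3); 0 for identical topologies, 1 for maximally different binary
#' topologies.
#'
#' @inheritParams k_score
#' @param t1,t2 Trees on the same leaf set with n >= 4 leaves.
#' @return Scalar in [0, 1].
#' @export
rf_normalized <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  n <- length(t1$tip.label)
  if (n < 4) stop("RF distance requires at least 4 leaves")
  split_set <- function(tr) {
    bt <- .branch_table(tr)
    bt$key[!startsWith(bt$key, "tip:")]
  }
  s1 <- split_set(t1)
  s2 <- split_set(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  d / (2 * (n - 3))
}
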