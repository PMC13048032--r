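# Methods for fitted sscpe objects.

#' @export
print.sscpe <- function(x, ...) {
  cat(sprintf("sscpe fit: model %s, %d columns, %d sequences, %d structure(s)\n",
              x$model, nrow(x$P), nrow(x$msa), length(x$structures)))
  if (length(x$lambda))
    cat("  Lambda:", paste(sprintf("%s = %.4f", names(x$lambda), x$lambda),
                           collapse = ", "),
        if (!is.null(x$reg)) sprintf(" (R = %.4g)", x$reg$chosen_R) else "",
        "\n")
  cat(sprintf("  symmetric KL per site: %.4f  mean entropy: %.4f\n",
              x$kl, mean(x$entropy)))
  o <- x$models$options
  cat(sprintf("  exchangeability: %s%s%s on %s\n",
              if (o["hb"]) "HB" else "noHB", if (o["fl"]) "+FL" else "+noFL",
              if (o["rate1"]) "+rate1" else "+rate0", x$empirical$name))
  invisible(x)
}

#' @export
summary.sscpe <- function(object, ...) {
  out <- list(model = object$model, lambda = object$lambda,
              chosen_R = if (!is.null(object$reg)) object$reg$chosen_R else NA,
              kl = object$kl, ll = object$ll,
              n_col = nrow(object$P), n_seq = nrow(object$msa),
              n_struct = length(object$structures),
              mean_entropy = mean(object$entropy),
              mean_rate = mean(object$rates),
              p_glob = object$p_glob,
              options = object$models$options,
              empirical = object$empirical$name,
              summary_table = object$summary)
  class(out) <- "summary.sscpe"
  out
}

#' @export
print.summary.sscpe <- function(x, ...) {
  cat(sprintf("Site-specific profile model %s\n", x$model))
  cat(sprintf("  %d columns, %d sequences, %d structure(s)\n",
              x$n_col, x$n_seq, x$n_struct))
  if (length(x$lambda))
    cat("  selection parameters:",
        paste(sprintf("%s = %.4f", names(x$lambda), x$lambda), collapse = ", "),
        sprintf("(ridge R = %.4g)\n", x$chosen_R))
  cat(sprintf("  symmetric KL/site %.4f, profile loglik/site %.4f\n",
              x$kl, x$ll))
  cat(sprintf("  mean site entropy %.4f, mean predicted rate %.4f\n",
              x$mean_entropy, x$mean_rate))
  cat("  option ranking by approximate likelihood:\n")
  print(utils::head(x$summary_table, 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.sscpe <- function(object, ...) {
  c(object$lambda, p_glob = unname(object$p_glob))
}

#' @export
logLik.sscpe <- function(object, ...) {
  # log-likelihood of the observed residues under the site profiles
  aa <- aa_alphabet()
  ll <- 0
  n <- 0
  for (i in seq_len(ncol(object$msa))) {
    x <- object$msa[, i]
    x <- x[x %in% aa]
    ll <- ll + sum(log(object$P[i, match(x, aa)]))
    n <- n + length(x)
  }
  structure(ll, df = length(object$lambda) + 19, nobs = n, class = "logLik")
}

#' @export
fitted.sscpe <- function(object, ...) object$P

#' @export
residuals.sscpe <- function(object, ...) object$msa_profile$f - object$P

#' Diagnostic plots for a fitted profile model
#'
#' Two base-graphics panels: site entropy against the native contact number
#' of the site, and the fitted stationary frequencies against the observed
#' MSA frequencies.
#'
#' @param x A fitted \code{sscpe} object.
#' @param which Panels to draw (subset of 1:2).
#' @param ... Passed to \code{plot}.
#' @export
plot.sscpe <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    ok <- !is.na(x$contacts)
    plot(x$contacts[ok], x$entropy[ok], xlab = "native contacts n_i",
         ylab = "site entropy S_i", main = x$model, ...)
    if (sum(ok) > 3)
      graphics::lines(stats::lowess(x$contacts[ok], x$entropy[ok]),
                      col = 2, lwd = 2)
  }
  if (2 %in% which) {
    plot(as.vector(x$msa_profile$f), as.vector(x$P),
         xlab = "observed MSA frequency", ylab = "fitted frequency",
         log = "xy", pch = ".", ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Simulate alignments from a fitted profile model
#'
#' Columns are drawn from the fitted stationary distributions, either
#' i.i.d. (\code{nsim} sequences) or along a tree with the fitted
#' site-specific substitution models.
#'
#' @param object A fitted \code{sscpe} object.
#' @param nsim Number of sequences (i.i.d. mode).
#' @param seed Integer seed.
#' @param tree Optional \code{ape::phylo} tree; if given, one sequence per
#'   leaf is evolved with the fitted site models.
#' @param ... Unused.
#' @return Character MSA matrix.
#' @export
simulate.sscpe <- function(object, nsim = 100, seed = 1, tree = NULL, ...) {
  sample_msa(object$P, n_seq = nsim, tree = tree,
             models = if (!is.null(tree)) object$models else NULL,
             seed = seed)
}
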