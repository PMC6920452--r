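#' Generate a pseudo-observed dataset under the null
#'
#' Allocates the template's `N` observations independently to cells, with
#' cell probability proportional to the product of the template's row and
#' column marginal frequencies (`allocation = "margin"`, the independence
#' null whose expected margins match the template) or uniform over cells
#' (`allocation = "uniform"`). Realizations with an empty row or column —
#' for which the fixed-margin test is undefined — are discarded and
#' redrawn; the number discarded is returned as an attribute.
#'
#' @param template a [contingency_matrix()] providing shape, N and margins.
#' @param allocation `"margin"` or `"uniform"`.
#' @param max_tries redraw limit.
#' @return a [contingency_matrix()] of the template's shape and total,
#'   with attribute `"n_excluded"` (discarded realizations).
#' @export
generate_pseudo_dataset <- function(template,
                                    allocation = c("margin", "uniform"),
                                    max_tries = 100000L) {
  allocation <- match.arg(allocation)
  template <- if (inherits(template, "contingency_matrix")) template else
    contingency_matrix(template)
  N <- sum(template)
  R <- nrow(template); C <- ncol(template)
  prob <- if (allocation == "margin")
    as.vector(outer(rowSums(template), colSums(template))) / N^2 else
      rep(1 / (R * C), R * C)

  excluded <- 0L
  repeat {
    cells <- as.vector(stats::rmultinom(1L, N, prob))
    m <- matrix(cells, R, C, dimnames = dimnames(template))
    if (all(rowSums(m) > 0L) && all(colSums(m) > 0L)) break
    excluded <- excluded + 1L
    if (excluded >= max_tries)
      stop("exceeded ", max_tries, " redraws: empty margins too likely ",
           "for this template")
  }
  out <- contingency_matrix(m)
  attr(out, "n_excluded") <- excluded
  out
}

#' Self-validation of the null model
#'
#' Confirms the Type I / Type II error behaviour of the fixed-margin
#' randomization test by repeatedly generating pseudo-observed tables
#' under the null ([generate_pseudo_dataset()]), running the whole-table
#' test on each, and summarising the resulting P-values: the rejection
#' rate at `alpha` should match `alpha`, and the P-value distribution
#' should be rectangular (flat) up to the discreteness of the permutation
#' P.
#'
#' @param template a [contingency_matrix()]; its shape and margins define
#'   the pseudo-data generator (study scale: the 25 x 11, N = 226 table).
#' @param n_tests number of pseudo-datasets analysed (full scale 10000).
#' @param reps_per_test random tables per test (full scale 10000).
#' @param alpha nominal significance level (default 0.05).
#' @param seed integer seed for the whole harness.
#' @param allocation pseudo-data allocation rule, see
#'   [generate_pseudo_dataset()].
#' @param n_bins histogram bins for the uniformity summary.
#' @return an object of class `null_validation`: `n_tests`,
#'   `reps_per_test`, `alpha`, `rejection_rate`, `p_values`,
#'   `p_histogram`, `uniformity_statistic` (chi-squared goodness-of-fit
#'   against uniform bin counts), `uniformity_p`, `n_excluded` (total
#'   discarded pseudo-tables).
#' @examples
#' tpl <- simulate_matrix(sim_config(5, 3, 80, seed = 2), require_full = TRUE)
#' v <- validate_null(tpl, n_tests = 50, reps_per_test = 200, seed = 3)
#' v$rejection_rate
#' @export
validate_null <- function(template, n_tests = 10000L,
                          reps_per_test = 10000L, alpha = 0.05,
                          seed = NULL,
                          allocation = c("margin", "uniform"),
                          n_bins = 20L) {
  allocation <- match.arg(allocation)
  stopifnot(n_tests >= 1L, reps_per_test >= 1L, alpha >= 0, alpha <= 1)
  template <- if (inherits(template, "contingency_matrix")) template else
    contingency_matrix(template)
  if (!is.null(seed)) set.seed(seed)
  # independent child seed per test keeps each replicate replayable
  child_seeds <- sample.int(.Machine$integer.max, 2L * n_tests)

  p_values <- numeric(n_tests)
  n_excluded <- 0L
  for (t in seq_len(n_tests)) {
    set.seed(child_seeds[2L * t - 1L])
    pseudo <- generate_pseudo_dataset(template, allocation)
    n_excluded <- n_excluded + attr(pseudo, "n_excluded")
    p_values[t] <- whole_table_p(pseudo, reps_per_test,
                                 seed = child_seeds[2L * t])
  }

  # significance level 0 rejects nothing, even though two-tailed
  # permutation P-values can be exactly 0
  rejection_rate <- if (alpha <= 0) 0 else mean(p_values <= alpha)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  hist_counts <- table(cut(p_values, breaks, include.lowest = TRUE))
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(hist_counts),
                      p = rep(1 / n_bins, n_bins)))
  structure(list(n_tests = n_tests, reps_per_test = reps_per_test,
                 alpha = alpha, rejection_rate = rejection_rate,
                 p_values = p_values,
                 p_histogram = stats::setNames(as.vector(hist_counts),
                                               names(hist_counts)),
                 uniformity_statistic = unname(gof$statistic),
                 uniformity_p = gof$p.value,
                 n_excluded = n_excluded, allocation = allocation,
                 seed = seed),
            class = "null_validation")
}

# fast path: whole-table permutation P only (no cell statistics)
whole_table_p <- function(x, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- rowSums(x); cc <- colSums(x)
  tabs <- rtables_fixed_margins(M, r, cc)
  flat <- matrix(unlist(tabs, use.names = FALSE), nrow = M, byrow = TRUE)
  mu <- colMeans(flat)
  if (any(mu == 0)) {
    # a cell never occupied across the stream: drop it from the statistic
    keep <- mu > 0
    flat <- flat[, keep, drop = FALSE]
    obs <- as.vector(unclass(x))[keep]
    mu <- mu[keep]
  } else obs <- as.vector(unclass(x))
  chi2_ran <- rowSums(sweep(flat, 2L, mu)^2 / rep(mu, each = M))
  chi2_obs <- sum((obs - mu)^2 / mu)
  two_tailed_p(sum(chi2_ran >= chi2_obs), sum(chi2_ran <= chi2_obs), M)
}

#' @export
print.null_validation <- function(x, ...) {
  cat("Null-model self-validation\n")
  cat(sprintf("  %d pseudo-datasets x %d randomizations each (%s allocation)\n",
              x$n_tests, x$reps_per_test, x$allocation))
  cat(sprintf("  rejection rate at alpha = %.3g: %.4f (expected %.3g)\n",
              x$alpha, x$rejection_rate, x$alpha))
  cat(sprintf("  P-value uniformity chi2 = %.2f (P = %.3f), %d bins\n",
              x$uniformity_statistic, x$uniformity_p,
              length(x$p_histogram)))
  cat(sprintf("  pseudo-tables discarded for empty margins: %d\n",
              x$n_excluded))
  invisible(x)
}

#' @method plot null_validation
#' @export
plot.null_validation <- function(x, ...) {
  graphics::hist(x$p_values, breaks = seq(0, 1, length.out = 21),
                 main = "Null P-value distribution", xlab = "P-value",
                 col = "grey80", ...)
  graphics::abline(h = x$n_tests / 20, lty = 2)
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param x a [validate_null()] result.
#' @param path output path.
#' @export
write_validation_report <- function(x, path) {
  jsonlite::write_json(
    list(n_tests = x$n_tests, reps_per_test = x$reps_per_test,
         alpha = x$alpha, rejection_rate = x$rejection_rate,
         p_histogram = as.list(x$p_histogram),
         uniformity_statistic = x$uniformity_statistic,
         uniformity_p = x$uniformity_p, n_excluded = x$n_excluded,
         allocation = x$allocation, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
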