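#' Sample a random table with fixed margins
#'
#' Draws a contingency table uniformly from the conditional (multivariate
#' hypergeometric) distribution of tables with the given row and column
#' totals, using Patefield's AS159 algorithm as implemented by
#' [stats::r2dtable()]. This is the null model of the spatial test: it
#' redistributes observations while holding both the per-haplotype and the
#' per-location sampling totals fixed.
#'
#' @param row_totals,col_totals non-negative integer margins; must sum to
#'   the same grand total.
#' @param n number of tables to draw.
#' @return for `n = 1` an integer matrix; otherwise a list of matrices.
#' @examples
#' sample_random_table(c(2, 2), c(2, 2))
#' @export
sample_random_table <- function(row_totals, col_totals, n = 1L) {
  row_totals <- as.integer(row_totals)
  col_totals <- as.integer(col_totals)
  if (any(row_totals < 0) || any(col_totals < 0))
    stop("margins must be non-negative")
  if (sum(row_totals) != sum(col_totals))
    stop("row and column totals disagree: ", sum(row_totals), " vs ",
         sum(col_totals))
  if (sum(row_totals) == 0L)
    stop("grand total must be positive")
  tabs <- rtables_fixed_margins(n, row_totals, col_totals)
  if (n == 1L) tabs[[1L]] else tabs
}

# r2dtable requires >= 2 rows and columns; single-margin tables are forced
rtables_fixed_margins <- function(n, r, cc) {
  if (length(r) == 1L)
    return(replicate(n, matrix(cc, 1L), simplify = FALSE))
  if (length(cc) == 1L)
    return(replicate(n, matrix(r, ncol = 1L), simplify = FALSE))
  stats::r2dtable(n, r, cc)
}

#' Build the null ensemble for a contingency matrix
#'
#' Accumulates, over `M` fixed-margin random tables, the per-cell null mean
#' and the tail counts needed for permutation P-values: per cell, how often
#' the randomized count was `>=` (and `<=`) the observed count; for the
#' whole table, how often the randomized chi-squared statistic was `>=`
#' (`<=`) the observed one. `mode = "analytic"` fills the means with the
#' closed form `r_i * c_j / N` (the classical independence expectation)
#' and leaves tail counts unset; it exists for speed and as an internal
#' oracle, the Monte-Carlo mode being the faithful procedure.
#'
#' The Monte-Carlo scheme is two-pass over a single table stream: pass one
#' accumulates the null means, pass two regenerates the same stream (same
#' seed) to count tails against those means, so that the randomized
#' statistics are measured against the ensemble's own expectation.
#'
#' @param x a [contingency_matrix()].
#' @param M number of random tables (study-scale default 10000).
#' @param mode `"monte_carlo"` or `"analytic"`.
#' @param seed optional integer seed for the table stream.
#' @return an object of class `null_ensemble` with elements `mean`,
#'   `n_ge`, `n_le` (per-cell tail counts), `chi2_ran` (the M randomized
#'   whole-table statistics), `M`, `mode`.
#' @export
build_null_ensemble <- function(x, M = 10000L,
                                mode = c("monte_carlo", "analytic"),
                                seed = NULL) {
  mode <- match.arg(mode)
  x <- if (inherits(x, "contingency_matrix")) x else contingency_matrix(x)
  r <- rowSums(x); cc <- colSums(x); N <- sum(x)

  if (mode == "analytic") {
    mu <- outer(r, cc) / N
    ens <- list(mean = mu, n_ge = NULL, n_le = NULL, chi2_ran = NULL,
                M = 0L, mode = mode, dim = dim(x))
    class(ens) <- "null_ensemble"
    return(ens)
  }

  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tabs <- rtables_fixed_margins(M, r, cc)
  # M x (R*C) layout: each row one flattened table
  flat <- matrix(unlist(tabs, use.names = FALSE), nrow = M, byrow = TRUE)
  mu_vec <- colMeans(flat)
  if (any(mu_vec == 0))
    stop("Monte-Carlo null mean of zero encountered; increase M or drop ",
         "the offending sparse cells")
  mu <- matrix(mu_vec, nrow(x), ncol(x), dimnames = dimnames(x))

  obs_vec <- as.vector(unclass(x))
  n_ge <- matrix(colSums(flat >= rep(obs_vec, each = M)), nrow(x), ncol(x),
                 dimnames = dimnames(x))
  n_le <- matrix(colSums(flat <= rep(obs_vec, each = M)), nrow(x), ncol(x),
                 dimnames = dimnames(x))
  chi2_ran <- rowSums(sweep(flat, 2L, mu_vec)^2 / rep(mu_vec, each = M))

  structure(list(mean = mu, n_ge = n_ge, n_le = n_le, chi2_ran = chi2_ran,
                 M = M, mode = mode, dim = dim(x)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble (%s), %d x %d table", x$mode,
              x$dim[1], x$dim[2]))
  if (x$mode == "monte_carlo") cat(sprintf(", M = %d tables", x$M))
  cat("\n")
  invisible(x)
}

#' Whole-table chi-squared statistic against the null mean
#'
#' `sum((Z_obs - Zbar_ran)^2 / Zbar_ran)` over all cells, where `Zbar_ran`
#' is the null-ensemble mean. With analytic means this is exactly the
#' Pearson chi-squared statistic.
#'
#' @param x a [contingency_matrix()].
#' @param ensemble a [build_null_ensemble()] result of matching shape.
#' @return a single non-negative number.
#' @export
chi_squared_obs <- function(x, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"),
            all(dim(x) == ensemble$dim))
  if (any(ensemble$mean <= 0))
    stop("null mean contains non-positive cells")
  sum((unclass(x) - ensemble$mean)^2 / ensemble$mean)
}

#' Per-cell difference from the null expectation
#'
#' The per-cell effect statistic: observed count minus its null-model mean.
#' Positive values mean the haplotype is more common at that location than
#' the fixed-margin null predicts, negative values less common. In analytic
#' mode every row and column of the result sums exactly to zero, because
#' the margins are fixed.
#'
#' @inheritParams chi_squared_obs
#' @return a numeric matrix of the same shape as `x`.
#' @export
ts_diff <- function(x, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"),
            all(dim(x) == ensemble$dim))
  unclass(x) - ensemble$mean
}

# two-tailed permutation p from inclusive tail counts, capped at 1
# (shape of the tail-count input is preserved)
two_tailed_p <- function(n_ge, n_le, M) {
  p <- pmin(n_ge, n_le) / M * 2
  p[p > 1] <- 1
  p
}
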