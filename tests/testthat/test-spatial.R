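test_that("fixed-margin sampling honours forced tables and margin mismatches", {
  expect_equal(sample_random_table(3, 3), matrix(3))
  expect_equal(sample_random_table(c(1, 1), c(2, 0)),
               matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(sample_random_table(c(2, 1), c(1, 1)), "disagree")
  expect_error(sample_random_table(c(0, 0), c(0, 0)), "positive")
})

test_that("sampled tables follow the conditional hypergeometric distribution", {
  # margins [2,2]/[2,2]: top-left cell is 0/1/2 with probability 1/6, 4/6, 1/6
  set.seed(101)
  n <- 60000
  tl <- vapply(sample_random_table(c(2, 2), c(2, 2), n = n),
               function(m) m[1, 1], numeric(1))
  p_exp <- c(`0` = 1 / 6, `1` = 4 / 6, `2` = 1 / 6)
  p_obs <- table(factor(tl, levels = 0:2)) / n
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_true(all(abs(as.vector(p_obs) - p_exp) <= 3 * se))
})

test_that("every sampled table preserves both margins exactly", {
  set.seed(103)
  for (k in 1:10) {
    m <- random_count_matrix(sample(2:6, 1), sample(2:5, 1), sample(20:80, 1))
    tabs <- sample_random_table(rowSums(m), colSums(m), n = 50)
    expect_true(all(vapply(tabs, function(t)
      all(rowSums(t) == rowSums(m)) && all(colSums(t) == colSums(m)),
      logical(1))))
  }
})

test_that("null ensemble means: analytic closed form and Monte-Carlo convergence", {
  m <- contingency_matrix(matrix(c(1, 1, 1, 1), 2, 2))
  ens <- build_null_ensemble(m, mode = "analytic")
  expect_equal(unname(ens$mean), matrix(1, 2, 2))

  # single-row matrix: mean equals the column totals
  m1 <- contingency_matrix(matrix(c(3, 5, 2), 1, 3))
  expect_equal(unname(build_null_ensemble(m1, mode = "analytic")$mean),
               matrix(c(3, 5, 2), 1, 3))
  mc1 <- build_null_ensemble(m1, M = 10, seed = 1)
  expect_equal(unname(mc1$mean), matrix(c(3, 5, 2), 1, 3))

  # MC mean approaches the analytic mean within 3 SE of the
  # multivariate-hypergeometric cell variance
  m2 <- contingency_matrix(random_count_matrix(4, 3, 120))
  M <- 10000
  mc <- build_null_ensemble(m2, M = M, seed = 11)
  an <- build_null_ensemble(m2, mode = "analytic")
  r <- rowSums(m2); cc <- colSums(m2); N <- sum(m2)
  v <- outer(r, cc) * outer(N - r, N - cc) / (N^2 * (N - 1))
  expect_true(all(abs(mc$mean - an$mean) <= 3 * sqrt(v / M)))
})

test_that("whole-table statistic matches hand values and the Pearson oracle", {
  m0 <- contingency_matrix(matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(chi_squared_obs(m0, build_null_ensemble(m0, mode = "analytic")),
               0)
  m1 <- contingency_matrix(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(chi_squared_obs(m1, build_null_ensemble(m1, mode = "analytic")),
               2)
  set.seed(107)
  for (k in 1:10) {
    m <- contingency_matrix(random_count_matrix(sample(3:6, 1),
                                                sample(2:4, 1), 100))
    pearson <- suppressWarnings(
      stats::chisq.test(unclass(m), correct = FALSE)$statistic)
    expect_equal(chi_squared_obs(m, build_null_ensemble(m, mode = "analytic")),
                 unname(pearson), tolerance = 1e-9)
  }
})

test_that("per-cell differences have zero row/column sums under analytic means", {
  m1 <- contingency_matrix(matrix(c(3, 1, 1, 3), 2, 2))
  td1 <- ts_diff(m1, build_null_ensemble(m1, mode = "analytic"))
  expect_equal(unname(td1), matrix(c(1, -1, -1, 1), 2, 2))
  set.seed(109)
  for (k in 1:8) {
    m <- contingency_matrix(random_count_matrix(5, 4, 90))
    td <- ts_diff(m, build_null_ensemble(m, mode = "analytic"))
    expect_equal(unname(rowSums(td)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(colSums(td)), rep(0, 4), tolerance = 1e-12)
  }
})

test_that("degenerate tables give capped P-values", {
  # a 1x1 table is forced: observed equals every randomization, P caps at 1
  st <- spatial_test(contingency_matrix(matrix(5)), M = 200, seed = 5)
  expect_equal(st$chi2_obs, 0)
  expect_equal(st$p_whole, 1)
  expect_equal(unname(st$p_cell), matrix(1))
  expect_false(any(st$significant))
})

test_that("whole-table and cell P-values match exact 2x2 enumeration", {
  # margins [2,2]/[2,2] admit three tables with top-left 0/1/2 at
  # probabilities 1/6, 4/6, 1/6; chi2 (analytic means all 1) is 4, 0, 4.
  # For observed [[2,0],[0,2]]: P(chi2 >= 4) = 1/3, P(chi2 <= 4) = 1,
  # two-tailed P = 2/3; cell (1,1): P(X >= 2) = 1/6, P(X <= 2) = 1 -> 1/3.
  m <- contingency_matrix(matrix(c(2, 0, 0, 2), 2, 2))
  M <- 6000
  st <- spatial_test(m, M = M, means = "analytic", seed = 13)
  se_whole <- 2 * sqrt((1 / 3) * (2 / 3) / M)
  expect_lt(abs(st$p_whole - 2 / 3), 3 * se_whole)
  se_cell <- 2 * sqrt((1 / 6) * (5 / 6) / M)
  expect_lt(abs(st$p_cell[1, 1] - 1 / 3), 3 * se_cell)
})

test_that("identical seeds give identical tests; P-values never exceed 1", {
  m <- contingency_matrix(random_count_matrix(4, 3, 80))
  s1 <- spatial_test(m, M = 500, seed = 99)
  s2 <- spatial_test(m, M = 500, seed = 99)
  expect_identical(s1$p_cell, s2$p_cell)
  expect_identical(s1$chi2_obs, s2$chi2_obs)
  expect_true(all(s1$p_cell <= 1) && s1$p_whole <= 1)
  expect_true(all(s1$p_cell >= 0))
})

test_that("analytic results are invariant under row/column permutation", {
  m <- random_count_matrix(5, 4, 100)
  pr <- sample(5); pc <- sample(4)
  mp <- m[pr, pc]
  c1 <- chi_squared_obs(contingency_matrix(m),
                        build_null_ensemble(contingency_matrix(m),
                                            mode = "analytic"))
  c2 <- chi_squared_obs(contingency_matrix(mp),
                        build_null_ensemble(contingency_matrix(mp),
                                            mode = "analytic"))
  expect_equal(c1, c2, tolerance = 1e-12)
  td <- ts_diff(contingency_matrix(m),
                build_null_ensemble(contingency_matrix(m), mode = "analytic"))
  tdp <- ts_diff(contingency_matrix(mp),
                 build_null_ensemble(contingency_matrix(mp),
                                     mode = "analytic"))
  expect_equal(unname(tdp), unname(td[pr, pc]), tolerance = 1e-12)
})

test_that("BH calls match the brute-force step-up oracle", {
  expect_false(any(fdr_calls(rep(1, 20), q = 0.1)))
  p <- c(0.001, 0.02, 0.03, 0.04, rep(0.5, 16))
  expect_identical(unname(fdr_calls(p, q = 0.05)), brute_bh(p, 0.05))
  set.seed(111)
  for (k in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(unname(fdr_calls(p, q)), brute_bh(p, q))
  }
})

test_that("pooling locations preserves rows and the grand total", {
  m <- contingency_matrix(random_count_matrix(5, 4, 70))
  ident <- stats::setNames(colnames(m), colnames(m))
  expect_equal(unclass(pool_locations(m, ident)), unclass(m))
  grouping <- stats::setNames(c("g1", "g1", "g2", "g2"), colnames(m))
  pooled <- pool_locations(m, grouping)
  expect_equal(sum(pooled), sum(m))
  expect_equal(unname(rowSums(pooled)), unname(rowSums(m)))
  expect_equal(ncol(pooled), 2)
  expect_error(pool_locations(m, grouping[-1]), "no group assigned")
})

test_that("empty rows and columns are dropped with a warning before testing", {
  m <- matrix(c(2, 0, 3, 0, 0, 0, 1, 0, 4), 3, 3)
  expect_warning(cm <- contingency_matrix(m), "empty")
  expect_equal(dim(cm), c(2, 2))
  expect_true(all(rowSums(cm) > 0) && all(colSums(cm) > 0))
})

test_that("structured matrices are detected while direction tracks the sign", {
  m <- contingency_matrix(matrix(c(20, 2, 2, 20), 2, 2))
  st <- spatial_test(m, M = 2000, seed = 17)
  expect_lt(st$p_whole, 0.01)
  expect_identical(unname(st$direction),
                   matrix(c("over", "under", "under", "over"), 2, 2))
})
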