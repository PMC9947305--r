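test_that("colony mortality table reproduces the published chi-squared", {
  tab <- matrix(c(69, 178, 40, 209), nrow = 2, byrow = TRUE)
  r <- chisq_test(tab, yates = TRUE)
  expect_equal(r$statistic, 9.510, tolerance = 1e-3)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, 0.002, tolerance = 0.05)

  # hand-computed Pearson oracle, no correction
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson <- sum((tab - expected)^2 / expected)
  r2 <- chisq_test(tab, yates = FALSE)
  expect_equal(r2$statistic, pearson, tolerance = 1e-10)
  expect_equal(pearson, 10.19, tolerance = 1e-2)
})

test_that("degenerate and invalid contingency tables behave", {
  r <- chisq_test(matrix(5, 2, 2), yates = FALSE, monte_carlo_B = 200, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$mc_p, 1)
  expect_error(chisq_test(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
  expect_error(chisq_test(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
})

test_that("Monte Carlo p converges to the asymptotic p on balanced tables", {
  # 100-per-cell null table: statistic 0, both p values exactly 1
  r <- chisq_test(matrix(100, 2, 2), yates = FALSE, monte_carlo_B = 20000, seed = 42)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$mc_p, 1)
  # large balanced table with mild signal: |MC - asymptotic| < 0.02
  tab <- matrix(1000, 2, 2); tab[1, 1] <- 1040; tab[2, 2] <- 1040
  r2 <- chisq_test(tab, yates = FALSE, monte_carlo_B = 20000, seed = 42)
  expect_gte(r2$mc_p, 1 / 20001)
  expect_lt(abs(r2$mc_p - r2$p_value), 0.02)
})

test_that("closed-form factor deviance matches known values", {
  # single level, 5 deaths / 10 bees: D = 2 * 10 * ln 2
  f <- fit_factor_logit(rep(c(0, 1), each = 5), rep("a", 10))
  expect_equal(f$deviance, 20 * log(2), tolerance = 1e-12)

  # perfectly separated cells fit exactly
  f2 <- fit_factor_logit(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_equal(f2$deviance, 0)

  # two levels both at 0.5 carry no between-level information
  y <- rep(c(0, 1, 0, 1), each = 2)
  f3 <- fit_factor_logit(y, rep(c("a", "b"), each = 4))
  f0 <- fit_factor_logit(y, rep("all", 8))
  expect_equal(f3$deviance, f0$deviance, tolerance = 1e-12)

  expect_error(fit_factor_logit(c(1, 0), factor(c("a", "a"), levels = c("a", "b"))),
               "empty")
})

test_that("closed-form and iterative fits agree on random factor designs", {
  set.seed(99)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    n <- sample(20:80, 1)
    f <- sample(letters[1:k], n, TRUE)
    y <- rbinom(n, 1, runif(k)[match(f, letters[1:k])])
    if (length(unique(f)) < 2) next
    a <- fit_factor_logit(y, f, method = "cells")
    b <- fit_factor_logit(y, f, method = "irls")
    expect_lt(abs(a$deviance - b$deviance), 1e-8)
  }
})

test_that("deviance partition shares sum to one and double to H2", {
  cfg <- sim_config(seed = 77, n_control = 0)
  w <- simulate_colonies(cfg)$workers
  p <- partition_deviance(w$survived, w$colony, w$true_patriline)
  expect_equal(p$share_colony + p$share_patriline + p$share_residual, 1,
               tolerance = 1e-10)
  expect_true(p$share_colony >= -1e-12 && p$share_patriline >= -1e-12)
  expect_equal(p$h2, 2 * p$share_patriline)
  expect_gte(p$h2_corrected, 0)

  # invariant to relabeling of colonies and patrilines
  perm_c <- stats::setNames(c("X", "Y"), unique(w$colony))
  perm_p <- stats::setNames(sample(paste0("Z", seq_along(unique(w$true_patriline)))),
                            unique(w$true_patriline))
  p2 <- partition_deviance(w$survived, perm_c[w$colony], perm_p[w$true_patriline])
  expect_equal(p$share_patriline, p2$share_patriline, tolerance = 1e-12)
})

test_that("published share triplets give the published H2 values", {
  p1 <- partition_from_shares(0.020, 0.189, 0.791)
  expect_equal(p1$h2, 0.378, tolerance = 1e-12)
  p2 <- partition_from_shares(0.022, 0.172, 0.806)
  expect_equal(p2$h2, 0.344, tolerance = 1e-12)
  expect_error(partition_from_shares(0.5, 0.5, 0.5), "sum to 1")
})

test_that("a patriline spanning colonies violates nesting", {
  expect_error(partition_deviance(c(0, 1, 0, 1), c("A", "A", "B", "B"),
                                  c("p1", "p1", "p1", "p2")), "nesting|span")
})

test_that("with no patriline effects the corrected share is near zero", {
  cfg <- sim_config(n_colonies = 1, workers_per_colony = 2000, k_patrilines = 20,
                    sigma_patriline = 0, sigma_colony = 0, seed = 15, n_control = 0)
  w <- simulate_colony(cfg)$workers
  p <- partition_deviance(w$survived, w$colony, w$true_patriline)
  expect_lt(p$share_patriline_corrected, 0.02)
})

test_that("the minimum-workers filter keeps exactly the large patrilines", {
  d <- data.frame(patriline = rep(c("a", "b", "c", "d"), c(6, 5, 4, 1)))
  out <- filter_min_workers(d, 5)
  expect_setequal(unique(out$patriline), c("a", "b"))
  expect_equal(attr(out, "n_patrilines_kept"), 2L)
  expect_identical(filter_min_workers(d, 1)$patriline, d$patriline)
  expect_warning(out2 <- filter_min_workers(d, 10), "no patriline")
  expect_equal(nrow(out2), 0L)
})

test_that("type-II analysis of deviance matches sequential and oracle fits", {
  set.seed(21)
  n <- 120
  colony <- sample(c("C1", "C2"), n, TRUE)
  pat <- paste0(colony, "_", sample(1:4, n, TRUE))
  y <- rbinom(n, 1, ifelse(pat %in% c("C1_1", "C2_2"), 0.8, 0.4))

  # single term: type-II LR equals the sequential null-vs-term difference
  a1 <- anodev_type2(y, list(patriline = pat))
  d_null <- fit_factor_logit(y, rep("all", n))$deviance
  d_pat <- fit_factor_logit(y, pat)$deviance
  expect_equal(a1$lr_chisq, d_null - d_pat, tolerance = 1e-8)
  expect_equal(a1$df, length(unique(pat)) - 1L)

  # nested two-term design: LR for the nested term matches the closed-form
  # cell-mean two-fit oracle
  a2 <- anodev_type2(y, list(colony = colony, patriline = pat))
  d_col <- fit_factor_logit(y, colony)$deviance
  row_pat <- a2[a2$term == "patriline", ]
  expect_equal(row_pat$lr_chisq, d_col - d_pat, tolerance = 1e-8)

  # aliased term: a duplicate of another term is flagged
  a3 <- anodev_type2(y, list(p1 = pat, p2 = pat))
  expect_true(all(a3$aliased))
  expect_true(all(a3$p == 1))
})

test_that("correlation test reproduces the t-from-r identity", {
  expect_equal(cor_t_from_r(-0.513, 18), -2.537, tolerance = 2e-3)

  set.seed(4)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- pearson_cor_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)

  expect_equal(pearson_cor_test(x, x)$r, 1)
  expect_equal(pearson_cor_test(x, x)$p_value, 0)
  expect_equal(pearson_cor_test(x, -x)$r, -1)
  expect_error(pearson_cor_test(x, rep(1, 20)), "variance")
})
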