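test_that("submodel fits match closed-form expectations", {
  set.seed(21)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  f0 <- fit_submodel(X, y, integer(0), task = "continuous")
  expect_equal(unique(round(f0$fitted, 12)), round(mean(y), 12))

  y2 <- 2 * X[, 5]
  f5 <- fit_submodel(X, y2, 5L, task = "continuous")
  expect_equal(unname(f5$coefficients[2]), 2, tolerance = 1e-10)
  expect_lt(max(abs(y2 - f5$fitted)), 1e-10)

  Xd <- cbind(X, X[, 1])
  expect_error(fit_submodel(Xd, y, c(1L, 7L), task = "continuous"),
               "singular")
})

test_that("residuals are raw for continuous and signed deviance for binary", {
  f <- fit_submodel(matrix(rnorm(3), 3, 1), c(1, 2, 3), integer(0),
                    task = "continuous")
  expect_equal(as.numeric(compute_residuals(f, c(1, 2, 3))), c(-1, 0, 1))
  expect_equal(attr(compute_residuals(f, c(1, 2, 3)), "kind"), "raw")

  yb <- rep(c(0, 1), each = 10)
  fb <- fit_submodel(matrix(rnorm(20), 20, 1), yb, integer(0), task = "binary")
  r <- compute_residuals(fb, yb)
  # intercept-only at prevalence 0.5: |d| = sqrt(2 log 2) for everyone
  expect_equal(abs(as.numeric(r)), rep(sqrt(2 * log(2)), 20),
               tolerance = 1e-8)
  expect_equal(attr(r, "kind"), "deviance")
  expect_equal(sign(as.numeric(r)), ifelse(yb == 1, 1, -1))

  yfit <- c(1, 2, 3)
  fperf <- fit_submodel(matrix(c(1, 2, 3)), yfit, 1L, task = "continuous")
  expect_lt(max(abs(compute_residuals(fperf, yfit))), 1e-10)
})

test_that("the chunked scan equals a brute-force serial scan", {
  set.seed(31)
  X <- matrix(rnorm(200 * 500), 200, 500)
  r <- rnorm(200)
  oracle <- which.max(abs(apply(X, 2, function(x) cor(x, r))))
  for (cs in c(1L, 17L, 500L)) {
    got <- scan_best_feature(X, r, chunk_size = cs)
    expect_equal(got$index, oracle)
    expect_equal(got$abs_correlation, abs(cor(X[, oracle], r)),
                 tolerance = 1e-12)
  }
})

test_that("scan ties break to the lowest index and degenerate cases signal", {
  set.seed(32)
  X <- matrix(rnorm(40 * 8), 40, 8)
  X[, 7] <- X[, 3]  # exact tie between columns 3 and 7
  got <- scan_best_feature(X, X[, 3] + rnorm(40, sd = 0.01))
  expect_equal(got$index, 3L)
  # zero-variance candidates skipped
  Xz <- cbind(rep(1, 40), X[, 1])
  expect_equal(scan_best_feature(Xz, rnorm(40))$index, 2L)
  # all candidates excluded or constant -> exhaustion
  expect_null(scan_best_feature(Xz[, 1, drop = FALSE], rnorm(40)))
  expect_null(scan_best_feature(X, rep(0, 40)))
})

test_that("stopping test follows the chi-squared law on the deviance", {
  st <- stopping_test(-10, -10, 100)
  expect_equal(st$p_value, 1)
  expect_equal(st$delta_bic, log(100))

  # boundary at alpha = 0.05, n = 100: D solving P(chisq1 > D) = 0.05,
  # found by root-finding on the CDF (independent of qchisq)
  D <- uniroot(function(d) pchisq(d, 1, lower.tail = FALSE) - 0.05,
               c(0.1, 30), tol = 1e-12)$root
  expect_equal(D, 3.841, tolerance = 1e-3)
  st <- stopping_test(0, D / 2, 100)
  expect_equal(st$p_value, 0.05, tolerance = 1e-9)
  expect_equal(st$delta_bic, D + log(100))

  expect_error(stopping_test(0, -1, 100), "decreased")
})

test_that("significance levels map to delta-BIC thresholds monotonically", {
  # chi-squared median located by root-finding, not the quantile function
  med <- uniroot(function(d) pchisq(d, 1) - 0.5, c(0.01, 5), tol = 1e-12)$root
  expect_equal(pvalue_to_dbic(0.5, exp(1)), med + 1, tolerance = 1e-9)
  a <- threshold_grid()
  d <- pvalue_to_dbic(a, 1177)
  expect_true(all(diff(d) < 0))                       # decreasing in alpha
  expect_lt(pvalue_to_dbic(0.05, 100), pvalue_to_dbic(0.05, 1000))
  expect_error(pvalue_to_dbic(0, 100), "alpha")
  expect_error(pvalue_to_dbic(1.2, 100), "alpha")
})

test_that("selection recovers a deterministic single-variant signal and stops", {
  set.seed(41)
  X <- random_dosage_instance(500, 30, seed = 41)
  y <- 1.5 * X[, 5] + rnorm(500, sd = 0.3)
  path <- epilogi_select(X, y, alpha = 1e-6)
  expect_equal(path$steps$variant_index[1], 5L)
  expect_true(all(path$steps$p_value <= 1e-6))
  # cap honoured
  y2 <- X[, 1] + X[, 2] + X[, 3] + rnorm(500, sd = 0.2)
  p2 <- epilogi_select(X, y2, alpha = 0.05, max_features = 2)
  expect_equal(nrow(p2$steps), 2L)
})

test_that("fit improves monotonically along the path", {
  set.seed(42)
  sim <- simulate_gwas(simulation_config(n_samples = 300, n_variants = 200,
                                         n_causal = 6, h2 = 0.8), seed = 42)
  X <- sim$genotypes$dosages
  y <- as.numeric(sim$phenotype)
  path <- epilogi_select(X, y, alpha = 0.05)
  expect_gt(nrow(path$steps), 1)
  sel <- selected_variants(path)
  rss <- vapply(0:length(sel), function(k) {
    f <- fit_submodel(X, y, sel[seq_len(k)], task = "continuous")
    sum((y - f$fitted)^2)
  }, numeric(1))
  expect_true(all(diff(rss) < 1e-8))
})

test_that("selection is deterministic and chunk-order invariant", {
  set.seed(43)
  X <- random_dosage_instance(150, 120, seed = 43)
  y <- X[, 10] - 0.8 * X[, 50] + rnorm(150, sd = 0.5)
  p1 <- epilogi_select(X, y, alpha = 0.05, chunk_size = 7)
  p2 <- epilogi_select(X, y, alpha = 0.05, chunk_size = 7)
  expect_identical(p1$steps, p2$steps)
})

test_that("truncating a loose path reproduces a stricter run exactly", {
  set.seed(44)
  sim <- simulate_gwas(simulation_config(n_samples = 400, n_variants = 300,
                                         n_causal = 8, h2 = 0.6), seed = 44)
  X <- sim$genotypes$dosages
  y <- as.numeric(sim$phenotype)
  loose <- epilogi_select(X, y, alpha = 0.8, max_features = 30)
  for (a in c(1e-6, 1e-3, 0.05)) {
    direct <- epilogi_select(X, y, alpha = a, max_features = 30)
    cut <- truncate_path(loose, a)
    expect_identical(cut$steps, direct$steps)
    expect_equal(cut$alpha, a)
  }
  expect_error(truncate_path(loose, 0.9), "truncate")
})

test_that("binary selection works end to end", {
  set.seed(45)
  X <- random_dosage_instance(300, 50, seed = 45)
  eta <- -0.5 + 1.2 * X[, 7]
  y <- rbinom(300, 1, plogis(eta))
  path <- epilogi_select(X, phenotype_vector(y, "binary"), alpha = 1e-4)
  expect_equal(path$steps$variant_index[1], 7L)
  expect_equal(path$task, "binary")
})
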