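test_that("partial correlation recovers known conditional structure", {
  set.seed(51)
  n <- 400
  x <- rnorm(n); z <- rnorm(n)
  y <- x + z
  res <- partial_correlation_test(x, y, z)
  expect_gt(res$rho, 0.99)
  expect_lt(res$p_value, 1e-10)

  # conditioning away everything is the stated degenerate convention
  res2 <- partial_correlation_test(z, y, z)
  expect_equal(res2$rho, 0)
  expect_equal(res2$p_value, 1)

  expect_error(partial_correlation_test(1:4, 1:4, 1:4), "n >= 5")
})

test_that("partial-correlation p-values are uniform under the null", {
  set.seed(52)
  n <- 200
  p <- replicate(1000, {
    partial_correlation_test(rnorm(n), rnorm(n), rnorm(n))$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("equivalence testing accepts duplicates and rejects noise", {
  set.seed(53)
  X <- random_dosage_instance(500, 20, seed = 53)
  X[, 9] <- X[, 2]                       # exact copy
  y <- X[, 2] + rnorm(500, sd = 0.4)
  r <- y - mean(y)                       # residuals before selecting col 2

  dup <- test_equivalence(2L, 9L, r, X, alpha_eq = 0.05)
  expect_true(dup$is_equivalent)
  expect_equal(dup$p_RrC, 1)
  expect_equal(dup$p_rCR, 1)

  # independent noise column is not a substitute for a strong signal
  noise <- test_equivalence(2L, 15L, r, X, alpha_eq = 0.05)
  expect_false(noise$is_equivalent)
  expect_lt(noise$p_RrC, 1e-6)

  # alpha_eq = 1 can never be exceeded
  expect_false(test_equivalence(2L, 9L, r, X, alpha_eq = 1)$is_equivalent)
  expect_error(test_equivalence(2L, 2L, r, X), "distinct")
})

test_that("duplicated selected variants land in an equivalence class", {
  set.seed(54)
  X <- random_dosage_instance(400, 25, seed = 54)
  X[, 9] <- X[, 2]
  y <- 1.2 * X[, 2] - X[, 17] + rnorm(400, sd = 0.5)
  path <- epilogi_select(X, y, alpha = 1e-4)
  sel <- selected_variants(path)
  expect_true(2L %in% sel || 9L %in% sel)
  expect_false(all(c(2L, 9L) %in% sel))  # the duplicate is not re-selected
  sg <- find_equivalents(X, path, y, alpha_eq = 0.05)
  k <- which(sel %in% c(2L, 9L))
  twin <- setdiff(c(2L, 9L), sel[k])
  expect_true(twin %in% sg$classes[[k]]$members$C)
  sizes <- vapply(sg$classes, function(cl) nrow(cl$members), integer(1))
  expect_equal(sg$signature_count, prod(1 + sizes))
  expect_gte(sg$signature_count, 2)
})

test_that("highly correlated causal proxies are reported equivalent", {
  set.seed(55)
  hits <- replicate(100, {
    # two near-perfect copies of one latent causal locus (r ~ 0.99):
    # the unique variation of either copy is a single genotyping error,
    # statistically invisible at this signal-to-noise, so each must be
    # reported as a substitute for the other
    n <- 1000
    latent <- rbinom(n, 2, 0.4)
    corrupt <- function(x) {
      if (runif(1) < 0.5) x[sample.int(n, 1)] <- sample(0:2, 1)
      x
    }
    X <- cbind(corrupt(latent), corrupt(latent),
               matrix(sample(0:2, n * 18, replace = TRUE), n, 18))
    y <- latent + rnorm(n, sd = 3)
    path <- epilogi_select(X, y, alpha = 1e-4)
    sel <- selected_variants(path)
    if (sum(c(1L, 2L) %in% sel) != 1) return(NA)
    k <- which(sel %in% c(1L, 2L))
    sg <- find_equivalents(X, path, y, alpha_eq = 0.05)
    other <- setdiff(c(1L, 2L), sel[k])
    other %in% sg$classes[[k]]$members$C
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("prescreening never changes the surviving equivalence classes", {
  set.seed(56)
  X <- random_dosage_instance(300, 30, seed = 56)
  X[, 12] <- X[, 4]
  y <- X[, 4] + 0.8 * X[, 20] + rnorm(300, sd = 0.6)
  path <- epilogi_select(X, y, alpha = 1e-3)
  full <- find_equivalents(X, path, y, prescreen_fraction = 0)
  screened <- find_equivalents(X, path, y, prescreen_fraction = 0.5)
  for (k in seq_along(full$classes)) {
    expect_true(all(screened$classes[[k]]$members$C %in%
                      full$classes[[k]]$members$C))
  }
})

test_that("signature enumeration is deterministic, complete, and truncates", {
  ref <- c(10L, 20L, 30L)
  mk_class <- function(R, members) {
    ids <- if (length(members)) paste0("v", members) else character(0)
    list(R = R, R_id = paste0("v", R),
         members = data.frame(C = members, C_id = ids,
                              p_RrC = rep(0.5, length(members)),
                              p_rCR = rep(0.5, length(members)),
                              stringsAsFactors = FALSE))
  }
  s <- structure(list(reference_signature = ref,
                      reference_ids = paste0("v", ref),
                      classes = list(mk_class(10L, c(11L, 12L)),
                                     mk_class(20L, integer(0)),
                                     mk_class(30L, 31L)),
                      alpha_eq = 0.05,
                      signature_count = (1 + 2) * (1 + 0) * (1 + 1)),
                 class = "signature_set")
  expect_equal(s$signature_count, 6)
  sigs <- enumerate_signatures(s, limit = 100)
  expect_equal(length(sigs), 6)
  expect_equal(sigs[[1]], ref)                        # reference first
  # single substitutions in path order, then member order, then pairs
  expect_equal(sigs[[2]], c(11L, 20L, 30L))
  expect_equal(sigs[[3]], c(12L, 20L, 30L))
  expect_equal(sigs[[4]], c(10L, 20L, 31L))
  expect_equal(sigs[[5]], c(11L, 20L, 31L))
  expect_equal(sigs[[6]], c(12L, 20L, 31L))
  # no repeats, constant cardinality
  expect_equal(anyDuplicated(sigs), 0L)
  expect_true(all(lengths(sigs) == 3))
  # truncation leaves the count untouched
  expect_equal(length(enumerate_signatures(s, limit = 4)), 4)
  expect_equal(s$signature_count, 6)

  s0 <- structure(list(reference_signature = ref,
                       reference_ids = paste0("v", ref),
                       classes = list(mk_class(10L, integer(0)),
                                      mk_class(20L, integer(0)),
                                      mk_class(30L, integer(0))),
                       alpha_eq = 0.05, signature_count = 1),
                  class = "signature_set")
  expect_equal(enumerate_signatures(s0, 10), list(ref))
})

test_that("single-substitution signatures predict about as well as the reference", {
  set.seed(57)
  ok <- replicate(20, {
    # perfect-LD pairs: two causal columns carry a near-duplicate
    # (one genotyping error apart), so substitutes exist by design
    n <- 500
    sim <- simulate_gwas(simulation_config(n_samples = n, n_variants = 150,
                                           n_causal = 4, h2 = 0.8,
                                           ld_rho = 0.2), seed = sample.int(1e6, 1))
    X <- sim$genotypes$dosages
    for (j in sim$truth$causal_indices[1:2]) {
      twin <- X[, j]
      twin[sample.int(n, 1)] <- sample(0:2, 1)
      X[, sample(setdiff(seq_len(150), sim$truth$causal_indices), 1)] <- twin
    }
    y <- as.numeric(sim$phenotype)
    path <- epilogi_select(X, y, alpha = 1e-4)
    if (!nrow(path$steps)) return(NA)
    sg <- find_equivalents(X, path, y)
    sigs <- enumerate_signatures(sg, limit = 10)
    if (length(sigs) < 2) return(NA)
    r2 <- vapply(sigs, function(s) {
      f <- fit_submodel(X, y, s, task = "continuous")
      predictive_metrics(y, f$fitted, "continuous")
    }, numeric(1))
    all(abs(r2[-1] - r2[1]) < 0.05)
  })
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})
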