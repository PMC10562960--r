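#' Fit the working submodel on a set of selected variants
#'
#' Continuous outcomes are fitted by ordinary least squares with an
#' intercept; binary outcomes by maximum-likelihood logistic regression
#' with an intercept. Used internally by [epilogi_select()] at every
#' step of the greedy path, and exposed for inspection.
#'
#' @param g a [genotype_matrix] or numeric matrix (no missing values).
#' @param y phenotype vector (see [phenotype_vector()]).
#' @param S integer vector of selected variant column indices (may be
#'   empty: intercept-only model).
#' @param task `"continuous"` or `"binary"`; defaults to the task
#'   recorded on `y`.
#' @param maxit iteration cap for the logistic fit; on non-convergence a
#'   ridge-stabilized fit is used and flagged in the result.
#' @param eps probability clipping bound for the logistic
#'   log-likelihood.
#' @return A list with `coefficients`, `fitted` (probabilities for
#'   binary), `loglik`, `task`, `S`, and `ridge_stabilized` flag.
#' @export
fit_submodel <- function(g, y, S = integer(0), task = NULL,
                         maxit = 100L, eps = 1e-10) {
  X <- dosage_matrix(g)
  task <- task %||% pheno_task(y)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (anyNA(X[, S, drop = FALSE]) || anyNA(y)) {
    stop("fit_submodel requires imputed (non-missing) inputs")
  }
  S <- as.integer(S)
  design <- cbind(`(Intercept)` = 1, X[, S, drop = FALSE])
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))]
    bad <- S[dropped[dropped > 1] - 1L]
    stop("singular design: variant column(s) ",
         paste(bad, collapse = ", "), " collinear with the model")
  }
  if (task == "binary") {
    if (length(unique(y)) < 2) stop("binary phenotype must contain both classes")
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = maxit))
    )
    ridge_flag <- FALSE
    if (!fit$converged) {
      # separable data: refit with a small L2 penalty for stability
      ridge_flag <- TRUE
      if (length(S) >= 1) {
        Xs <- design[, -1, drop = FALSE]
        Xr <- if (ncol(Xs) == 1) cbind(Xs, Xs) else Xs  # glmnet needs >= 2 cols
        rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                             lambda = 1e-4, standardize = FALSE)
        p <- as.numeric(stats::predict(rf, Xr, type = "response"))
        b <- as.numeric(rf$beta)
        coefs <- c(as.numeric(rf$a0), if (ncol(Xs) == 1) sum(b) else b)
      } else {
        p <- rep(mean(y), n)
        coefs <- stats::qlogis(mean(y))
      }
    } else {
      p <- fit$fitted.values
      coefs <- fit$coefficients
    }
    p <- pmin(pmax(p, eps), 1 - eps)
    ll <- sum(y * log(p) + (1 - y) * log(1 - p))
    out <- list(coefficients = coefs, fitted = p, loglik = ll,
                task = task, S = S, n = n, ridge_stabilized = ridge_flag)
  } else {
    fit <- stats::lm.fit(design, y)
    res <- fit$residuals
    rss <- sum(res^2)
    # Gaussian profile log-likelihood; floor the RSS to keep an exact
    # fit finite (the selection loop stops on zero-variance residuals
    # before this matters)
    rss <- max(rss, 1e-300)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    out <- list(coefficients = fit$coefficients, fitted = fit$fitted.values,
                loglik = ll, task = task, S = S, n = n,
                ridge_stabilized = FALSE)
  }
  class(out) <- "epilogi_fit"
  out
}

#' Residuals of the working submodel
#'
#' Continuous task: raw residuals `y - yhat`. Binary task: signed
#' deviance residuals
#' `sign(y - p) * sqrt(-2 * (y*log(p) + (1-y)*log(1-p)))` with fitted
#' probabilities clipped away from 0 and 1.
#'
#' @param model a fit from [fit_submodel()].
#' @param y the phenotype vector the model was fitted on.
#' @param eps probability clipping bound.
#' @return A numeric vector of residuals with attribute `kind`
#'   (`"raw"` or `"deviance"`).
#' @export
compute_residuals <- function(model, y, eps = 1e-10) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(model$fitted))
  if (model$task == "binary") {
    p <- pmin(pmax(model$fitted, eps), 1 - eps)
    d2 <- -2 * (y * log(p) + (1 - y) * log(1 - p))
    r <- sign(y - p) * sqrt(pmax(d2, 0))
    structure(r, kind = "deviance")
  } else {
    structure(y - model$fitted, kind = "raw")
  }
}

#' Scan all candidate variants for the one most correlated with the
#' residuals
#'
#' Computes `|Pearson cor(x_j, r)|` for every candidate column and
#' returns the maximizer. The scan is performed over chunks of columns;
#' the result is independent of chunk size and chunk order (each chunk
#' keeps its best candidate, then the global best is taken, ties broken
#' towards the lowest column index). Zero-variance candidates are
#' skipped.
#'
#' @param g a [genotype_matrix] or numeric matrix (no missing values).
#' @param r residual vector.
#' @param excluded integer vector of column indices to skip.
#' @param chunk_size number of columns scanned per chunk.
#' @return `list(index =, abs_correlation =)`, or `NULL` when no valid
#'   candidate remains (exhaustion).
#' @export
scan_best_feature <- function(g, r, excluded = integer(0),
                              chunk_size = 10000L) {
  X <- dosage_matrix(g)
  r <- as.numeric(r)
  stopifnot(nrow(X) == length(r), chunk_size >= 1)
  m <- ncol(X)
  rc <- r - mean(r)
  rnorm2 <- sqrt(sum(rc^2))
  if (rnorm2 < 1e-12) return(NULL)  # perfect fit: no signal left
  candidates <- setdiff(seq_len(m), excluded)
  if (!length(candidates)) return(NULL)
  best_idx <- NA_integer_
  best_cor <- -Inf
  starts <- seq(1L, length(candidates), by = chunk_size)
  for (s in starts) {
    idx <- candidates[s:min(s + chunk_size - 1L, length(candidates))]
    Xc <- X[, idx, drop = FALSE]
    mu <- colMeans(Xc)
    # colSums (not crossprod) so the floating-point summation order per
    # column is independent of the chunk shape: scans are bit-identical
    # for every chunk size
    num <- colSums(Xc * rc)                        # sum x*rc = sum (x-mu)*rc
    ss <- colSums(Xc^2) - nrow(Xc) * mu^2
    valid <- ss > 1e-12
    if (!any(valid)) next
    ac <- abs(num[valid]) / (sqrt(ss[valid]) * rnorm2)
    k <- which.max(ac)                              # first max = lowest index
    if (ac[k] > best_cor + 1e-15 ||
        (abs(ac[k] - best_cor) <= 1e-15 && idx[valid][k] < best_idx)) {
      best_cor <- ac[k]
      best_idx <- idx[valid][k]
    }
  }
  if (is.na(best_idx)) return(NULL)
  list(index = best_idx, abs_correlation = min(best_cor, 1))
}

#' Likelihood-ratio stopping test for one added variant
#'
#' The deviance `D = 2*(ll_with - ll_without)` of nested models
#' differing by one coefficient is referred to a chi-squared
#' distribution with 1 degree of freedom; the statistic is also
#' reported on the delta-BIC scale `D + log(n)`, under which the
#' significance levels 1e-6 and 0.8 at n = 1177 correspond to
#' thresholds 31.00 and 7.13.
#'
#' @param ll_without log-likelihood of the model without the candidate.
#' @param ll_with log-likelihood with the candidate added.
#' @param n training sample count.
#' @param tol tolerance for a slightly negative deviance from numerical
#'   noise.
#' @return `list(delta_bic =, p_value =)`.
#' @export
stopping_test <- function(ll_without, ll_with, n, tol = 1e-6) {
  D <- 2 * (ll_with - ll_without)
  if (D < -tol) {
    stop(sprintf("nested-model log-likelihood decreased (D = %.3g): inconsistent fits", D))
  }
  D <- max(D, 0)
  list(delta_bic = D + log(n),
       p_value = stats::pchisq(D, df = 1, lower.tail = FALSE))
}

#' Convert a significance level to the equivalent delta-BIC threshold
#'
#' `Q_chisq1(1 - alpha) + log(n)`: the delta-BIC value at which the
#' stopping test is exactly on the acceptance boundary. Strictly
#' decreasing in `alpha` and increasing in `n`; alpha = 1e-6 and
#' alpha = 0.8 at n = 1177 give 31.00 and 7.13.
#'
#' @param alpha significance level in (0, 1); vectorized.
#' @param n training sample count (>= 2).
#' @return Numeric delta-BIC threshold(s).
#' @export
pvalue_to_dbic <- function(alpha, n) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie strictly in (0, 1)")
  if (n < 2) stop("n must be >= 2")
  stats::qchisq(1 - alpha, df = 1) + log(n)
}

#' Greedy residual-correlation variant selection
#'
#' Generalized Orthogonal Matching Pursuit for genotype data: starting
#' from the empty set, each iteration fits the working model on the
#' current selection, computes its residuals, scans all remaining
#' variants for the one most correlated with the residuals, and accepts
#' it if the chi-squared stopping test on the likelihood-ratio
#' statistic is significant at `alpha`. Selection stops at the first
#' rejected candidate, candidate exhaustion, or the `max_features` cap.
#' The selected set, in order, is the *reference signature*.
#'
#' Candidates whose dosage column is (numerically) collinear with the
#' current design are skipped and recorded in `collinear`; they remain
#' available to the equivalence stage (see [find_equivalents()]).
#'
#' @param g a [genotype_matrix] or numeric matrix; must contain no
#'   missing values (see [impute_missing()]).
#' @param y phenotype vector.
#' @param alpha significance threshold for the stopping test.
#' @param max_features cap on the number of selected variants.
#' @param chunk_size columns per scan chunk (does not affect results).
#' @param task `"continuous"` or `"binary"`; defaults to the task
#'   recorded on `y`.
#' @return An object of class `selection_path`: list with `steps` (a
#'   data.frame: `variant_index`, `variant_id`, `abs_correlation`,
#'   `delta_bic`, `p_value`), `alpha`, `max_features`, `n_train`,
#'   `task`, and `collinear` (skipped collinear candidate indices).
#' @export
epilogi_select <- function(g, y, alpha = 0.05, max_features = 50L,
                           chunk_size = 10000L, task = NULL) {
  X <- dosage_matrix(g)
  task <- task %||% pheno_task(y)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("genotype and phenotype sample counts differ")
  if (anyNA(X)) stop("genotype matrix contains missing values; impute first")
  if (n < 10) stop("need at least 10 samples")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")

  vids <- variant_ids(g)
  selected <- integer(0)
  collinear <- integer(0)
  steps <- list()
  fit <- fit_submodel(X, y, selected, task = task)

  while (length(selected) < max_features) {
    r <- compute_residuals(fit, y)
    scan <- NULL
    repeat {
      scan <- scan_best_feature(X, r, excluded = c(selected, collinear),
                                chunk_size = chunk_size)
      if (is.null(scan)) break
      if (partial_variance(X, selected, scan$index) >= 1e-10) break
      collinear <- c(collinear, scan$index)
    }
    if (is.null(scan)) break  # exhaustion (or perfect fit)
    fit_j <- fit_submodel(X, y, c(selected, scan$index), task = task)
    st <- stopping_test(fit$loglik, fit_j$loglik, n)
    if (st$p_value > alpha) break
    selected <- c(selected, scan$index)
    steps[[length(steps) + 1L]] <- data.frame(
      variant_index = scan$index,
      variant_id = vids[scan$index],
      abs_correlation = scan$abs_correlation,
      delta_bic = st$delta_bic,
      p_value = st$p_value,
      stringsAsFactors = FALSE)
    fit <- fit_j
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(variant_index = integer(0), variant_id = character(0),
               abs_correlation = numeric(0), delta_bic = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  structure(list(steps = steps, alpha = alpha,
                 max_features = as.integer(max_features),
                 n_train = n, task = task, collinear = collinear),
            class = "selection_path")
}

# Residual variance of candidate column j after projecting on the
# intercept plus the currently selected columns; near-zero means the
# candidate is collinear with the design.
partial_variance <- function(X, selected, j) {
  x <- X[, j]
  design <- cbind(1, X[, selected, drop = FALSE])
  res <- stats::lm.fit(design, x)$residuals
  sum(res^2) / length(x)
}

#' @export
print.selection_path <- function(x, ...) {
  cat(sprintf("selection_path: %d variant(s) at alpha = %g (n = %d, %s task)\n",
              nrow(x$steps), x$alpha, x$n_train, x$task))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Variant indices of a selection path (the reference signature)
#' @param path a `selection_path`.
#' @return Integer vector of selected variant column indices, in
#'   selection order.
#' @export
selected_variants <- function(path) path$steps$variant_index

#' Restrict a selection path to a stricter significance threshold
#'
#' The greedy path at a stricter `alpha` is exactly the prefix of a
#' looser-alpha path up to (excluding) the first step whose stopping
#' p-value exceeds the stricter threshold: selection halts at the first
#' rejected candidate, and all earlier accepted steps are unaffected by
#' the threshold. This makes evaluating a whole threshold grid a single
#' selection run at the loosest threshold.
#'
#' @param path a `selection_path` computed at some alpha.
#' @param alpha a threshold no looser than `path$alpha`.
#' @return A `selection_path` at the stricter alpha.
#' @export
truncate_path <- function(path, alpha) {
  stopifnot(inherits(path, "selection_path"))
  if (alpha > path$alpha) {
    stop("can only truncate to a threshold at most the path's alpha")
  }
  cut <- which(path$steps$p_value > alpha)
  keep <- if (length(cut)) seq_len(cut[1] - 1L) else seq_len(nrow(path$steps))
  out <- path
  out$steps <- path$steps[keep, , drop = FALSE]
  out$alpha <- alpha
  out
}
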