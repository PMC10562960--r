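#' Causal-recovery metrics
#'
#' True-positive rate: fraction of causal variants recovered,
#' `|selected ∩ causal| / |causal|`. False-discovery rate: fraction of
#' the selection that is non-causal, `|selected \ causal| / |selected|`,
#' defined as 0 for an empty selection.
#'
#' @param selected integer (or character) vector of selected variants.
#' @param causal non-empty vector of causal variants, same id space.
#' @return `list(tpr =, fdr =, counted_with_equivalents = FALSE)`.
#' @export
tpr_fdr <- function(selected, causal) {
  if (!length(causal)) stop("causal set is empty: TPR undefined")
  selected <- unique(selected)
  causal <- unique(causal)
  tp <- length(intersect(selected, causal))
  list(tpr = tp / length(causal),
       fdr = if (length(selected)) (length(selected) - tp) / length(selected) else 0,
       counted_with_equivalents = FALSE)
}

#' Causal-recovery metrics counting equivalent substitutes
#'
#' The selection is widened to the reference signature plus every
#' member of every equivalence class before computing TPR/FDR: a causal
#' variant found only as a statistical substitute still counts as
#' recovered.
#'
#' @param sigset a `signature_set` from [find_equivalents()].
#' @param causal non-empty vector of causal variant indices.
#' @return As [tpr_fdr()], with `counted_with_equivalents = TRUE`.
#' @export
tpr_fdr_with_equivalents <- function(sigset, causal) {
  stopifnot(inherits(sigset, "signature_set"))
  widened <- unique(c(sigset$reference_signature,
                      unlist(lapply(sigset$classes, function(cl) cl$members$C))))
  out <- tpr_fdr(widened, causal)
  out$counted_with_equivalents <- TRUE
  out
}

#' Predictive performance metric
#'
#' Continuous task: coefficient of determination
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (can be
#' negative for predictors worse than the mean). Binary task:
#' rank-based area under the ROC curve with ties counted 0.5.
#'
#' @param y_true observed outcomes (0/1 for binary).
#' @param y_pred predictions (scores/probabilities for binary).
#' @param task `"continuous"` or `"binary"`; defaults to the task
#'   recorded on `y_true`.
#' @return A single numeric value (R-squared or AUC).
#' @export
predictive_metrics <- function(y_true, y_pred, task = NULL) {
  task <- task %||% pheno_task(y_true)
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (task == "binary") {
    n1 <- sum(y_true == 1)
    n0 <- sum(y_true == 0)
    if (n1 == 0 || n0 == 0) stop("AUC needs both classes in y_true")
    rk <- rank(y_pred)  # midranks: ties contribute 0.5
    (sum(rk[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    tss <- sum((y_true - mean(y_true))^2)
    if (tss <= 0) stop("constant y_true: R-squared undefined")
    1 - sum((y_true - y_pred)^2) / tss
  }
}

#' Logarithmically spaced significance-threshold grid
#'
#' `k` thresholds equispaced in log10 between `p_min` and `p_max`
#' inclusive; the default reproduces the 10-point grid from 1e-6 to
#' 0.8.
#'
#' @param p_min,p_max grid endpoints, `0 < p_min < p_max < 1`.
#' @param k number of points (>= 2).
#' @return Increasing numeric vector of length `k`.
#' @export
threshold_grid <- function(p_min = 1e-6, p_max = 0.8, k = 10L) {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1)
  if (k < 2) stop("k must be >= 2")
  10^seq(log10(p_min), log10(p_max), length.out = k)
}

#' Univariate (standard GWAS) variant selection
#'
#' Every variant is tested for marginal association with the phenotype
#' in isolation: simple linear regression (t-test on the slope) for
#' continuous outcomes, a score test for logistic regression on a
#' single covariate for binary outcomes. Variants with p-value at or
#' below the genome-wide threshold are selected. Constant variants get
#' p = 1.
#'
#' @param g a [genotype_matrix] or numeric matrix (no missing values).
#' @param y phenotype vector.
#' @param threshold significance threshold; default the conventional
#'   genome-wide 5e-8.
#' @param task `"continuous"` or `"binary"`.
#' @return `list(selected = indices, p_values = per-variant vector)`.
#' @export
univariate_gwas_select <- function(g, y, threshold = 5e-8, task = NULL) {
  X <- dosage_matrix(g)
  task <- task %||% pheno_task(y)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (anyNA(X)) stop("genotype matrix contains missing values; impute first")
  mu <- colMeans(X)
  ssx <- colSums(X^2) - n * mu^2
  constant <- ssx <= 1e-12
  if (task == "binary") {
    pbar <- mean(y)
    # score test: U = sum x*(y - pbar); Var(U) = pbar*(1-pbar)*ss_x
    U <- as.numeric(crossprod(X, y - pbar))
    V <- pbar * (1 - pbar) * ssx
    stat <- ifelse(constant, 0, U^2 / pmax(V, 1e-300))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    r <- ifelse(constant, 0,
                as.numeric(crossprod(X, yc)) / sqrt(pmax(ssx, 1e-300) * ssy))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  p[constant] <- 1
  list(selected = which(p <= threshold), p_values = p)
}

#' Reproducible train/test hold-out split
#'
#' Draws a test set of `round(n * fraction)` samples; for binary tasks
#' the split is stratified by class so neither side loses a class.
#'
#' @param n sample count (or a phenotype vector, from which `n` and the
#'   task are taken).
#' @param fraction test fraction in (0, 1); default 0.1.
#' @param seed optional integer seed.
#' @param y optional binary phenotype for stratification.
#' @return `list(train = indices, test = indices)`, disjoint and
#'   exhaustive.
#' @export
holdout_split <- function(n, fraction = 0.1, seed = NULL, y = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(y)) {
    n_test <- max(1L, round(n * fraction))
    test <- sort(sample.int(n, n_test))
  } else {
    y <- as.numeric(y)
    stopifnot(length(y) == n)
    test <- sort(unlist(lapply(split(seq_len(n), y), function(idx) {
      sample(idx, max(1L, round(length(idx) * fraction)))
    }), use.names = FALSE))
  }
  train <- setdiff(seq_len(n), test)
  if (!is.null(y) &&
      (length(unique(y[train])) < 2 || length(unique(y[test])) < 2)) {
    stop("hold-out split left a class empty")
  }
  list(train = train, test = test)
}
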