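#' Build the configuration grid
#'
#' A configuration is one full pipeline instantiation: imputation mode,
#' selection significance threshold, equivalence threshold, selection
#' cap, and a model family with its hyper-parameters. The default grid
#' is the Cartesian product of the threshold grid with three model
#' settings (two ridge penalties and a random forest), gated by task:
#' ridge-logistic only for binary outcomes, ridge-linear only for
#' continuous ones.
#'
#' @param task `"continuous"` or `"binary"`.
#' @param grid selection thresholds, typically [threshold_grid()].
#' @param models optional list of model settings
#'   `list(family =, lambda = | num_trees =)`; families:
#'   `"ridge-linear"`, `"ridge-logistic"`, `"random-forest"`.
#' @param alpha_eq equivalence threshold attached to every
#'   configuration.
#' @param max_features selection cap attached to every configuration.
#' @param imputation imputation mode (`"mean"` or `"mode"`).
#' @return A list of configuration lists, in deterministic order
#'   (thresholds vary fastest).
#' @export
make_configurations <- function(task = c("continuous", "binary"),
                                grid = threshold_grid(),
                                models = NULL, alpha_eq = 0.05,
                                max_features = 50L, imputation = "mean") {
  task <- match.arg(task)
  if (is.null(models)) {
    ridge <- if (task == "binary") "ridge-logistic" else "ridge-linear"
    models <- list(list(family = ridge, lambda = 0.1),
                   list(family = ridge, lambda = 1),
                   list(family = "random-forest", num_trees = 300L))
  }
  ok <- vapply(models, function(mo) {
    !(task == "continuous" && mo$family == "ridge-logistic") &&
      !(task == "binary" && mo$family == "ridge-linear")
  }, logical(1))
  models <- models[ok]
  configs <- list()
  for (mo in models) {
    for (a in grid) {
      configs[[length(configs) + 1L]] <- list(
        alpha = a, alpha_eq = alpha_eq,
        max_features = as.integer(max_features),
        imputation = imputation, model = mo, task = task,
        label = sprintf("%s(alpha=%.3g)", mo$family, a))
    }
  }
  configs
}

# Fit one configured model on the selected columns and return a
# prediction closure. Empty selections fall back to the training mean /
# prevalence; single-column ridge configs use an unpenalized glm fit
# (glmnet requires two or more predictors).
fit_config_model <- function(X, y, selected, model, task, seed = 1L) {
  p <- length(selected)
  if (model$family == "random-forest") {
    df <- as.data.frame(X[, selected, drop = FALSE])
    names(df) <- paste0("x", seq_len(ncol(df)))
    if (p == 0) {
      const <- mean(y)
      return(function(Xnew) rep(const, nrow(Xnew)))
    }
    if (task == "binary") {
      rf <- ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                           num.trees = model$num_trees %||% 300L,
                           probability = TRUE, seed = seed,
                           num.threads = 1)
      return(function(Xnew) {
        dn <- as.data.frame(Xnew[, selected, drop = FALSE])
        names(dn) <- names(df)
        stats::predict(rf, data = dn, num.threads = 1)$predictions[, "1"]
      })
    }
    rf <- ranger::ranger(x = df, y = y, num.trees = model$num_trees %||% 300L,
                         seed = seed, num.threads = 1)
    return(function(Xnew) {
      dn <- as.data.frame(Xnew[, selected, drop = FALSE])
      names(dn) <- names(df)
      stats::predict(rf, data = dn, num.threads = 1)$predictions
    })
  }
  # ridge families
  if (p == 0) {
    const <- mean(y)
    return(function(Xnew) rep(const, nrow(Xnew)))
  }
  fam <- if (model$family == "ridge-logistic") "binomial" else "gaussian"
  if (p == 1) {
    dat <- data.frame(y = y, x1 = X[, selected])
    fit <- if (fam == "binomial") {
      stats::glm(y ~ x1, data = dat, family = stats::binomial())
    } else {
      stats::lm(y ~ x1, data = dat)
    }
    return(function(Xnew) {
      as.numeric(stats::predict(fit,
        newdata = data.frame(x1 = Xnew[, selected]),
        type = "response"))
    })
  }
  gl <- glmnet::glmnet(X[, selected, drop = FALSE], y, family = fam,
                       alpha = 0, lambda = model$lambda %||% 0.1)
  function(Xnew) {
    as.numeric(stats::predict(gl, Xnew[, selected, drop = FALSE],
                              type = "response"))
  }
}

# Stratified (binary) or plain fold assignment shared by all
# configurations.
assign_folds <- function(y, task, folds) {
  n <- length(y)
  if (task == "binary") {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  } else {
    sample(rep_len(seq_len(folds), n))
  }
}

#' Cross-validate the full pipeline over a configuration grid
#'
#' For each fold, the entire pipeline — imputation, greedy selection,
#' model fitting — runs on the training part only, and the held-out
#' part is predicted; selection is always inside the loop. All
#' configurations share the same fold assignment (paired comparison).
#' Configurations differing only in their selection threshold share
#' one greedy run per fold: the path is computed at the loosest
#' threshold and cut back per configuration with [truncate_path()],
#' which is exact.
#'
#' @param g a [genotype_matrix] or numeric matrix.
#' @param y phenotype vector.
#' @param configs list from [make_configurations()].
#' @param folds number of folds (up to `n` for leave-one-out).
#' @param seed optional integer seed (folds, forests).
#' @param chunk_size scan chunk size passed to [epilogi_select()].
#' @return An object of class `prediction_table`: list with `pred`
#'   (n-by-n_configs out-of-fold prediction matrix), `folds` (per-sample
#'   fold id), `configs`, `task`.
#' @export
cross_validate <- function(g, y, configs, folds = 10L, seed = NULL,
                           chunk_size = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  X <- dosage_matrix(g)
  task <- configs[[1]]$task
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 2 * 1, folds >= 2, folds <= n)
  fold_id <- assign_folds(y, task, folds)
  pred <- matrix(NA_real_, n, length(configs))
  alphas <- vapply(configs, `[[`, numeric(1), "alpha")
  caps <- vapply(configs, `[[`, integer(1), "max_features")
  imp_modes <- vapply(configs, `[[`, character(1), "imputation")
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (!length(te)) next
    for (imp in unique(imp_modes)) {
      cset <- which(imp_modes == imp)
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      if (anyNA(Xtr) || anyNA(Xte)) {
        gi <- impute_missing(genotype_matrix(Xtr, imputed = imp), imp)
        fills <- if (imp == "mean") colMeans(Xtr, na.rm = TRUE) else
          apply(Xtr, 2, function(x) {
            tab <- table(x); as.numeric(names(tab))[which.max(tab)]
          })
        Xtr <- gi$dosages
        for (j in which(colSums(is.na(Xte)) > 0)) {
          Xte[is.na(Xte[, j]), j] <- fills[j]
        }
      }
      path_loose <- epilogi_select(Xtr, y[tr], alpha = max(alphas[cset]),
                                   max_features = max(caps[cset]),
                                   chunk_size = chunk_size, task = task)
      for (ci in cset) {
        pth <- truncate_path(path_loose, alphas[ci])
        sel <- utils::head(selected_variants(pth), caps[ci])
        fc <- fit_config_model(Xtr, y[tr], sel, configs[[ci]]$model, task,
                               seed = sample.int(.Machine$integer.max, 1))
        pred[te, ci] <- fc(Xte)
      }
    }
  }
  structure(list(pred = pred, folds = fold_id, configs = configs,
                 task = task),
            class = "prediction_table")
}

#' Bootstrap-bias-corrected cross-validation estimate
#'
#' Corrects the cross-validation estimate of the winning configuration
#' for the optimism of having tried many configurations ("winner's
#' curse"). For each of `B` bootstrap draws of sample indices, the
#' configuration maximizing the metric on the pooled in-bag out-of-fold
#' predictions is picked and scored on the out-of-bag samples; the
#' corrected estimate is the mean of the `B` out-of-bag scores and the
#' 95% confidence interval their 2.5/97.5 percentiles.
#'
#' @param pt a `prediction_table` from [cross_validate()].
#' @param y the phenotype vector.
#' @param metric metric function `(y_true, y_pred) -> value`; default
#'   [predictive_metrics()] for the table's task.
#' @param B number of bootstrap draws; `B = 1` yields a degenerate
#'   interval (with a warning).
#' @param seed optional integer seed.
#' @param max_retries redraw attempts when the out-of-bag set cannot be
#'   scored (empty or single-class).
#' @return `list(bbc_estimate =, ci95 = c(low, high), scores =)`.
#' @export
bbc_cv <- function(pt, y, metric = NULL, B = 500L, seed = NULL,
                   max_retries = 100L) {
  stopifnot(inherits(pt, "prediction_table"), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(y)
  task <- pt$task
  metric <- metric %||% function(yt, yp) predictive_metrics(yt, yp, task)
  n <- length(y)
  stopifnot(nrow(pt$pred) == n)
  scorable <- function(idx) {
    length(idx) >= 2 &&
      (task != "binary" || length(unique(y[idx])) == 2) &&
      (task != "continuous" || stats::var(y[idx]) > 0)
  }
  scores <- numeric(B)
  for (b in seq_len(B)) {
    for (tryi in seq_len(max_retries)) {
      ib <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(ib))
      if (scorable(ib) && scorable(oob)) break
      if (tryi == max_retries) stop("could not draw a scorable bootstrap split")
    }
    in_scores <- vapply(seq_len(ncol(pt$pred)), function(ci) {
      metric(y[ib], pt$pred[ib, ci])
    }, numeric(1))
    winner <- which.max(in_scores)  # ties: first (lowest config index)
    scores[b] <- metric(y[oob], pt$pred[oob, winner])
  }
  if (B == 1) warning("B = 1: confidence interval is degenerate")
  list(bbc_estimate = mean(scores),
       ci95 = unname(stats::quantile(scores, c(0.025, 0.975), type = 7)),
       scores = scores)
}

#' Run the full selection-plus-modeling harness
#'
#' Cross-validates every configuration, picks the raw winner, computes
#' the bootstrap-bias-corrected performance estimate with its 95%
#' confidence interval, then refits the winning configuration on *all*
#' samples (no samples lost to estimation) and attaches the final
#' reference signature and its equivalence classes.
#'
#' @param g a [genotype_matrix] or numeric matrix.
#' @param y phenotype vector.
#' @param task `"continuous"` or `"binary"`; defaults to the task
#'   recorded on `y`.
#' @param configs configuration list; default [make_configurations()]
#'   for the task.
#' @param folds cross-validation folds.
#' @param B bootstrap draws for [bbc_cv()].
#' @param seed optional integer seed governing the whole run.
#' @param chunk_size scan chunk size.
#' @return An object of class `performance_report`: list with
#'   `raw_estimates` (per configuration), `winner` (index),
#'   `winner_label`, `bbc_estimate`, `ci95`, `final_signature`
#'   (signature_set on all data), `final_model` (prediction closure),
#'   `n_train` (always the full n), `task`, `configs`.
#' @export
run_automl <- function(g, y, task = NULL, configs = NULL, folds = 10L,
                       B = 500L, seed = NULL, chunk_size = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  task <- task %||% pheno_task(y)
  configs <- configs %||% make_configurations(task)
  X <- dosage_matrix(g)
  y <- as.numeric(y)
  pt <- cross_validate(X, y, configs, folds = folds, seed = NULL,
                       chunk_size = chunk_size)
  raw <- vapply(seq_along(configs), function(ci) {
    predictive_metrics(y, pt$pred[, ci], task)
  }, numeric(1))
  winner <- which.max(raw)
  bbc <- bbc_cv(pt, y, B = B, seed = NULL)
  wc <- configs[[winner]]
  if (anyNA(X)) {
    X <- impute_missing(genotype_matrix(X), wc$imputation)$dosages
  }
  final_path <- epilogi_select(X, y, alpha = wc$alpha,
                               max_features = wc$max_features,
                               chunk_size = chunk_size, task = task)
  final_sig <- if (nrow(final_path$steps)) {
    find_equivalents(X, final_path, y, alpha_eq = wc$alpha_eq)
  } else NULL
  final_model <- fit_config_model(X, y, selected_variants(final_path),
                                  wc$model, task,
                                  seed = sample.int(.Machine$integer.max, 1))
  structure(list(raw_estimates = raw, winner = winner,
                 winner_label = wc$label, bbc_estimate = bbc$bbc_estimate,
                 ci95 = bbc$ci95, final_path = final_path,
                 final_signature = final_sig, final_model = final_model,
                 n_train = length(y), task = task, configs = configs,
                 prediction_table = pt),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report: %d configuration(s), winner %s\n",
              length(x$configs), x$winner_label))
  cat(sprintf("  raw winner estimate: %.4f\n", x$raw_estimates[x$winner]))
  cat(sprintf("  BBC-corrected estimate: %.4f [%.4f, %.4f]\n",
              x$bbc_estimate, x$ci95[1], x$ci95[2]))
  cat(sprintf("  final model trained on all %d samples; signature of %d variant(s)\n",
              x$n_train, nrow(x$final_path$steps)))
  invisible(x)
}
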