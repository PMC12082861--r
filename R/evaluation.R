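#' Confusion-matrix classification metrics
#'
#' Exact confusion counts with the four commonly used classification
#' measurements plus the F-measure: accuracy = (TP+TN)/n, precision =
#' TP/(TP+FP), sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' F-measure = harmonic mean of precision and sensitivity. A ratio with a
#' zero denominator is reported as 0 and flagged in `undefined`.
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`, the five metrics
#'   and `undefined` (comma-separated names of zero-denominator metrics,
#'   `""` if none).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  accuracy <- ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  precision <- ratio(tp, tp + fp, "precision")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  f_measure <- if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f_measure")
    0
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = accuracy, precision = precision,
    sensitivity = sensitivity, specificity = specificity,
    f_measure = f_measure,
    undefined = paste(undefined, collapse = ",")
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (tied scores enter
#' simultaneously), collecting (FPR, TPR) points from (0,0) to (1,1), and
#' integrates the curve by the trapezoid rule. With the 0.5-per-tie
#' convention this AUC equals the Mann-Whitney U statistic of the positive
#' class scores over the negative class scores divided by the product of
#' class sizes.
#'
#' @param y_true Binary 0/1 labels with both classes present.
#' @param scores Real-valued classifier scores (higher = more positive).
#' @return A list with `points` (tibble `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_and_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || length(unique(y_true)) < 2L) {
    stop("y_true must contain both classes", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # group tied scores so they cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  points <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
    utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

fit_baseline <- function(model, x_train, y_train, x_test) {
  n_test <- nrow(x_test)
  switch(model,
    logistic = {
      fit <- suppressWarnings(stats::glm.fit(
        cbind(1, x_train), y_train,
        family = stats::binomial()
      ))
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      stats::plogis(drop(cbind(1, x_test) %*% coefs))
    },
    svm = {
      fit <- e1071::svm(
        x = x_train, y = factor(y_train, levels = c(0L, 1L)),
        kernel = "radial", probability = TRUE, scale = FALSE
      )
      pr <- stats::predict(fit, x_test, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(
        x = as.data.frame(x_train), y = factor(y_train, levels = c(0L, 1L))
      )
      stats::predict(fit, as.data.frame(x_test), type = "raw")[, "1"]
    },
    gdbt = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("the gdbt comparator needs the xgboost package", call. = FALSE)
      }
      fit <- xgboost::xgboost(
        data = x_train, label = y_train,
        nrounds = 50, objective = "binary:logistic",
        max_depth = 3, eta = 0.1, verbose = 0, nthread = 1
      )
      stats::predict(fit, x_test)
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Stratified K-fold cross-validated model comparison
#'
#' Compares single classifiers (`"logistic"`, `"svm"`, `"naive_bayes"`,
#' optionally `"gdbt"`) with the boosted stacked `"ensemble"` under
#' stratified K-fold cross-validation. Held-out scoring always uses
#' original rows only; synthetic rows (which carry provenance flags) are
#' never scored. Three augmentation policies are offered:
#'
#' * `"none"` — no augmentation.
#' * `"train_folds_only"` — SMOTE is run inside each fold on the training
#'   originals only (leakage-safe, the default).
#' * `"whole_dataset_first"` — SMOTE is run once on the full dataset before
#'   splitting; synthetic rows join every training set. This reproduces a
#'   workflow that augments before cross-validation and is optimistic,
#'   since synthetic rows interpolated from test-fold originals reach the
#'   training data.
#'
#' Per model, per-fold metrics are aggregated to means and SDs; pooled
#' out-of-fold scores give one ROC/AUC per model; and each baseline is
#' compared with the ensemble by a paired two-sided t test on per-fold
#' accuracies.
#'
#' @param data A design tibble with `label` (original rows only; any
#'   `provenance` column must be all `"original"`).
#' @param models Character vector of model names; default the three
#'   classical baselines plus the ensemble.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and seeded fits.
#' @param augmentation Augmentation policy (see above).
#' @param smote_m,smote_k SMOTE parameters when augmentation is on.
#' @param n_rounds,stacking Ensemble hyperparameters.
#' @return An `eval_report`: `$metrics` (model x fold), `$summary`
#'   (mean/SD per model/metric), `$roc` (points per model), `$auc`,
#'   `$comparisons` (paired t-test p-values vs the ensemble), and the
#'   settings used.
#' @export
kfold_evaluate <- function(data,
                           models = c(
                             "logistic", "svm", "naive_bayes", "ensemble"
                           ),
                           k = 5, seed = NULL,
                           augmentation = c(
                             "train_folds_only", "none", "whole_dataset_first"
                           ),
                           smote_m = 1, smote_k = 5,
                           n_rounds = 10,
                           stacking = "out_of_fold") {
  augmentation <- match.arg(augmentation)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if ("provenance" %in% names(data) && any(data$provenance != "original")) {
    stop("pass original rows only; augmentation is applied per policy",
      call. = FALSE
    )
  }
  y <- check_binary_labels(data$label, "data$label")
  maybe_set_seed(seed)
  folds <- stratified_folds(y, k)
  roles <- design_roles(data)

  whole_aug <- NULL
  if (augmentation == "whole_dataset_first") {
    whole_aug <- smote_augment(data, m = smote_m, k = smote_k)
  }

  metric_rows <- list()
  score_store <- stats::setNames(
    replicate(length(models), numeric(nrow(data)), simplify = FALSE), models
  )

  for (f in seq_len(k)) {
    te <- folds == f
    train_tab <- data[!te, , drop = FALSE]
    attr(train_tab, "roles") <- roles
    if (augmentation == "train_folds_only") {
      train_tab <- smote_augment(train_tab, m = smote_m, k = smote_k)
    } else if (augmentation == "whole_dataset_first") {
      synth <- whole_aug[whole_aug$provenance == "smote", , drop = FALSE]
      train_tab <- dplyr::bind_rows(
        dplyr::mutate(train_tab, provenance = "original"), synth
      )
    }
    x_train <- as_feature_matrix(train_tab)
    y_train <- as.integer(train_tab$label)
    x_test <- as_feature_matrix(data[te, , drop = FALSE])
    y_test <- y[te]

    for (mdl in models) {
      if (mdl == "ensemble") {
        fit <- fit_ensemble(train_tab,
          n_rounds = n_rounds, stacking = stacking
        )
        pr <- predict(fit, x_test)$.pred_prob
      } else {
        pr <- fit_baseline(mdl, x_train, y_train, x_test)
      }
      score_store[[mdl]][te] <- pr
      metric_rows[[length(metric_rows) + 1L]] <- dplyr::mutate(
        compute_metrics(y_test, as.integer(pr >= 0.5)),
        model = mdl, fold = f, .before = 1
      )
    }
  }

  metrics <- dplyr::bind_rows(metric_rows)
  summary <- dplyr::summarise(
    dplyr::group_by(
      tidyr::pivot_longer(
        metrics[c(
          "model", "fold", "accuracy", "precision",
          "sensitivity", "specificity", "f_measure"
        )],
        cols = -c("model", "fold"),
        names_to = "metric", values_to = "value"
      ),
      .data$model, .data$metric
    ),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  roc <- lapply(score_store, function(s) roc_and_auc(y, s))
  auc <- tibble::tibble(
    model = models,
    auc = vapply(roc, `[[`, numeric(1), "auc")
  )
  comparisons <- NULL
  if ("ensemble" %in% models && length(models) > 1L) {
    acc <- tidyr::pivot_wider(
      metrics[c("model", "fold", "accuracy")],
      names_from = "model", values_from = "accuracy"
    )
    others <- setdiff(models, "ensemble")
    comparisons <- tibble::tibble(
      model = others,
      p_value = vapply(others, function(mdl) {
        p <- tryCatch(
          stats::t.test(acc$ensemble, acc[[mdl]], paired = TRUE)$p.value,
          error = function(e) NA_real_
        )
        # constant fold differences give no paired evidence either way
        if (!is.finite(p)) NA_real_ else p
      }, numeric(1))
    )
  }
  structure(
    list(
      metrics = metrics,
      summary = summary,
      roc = lapply(roc, `[[`, "points"),
      auc = auc,
      comparisons = comparisons,
      k = as.integer(k), seed = seed,
      augmentation = augmentation,
      models = models
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(
    "<eval_report> K = ", x$k, ", augmentation = ", x$augmentation, "\n",
    sep = ""
  )
  acc <- x$summary[x$summary$metric == "accuracy", ]
  print(dplyr::left_join(acc, x$auc, by = "model"))
  invisible(x)
}

#' Tidy components of an evaluation report
#'
#' @param x An `eval_report`.
#' @param which One of `"metrics"` (per model x fold), `"summary"`
#'   (mean/SD), `"auc"`, `"comparisons"` (paired tests vs ensemble).
#' @param ... Unused.
#' @return The requested tibble.
#' @exportS3Method
tidy.eval_report <- function(x, which = c(
                               "metrics", "summary", "auc", "comparisons"
                             ), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Bar chart of per-model metrics or overlaid ROC curves
#'
#' @param object An `eval_report`.
#' @param type `"metrics"` or `"roc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.eval_report <- function(object, type = c("metrics", "roc"), ...) {
  type <- match.arg(type)
  if (type == "metrics") {
    ggplot2::ggplot(
      object$summary,
      ggplot2::aes(.data$metric, .data$mean, fill = .data$model)
    ) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(
        ggplot2::aes(
          ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
        ),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3
      ) +
      ggplot2::labs(y = "cross-validated mean", x = NULL) +
      ggplot2::theme_minimal()
  } else {
    pts <- dplyr::bind_rows(object$roc, .id = "model")
    ggplot2::ggplot(
      pts, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)
    ) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = 2, colour = "grey") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate") +
      ggplot2::theme_minimal()
  }
}

#' Write an evaluation report to disk
#'
#' Writes `eval_report.json` (summary, AUC, comparisons, settings),
#' `metrics.csv` (model x fold x metric) and one `roc_<model>.csv` per
#' model.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      k = report$k,
      seed = report$seed,
      augmentation = report$augmentation,
      models = report$models,
      summary = report$summary,
      auc = report$auc,
      comparisons = report$comparisons
    ),
    file.path(dir, "eval_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  for (mdl in names(report$roc)) {
    readr::write_csv(
      report$roc[[mdl]], file.path(dir, paste0("roc_", mdl, ".csv"))
    )
  }
  invisible(dir)
}
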