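#' Specify a weak learner family for boosting
#'
#' Three families are offered, matching the ensemble's heterogeneous base
#' classifiers: regularized logistic regression, an RBF support vector
#' machine and Gaussian naive Bayes. Boosting requires per-sample weights:
#' families that can fit weights directly do (`"weighted_fit"`: logistic
#' via weighted IRLS, naive Bayes via weighted class moments); the SVM
#' cannot, so it is trained on a seeded weighted resample of the data
#' (`"resample"`). The mode used is recorded on the spec.
#'
#' @param family `"logistic"`, `"support_vector"` or `"naive_bayes"`.
#' @param mode `"weighted_fit"` or `"resample"`; default is the family's
#'   natural mode.
#' @param ... Family hyperparameters: `cost` and `gamma` for the SVM
#'   (defaults `cost = 1`, gamma = 1/p), `var_floor` for naive Bayes.
#' @return A `weak_learner_spec` with `$fit(x, y, w)` and
#'   `$predict(model, x)` functions (labels in 0/1).
#' @export
weak_learner <- function(family = c("logistic", "support_vector", "naive_bayes"),
                         mode = NULL, ...) {
  family <- match.arg(family)
  params <- list(...)
  mode <- mode %||% switch(family,
    logistic = "weighted_fit",
    support_vector = "resample",
    naive_bayes = "weighted_fit"
  )
  mode <- match.arg(mode, c("weighted_fit", "resample"))
  fns <- switch(family,
    logistic = list(
      fit = function(x, y, w) fit_weighted_logistic(x, y, w),
      predict = function(model, x) {
        p <- stats::plogis(drop(cbind(1, x) %*% model$coef))
        as.integer(p >= 0.5)
      }
    ),
    support_vector = list(
      fit = function(x, y, w) {
        fit_resampled_svm(x, y, w,
          cost = params$cost %||% 1,
          gamma = params$gamma %||% (1 / ncol(x))
        )
      },
      predict = function(model, x) {
        as.integer(as.character(stats::predict(model, x)))
      }
    ),
    naive_bayes = list(
      fit = function(x, y, w) {
        fit_weighted_gnb(x, y, w, var_floor = params$var_floor %||% 1e-9)
      },
      predict = function(model, x) predict_weighted_gnb(model, x)
    )
  )
  structure(
    list(
      family = family, mode = mode, params = params,
      fit = fns$fit, predict = fns$predict
    ),
    class = "weak_learner_spec"
  )
}

#' A custom weak learner (e.g. a deterministic stub for testing)
#'
#' @param fit `function(x, y, w)` returning a model object (or `NULL` on
#'   failure).
#' @param predict `function(model, x)` returning 0/1 predictions.
#' @param family Label recorded on the spec.
#' @return A `weak_learner_spec`.
#' @export
weak_learner_custom <- function(fit, predict, family = "custom") {
  structure(
    list(
      family = family, mode = "custom", params = list(),
      fit = fit, predict = predict
    ),
    class = "weak_learner_spec"
  )
}

fit_weighted_logistic <- function(x, y, w) {
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, x), y,
    weights = w * length(y),
    family = stats::binomial()
  ))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  list(coef = coefs)
}

fit_resampled_svm <- function(x, y, w, cost = 1, gamma = NULL) {
  n <- length(y)
  idx <- sample.int(n, n, replace = TRUE, prob = w)
  # a weighted bootstrap can drop a class entirely; reinstate its
  # highest-weight member so the fit stays two-class
  for (cls in c(0L, 1L)) {
    if (!any(y[idx] == cls)) {
      pool <- which(y == cls)
      idx[sample.int(n, 1)] <- pool[which.max(w[pool])]
    }
  }
  tryCatch(
    e1071::svm(
      x = x[idx, , drop = FALSE],
      y = factor(y[idx], levels = c(0L, 1L)),
      kernel = "radial", cost = cost,
      gamma = gamma %||% (1 / ncol(x)),
      scale = FALSE
    ),
    error = function(e) NULL
  )
}

fit_weighted_gnb <- function(x, y, w, var_floor = 1e-9) {
  w <- w / sum(w)
  classes <- c(0L, 1L)
  stats_by_class <- lapply(classes, function(cls) {
    wi <- w[y == cls]
    xi <- x[y == cls, , drop = FALSE]
    wt <- sum(wi)
    mu <- colSums(xi * wi) / wt
    va <- colSums(sweep(xi, 2, mu)^2 * wi) / wt
    list(prior = wt, mu = mu, var = pmax(va, var_floor))
  })
  names(stats_by_class) <- as.character(classes)
  list(classes = classes, stats = stats_by_class)
}

predict_weighted_gnb <- function(model, x) {
  scores <- vapply(model$classes, function(cls) {
    st <- model$stats[[as.character(cls)]]
    ll <- -0.5 * rowSums(
      sweep(sweep(x, 2, st$mu)^2, 2, st$var, "/") +
        matrix(log(2 * pi * st$var),
          nrow(x), ncol(x),
          byrow = TRUE
        )
    )
    ll + log(st$prior)
  }, numeric(nrow(x)))
  scores <- matrix(scores, ncol = 2)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Uniform initial boosting weight distribution
#'
#' @param n Number of training samples (>= 1).
#' @return A probability vector of length `n`, each entry `1/n`.
#' @export
init_weights <- function(n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  rep(1 / n, n)
}

#' Weak-classifier weight from its weighted error
#'
#' \eqn{\alpha = \frac{1}{2}\ln((1-\epsilon)/\epsilon)}, with \eqn{\epsilon}
#' clipped into `[eps_min, 1 - eps_min]` so the weight stays finite at the
#' formula's poles. An error of exactly 0.5 (no better than chance) gives
#' zero weight; the clip ceiling is the weight of a perfect classifier.
#'
#' @param epsilon Weighted error rate in `[0, 1]`.
#' @param eps_min Clipping bound (default 1e-10).
#' @return The round weight alpha.
#' @export
boost_alpha <- function(epsilon, eps_min = 1e-10) {
  eps_c <- pmin(pmax(epsilon, eps_min), 1 - eps_min)
  0.5 * log((1 - eps_c) / eps_c)
}

#' AdaBoost a weak learner family
#'
#' Standard discrete AdaBoost: starting from uniform weights, each round
#' fits the weak learner under the current distribution \eqn{D_t}, computes
#' the weighted error \eqn{\epsilon_t = \sum_{h_t(x_i) \ne y_i} D_t(i)},
#' sets \eqn{\alpha_t = \frac{1}{2}\ln((1-\epsilon_t)/\epsilon_t)} (with
#' \eqn{\epsilon_t} clipped to `[eps_min, 1 - eps_min]` so the weight stays
#' finite) and reweights
#' \eqn{D_{t+1}(i) \propto D_t(i) e^{\mp \alpha_t}} (down for correct, up
#' for misclassified), renormalized to sum to 1. A round with
#' \eqn{\epsilon_t \ge 0.5} triggers one weight re-initialization; a second
#' such round stops boosting early. A perfect round
#' (\eqn{\epsilon_t \le} `eps_min`) is recorded and boosting stops, since
#' the weight update leaves the distribution unchanged and further rounds
#' would repeat it. A weak learner failing to fit skips the round with a
#' warning.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels with both classes present.
#' @param learner A `weak_learner_spec`.
#' @param n_rounds Maximum number of boosting rounds T (default 10).
#' @param seed Integer seed (needed when the learner resamples).
#' @param eps_min Error clipping bound (default 1e-10).
#' @return A `boosted_classifier`: per-round models, weights
#'   \eqn{\alpha_t}, errors \eqn{\epsilon_t}, and the full weight history
#'   (a (rounds + 1) x n matrix, each row summing to 1).
#' @export
boost <- function(x, y, learner, n_rounds = 10, seed = NULL,
                  eps_min = 1e-10) {
  stopifnot(inherits(learner, "weak_learner_spec"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- check_binary_labels(y)
  maybe_set_seed(seed)
  n <- length(y)
  d <- init_weights(n)
  history <- list(d)
  rounds <- list()
  reinit_used <- FALSE
  t <- 0L
  while (t < n_rounds) {
    t <- t + 1L
    model <- learner$fit(x, y, d)
    if (is.null(model)) {
      warning("weak learner failed to fit in round ", t, "; round skipped",
        call. = FALSE
      )
      next
    }
    pred <- learner$predict(model, x)
    eps <- sum(d[pred != y])
    if (eps >= 0.5) {
      if (reinit_used) break
      d <- init_weights(n)
      reinit_used <- TRUE
      next
    }
    alpha <- boost_alpha(eps, eps_min)
    rounds[[length(rounds) + 1L]] <- list(
      model = model, alpha = alpha, epsilon = eps
    )
    d <- d * exp(ifelse(pred == y, -alpha, alpha))
    d <- d / sum(d)
    history[[length(history) + 1L]] <- d
    if (eps <= eps_min) break
  }
  if (!length(rounds)) {
    stop("no boosting round succeeded; weak learner never beat chance",
      call. = FALSE
    )
  }
  structure(
    list(
      family = learner$family,
      learner = learner,
      rounds = rounds,
      weight_history = do.call(rbind, history),
      n_rounds = as.integer(n_rounds),
      seed = seed,
      feature_names = colnames(x)
    ),
    class = "boosted_classifier"
  )
}

#' Boosted margin score of samples
#'
#' The weighted vote \eqn{H_{mT}(x) = \sum_t \alpha_t h_t(x)} with each
#' weak prediction mapped to \eqn{\{-1, +1\}}; the sign is the boosted hard
#' prediction and the magnitude its confidence.
#'
#' @param object A fitted `boosted_classifier`.
#' @param x Feature matrix.
#' @return A numeric score per sample.
#' @export
boosted_score <- function(object, x) {
  if (!inherits(object, "boosted_classifier") || !length(object$rounds)) {
    stop("need a fitted boosted_classifier", call. = FALSE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  score <- numeric(nrow(x))
  for (r in object$rounds) {
    h <- 2 * object$learner$predict(r$model, x) - 1
    score <- score + r$alpha * h
  }
  score
}

#' @export
predict.boosted_classifier <- function(object, newdata, ...) {
  as.integer(boosted_score(object, newdata) >= 0)
}

#' Per-round weights and errors of a boosted classifier
#'
#' @param x A `boosted_classifier`.
#' @param ... Unused.
#' @return A tibble with `round`, `alpha`, `epsilon`.
#' @exportS3Method
tidy.boosted_classifier <- function(x, ...) {
  tibble::tibble(
    round = seq_along(x$rounds),
    alpha = vapply(x$rounds, `[[`, numeric(1), "alpha"),
    epsilon = vapply(x$rounds, `[[`, numeric(1), "epsilon")
  )
}

#' Fit the boosted heterogeneous ensemble with logistic stacking
#'
#' Boosts each of the three weak-learner families on the design matrix,
#' forms the three-column matrix of boosted margin scores
#' \eqn{[H_{1T}, H_{2T}, H_{3T}]}, and fits a logistic combiner
#' \deqn{\log(H(x)/(1-H(x))) = c_0 + \sum_{m=1}^{3} c_m H_{mT}(x)}
#' on it. The stacking scores come either from the training data itself
#' (`"in_sample"`) or from internal stratified 5-fold out-of-fold
#' prediction (`"out_of_fold"`, the default, which avoids optimistic
#' combiner weights). The final per-family members are always refit on the
#' full data.
#'
#' A degenerate (constant or aliased) score column gets a zero combiner
#' coefficient with a warning.
#'
#' @param data A design tibble with a `label` column (original and/or
#'   augmented rows; every row is used for training).
#' @param n_rounds Boosting rounds T per family (default 10).
#' @param stacking `"out_of_fold"` (default) or `"in_sample"`.
#' @param seed Integer seed.
#' @param learners A named list of three `weak_learner_spec`s (default:
#'   logistic, support vector, naive Bayes).
#' @param inner_k Folds for out-of-fold stacking (default 5).
#' @return An `ensemble_model` with `$members` (boosted classifiers),
#'   `$coef` (c0..c3), and training metadata.
#' @export
fit_ensemble <- function(data, n_rounds = 10,
                         stacking = c("out_of_fold", "in_sample"),
                         seed = NULL,
                         learners = NULL, inner_k = 5) {
  stacking <- match.arg(stacking)
  y <- check_binary_labels(data$label, "data$label")
  x <- as_feature_matrix(data)
  learners <- learners %||% list(
    logistic = weak_learner("logistic"),
    support_vector = weak_learner("support_vector"),
    naive_bayes = weak_learner("naive_bayes")
  )
  m_names <- names(learners)
  maybe_set_seed(seed)

  members <- lapply(learners, function(sp) {
    boost(x, y, sp, n_rounds = n_rounds)
  })

  if (stacking == "in_sample") {
    scores <- vapply(
      members, function(mb) boosted_score(mb, x), numeric(nrow(x))
    )
    score_y <- y
  } else {
    folds <- stratified_folds(y, inner_k)
    scores <- matrix(NA_real_, nrow(x), length(learners))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      te <- folds == f
      for (j in seq_along(learners)) {
        mb <- boost(
          x[tr, , drop = FALSE], y[tr], learners[[j]],
          n_rounds = n_rounds
        )
        scores[te, j] <- boosted_score(mb, x[te, , drop = FALSE])
      }
    }
    score_y <- y
  }
  colnames(scores) <- m_names

  keep <- apply(scores, 2, function(s) stats::sd(s) > 0)
  if (!all(keep)) {
    warning(
      "constant stacking score column(s) dropped from the combiner: ",
      paste(m_names[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, scores[, keep, drop = FALSE]), score_y,
    family = stats::binomial()
  ))
  coefs <- stats::setNames(numeric(length(learners) + 1L), c("c0", m_names))
  got <- fit$coefficients
  got[is.na(got)] <- 0
  coefs["c0"] <- got[1]
  coefs[m_names[keep]] <- got[-1]
  if (anyNA(fit$coefficients)) {
    warning("aliased stacking column(s) assigned zero weight", call. = FALSE)
  }

  structure(
    list(
      members = members,
      coef = coefs,
      stacking = stacking,
      n_rounds = as.integer(n_rounds),
      seed = seed,
      feature_names = colnames(x)
    ),
    class = "ensemble_model"
  )
}

#' Predict outcome probabilities and labels from the ensemble
#'
#' Computes each member's boosted margin score on the new samples and maps
#' the stacked linear predictor through the logistic function to get
#' \eqn{H(x) \in (0, 1)}; the hard label is 1 iff `H(x) >= threshold`.
#'
#' @param object An `ensemble_model`.
#' @param newdata A tibble or matrix containing the model's feature
#'   columns.
#' @param threshold Classification threshold on the probability
#'   (default 0.5).
#' @param ... Unused.
#' @return A tibble with `.pred_prob` and `.pred_class`.
#' @export
predict.ensemble_model <- function(object, newdata, threshold = 0.5, ...) {
  x <- if (is.matrix(newdata)) {
    newdata
  } else {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing)) {
      stop("newdata lacks feature column(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    as.matrix(newdata[object$feature_names])
  }
  storage.mode(x) <- "double"
  scores <- vapply(
    object$members, function(mb) boosted_score(mb, x), numeric(nrow(x))
  )
  scores <- matrix(scores, nrow = nrow(x))
  eta <- object$coef[1] + drop(scores %*% object$coef[-1])
  prob <- stats::plogis(eta)
  tibble::tibble(
    .pred_prob = prob,
    .pred_class = as.integer(prob >= threshold)
  )
}

#' Stacking coefficients of a fitted ensemble
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return A tibble with `term` (c0 and one term per member family) and
#'   `estimate`.
#' @exportS3Method
tidy.ensemble_model <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of a fitted ensemble
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return A tibble with member families, rounds fitted, stacking mode and
#'   seed.
#' @exportS3Method
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    families = paste(
      vapply(x$members, `[[`, character(1), "family"),
      collapse = "+"
    ),
    n_rounds = x$n_rounds,
    rounds_fitted = paste(
      vapply(x$members, function(m) length(m$rounds), integer(1)),
      collapse = "/"
    ),
    stacking = x$stacking,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> stacking =", x$stacking, "\n")
  print(tidy(x))
  invisible(x)
}

#' Serialize a fitted ensemble's structure to JSON
#'
#' Writes the stacking coefficients and every member's per-round weights
#' and errors (not the weak-learner objects themselves, which are R-native)
#' so a run's model structure is inspectable as text.
#'
#' @param model An `ensemble_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(model, path) {
  jsonlite::write_json(
    list(
      coef = as.list(model$coef),
      stacking = model$stacking,
      n_rounds = model$n_rounds,
      members = lapply(model$members, function(m) {
        list(
          family = m$family,
          alpha = vapply(m$rounds, `[[`, numeric(1), "alpha"),
          epsilon = vapply(m$rounds, `[[`, numeric(1), "epsilon")
        )
      }),
      features = model$feature_names
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold keeps both classes when counts allow
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has fewer members (", length(idx),
        ") than folds (", k, "); stratification impossible",
        call. = FALSE
      )
    }
    folds[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}
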