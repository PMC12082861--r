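#' Two-sample optimum sample size for one feature
#'
#' The classical power-based sample size for detecting a between-class mean
#' difference:
#' \deqn{n = \sigma^2 (Q_1^{-1} + Q_2^{-1}) (\mu_\alpha + \mu_\beta)^2 / \delta^2}
#' where \eqn{\sigma} is the pooled standard deviation, \eqn{\delta} the
#' observed mean difference, \eqn{Q_1, Q_2} the class proportions and
#' \eqn{\mu_\alpha, \mu_\beta} standard-normal quantiles for the two error
#' rates (defaults: two-sided \eqn{\alpha = 0.05} giving 1.96, and
#' \eqn{\beta = 0.2} giving 0.8416). The result is rounded up. A zero mean
#' difference makes the requirement infinite, flagged as such.
#'
#' @param x0,x1 Feature values in class 0 and class 1 (non-empty, positive
#'   pooled SD).
#' @param alpha Type-I error rate (two-sided).
#' @param beta Type-II error rate.
#' @return A list with `n` (possibly `Inf`), `sigma`, `delta`, `q1`, `q2`,
#'   `mu_alpha`, `mu_beta`, `infinite` flag.
#' @export
estimate_sample_size <- function(x0, x1, alpha = 0.05, beta = 0.2) {
  n0 <- length(x0)
  n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) {
    stop("both classes need >= 2 values", call. = FALSE)
  }
  sigma2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) /
    (n0 + n1 - 2)
  if (sigma2 <= 0) stop("pooled standard deviation must be positive", call. = FALSE)
  delta <- mean(x1) - mean(x0)
  q1 <- n0 / (n0 + n1)
  q2 <- n1 / (n0 + n1)
  mu_alpha <- stats::qnorm(1 - alpha / 2)
  mu_beta <- stats::qnorm(1 - beta)
  if (delta == 0) {
    n <- Inf
  } else {
    n <- ceiling(sigma2 * (1 / q1 + 1 / q2) * (mu_alpha + mu_beta)^2 / delta^2)
  }
  list(
    n = n, sigma = sqrt(sigma2), delta = delta, q1 = q1, q2 = q2,
    mu_alpha = mu_alpha, mu_beta = mu_beta, infinite = !is.finite(n)
  )
}

#' Aggregate per-feature sample size requirements into one per dataset
#'
#' The default aggregation is the maximum: only the largest per-feature
#' requirement guarantees that every feature is adequately powered. The
#' mean is available as a laxer alternative.
#'
#' @param feature_ns Numeric vector of per-feature requirements (may
#'   contain `Inf` flags from zero-difference features).
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return A single count (possibly `Inf`).
#' @export
dataset_sample_size <- function(feature_ns, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(feature_ns)) stop("need >= 1 feature estimate", call. = FALSE)
  if (all(!is.finite(feature_ns))) {
    stop("all per-feature requirements are infinite: ",
      "insufficient regardless of augmentation",
      call. = FALSE
    )
  }
  out <- switch(aggregate,
    max = max(feature_ns),
    mean = ceiling(mean(feature_ns[is.finite(feature_ns)]))
  )
  out
}

#' Per-feature and per-block sample size requirements of a design matrix
#'
#' Runs [estimate_sample_size()] on every feature column and aggregates per
#' block and overall (maximum over blocks by default). The overall
#' requirement is what the augmentation decision compares the available
#' sample count against.
#'
#' @param design A design tibble with a `label` column (e.g. from
#'   [assemble_design()]).
#' @param alpha,beta Error rates passed to [estimate_sample_size()].
#' @param aggregate Per-block aggregation rule (see
#'   [dataset_sample_size()]).
#' @return A `sample_size_estimate`: `$per_feature` tibble, `$per_block`
#'   tibble, `$overall` count, `$n_available`, `$sufficient` flag.
#' @export
estimate_design_sample_size <- function(design, alpha = 0.05, beta = 0.2,
                                        aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  y <- check_binary_labels(design$label, "design labels")
  roles <- design_roles(design)
  cols <- feature_columns(design)
  per_feature <- purrr::map(cols, function(f) {
    est <- estimate_sample_size(
      design[[f]][y == 0L], design[[f]][y == 1L],
      alpha = alpha, beta = beta
    )
    tibble::tibble(
      column = f,
      block = if (!is.null(roles)) {
        roles$block[match(f, roles$column)]
      } else {
        NA_character_
      },
      sigma = est$sigma, delta = est$delta, n = est$n
    )
  })
  per_feature <- dplyr::bind_rows(per_feature)
  per_block <- dplyr::summarise(
    dplyr::group_by(per_feature, .data$block),
    n = dataset_sample_size(.data$n, aggregate = aggregate),
    .groups = "drop"
  )
  overall <- dataset_sample_size(per_block$n, aggregate = "max")
  structure(
    list(
      per_feature = per_feature,
      per_block = per_block,
      overall = overall,
      n_available = nrow(design),
      sufficient = nrow(design) >= overall,
      alpha = alpha, beta = beta, aggregate = aggregate
    ),
    class = "sample_size_estimate"
  )
}

#' Sample size requirements from the selected raw features of a cohort
#'
#' The study-faithful variant: [estimate_sample_size()] runs on every
#' selected feature of every block (the raw selected values, before any
#' principal component reduction), aggregated per block and overall.
#' Binary discrete features enter the same formula, their Bernoulli spread
#' acting as the per-class variance. Features whose class means happen to
#' coincide exactly are skipped with their infinite flag recorded.
#'
#' @param cohort A labelled `multiomics_cohort`.
#' @param report The `selection_report` from [select_features()].
#' @param alpha,beta Error rates.
#' @param aggregate Per-block aggregation rule.
#' @return A `sample_size_estimate` (same shape as
#'   [estimate_design_sample_size()]).
#' @export
estimate_cohort_sample_size <- function(cohort, report,
                                        alpha = 0.05, beta = 0.2,
                                        aggregate = c("max", "mean")) {
  stopifnot(
    inherits(cohort, "multiomics_cohort"),
    inherits(report, "selection_report")
  )
  aggregate <- match.arg(aggregate)
  y <- check_binary_labels(cohort$labels, "cohort labels")
  per_feature <- list()
  for (b in cohort$blocks) {
    sel <- selected_features(report, b$name)
    if (!length(sel)) next
    rows <- purrr::map(sel, function(f) {
      v <- as.numeric(b$values[[f]])
      est <- estimate_sample_size(v[y == 0L], v[y == 1L],
        alpha = alpha, beta = beta
      )
      tibble::tibble(
        column = f, block = b$name,
        sigma = est$sigma, delta = est$delta, n = est$n
      )
    })
    per_feature[[b$name]] <- dplyr::bind_rows(rows)
  }
  if (!length(per_feature)) {
    stop("selection is empty; no features to estimate", call. = FALSE)
  }
  per_feature <- dplyr::bind_rows(per_feature)
  per_block <- dplyr::summarise(
    dplyr::group_by(per_feature, .data$block),
    n = dataset_sample_size(.data$n, aggregate = aggregate),
    .groups = "drop"
  )
  overall <- dataset_sample_size(per_block$n, aggregate = "max")
  structure(
    list(
      per_feature = per_feature,
      per_block = per_block,
      overall = overall,
      n_available = length(y),
      sufficient = length(y) >= overall,
      alpha = alpha, beta = beta, aggregate = aggregate
    ),
    class = "sample_size_estimate"
  )
}

#' @export
print.sample_size_estimate <- function(x, ...) {
  cat(
    "<sample_size_estimate> required n = ", x$overall,
    " vs available n = ", x$n_available,
    if (x$sufficient) " (sufficient)\n" else " (augmentation needed)\n",
    sep = ""
  )
  print(x$per_block)
  invisible(x)
}

snap_to_categories <- function(new_vals, original_vals) {
  cats <- sort(unique(original_vals))
  cats[vapply(
    new_vals, function(v) which.min(abs(cats - v)), integer(1)
  )]
}

#' SMOTE whole-dataset augmentation
#'
#' For every original row, its `k` same-label Euclidean nearest neighbours
#' are found; `m` of them are drawn uniformly without replacement, and for
#' each a synthetic row is interpolated as
#' \eqn{x_{new} = x_i + u (x_{ij} - x_i)} with a single uniform
#' \eqn{u \sim U(0,1)} per generated row (one scalar gap multiplier, not
#' per-coordinate). The synthetic row inherits its seed row's label, so
#' class balance is preserved exactly and every generated coordinate lies
#' on the segment between seed and neighbour. Used here to enlarge a whole
#' near-balanced dataset, not to rebalance classes.
#'
#' Discrete pass-through columns (identified via [design_roles()]) are
#' interpolated and then snapped to the nearest original category so they
#' keep their coding semantics.
#'
#' @param data A design tibble with `label` (and optionally `sample_id`)
#'   columns.
#' @param m Synthetic rows per original row (`m <= k`), default 1.
#' @param k Number of same-label nearest neighbours, default 5. A class
#'   with fewer than `k + 1` members has `k` reduced for it, with a
#'   warning.
#' @param seed Integer seed for the neighbour draws and gap multipliers.
#' @return An `augmentation_result` tibble: originals followed by
#'   generated rows, with a `provenance` column (`"original"` / `"smote"`)
#'   and attributes `f1_before`, `f1_after` (maximum Fisher's discriminant
#'   ratio, see [fisher_ratio_f1()]) and `params`.
#' @export
smote_augment <- function(data, m = 1, k = 5, seed = NULL) {
  if (m > k) stop("m must be <= k", call. = FALSE)
  if (m < 1L || k < 1L) stop("m and k must be >= 1", call. = FALSE)
  y <- check_binary_labels(data$label, "data$label")
  maybe_set_seed(seed)
  x <- as_feature_matrix(data)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  roles <- design_roles(data)
  discrete_cols <- if (!is.null(roles)) {
    roles$column[roles$role == "passthrough"]
  } else {
    character()
  }

  warned <- integer()
  new_rows <- vector("list", n)
  new_labels <- vector("list", n)
  seed_ids <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- setdiff(which(y == y[i]), i)
    k_i <- min(k, length(pool))
    if (k_i < 1L) {
      stop("class of row ", i, " has a single member; cannot interpolate",
        call. = FALSE
      )
    }
    if (k_i < k && !(y[i] %in% warned)) {
      warning(
        "class ", y[i], " has fewer than k + 1 members; using k = ", k_i,
        call. = FALSE
      )
      warned <- c(warned, y[i])
    }
    nb <- pool[order(d[i, pool])][seq_len(k_i)]
    chosen <- nb[sample.int(k_i, min(m, k_i))]
    gen <- matrix(NA_real_, length(chosen), ncol(x))
    for (j in seq_along(chosen)) {
      u <- stats::runif(1)
      gen[j, ] <- x[i, ] + u * (x[chosen[j], ] - x[i, ])
    }
    new_rows[[i]] <- gen
    new_labels[[i]] <- rep(y[i], length(chosen))
    seed_ids[[i]] <- rep(i, length(chosen))
  }
  gen <- do.call(rbind, new_rows)
  colnames(gen) <- colnames(x)
  gen <- tibble::as_tibble(gen)
  for (col in discrete_cols) {
    gen[[col]] <- snap_to_categories(gen[[col]], data[[col]])
  }
  seed_idx <- unlist(seed_ids)
  gen_tab <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = if ("sample_id" %in% names(data)) {
        paste0(data$sample_id[seed_idx], ".smote", stats::ave(
          seed_idx, seed_idx,
          FUN = seq_along
        ))
      } else {
        paste0("smote", seq_along(seed_idx))
      },
      label = unlist(new_labels)
    ),
    gen
  )
  orig_tab <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = if ("sample_id" %in% names(data)) {
        data$sample_id
      } else {
        paste0("orig", seq_len(n))
      },
      label = y
    ),
    tibble::as_tibble(x)
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(orig_tab, provenance = "original"),
    dplyr::mutate(gen_tab, provenance = "smote")
  )
  f1_before <- fisher_ratio_f1(x, y)$f1
  f1_after <- fisher_ratio_f1(as_feature_matrix(out), out$label)$f1
  attr(out, "roles") <- roles
  attr(out, "f1_before") <- f1_before
  attr(out, "f1_after") <- f1_after
  attr(out, "params") <- list(method = "smote", m = m, k = k, seed = seed)
  class(out) <- c("augmentation_result", class(tibble::tibble()))
  out
}

#' Gaussian-noise augmentation baseline
#'
#' Generates one synthetic row per original by adding independent Gaussian
#' noise per feature, scaled by `scale` times that feature's standard
#' deviation; labels are copied. This is the simple jitter baseline SMOTE
#' is compared against: it inflates within-class spread, so it tends to
#' lower the maximum Fisher's discriminant ratio where SMOTE raises it.
#'
#' @param data A design tibble with a `label` column.
#' @param scale Noise scale as a multiple of each feature's SD
#'   (default 0.2; `0` duplicates the originals).
#' @param seed Integer seed.
#' @return An `augmentation_result` tibble with provenance
#'   `"original"` / `"noise"` and `f1_before` / `f1_after` attributes.
#' @export
noise_augment <- function(data, scale = 0.2, seed = NULL) {
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  y <- check_binary_labels(data$label, "data$label")
  maybe_set_seed(seed)
  x <- as_feature_matrix(data)
  n <- nrow(x)
  sds <- apply(x, 2, stats::sd)
  noise <- matrix(stats::rnorm(n * ncol(x)), n, ncol(x))
  gen <- x + sweep(noise, 2, scale * sds, "*")
  gen <- tibble::as_tibble(gen)
  roles <- design_roles(data)
  discrete_cols <- if (!is.null(roles)) {
    roles$column[roles$role == "passthrough"]
  } else {
    character()
  }
  for (col in discrete_cols) {
    gen[[col]] <- snap_to_categories(gen[[col]], data[[col]])
  }
  gen_tab <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = if ("sample_id" %in% names(data)) {
        paste0(data$sample_id, ".noise1")
      } else {
        paste0("noise", seq_len(n))
      },
      label = y
    ),
    gen
  )
  orig_tab <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = if ("sample_id" %in% names(data)) {
        data$sample_id
      } else {
        paste0("orig", seq_len(n))
      },
      label = y
    ),
    tibble::as_tibble(x)
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(orig_tab, provenance = "original"),
    dplyr::mutate(gen_tab, provenance = "noise")
  )
  attr(out, "roles") <- roles
  attr(out, "f1_before") <- fisher_ratio_f1(x, y)$f1
  attr(out, "f1_after") <- fisher_ratio_f1(as_feature_matrix(out), out$label)$f1
  attr(out, "params") <- list(method = "noise", scale = scale, seed = seed)
  class(out) <- c("augmentation_result", class(tibble::tibble()))
  out
}

#' Augmentation quality before and after generation
#'
#' @param x An `augmentation_result`.
#' @param ... Unused.
#' @return A one-row tibble: method, parameters, row counts, maximum
#'   Fisher's discriminant ratio before and after augmentation.
#' @exportS3Method
glance.augmentation_result <- function(x, ...) {
  p <- attr(x, "params", exact = TRUE)
  tibble::tibble(
    method = p$method,
    n_original = sum(x$provenance == "original"),
    n_generated = sum(x$provenance != "original"),
    f1_before = attr(x, "f1_before", exact = TRUE),
    f1_after = attr(x, "f1_after", exact = TRUE)
  )
}

#' Scatter originals against generated rows on two design columns
#'
#' @param object An `augmentation_result`.
#' @param columns Two feature columns to plot (default: first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.augmentation_result <- function(object, columns = NULL, ...) {
  cols <- columns %||% utils::head(feature_columns(object), 2)
  if (length(cols) < 2L) stop("need two feature columns", call. = FALSE)
  df <- tibble::tibble(
    x = object[[cols[1]]], y = object[[cols[2]]],
    provenance = object$provenance, label = factor(object$label)
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$x, .data$y,
      colour = .data$label, shape = .data$provenance
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = cols[1], y = cols[2]) +
    ggplot2::theme_minimal()
}

#' Maximum Fisher's discriminant ratio of a labelled dataset
#'
#' Per feature, \eqn{f_i = (\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2)};
#' the dataset-level complexity score is the maximum over features. A high
#' value means at least one feature separates the classes well (low class
#' overlap, easier classification). The per-class spread is the sample
#' standard deviation by default; `spread = "se"` divides each class
#' variance by its sample count instead.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Binary 0/1 labels; each class needs >= 2 samples.
#' @param spread `"sd"` (default) or `"se"`.
#' @return A list with `per_feature` (tibble of `feature`, `f`) and `f1`
#'   (the maximum). A feature with zero numerator and denominator scores 0;
#'   zero denominator with positive numerator scores `Inf`.
#' @export
fisher_ratio_f1 <- function(x, y, spread = c("sd", "se")) {
  spread <- match.arg(spread)
  y <- check_binary_labels(y)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L) {
    stop("each class needs >= 2 samples", call. = FALSE)
  }
  x1 <- x[y == 1L, , drop = FALSE]
  x0 <- x[y == 0L, , drop = FALSE]
  num <- (colMeans(x1) - colMeans(x0))^2
  v1 <- apply(x1, 2, stats::var)
  v0 <- apply(x0, 2, stats::var)
  if (spread == "se") {
    v1 <- v1 / nrow(x1)
    v0 <- v0 / nrow(x0)
  }
  den <- v1 + v0
  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  list(
    per_feature = tibble::tibble(
      feature = colnames(x) %||% paste0("V", seq_along(f)),
      f = unname(f)
    ),
    f1 = max(f)
  )
}
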