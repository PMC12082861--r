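#' Select discrete features by exact or chi-square association tests
#'
#' For each feature a feature-level x class-label contingency table is
#' built. Under `method = "auto"` Fisher's exact test is used whenever any
#' expected cell count is below 5 (the conventional validity condition for
#' the chi-square approximation) and the feature is binary; otherwise the
#' chi-square test of independence is used. Features with association
#' p-value below `alpha` are selected. A constant feature carries no
#' information and is reported with p = 1.
#'
#' @param values A data frame / tibble of small-cardinality integer codes
#'   (samples x features).
#' @param labels Binary 0/1 outcome vector.
#' @param alpha Significance level (default 0.05).
#' @param method `"auto"` (expected-count switch), `"fisher"` or `"chisq"`.
#' @return A tibble with one row per feature: `feature_id`, `test_name`,
#'   `statistic`, `p_value`, `selected`.
#' @export
select_discrete <- function(values, labels, alpha = 0.05,
                            method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  labels <- check_binary_labels(labels)
  values <- tibble::as_tibble(values)
  if (ncol(values) == 0L) {
    return(tibble::tibble(
      feature_id = character(), test_name = character(),
      statistic = numeric(), p_value = numeric(), selected = logical()
    ))
  }
  rows <- purrr::map(names(values), function(f) {
    v <- values[[f]]
    lv <- sort(unique(v))
    if (length(lv) < 2L) {
      return(tibble::tibble(
        feature_id = f, test_name = "constant",
        statistic = NA_real_, p_value = 1, selected = FALSE
      ))
    }
    tab <- table(factor(v, levels = lv), factor(labels, levels = c(0L, 1L)))
    tab <- matrix(as.numeric(tab), nrow = length(lv))
    use <- method
    if (use == "auto") {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use <- if (any(expected < 5) && nrow(tab) == 2L) "fisher" else "chisq"
    }
    if (use == "fisher" && nrow(tab) != 2L) use <- "chisq"
    if (use == "fisher") {
      p <- fisher_exact_p(tab)
      tibble::tibble(
        feature_id = f, test_name = "fisher",
        statistic = NA_real_, p_value = p, selected = p < alpha
      )
    } else {
      res <- chi_square_p(tab)
      tibble::tibble(
        feature_id = f, test_name = "chi2",
        statistic = res$statistic, p_value = res$p_value,
        selected = res$p_value < alpha
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Select continuous features by integrating three two-sample tests
#'
#' Each feature's values are split by class label and tested with the
#' pooled-variance t test, the Mann-Whitney U test and one-way ANOVA. The
#' three p-values are then integrated according to `rule`:
#' `"all"` (default, most conservative) requires every p below `alpha`,
#' `"majority"` at least two, `"any"` at least one.
#'
#' @param values A data frame / tibble of finite reals (samples x features).
#' @param labels Binary 0/1 outcome vector; each class must have >= 2
#'   samples.
#' @param alpha Significance level.
#' @param rule Integration rule: `"all"`, `"majority"` or `"any"`.
#' @return A tibble with one row per feature carrying all three statistics
#'   and p-values plus the integrated `selected` flag.
#' @export
select_continuous <- function(values, labels, alpha = 0.05,
                              rule = c("all", "majority", "any")) {
  rule <- match.arg(rule)
  labels <- check_binary_labels(labels)
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L) {
    stop("each class needs >= 2 samples for continuous selection",
      call. = FALSE
    )
  }
  values <- tibble::as_tibble(values)
  i0 <- labels == 0L
  i1 <- labels == 1L
  rows <- purrr::map(names(values), function(f) {
    v <- values[[f]]
    x1 <- v[i1]
    x0 <- v[i0]
    tt <- student_t(x1, x0)
    uu <- mann_whitney_u(x1, x0)
    ff <- anova_f(list(x1, x0))
    ps <- c(tt$p_value, uu$p_value, ff$p_value)
    hits <- sum(ps < alpha, na.rm = TRUE)
    selected <- switch(rule,
      all = !anyNA(ps) && hits == 3L,
      majority = hits >= 2L,
      any = hits >= 1L
    )
    tibble::tibble(
      feature_id = f,
      t_statistic = tt$statistic, t_p = tt$p_value,
      u_statistic = uu$statistic, u_p = uu$p_value,
      f_statistic = ff$statistic, f_p = ff$p_value,
      selected = selected
    )
  })
  dplyr::bind_rows(rows)
}

#' Run feature selection over every block of a cohort
#'
#' Applies [select_discrete()] to discrete blocks and [select_continuous()]
#' to continuous blocks. Optionally applies Benjamini-Hochberg adjustment
#' within each block before thresholding (off by default; selection is then
#' on raw per-test p-values).
#'
#' @param cohort A labelled `multiomics_cohort` (no missing labels; see
#'   [filter_labelled()]).
#' @param alpha Significance level used by every test.
#' @param rule Integration rule for continuous blocks (see
#'   [select_continuous()]).
#' @param discrete_method Test choice for discrete blocks (see
#'   [select_discrete()]).
#' @param adjust `"none"` (default) or `"BH"` for within-block
#'   Benjamini-Hochberg adjustment of each test's p-values.
#' @return A `selection_report`: `$results` is a tidy per-feature tibble
#'   with a `block` column; `$alpha`, `$rule`, `$discrete_method`,
#'   `$adjust` record the settings.
#' @export
select_features <- function(cohort, alpha = 0.05,
                            rule = c("all", "majority", "any"),
                            discrete_method = c("auto", "fisher", "chisq"),
                            adjust = c("none", "BH")) {
  stopifnot(inherits(cohort, "multiomics_cohort"))
  rule <- match.arg(rule)
  discrete_method <- match.arg(discrete_method)
  adjust <- match.arg(adjust)
  if (anyNA(cohort$labels)) {
    stop("cohort has missing labels; run filter_labelled() first",
      call. = FALSE
    )
  }
  results <- purrr::map(cohort$blocks, function(b) {
    if (b$kind == "discrete") {
      res <- select_discrete(b$values, cohort$labels,
        alpha = alpha, method = discrete_method
      )
      if (adjust == "BH") {
        res$p_value <- stats::p.adjust(res$p_value, method = "BH")
        res$selected <- res$p_value < alpha
      }
      dplyr::mutate(res, block = b$name, kind = "discrete", .before = 1)
    } else {
      res <- select_continuous(b$values, cohort$labels,
        alpha = alpha, rule = rule
      )
      if (adjust == "BH") {
        res$t_p <- stats::p.adjust(res$t_p, method = "BH")
        res$u_p <- stats::p.adjust(res$u_p, method = "BH")
        res$f_p <- stats::p.adjust(res$f_p, method = "BH")
        hits <- (res$t_p < alpha) + (res$u_p < alpha) + (res$f_p < alpha)
        res$selected <- switch(rule,
          all = hits == 3L, majority = hits >= 2L, any = hits >= 1L
        )
      }
      dplyr::mutate(res, block = b$name, kind = "continuous", .before = 1)
    }
  })
  structure(
    list(
      results = dplyr::bind_rows(results),
      alpha = alpha, rule = rule,
      discrete_method = discrete_method, adjust = adjust
    ),
    class = "selection_report"
  )
}

#' Selected feature identifiers of one block
#'
#' @param report A `selection_report`.
#' @param block Block name.
#' @return Character vector of selected feature ids.
#' @export
selected_features <- function(report, block) {
  stopifnot(inherits(report, "selection_report"))
  res <- report$results
  res$feature_id[res$block == block & res$selected]
}

#' @export
print.selection_report <- function(x, ...) {
  cat(
    "<selection_report> alpha = ", x$alpha, ", rule = ", x$rule,
    ", adjust = ", x$adjust, "\n",
    sep = ""
  )
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection report into its per-feature table
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @exportS3Method
tidy.selection_report <- function(x, ...) {
  x$results
}

#' One row per block: tested and selected feature counts
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return A tibble with `block`, `n_tested`, `n_selected`.
#' @exportS3Method
glance.selection_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$block),
    n_tested = dplyr::n(),
    n_selected = sum(.data$selected),
    .groups = "drop"
  )
}

#' Write a selection report to CSV
#'
#' One row per feature with every statistic, p-value and the selected flag.
#'
#' @param report A `selection_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  readr::write_csv(tidy(report), path)
  invisible(path)
}
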