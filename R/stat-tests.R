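#' Statistical test primitives for feature selection
#'
#' The selection pipelines are assembled from five primitive tests, each
#' implemented from its defining formula rather than wrapped from
#' `stats::`, so that every arithmetic step is open to inspection and the
#' test suite can compare them against independent oracles
#' (enumeration, brute-force sums, `stats::fisher.test()` and friends).
#'
#' @name stat_primitives
NULL

validate_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("expected a 2x2 contingency table", call. = FALSE)
  }
  if (anyNA(tab) || any(tab < 0) || any(!is.finite(tab))) {
    stop("contingency cells must be finite non-negative counts", call. = FALSE)
  }
  if (any(abs(tab - round(tab)) > 1e-8)) {
    stop("contingency cells must be integer counts", call. = FALSE)
  }
  round(tab)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: with all margins fixed,
#' every attainable table's point probability is computed and those no more
#' probable than the observed table are summed. A small relative tolerance
#' (1e-7) guards the "no more probable" comparison against floating-point
#' ties, matching the convention of [stats::fisher.test()].
#'
#' @param tab A 2x2 matrix of non-negative counts (rows: feature level,
#'   columns: class label).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_p(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_p <- function(tab) {
  tab <- validate_2x2(tab)
  n <- sum(tab)
  if (n == 0) {
    warning("empty contingency table; p set to 1", call. = FALSE)
    return(1)
  }
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Chi-square test of independence
#'
#' Pearson's statistic \eqn{\chi^2 = \sum_i (x_i - n p_i)^2 / (n p_i)} with
#' expected proportions taken from the table margins; the p-value comes from
#' the chi-square distribution with (r-1)(c-1) degrees of freedom (1 for a
#' 2x2 table). No continuity correction is applied. A zero expected cell is
#' an error: the caller should use [fisher_exact_p()] instead.
#'
#' @param tab A contingency table (matrix of non-negative counts).
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
chi_square_p <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab) || any(tab < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) {
    stop("zero expected cell count; use Fisher's exact test instead",
      call. = FALSE
    )
  }
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(
    statistic = statistic,
    p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
    df = df
  )
}

#' Pooled-variance two-sample t test
#'
#' The classical Student statistic
#' \eqn{t = (\bar x_1 - \bar x_2) / (s_p \sqrt{1/n_1 + 1/n_2})} with the
#' pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}, two-sided
#' p from the t distribution on \eqn{n_1+n_2-2} degrees of freedom.
#'
#' When the pooled variance is exactly zero the statistic is degenerate:
#' equal means give t = 0 (p = 1); unequal constant samples give p = 0 with
#' a degenerate flag.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @return A list with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
student_t <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each sample needs >= 2 values", call. = FALSE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / df
  dm <- mean(x1) - mean(x2)
  if (sp2 == 0) {
    if (dm == 0) {
      return(list(statistic = 0, p_value = 1, df = df, degenerate = FALSE))
    }
    return(list(
      statistic = sign(dm) * Inf, p_value = 0, df = df, degenerate = TRUE
    ))
  }
  statistic <- dm / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  list(
    statistic = statistic,
    p_value = 2 * stats::pt(-abs(statistic), df = df),
    df = df,
    degenerate = FALSE
  )
}

#' Mann-Whitney U test
#'
#' The U statistic is the pairwise score sum
#' \eqn{U = \sum_i \sum_j S(x_i, y_j)} with S = 1 when \eqn{y_j < x_i},
#' 0.5 on a tie and 0 otherwise (computed via midranks, which is exactly
#' that double sum). The two-sided p-value uses the normal approximation
#' with tie-corrected variance and no continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `statistic` (U for x over y), `p_value`,
#'   `degenerate`.
#' @export
mann_whitney_u <- function(x, y) {
  n <- length(x)
  m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty", call. = FALSE)
  combined <- c(x, y)
  r <- rank(combined)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  nn <- n + m
  ties <- table(combined)
  tie_term <- sum(ties^3 - ties)
  v <- n * m / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  if (v <= 0) {
    # every value tied: U is exactly n*m/2, no evidence either way
    return(list(statistic = u, p_value = 1, degenerate = TRUE))
  }
  z <- (u - mu) / sqrt(v)
  list(
    statistic = u,
    p_value = 2 * stats::pnorm(-abs(z)),
    degenerate = FALSE
  )
}

#' One-way analysis of variance
#'
#' F = MS_treatment / MS_error from the standard sum-of-squares
#' decomposition SS_total = SS_treatment + SS_error, with the p-value from
#' the F distribution. With zero error mean square the result is degenerate:
#' zero treatment mean square too means no variation at all
#' (statistic undefined); positive treatment mean square means perfect
#' separation (p = 0).
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty, with at least one error degree of freedom in total).
#' @return A list with `statistic`, `p_value`, `df_treatment`, `df_error`,
#'   `ss_treatment`, `ss_error`, `degenerate`.
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs >= 1 value", call. = FALSE)
  n <- sum(sizes)
  k <- length(groups)
  df_t <- k - 1L
  df_e <- n - k
  if (df_e < 1L) stop("no error degrees of freedom", call. = FALSE)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ss_t <- sum(sizes * (means - grand)^2)
  ss_e <- sum(vapply(
    seq_along(groups),
    function(i) sum((groups[[i]] - means[i])^2), numeric(1)
  ))
  ms_t <- ss_t / df_t
  ms_e <- ss_e / df_e
  if (ms_e == 0) {
    if (ms_t == 0) {
      return(list(
        statistic = NA_real_, p_value = NA_real_,
        df_treatment = df_t, df_error = df_e,
        ss_treatment = ss_t, ss_error = ss_e, degenerate = TRUE
      ))
    }
    return(list(
      statistic = Inf, p_value = 0,
      df_treatment = df_t, df_error = df_e,
      ss_treatment = ss_t, ss_error = ss_e, degenerate = TRUE
    ))
  }
  statistic <- ms_t / ms_e
  list(
    statistic = statistic,
    p_value = stats::pf(statistic, df_t, df_e, lower.tail = FALSE),
    df_treatment = df_t, df_error = df_e,
    ss_treatment = ss_t, ss_error = ss_e, degenerate = FALSE
  )
}
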