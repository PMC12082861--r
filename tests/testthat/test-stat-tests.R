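test_that("Fisher exact p matches enumeration oracle and stats::fisher.test", {
  set.seed(11)
  for (i in 1:200) {
    cells <- as.numeric(sample(0:12, 4, replace = TRUE))
    if (sum(cells) == 0) next
    tab <- matrix(cells, 2)
    p <- fisher_exact_p(tab)
    expect_equal(p, fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      tolerance = 1e-12
    )
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher exact p: symmetry, no-association and degenerate cases", {
  # identical rows carry no association
  expect_equal(fisher_exact_p(matrix(c(4, 4, 7, 7), 2)), 1)
  # complete separation: full enumeration over the 6 tables of (5,0,0,5)
  expect_equal(
    fisher_exact_p(matrix(c(5, 0, 0, 5), 2)),
    fisher_oracle(5, 0, 0, 5)
  )
  # transposing swaps rows/columns but keeps p
  set.seed(2)
  for (i in 1:25) {
    tab <- matrix(sample(0:9, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_p(tab), fisher_exact_p(t(tab)))
  }
  expect_warning(p <- fisher_exact_p(matrix(0, 2, 2)), "empty")
  expect_equal(p, 1)
  expect_error(fisher_exact_p(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("chi-square statistic matches the ad-bc textbook form on 2x2", {
  # algebraic oracle: chi2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  chk <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  res <- chi_square_p(matrix(c(10, 30, 20, 40), 2))
  expect_equal(res$statistic, chk(10, 20, 30, 40), tolerance = 1e-12)
  expect_equal(res$df, 1L)
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(sample(1:30, 4), 2)
    res <- chi_square_p(tab)
    expect_equal(
      res$statistic, chk(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      tolerance = 1e-10
    )
    # scaling homogeneity: doubling all cells doubles the statistic
    expect_equal(chi_square_p(2 * tab)$statistic, 2 * res$statistic,
      tolerance = 1e-10
    )
  }
})

test_that("chi-square handles exact independence and zero expected cells", {
  res <- chi_square_p(matrix(c(10, 20, 10, 20), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square_p(matrix(c(0, 0, 3, 4), 2)), "Fisher")
})

test_that("pooled t statistic matches hand arithmetic and stats::t.test", {
  # x1 = {1,2,3}, x2 = {4,5,6}: s1^2 = s2^2 = 1, sp = 1,
  # t = (2 - 5)/(1 * sqrt(1/3 + 1/3)) = -3 / sqrt(2/3)
  res <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    x1 <- rnorm(7)
    x2 <- rnorm(9, mean = runif(1, -1, 1))
    res <- student_t(x1, x2)
    ref <- stats::t.test(x1, x2, var.equal = TRUE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    # antisymmetry
    swapped <- student_t(x2, x1)
    expect_equal(swapped$statistic, -res$statistic)
    expect_equal(swapped$p_value, res$p_value)
  }
})

test_that("t test degenerate cases follow the zero-variance contract", {
  same <- student_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- student_t(c(1, 1, 1), c(2, 2, 2))
  expect_true(sep$degenerate)
  expect_equal(sep$p_value, 0)
  expect_error(student_t(1, c(1, 2)), ">= 2")
})

test_that("Mann-Whitney U equals the defining double sum, ties scored 0.5", {
  set.seed(5)
  for (i in 1:30) {
    # integer-valued samples force ties
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 8, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$statistic, u_bruteforce(x, y))
  }
  # complete separation and identical multisets
  expect_equal(mann_whitney_u(c(5, 6, 7), c(1, 2))$statistic, 6)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  all_tied <- mann_whitney_u(c(2, 2), c(2, 2, 2))
  expect_equal(all_tied$statistic, 3)
  expect_equal(all_tied$p_value, 1)
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("Mann-Whitney p matches the tie-corrected normal approximation", {
  set.seed(6)
  x <- sample(1:10, 20, replace = TRUE)
  y <- sample(3:12, 15, replace = TRUE)
  res <- mann_whitney_u(x, y)
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("ANOVA decomposes sums of squares and matches aov", {
  set.seed(7)
  groups <- list(rnorm(8), rnorm(6, 1), rnorm(7, -0.5))
  res <- anova_f(groups)
  # SS_total = SS_treatment + SS_error
  all_vals <- unlist(groups)
  expect_equal(
    res$ss_treatment + res$ss_error,
    sum((all_vals - mean(all_vals))^2),
    tolerance = 1e-10
  )
  ref <- summary(stats::aov(
    v ~ g,
    data = data.frame(
      v = all_vals,
      g = factor(rep(seq_along(groups), lengths(groups)))
    )
  ))[[1]]
  expect_equal(res$statistic, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("two-group ANOVA F equals t squared", {
  set.seed(8)
  for (i in 1:20) {
    x1 <- rnorm(9)
    x2 <- rnorm(11, 0.5)
    f <- anova_f(list(x1, x2))
    t <- student_t(x1, x2)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p_value, t$p_value, tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases are flagged", {
  allsame <- anova_f(list(c(1, 1, 1), c(1, 1)))
  expect_true(allsame$degenerate)
  expect_true(is.na(allsame$statistic))
  separated <- anova_f(list(c(1, 1, 1), c(2, 2)))
  expect_true(separated$degenerate)
  expect_equal(separated$p_value, 0)
  expect_error(anova_f(list(c(1, 2))), ">= 2 groups")
})

test_that("all five primitives return p-values inside [0, 1]", {
  set.seed(9)
  for (i in 1:40) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) > 0) {
      expect_gte(fisher_exact_p(tab), 0)
      expect_lte(fisher_exact_p(tab), 1)
    }
    x <- rnorm(6)
    y <- rnorm(5)
    for (p in c(
      student_t(x, y)$p_value,
      mann_whitney_u(x, y)$p_value,
      anova_f(list(x, y))$p_value
    )) {
      expect_gte(p, 0)
      expect_lte(p, 1)
    }
  }
})
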