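test_that("sample size formula matches direct substitution", {
  # sigma = 1, Q1 = Q2 = 0.5, delta = 0.5:
  # n = ceil(1 * 4 * (1.9600 + 0.8416)^2 / 0.25)
  x0 <- c(-1, 0, 1) * sqrt(1 / stats::var(c(-1, 0, 1))) # unit variance
  x1 <- x0 + 0.5
  est <- estimate_sample_size(x0, x1)
  byhand <- ceiling(
    1 * (2 + 2) * (stats::qnorm(0.975) + stats::qnorm(0.8))^2 / 0.5^2
  )
  expect_equal(est$n, byhand)
  expect_equal(est$sigma, 1, tolerance = 1e-12)
  expect_equal(est$mu_alpha, stats::qnorm(0.975))
  expect_equal(est$mu_beta, stats::qnorm(0.8))
})

test_that("requirement scales as sigma^2 and 1/delta^2", {
  set.seed(41)
  x0 <- rnorm(200)
  x1 <- rnorm(200, 0.4)
  n1 <- estimate_sample_size(x0, x1)$n
  # doubling the gap divides the requirement by ~4
  n2 <- estimate_sample_size(x0, x1 + (mean(x1) - mean(x0)))$n
  expect_lt(abs(n2 - n1 / 4), max(2, 0.05 * n1))
  # doubling sigma (same delta) multiplies by ~4
  d <- mean(x1) - mean(x0)
  n3 <- estimate_sample_size(2 * (x0 - mean(x0)),
    2 * (x1 - mean(x1)) + d
  )$n
  expect_lt(abs(n3 - 4 * n1), max(4, 0.05 * n3))
})

test_that("zero mean difference flags an infinite requirement", {
  x <- c(1, 2, 3, 4)
  est <- estimate_sample_size(x, x)
  expect_true(est$infinite)
  expect_equal(est$n, Inf)
  expect_error(dataset_sample_size(c(Inf, Inf)), "insufficient regardless")
})

test_that("per-dataset aggregation takes the most demanding feature", {
  expect_equal(dataset_sample_size(c(86, 231, 142, 157)), 231)
  expect_equal(dataset_sample_size(99), 99)
  expect_equal(dataset_sample_size(c(10, 20), aggregate = "mean"), 15)
})

test_that("SMOTE doubles the dataset at m = 1 and preserves balance", {
  design <- toy_design(n = 40)
  aug <- smote_augment(design, m = 1, k = 5, seed = 1)
  expect_equal(nrow(aug), 80)
  expect_equal(sum(aug$provenance == "smote"), 40)
  expect_equal(table(aug$label[aug$provenance == "smote"]),
    table(design$label),
    ignore_attr = TRUE
  )
  g <- glance(aug)
  expect_equal(g$n_generated, g$n_original)
})

test_that("every SMOTE row lies on its seed-neighbour segment", {
  design <- toy_design(n = 30, seed = 3)
  aug <- smote_augment(design, m = 2, k = 4, seed = 2)
  x <- as.matrix(design[c("x1", "x2")])
  synth <- aug[aug$provenance == "smote", ]
  for (r in seq_len(nrow(synth))) {
    seed_id <- sub("\\.smote[0-9]+$", "", synth$sample_id[r])
    i <- match(seed_id, design$sample_id)
    same <- which(design$label == design$label[i])
    p <- c(synth$x1[r], synth$x2[r])
    # the generated point must sit inside the coordinate-wise box of the
    # seed and at least one same-label sample (its chosen neighbour)
    ok <- vapply(setdiff(same, i), function(j) {
      all(p >= pmin(x[i, ], x[j, ]) - 1e-12) &&
        all(p <= pmax(x[i, ], x[j, ]) + 1e-12)
    }, logical(1))
    expect_true(any(ok))
  }
})

test_that("SMOTE interpolation collapses when neighbours coincide", {
  design <- tibble::tibble(
    label = rep(c(0L, 1L), each = 4),
    x1 = rep(c(2, 5), each = 4),
    x2 = rep(c(-1, 1), each = 4)
  )
  aug <- smote_augment(design, m = 1, k = 3, seed = 4)
  synth <- aug[aug$provenance == "smote", ]
  expect_equal(synth$x1, rep(c(2, 5), each = 4))
  expect_equal(synth$x2, rep(c(-1, 1), each = 4))
})

test_that("SMOTE is deterministic given a seed and reduces k when needed", {
  design <- toy_design(n = 40)
  a <- smote_augment(design, m = 1, k = 5, seed = 9)
  b <- smote_augment(design, m = 1, k = 5, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- smote_augment(design, m = 1, k = 5, seed = 10)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  tiny <- toy_design(n = 8)
  w <- capture_warnings(smote_augment(tiny, m = 1, k = 5, seed = 1))
  expect_match(w, "fewer than", all = TRUE)
  expect_length(w, 2) # once per class
  expect_error(smote_augment(design, m = 6, k = 5), "m must be <= k")
})

test_that("discrete pass-through columns keep their category codes", {
  design <- toy_design(n = 40)
  design$mut <- rep(c(0L, 1L), 20)
  attr(design, "roles") <- tibble::tibble(
    column = c("x1", "x2", "mut"),
    role = c("pc", "pc", "passthrough"),
    block = c("a", "a", "b")
  )
  aug <- smote_augment(design, m = 1, k = 5, seed = 5)
  expect_true(all(aug$mut %in% c(0L, 1L)))
})

test_that("noise augmentation copies labels and scale 0 duplicates", {
  design <- toy_design(n = 30)
  aug0 <- noise_augment(design, scale = 0, seed = 1)
  expect_equal(nrow(aug0), 60)
  synth <- aug0[aug0$provenance == "noise", ]
  expect_equal(synth$x1, design$x1)
  expect_equal(synth$label, design$label)
  aug <- noise_augment(design, scale = 0.5, seed = 1)
  expect_false(any(aug$x1[aug$provenance == "noise"] == design$x1))
  expect_identical(
    tibble::as_tibble(noise_augment(design, scale = 0.5, seed = 2)),
    tibble::as_tibble(noise_augment(design, scale = 0.5, seed = 2))
  )
})

test_that("Fisher ratio matches its defining formula and is max-invariant", {
  set.seed(42)
  y <- rep(c(0L, 1L), each = 20)
  x <- cbind(a = rnorm(40) + 1.5 * y, b = rnorm(40))
  fr <- fisher_ratio_f1(x, y)
  byhand <- (mean(x[y == 1, "a"]) - mean(x[y == 0, "a"]))^2 /
    (stats::var(x[y == 1, "a"]) + stats::var(x[y == 0, "a"]))
  expect_equal(fr$per_feature$f[1], byhand, tolerance = 1e-12)
  # permuting feature order leaves the max unchanged
  expect_equal(fisher_ratio_f1(x[, c(2, 1)], y)$f1, fr$f1)
  # appending a duplicate of an informative feature cannot decrease F1
  expect_gte(fisher_ratio_f1(cbind(x, x[, "a"]), y)$f1, fr$f1)
})

test_that("Fisher ratio degenerate features follow the zero conventions", {
  y <- rep(c(0L, 1L), each = 3)
  const <- matrix(1, 6, 1)
  expect_equal(fisher_ratio_f1(const, y)$f1, 0)
  sep <- matrix(rep(c(0, 1), each = 3), 6, 1)
  expect_equal(fisher_ratio_f1(sep, y)$f1, Inf)
})

test_that("identical class distributions give near-zero F1", {
  set.seed(43)
  y <- rep(c(0L, 1L), each = 250)
  x <- matrix(rnorm(500 * 3), ncol = 3)
  expect_lt(fisher_ratio_f1(x, y)$f1, 0.2)
})

test_that("standard-error spread variant scales the ratio up", {
  set.seed(44)
  y <- rep(c(0L, 1L), each = 30)
  x <- matrix(rnorm(60) + y, ncol = 1)
  expect_gt(
    fisher_ratio_f1(x, y, spread = "se")$f1,
    fisher_ratio_f1(x, y, spread = "sd")$f1
  )
})
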