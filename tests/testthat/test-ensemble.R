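# a stub weak learner replaying a fixed prediction sequence, one vector
# per fitted round, so boosting arithmetic can be checked by hand
stub_learner <- function(pred_rounds) {
  counter <- new.env(parent = emptyenv())
  counter$t <- 0L
  weak_learner_custom(
    fit = function(x, y, w) {
      counter$t <- counter$t + 1L
      list(round = counter$t)
    },
    predict = function(model, x) pred_rounds[[model$round]],
    family = "stub"
  )
}

test_that("initial weights are uniform and sum to one", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  expect_equal(sum(init_weights(37)), 1)
  expect_error(init_weights(0), ">= 1")
})

test_that("round weight formula handles chance, clipping and poles", {
  expect_equal(boost_alpha(0.5), 0)
  expect_equal(boost_alpha(0.25), 0.5 * log(3))
  # poles are clipped symmetrically
  expect_equal(boost_alpha(0), -boost_alpha(1))
  expect_true(is.finite(boost_alpha(0)))
  expect_equal(boost_alpha(0), 0.5 * log((1 - 1e-10) / 1e-10))
})

test_that("two boosting rounds match the hand-computed weight arithmetic", {
  # 6 samples; round 1 misclassifies sample 1; round 2 misclassifies 2, 3
  y <- c(1L, 1L, 0L, 0L, 1L, 0L)
  preds <- list(
    c(0L, 1L, 0L, 0L, 1L, 0L), # wrong on sample 1 only
    c(1L, 0L, 1L, 0L, 1L, 0L) # wrong on samples 2 and 3
  )
  x <- matrix(0, 6, 1)
  bc <- boost(x, y, stub_learner(preds), n_rounds = 2)
  expect_length(bc$rounds, 2)
  # eps1 = 1/6, alpha1 = log(5)/2; eps2 on D2 = 2/10, alpha2 = log(4)/2
  expect_equal(bc$rounds[[1]]$epsilon, 1 / 6)
  expect_equal(bc$rounds[[1]]$alpha, 0.5 * log(5))
  expect_equal(bc$rounds[[2]]$epsilon, 1 / 5)
  expect_equal(bc$rounds[[2]]$alpha, log(2))
  # D2: misclassified sample moves to 1/2, the rest to 1/10
  expect_equal(
    bc$weight_history[2, ], c(1 / 2, rep(1 / 10, 5)),
    tolerance = 1e-12
  )
  # D3 from the second update
  expect_equal(
    bc$weight_history[3, ],
    c(5 / 16, 1 / 4, 1 / 4, 1 / 16, 1 / 16, 1 / 16),
    tolerance = 1e-12
  )
})

test_that("every boosting weight distribution sums to one", {
  run <- list(
    boost(
      as.matrix(toy_design(30)[c("x1", "x2")]), toy_design(30)$label,
      weak_learner("logistic"),
      n_rounds = 6
    ),
    boost(
      as.matrix(toy_design(30, shift = 0.5)[c("x1", "x2")]),
      toy_design(30, shift = 0.5)$label,
      weak_learner("naive_bayes"),
      n_rounds = 8
    )
  )
  for (bc in run) {
    expect_true(all(abs(rowSums(bc$weight_history) - 1) < 1e-10))
  }
})

test_that("misclassified-vs-correct weight ratio grows by exp(2 alpha)", {
  y <- c(1L, 0L, 1L, 0L)
  preds <- list(c(0L, 0L, 1L, 0L)) # misclassifies sample 1 only
  bc <- boost(matrix(0, 4, 1), y, stub_learner(preds), n_rounds = 1)
  a <- bc$rounds[[1]]$alpha
  d1 <- bc$weight_history[1, ]
  d2 <- bc$weight_history[2, ]
  expect_equal(
    (d2[1] / d2[2]) / (d1[1] / d1[2]), exp(2 * a),
    tolerance = 1e-12
  )
})

test_that("a perfect weak learner hits the clip ceiling, weights unchanged", {
  y <- rep(c(0L, 1L), 5)
  preds <- list(y)
  bc <- boost(matrix(0, 10, 1), y, stub_learner(preds), n_rounds = 5)
  expect_length(bc$rounds, 1) # further rounds would repeat
  expect_equal(bc$rounds[[1]]$alpha, boost_alpha(0))
  expect_equal(bc$weight_history[2, ], rep(0.1, 10))
})

test_that("persistently chance-level rounds re-init once then stop", {
  y <- rep(c(0L, 1L), each = 4)
  bad <- rep(c(1L, 0L), each = 4) # always completely wrong: eps = 1
  bc_err <- tryCatch(
    boost(matrix(0, 8, 1), y, stub_learner(rep(list(bad), 5)), n_rounds = 5),
    error = function(e) e
  )
  expect_s3_class(bc_err, "error")
  expect_match(conditionMessage(bc_err), "never beat chance")
})

test_that("boosting drives training error to zero on separable data", {
  d <- toy_design(n = 40, shift = 4, seed = 13)
  x <- as.matrix(d[c("x1", "x2")])
  bc <- boost(x, d$label, weak_learner("logistic"), n_rounds = 10)
  expect_equal(mean(predict(bc, x) != d$label), 0)
})

test_that("boosted score is the signed alpha-weighted vote", {
  y <- c(0L, 1L, 0L, 1L)
  preds <- list(c(0L, 1L, 1L, 1L)) # one mistake -> eps 1/4, alpha log(3)/2
  bc <- boost(matrix(0, 4, 1), y, stub_learner(preds), n_rounds = 1)
  sc <- boosted_score(bc, matrix(0, 4, 1))
  a <- bc$rounds[[1]]$alpha
  expect_equal(sc, a * c(-1, 1, 1, 1))
  # flipping every weak prediction negates the score
  flipped <- bc
  flipped$learner <- weak_learner_custom(
    fit = function(x, y, w) NULL,
    predict = function(model, x) 1L - preds[[1]]
  )
  expect_equal(boosted_score(flipped, matrix(0, 4, 1)), -sc)
  expect_error(boosted_score(list(), matrix(0, 1, 1)), "fitted")
})

test_that("seeded boosting of a resampling learner is reproducible", {
  d <- toy_design(n = 40, shift = 1, seed = 21)
  x <- as.matrix(d[c("x1", "x2")])
  b1 <- boost(x, d$label, weak_learner("support_vector"),
    n_rounds = 4, seed = 5
  )
  b2 <- boost(x, d$label, weak_learner("support_vector"),
    n_rounds = 4, seed = 5
  )
  expect_equal(tidy(b1), tidy(b2))
  expect_equal(
    boosted_score(b1, x), boosted_score(b2, x)
  )
})

test_that("the stacked ensemble produces calibrated in-range probabilities", {
  d <- toy_design(n = 60, shift = 2, seed = 31)
  em <- fit_ensemble(d, n_rounds = 5, seed = 7)
  expect_s3_class(em, "ensemble_model")
  pr <- predict(em, d)
  expect_true(all(pr$.pred_prob > 0 & pr$.pred_prob < 1))
  expect_true(all(pr$.pred_class %in% 0:1))
  expect_equal(nrow(tidy(em)), 4) # c0..c3
  expect_equal(glance(em)$n_members, 3)
  # threshold 0 labels everything positive
  expect_true(all(predict(em, d, threshold = 0)$.pred_class == 1))
})

test_that("zero stacking coefficients give probability one half", {
  d <- toy_design(n = 40, shift = 2, seed = 32)
  em <- fit_ensemble(d, n_rounds = 3, seed = 8)
  em$coef[] <- 0
  expect_equal(predict(em, d)$.pred_prob, rep(0.5, 40))
})

test_that("in-sample and out-of-fold stacking both fit and are recorded", {
  d <- toy_design(n = 50, shift = 1.5, seed = 33)
  for (mode in c("in_sample", "out_of_fold")) {
    em <- suppressWarnings(
      fit_ensemble(d, n_rounds = 3, stacking = mode, seed = 9)
    )
    expect_equal(em$stacking, mode)
    expect_true(all(is.finite(em$coef)))
  }
})

test_that("prediction on incompatible columns names the missing ones", {
  d <- toy_design(n = 40, seed = 34)
  em <- fit_ensemble(d, n_rounds = 2, seed = 10)
  expect_error(predict(em, d[c("sample_id", "label", "x1")]), "x2")
})

test_that("single-class labels are rejected before boosting", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(
    boost(x, rep(1L, 10), weak_learner("logistic")), "both classes"
  )
})
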