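# shared fixtures, built in code

# a small, quickly generated cohort: two discrete + one continuous block
small_cohort_config <- function(seed = 1, n_samples = 60,
                                effect_size = 1.5,
                                label_missing_count = 0) {
  cohort_config(
    n_samples = n_samples,
    class_balance = 0.5,
    blocks = dplyr::bind_rows(
      block_spec("clin", "discrete", 5, 2, effect_size = effect_size),
      block_spec("prot", "continuous", 40, 8, effect_size = effect_size)
    ),
    label_missing_count = label_missing_count,
    seed = seed
  )
}

# a simple labelled 2-D design tibble with well separated classes
toy_design <- function(n = 40, shift = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  tibble::tibble(
    sample_id = sprintf("T%03d", seq_len(n)),
    label = y,
    x1 = stats::rnorm(n) + shift * y,
    x2 = stats::rnorm(n)
  )
}

# memoised default-cohort runs so several test files can share the
# expensive generate -> select -> reduce chain for a given seed
.run_cache <- new.env(parent = emptyenv())

default_cohort_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.run_cache[[key]])) {
    return(.run_cache[[key]])
  }
  cohort <- filter_labelled(generate_cohort(cohort_config(seed = seed)))
  report <- select_features(cohort)
  design <- assemble_design(cohort, report)
  truth <- lapply(cohort$blocks, function(b) b$informative_ids)
  names(truth) <- names(cohort$blocks)
  out <- list(
    cohort = cohort, report = report, design = design, truth = truth
  )
  .run_cache[[key]] <- out
  out
}

# brute-force hypergeometric enumeration oracle for Fisher's exact test,
# written from the factorial point-mass formula (independent of dhyper)
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1)
  p <- exp(lp)
  p_obs <- exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# direct double-loop Mann-Whitney U (the defining pairwise score sum)
u_bruteforce <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      u <- u + if (yj < xi) 1 else if (yj == xi) 0.5 else 0
    }
  }
  u
}
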