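#' Configure a full pipeline run
#'
#' Collects every stage's parameters behind one object with one master
#' seed; each stage receives a seed derived deterministically from it via
#' [derive_seed()], so a configuration reproduces a run bit for bit.
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` to read a cohort from `input_dir`.
#' @param input_dir Directory with block CSVs + `labels.csv` +
#'   `truth.json` (see [write_cohort()]); ignored when `cohort` is given.
#' @param alpha Selection significance level.
#' @param rule Integration rule for continuous selection.
#' @param L Principal components per continuous block.
#' @param ss_alpha,ss_beta Error rates for sample-size estimation.
#' @param aggregate Per-block sample-size aggregation rule.
#' @param augment `"auto"` (augment only when the available sample count is
#'   below the estimated requirement), `"always"`, or `"never"`.
#' @param smote_m,smote_k SMOTE parameters.
#' @param n_rounds Boosting rounds per weak-learner family.
#' @param stacking Stacking mode for the ensemble.
#' @param k Cross-validation folds.
#' @param augmentation_policy Cross-validation augmentation policy (see
#'   [kfold_evaluate()]).
#' @param models Models to evaluate.
#' @param seed Master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(seed = derive_seed(seed, "simulate")),
                            input_dir = NULL,
                            alpha = 0.05, rule = "all", L = 2,
                            ss_alpha = 0.05, ss_beta = 0.2,
                            aggregate = "max",
                            augment = c("auto", "always", "never"),
                            smote_m = 1, smote_k = 5,
                            n_rounds = 10, stacking = "out_of_fold",
                            k = 5,
                            augmentation_policy = "train_folds_only",
                            models = c(
                              "logistic", "svm", "naive_bayes", "ensemble"
                            ),
                            seed = 1) {
  augment <- match.arg(augment)
  config <- structure(
    list(
      cohort = cohort, input_dir = input_dir,
      alpha = alpha, rule = rule, L = L,
      ss_alpha = ss_alpha, ss_beta = ss_beta, aggregate = aggregate,
      augment = augment, smote_m = smote_m, smote_k = smote_k,
      n_rounds = n_rounds, stacking = stacking,
      k = k, augmentation_policy = augmentation_policy,
      models = models,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly; errors describe the offending field.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$cohort) && is.null(config$input_dir)) {
    stop("config needs either a cohort spec or an input_dir", call. = FALSE)
  }
  if (!is.null(config$input_dir) && is.null(config$cohort) &&
    !dir.exists(config$input_dir)) {
    stop("input_dir does not exist: ", config$input_dir, call. = FALSE)
  }
  if (!is.null(config$cohort)) stopifnot(inherits(config$cohort, "cohort_config"))
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!config$rule %in% c("all", "majority", "any")) {
    stop("rule must be all/majority/any", call. = FALSE)
  }
  if (config$smote_m > config$smote_k) stop("smote_m must be <= smote_k", call. = FALSE)
  if (config$k < 2) stop("k must be >= 2", call. = FALSE)
  if (!config$augmentation_policy %in%
    c("none", "train_folds_only", "whole_dataset_first")) {
    stop("unknown augmentation_policy", call. = FALSE)
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; an
#' optional `cohort:` mapping (with optional `blocks:` list of block
#' specifications) configures the synthetic generator.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    blocks <- if (!is.null(raw$cohort$blocks)) {
      dplyr::bind_rows(lapply(raw$cohort$blocks, function(b) {
        block_spec(
          b$name, b$kind, b$n_features, b$n_informative,
          effect_size = b$effect_size %||% 1,
          noise_sd = b$noise_sd %||% 1
        )
      }))
    } else {
      default_blocks()
    }
    cohort <- cohort_config(
      n_samples = raw$cohort$n_samples %||% 144,
      class_balance = raw$cohort$class_balance %||% (70 / 144),
      blocks = blocks,
      label_missing_count = raw$cohort$label_missing_count %||% 0,
      seed = derive_seed(seed, "simulate")
    )
  }
  args <- raw[setdiff(names(raw), c("cohort"))]
  args$cohort <- cohort %||% cohort_config(seed = derive_seed(seed, "simulate"))
  do.call(pipeline_config, args)
}

#' Run the full workflow into an output directory
#'
#' Executes the stages in order — simulate (or load), label filter, feature
#' selection, dimensional reduction, sample-size estimation, augmentation,
#' ensemble training, K-fold evaluation — writing each stage's artifacts
#' and a `manifest.json` listing every output file with its MD5 hash, the
#' configuration and the per-stage seeds. Re-running with an identical
#' configuration reproduces identical artifacts.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(
    lapply(
      c("simulate", "select", "reduce", "augment", "train", "evaluate"),
      function(s) derive_seed(config$seed, s)
    ),
    c("simulate", "select", "reduce", "augment", "train", "evaluate")
  )
  stage <- "simulate"
  result <- tryCatch(
    {
      cohort <- if (!is.null(config$cohort)) {
        generate_cohort(config$cohort)
      } else {
        read_cohort(config$input_dir)
      }
      cohort <- filter_labelled(cohort)
      write_cohort(cohort, file.path(out_dir, "cohort"))

      stage <- "select"
      report <- select_features(cohort,
        alpha = config$alpha, rule = config$rule
      )
      write_selection_report(report, file.path(out_dir, "selection_report.csv"))

      stage <- "reduce"
      design <- assemble_design(cohort, report, L = config$L)
      write_design(design, out_dir)

      stage <- "augment"
      est <- estimate_cohort_sample_size(cohort, report,
        alpha = config$ss_alpha, beta = config$ss_beta,
        aggregate = config$aggregate
      )
      do_augment <- switch(config$augment,
        always = TRUE, never = FALSE, auto = !est$sufficient
      )
      aug <- NULL
      if (do_augment) {
        aug <- smote_augment(design,
          m = config$smote_m, k = config$smote_k,
          seed = seeds$augment
        )
        readr::write_csv(
          tibble::as_tibble(aug), file.path(out_dir, "augmented.csv")
        )
      }
      jsonlite::write_json(
        list(
          required_n = est$overall,
          available_n = est$n_available,
          per_block = est$per_block,
          sufficient = est$sufficient,
          augmented = do_augment,
          status = if (do_augment) {
            "augmented"
          } else {
            paste0(
              "skipped: n = ", est$n_available,
              " >= requirement ", est$overall
            )
          },
          params = list(
            m = config$smote_m, k = config$smote_k, seed = seeds$augment
          ),
          f1_before = if (do_augment) attr(aug, "f1_before") else NULL,
          f1_after = if (do_augment) attr(aug, "f1_after") else NULL
        ),
        file.path(out_dir, "augmentation_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
      )

      stage <- "train"
      train_tab <- if (do_augment) aug else design
      model <- fit_ensemble(train_tab,
        n_rounds = config$n_rounds, stacking = config$stacking,
        seed = seeds$train
      )
      write_ensemble_json(model, file.path(out_dir, "ensemble_model.json"))

      stage <- "evaluate"
      eval_aug <- if (do_augment) config$augmentation_policy else "none"
      report_eval <- kfold_evaluate(design,
        models = config$models, k = config$k, seed = seeds$evaluate,
        augmentation = eval_aug,
        smote_m = config$smote_m, smote_k = config$smote_k,
        n_rounds = config$n_rounds, stacking = config$stacking
      )
      write_eval_report(report_eval, out_dir)
      list(model = model, eval = report_eval, estimate = est)
    },
    error = function(e) {
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )

  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seeds = seeds,
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }),
    config = config_to_list(config)
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(manifest, result))
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$cohort)) {
    out$cohort <- c(
      out$cohort[c("n_samples", "class_balance", "label_missing_count", "seed")],
      list(blocks = out$cohort$blocks)
    )
  }
  out
}
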