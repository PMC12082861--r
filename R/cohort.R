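#' Specify the omics blocks of a synthetic cohort
#'
#' Each row describes one block: a discrete block holds small-cardinality
#' integer codes (clinical categories, binary mutation indicators), a
#' continuous block holds finite real abundances (log2-normalized
#' proteomic / phosphoproteomic intensities). `n_informative` features per
#' block carry a class signal: a standardized mean shift of `effect_size`
#' (in units of `noise_sd`) for continuous blocks, a log-odds shift of
#' `effect_size` for discrete blocks.
#'
#' @param name Block name.
#' @param kind `"discrete"` or `"continuous"`.
#' @param n_features Number of features in the block.
#' @param n_informative Number of class-associated features
#'   (`<= n_features`).
#' @param effect_size Non-negative effect size (standardized mean shift or
#'   log-odds of association).
#' @param noise_sd Standard deviation of the continuous noise (ignored for
#'   discrete blocks beyond validation).
#' @return A one-row tibble.
#' @export
block_spec <- function(name, kind = c("continuous", "discrete"),
                       n_features, n_informative,
                       effect_size = 1, noise_sd = 1) {
  kind <- match.arg(kind)
  if (n_informative > n_features) {
    stop("n_informative must be <= n_features in block '", name, "'",
      call. = FALSE
    )
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  tibble::tibble(
    name = as.character(name), kind = kind,
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd)
  )
}

#' Default desk-scale block layout
#'
#' Mirrors a four-block multiomics study at reduced width: two small
#' discrete blocks (clinical, somatic mutation) and two wide continuous
#' blocks (proteomics, phosphoproteomics), preserving the informative
#' feature counts of the motivating study (3 / 3 / 89 / 15) while keeping
#' the total width tractable for tests.
#'
#' @return A tibble of block specifications.
#' @export
default_blocks <- function() {
  dplyr::bind_rows(
    block_spec("clinical", "discrete", 10, 3, effect_size = 1.5),
    block_spec("mutation", "discrete", 20, 3, effect_size = 1.5),
    block_spec("proteomics", "continuous", 600, 89, effect_size = 1.0),
    block_spec("phospho", "continuous", 1000, 15, effect_size = 1.0)
  )
}

#' Configure a synthetic multiomics cohort
#'
#' The defaults emulate the study conditions the pipeline was designed for:
#' 144 patients with a near-balanced binary outcome (70 positives), four
#' omics blocks, and no missing labels.
#'
#' @param n_samples Number of samples (default 144).
#' @param class_balance Fraction of positive (outcome = 1) samples, strictly
#'   between 0 and 1 (default 70/144).
#' @param blocks A tibble of block specifications (see [block_spec()]).
#' @param label_missing_count Number of samples emitted with a missing
#'   outcome label (encoded `NA_integer_`).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_samples = 144,
                          class_balance = 70 / 144,
                          blocks = default_blocks(),
                          label_missing_count = 0,
                          seed = 1) {
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must be strictly between 0 and 1", call. = FALSE)
  }
  if (label_missing_count < 0 || label_missing_count > n_samples) {
    stop("label_missing_count must be in [0, n_samples]", call. = FALSE)
  }
  blocks <- tibble::as_tibble(blocks)
  needed <- c(
    "name", "kind", "n_features", "n_informative", "effect_size", "noise_sd"
  )
  if (!all(needed %in% names(blocks))) {
    stop("blocks must have columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(blocks$name)) stop("block names must be unique", call. = FALSE)
  if (any(blocks$n_informative > blocks$n_features)) {
    stop("n_informative must be <= n_features for every block", call. = FALSE)
  }
  if (any(blocks$effect_size < 0)) stop("effect_size must be >= 0", call. = FALSE)
  structure(
    list(
      n_samples = as.integer(n_samples),
      class_balance = class_balance,
      blocks = blocks,
      label_missing_count = as.integer(label_missing_count),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# baseline carrier rate for discrete synthetic features; informative
# features shift its log-odds by +/- effect_size/2 per class
.discrete_base_rate <- 0.3

#' Generate a synthetic multiomics cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. Continuous informative features are Gaussian with between-class
#' mean difference `effect_size * noise_sd` (means at -/+ half the shift,
#' shared variance); non-informative features are identically distributed
#' in both classes. Discrete features are binary with per-class Bernoulli
#' rates whose log-odds differ by `effect_size` for informative features.
#' The identities of informative features are recorded for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return A `multiomics_cohort`: sample ids, integer labels (0/1, with
#'   `NA` marking a missing outcome), and a named list of omics blocks.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_pos <- round(n * config$class_balance)
  if (n_pos < 1 || n_pos > n - 1) {
    stop("class_balance leaves a class empty at this n_samples", call. = FALSE)
  }
  classes <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  sample_ids <- sprintf("S%04d", seq_len(n))

  blocks <- vector("list", nrow(config$blocks))
  names(blocks) <- config$blocks$name
  for (b in seq_len(nrow(config$blocks))) {
    spec <- config$blocks[b, ]
    p <- spec$n_features
    feature_ids <- sprintf("%s_f%04d", spec$name, seq_len(p))
    informative <- sort(sample(p, spec$n_informative))
    if (spec$kind == "continuous") {
      values <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
      if (length(informative)) {
        shift <- (classes - 0.5) * spec$effect_size * spec$noise_sd
        values[, informative] <- values[, informative] + shift
      }
    } else {
      p0 <- .discrete_base_rate
      rate <- matrix(p0, n, p)
      if (length(informative)) {
        lo <- stats::qlogis(p0)
        rate[, informative] <- stats::plogis(
          lo + (classes - 0.5) * spec$effect_size
        )
      }
      values <- matrix(
        as.integer(stats::runif(n * p) < rate), n, p
      )
    }
    colnames(values) <- feature_ids
    blocks[[b]] <- structure(
      list(
        name = spec$name,
        kind = spec$kind,
        values = tibble::as_tibble(values),
        feature_ids = feature_ids,
        informative_ids = feature_ids[informative]
      ),
      class = "omics_block"
    )
  }

  labels <- classes
  if (config$label_missing_count > 0) {
    labels[sample(n, config$label_missing_count)] <- NA_integer_
  }

  structure(
    list(
      sample_ids = sample_ids,
      labels = labels,
      blocks = blocks,
      config = config
    ),
    class = "multiomics_cohort"
  )
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat(
    "<multiomics_cohort> ", length(x$sample_ids), " samples (",
    sum(x$labels == 1L, na.rm = TRUE), " positive, ",
    sum(x$labels == 0L, na.rm = TRUE), " negative, ",
    sum(is.na(x$labels)), " unlabelled)\n",
    sep = ""
  )
  for (b in x$blocks) {
    cat(
      "  block ", b$name, " [", b$kind, "]: ",
      length(b$feature_ids), " features\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Drop samples with a missing outcome label
#'
#' Removes every sample whose label is missing from the label vector, the
#' sample ids and all blocks, preserving order. This is the label
#' completeness filter applied before any analysis: only labelled samples
#' carry information for a supervised model.
#'
#' @param cohort A `multiomics_cohort`.
#' @return The filtered cohort.
#' @export
filter_labelled <- function(cohort) {
  stopifnot(inherits(cohort, "multiomics_cohort"))
  keep <- !is.na(cohort$labels)
  if (!any(keep)) {
    warning("all labels missing; returning an empty cohort", call. = FALSE)
  }
  cohort$sample_ids <- cohort$sample_ids[keep]
  cohort$labels <- cohort$labels[keep]
  cohort$blocks <- lapply(cohort$blocks, function(b) {
    b$values <- b$values[keep, , drop = FALSE]
    b
  })
  cohort
}

#' Write a cohort to a directory of delimited text files
#'
#' One `<block>.csv` per block (samples as rows, first column `sample_id`),
#' a `labels.csv` (`sample_id,label`, empty field for a missing label), and
#' a `truth.json` sidecar recording the informative feature identities and
#' the generating configuration for recovery tests.
#'
#' @param cohort A `multiomics_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multiomics_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in cohort$blocks) {
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = cohort$sample_ids), b$values
    )
    readr::write_csv(out, file.path(dir, paste0(b$name, ".csv")))
  }
  readr::write_csv(
    tibble::tibble(sample_id = cohort$sample_ids, label = cohort$labels),
    file.path(dir, "labels.csv"),
    na = ""
  )
  truth <- list(
    blocks = lapply(cohort$blocks, function(b) {
      list(name = b$name, kind = b$kind, informative_ids = b$informative_ids)
    }),
    config = if (!is.null(cohort$config)) {
      c(
        cohort$config[c(
          "n_samples", "class_balance", "label_missing_count", "seed"
        )],
        list(blocks = cohort$config$blocks)
      )
    }
  )
  jsonlite::write_json(
    truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the block CSVs, `labels.csv` and
#'   `truth.json`.
#' @return A `multiomics_cohort`.
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(truth_path)) {
    stop("no truth.json in ", dir, "; not a cohort directory", call. = FALSE)
  }
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  labels_tab <- readr::read_csv(
    file.path(dir, "labels.csv"),
    col_types = readr::cols(
      sample_id = readr::col_character(), label = readr::col_integer()
    ),
    na = ""
  )
  block_meta <- truth$blocks
  blocks <- list()
  for (i in seq_along(block_meta)) {
    meta <- block_meta[[i]]
    tab <- readr::read_csv(
      file.path(dir, paste0(meta$name, ".csv")),
      col_types = readr::cols(
        sample_id = readr::col_character(),
        .default = readr::col_double()
      )
    )
    stopifnot(identical(tab$sample_id, labels_tab$sample_id))
    values <- tab[setdiff(names(tab), "sample_id")]
    if (meta$kind == "discrete") {
      values <- dplyr::mutate(
        values, dplyr::across(dplyr::everything(), as.integer)
      )
    }
    blocks[[meta$name]] <- structure(
      list(
        name = meta$name, kind = meta$kind,
        values = values,
        feature_ids = names(values),
        informative_ids = unlist(meta$informative_ids) %||% character()
      ),
      class = "omics_block"
    )
  }
  structure(
    list(
      sample_ids = labels_tab$sample_id,
      labels = labels_tab$label,
      blocks = blocks,
      config = NULL
    ),
    class = "multiomics_cohort"
  )
}
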