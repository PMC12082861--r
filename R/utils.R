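# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage seeds so a single
#' knob reproduces a whole pipeline run. Kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage index (1-based) or stage name known to the pipeline.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(
      simulate = 1L, select = 2L, reduce = 3L, augment = 4L,
      train = 5L, evaluate = 6L
    )
    if (!stage %in% names(stages)) {
      stop("unknown stage: ", stage, call. = FALSE)
    }
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stage)) %% 2147483647)
}

# set the RNG only when the caller supplied a seed
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# numeric feature columns of a design-like tibble (everything except
# bookkeeping columns)
feature_columns <- function(data, label_col = "label") {
  drop <- c("sample_id", label_col, "provenance")
  setdiff(names(data), drop)
}

as_feature_matrix <- function(data, label_col = "label") {
  cols <- feature_columns(data, label_col)
  x <- as.matrix(data[cols])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

check_binary_labels <- function(y, arg = "labels") {
  if (anyNA(y)) stop(arg, " contain missing values", call. = FALSE)
  if (!all(y %in% c(0, 1))) {
    stop(arg, " must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop(arg, " must contain both classes", call. = FALSE)
  }
  as.integer(y)
}
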