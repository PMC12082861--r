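#' Fit a principal component transform on a selected feature matrix
#'
#' Classical PCA: the data are column-centered (no unit-variance scaling by
#' default, since omics abundances are assumed already median-normalized
#' and log2-transformed upstream) and the scores are `T_L = X W_L` with the
#' first `L` loading columns retained, ordered by decreasing explained
#' variance. For reproducibility across linear-algebra backends each
#' loading column's largest-magnitude element is made positive.
#'
#' @param x Numeric matrix or data frame (samples x features).
#' @param L Number of components to retain; must satisfy
#'   `L <= min(nrow(x) - 1, ncol(x))`.
#' @param scale Scale columns to unit variance before the fit
#'   (default `FALSE`).
#' @return A `pca_transform` with `loadings` (features x L, orthonormal
#'   columns), `centers`, `scales`, `explained` (variance fractions for all
#'   components) and `L`.
#' @export
fit_pca <- function(x, L = 2, scale = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need >= 2 samples to fit a PCA", call. = FALSE)
  l_max <- min(n - 1L, p)
  if (L < 1L || L > l_max) {
    stop("L = ", L, " not attainable; choose L in 1..", l_max, call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  w <- fit$rotation[, seq_len(L), drop = FALSE]
  # sign convention: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(w))) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) w[, j] <- -w[, j]
  }
  structure(
    list(
      loadings = w,
      centers = fit$center,
      scales = if (scale) fit$scale else NULL,
      explained = fit$sdev^2 / sum(fit$sdev^2),
      L = as.integer(L)
    ),
    class = "pca_transform"
  )
}

#' Project new samples onto a fitted principal component transform
#'
#' @param object A `pca_transform`.
#' @param newdata Numeric matrix or data frame with the same feature
#'   columns the transform was fitted on.
#' @param ... Unused.
#' @return A samples x L score matrix.
#' @export
predict.pca_transform <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  x <- sweep(x, 2, object$centers)
  if (!is.null(object$scales)) x <- sweep(x, 2, object$scales, "/")
  x %*% object$loadings
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(
    "<pca_transform> ", nrow(x$loadings), " features -> ", x$L,
    " components (", round(100 * sum(x$explained[seq_len(x$L)]), 1),
    "% variance)\n",
    sep = ""
  )
  invisible(x)
}

#' Assemble the unified post-selection design matrix
#'
#' Selected discrete features pass through unchanged (column names are
#' `<block>.<feature>`); each continuous block's selected features are
#' reduced independently to their first `L` principal components (columns
#' `<block>_PC1`, `<block>_PC2`, ...). Block order follows the cohort;
#' component columns follow component index. A continuous block with fewer
#' selected features than `L` keeps all attainable components with a
#' warning; a block with no selected features (or `L = 0`) is absent.
#'
#' @param cohort A labelled `multiomics_cohort`.
#' @param report The `selection_report` from [select_features()].
#' @param L Components per continuous block: a single number or a named
#'   vector keyed by block name (default 2).
#' @param scale Passed to [fit_pca()].
#' @return A `reduced_dataset` tibble (`sample_id`, `label`, then feature
#'   columns) with attributes `roles` (column / role / block) and
#'   `transforms` (fitted `pca_transform`s by block).
#' @export
assemble_design <- function(cohort, report, L = 2, scale = FALSE) {
  stopifnot(
    inherits(cohort, "multiomics_cohort"),
    inherits(report, "selection_report")
  )
  if (anyNA(cohort$labels)) {
    stop("cohort has missing labels; run filter_labelled() first",
      call. = FALSE
    )
  }
  cols <- list()
  roles <- list()
  transforms <- list()
  for (b in cohort$blocks) {
    sel <- selected_features(report, b$name)
    if (!length(sel)) next
    l_block <- if (!is.null(names(L))) {
      if (b$name %in% names(L)) as.integer(L[[b$name]]) else 2L
    } else {
      as.integer(L[1])
    }
    if (b$kind == "discrete") {
      v <- b$values[sel]
      names(v) <- paste(b$name, sel, sep = ".")
      cols[[b$name]] <- v
      roles[[b$name]] <- tibble::tibble(
        column = names(v), role = "passthrough", block = b$name
      )
    } else {
      if (l_block == 0L) next
      l_eff <- min(l_block, length(sel), nrow(b$values) - 1L)
      if (l_eff < l_block) {
        warning(
          "block '", b$name, "': only ", l_eff,
          " principal component(s) attainable (requested ", l_block, ")",
          call. = FALSE
        )
      }
      pt <- fit_pca(b$values[sel], L = l_eff, scale = scale)
      scores <- predict(pt, b$values[sel])
      colnames(scores) <- paste0(b$name, "_PC", seq_len(l_eff))
      cols[[b$name]] <- tibble::as_tibble(scores)
      roles[[b$name]] <- tibble::tibble(
        column = colnames(scores), role = "pc", block = b$name
      )
      transforms[[b$name]] <- pt
    }
  }
  if (!length(cols)) {
    stop("selection is empty for every block; nothing to assemble",
      call. = FALSE
    )
  }
  design <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = cohort$sample_ids,
      label = as.integer(cohort$labels)
    ),
    cols
  )
  attr(design, "roles") <- dplyr::bind_rows(roles)
  attr(design, "transforms") <- transforms
  class(design) <- c("reduced_dataset", class(tibble::tibble()))
  design
}

#' Column roles of a reduced design matrix
#'
#' @param design A `reduced_dataset` (or any tibble carrying a `roles`
#'   attribute).
#' @return A tibble with `column`, `role` (`"passthrough"` or `"pc"`) and
#'   `block`, or `NULL` when the attribute is absent.
#' @export
design_roles <- function(design) {
  attr(design, "roles", exact = TRUE)
}

#' Write a reduced design matrix and its PCA transforms
#'
#' Writes `design.csv` plus one `pca_<block>.json` per continuous block
#' (centers, loadings, explained-variance fractions).
#'
#' @param design A `reduced_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(design), file.path(dir, "design.csv"))
  transforms <- attr(design, "transforms", exact = TRUE)
  for (nm in names(transforms)) {
    pt <- transforms[[nm]]
    jsonlite::write_json(
      list(
        block = nm,
        centers = as.list(pt$centers),
        loadings = apply(pt$loadings, 2, identity, simplify = FALSE),
        explained = pt$explained,
        L = pt$L
      ),
      file.path(dir, paste0("pca_", nm, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Scatter the first two principal components of one block
#'
#' A diagnostic mirror of the "do the leading components separate the
#' classes" check: held against the synthetic generator, informative
#' features sharing a class shift should pull the two classes apart in
#' PC space.
#'
#' @param object A `reduced_dataset`.
#' @param block Block whose components to plot (default: first block with
#'   principal components).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.reduced_dataset <- function(object, block = NULL, ...) {
  roles <- design_roles(object)
  pc_roles <- roles[roles$role == "pc", ]
  if (!nrow(pc_roles)) stop("design has no principal components", call. = FALSE)
  block <- block %||% pc_roles$block[1]
  cols <- pc_roles$column[pc_roles$block == block]
  if (length(cols) < 2L) {
    stop("block '", block, "' has fewer than two components", call. = FALSE)
  }
  df <- tibble::tibble(
    x = object[[cols[1]]], y = object[[cols[2]]],
    label = factor(object$label)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = cols[1], y = cols[2], colour = "outcome",
      title = paste0("Leading principal components: ", block)
    ) +
    ggplot2::theme_minimal()
}
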