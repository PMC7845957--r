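#' Assemble the texture feature table of a speckle image set
#'
#' For every image, every Haralick parameter and every direction, the
#' parameter is computed at each separation distance and its distance curve
#' is summarized by the asymptote `y0` of an exponential fit
#' (`y = y0 + A exp(-B d)`; `A` and `B` are discarded as they track curve
#' shape, not roughness). With the defaults — 10 distances, 4 directions,
#' 8 parameters — each parameter contributes 44 features
#' (4 x 10 raw values + 4 y0), for p = 352 columns in total.
#'
#' Column names are `PARAM_thetaDEG_dK` / `PARAM_thetaDEG_y0` (for example
#' `ASM_45_d3`, `CON_0_y0`), ordered parameter-major, then direction, then
#' distance with `y0` last, so serialized feature tables and models are
#' stable across runs.
#'
#' @param images A tibble with list-column `image` of `speckle_image`
#'   objects (as returned by [simulate_speckle_dataset()]), and optionally
#'   `id` and `ra_nm` columns; or a bare list of images/matrices.
#' @param distances Integer separation distances (default 1..10).
#' @param directions Directions in degrees (default all four).
#' @param parameters Haralick parameter subset (default all eight).
#' @param levels Gray levels for the co-occurrence matrices.
#' @param log_base Log base for the entropy features.
#' @return A tibble: `id`, `ra_nm` (if labels were present), then the
#'   feature columns. Assembly fails loudly — naming the image, parameter
#'   and direction — if any exponential fit does not converge or an
#'   undefined correlation (`NA`) appears.
#' @export
#' @examples
#' ds <- simulate_speckle_dataset(c(100, 1000), seed = 1,
#'                                grid_size = c(64, 64))
#' dim(speckle_features(ds, distances = 1:4, directions = 0,
#'                      parameters = "CON", levels = 64))
speckle_features <- function(images,
                             distances = 1:10,
                             directions = c(0, 45, 90, 135),
                             parameters = haralick_parameters(),
                             levels = 256L,
                             log_base = exp(1)) {
  images <- as_image_tibble(images)
  parameters <- match.arg(parameters, haralick_parameters(),
                          several.ok = TRUE)
  rows <- lapply(seq_len(nrow(images)), function(i) {
    feature_row(images$image[[i]], images$id[i], distances, directions,
                parameters, levels, log_base)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(id = images$id),
    if ("ra_nm" %in% names(images)) tibble::tibble(ra_nm = images$ra_nm),
    out
  )
  stopifnot(!anyNA(out))
  out
}

#' The eight supported Haralick parameter names
#' @return Character vector.
#' @export
haralick_parameters <- function() {
  c("ASM", "CON", "IDM", "ENT", "DA", "DV", "DE", "CORR")
}

feature_row <- function(image, id, distances, directions, parameters,
                        levels, log_base) {
  stack <- glcm_stack(image, distances, directions, levels)
  values <- haralick_stack(stack, log_base)
  out <- list()
  for (p in parameters) {
    for (th in directions) {
      curve <- values[values$direction == th, ]
      curve <- curve[order(curve$distance), ]
      y <- curve[[p]]
      if (anyNA(y)) {
        stop(sprintf("undefined %s (image %s, direction %g deg)",
                     p, id, th), call. = FALSE)
      }
      nm <- sprintf("%s_%g_d%d", p, th, curve$distance)
      out[nm] <- as.list(y)
      fit <- fit_exponential(curve$distance, y)
      if (!fit$converged) {
        stop(sprintf(
          "exponential fit failed (image %s, parameter %s, direction %g deg): %s",
          id, p, th, fit$message), call. = FALSE)
      }
      out[[sprintf("%s_%g_y0", p, th)]] <- fit$y0
    }
  }
  tibble::as_tibble(out)
}

as_image_tibble <- function(images) {
  if (is.data.frame(images)) {
    if (!"image" %in% names(images)) {
      stop("`images` data frame needs an `image` list-column.",
           call. = FALSE)
    }
    if (!"id" %in% names(images)) {
      images$id <- sprintf("img_%02d", seq_len(nrow(images)))
    }
    return(images)
  }
  if (inherits(images, "speckle_image") || is.matrix(images)) {
    images <- list(images)
  }
  tibble::tibble(id = sprintf("img_%02d", seq_along(images)),
                 image = images)
}

#' Feature column names and parameter blocks of a feature table
#'
#' `feature_cols()` returns every column name except the `id`/`ra_nm`
#' labels; `feature_block()` maps feature column names to their Haralick
#' parameter block (the name prefix, e.g. `"ASM"` for `ASM_45_d3`).
#'
#' @param ds A feature tibble.
#' @param cols Character vector of feature column names.
#' @return Character vector.
#' @export
feature_cols <- function(ds) {
  setdiff(names(ds), c("id", "ra_nm"))
}

#' @rdname feature_cols
#' @export
feature_block <- function(cols) {
  vapply(strsplit(cols, "_", fixed = TRUE), `[[`, "", 1L)
}

as_feature_matrix <- function(ds) {
  m <- as.matrix(ds[feature_cols(ds)])
  rownames(m) <- if ("id" %in% names(ds)) ds$id else NULL
  m
}

#' Replace feature blocks by their reciprocals
#'
#' ASM, IDM and CORR rise with surface roughness while the remaining
#' parameters fall; replacing those blocks cell-wise by `1/v` gives every
#' feature the same rating (decreasing in Ra) before correlation screening
#' and PCA. Applying the transform twice returns the original values.
#'
#' @param ds A feature tibble from [speckle_features()].
#' @param blocks Parameter blocks to invert (default `ASM`, `IDM`, `CORR`).
#' @return The feature tibble with the listed blocks inverted.
#' @export
reciprocal_features <- function(ds, blocks = c("ASM", "IDM", "CORR")) {
  cols <- feature_cols(ds)
  target <- cols[feature_block(cols) %in% blocks]
  for (cl in target) {
    v <- ds[[cl]]
    bad <- which(abs(v) < 1e-12)
    if (length(bad)) {
      stop(sprintf("near-zero value in column %s, row %d: cannot invert.",
                   cl, bad[1]), call. = FALSE)
    }
    ds[[cl]] <- 1 / v
  }
  ds
}

#' Pairwise correlation matrix of the feature table
#'
#' Pearson correlation between every pair of feature columns, computed with
#' sample (n - 1) denominators as
#' \eqn{R = \frac{1}{n-1}\left(\frac{X-m}{\sigma}\right)^T
#'            \left(\frac{X-m}{\sigma}\right)}.
#' The diagonal is exactly 1: a feature compared with itself.
#'
#' @param ds A feature tibble (label columns `id`/`ra_nm` are ignored).
#' @return A p x p symmetric numeric matrix with dimnames.
#' @export
feature_correlation <- function(ds) {
  x <- as_feature_matrix(ds)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observations.", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds <= 0)) {
    stop(sprintf("zero-variance column: %s",
                 colnames(x)[which(sds <= 0)[1]]), call. = FALSE)
  }
  xs <- scale(x, center = TRUE, scale = sds)
  r <- crossprod(xs) / (n - 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1  # self-correlation is 1 by definition, not up to rounding
  r
}

#' Screen feature blocks by their correlation with the rest of the table
#'
#' In `"block"` mode each parameter block is scored by the median absolute
#' correlation between its columns and all out-of-block columns; blocks
#' scoring below `threshold` (0.8 by default, the conventional boundary of a
#' "strong" correlation) are dropped whole. `"explicit"` mode drops the
#' named blocks unconditionally — with the default table this removes the
#' 44 CORR columns, taking p from 352 to 308.
#'
#' @param ds A feature tibble.
#' @param r Correlation matrix from [feature_correlation()]; computed from
#'   `ds` when `NULL`. Ignored in explicit mode.
#' @param threshold Minimum block score to retain (block mode).
#' @param mode `"block"` or `"explicit"`.
#' @param drop_blocks Blocks to drop in explicit mode.
#' @return A list: `data` (screened tibble) and `report` (one row per
#'   block: its score, whether it was dropped, and its column count).
#' @export
select_features <- function(ds, r = NULL, threshold = 0.8,
                            mode = c("block", "explicit"),
                            drop_blocks = "CORR") {
  mode <- match.arg(mode)
  cols <- feature_cols(ds)
  blocks <- feature_block(cols)
  block_names <- unique(blocks)
  if (mode == "block") {
    if (is.null(r)) r <- feature_correlation(ds)
    if (!identical(dim(r), c(length(cols), length(cols)))) {
      stop("`r` does not match the feature columns of `ds`.", call. = FALSE)
    }
    score <- vapply(block_names, function(b) {
      inside <- blocks == b
      stats::median(abs(r[inside, !inside, drop = FALSE]))
    }, numeric(1))
    dropped <- score < threshold
  } else {
    score <- rep(NA_real_, length(block_names))
    dropped <- block_names %in% drop_blocks
  }
  if (all(dropped)) stop("selection would drop every feature block.",
                         call. = FALSE)
  keep_cols <- cols[!blocks %in% block_names[dropped]]
  report <- tibble::tibble(
    block = block_names,
    score = score,
    dropped = dropped,
    n_cols = as.integer(table(factor(blocks, levels = block_names)))
  )
  list(
    data = ds[c(intersect(c("id", "ra_nm"), names(ds)), keep_cols)],
    report = report
  )
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Applies \eqn{\bar x_j = (x_j - m_j)/\sigma_j} per column with sample
#' standard deviations. The constants are attached so the identical
#' transform can be replayed on new observations at prediction time.
#'
#' @param ds A feature tibble.
#' @param constants Optional `standardization_constants` from a previous
#'   call, to standardize new data with the stored means/sds.
#' @return The standardized tibble with attribute `"constants"` (a
#'   `standardization_constants` list: `mean`, `sd`, `columns`).
#' @export
standardize_features <- function(ds, constants = NULL) {
  cols <- feature_cols(ds)
  if (is.null(constants)) {
    x <- as_feature_matrix(ds)
    mu <- colMeans(x)
    sds <- apply(x, 2L, stats::sd)
    if (any(sds <= 0)) {
      stop(sprintf("zero-variance column: %s", cols[which(sds <= 0)[1]]),
           call. = FALSE)
    }
    constants <- structure(
      list(mean = mu, sd = sds, columns = cols),
      class = "standardization_constants"
    )
  } else {
    if (!identical(constants$columns, cols)) {
      stop("feature columns do not match the stored constants.",
           call. = FALSE)
    }
  }
  for (k in seq_along(cols)) {
    ds[[cols[k]]] <- (ds[[cols[k]]] - constants$mean[k]) / constants$sd[k]
  }
  attr(ds, "constants") <- constants
  ds
}

#' Standardization constants of a standardized feature table
#' @param ds Output of [standardize_features()].
#' @return A `standardization_constants` object.
#' @export
feature_constants <- function(ds) {
  attr(ds, "constants")
}

#' Write a feature table to CSV
#'
#' Label columns first (`id`, `ra_nm`), then the feature columns in their
#' canonical order; re-running an identical pipeline produces a
#' byte-identical file.
#'
#' @param ds A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(ds, path) {
  readr::write_csv(ds, path, progress = FALSE)
  invisible(path)
}
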