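#' Train the end-to-end roughness measurement pipeline
#'
#' Runs the full chain on a labelled image set: texture feature assembly,
#' reciprocal rating alignment, correlation screening, standardization,
#' principal component analysis, and exponential calibration of the first
#' principal-component score against the Ra labels. The returned object
#' freezes every stage (configuration, retained columns, standardization
#' constants, first eigenvector, calibration curve) so new images can be
#' pushed through the identical transform with [predict()].
#'
#' @param images Labelled image tibble (`image` list-column plus `ra_nm`),
#'   e.g. from [simulate_speckle_dataset()]; at least 5 images spanning more
#'   than a decade of Ra.
#' @inheritParams speckle_features
#' @param reciprocal_blocks Blocks replaced by their reciprocals before
#'   screening (see [reciprocal_features()]).
#' @param selection `"explicit"` (default: drop `drop_blocks` outright, the
#'   standard screening outcome for the correlation block) or `"block"`
#'   (data-driven: drop blocks whose median absolute out-of-block
#'   correlation falls below `threshold`).
#' @param drop_blocks,threshold Passed to [select_features()].
#' @return A `roughness_pipeline` object.
#' @export
#' @examples
#' \donttest{
#' ds <- simulate_speckle_dataset(seed = 1)
#' pipe <- train_roughness_pipeline(ds)
#' glance(pipe)
#' }
train_roughness_pipeline <- function(images,
                                     distances = 1:10,
                                     directions = c(0, 45, 90, 135),
                                     parameters = haralick_parameters(),
                                     levels = 256L,
                                     log_base = exp(1),
                                     reciprocal_blocks = c("ASM", "IDM",
                                                           "CORR"),
                                     selection = c("explicit", "block"),
                                     drop_blocks = "CORR",
                                     threshold = 0.8) {
  selection <- match.arg(selection)
  if (!is.data.frame(images) || !"ra_nm" %in% names(images)) {
    stop("`images` must be a data frame with an `ra_nm` label column.",
         call. = FALSE)
  }
  if (nrow(images) < 5L) {
    stop("need at least 5 labelled images to train.", call. = FALSE)
  }
  features <- speckle_features(images, distances, directions, parameters,
                               levels, log_base)
  features <- reciprocal_features(features, reciprocal_blocks)
  sel <- select_features(features, threshold = threshold, mode = selection,
                         drop_blocks = drop_blocks)
  standardized <- standardize_features(sel$data)
  pca <- speckle_pca(standardized)
  calibration <- calibrate_roughness(pca$scores[, 1L], images$ra_nm)
  structure(
    list(
      config = list(
        distances = as.integer(distances),
        directions = as.numeric(directions),
        parameters = parameters,
        levels = as.integer(levels),
        log_base = log_base,
        reciprocal_blocks = reciprocal_blocks,
        selection = selection,
        drop_blocks = drop_blocks,
        threshold = threshold
      ),
      selection_report = sel$report,
      constants = feature_constants(standardized),
      eigenvector = stats::setNames(pca$vectors[, 1L], pca$columns),
      pca_summary = list(values = pca$values,
                         variance_pct = pca$variance_pct,
                         n_components = pca$n_components),
      calibration = calibration,
      training = tibble::tibble(id = images$id %||%
                                  sprintf("img_%02d", seq_len(nrow(images))),
                                ra_nm = images$ra_nm,
                                pc1 = unname(pca$scores[, 1L]))
    ),
    class = "roughness_pipeline"
  )
}

#' @export
print.roughness_pipeline <- function(x, ...) {
  cat("<roughness_pipeline>", length(x$eigenvector), "features retained,",
      "PC1 explains", signif(x$pca_summary$variance_pct[1], 4), "%\n")
  print(x$calibration)
  invisible(x)
}

#' @method glance roughness_pipeline
#' @export
glance.roughness_pipeline <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$training),
    n_features = length(x$eigenvector),
    pc1_percent = x$pca_summary$variance_pct[1],
    calibration_r2 = x$calibration$r_squared,
    calibration_rmse = x$calibration$rmse
  )
}

#' Predict surface roughness for new speckle images
#'
#' Each image is pushed through the frozen training transform: feature row
#' with the training configuration, reciprocal blocks, retained columns,
#' stored standardization constants, projection on the stored first
#' eigenvector, and inversion of the calibration curve. Predictions outside
#' the calibrated score or Ra range are flagged, not refused.
#'
#' @param object A `roughness_pipeline`.
#' @param images An image tibble, a single `speckle_image`, or a list.
#' @param ... Unused.
#' @return A tibble: `id`, `pc1`, `ra_nm_pred`, `extrapolated`.
#' @export
predict.roughness_pipeline <- function(object, images, ...) {
  images <- as_image_tibble(images)
  cfg <- object$config
  features <- speckle_features(images, cfg$distances, cfg$directions,
                               cfg$parameters, cfg$levels, cfg$log_base)
  features <- reciprocal_features(features, cfg$reciprocal_blocks)
  keep <- c(intersect(c("id", "ra_nm"), names(features)),
            object$constants$columns)
  if (!all(object$constants$columns %in% names(features))) {
    stop("new images do not yield the training feature columns.",
         call. = FALSE)
  }
  features <- features[keep]
  standardized <- standardize_features(features, object$constants)
  scores <- as_feature_matrix(standardized) %*%
    cbind(unname(object$eigenvector))
  inv <- invert_calibration(object$calibration, as.numeric(scores))
  tibble::tibble(
    id = images$id,
    pc1 = inv$score,
    ra_nm_pred = inv$ra_nm,
    extrapolated = inv$extrapolated
  )
}

#' Serialize a trained pipeline to JSON
#'
#' A single versioned document holding the configuration, retained columns,
#' standardization constants, first eigenvector and calibration curve —
#' everything [predict()] needs.
#'
#' @param x A `roughness_pipeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_json <- function(x, path) {
  stopifnot(inherits(x, "roughness_pipeline"))
  obj <- list(
    schema = "roughness_pipeline/1",
    config = x$config,
    selection_report = x$selection_report,
    constants = list(mean = unname(x$constants$mean),
                     sd = unname(x$constants$sd),
                     columns = x$constants$columns),
    eigenvector = unname(x$eigenvector),
    pca_summary = x$pca_summary,
    calibration = list(
      y0 = x$calibration$fit$y0,
      A = x$calibration$fit$A,
      B = x$calibration$fit$B,
      r_squared = x$calibration$r_squared,
      rmse = x$calibration$rmse,
      ra_range = x$calibration$ra_range,
      score_range = x$calibration$score_range
    ),
    training = x$training
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Restore a trained pipeline from JSON
#'
#' @param path Path written by [write_pipeline_json()].
#' @return A `roughness_pipeline`.
#' @export
read_pipeline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "roughness_pipeline/1")) {
    stop("unrecognized pipeline schema.", call. = FALSE)
  }
  cal_fit <- new_exp_fit(
    y0 = obj$calibration$y0, A = obj$calibration$A, B = obj$calibration$B,
    x = obj$training$ra_nm[order(obj$training$ra_nm)],
    y = obj$training$pc1[order(obj$training$ra_nm)],
    converged = TRUE, r_squared = obj$calibration$r_squared,
    message = "restored"
  )
  structure(
    list(
      config = obj$config,
      selection_report = tibble::as_tibble(obj$selection_report),
      constants = structure(
        list(mean = stats::setNames(obj$constants$mean,
                                    obj$constants$columns),
             sd = stats::setNames(obj$constants$sd, obj$constants$columns),
             columns = obj$constants$columns),
        class = "standardization_constants"
      ),
      eigenvector = stats::setNames(obj$eigenvector,
                                    obj$constants$columns),
      pca_summary = obj$pca_summary,
      calibration = structure(
        list(fit = cal_fit,
             r_squared = obj$calibration$r_squared,
             rmse = obj$calibration$rmse,
             ra_range = obj$calibration$ra_range,
             score_range = obj$calibration$score_range),
        class = "roughness_calibration"
      ),
      training = tibble::as_tibble(obj$training)
    ),
    class = "roughness_pipeline"
  )
}
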