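#' Calibrate the first-principal-component score against roughness
#'
#' Fits `PC1 = y0 + A * exp(-B * Ra)` by nonlinear least squares (see
#' [fit_exponential()]) and reports the coefficient of determination and
#' the root-mean-square error of fitted vs observed scores, in score units.
#'
#' @param scores Numeric PC1 score per observation.
#' @param ra_nm Matching roughness labels in nanometres; at least five
#'   observations spanning more than one decade are required.
#' @return A `roughness_calibration`: list with `fit` (an `exp_fit`),
#'   `r_squared`, `rmse`, `ra_range`, `score_range`.
#' @export
#' @examples
#' ra <- c(10, 50, 120, 300, 800, 2000)
#' s <- 5 + 20 * exp(-0.002 * ra)
#' cal <- calibrate_roughness(s, ra)
#' glance(cal)
calibrate_roughness <- function(scores, ra_nm) {
  if (length(scores) != length(ra_nm)) {
    stop("`scores` and `ra_nm` must have equal length.", call. = FALSE)
  }
  if (length(scores) < 5L) {
    stop("need at least 5 labelled observations.", call. = FALSE)
  }
  if (any(ra_nm <= 0)) stop("`ra_nm` must be positive.", call. = FALSE)
  if (max(ra_nm) / min(ra_nm) <= 10) {
    stop("labels must span more than one decade of Ra.", call. = FALSE)
  }
  if (diff(range(scores)) == 0) {
    stop("constant scores carry no roughness information.", call. = FALSE)
  }
  ord <- order(ra_nm)
  fit <- fit_exponential(ra_nm[ord], scores[ord])
  if (!fit$converged) {
    stop("calibration fit did not converge: ", fit$message, call. = FALSE)
  }
  structure(
    list(
      fit = fit,
      r_squared = fit$r_squared,
      rmse = sqrt(mean((fit$data$y - fit$fitted)^2)),
      ra_range = range(ra_nm),
      score_range = range(scores)
    ),
    class = "roughness_calibration"
  )
}

#' @export
print.roughness_calibration <- function(x, ...) {
  cat(sprintf(
    "<roughness_calibration> PC1 = %.4g + %.4g exp(-%.3g Ra), R^2 = %.4f, RMSE = %.4g (score units), Ra %.4g..%.4g nm\n",
    x$fit$y0, x$fit$A, x$fit$B, x$r_squared, x$rmse,
    x$ra_range[1], x$ra_range[2]))
  invisible(x)
}

#' @method tidy roughness_calibration
#' @export
tidy.roughness_calibration <- function(x, ...) tidy(x$fit)

#' @method glance roughness_calibration
#' @export
glance.roughness_calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    rmse = x$rmse,
    ra_min = x$ra_range[1],
    ra_max = x$ra_range[2],
    nobs = nrow(x$fit$data)
  )
}

#' Invert a calibration: map a PC1 score to roughness
#'
#' Solves the calibration curve for Ra:
#' \eqn{R_a = -\frac{1}{B}\ln\frac{s - y_0}{A}}.
#' Scores outside the fitted score range, or inverted values outside the
#' calibrated Ra range, are flagged as extrapolation (never refused).
#'
#' @param cal A `roughness_calibration`.
#' @param scores Numeric scores to invert.
#' @return A tibble with `score`, `ra_nm`, `extrapolated`.
#' @export
invert_calibration <- function(cal, scores) {
  stopifnot(inherits(cal, "roughness_calibration"))
  f <- cal$fit
  arg <- (scores - f$y0) / f$A
  if (any(arg <= 0)) {
    stop("score outside the calibration domain: (s - y0)/A must be > 0.",
         call. = FALSE)
  }
  ra <- -log(arg) / f$B
  tol_s <- 1e-8 * diff(cal$score_range)
  tol_r <- 1e-8 * max(cal$ra_range)
  tibble::tibble(
    score = scores,
    ra_nm = ra,
    extrapolated = scores < cal$score_range[1] - tol_s |
      scores > cal$score_range[2] + tol_s |
      ra < cal$ra_range[1] - tol_r | ra > cal$ra_range[2] + tol_r
  )
}
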