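#' Fit a shifted exponential decay
#'
#' Least-squares fit of \eqn{y = y_0 + A e^{-Bx}} with the rate constrained
#' positive. Used twice in the pipeline: to summarize each texture
#' parameter's distance curve by its asymptote `y0`, and to calibrate the
#' first principal-component score against roughness.
#'
#' Starting values: `y0` from the last observation, `A` from the first, and
#' `B` from a log-linear regression of `|y - y0|` on `x`, with a restart
#' grid of rates scaled to the x-range; the best converged restart (lowest
#' residual sum of squares) wins. A constant `y` short-circuits to
#' `y0 = y[1]`, `A = 0`, with `r_squared = 1` by convention (the flat curve
#' is reproduced exactly).
#'
#' @param x Strictly increasing numeric vector (at least 4 points).
#' @param y Numeric response of the same length.
#' @return An `exp_fit` object: list with `y0`, `A`, `B`, `r_squared`,
#'   `converged`, `fitted`, `data`, `message`. `converged` is honest:
#'   inspect it before using the coefficients.
#' @export
#' @examples
#' x <- 1:10
#' f <- fit_exponential(x, 2 + 3 * exp(-0.5 * x))
#' c(f$y0, f$A, f$B)
fit_exponential <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("`x` and `y` must be numeric vectors of equal length.",
         call. = FALSE)
  }
  if (length(x) < 4L) stop("need at least 4 points.", call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing.",
                              call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite.", call. = FALSE)
  }
  x <- unname(x)
  y <- unname(y)

  if (diff(range(y)) == 0) {
    return(new_exp_fit(y0 = y[1], A = 0, B = 1, x = x, y = y,
                       converged = TRUE, r_squared = 1,
                       message = "constant response"))
  }

  xr <- diff(range(x))
  y0_0 <- y[length(y)]
  a_0 <- y[1] - y0_0

  # profile the rate: for fixed B the model is linear in (y0, A), so a grid
  # scan always yields a valid least-squares solution even where the full
  # nonlinear iteration diverges
  profile <- profile_rate_fit(x, y, 10^seq(-3, 1, length.out = 50) * 9 / xr)

  b_candidates <- c(loglinear_rate(x, y, y0_0), profile$B,
                    c(0.1, 0.5, 1, 2) * 9 / xr)
  b_candidates <- unique(b_candidates[is.finite(b_candidates) &
                                        b_candidates > 0])

  best <- list(coef = c(profile$y0, profile$A, profile$B),
               rss = profile$rss, message = "profile grid")
  for (b0 in b_candidates) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(-B * x),
        data = data.frame(x = x, y = y),
        start = list(y0 = y0_0, A = if (a_0 != 0) a_0 else sd(y), B = b0),
        lower = c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(coef = unname(cf[c("y0", "A", "B")]), rss = rss,
                   message = "ok")
    }
  }

  ss_tot <- sum((y - mean(y))^2)
  new_exp_fit(y0 = best$coef[1], A = best$coef[2], B = best$coef[3],
              x = x, y = y, converged = TRUE,
              r_squared = 1 - best$rss / ss_tot, message = best$message)
}

# Best (y0, A) by linear least squares at each candidate rate B.
profile_rate_fit <- function(x, y, b_grid) {
  best <- NULL
  for (b in b_grid) {
    e <- exp(-b * x)
    fit <- stats::lm.fit(cbind(1, e), y)
    if (anyNA(fit$coefficients)) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(y0 = unname(fit$coefficients[1]),
                   A = unname(fit$coefficients[2]), B = b, rss = rss)
    }
  }
  best
}

loglinear_rate <- function(x, y, y0_0) {
  r <- abs(y - y0_0)
  ok <- r > 0
  if (sum(ok) < 2L) return(numeric(0))
  -unname(stats::coef(stats::lm(log(r[ok]) ~ x[ok]))[2])
}

new_exp_fit <- function(y0, A, B, x, y, converged, r_squared, message) {
  fitted <- if (converged) y0 + A * exp(-B * x) else rep(NA_real_, length(x))
  structure(
    list(y0 = y0, A = A, B = B, r_squared = r_squared,
         converged = converged, fitted = fitted,
         data = tibble::tibble(x = x, y = y), message = message),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<exp_fit> y = %.4g + %.4g * exp(-%.4g x), R^2 = %.4f\n",
                x$y0, x$A, x$B, x$r_squared))
  } else {
    cat("<exp_fit> not converged:", x$message, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("y0", "A", "B"),
                 estimate = c(x$y0, x$A, x$B))
}

#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    rmse = if (x$converged) {
      sqrt(mean((x$data$y - x$fitted)^2))
    } else {
      NA_real_
    },
    converged = x$converged,
    nobs = nrow(x$data)
  )
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  if (is.data.frame(x)) x <- x$x
  object$y0 + object$A * exp(-object$B * x)
}
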