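#' Specify a rough surface to simulate
#'
#' A `surface_spec` describes a Gaussian-correlated random surface by its
#' target arithmetic-mean roughness, lateral correlation length, grid size
#' and pixel pitch. It is the input contract of [generate_surface()].
#'
#' @param ra_target Target average roughness Ra in nanometres (> 0).
#' @param correlation_length Lateral correlation length of the surface in
#'   micrometres (> 0); the standard deviation of the Gaussian smoothing
#'   kernel applied to white noise.
#' @param grid_size Integer vector `c(rows, cols)`, each at least 16.
#' @param pixel_pitch Physical size of one grid cell in micrometres (> 0).
#'
#' @return An object of class `surface_spec`.
#' @export
#' @examples
#' surface_spec(ra_target = 500)
surface_spec <- function(ra_target,
                         correlation_length = 100,
                         grid_size = c(400L, 400L),
                         pixel_pitch = 25) {
  if (!is.numeric(ra_target) || length(ra_target) != 1L ||
      !is.finite(ra_target) || ra_target <= 0) {
    stop("`ra_target` must be a single positive, finite number (nm).",
         call. = FALSE)
  }
  if (!is.numeric(correlation_length) || correlation_length <= 0) {
    stop("`correlation_length` must be positive (um).", call. = FALSE)
  }
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 2L || any(grid_size < 16L)) {
    stop("`grid_size` must be two integers, each >= 16.", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be positive (um).", call. = FALSE)
  }
  structure(
    list(
      ra_target = as.numeric(ra_target),
      correlation_length = as.numeric(correlation_length),
      grid_size = grid_size,
      pixel_pitch = as.numeric(pixel_pitch)
    ),
    class = "surface_spec"
  )
}

#' @export
print.surface_spec <- function(x, ...) {
  cat("<surface_spec> Ra", x$ra_target, "nm, corr. length",
      x$correlation_length, "um,", x$grid_size[1], "x", x$grid_size[2],
      "px @", x$pixel_pitch, "um/px\n")
  invisible(x)
}

#' Generate a random rough surface with prescribed Ra
#'
#' Draws a white Gaussian height field, low-pass filters it with a Gaussian
#' kernel whose standard deviation is the requested correlation length, then
#' recentres and rescales so the achieved arithmetic-mean roughness equals
#' `spec$ra_target` exactly (Ra is homogeneous of degree one in the heights,
#' so the rescaling is exact, not iterative).
#'
#' @param spec A [surface_spec()].
#' @param seed Integer seed; the same `(spec, seed)` pair always yields the
#'   identical surface.
#'
#' @return A `height_map` object: list with `heights` (matrix, nm),
#'   `pixel_pitch` (um), `spec` and `seed`.
#' @export
#' @examples
#' h <- generate_surface(surface_spec(200), seed = 1)
#' surface_ra(h)
generate_surface <- function(spec, seed) {
  if (!inherits(spec, "surface_spec")) {
    stop("`spec` must be a `surface_spec`.", call. = FALSE)
  }
  seed <- check_seed(seed)
  nr <- spec$grid_size[1]
  nc <- spec$grid_size[2]
  z <- with_local_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  sigma_px <- spec$correlation_length / spec$pixel_pitch
  z <- gaussian_filter_fft(z, sigma_px)
  z <- z - mean(z)
  ra_raw <- mean(abs(z))
  if (ra_raw <= 0) stop("degenerate surface draw; try another seed.",
                        call. = FALSE)
  structure(
    list(
      heights = z * (spec$ra_target / ra_raw),
      pixel_pitch = spec$pixel_pitch,
      spec = spec,
      seed = seed
    ),
    class = "height_map"
  )
}

#' Arithmetic-mean surface roughness
#'
#' Ra is the mean absolute deviation of the heights from the mean plane,
#' the quantity a stylus profilometer reports:
#' \deqn{R_a = \frac{1}{N}\sum_i |h_i - \bar h|}
#'
#' @param h A `height_map` or a numeric vector/matrix of heights in nm.
#' @return Ra in nanometres (non-negative scalar).
#' @export
surface_ra <- function(h) {
  if (inherits(h, "height_map")) h <- h$heights
  if (!is.numeric(h) || length(h) < 2L) {
    stop("need at least two height samples.", call. = FALSE)
  }
  if (!all(is.finite(h))) stop("heights must be finite.", call. = FALSE)
  mean(abs(h - mean(h)))
}

# Periodic Gaussian low-pass filter; sigma_px in pixels, applied in the
# frequency domain so the cost is two FFTs regardless of kernel width.
gaussian_filter_fft <- function(z, sigma_px) {
  if (sigma_px <= 0) return(z)
  nr <- nrow(z)
  nc <- ncol(z)
  fr <- fft_freq(nr)
  fc <- fft_freq(nc)
  hr <- exp(-2 * pi^2 * sigma_px^2 * fr^2)
  hc <- exp(-2 * pi^2 * sigma_px^2 * fc^2)
  transfer <- outer(hr, hc)
  Re(stats::fft(stats::fft(z) * transfer, inverse = TRUE)) / (nr * nc)
}

# Discrete Fourier sample frequencies (cycles per sample), numpy-style order.
fft_freq <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / n
}
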