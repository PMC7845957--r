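#' Specify a gray-level co-occurrence matrix
#'
#' @param distance Pixel separation d (integer >= 1).
#' @param direction One of 0, 45, 90, 135 (degrees): horizontal, right
#'   diagonal, vertical, left diagonal.
#' @param levels Number of gray levels L (default 256 for 8-bit images).
#' @param symmetric If `TRUE` (default) pairs are counted in both the
#'   forward and backward sense, making the matrix symmetric about its
#'   principal diagonal.
#'
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(distance = 1L, direction = 0, levels = 256L,
                      symmetric = TRUE) {
  distance <- as.integer(distance)
  levels <- as.integer(levels)
  if (length(distance) != 1L || is.na(distance) || distance < 1L) {
    stop("`distance` must be an integer >= 1.", call. = FALSE)
  }
  if (!direction %in% c(0, 45, 90, 135)) {
    stop("`direction` must be one of 0, 45, 90, 135 degrees.", call. = FALSE)
  }
  if (length(levels) != 1L || is.na(levels) || levels < 2L) {
    stop("`levels` must be an integer >= 2.", call. = FALSE)
  }
  structure(
    list(distance = distance, direction = as.numeric(direction),
         levels = levels, symmetric = isTRUE(symmetric)),
    class = "glcm_spec"
  )
}

# (row, col) offset of the forward neighbour for each direction, 0 deg
# horizontal; 45/135 follow the image-axis convention (rows grow downward).
glcm_offset <- function(spec) {
  d <- spec$distance
  switch(as.character(spec$direction),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d))
}

#' Count gray-level co-occurrences
#'
#' Counts ordered pixel pairs `(i, j)` separated by the offset of
#' `spec$direction` at `spec$distance`; with `symmetric = TRUE` the backward
#' offset is counted as well, so the count matrix equals its transpose.
#' Neighbours falling outside the image are skipped (no padding).
#'
#' @param image A `speckle_image` or integer matrix with values in
#'   `0..levels-1`.
#' @param spec A [glcm_spec()].
#' @return A `glcm_counts` object: list with integer matrix `counts`
#'   (`levels` x `levels`) and `spec`.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE)
#' compute_glcm(m, glcm_spec(1, 0, levels = 4))$counts
compute_glcm <- function(image, spec) {
  px <- as_pixel_matrix(image)
  stopifnot(inherits(spec, "glcm_spec"))
  L <- spec$levels
  if (any(px < 0) || any(px >= L) || any(px != trunc(px))) {
    stop("pixel values must be integers in [0, levels).", call. = FALSE)
  }
  off <- glcm_offset(spec)
  if (abs(off[1]) >= nrow(px) || abs(off[2]) >= ncol(px)) {
    stop("offset exceeds image extent.", call. = FALSE)
  }
  counts <- pair_counts(px, off, L)
  if (spec$symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0L) stop("no valid pixel pairs for this offset.",
                              call. = FALSE)
  structure(list(counts = counts, spec = spec), class = "glcm_counts")
}

# Vectorized ordered-pair tabulation for one (row, col) offset.
pair_counts <- function(px, off, L) {
  nr <- nrow(px)
  nc <- ncol(px)
  rows <- seq.int(max(1L, 1L - off[1]), min(nr, nr - off[1]))
  cols <- seq.int(max(1L, 1L - off[2]), min(nc, nc - off[2]))
  a <- px[rows, cols, drop = FALSE]
  b <- px[rows + off[1], cols + off[2], drop = FALSE]
  counts <- tabulate(as.integer(a) * L + as.integer(b) + 1L, nbins = L * L)
  matrix(as.integer(counts), L, L, byrow = TRUE)
}

#' Normalize a co-occurrence count matrix
#'
#' Divides each cell by the grand total so the cells sum to one; the result
#' is the joint probability of observing the gray-level pair at the spec's
#' offset.
#'
#' @param cm A `glcm_counts` from [compute_glcm()].
#' @return A `glcm` object: list with matrix `probabilities` and `spec`.
#' @export
normalize_glcm <- function(cm) {
  stopifnot(inherits(cm, "glcm_counts"))
  total <- sum(cm$counts)
  if (total <= 0) stop("cannot normalize an all-zero count matrix.",
                       call. = FALSE)
  structure(
    list(probabilities = cm$counts / total, spec = cm$spec),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("<glcm> d =", x$spec$distance, ", theta =", x$spec$direction,
      "deg, L =", x$spec$levels,
      if (x$spec$symmetric) "(symmetric)\n" else "\n")
  invisible(x)
}

#' Compute a stack of GLCMs over distances and directions
#'
#' The default grid — distances 1..10 pixels by the four directions — yields
#' the forty matrices on which the texture features are based.
#'
#' @inheritParams compute_glcm
#' @param distances Integer vector of separation distances.
#' @param directions Numeric vector drawn from `c(0, 45, 90, 135)`.
#' @param levels Number of gray levels.
#' @param symmetric Passed to [glcm_spec()].
#' @return A tibble with columns `distance`, `direction` and list-column
#'   `glcm` of normalized [glcm] objects.
#' @export
glcm_stack <- function(image, distances = 1:10,
                       directions = c(0, 45, 90, 135),
                       levels = 256L, symmetric = TRUE) {
  px <- as_pixel_matrix(image)
  grid <- expand.grid(distance = as.integer(distances),
                      direction = as.numeric(directions),
                      KEEP.OUT.ATTRS = FALSE)
  glcms <- lapply(seq_len(nrow(grid)), function(k) {
    normalize_glcm(compute_glcm(
      px, glcm_spec(grid$distance[k], grid$direction[k], levels, symmetric)
    ))
  })
  tibble::tibble(distance = grid$distance, direction = grid$direction,
                 glcm = glcms)
}

#' Export a GLCM as a dense CSV matrix
#'
#' Rows and columns are labelled with their gray levels.
#'
#' @param g A `glcm` or `glcm_counts` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_glcm_csv <- function(g, path) {
  m <- if (inherits(g, "glcm")) g$probabilities else g$counts
  L <- ncol(m)
  df <- as.data.frame(m)
  names(df) <- as.character(0:(L - 1))
  df <- cbind(gray = 0:(L - 1), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
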