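#' Gray-level difference marginal of a GLCM
#'
#' `values[k + 1]` is the total probability mass on the k-th diagonal pair
#' of the matrix, i.e. \eqn{P_{x-y}(k) = \sum_{|i-j|=k} P(i,j)};
#' `values[1]` (k = 0) is the mass on the principal diagonal.
#'
#' @param P A normalized `glcm` from [normalize_glcm()].
#' @return Numeric vector of length `levels` indexed by k = 0..L-1; sums
#'   to 1.
#' @export
diff_marginal <- function(P) {
  p <- glcm_probabilities(P)
  L <- ncol(p)
  k <- abs(.row(dim(p)) - .col(dim(p)))
  out <- numeric(L)
  sums <- rowsum(as.vector(p), as.vector(k))
  out[as.integer(rownames(sums)) + 1L] <- sums[, 1L]
  out
}

#' Haralick statistical parameters of a GLCM
#'
#' Computes the eight second-order texture statistics from a normalized
#' co-occurrence matrix P over gray levels `0..L-1` (difference marginal
#' \eqn{P_{x-y}} as in [diff_marginal()]):
#' \itemize{
#'   \item `ASM` angular second moment \eqn{\sum P(i,j)^2} — image
#'     homogeneity; 1 only for a single-cell matrix.
#'   \item `CON` contrast \eqn{\sum_n n^2 \sum_{|i-j|=n} P(i,j)} — weight
#'     grows with distance from the principal diagonal.
#'   \item `IDM` inverse difference moment
#'     \eqn{\sum P(i,j) / (1 + (i-j)^2)}.
#'   \item `ENT` entropy \eqn{-\sum P \log P} (with `0 log 0 := 0`).
#'   \item `DA` difference average \eqn{\sum_k k P_{x-y}(k)}.
#'   \item `DV` difference variance \eqn{\sum_k (k - DA)^2 P_{x-y}(k)}.
#'   \item `DE` difference entropy \eqn{-\sum_k P_{x-y}(k)\log P_{x-y}(k)}.
#'   \item `CORR` correlation
#'     \eqn{\sum P(i,j)(i-\mu_x)(j-\mu_y) / (\sigma_x \sigma_y)}; `NA` when
#'     either marginal standard deviation is zero (e.g. a constant image),
#'     never silently 0.
#' }
#'
#' Logarithms are natural by default (`log_base` changes only the scale of
#' the two entropy features, which later standardization removes anyway).
#'
#' @param P A normalized `glcm`.
#' @param log_base Base of the logarithm used by `ENT` and `DE`.
#' @return A one-row tibble with columns `distance`, `direction` (taken from
#'   the GLCM spec, `NA` for bare matrices) and the eight parameters.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 0, 1), 2, 2)
#' g <- normalize_glcm(compute_glcm(m, glcm_spec(1, 0, levels = 2)))
#' haralick_features(g)
haralick_features <- function(P, log_base = exp(1)) {
  p <- glcm_probabilities(P)
  L <- ncol(p)
  i <- .row(dim(p)) - 1L
  j <- .col(dim(p)) - 1L
  k <- 0:(L - 1)

  pxy <- diff_marginal(P)
  asm <- sum(p^2)
  con <- sum(k^2 * pxy)
  idm <- sum(p / (1 + (i - j)^2))
  ent <- -sum(xlogx(p)) / log(log_base)
  da <- sum(k * pxy)
  dv <- sum((k - da)^2 * pxy)
  de <- -sum(xlogx(pxy)) / log(log_base)

  mu_x <- sum(i * p)
  mu_y <- sum(j * p)
  sd_x <- sqrt(sum((i - mu_x)^2 * p))
  sd_y <- sqrt(sum((j - mu_y)^2 * p))
  corr <- if (sd_x * sd_y > 0) {
    sum(p * (i - mu_x) * (j - mu_y)) / (sd_x * sd_y)
  } else {
    NA_real_
  }

  spec <- if (inherits(P, "glcm")) P$spec else NULL
  tibble::tibble(
    distance = if (is.null(spec)) NA_integer_ else spec$distance,
    direction = if (is.null(spec)) NA_real_ else spec$direction,
    ASM = asm, CON = con, IDM = idm, ENT = ent,
    DA = da, DV = dv, DE = de, CORR = corr
  )
}

#' Haralick parameters for every GLCM of a stack
#'
#' @param stack A tibble from [glcm_stack()].
#' @inheritParams haralick_features
#' @return A tibble with one row per (distance, direction).
#' @export
haralick_stack <- function(stack, log_base = exp(1)) {
  stopifnot(is.data.frame(stack), "glcm" %in% names(stack))
  dplyr::bind_rows(lapply(stack$glcm, haralick_features,
                          log_base = log_base))
}

# x * log(x) with the 0 log 0 := 0 convention.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  dim(out) <- dim(x)
  out
}

glcm_probabilities <- function(P) {
  p <- if (inherits(P, "glcm")) P$probabilities else P
  if (!is.matrix(p) || !is.numeric(p)) {
    stop("`P` must be a `glcm` or a numeric matrix.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
    stop("`P` must be a normalized GLCM (non-negative, summing to 1).",
         call. = FALSE)
  }
  p
}
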