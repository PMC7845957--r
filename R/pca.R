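#' Covariance matrix of a standardized feature table
#'
#' \eqn{C = X^T X / (n-1)} for standardized X (zero-mean, unit-variance
#' columns), in which case C coincides with the pairwise correlation matrix.
#' The input is checked and the call fails on unstandardized data.
#'
#' @param x A standardized feature tibble (from [standardize_features()])
#'   or numeric matrix.
#' @return A p x p symmetric matrix with unit diagonal.
#' @export
covariance_matrix <- function(x) {
  x <- if (is.data.frame(x)) as_feature_matrix(x) else as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations.", call. = FALSE)
  mu <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  if (max(abs(mu)) > 1e-8 || max(abs(v - 1)) > 1e-6) {
    stop("input is not standardized (zero mean, unit variance).",
         call. = FALSE)
  }
  crossprod(x) / (n - 1)
}

#' Eigendecomposition of a symmetric covariance matrix
#'
#' Real eigenpairs in descending eigenvalue order. Eigenvector signs are
#' fixed so each column's entry sum is non-negative (ties broken by making
#' the first nonzero entry positive) — the sign of an eigenvector is
#' otherwise arbitrary, and this convention makes an all-positive first
#' component report as such.
#'
#' @param C Symmetric numeric matrix (asymmetry beyond 1e-8 is an error).
#' @return A list with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
eigendecompose <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("`C` must be symmetric.", call. = FALSE)
  }
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vec <- apply(e$vectors, 2L, fix_eigenvector_sign)
  dim(vec) <- dim(e$vectors)
  dimnames(vec) <- dimnames(e$vectors)
  if (!is.null(colnames(C))) rownames(vec) <- colnames(C)
  list(values = e$values, vectors = vec)
}

fix_eigenvector_sign <- function(v) {
  s <- sum(v)
  if (abs(s) > 1e-12) {
    if (s < 0) -v else v
  } else {
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) -v else v
  }
}

#' Project observations onto eigenvector axes
#'
#' \eqn{Y = X A}: column j of the result is the j-th principal-component
#' score vector.
#'
#' @param x Standardized data (tibble or matrix).
#' @param vectors Eigenvector matrix (p x k).
#' @return n x k score matrix.
#' @export
project_scores <- function(x, vectors) {
  x <- if (is.data.frame(x)) as_feature_matrix(x) else as.matrix(x)
  vectors <- as.matrix(vectors)
  if (ncol(x) != nrow(vectors)) {
    stop("shape mismatch: ncol(x) must equal nrow(vectors).", call. = FALSE)
  }
  y <- x %*% vectors
  colnames(y) <- paste0("PC", seq_len(ncol(y)))
  y
}

#' Percent of total variance per component
#'
#' \eqn{100\,\lambda_j / \sum_k \lambda_k}; eigenvalues that are tiny and
#' negative (numerical noise) are clipped to zero first.
#'
#' @param values Eigenvalues.
#' @return Percentages summing to 100.
#' @export
variance_fractions <- function(values) {
  if (any(values < -1e-10 * max(abs(values), 1))) {
    stop("eigenvalues must be non-negative up to numerical noise.",
         call. = FALSE)
  }
  values <- pmax(values, 0)
  total <- sum(values)
  if (total <= 0) stop("all-zero eigenvalue spectrum.", call. = FALSE)
  100 * values / total
}

#' Principal component analysis of a standardized feature table
#'
#' Covariance matrix, eigendecomposition, scores and variance fractions in
#' one step. For n observations of centered data at most n - 1 eigenvalues
#' are meaningfully nonzero; `n_components` counts those above
#' `tol * max(eigenvalue)`.
#'
#' @param ds A standardized feature tibble (or matrix).
#' @param tol Relative eigenvalue tolerance defining a "zero" eigenvalue.
#' @return A `speckle_pca` object: eigenvalues, eigenvectors (columns,
#'   labelled by feature), scores, `variance_pct`, `n_components`,
#'   standardization `constants` (if the input carried them), column
#'   labels.
#' @export
#' @examples
#' x <- scale(matrix(rnorm(40), 10, 4))
#' x <- scale(x, center = FALSE, scale = apply(x, 2, sd))
#' p <- speckle_pca(x)
#' p$variance_pct
speckle_pca <- function(ds, tol = 1e-10) {
  C <- covariance_matrix(ds)
  e <- eigendecompose(C)
  x <- if (is.data.frame(ds)) as_feature_matrix(ds) else as.matrix(ds)
  scores <- project_scores(x, e$vectors)
  structure(
    list(
      values = e$values,
      vectors = e$vectors,
      scores = scores,
      variance_pct = variance_fractions(e$values),
      n_components = sum(e$values > tol * max(e$values)),
      constants = if (is.data.frame(ds)) feature_constants(ds) else NULL,
      columns = colnames(x)
    ),
    class = "speckle_pca"
  )
}

#' @export
print.speckle_pca <- function(x, ...) {
  cat("<speckle_pca>", length(x$values), "features,", nrow(x$scores),
      "observations,", x$n_components, "components above tolerance\n")
  cat("variance explained (%):",
      paste(signif(x$variance_pct[1:min(3, length(x$variance_pct))], 4),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @method tidy speckle_pca
#' @export
tidy.speckle_pca <- function(x, matrix = c("eigenvalues", "scores",
                                           "loadings"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble::tibble(
      PC = seq_along(x$values),
      eigenvalue = x$values,
      percent = x$variance_pct,
      cumulative = cumsum(x$variance_pct)
    ),
    scores = {
      s <- tibble::as_tibble(x$scores)
      dplyr::bind_cols(tibble::tibble(id = rownames(x$scores) %||%
                                        as.character(seq_len(nrow(s)))), s)
    },
    loadings = {
      l <- tibble::as_tibble(x$vectors, .name_repair = ~ paste0(
        "PC", seq_along(.x)))
      dplyr::bind_cols(tibble::tibble(feature = x$columns), l)
    }
  )
}

#' @method glance speckle_pca
#' @export
glance.speckle_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$values),
    n_obs = nrow(x$scores),
    n_components = x$n_components,
    pc1_percent = x$variance_pct[1]
  )
}

#' Serialize a PCA model to JSON
#'
#' Stores eigenvalues, variance fractions, the first `k` eigenvectors, the
#' standardization constants and column labels.
#'
#' @param x A `speckle_pca`.
#' @param path Output path.
#' @param k Number of eigenvectors to keep (default 3).
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(x, path, k = 3L) {
  k <- min(k, ncol(x$vectors))
  obj <- list(
    schema = "speckle_pca/1",
    eigenvalues = x$values,
    variance_pct = x$variance_pct,
    n_components = x$n_components,
    columns = x$columns,
    vectors = lapply(seq_len(k), function(j) unname(x$vectors[, j])),
    constants = if (!is.null(x$constants)) {
      list(mean = unname(x$constants$mean), sd = unname(x$constants$sd),
           columns = x$constants$columns)
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}
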