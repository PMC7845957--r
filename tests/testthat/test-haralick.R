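checkerboard_glcm <- function() {
  as_glcm(matrix(c(0, 0.5, 0.5, 0), 2, 2))
}

test_that("difference marginal pools probability by |i - j|", {
  single <- as_glcm(diag(c(0, 1, 0, 0)))
  expect_identical(diff_marginal(single), c(1, 0, 0, 0))

  expect_identical(diff_marginal(checkerboard_glcm()), c(0, 1))

  # symmetric four-cell GLCM of the 2x2 four-value image: all mass at k = 1
  p <- matrix(0, 4, 4)
  p[1, 2] <- p[2, 1] <- p[3, 4] <- p[4, 3] <- 0.25
  expect_identical(diff_marginal(as_glcm(p)), c(0, 1, 0, 0))
  expect_equal(sum(diff_marginal(as_glcm(p))), 1, tolerance = 1e-12)

  expect_error(diff_marginal(as_glcm(p / 2)), "normalized")
})

test_that("a perfectly homogeneous image gives the degenerate parameter values", {
  h <- haralick_features(as_glcm(diag(c(0, 0, 1, 0))))
  expect_equal(h$ASM, 1)
  expect_equal(h$CON, 0)
  expect_equal(h$IDM, 1)
  expect_equal(h$ENT, 0)
  expect_equal(h$DA, 0)
  expect_equal(h$DV, 0)
  expect_equal(h$DE, 0)
  expect_true(is.na(h$CORR))  # zero marginal spread: undefined, not 0
})

test_that("the two-level checkerboard matches its closed-form values", {
  h <- haralick_features(checkerboard_glcm())
  expect_equal(h$ASM, 0.5)
  expect_equal(h$CON, 1)
  expect_equal(h$IDM, 0.5)
  expect_equal(h$ENT, log(2))
  expect_equal(h$DA, 1)
  expect_equal(h$DV, 0)
  expect_equal(h$DE, 0)
  expect_equal(h$CORR, -1)
})

test_that("the uniform GLCM attains maximal entropy and minimal ASM", {
  for (L in c(4, 16)) {
    h <- haralick_features(as_glcm(matrix(1 / L^2, L, L)))
    expect_equal(h$ENT, 2 * log(L))
    expect_equal(h$ASM, 1 / L^2)
  }
})

test_that("contrast and difference average agree between direct and marginal routes", {
  set.seed(5)
  for (rep in 1:5) {
    L <- 8
    raw <- matrix(stats::runif(L * L), L, L)
    raw <- raw + t(raw)
    p <- raw / sum(raw)
    h <- haralick_features(as_glcm(p))
    i <- .row(dim(p)) - 1
    j <- .col(dim(p)) - 1
    expect_equal(h$CON, sum((i - j)^2 * p), tolerance = 1e-10)
    expect_equal(h$DA, sum(abs(i - j) * p), tolerance = 1e-10)
    # symmetric P: equal row and column means/spreads
    expect_equal(sum(i * p), sum(j * p), tolerance = 1e-12)
    expect_equal(sum((i - sum(i * p))^2 * p),
                 sum((j - sum(j * p))^2 * p), tolerance = 1e-12)
    expect_true(h$CORR >= -1 && h$CORR <= 1)
    expect_true(h$ASM < 1 && h$ENT > 0)
  }
})

test_that("the logarithm base only rescales the entropy features", {
  set.seed(8)
  raw <- matrix(stats::runif(16), 4, 4)
  p <- as_glcm((raw + t(raw)) / sum(raw + t(raw)))
  nat <- haralick_features(p)
  b2 <- haralick_features(p, log_base = 2)
  expect_equal(b2$ENT, nat$ENT / log(2))
  expect_equal(b2$DE, nat$DE / log(2))
  expect_equal(b2$CON, nat$CON)
})

test_that("texture parameters trend with roughness as rough images homogenize", {
  # mean parameter value per roughness over the fixed seed set (smooth-end
  # differences are below single-draw noise)
  per_seed <- lapply(101:105, function(s) {
    dplyr::bind_rows(lapply(default_sim(s)$image, function(im) {
      haralick_features(normalize_glcm(compute_glcm(im, glcm_spec(1, 0))))
    }))
  })
  for (p in c("ASM", "IDM")) {
    avg <- rowMeans(vapply(per_seed, `[[`, numeric(12), p))
    expect_false(is.unsorted(avg))          # non-decreasing in Ra
  }
  for (p in c("CON", "ENT", "DA", "DV", "DE")) {
    avg <- rowMeans(vapply(per_seed, `[[`, numeric(12), p))
    expect_false(is.unsorted(rev(avg)))     # non-increasing in Ra
  }
})
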