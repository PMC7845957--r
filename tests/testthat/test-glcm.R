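test_that("hand-enumerated co-occurrence counts are reproduced", {
  # constant 4x4 image: 12 horizontal ordered pairs, doubled by symmetry
  const <- matrix(5L, 4, 4)
  cm <- compute_glcm(const, glcm_spec(1, 0, levels = 8))
  expect_identical(cm$counts[6, 6], 24L)
  expect_identical(sum(cm$counts), 24L)

  # 2x2 image with four distinct values, horizontal, symmetric
  m <- matrix(c(0L, 1L, 2L, 3L), 2, 2, byrow = TRUE)
  cm2 <- compute_glcm(m, glcm_spec(1, 0, levels = 4))
  expect_identical(cm2$counts[1, 2], 1L)  # (0,1)
  expect_identical(cm2$counts[2, 1], 1L)
  expect_identical(cm2$counts[3, 4], 1L)  # (2,3)
  expect_identical(cm2$counts[4, 3], 1L)
  expect_identical(sum(cm2$counts), 4L)
})

test_that("symmetric counts equal their transpose for arbitrary images", {
  set.seed(1)
  for (theta in c(0, 45, 90, 135)) {
    px <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    cm <- compute_glcm(px, glcm_spec(2, theta, levels = 8))
    expect_identical(cm$counts, t(cm$counts))
  }
})

test_that("vectorized counting matches the brute-force pair enumeration oracle", {
  set.seed(42)
  for (rep in 1:4) {
    nr <- sample(5:16, 1)
    nc <- sample(5:16, 1)
    L <- sample(3:8, 1)
    px <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
    for (theta in c(0, 45, 90, 135)) {
      for (d in 1:3) {
        for (sym in c(TRUE, FALSE)) {
          got <- compute_glcm(px, glcm_spec(d, theta, L, sym))$counts
          want <- glcm_count_oracle(px, d, theta, L, sym)
          expect_identical(got, want)
        }
      }
    }
  }
})

test_that("normalization divides by the grand total and sums to one", {
  const <- matrix(5L, 4, 4)
  g <- normalize_glcm(compute_glcm(const, glcm_spec(1, 0, levels = 8)))
  expect_identical(g$probabilities[6, 6], 1)

  m <- matrix(c(0L, 1L, 2L, 3L), 2, 2, byrow = TRUE)
  g2 <- normalize_glcm(compute_glcm(m, glcm_spec(1, 0, levels = 4)))
  expect_identical(sort(g2$probabilities[g2$probabilities > 0]),
                   rep(0.25, 4))
  expect_equal(sum(g2$probabilities), 1, tolerance = 1e-12)

  zero <- structure(list(counts = matrix(0L, 4, 4),
                         spec = glcm_spec(1, 0, levels = 4)),
                    class = "glcm_counts")
  expect_error(normalize_glcm(zero), "all-zero")
})

test_that("every GLCM of a stack is normalized within 1e-12", {
  im <- default_sim()$image[[5]]
  st <- glcm_stack(im, distances = c(1, 5, 10))
  sums <- vapply(st$glcm, function(g) sum(g$probabilities), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the default stack has forty matrices matching individual computation", {
  set.seed(3)
  px <- matrix(sample(0:15, 40 * 40, replace = TRUE), 40, 40)
  st <- glcm_stack(px, levels = 16)
  expect_identical(nrow(st), 40L)
  expect_identical(nrow(glcm_stack(px, distances = 1, directions = 0,
                                   levels = 16)), 1L)
  k <- which(st$distance == 7 & st$direction == 135)
  direct <- normalize_glcm(compute_glcm(px, glcm_spec(7, 135, 16)))
  expect_identical(st$glcm[[k]]$probabilities, direct$probabilities)
})

test_that("invalid images and offsets are rejected", {
  px <- matrix(0:3, 2, 2)
  expect_error(compute_glcm(px, glcm_spec(2, 0, levels = 4)), "offset")
  expect_error(compute_glcm(px, glcm_spec(1, 0, levels = 2)),
               "\\[0, levels\\)")
  expect_error(glcm_spec(0, 0), ">= 1")
  expect_error(glcm_spec(1, 30), "direction")
})

test_that("co-occurrence mass concentrates toward the diagonal as Ra grows", {
  near_diag_mass <- function(im) {
    p <- normalize_glcm(compute_glcm(im, glcm_spec(1, 0)))$probabilities
    sum(p[abs(.row(dim(p)) - .col(dim(p))) <= 2])
  }
  # averaged over the fixed seed set: at the smooth end the concentration
  # differences are smaller than the single-draw noise
  mass <- vapply(101:105, function(s) {
    vapply(default_sim(s)$image, near_diag_mass, numeric(1))
  }, numeric(12))
  expect_false(is.unsorted(rowMeans(mass)))
  # within one dataset the trend over the well-separated roughness values
  # (every other grid point) is strictly monotone
  single <- vapply(default_sim()$image, near_diag_mass, numeric(1))
  expect_false(is.unsorted(single[seq(1, 12, by = 2)], strictly = TRUE))
})

test_that("a GLCM exports to a labelled dense CSV", {
  m <- matrix(c(0L, 1L, 2L, 3L), 2, 2, byrow = TRUE)
  g <- normalize_glcm(compute_glcm(m, glcm_spec(1, 0, levels = 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_glcm_csv(g, path)
  back <- utils::read.csv(path)
  expect_identical(dim(back), c(4L, 5L))
  expect_equal(back$X1[1], 0.25)
})
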