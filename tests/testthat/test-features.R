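test_that("feature-count arithmetic holds for arbitrary configurations", {
  ds <- small_sim()[1:2, ]
  # 1 parameter, 1 direction, 10 distances -> 10 raw + 1 y0 = 11 features
  f <- speckle_features(ds, distances = 1:10, directions = 0,
                        parameters = "CON")
  expect_identical(dim(f), c(2L, 2L + 11L))
  expect_identical(
    names(f)[3:13],
    c(paste0("CON_0_d", 1:10), "CON_0_y0"))

  # p = #params x (#dirs x #dists + #dirs)
  f2 <- speckle_features(ds, distances = 1:5,
                         directions = c(0, 90),
                         parameters = c("ASM", "ENT", "DA"))
  expect_identical(length(feature_cols(f2)), 3L * (2L * 5L + 2L))
})

test_that("reciprocal alignment inverts the named blocks and is an involution", {
  ds <- tibble::tibble(id = c("a", "b"),
                       ASM_0_d1 = c(0.5, 0.25),
                       CON_0_d1 = c(3, 4),
                       IDM_0_y0 = c(2, 4))
  r <- reciprocal_features(ds)
  expect_equal(r$ASM_0_d1, c(2, 4))
  expect_equal(r$IDM_0_y0, c(0.5, 0.25))
  expect_equal(r$CON_0_d1, c(3, 4))  # untouched block
  expect_equal(reciprocal_features(r), ds)

  ds$ASM_0_d1[1] <- 1e-15
  expect_error(reciprocal_features(ds), "ASM_0_d1")
})

test_that("after alignment every parameter trends the same way with roughness", {
  feats <- speckle_features(default_sim(), distances = 1:10,
                            directions = 0,
                            parameters = c("ASM", "CON"))
  feats <- reciprocal_features(feats)
  rho_asm <- cor(feats$ra_nm, feats$ASM_0_d1, method = "spearman")
  rho_con <- cor(feats$ra_nm, feats$CON_0_d1, method = "spearman")
  expect_identical(sign(rho_asm), sign(rho_con))
})

test_that("pairwise correlation reproduces hand-computed values", {
  ds <- tibble::tibble(A_x = c(1, 2, 3), B_x = c(2, 4, 6),
                       C_x = c(-1, -2, -3))
  r <- feature_correlation(ds)
  expect_identical(unname(diag(r)), rep(1, 3))
  expect_equal(r["A_x", "B_x"], 1)
  expect_equal(r["A_x", "C_x"], -1)

  expect_error(feature_correlation(ds[1:2, ]), "at least 3")
  ds$B_x <- c(5, 5, 5)
  expect_error(feature_correlation(ds), "B_x")
})

test_that("explicit selection drops whole blocks; threshold zero drops nothing", {
  ds <- small_sim()
  feats <- speckle_features(ds)
  expect_identical(length(feature_cols(feats)), 352L)
  sel <- select_features(feats, mode = "explicit", drop_blocks = "CORR")
  expect_identical(length(feature_cols(sel$data)), 308L)
  expect_identical(sel$report$n_cols,
                   rep(44L, 8))
  expect_true(sel$report$dropped[sel$report$block == "CORR"])

  r <- feature_correlation(feats)
  sel0 <- select_features(feats, r, threshold = 0, mode = "block")
  expect_identical(length(feature_cols(sel0$data)), 352L)
})

test_that("block-mode screening drops an uninformative noise block", {
  ds <- small_sim()
  feats <- speckle_features(ds)
  # replace the CORR block by pure noise, unrelated to roughness
  set.seed(31)
  corr_cols <- feature_cols(feats)[feature_block(feature_cols(feats)) ==
                                     "CORR"]
  for (cl in corr_cols) feats[[cl]] <- stats::rnorm(nrow(feats))
  sel <- select_features(feats, threshold = 0.8, mode = "block")
  expect_identical(length(feature_cols(sel$data)), 308L)
  rep_corr <- sel$report[sel$report$block == "CORR", ]
  expect_true(rep_corr$dropped)
  expect_lt(rep_corr$score, 0.8)
  expect_true(all(sel$report$score[!sel$report$dropped] >= 0.8))
})

test_that("standardization yields exact zero mean and unit variance", {
  ds <- tibble::tibble(F_x = c(1, 2, 3), G_x = c(10, 30, 20))
  std <- standardize_features(ds)
  expect_equal(std$F_x, c(-1, 0, 1))
  for (cl in names(std)) {
    expect_equal(mean(std[[cl]]), 0, tolerance = 1e-10)
    expect_equal(stats::var(std[[cl]]), 1, tolerance = 1e-10)
  }
  # idempotent and replayable with stored constants
  std2 <- standardize_features(std)
  replay <- standardize_features(ds, feature_constants(std))
  for (cl in names(std)) {
    expect_equal(std2[[cl]], std[[cl]], tolerance = 1e-10)
    expect_equal(replay[[cl]], std[[cl]])
  }

  expect_error(standardize_features(tibble::tibble(F_x = c(2, 2, 2))),
               "F_x")
})

test_that("feature assembly is deterministic down to the serialized CSV", {
  ds <- small_sim()[1:3, ]
  f1 <- speckle_features(ds, distances = 1:5, directions = c(0, 90),
                         parameters = c("ASM", "CON"))
  f2 <- speckle_features(ds, distances = 1:5, directions = c(0, 90),
                         parameters = c("ASM", "CON"))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(f1, p1)
  write_features_csv(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("correlation of standardized data equals its covariance matrix", {
  ds <- small_sim()
  feats <- speckle_features(ds, distances = 1:6, directions = 0,
                            parameters = c("CON", "ENT"))
  std <- standardize_features(feats)
  expect_equal(unclass(feature_correlation(feats)),
               unclass(covariance_matrix(std)), tolerance = 1e-10)
})
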