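test_that("a flat surface without aperture or diffuse screen images to a single bright spot", {
  h <- generate_surface(surface_spec(1e-6, grid_size = c(64, 64)), seed = 1)
  cfg <- optics_config(spot_diameter = 1e6, diffuse_phase = FALSE)
  # scale so the specular peak (total energy in the zero-frequency bin)
  # maps to gray 250; everything else is sidelobe noise orders below
  img <- render_speckle(h, cfg, seed = 1, intensity_scale = 250 / 64^2)
  px <- img$pixels
  centre <- c(33L, 33L)  # zero-frequency bin after centring, n/2 + 1
  expect_identical(which(px == max(px), arr.ind = TRUE)[1, ],
                   c(row = centre[1], col = centre[2]))
  expect_identical(px[33, 33], 250L)
  expect_identical(sum(px > 0), 1L)
})

test_that("rendering is deterministic for fixed seed", {
  h <- generate_surface(surface_spec(800, grid_size = c(64, 64)), seed = 2)
  cfg <- optics_config()
  i1 <- render_speckle(h, cfg, seed = 9)
  i2 <- render_speckle(h, cfg, seed = 9)
  i3 <- render_speckle(h, cfg, seed = 10)
  expect_identical(i1$pixels, i2$pixels)
  expect_false(identical(i1$pixels, i3$pixels))
  expect_true(all(i1$pixels >= 0 & i1$pixels <= 255))
})

test_that("speckle contrast is near unity for roughness far beyond a quarter wavelength", {
  cfg <- optics_config(spot_diameter = 2)
  contrasts <- vapply(1:20, function(s) {
    h <- generate_surface(surface_spec(1000, grid_size = c(160, 160)),
                          seed = s)
    speckle_contrast(render_speckle(h, cfg, seed = 1000 + s))
  }, numeric(1))
  expect_equal(mean(contrasts), 1, tolerance = 0.1)
})

test_that("speckle grain size scales inversely with the illuminated spot diameter", {
  h <- generate_surface(surface_spec(500, grid_size = c(256, 256)),
                        seed = 7)
  g_narrow <- speckle_grain_size(
    render_speckle(h, optics_config(spot_diameter = 1), seed = 3))
  g_wide <- speckle_grain_size(
    render_speckle(h, optics_config(spot_diameter = 2), seed = 3))
  expect_gt(g_narrow, g_wide)
  expect_equal(g_narrow / g_wide, 2, tolerance = 0.25)
})

test_that("simulated datasets are labelled, sized and reproducible", {
  ds <- default_sim()
  expect_identical(nrow(ds), 12L)
  expect_identical(dim(ds$image[[1]]$pixels), c(400L, 400L))
  expect_identical(ds$ra_nm, default_ra_grid())

  small1 <- simulate_speckle_dataset(c(50, 500), seed = 5,
                                     grid_size = c(48, 48))
  small2 <- simulate_speckle_dataset(c(50, 500), seed = 5,
                                     grid_size = c(48, 48))
  expect_identical(lapply(small1$image, `[[`, "pixels"),
                   lapply(small2$image, `[[`, "pixels"))
  expect_error(simulate_speckle_dataset(numeric(0)), "non-empty")
  expect_error(simulate_speckle_dataset(c(100, -5)), "positive")
})

test_that("mean gray level decreases with roughness, endpoints included", {
  ds <- default_sim()
  mg <- vapply(ds$image, function(im) mean(im$pixels), numeric(1))
  expect_lt(mg[12], mg[1])          # Ra 2500 nm darker than Ra 10 nm
  expect_false(is.unsorted(rev(mg)))  # non-increasing across the grid
})

test_that("mean bright-patch area grows with roughness over a fixed seed set", {
  areas <- vapply(101:105, function(s) {
    ds <- default_sim(seed = s)
    vapply(ds$image, function(im) bright_patch_stats(im)$mean_area,
           numeric(1))
  }, numeric(12))
  expect_false(is.unsorted(rowMeans(areas)))
})
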