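# Literal pair-enumeration oracle for co-occurrence counting: a double loop
# over every pixel and the direction offset, nothing shared with the
# vectorized implementation.
glcm_count_oracle <- function(px, d, theta, L, symmetric = TRUE) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0L, L, L)
  offsets <- if (symmetric) list(off, -off) else list(off)
  for (o in offsets) {
    for (r in seq_len(nrow(px))) {
      for (cl in seq_len(ncol(px))) {
        r2 <- r + o[1]
        c2 <- cl + o[2]
        if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
          i <- px[r, cl] + 1L
          j <- px[r2, c2] + 1L
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# Eigenvalues via the characteristic polynomial: det(C - lambda I) = 0,
# solved by polynomial root finding. Independent of eigen().
eigenvalues_charpoly_oracle <- function(C) {
  coefs <- pracma::charpoly(C)      # monic, highest degree first
  roots <- polyroot(rev(coefs))
  sort(Re(roots), decreasing = TRUE)
}

# A normalized GLCM object wrapped around a bare probability matrix.
as_glcm <- function(p, distance = 1L, direction = 0) {
  structure(
    list(probabilities = p,
         spec = glcm_spec(distance, direction, levels = ncol(p))),
    class = "glcm"
  )
}

# Shared simulated dataset at the default study conditions (12 images,
# Ra 10..2500 nm, 400x400 px), generated once per test run.
default_sim_env <- new.env(parent = emptyenv())
default_sim <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(default_sim_env[[key]])) {
    default_sim_env[[key]] <- simulate_speckle_dataset(seed = seed)
  }
  default_sim_env[[key]]
}

trained_pipeline <- function(seed = 42) {
  key <- paste0("p", seed)
  if (is.null(default_sim_env[[key]])) {
    default_sim_env[[key]] <-
      train_roughness_pipeline(default_sim(seed))
  }
  default_sim_env[[key]]
}

# A quick low-resolution labelled dataset for plumbing tests.
small_sim <- function(ra = c(20, 60, 180, 600, 2000, 2400), seed = 7) {
  simulate_speckle_dataset(ra, seed = seed, grid_size = c(96L, 96L),
                           cfg = optics_config(spot_diameter = 1))
}
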