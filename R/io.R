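#' Read an 8-bit grayscale speckle image
#'
#' Reads PNG or TIFF. RGB input is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) with a warning; bit depths above 8 are
#' an error unless `convert = TRUE`, which rescales to 0..255.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @param roi Optional `c(rows, cols)`: centred region-of-interest crop
#'   applied after reading (the conventional analysis window is 400 x 400).
#' @param convert Allow depth conversion of non-8-bit input.
#' @return A `speckle_image` with `ra_nm = NA` (unlabelled).
#' @export
read_speckle_image <- function(path, roi = NULL, convert = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) {
      warning("RGB input converted to luminance.", call. = FALSE)
      raw <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  px <- raw * 255
  if (max(abs(px - round(px))) > 1e-6) {
    if (!convert) {
      stop("image is not 8-bit; pass `convert = TRUE` to rescale.",
           call. = FALSE)
    }
    px <- px / max(px) * 255
  }
  px <- round_half_up(px)
  px[px > 255] <- 255
  storage.mode(px) <- "integer"
  if (!is.null(roi)) px <- centered_crop(px, roi)
  structure(
    list(pixels = px, ra_nm = NA_real_, seed = NA_integer_,
         intensity_scale = NA_real_, spec = NULL, cfg = NULL, path = path),
    class = "speckle_image"
  )
}

centered_crop <- function(px, roi) {
  roi <- as.integer(roi)
  if (length(roi) != 2L || any(roi < 1L) || any(roi > dim(px))) {
    stop("`roi` must be two integers within the image extent.",
         call. = FALSE)
  }
  r0 <- floor((nrow(px) - roi[1]) / 2)
  c0 <- floor((ncol(px) - roi[2]) / 2)
  px[r0 + seq_len(roi[1]), c0 + seq_len(roi[2]), drop = FALSE]
}

#' Write a speckle image as 8-bit grayscale PNG
#'
#' Round-trips bit-exactly through [read_speckle_image()].
#'
#' @param image A `speckle_image` or integer matrix (0..255).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_speckle_image <- function(image, path) {
  px <- as_pixel_matrix(image)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Writes one 8-bit grayscale PNG per roughness value plus a sidecar
#' `labels.csv` with columns `image_path`, `ra_nm`, `seed`.
#'
#' @inheritParams simulate_speckle_dataset
#' @param out_dir Output directory (created if missing).
#' @return The labels tibble, invisibly.
#' @export
simulate_to_dir <- function(out_dir, ra_nm = default_ra_grid(),
                            cfg = optics_config(), seed = 1,
                            correlation_length = 100,
                            grid_size = c(400L, 400L), pixel_pitch = 25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_speckle_dataset(ra_nm, cfg, seed, correlation_length,
                                 grid_size, pixel_pitch)
  paths <- file.path(out_dir, paste0(ds$id, ".png"))
  purrr::walk2(ds$image, paths, write_speckle_image)
  labels <- tibble::tibble(image_path = basename(paths), ra_nm = ds$ra_nm,
                           seed = ds$seed)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"),
                   progress = FALSE)
  invisible(labels)
}

#' Read a directory written by [simulate_to_dir()]
#'
#' @param dir Directory containing images and a `labels.csv` sidecar
#'   (optional; without it the images are unlabelled).
#' @param roi Optional centred crop, passed to [read_speckle_image()].
#' @return An image tibble (`id`, `ra_nm` if labelled, `image`).
#' @export
read_image_dir <- function(dir, roi = NULL) {
  labels_path <- file.path(dir, "labels.csv")
  if (file.exists(labels_path)) {
    labels <- readr::read_csv(labels_path, show_col_types = FALSE,
                              progress = FALSE)
    paths <- file.path(dir, labels$image_path)
    tibble::tibble(
      id = tools::file_path_sans_ext(basename(paths)),
      ra_nm = labels$ra_nm,
      image = lapply(paths, read_speckle_image, roi = roi)
    )
  } else {
    paths <- list.files(dir, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(paths)) stop("no images found in ", dir, call. = FALSE)
    tibble::tibble(
      id = tools::file_path_sans_ext(basename(paths)),
      image = lapply(paths, read_speckle_image, roi = roi)
    )
  }
}
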