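#' Read a grayscale (multi-page) TIFF
#'
#' Pages are returned as numeric matrices holding the stored integer sample
#' values (no 0-1 rescaling). Multi-page files - e.g. the four spectral
#' channels of a 2PM detector - yield one matrix per page, in page order.
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF.
#' @return List of numeric matrices.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "pgbm3d_input_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        abort(sprintf("page %d of %s is not grayscale (%d channels)",
                      i, path, dim(p)[3L]), class = "pgbm3d_format_error")
      p <- p[, , 1L]
    }
    storage.mode(p) <- "double"
    p
  })
}

#' Write images to a grayscale TIFF
#'
#' Values are rounded to integers and clipped to the bit depth's range;
#' the number of clipped pixels is reported through a warning and returned.
#'
#' @param path Output path.
#' @param images A matrix or list of matrices (written as pages).
#' @param bit_depth 8 or 16.
#' @return Invisibly, the number of clipped pixels.
#' @export
write_tiff <- function(path, images, bit_depth = 16) {
  if (!bit_depth %in% c(8, 16))
    abort("`bit_depth` must be 8 or 16", class = "pgbm3d_input_error")
  if (is.matrix(images)) images <- list(images)
  purrr::walk(images, assert_image, arg = "image")
  top <- 2^bit_depth - 1
  clipped <- 0L
  pages <- lapply(images, function(img) {
    v <- round(img)
    clipped <<- clipped + sum(v < 0 | v > top)
    pmin(pmax(v, 0), top) / top
  })
  if (clipped > 0L)
    warning(sprintf("%d pixel(s) outside the %d-bit range were clipped",
                    clipped, bit_depth), call. = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(clipped)
}

#' Load a calibration series from a TIFF directory plus a JSON manifest
#'
#' The manifest maps file names to excitation levels; files at level 0 are
#' dark frames, all others flat fields (sorted by level). Multi-page files
#' contribute every page at their file's level.
#'
#' @param dir Directory holding the TIFF files.
#' @param manifest Path to a JSON object `{ "file.tif": level, ... }`.
#' @return A [calibration_series()].
#' @export
read_calibration_dir <- function(dir, manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (length(man) == 0L)
    abort("empty calibration manifest", class = "pgbm3d_input_error")
  lv <- as.numeric(man)
  files <- file.path(dir, names(man))
  imgs <- lapply(files, read_tiff)
  n_pages <- lengths(imgs)
  all_imgs <- unlist(imgs, recursive = FALSE)
  all_lv <- rep(lv, n_pages)
  is_dark <- all_lv == 0
  ord <- order(all_lv[!is_dark])
  calibration_series(all_imgs[!is_dark][ord],
                     levels = all_lv[!is_dark][ord],
                     darks = all_imgs[is_dark])
}
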