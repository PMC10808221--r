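#' Read a single-channel grayscale TIFF
#'
#' Loads an 8/16-bit integer or 32-bit float grayscale TIFF losslessly. The
#' physical scale is taken from the `pixel_size_nm` argument, not from TIFF
#' tags (the acquisition pixel size is fixed by the analysis parameters).
#' RGB and multi-page TIFFs are rejected.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_nm physical pixel size (nm).
#' @param channel optional channel label.
#' @return A [pixel_image()] with intensities on their native integer scale.
#' @export
read_image <- function(path, pixel_size_nm = 20, channel = NA_character_) {
  if (!file.exists(path))
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  img <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                  error = function(e)
                    stop(sprintf("unreadable TIFF '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(img) != 1)
    stop(sprintf("multi-page TIFF not supported: '%s'", path), call. = FALSE)
  img <- img[[1]]
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1)
      stop(sprintf("RGB/multi-sample TIFF not supported: '%s'", path),
           call. = FALSE)
    img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  pixel_image(img, pixel_size_nm, channel)
}

#' Write a pixel image as 16-bit grayscale TIFF
#'
#' Values are rounded and clipped to `[0, 65535]`; the written file is
#' deterministic for identical inputs.
#'
#' @param img a [pixel_image()] or matrix.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  img <- as_pixel_image(img)
  v <- pmin(pmax(round(img$values), 0), 65535)
  ok <- tryCatch({
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop(sprintf("cannot write TIFF '%s'", path), call. = FALSE)
  invisible(path)
}

# locale-independent CSV writer with stable column order; doubles are
# written with 17 significant digits so re-reading reproduces them exactly
write_table_csv <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
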