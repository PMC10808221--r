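#' Pixel image with physical scale
#'
#' Lightweight container for a single-channel 2D intensity grid together with
#' its physical pixel size. Every geometric parameter in the analysis (ROI
#' diameters, linescan lengths, distance thresholds) converts between pixels
#' and nanometers through `pixel_size_nm`.
#'
#' The coordinate convention is matrix-style: `values[row, col]`, with the
#' physical position of the center of pixel `(row, col)` at
#' `x = (col - 0.5) * pixel_size_nm`, `y = (row - 0.5) * pixel_size_nm`.
#'
#' @param values numeric matrix of non-negative, finite intensities (a.u.).
#' @param pixel_size_nm physical edge length of one pixel in nanometers.
#' @param channel optional channel label (e.g. `"A"`, `"B"`, an antibody name).
#' @return An object of class `pixel_image`: a list with elements `values`,
#'   `pixel_size_nm` and `channel`.
#' @examples
#' img <- pixel_image(matrix(0, 64, 64), pixel_size_nm = 20, channel = "A")
#' dim(img)
#' @export
pixel_image <- function(values, pixel_size_nm = 20, channel = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, pixel_size_nm = as.numeric(pixel_size_nm),
         channel = as.character(channel)),
    class = "pixel_image"
  )
}

#' @export
dim.pixel_image <- function(x) dim(x$values)

#' @export
print.pixel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<pixel_image> %d x %d px (%.2f x %.2f um), %.3g nm/px, channel %s\n",
    d[1], d[2], d[1] * x$pixel_size_nm / 1000, d[2] * x$pixel_size_nm / 1000,
    x$pixel_size_nm, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# coerce a matrix or pixel_image to pixel_image, inheriting defaults
as_pixel_image <- function(x, pixel_size_nm = 20, channel = NA_character_) {
  if (inherits(x, "pixel_image")) return(x)
  pixel_image(x, pixel_size_nm = pixel_size_nm, channel = channel)
}

# field dimensions in nm
image_extent_nm <- function(img) {
  d <- dim(img$values)
  c(height_nm = d[1] * img$pixel_size_nm, width_nm = d[2] * img$pixel_size_nm)
}
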