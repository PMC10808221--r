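#' Digital-disk ROI offsets
#'
#' Integer pixel offsets of the digital disk of diameter `diameter_px`
#' centered on one pixel: offsets with `dx^2 + dy^2 <= ((d - 1) / 2)^2`.
#' For the standard 5-pixel (100 nm at 20 nm/px) ROI this is the 13-pixel
#' digital disk (radius 2 px about the central pixel), the discrete
#' circular ROI convention of common image-analysis tools.
#'
#' @param diameter_px ROI diameter in pixels (odd).
#' @return Two-column integer matrix of `(drow, dcol)` offsets.
#' @export
roi_disk_offsets <- function(diameter_px = 5) {
  r <- (diameter_px - 1) / 2
  ri <- floor(r)
  g <- expand.grid(drow = -ri:ri, dcol = -ri:ri)
  g <- g[g$drow^2 + g$dcol^2 <= r^2, , drop = FALSE]
  as.matrix(g[order(g$drow, g$dcol), , drop = FALSE])
}

roi_footprint <- function(img, pos, diameter_px) {
  off <- roi_disk_offsets(diameter_px)
  rows <- pos[1] + off[, 1]
  cols <- pos[2] + off[, 2]
  d <- dim(img$values)
  if (any(rows < 1 | rows > d[1] | cols < 1 | cols > d[2]))
    stop("ROI footprint crosses the image border", call. = FALSE)
  cbind(row = rows, col = cols)
}

#' Mean intensity in a circular ROI
#'
#' Mean of the pixel values in the digital disk centered on the maximum
#' position (see [roi_disk_offsets()]). The standard measurement ROI is
#' 5 pixels in diameter (100 nm at 20 nm/px), a 13-pixel digital disk.
#'
#' @param img [pixel_image()] or matrix.
#' @param pos integer `(row, col)` of the central pixel.
#' @param diameter_px ROI diameter in pixels.
#' @return Mean intensity (a.u.). Errors if the footprint crosses the image
#'   border (callers must pre-filter border maxima).
#' @export
roi_mean <- function(img, pos, diameter_px = 5) {
  img <- as_pixel_image(img)
  fp <- roi_footprint(img, pos, diameter_px)
  mean(img$values[fp])
}

#' Background correction
#'
#' Subtracts a background level (measured with [roi_mean()] at an off-sheet
#' position, or known from simulation) from a raw ROI intensity. Negative
#' results are retained, not clipped: the downstream 2 a.u. noise gate is
#' the place where near-zero intensities are handled.
#'
#' @param raw raw intensity (a.u.).
#' @param bg background intensity (a.u.).
#' @return `raw - bg`.
#' @export
background_correct <- function(raw, bg) raw - bg

#' Subpixel fluorescence mass center
#'
#' Intensity-weighted centroid of the ROI footprint, using
#' background-corrected intensities clipped at zero as weights, converted to
#' physical coordinates. This is the subpixel position used for
#' cluster-to-cluster distance measurements. If the total weight is zero the
#' center of the central pixel is returned.
#'
#' @param img [pixel_image()] or matrix.
#' @param pos integer `(row, col)` of the maximum.
#' @param diameter_px ROI diameter in pixels.
#' @param background background level subtracted before weighting (a.u.).
#' @return Named numeric `c(x_nm, y_nm)`.
#' @export
mass_center <- function(img, pos, diameter_px = 5, background = 0) {
  img <- as_pixel_image(img)
  fp <- roi_footprint(img, pos, diameter_px)
  w <- pmax(img$values[fp] - background, 0)
  p <- img$pixel_size_nm
  if (sum(w) == 0)
    return(c(x_nm = (pos[2] - 0.5) * p, y_nm = (pos[1] - 0.5) * p))
  c(x_nm = sum(w * (fp[, "col"] - 0.5)) / sum(w) * p,
    y_nm = sum(w * (fp[, "row"] - 0.5)) / sum(w) * p)
}

#' Horizontal and vertical linescan profiles
#'
#' Extracts the two intensity profiles used for cluster classification: a
#' horizontal and a vertical linescan of `length_px` samples, each sample
#' the mean across `width_px` perpendicular pixels, centered on the maximum.
#'
#' @param img [pixel_image()] or matrix.
#' @param pos integer `(row, col)` of the maximum.
#' @param length_px odd scan length in pixels (default 31).
#' @param width_px odd scan width in pixels (default 3).
#' @return List with numeric vectors `horizontal` and `vertical`, or `NULL`
#'   if the window does not fit inside the image (border case).
#' @export
linescan_profiles <- function(img, pos, length_px = 31, width_px = 3) {
  img <- as_pixel_image(img)
  stopifnot(length_px %% 2 == 1, width_px %% 2 == 1)
  hl <- (length_px - 1L) / 2L
  hw <- (width_px - 1L) / 2L
  d <- dim(img$values)
  if (pos[1] - max(hl, hw) < 1 || pos[1] + max(hl, hw) > d[1] ||
      pos[2] - max(hl, hw) < 1 || pos[2] + max(hl, hw) > d[2])
    return(NULL)
  rows_h <- (pos[1] - hw):(pos[1] + hw)
  cols_h <- (pos[2] - hl):(pos[2] + hl)
  horizontal <- colMeans(img$values[rows_h, cols_h, drop = FALSE])
  rows_v <- (pos[1] - hl):(pos[1] + hl)
  cols_v <- (pos[2] - hw):(pos[2] + hw)
  vertical <- rowMeans(img$values[rows_v, cols_v, drop = FALSE])
  list(horizontal = unname(horizontal), vertical = unname(vertical))
}

#' Fit a Gaussian to a linescan profile
#'
#' Bounded least-squares fit of `b + A * exp(-(x - mu)^2 / (2 * sigma^2))`
#' to a profile sampled at `x = 0, 1, ..., n-1`, with `A >= 0`,
#' `sigma` in `(0.5, 15]` px and `mu` in `[0, n-1]`. The additive offset
#' `b` absorbs nonzero membrane background, which would otherwise bias
#' `sigma`. The fit quality is `r2 = 1 - SSres/SStot` with `SStot` about the
#' profile mean. Degenerate (zero-variance) profiles and non-convergence
#' return `r2 = -Inf` as a sentinel rather than raising an error, so such
#' maxima simply never classify as clusters.
#'
#' @param profile numeric vector of finite intensities (standard length 31).
#' @param orientation label stored with the fit.
#' @return An object of class `linescan_fit`: list with `A`, `mu`, `sigma`,
#'   `b`, `r2`, `fitted`, `profile`, `orientation`, `converged`.
#' @export
fit_gaussian_profile <- function(profile,
                                 orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(profile) || !all(is.finite(profile)))
    stop("`profile` must be a finite numeric vector", call. = FALSE)
  n <- length(profile)
  x <- seq_len(n) - 1
  sentinel <- function() {
    structure(list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
                   b = NA_real_, r2 = -Inf, fitted = rep(NA_real_, n),
                   profile = profile, orientation = orientation,
                   converged = FALSE),
              class = "linescan_fit")
  }
  sstot <- sum((profile - mean(profile))^2)
  if (sstot == 0) return(sentinel())

  start <- list(A = max(profile) - min(profile),
                mu = x[which.max(profile)], sigma = 2, b = min(profile))
  if (start$A <= 0) start$A <- 1e-6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = data.frame(x = x, y = profile),
      start = start,
      lower = c(A = 0, mu = 0, sigma = 0.5 + 1e-9, b = -Inf),
      upper = c(A = Inf, mu = n - 1, sigma = 15, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(sentinel())
  cf <- stats::coef(fit)
  fitted_vals <- cf[["b"]] + cf[["A"]] *
    exp(-(x - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  r2 <- 1 - sum((profile - fitted_vals)^2) / sstot
  structure(list(A = cf[["A"]], mu = cf[["mu"]], sigma = cf[["sigma"]],
                 b = cf[["b"]], r2 = r2, fitted = fitted_vals,
                 profile = profile, orientation = orientation,
                 converged = TRUE),
            class = "linescan_fit")
}

#' @export
print.linescan_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<linescan_fit> %s: no fit (degenerate or non-convergent)\n",
                x$orientation))
    return(invisible(x))
  }
  cat(sprintf(
    "<linescan_fit> %s: A = %.4g, mu = %.3f px, sigma = %.3f px, b = %.4g, R^2 = %.4f\n",
    x$orientation, x$A, x$mu, x$sigma, x$b, x$r2))
  invisible(x)
}

#' @export
coef.linescan_fit <- function(object, ...)
  c(A = object$A, mu = object$mu, sigma = object$sigma, b = object$b)

#' @export
predict.linescan_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq_along(object$profile) - 1 else
    as.numeric(newdata)
  object$b + object$A * exp(-(x - object$mu)^2 / (2 * object$sigma^2))
}

#' @export
residuals.linescan_fit <- function(object, ...)
  object$profile - object$fitted

#' Full width at half maximum of a fitted profile
#'
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma * pixel_size_nm`, the size measure
#' assigned to each cluster.
#'
#' @param fit a `linescan_fit`, or a numeric `sigma` in pixels.
#' @param pixel_size_nm physical pixel size (nm).
#' @return FWHM in nm.
#' @export
fwhm_nm <- function(fit, pixel_size_nm = 20) {
  sigma <- if (inherits(fit, "linescan_fit")) fit$sigma else as.numeric(fit)
  2 * sqrt(2 * log(2)) * sigma * pixel_size_nm
}

#' Cluster classification rule
#'
#' A maximum is rated a cluster iff its best linescan fit has
#' `r2 > r2_threshold` (strict) and a centered peak,
#' `|mu - (length-1)/2| <= center_window_px` (the central 10 pixels of a
#' 31-pixel profile), and it is not border-flagged.
#'
#' @param r2 fit quality of the best fit.
#' @param mu fitted peak position (px index) of the best fit.
#' @param border_flag logical; `TRUE` forces `FALSE`.
#' @param r2_threshold quality threshold (default 0.8).
#' @param center_px profile center index (default 15 for a 31-px profile).
#' @param center_window_px allowed |mu - center| (default 5 px).
#' @return Logical.
#' @export
classify_cluster <- function(r2, mu, border_flag = FALSE, r2_threshold = 0.8,
                             center_px = 15, center_window_px = 5) {
  ok <- !border_flag & is.finite(r2) & r2 > r2_threshold &
    is.finite(mu) & abs(mu - center_px) <= center_window_px
  ok & TRUE
}

#' Measure and classify all maxima of one channel
#'
#' For every detected maximum: measures the background-corrected ROI mean in
#' its own channel and at the same position in the other channel, the
#' subpixel fluorescence mass center, and the horizontal and vertical
#' linescan Gaussian fits; selects the best fit (higher `r2`, ties going to
#' horizontal) and classifies the maximum as a cluster.
#'
#' @param img_self [pixel_image()] the maxima were detected in (blurred,
#'   crosstalk-corrected as configured).
#' @param img_other matching image of the other channel (same preprocessing),
#'   or `NULL` to skip cross-channel intensities.
#' @param maxima a `maxima_list` from [find_maxima()].
#' @param params an [analysis_params()] list.
#' @param background_self,background_other background levels (a.u.) to
#'   subtract, e.g. from [roi_mean()] at the configured off-sheet position.
#' @return Data frame of class `maxima_table`, one row per maximum:
#'   `row`, `col`, `x_nm`, `y_nm`, `intensity_self`, `intensity_other`,
#'   `A`, `mu_px`, `sigma_px`, `r2`, `orientation`, `fwhm_nm`,
#'   `is_cluster`, `border_flag`.
#' @export
measure_maxima <- function(img_self, img_other, maxima,
                           params = analysis_params(),
                           background_self = 0, background_other = 0) {
  img_self <- as_pixel_image(img_self)
  if (!is.null(img_other)) img_other <- as_pixel_image(img_other)
  n <- nrow(maxima)
  p <- img_self$pixel_size_nm
  center_px <- (params$linescan_length_px - 1) / 2
  out <- data.frame(
    row = maxima$row, col = maxima$col,
    x_nm = rep(NA_real_, n), y_nm = rep(NA_real_, n),
    intensity_self = rep(NA_real_, n), intensity_other = rep(NA_real_, n),
    A = rep(NA_real_, n), mu_px = rep(NA_real_, n),
    sigma_px = rep(NA_real_, n), r2 = rep(-Inf, n),
    orientation = rep(NA_character_, n), fwhm_nm = rep(NA_real_, n),
    is_cluster = rep(FALSE, n), border_flag = maxima$border_flag
  )
  d <- dim(img_self$values)
  roi_r <- floor(params$roi_diameter_px / 2)
  for (k in seq_len(n)) {
    pos <- c(maxima$row[k], maxima$col[k])
    roi_fits <- pos[1] - roi_r >= 1 && pos[1] + roi_r <= d[1] &&
      pos[2] - roi_r >= 1 && pos[2] + roi_r <= d[2]
    if (roi_fits) {
      raw_self <- roi_mean(img_self, pos, params$roi_diameter_px)
      out$intensity_self[k] <- background_correct(raw_self, background_self)
      if (!is.null(img_other)) {
        raw_other <- roi_mean(img_other, pos, params$roi_diameter_px)
        out$intensity_other[k] <- background_correct(raw_other,
                                                     background_other)
      }
      mc <- mass_center(img_self, pos, params$roi_diameter_px,
                        background = background_self)
      out$x_nm[k] <- mc[["x_nm"]]
      out$y_nm[k] <- mc[["y_nm"]]
    } else {
      out$x_nm[k] <- (pos[2] - 0.5) * p
      out$y_nm[k] <- (pos[1] - 0.5) * p
    }
    if (out$border_flag[k]) next  # no linescan window; never a cluster
    prof <- linescan_profiles(img_self, pos, params$linescan_length_px,
                              params$linescan_width_px)
    if (is.null(prof)) { out$border_flag[k] <- TRUE; next }
    fit_h <- fit_gaussian_profile(prof$horizontal, "horizontal")
    fit_v <- fit_gaussian_profile(prof$vertical, "vertical")
    best <- if (fit_v$r2 > fit_h$r2) fit_v else fit_h  # tie -> horizontal
    if (best$converged) {
      out$A[k] <- best$A
      out$mu_px[k] <- best$mu
      out$sigma_px[k] <- best$sigma
      out$r2[k] <- best$r2
      out$orientation[k] <- best$orientation
      out$fwhm_nm[k] <- fwhm_nm(best, p)
    }
    out$is_cluster[k] <- classify_cluster(
      best$r2, best$mu, out$border_flag[k],
      r2_threshold = params$r2_threshold, center_px = center_px,
      center_window_px = params$center_window_px)
  }
  structure(out, pixel_size_nm = p,
            source_channel = attr(maxima, "source_channel"),
            class = c("maxima_table", "data.frame"))
}
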