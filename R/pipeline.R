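#' Analysis parameters
#'
#' All numeric constants of the analysis in one validated object. Defaults
#' reproduce the standard settings: 20 nm pixels, blur sigma 0.5 px, noise
#' tolerance 4 (CD9/CD81/CD151-type stainings), 5 px (100 nm) measurement
#' ROI, 31 x 3 px linescans, R^2 > 0.8 with the peak in the central 10 px,
#' 60 nm overlap threshold, 900 nm neighbor circle, 2 a.u. noise gate,
#' 50% crosstalk factor, 10 nm distance-histogram bins.
#'
#' @param pixel_size_nm physical pixel size (nm).
#' @param blur_sigma_px Gaussian blur sigma (px).
#' @param noise_tolerance prominence threshold for the own channel; a named
#'   vector per channel label is accepted (see
#'   [default_noise_tolerances()]).
#' @param roi_diameter_px measurement-ROI diameter (px).
#' @param linescan_length_px linescan length (px, odd).
#' @param linescan_width_px linescan width (px, odd).
#' @param r2_threshold cluster fit-quality threshold.
#' @param center_window_px allowed |mu - center| of the fitted peak (px).
#' @param overlap_threshold_nm overlap distance threshold (nm, inclusive).
#' @param neighbor_diameter_nm neighbor-counting circle diameter (nm).
#' @param noise_level_au intensity noise gate (a.u., inclusive below).
#' @param crosstalk_factor fraction for crosstalk subtraction.
#' @param crosstalk_channel which channel to crosstalk-correct with the
#'   other before analysis: `"none"` (default), `"self"` or `"other"`.
#' @param distance_bin_nm distance-histogram bin width (nm).
#' @param background_roi optional `(row, col)` of an off-sheet background
#'   ROI center; if `NULL` the image median is used as background estimate.
#' @param border_px margin within which maxima are flagged (px).
#' @param exclude_edge drop border-pixel maxima entirely in detection.
#' @return Validated list of class `analysis_params`.
#' @export
analysis_params <- function(pixel_size_nm = 20,
                            blur_sigma_px = 0.5,
                            noise_tolerance = 4,
                            roi_diameter_px = 5,
                            linescan_length_px = 31,
                            linescan_width_px = 3,
                            r2_threshold = 0.8,
                            center_window_px = 5,
                            overlap_threshold_nm = 60,
                            neighbor_diameter_nm = 900,
                            noise_level_au = 2,
                            crosstalk_factor = 0.5,
                            crosstalk_channel = c("none", "self", "other"),
                            distance_bin_nm = 10,
                            background_roi = NULL,
                            border_px = 15L,
                            exclude_edge = FALSE) {
  crosstalk_channel <- match.arg(crosstalk_channel)
  p <- list(pixel_size_nm = pixel_size_nm, blur_sigma_px = blur_sigma_px,
            noise_tolerance = noise_tolerance,
            roi_diameter_px = roi_diameter_px,
            linescan_length_px = as.integer(linescan_length_px),
            linescan_width_px = as.integer(linescan_width_px),
            r2_threshold = r2_threshold,
            center_window_px = center_window_px,
            overlap_threshold_nm = overlap_threshold_nm,
            neighbor_diameter_nm = neighbor_diameter_nm,
            noise_level_au = noise_level_au,
            crosstalk_factor = crosstalk_factor,
            crosstalk_channel = crosstalk_channel,
            distance_bin_nm = distance_bin_nm,
            background_roi = background_roi,
            border_px = as.integer(border_px),
            exclude_edge = isTRUE(exclude_edge))
  validate_params(p)
  structure(p, class = "analysis_params")
}

validate_params <- function(p) {
  fail <- function(f, msg)
    stop(sprintf("invalid analysis_params: `%s` %s", f, msg), call. = FALSE)
  pos <- function(f) {
    v <- p[[f]]
    if (!is.numeric(v) || !all(is.finite(v)) || any(v <= 0))
      fail(f, "must be positive")
  }
  for (f in c("pixel_size_nm", "noise_tolerance", "roi_diameter_px",
              "linescan_length_px", "linescan_width_px",
              "overlap_threshold_nm", "neighbor_diameter_nm",
              "distance_bin_nm", "center_window_px")) pos(f)
  if (!is.numeric(p$blur_sigma_px) || p$blur_sigma_px < 0)
    fail("blur_sigma_px", "must be non-negative")
  if (p$r2_threshold <= 0 || p$r2_threshold >= 1)
    fail("r2_threshold", "must lie in (0, 1)")
  if (p$linescan_length_px %% 2 != 1)
    fail("linescan_length_px", "must be odd")
  if (p$linescan_width_px %% 2 != 1)
    fail("linescan_width_px", "must be odd")
  if (p$crosstalk_factor < 0 || p$crosstalk_factor > 1)
    fail("crosstalk_factor", "must lie in [0, 1]")
  if (p$noise_level_au < 0) fail("noise_level_au", "must be non-negative")
  if (!is.null(p$background_roi) && length(p$background_roi) != 2)
    fail("background_roi", "must be NULL or (row, col)")
  invisible(p)
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", f,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# resolve a per-channel noise tolerance
tolerance_for <- function(noise_tolerance, channel) {
  if (length(noise_tolerance) == 1 && is.null(names(noise_tolerance)))
    return(as.numeric(noise_tolerance))
  if (!is.null(names(noise_tolerance)) && channel %in% names(noise_tolerance))
    return(as.numeric(noise_tolerance[[channel]]))
  as.numeric(noise_tolerance[[1]])
}

# background level for one image: configured ROI or the image median
estimate_background <- function(img, params) {
  if (!is.null(params$background_roi))
    roi_mean(img, params$background_roi, params$roi_diameter_px)
  else
    stats::median(img$values)
}

#' Run the full two-channel cluster analysis on one membrane sheet
#'
#' Executes the complete pipeline on an image pair: optional crosstalk
#' correction, Gaussian blur, maxima detection in both channels, per-maximum
#' quantification and cluster classification, directional cross-channel
#' shortest-distance/overlap analysis, neighbored-maxima crowding counts,
#' cluster densities, and the through-origin inter-channel intensity
#' regressions. Fully deterministic given its inputs.
#'
#' @param self [pixel_image()], matrix, or TIFF path: the source channel.
#' @param other [pixel_image()], matrix, or TIFF path: the target channel.
#' @param mask optional binary sheet mask ([pixel_image()], matrix or TIFF
#'   path); nonzero = on-sheet. Maxima off the mask are discarded and the
#'   mask area is used for densities.
#' @param params an [analysis_params()].
#' @param channels length-2 character: labels for the two channels (used to
#'   look up per-channel noise tolerances).
#' @return Object of class `sheet_analysis` with elements `maxima` (named
#'   list of `maxima_table`s), `distances`, `overlap` (named list, both
#'   directions), `neighbor_counts`, `neighbor_hist`, `density`,
#'   `regression`, `background`, `area_um2`, `params`, `channels`.
#' @examples
#' cfg <- sim_config(image_size_px = c(256, 256), density_per_um2 = 4,
#'                   seed = 7)
#' ds <- simulate(cfg)
#' res <- analyze_sheet(ds$images$A, ds$images$B)
#' res
#' @export
analyze_sheet <- function(self, other, mask = NULL,
                          params = analysis_params(),
                          channels = c("A", "B")) {
  validate_params(params)
  load_img <- function(x, ch) {
    if (is.character(x))
      read_image(x, pixel_size_nm = params$pixel_size_nm, channel = ch)
    else {
      img <- as_pixel_image(x, pixel_size_nm = params$pixel_size_nm,
                            channel = ch)
      img$channel <- ch
      img$pixel_size_nm <- params$pixel_size_nm
      img
    }
  }
  img_self <- load_img(self, channels[1])
  img_other <- load_img(other, channels[2])
  if (!identical(dim(img_self$values), dim(img_other$values)))
    stop("channel images must have identical shape", call. = FALSE)
  if (!is.null(mask)) {
    mask_img <- load_img(mask, "mask")
    if (!identical(dim(mask_img$values), dim(img_self$values)))
      stop("mask must have the same shape as the images", call. = FALSE)
  } else mask_img <- NULL

  # preprocessing: crosstalk, then blur
  if (params$crosstalk_channel == "self")
    img_self <- correct_crosstalk(img_self, img_other,
                                  params$crosstalk_factor)
  if (params$crosstalk_channel == "other")
    img_other <- correct_crosstalk(img_other, img_self,
                                   params$crosstalk_factor)
  img_self <- gaussian_blur(img_self, params$blur_sigma_px)
  img_other <- gaussian_blur(img_other, params$blur_sigma_px)

  bg <- c(estimate_background(img_self, params),
          estimate_background(img_other, params))
  names(bg) <- channels

  analyze_channel <- function(img_a, img_b, ch) {
    mx <- find_maxima(img_a, tolerance_for(params$noise_tolerance, ch),
                      exclude_edge = params$exclude_edge,
                      border_px = params$border_px)
    if (!is.null(mask_img) && nrow(mx)) {
      keep <- mask_img$values[cbind(mx$row, mx$col)] != 0
      mx <- mx[keep, , drop = FALSE]
      attr(mx, "source_channel") <- ch
    }
    measure_maxima(img_a, img_b, mx, params,
                   background_self = bg[[img_a$channel]],
                   background_other = bg[[img_b$channel]])
  }
  tab_self <- analyze_channel(img_self, img_other, channels[1])
  tab_other <- analyze_channel(img_other, img_self, channels[2])
  maxima <- stats::setNames(list(tab_self, tab_other), channels)

  area_um2 <- if (!is.null(mask_img))
    sheet_area_um2(mask_img) else
      prod(dim(img_self$values)) * (params$pixel_size_nm / 1000)^2

  clusters <- lapply(maxima, function(tb)
    tb[tb$is_cluster, c("x_nm", "y_nm"), drop = FALSE])
  density <- vapply(clusters, function(cl)
    cluster_density(nrow(cl), area_um2), numeric(1))

  distances <- list(); overlap <- list()
  dir_names <- c(paste(channels[1], channels[2], sep = "->"),
                 paste(channels[2], channels[1], sep = "->"))
  if (nrow(clusters[[1]]) && nrow(clusters[[2]])) {
    d_ab <- shortest_cross_distances(clusters[[1]], clusters[[2]],
                                     params$overlap_threshold_nm)
    d_ba <- shortest_cross_distances(clusters[[2]], clusters[[1]],
                                     params$overlap_threshold_nm)
    distances <- stats::setNames(list(d_ab, d_ba), dir_names)
    overlap <- stats::setNames(list(overlap_fraction(d_ab),
                                    overlap_fraction(d_ba)), dir_names)
  }

  ncounts <- lapply(maxima, function(tb) {
    if (!nrow(tb)) return(structure(integer(0),
                                    diameter_nm = params$neighbor_diameter_nm))
    p <- params$pixel_size_nm
    neighbor_counts(cbind(x_nm = (tb$col - 0.5) * p,
                          y_nm = (tb$row - 0.5) * p),
                    params$neighbor_diameter_nm)
  })
  nhist <- lapply(ncounts, function(ct)
    if (length(ct)) percent_histogram(ct, 1, origin = -0.5) else NULL)

  regression <- stats::setNames(lapply(maxima, function(tb) {
    ok <- is.finite(tb$intensity_self) & is.finite(tb$intensity_other)
    if (sum(ok) >= 2)
      origin_regression(tb$intensity_self[ok], tb$intensity_other[ok],
                        params$noise_level_au)
    else NULL
  }), channels)

  structure(list(maxima = maxima, distances = distances, overlap = overlap,
                 neighbor_counts = ncounts, neighbor_hist = nhist,
                 density = density, regression = regression,
                 background = bg, area_um2 = area_um2, params = params,
                 channels = channels),
            class = "sheet_analysis")
}

#' @export
print.sheet_analysis <- function(x, ...) {
  cat(sprintf("<sheet_analysis> %s vs %s, %.2f um^2 analyzed\n",
              x$channels[1], x$channels[2], x$area_um2))
  for (ch in x$channels) {
    tb <- x$maxima[[ch]]
    cat(sprintf("  %s: %d maxima, %d clusters (%.2f clusters/um^2)\n",
                ch, nrow(tb), sum(tb$is_cluster), x$density[[ch]]))
  }
  for (dn in names(x$overlap))
    cat(sprintf("  overlap %s: %.1f%% (threshold %.0f nm)\n", dn,
                100 * x$overlap[[dn]], x$params$overlap_threshold_nm))
  invisible(x)
}

#' @export
summary.sheet_analysis <- function(object, ...) {
  x <- object
  rows <- lapply(x$channels, function(ch) {
    tb <- x$maxima[[ch]]
    reg <- x$regression[[ch]]
    data.frame(
      channel = ch,
      n_maxima = nrow(tb),
      n_clusters = sum(tb$is_cluster),
      density_per_um2 = unname(x$density[[ch]]),
      median_fwhm_nm = stats::median(tb$fwhm_nm[tb$is_cluster], na.rm = TRUE),
      mean_neighbors = if (length(x$neighbor_counts[[ch]]))
        mean(x$neighbor_counts[[ch]]) else NA_real_,
      slope = if (is.null(reg)) NA_real_ else reg$slope,
      r2 = if (is.null(reg)) NA_real_ else reg$r2,
      pct_both = if (is.null(reg)) NA_real_ else 100 * reg$frac_both
    )
  })
  out <- do.call(rbind, rows)
  ov <- unlist(x$overlap)
  attr(out, "overlap_pct") <- 100 * ov
  class(out) <- c("summary.sheet_analysis", "data.frame")
  out
}

#' @export
print.summary.sheet_analysis <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  ov <- attr(x, "overlap_pct")
  if (length(ov))
    for (dn in names(ov))
      cat(sprintf("overlap %s: %.1f%%\n", dn, ov[[dn]]))
  invisible(x)
}

#' @export
plot.sheet_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (length(x$distances)) {
    h <- distance_histogram(x$distances[[1]], x$params$distance_bin_nm)
    graphics::plot(h$bin_center, h$percent, type = "h", lwd = 3,
                   xlab = "nearest-neighbor distance (nm)",
                   ylab = "% of clusters",
                   main = names(x$distances)[1])
    graphics::abline(v = x$params$overlap_threshold_nm, lty = 2)
  }
  ch <- x$channels[1]
  if (!is.null(x$neighbor_hist[[ch]])) {
    h <- x$neighbor_hist[[ch]]
    graphics::plot(h$bin_center, h$percent, type = "s", lwd = 2,
                   xlab = "neighbored maxima",
                   ylab = "% of maxima", main = ch)
  }
  invisible(x)
}

#' Write a sheet analysis to disk
#'
#' Writes `maxima.csv` (both channels), `distances.csv`, `neighbors.csv`,
#' `summary.csv`, `correlation.csv` and a `manifest.json` with parameter
#' echo and per-file MD5 checksums. Re-running the identical analysis
#' produces byte-identical files.
#'
#' @param result a `sheet_analysis`.
#' @param outdir output directory (created if needed).
#' @param image_id identifier recorded in the tables.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(result, outdir, image_id = "image") {
  stopifnot(inherits(result, "sheet_analysis"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outdir),
         call. = FALSE)
  files <- character(0)
  add <- function(df, name) {
    f <- file.path(outdir, name)
    write_table_csv(df, f)
    files <<- c(files, f)
  }
  mx <- do.call(rbind, lapply(result$channels, function(ch) {
    tb <- as.data.frame(result$maxima[[ch]])
    data.frame(image_id = rep(image_id, nrow(tb)),
               channel = rep(ch, nrow(tb)), tb)
  }))
  add(mx, "maxima.csv")
  if (length(result$distances)) {
    dd <- do.call(rbind, lapply(names(result$distances), function(dn) {
      tb <- as.data.frame(result$distances[[dn]])
      data.frame(image_id = rep(image_id, nrow(tb)),
                 direction = rep(dn, nrow(tb)), tb)
    }))
    add(dd, "distances.csv")
  }
  nb <- do.call(rbind, lapply(result$channels, function(ch) {
    ct <- result$neighbor_counts[[ch]]
    if (!length(ct)) return(NULL)
    data.frame(image_id = image_id, channel = ch,
               maximum_id = seq_along(ct), count = as.integer(ct))
  }))
  if (!is.null(nb)) add(nb, "neighbors.csv")
  sm0 <- summary(result)
  ov <- attr(sm0, "overlap_pct")
  sm <- as.data.frame(sm0)
  add(data.frame(image_id = rep(image_id, nrow(sm)), sm), "summary.csv")
  corr <- do.call(rbind, lapply(result$channels, function(ch) {
    reg <- result$regression[[ch]]
    if (is.null(reg)) return(NULL)
    data.frame(image_id = image_id, channel = ch, slope = reg$slope,
               r2 = reg$r2, n = reg$n, pct_both = 100 * reg$frac_both,
               pct_self_only = 100 * reg$frac_self_only,
               pct_below_noise = 100 * reg$frac_below_noise)
  }))
  if (!is.null(corr)) add(corr, "correlation.csv")
  manifest <- list(
    image_id = image_id,
    channels = result$channels,
    params = unclass(result$params),
    overlap_pct = as.list(if (length(ov)) ov else numeric(0)),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
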