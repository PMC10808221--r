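#' Crosstalk correction between spectral channels
#'
#' Removes co-excitation bleed-through by subtracting a fixed fraction of one
#' channel from another, clipping at zero. With the default `factor = 0.5`
#' half of the red-channel image is subtracted from the long-red-channel
#' image, the setting used when a 594-dye is co-excited by the 640 nm laser.
#'
#' @param long_red [pixel_image] (or matrix): the channel to be corrected.
#' @param red [pixel_image] (or matrix): the channel causing the bleed-through.
#' @param factor fraction of `red` to subtract, in `[0, 1]`.
#' @return A `pixel_image` with values `pmax(long_red - factor * red, 0)`.
#' @export
correct_crosstalk <- function(long_red, red, factor = 0.5) {
  long_red <- as_pixel_image(long_red)
  red <- as_pixel_image(red, pixel_size_nm = long_red$pixel_size_nm)
  if (!identical(dim(long_red$values), dim(red$values)))
    stop("crosstalk correction requires images of identical shape",
         call. = FALSE)
  if (long_red$pixel_size_nm != red$pixel_size_nm)
    stop("crosstalk correction requires identical pixel sizes", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor < 0 || factor > 1)
    stop("`factor` must be a single number in [0, 1]", call. = FALSE)
  out <- pmax(long_red$values - factor * red$values, 0)
  pixel_image(out, long_red$pixel_size_nm, long_red$channel)
}

# 1D Gaussian kernel truncated at +-ceiling(4*sigma), normalized to sum 1
gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# pad index vector reflectively: 1..n mirrored at the edges (no repeat of edge)
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j + 1L))
}

#' Gaussian blur
#'
#' Separable discrete Gaussian convolution with reflective boundary handling.
#' The kernel is truncated at `ceiling(4 * sigma_px)` pixels and renormalized
#' so that total intensity is conserved in the interior. `sigma_px = 0`
#' returns the input unchanged. The default `sigma_px = 0.5` is the standard
#' noise-reduction setting of the pipeline.
#'
#' @param img [pixel_image] or matrix.
#' @param sigma_px Gaussian standard deviation in pixels, `>= 0`.
#' @return A blurred `pixel_image`.
#' @export
gaussian_blur <- function(img, sigma_px = 0.5) {
  img <- as_pixel_image(img)
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || !is.finite(sigma_px) ||
      sigma_px < 0)
    stop("`sigma_px` must be a single non-negative number", call. = FALSE)
  if (sigma_px == 0) return(img)
  k <- gaussian_kernel_1d(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  v <- img$values
  n1 <- nrow(v); n2 <- ncol(v)
  # rows: pad reflectively then accumulate shifted copies (vectorized)
  conv_cols <- function(m, k, r) {
    n <- nrow(m)
    padded <- m[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k))
      out <- out + k[s] * padded[seq.int(s, s + n - 1L), , drop = FALSE]
    out
  }
  v <- conv_cols(v, k, r)          # along rows (vertical)
  v <- t(conv_cols(t(v), k, r))    # along columns (horizontal)
  pixel_image(v, img$pixel_size_nm, img$channel)
}

#' Detect local maxima with a noise-tolerance criterion
#'
#' Finds intensity maxima that stand out from their surroundings by more than
#' `noise_tolerance`, the prominence-style criterion used throughout the
#' cluster analysis. The normative contract: a candidate pixel `p` (with value
#' at least that of all 8-neighbors, outside-image treated as `-Inf`, and
#' strictly above the image's global minimum) is reported iff the 8-connected
#' region of pixels with value `> I(p) - noise_tolerance` reachable from `p`
#' contains no pixel higher than `I(p)` and no already-accepted maximum,
#' candidates being processed in descending value (ties row-major). For an
#' equal-valued plateau exactly one point is reported: the plateau pixel
#' nearest the plateau centroid, ties broken row-major.
#'
#' Maxima closer than `border_px` pixels to any image border are flagged so
#' that downstream linescan and ROI measurements, which need a full window,
#' can skip them.
#'
#' @param img [pixel_image] or matrix, already blurred/crosstalk-corrected as
#'   configured.
#' @param noise_tolerance positive prominence threshold in intensity units.
#' @param exclude_edge if `TRUE`, maxima on border pixels are dropped
#'   entirely (default `FALSE`, border maxima are reported but flagged).
#' @param border_px margin (pixels) within which maxima are `border_flag`ged.
#' @return A data frame of class `maxima_list` with columns `row`, `col`,
#'   `value`, `border_flag`, and attributes `noise_tolerance`,
#'   `pixel_size_nm`, `source_channel`.
#' @seealso [find_maxima_reference()] for the brute-force reference
#'   implementation used to validate this one.
#' @export
find_maxima <- function(img, noise_tolerance, exclude_edge = FALSE,
                        border_px = 15L) {
  img <- as_pixel_image(img)
  if (!is.numeric(noise_tolerance) || length(noise_tolerance) != 1 ||
      !is.finite(noise_tolerance) || noise_tolerance <= 0)
    stop("`noise_tolerance` must be a single positive number", call. = FALSE)
  m <- find_maxima_cpp(img$values, as.numeric(noise_tolerance))
  res <- data.frame(row = m[, 1L], col = m[, 2L],
                    value = img$values[cbind(m[, 1L], m[, 2L])])
  # deterministic row order: descending value, ties row-major
  if (nrow(res) > 1)
    res <- res[order(-res$value, res$row, res$col), , drop = FALSE]
  rownames(res) <- NULL
  d <- dim(img$values)
  on_border <- res$row == 1L | res$col == 1L | res$row == d[1] | res$col == d[2]
  if (exclude_edge && any(on_border)) {
    res <- res[!on_border, , drop = FALSE]
    rownames(res) <- NULL
  }
  res$border_flag <- res$row <= border_px | res$col <= border_px |
    res$row > d[1] - border_px | res$col > d[2] - border_px
  structure(res,
            noise_tolerance = as.numeric(noise_tolerance),
            pixel_size_nm = img$pixel_size_nm,
            source_channel = img$channel,
            class = c("maxima_list", "data.frame"))
}

#' Brute-force reference maxima finder
#'
#' Pure-R, per-candidate flood-fill implementation of the identical contract
#' as [find_maxima()]. Deliberately naive (a fresh breadth-first flood for
#' every candidate); kept as the ground-truth oracle against which the fast
#' implementation is validated on randomized images.
#'
#' @inheritParams find_maxima
#' @return Integer matrix with columns `row`, `col` of accepted maxima,
#'   ordered by descending value (ties row-major).
#' @export
find_maxima_reference <- function(img, noise_tolerance) {
  img <- as_pixel_image(img)
  v <- img$values
  nr <- nrow(v); nc <- ncol(v)
  gmin <- min(v)
  # neighbor offsets (8-connectivity)
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]

  # candidate test: value > gmin and >= all 8 neighbors (outside = -Inf)
  is_candidate <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (v[i, j] <= gmin) next
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && v[ii, jj] > v[i, j]) {
        ok <- FALSE; break
      }
    }
    is_candidate[i, j] <- ok
  }

  # group into equal-valued 8-connected plateaus; a plateau qualifies iff all
  # of its pixels are candidates; representative = pixel nearest centroid
  seen <- matrix(FALSE, nr, nc)
  reps <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seen[i, j] || !is_candidate[i, j]) next
    val <- v[i, j]
    comp <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    queue <- list(c(i, j)); qi <- 1L
    all_cand <- TRUE
    while (qi <= length(queue)) {
      p <- queue[[qi]]; qi <- qi + 1L
      for (k in seq_len(nrow(off))) {
        ii <- p[1] + off[k, 1]; jj <- p[2] + off[k, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!seen[ii, jj] && v[ii, jj] == val) {
          seen[ii, jj] <- TRUE
          if (!is_candidate[ii, jj]) all_cand <- FALSE
          comp <- rbind(comp, c(ii, jj))
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
    if (!all_cand) next
    # centroid distance scaled by plateau size^2: exact integer arithmetic
    m <- nrow(comp); si <- sum(comp[, 1]); sj <- sum(comp[, 2])
    d2 <- (m * comp[, 1] - si)^2 + (m * comp[, 2] - sj)^2
    ord <- order(d2, comp[, 1], comp[, 2])
    reps <- rbind(reps, c(comp[ord[1], ], val))
  }
  if (is.null(reps))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))

  reps <- reps[order(-reps[, 3], reps[, 1], reps[, 2]), , drop = FALSE]
  accepted <- matrix(FALSE, nr, nc)
  out <- NULL
  for (r in seq_len(nrow(reps))) {
    i0 <- reps[r, 1]; j0 <- reps[r, 2]; val <- reps[r, 3]
    thr <- val - noise_tolerance
    # BFS flood over pixels with value > thr
    visited <- matrix(FALSE, nr, nc)
    visited[i0, j0] <- TRUE
    queue <- list(c(i0, j0)); qi <- 1L
    ok <- TRUE
    while (qi <= length(queue)) {
      p <- queue[[qi]]; qi <- qi + 1L
      if (v[p[1], p[2]] > val || accepted[p[1], p[2]]) { ok <- FALSE; break }
      for (k in seq_len(nrow(off))) {
        ii <- p[1] + off[k, 1]; jj <- p[2] + off[k, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!visited[ii, jj] && v[ii, jj] > thr) {
          visited[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
    if (ok) {
      accepted[i0, j0] <- TRUE
      out <- rbind(out, c(i0, j0))
    }
  }
  if (is.null(out))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  colnames(out) <- c("row", "col")
  storage.mode(out) <- "integer"
  out
}

#' @export
print.maxima_list <- function(x, ...) {
  cat(sprintf("<maxima_list> %d maxima (channel %s, noise tolerance %.3g)\n",
              nrow(x), attr(x, "source_channel"), attr(x, "noise_tolerance")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# default per-antibody noise tolerances
#' Default noise tolerances per channel label
#'
#' Standard prominence thresholds for the antibodies the pipeline was
#' developed with: 4 for CD9/CD81/CD151, 8 for CD44, 5 for pERM, 6 for EWI-2.
#'
#' @return Named numeric vector.
#' @export
default_noise_tolerances <- function() {
  c(CD9 = 4, CD81 = 4, CD151 = 4, CD44 = 8, pERM = 5, `EWI-2` = 6)
}
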