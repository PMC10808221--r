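#' Shortest cross-channel distances
#'
#' For every source-channel cluster, the Euclidean distance to the nearest
#' target-channel cluster (subpixel mass-center positions, nm). The
#' measurement is directional: `A -> B` and `B -> A` are distinct analyses
#' and both are reported by the pipeline.
#'
#' @param src two-column matrix or data frame of source positions
#'   (`x_nm`, `y_nm`).
#' @param dst two-column matrix or data frame of target positions.
#' @param threshold_nm overlap threshold (default 60 nm, inclusive).
#' @return Data frame of class `distance_result` with columns `src_id`,
#'   `distance_nm`, `overlap`; attribute `threshold_nm`.
#' @export
shortest_cross_distances <- function(src, dst, threshold_nm = 60) {
  src <- as_xy(src); dst <- as_xy(dst)
  if (nrow(src) == 0)
    stop("`src` must contain at least one position", call. = FALSE)
  if (nrow(dst) == 0)
    stop("`dst` must contain at least one position (nearest neighbor undefined)",
         call. = FALSE)
  # vectorized per-source minimum, chunked to bound memory
  n <- nrow(src)
  d <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(dst)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    dx <- outer(src[idx, 1], dst[, 1], "-")
    dy <- outer(src[idx, 2], dst[, 2], "-")
    d[idx] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  structure(
    data.frame(src_id = seq_len(n), distance_nm = d,
               overlap = d <= threshold_nm),
    threshold_nm = threshold_nm,
    class = c("distance_result", "data.frame"))
}

as_xy <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_nm", "y_nm"), names(x))
    x <- if (length(cols) == 2) as.matrix(x[, cols]) else
      as.matrix(x[, 1:2])
  }
  if (!is.matrix(x) || ncol(x) < 2)
    stop("positions must be a 2-column matrix or data frame", call. = FALSE)
  storage.mode(x) <- "double"
  x[, 1:2, drop = FALSE]
}

#' Overlap fraction
#'
#' Fraction of source clusters whose nearest target-channel cluster lies
#' within the overlap threshold (inclusive; a distance of exactly 60 nm
#' counts as overlapping).
#'
#' @param d a `distance_result` from [shortest_cross_distances()].
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(d) {
  stopifnot(inherits(d, "distance_result"))
  mean(d$overlap)
}

#' Percentage histogram
#'
#' Histogram expressed as the percentage of observations per bin, the
#' presentation used for both the distance and the neighbored-maxima
#' distributions. Bins are left-closed, right-open, starting at `origin`.
#'
#' @param values numeric observations.
#' @param bin_width bin width (same units as `values`).
#' @param origin left edge of the first bin.
#' @return Data frame of class `percent_histogram` with columns `bin_center`
#'   and `percent`; attribute `n`.
#' @export
percent_histogram <- function(values, bin_width, origin = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite values to histogram", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  idx <- floor((values - origin) / bin_width)
  tab <- table(factor(idx, levels = min(idx):max(idx)))
  structure(
    data.frame(
      bin_center = origin + (as.integer(names(tab)) + 0.5) * bin_width,
      percent = 100 * as.integer(tab) / n),
    n = n,
    bin_width = bin_width,
    class = c("percent_histogram", "data.frame"))
}

#' Distance histogram
#'
#' Percentage of source clusters per nearest-neighbor distance bin
#' (default 10 nm bins starting at 0).
#'
#' @param d a `distance_result`.
#' @param bin_nm bin width in nm.
#' @return A [percent_histogram()].
#' @export
distance_histogram <- function(d, bin_nm = 10) {
  stopifnot(inherits(d, "distance_result"))
  percent_histogram(d$distance_nm, bin_nm, origin = 0)
}

#' Neighbored-maxima counts
#'
#' For every maximum of one channel, the number of other same-channel maxima
#' whose centers lie within a circle of diameter `diameter_nm` (default
#' 900 nm) centered on it; the maximum itself is never counted (the count in
#' the circle minus one). Pixel positions of the maxima are used, not
#' subpixel mass centers. The boundary is inclusive (distance exactly equal
#' to the radius counts).
#'
#' Implemented with spatial grid binning; validated against an explicit
#' O(n^2) pair enumeration (see [neighbor_counts_reference()]).
#'
#' @param positions two-column matrix or data frame of positions in nm
#'   (`x_nm`, `y_nm`).
#' @param diameter_nm search-circle diameter in nm.
#' @return Integer vector of neighbor counts, one per position, with
#'   attribute `diameter_nm`.
#' @export
neighbor_counts <- function(positions, diameter_nm = 900) {
  xy <- as_xy(positions)
  n <- nrow(xy)
  r <- diameter_nm / 2
  counts <- integer(n)
  if (n > 1) {
    # grid binning with cell size = radius; neighbors within one cell ring
    cx <- floor(xy[, 1] / r)
    cy <- floor(xy[, 2] / r)
    key <- paste(cx, cy)
    cells <- split(seq_len(n), key)
    cell_of <- match(key, names(cells))
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (nm in names(cells)) assign(nm, cells[[nm]], envir = lookup)
    r2 <- r * r
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        nm <- paste(cx[i] + dx, cy[i] + dy)
        hit <- if (exists(nm, envir = lookup, inherits = FALSE))
          get(nm, envir = lookup) else NULL
        if (!is.null(hit)) cand <- c(cand, hit)
      }
      dd <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
      counts[i] <- sum(dd <= r2) - 1L  # minus self
    }
  }
  structure(counts, diameter_nm = diameter_nm)
}

#' Brute-force neighbor counting (reference)
#'
#' Direct O(n^2) double-loop pair enumeration with the identical boundary
#' convention as [neighbor_counts()]; the oracle used for validation.
#'
#' @inheritParams neighbor_counts
#' @return Integer vector of neighbor counts.
#' @export
neighbor_counts_reference <- function(positions, diameter_nm = 900) {
  xy <- as_xy(positions)
  n <- nrow(xy)
  r2 <- (diameter_nm / 2)^2
  counts <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if ((xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2 <= r2)
        cnt <- cnt + 1L
    }
    counts[i] <- cnt
  }
  counts
}

#' Brute-force shortest cross distances (reference)
#'
#' Scalar double-loop nearest-neighbor search; the oracle used to validate
#' [shortest_cross_distances()].
#'
#' @inheritParams shortest_cross_distances
#' @return Numeric vector of nearest-neighbor distances (nm).
#' @export
cross_distances_reference <- function(src, dst) {
  src <- as_xy(src); dst <- as_xy(dst)
  out <- numeric(nrow(src))
  for (i in seq_len(nrow(src))) {
    best <- Inf
    for (j in seq_len(nrow(dst))) {
      d2 <- (src[i, 1] - dst[j, 1])^2 + (src[i, 2] - dst[j, 2])^2
      if (d2 < best) best <- d2
    }
    out[i] <- sqrt(best)
  }
  out
}

#' Cluster density
#'
#' Clusters per square micrometer, over the sheet-mask area if a mask is
#' supplied, else the full image area.
#'
#' @param n_clusters cluster count (or a positions table, in which case its
#'   row count is used).
#' @param area_um2 analyzed area in um^2.
#' @return Density per um^2.
#' @export
cluster_density <- function(n_clusters, area_um2) {
  if (is.data.frame(n_clusters) || is.matrix(n_clusters))
    n_clusters <- nrow(n_clusters)
  if (!is.finite(area_um2) || area_um2 <= 0)
    stop("`area_um2` must be positive (empty mask?)", call. = FALSE)
  n_clusters / area_um2
}

#' Sheet area from a binary mask
#'
#' @param mask logical/0-1 matrix or [pixel_image()]; nonzero = on-sheet.
#' @param pixel_size_nm pixel size (nm), taken from the image if available.
#' @return Area in um^2.
#' @export
sheet_area_um2 <- function(mask, pixel_size_nm = 20) {
  if (inherits(mask, "pixel_image")) {
    pixel_size_nm <- mask$pixel_size_nm
    mask <- mask$values
  }
  n_on <- sum(mask != 0)
  if (n_on == 0) stop("mask is empty: zero analyzable area", call. = FALSE)
  n_on * (pixel_size_nm / 1000)^2
}

#' Exclude positions near the field border
#'
#' Utility for edge-corrected spatial statistics: keeps only positions at
#' least `margin_nm` from every border of a field of the given extent.
#'
#' @param positions two-column matrix/data frame of positions (nm).
#' @param extent_nm `c(height_nm, width_nm)` of the field.
#' @param margin_nm exclusion margin (nm).
#' @return Logical vector: `TRUE` for interior positions.
#' @export
interior_mask <- function(positions, extent_nm, margin_nm) {
  xy <- as_xy(positions)
  xy[, 1] >= margin_nm & xy[, 1] <= extent_nm[2] - margin_nm &
    xy[, 2] >= margin_nm & xy[, 2] <= extent_nm[1] - margin_nm
}
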