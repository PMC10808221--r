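#' Simulation configuration for synthetic membrane-sheet images
#'
#' Defines the generative model for two-channel synthetic micrographs of
#' membrane sheets: protein assemblies scattered over the field (a fraction
#' of them agglomerated into "arranged crowds"), each assembly carrying
#' channel A, channel B, or both labels, rendered as diffraction-limited
#' Gaussian spots with Poisson shot noise and Gaussian read noise.
#'
#' Defaults emulate the imaging conditions the analysis was developed for:
#' 20 nm pixels, 3-5 assemblies per square micrometer, a STED point-spread
#' function of 65-100 nm FWHM, and log-normal spot brightness.
#'
#' @param image_size_px integer pair, image height and width in pixels.
#' @param pixel_size_nm physical pixel size (nm).
#' @param density_per_um2 areal density of assemblies (points) per um^2.
#' @param frac_both,frac_a_only,frac_b_only composition probabilities of an
#'   assembly carrying both labels, only A, or only B; must sum to 1.
#' @param crowd_fraction fraction of assemblies placed inside arranged
#'   crowds (a Thomas-type parent-child process) rather than scattered with
#'   complete spatial randomness.
#' @param crowd_radius_nm Gaussian scatter scale of assemblies about their
#'   crowd center (nm).
#' @param assemblies_per_crowd mean number of assemblies per crowd (Poisson).
#' @param amplitude_mean,amplitude_sd mean and standard deviation (natural
#'   scale) of the log-normal integrated spot brightness, per channel
#'   (length-1 values are recycled to both channels).
#' @param psf_fwhm_nm full width at half maximum of the Gaussian PSF (nm).
#' @param background_offset uniform background level added before shot
#'   noise (a.u.).
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param detect_prob per-assembly, per-channel probability that a carried
#'   label is actually detected (models epitope shielding / incomplete
#'   immunolabeling); in `(0, 1]`.
#' @param seed integer seed making the whole dataset reproducible.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(image_size_px = c(256, 256), seed = 1)
#' truth <- sample_positions(cfg)
#' head(truth)
#' @export
sim_config <- function(image_size_px = c(512L, 512L),
                       pixel_size_nm = 20,
                       density_per_um2 = 4,
                       frac_both = 0.4,
                       frac_a_only = 0.3,
                       frac_b_only = 0.3,
                       crowd_fraction = 0,
                       crowd_radius_nm = 450,
                       assemblies_per_crowd = 10,
                       amplitude_mean = c(800, 800),
                       amplitude_sd = c(400, 400),
                       psf_fwhm_nm = 100,
                       background_offset = 2,
                       read_noise_sd = 0.5,
                       detect_prob = 1,
                       seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = as.numeric(pixel_size_nm),
    density_per_um2 = as.numeric(density_per_um2),
    frac_both = as.numeric(frac_both),
    frac_a_only = as.numeric(frac_a_only),
    frac_b_only = as.numeric(frac_b_only),
    crowd_fraction = as.numeric(crowd_fraction),
    crowd_radius_nm = as.numeric(crowd_radius_nm),
    assemblies_per_crowd = as.numeric(assemblies_per_crowd),
    amplitude_mean = rep_len(as.numeric(amplitude_mean), 2L),
    amplitude_sd = rep_len(as.numeric(amplitude_sd), 2L),
    psf_fwhm_nm = as.numeric(psf_fwhm_nm),
    background_offset = as.numeric(background_offset),
    read_noise_sd = as.numeric(read_noise_sd),
    detect_prob = rep_len(as.numeric(detect_prob), 2L),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid sim_config: `%s` %s", field, msg),
         call. = FALSE)
  num_ok <- function(x) length(x) > 0 && all(is.finite(x))
  if (length(cfg$image_size_px) != 2 || any(is.na(cfg$image_size_px)) ||
      any(cfg$image_size_px < 1))
    fail("image_size_px", "must be two positive integers")
  if (!num_ok(cfg$pixel_size_nm) || cfg$pixel_size_nm <= 0)
    fail("pixel_size_nm", "must be positive")
  if (!num_ok(cfg$density_per_um2) || cfg$density_per_um2 <= 0)
    fail("density_per_um2", "must be positive")
  fr <- c(cfg$frac_both, cfg$frac_a_only, cfg$frac_b_only)
  if (!num_ok(fr) || any(fr < 0))
    fail("frac_both/frac_a_only/frac_b_only", "must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9)
    fail("frac_both/frac_a_only/frac_b_only", "must sum to 1")
  if (!num_ok(cfg$crowd_fraction) || cfg$crowd_fraction < 0 ||
      cfg$crowd_fraction > 1)
    fail("crowd_fraction", "must lie in [0, 1]")
  if (!num_ok(cfg$crowd_radius_nm) || cfg$crowd_radius_nm <= 0)
    fail("crowd_radius_nm", "must be positive")
  if (!num_ok(cfg$assemblies_per_crowd) || cfg$assemblies_per_crowd <= 0)
    fail("assemblies_per_crowd", "must be positive")
  if (!num_ok(cfg$amplitude_mean) || any(cfg$amplitude_mean <= 0))
    fail("amplitude_mean", "must be positive")
  if (!num_ok(cfg$amplitude_sd) || any(cfg$amplitude_sd < 0))
    fail("amplitude_sd", "must be non-negative")
  if (!num_ok(cfg$psf_fwhm_nm) || cfg$psf_fwhm_nm <= 0)
    fail("psf_fwhm_nm", "must be positive")
  if (!num_ok(cfg$background_offset) || cfg$background_offset < 0)
    fail("background_offset", "must be non-negative")
  if (!num_ok(cfg$read_noise_sd) || cfg$read_noise_sd < 0)
    fail("read_noise_sd", "must be non-negative")
  if (!num_ok(cfg$detect_prob) || any(cfg$detect_prob <= 0) ||
      any(cfg$detect_prob > 1))
    fail("detect_prob", "must lie in (0, 1]")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  ext <- x$image_size_px * x$pixel_size_nm / 1000
  cat(sprintf("<sim_config> %d x %d px (%.2f x %.2f um), %.3g nm/px\n",
              x$image_size_px[1], x$image_size_px[2], ext[1], ext[2],
              x$pixel_size_nm))
  cat(sprintf("  density %.3g/um^2; composition both/A/B = %.2f/%.2f/%.2f\n",
              x$density_per_um2, x$frac_both, x$frac_a_only, x$frac_b_only))
  cat(sprintf("  crowds: fraction %.2f, radius %.0f nm, mean %.3g per crowd\n",
              x$crowd_fraction, x$crowd_radius_nm, x$assemblies_per_crowd))
  cat(sprintf("  PSF FWHM %.0f nm; background %.3g; read noise %.3g; seed %d\n",
              x$psf_fwhm_nm, x$background_offset, x$read_noise_sd, x$seed))
  invisible(x)
}

# run code with a local, seeded RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample ground-truth assembly positions and composition
#'
#' Draws the latent truth table behind a synthetic image pair. A fraction
#' `1 - crowd_fraction` of assemblies follows complete spatial randomness
#' (a homogeneous Poisson process) over the field; the remaining fraction is
#' generated by a Thomas-type parent-child process: crowd centers are CSR
#' with intensity `crowd_fraction * density / assemblies_per_crowd`, child
#' counts are Poisson(`assemblies_per_crowd`), and children scatter
#' isotropically Gaussian with scale `crowd_radius_nm` about their parent.
#' Children falling outside the field are discarded, so the realized density
#' is slightly edge-deflated when crowds are enabled. Channel membership is
#' i.i.d. from the composition probabilities; per-channel amplitudes are
#' log-normal; per-channel detection flags are Bernoulli(`detect_prob`).
#'
#' @param config a [sim_config()].
#' @return A data frame of class `ground_truth` with columns `id`, `x_nm`,
#'   `y_nm`, `membership` (`"A"`, `"B"`, `"both"`), `amp_a`, `amp_b`
#'   (NA where the channel is not carried), `crowd_id` (NA outside crowds),
#'   `det_a`, `det_b`. The generating `config` is attached as an attribute.
#' @export
sample_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    h_nm <- config$image_size_px[1] * config$pixel_size_nm
    w_nm <- config$image_size_px[2] * config$pixel_size_nm
    area_um2 <- (h_nm / 1000) * (w_nm / 1000)

    # CSR component
    lam_csr <- (1 - config$crowd_fraction) * config$density_per_um2
    n_csr <- stats::rpois(1, lam_csr * area_um2)
    x <- stats::runif(n_csr, 0, w_nm)
    y <- stats::runif(n_csr, 0, h_nm)
    crowd_id <- rep(NA_integer_, n_csr)

    # Thomas component
    lam_par <- config$crowd_fraction * config$density_per_um2 /
      config$assemblies_per_crowd
    n_par <- stats::rpois(1, lam_par * area_um2)
    if (n_par > 0) {
      px <- stats::runif(n_par, 0, w_nm)
      py <- stats::runif(n_par, 0, h_nm)
      nch <- stats::rpois(n_par, config$assemblies_per_crowd)
      for (p in seq_len(n_par)) {
        if (nch[p] == 0) next
        cx <- px[p] + stats::rnorm(nch[p], 0, config$crowd_radius_nm)
        cy <- py[p] + stats::rnorm(nch[p], 0, config$crowd_radius_nm)
        keep <- cx >= 0 & cx < w_nm & cy >= 0 & cy < h_nm
        x <- c(x, cx[keep]); y <- c(y, cy[keep])
        crowd_id <- c(crowd_id, rep(p, sum(keep)))
      }
    }

    n <- length(x)
    membership <- sample(c("both", "A", "B"), n, replace = TRUE,
                         prob = c(config$frac_both, config$frac_a_only,
                                  config$frac_b_only))
    amp_a <- ifelse(membership %in% c("A", "both"),
                    rlnorm_msd(n, config$amplitude_mean[1],
                               config$amplitude_sd[1]), NA_real_)
    amp_b <- ifelse(membership %in% c("B", "both"),
                    rlnorm_msd(n, config$amplitude_mean[2],
                               config$amplitude_sd[2]), NA_real_)
    det_a <- membership %in% c("A", "both") &
      stats::runif(n) <= config$detect_prob[1]
    det_b <- membership %in% c("B", "both") &
      stats::runif(n) <= config$detect_prob[2]

    truth <- data.frame(
      id = seq_len(n), x_nm = x, y_nm = y, membership = membership,
      amp_a = amp_a, amp_b = amp_b, crowd_id = crowd_id,
      det_a = det_a, det_b = det_b
    )
    structure(truth, config = config,
              class = c("ground_truth", "data.frame"))
  })
}

# log-normal draws parameterized by natural-scale mean and sd
rlnorm_msd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d assemblies (%.1f%% both, %.1f%% A-only, %.1f%% B-only, %d in crowds)\n",
    nrow(x), 100 * mean(x$membership == "both"),
    100 * mean(x$membership == "A"), 100 * mean(x$membership == "B"),
    sum(!is.na(x$crowd_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  invisible(x)
}

#' Render one channel of a synthetic image
#'
#' Renders the detected spots of one channel as isotropic 2D Gaussians of
#' FWHM `psf_fwhm_nm` whose integral equals the drawn amplitude, evaluated
#' at pixel centers. With `noise = TRUE` pixel values are
#' `Poisson(signal + background_offset) + Normal(0, read_noise_sd)`,
#' clipped at zero and quantized to 16-bit; with `noise = FALSE` the exact
#' signal image (plus background) is returned unquantized, the deterministic
#' reference used for linearity and size-recovery checks.
#'
#' @param truth a `ground_truth` table from [sample_positions()].
#' @param config the generating [sim_config()].
#' @param channel `"A"` or `"B"`.
#' @param noise logical; apply shot/read noise and 16-bit quantization.
#' @return A [pixel_image()].
#' @export
render_image <- function(truth, config, channel = c("A", "B"), noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  channel <- match.arg(channel)
  h <- config$image_size_px[1]; w <- config$image_size_px[2]
  p <- config$pixel_size_nm
  if (nrow(truth) &&
      (any(truth$x_nm < 0 | truth$x_nm > w * p) ||
       any(truth$y_nm < 0 | truth$y_nm > h * p)))
    stop("truth positions must lie inside the image field", call. = FALSE)
  keep <- if (channel == "A") truth$det_a else truth$det_b
  amp <- if (channel == "A") truth$amp_a else truth$amp_b
  spots <- truth[keep, , drop = FALSE]
  amp <- amp[keep]

  sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / p
  signal <- matrix(0, h, w)
  if (nrow(spots)) {
    r <- ceiling(5 * sigma_px) + 1L
    norm <- 1 / (2 * pi * sigma_px^2)
    for (s in seq_len(nrow(spots))) {
      # spot center in pixel units (pixel k center at k - 0.5)
      cx <- spots$x_nm[s] / p + 0.5
      cy <- spots$y_nm[s] / p + 0.5
      j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
      i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
      if (j0 > j1 || i0 > i1) next
      gx <- exp(-((j0:j1) - cx)^2 / (2 * sigma_px^2))
      gy <- exp(-((i0:i1) - cy)^2 / (2 * sigma_px^2))
      signal[i0:i1, j0:j1] <- signal[i0:i1, j0:j1] +
        amp[s] * norm * (gy %o% gx)
    }
  }
  signal <- signal + config$background_offset
  if (!noise)
    return(pixel_image(signal, p, channel))

  # channel-specific sub-stream so A and B noise are independent but both
  # reproducible from the config seed
  with_seed(config$seed + ifelse(channel == "A", 1L, 2L), {
    v <- stats::rpois(length(signal), signal) +
      stats::rnorm(length(signal), 0, config$read_noise_sd)
    v <- pmin(pmax(round(v), 0), 65535)
    pixel_image(matrix(v, h, w), p, channel)
  })
}

#' Simulate a complete two-channel dataset
#'
#' Convenience method tying [sample_positions()] and [render_image()]
#' together: each simulation draws one truth table and renders both
#' channels. `nsim > 1` returns a list of independent datasets whose seeds
#' are derived from `seed` (or the config seed) by increments of 1000.
#'
#' @param object a [sim_config()].
#' @param nsim number of datasets.
#' @param seed optional integer overriding the config seed.
#' @param noise passed to [render_image()].
#' @param ... unused.
#' @return For `nsim = 1` a list with elements `truth`, `images` (list with
#'   `A` and `B`), and `config`; otherwise a list of such lists.
#' @export
simulate.sim_config <- function(object, nsim = 1, seed = NULL, noise = TRUE,
                                ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  one <- function(s) {
    cfg <- object
    cfg$seed <- as.integer(s)
    truth <- sample_positions(cfg)
    list(truth = truth,
         images = list(A = render_image(truth, cfg, "A", noise = noise),
                       B = render_image(truth, cfg, "B", noise = noise)),
         config = cfg)
  }
  if (nsim == 1) return(one(base_seed))
  lapply(seq_len(nsim) - 1L, function(k) one(base_seed + 1000L * k))
}

#' Write a simulated dataset to disk
#'
#' Writes one 16-bit grayscale TIFF per channel, the truth table as CSV, the
#' configuration as YAML, and a `manifest.json` listing every file with its
#' MD5 checksum. Identical configurations produce byte-identical outputs.
#'
#' @param truth `ground_truth` table.
#' @param images named list of [pixel_image()]s (names become file names).
#' @param outdir output directory, created if needed.
#' @param config the generating [sim_config()] (defaults to the config
#'   attached to `truth`).
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(truth, images, outdir,
                          config = attr(truth, "config")) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outdir),
         call. = FALSE)
  files <- character(0)
  for (ch in names(images)) {
    f <- file.path(outdir, sprintf("channel_%s.tif", ch))
    write_image(images[[ch]], f)
    files <- c(files, f)
  }
  f_truth <- file.path(outdir, "truth.csv")
  write_table_csv(as.data.frame(truth), f_truth)
  f_cfg <- file.path(outdir, "config.yaml")
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), f_cfg)
    files <- c(files, f_cfg)
  }
  files <- c(files, f_truth)
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    n_assemblies = nrow(truth)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
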