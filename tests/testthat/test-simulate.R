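test_that("config validation rejects out-of-range values", {
  expect_error(sim_config(frac_both = 0.5, frac_a_only = 0.5,
                          frac_b_only = 0.5), "sum to 1")
  expect_error(sim_config(crowd_fraction = 1.5), "crowd_fraction")
  expect_error(sim_config(psf_fwhm_nm = -1), "psf_fwhm_nm")
  expect_error(sim_config(detect_prob = 0), "detect_prob")
  expect_error(sim_config(density_per_um2 = Inf), "density_per_um2")
})

test_that("CSR assembly counts follow the Poisson(density * area) law", {
  # 5.12 x 5.12 um field at 4/um^2: lambda * A = 104.8576
  lambda_area <- 4 * 5.12^2
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(image_size_px = c(256L, 256L), density_per_um2 = 4,
                      crowd_fraction = 0, seed = s)
    nrow(sample_positions(cfg))
  }, numeric(1))
  se <- sqrt(lambda_area / 100)
  expect_lt(abs(mean(counts) - lambda_area), 3 * se)
  expect_gt(stats::var(counts), 0)  # it is a draw, not a constant
})

test_that("degenerate composition yields all-both tables", {
  cfg <- sim_config(image_size_px = c(256L, 256L), frac_both = 1,
                    frac_a_only = 0, frac_b_only = 0, seed = 2)
  truth <- sample_positions(cfg)
  expect_true(all(truth$membership == "both"))
  expect_true(all(is.finite(truth$amp_a) & is.finite(truth$amp_b)))
})

test_that("composition fractions converge to the configured probabilities", {
  cfg <- sim_config(image_size_px = c(2048L, 2048L), density_per_um2 = 8,
                    frac_both = 0.4, frac_a_only = 0.35, frac_b_only = 0.25,
                    seed = 3)
  truth <- sample_positions(cfg)
  expect_gt(nrow(truth), 1e4)
  expect_lt(abs(mean(truth$membership == "both") - 0.4), 0.02)
  expect_lt(abs(mean(truth$membership == "A") - 0.35), 0.02)
})

test_that("fully crowded fields carry crowd ids with the right mean size", {
  mean_children <- vapply(1:100, function(s) {
    cfg <- sim_config(image_size_px = c(512L, 512L), density_per_um2 = 4,
                      crowd_fraction = 1, assemblies_per_crowd = 10,
                      seed = s)
    truth <- sample_positions(cfg)
    expect_true(all(!is.na(truth$crowd_id)))
    mean(table(truth$crowd_id))
  }, numeric(1))
  # children are Poisson(10) per crowd; empty crowds and edge-discarded
  # children deflate the observed mean slightly, hence the generous 3 SE on
  # the conditional (nonzero) mean
  expect_lt(abs(mean(mean_children) - 10), 3 * sqrt(10 / 40) / sqrt(100) * 10)
  expect_gt(mean(mean_children), 8.5)
})

test_that("positions always fall inside the field and tables are seeded", {
  cfg <- sim_config(image_size_px = c(128L, 200L), crowd_fraction = 0.5,
                    seed = 9)
  t1 <- sample_positions(cfg)
  t2 <- sample_positions(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$x_nm >= 0 & t1$x_nm < 200 * 20))
  expect_true(all(t1$y_nm >= 0 & t1$y_nm < 128 * 20))
})

test_that("empty-field rendering is Poisson background plus nothing", {
  cfg <- sim_config(image_size_px = c(128L, 128L), background_offset = 10,
                    read_noise_sd = 0, seed = 4)
  truth <- single_spot_truth(100, 100)[0, ]  # zero rows
  img <- render_image(truth, cfg, "A")
  n <- length(img$values)
  expect_lt(abs(mean(img$values) - 10), 3 * sqrt(10 / n))
  # variance consistent with Poisson as well (loose factor-2 band)
  expect_gt(stats::var(as.vector(img$values)), 5)
  expect_lt(stats::var(as.vector(img$values)), 20)
})

test_that("a rendered spot integrates to its amplitude", {
  cfg <- spot_config(background_offset = 0, read_noise_sd = 0)
  # spot exactly on the center of pixel (32, 32), x = y = 630 nm
  truth <- single_spot_truth(630, 630, amp = 1234)
  img <- render_image(truth, cfg, "A", noise = FALSE)
  expect_lt(abs(sum(img$values) - 1234) / 1234, 0.005)
  # peak/total ratio of the pixel-sampled Gaussian: 1 / (2 pi sigma_px^2)
  sigma_px <- 100 / (2 * sqrt(2 * log(2))) / 20
  expect_equal(max(img$values) / sum(img$values),
               1 / (2 * pi * sigma_px^2), tolerance = 1e-3)
})

test_that("noiseless rendering is linear in the amplitudes", {
  cfg <- sim_config(image_size_px = c(128L, 128L), background_offset = 0,
                    seed = 6)
  truth <- sample_positions(cfg)
  img1 <- render_image(truth, cfg, "A", noise = FALSE)
  truth2 <- truth
  truth2$amp_a <- truth2$amp_a * 2
  img2 <- render_image(truth2, cfg, "A", noise = FALSE)
  expect_equal(img2$values, 2 * img1$values, tolerance = 1e-12)
})

test_that("undetected spots are retained in truth but not rendered", {
  cfg <- sim_config(image_size_px = c(256L, 256L), detect_prob = 0.6,
                    background_offset = 0, seed = 8)
  truth <- sample_positions(cfg)
  carries_a <- truth$membership %in% c("A", "both")
  expect_true(any(carries_a & !truth$det_a))  # dropouts recorded
  img <- render_image(truth, cfg, "A", noise = FALSE)
  # spots near the field border lose truncated Gaussian tails, hence the
  # few-percent slack on the total
  expect_lt(abs(sum(img$values) - sum(truth$amp_a[truth$det_a])) /
              sum(truth$amp_a[truth$det_a]), 0.05)
  expect_error(render_image(truth, cfg, "C"), "should be one of")
})

test_that("write_dataset round-trips and is byte-identical across runs", {
  cfg <- sim_config(image_size_px = c(96L, 96L), seed = 5)
  ds <- simulate(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(ds$truth, ds$images, d1, cfg)
  m2 <- write_dataset(ds$truth, ds$images, d2, cfg)
  md5 <- function(m) {
    v <- vapply(m$files, function(f) f$md5, "")
    names(v) <- vapply(m$files, function(f) f$name, "")
    v
  }
  expect_identical(md5(m1), md5(m2))
  # pixel-identical image round trip
  back <- read_image(file.path(d1, "channel_A.tif"))
  expect_equal(back$values, round(ds$images$A$values))
  # truth CSV row count and numeric fidelity
  tt <- utils::read.csv(file.path(d1, "truth.csv"))
  expect_identical(nrow(tt), nrow(ds$truth))
  expect_identical(tt$x_nm, ds$truth$x_nm)
  # checksum changes iff content changes
  writeLines("tampered", file.path(d1, "truth.csv"))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "truth.csv"))),
                         md5(m1)[["truth.csv"]]))
})
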