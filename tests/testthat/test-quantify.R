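test_that("the 5-px measurement ROI is the 13-pixel digital disk", {
  off <- roi_disk_offsets(5)
  expect_identical(nrow(off), 13L)
  expect_true(all(off[, 1]^2 + off[, 2]^2 <= 4))
  # uniform image: ROI mean equals the constant
  expect_equal(roi_mean(matrix(10, 21, 21), c(11, 11), 5), 10)
  # delta of 13 at the center spreads to a mean of 1 over the disk
  m <- matrix(0, 21, 21); m[11, 11] <- 13
  expect_equal(roi_mean(m, c(11, 11), 5), 1)
  expect_error(roi_mean(m, c(1, 1), 5), "border")
})

test_that("background correction preserves sign and simulator truth", {
  expect_identical(background_correct(10, 10), 0)
  expect_identical(background_correct(5, 7), -2)
  # flat simulated background, no noise: corrected intensity of an empty
  # region is zero to machine precision
  cfg <- spot_config(background_offset = 10, read_noise_sd = 0)
  img <- render_image(single_spot_truth(640, 640)[0, ], cfg, "A",
                      noise = FALSE)
  raw <- roi_mean(img, c(32, 32), 5)
  expect_lt(abs(background_correct(raw, 10)), 1e-9)
})

test_that("mass centers are exact on symmetric spots and recover subpixel
           offsets", {
  cfg <- spot_config(background_offset = 0)
  # spot exactly on the center of pixel (32, 32): x = y = 630 nm
  img <- render_image(single_spot_truth(630, 630), cfg, "A", noise = FALSE)
  mc <- mass_center(img, c(32, 32), 5)
  expect_equal(unname(mc), c(630, 630), tolerance = 1e-6)
  # zero-weight footprint falls back to the pixel center
  zero <- pixel_image(matrix(0, 21, 21), 20)
  expect_equal(unname(mass_center(zero, c(11, 11), 5)), c(210, 210))
  # a true subpixel offset of 0.3 px moves the centroid in the right
  # direction; the small window attenuates the displacement (the broad PSF
  # pedestal dilutes the weights), so recovery is partial but deterministic
  img2 <- render_image(single_spot_truth(636, 630), cfg, "A", noise = FALSE)
  mc2 <- mass_center(img2, c(32, 32), 5)
  expect_gt(mc2[["x_nm"]], 630.5)            # moved toward the truth
  expect_lt(mc2[["x_nm"]], 636)              # without overshooting
  expect_lt(abs(mc2[["x_nm"]] - 636) / 20, 0.25)
  expect_error(mass_center(img, c(2, 2), 5), "border")
})

test_that("linescan profiles average across the scan width", {
  # constant image: flat profiles
  pr <- linescan_profiles(matrix(4, 64, 64), c(32, 32))
  expect_identical(length(pr$horizontal), 31L)
  expect_true(all(pr$horizontal == 4) && all(pr$vertical == 4))
  # vertical ridge 3 px wide through pos: the horizontal profile is nonzero
  # exactly at the central indices 14:16, the vertical profile is constant
  m <- matrix(0, 64, 64); m[, 31:33] <- 9
  pr <- linescan_profiles(m, c(32, 32))
  expect_identical(which(pr$horizontal > 0) - 1L, 14:16)
  expect_equal(pr$horizontal[16], 9)  # index 15 (0-based) carries the ridge
  expect_true(all(pr$vertical == 9))
  # isotropic rendered spot: horizontal ~ vertical
  cfg <- spot_config(background_offset = 0)
  img <- render_image(single_spot_truth(630, 630), cfg, "A", noise = FALSE)
  pr <- linescan_profiles(img, c(32, 32))
  expect_equal(pr$horizontal, pr$vertical, tolerance = 1e-9)
  # border: no window
  expect_null(linescan_profiles(m, c(5, 32)))
})

test_that("gaussian profile fits recover exact parameters and flag
           degenerate input", {
  prof <- gauss_profile(A = 20, mu = 15, sigma = 2, b = 1)
  fit <- fit_gaussian_profile(prof)
  expect_equal(unname(coef(fit)), c(20, 15, 2, 1), tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(sum(residuals(fit)^2), 0, tolerance = 1e-12)
  # flat profile: sentinel, never a cluster
  flat <- fit_gaussian_profile(rep(3, 31))
  expect_identical(flat$r2, -Inf)
  expect_false(classify_cluster(flat$r2, flat$mu))
  expect_error(fit_gaussian_profile(c(1, NA, 3)), "finite")
})

test_that("fitted sigma is robust to shot noise on bright spots", {
  cfg <- spot_config(amplitude_mean = 2000, amplitude_sd = 0,
                     background_offset = 2, read_noise_sd = 0.5)
  true_sigma <- 100 / (2 * sqrt(2 * log(2))) / 20
  errs <- c()
  for (s in 1:60) {
    cfg$seed <- s
    truth <- single_spot_truth(640 + (s %% 7) * 3, 640, amp = 2000)
    img <- render_image(truth, cfg, "A", noise = TRUE)
    mx <- find_maxima(img, 4)
    if (!nrow(mx)) next
    pr <- linescan_profiles(img, c(mx$row[1], mx$col[1]))
    fh <- fit_gaussian_profile(pr$horizontal)
    fv <- fit_gaussian_profile(pr$vertical, "vertical")
    best <- if (fv$r2 > fh$r2) fv else fh
    errs <- c(errs, abs(best$sigma - true_sigma) / true_sigma)
  }
  expect_gt(length(errs), 50)
  expect_lt(stats::median(errs), 0.1)
})

test_that("cluster classification applies the strict R2 and centered-peak
           rules", {
  expect_true(classify_cluster(0.95, 15))
  expect_true(classify_cluster(0.81, 20))   # |mu - 15| = 5 allowed
  expect_false(classify_cluster(0.95, 4))   # off-center
  expect_false(classify_cluster(0.95, 20.5))
  expect_false(classify_cluster(0.8, 15))   # strict >
  expect_false(classify_cluster(0.95, 15, border_flag = TRUE))
})

test_that("FWHM follows the closed form and simulator truth", {
  expect_equal(fwhm_nm(2, 20), 2 * sqrt(2 * log(2)) * 2 * 20,
               tolerance = 1e-12)
  expect_equal(fwhm_nm(2, 20), 94.19, tolerance = 1e-3)
  # sigma for a 100 nm PSF at 20 nm/px inverts to 100 nm
  expect_equal(fwhm_nm(100 / (2 * sqrt(2 * log(2))) / 20, 20), 100,
               tolerance = 0.1)
  # noiseless rendered 80 nm spot measures 80 +- 2 nm
  cfg <- spot_config(psf_fwhm_nm = 80, background_offset = 0)
  img <- render_image(single_spot_truth(634, 627), cfg, "A", noise = FALSE)
  mx <- find_maxima(img, 0.5)
  pr <- linescan_profiles(img, c(mx$row[1], mx$col[1]))
  fit <- fit_gaussian_profile(pr$horizontal)
  expect_lt(abs(fwhm_nm(fit, 20) - 80), 2)
})

test_that("measure_maxima ties it together: clusters are maxima and scale
           invariance holds", {
  cfg <- sim_config(image_size_px = c(256L, 256L), background_offset = 0,
                    read_noise_sd = 0, seed = 12)
  ds <- simulate(cfg, noise = FALSE)
  img <- gaussian_blur(ds$images$A, 0.5)
  mx <- find_maxima(img, 4)
  tab <- measure_maxima(img, gaussian_blur(ds$images$B, 0.5), mx)
  expect_identical(nrow(tab), nrow(mx))
  expect_lte(sum(tab$is_cluster), nrow(tab))
  expect_true(all(!tab$is_cluster[tab$border_flag]))
  # clusters satisfy their defining invariants
  cl <- tab[tab$is_cluster, ]
  expect_true(all(cl$r2 > 0.8))
  expect_true(all(abs(cl$mu_px - 15) <= 5))
  expect_equal(cl$fwhm_nm, 2 * sqrt(2 * log(2)) * cl$sigma_px * 20)
  # intensity linearity: scaling image and tolerance by k scales intensities
  k <- 3
  img_k <- pixel_image(img$values * k, 20, "A")
  mx_k <- find_maxima(img_k, 4 * k)
  tab_k <- measure_maxima(img_k, NULL, mx_k)
  expect_identical(nrow(tab_k), nrow(tab))
  expect_equal(tab_k$intensity_self, k * tab$intensity_self,
               tolerance = 1e-9)
  expect_identical(tab_k$is_cluster, tab$is_cluster)
})
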