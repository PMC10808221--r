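test_that("a pure single-Gaussian histogram prefers the single model", {
  x <- 0:20
  hist <- structure(
    data.frame(bin_center = x,
               percent = 30 * exp(-(x - 6)^2 / (2 * 2.5^2))),
    n = 1000L, bin_width = 1,
    class = c("percent_histogram", "data.frame"))
  fit1 <- fit_crowding_mixture(hist, k = 1)
  expect_gte(fit1$r2, 0.999)
  expect_equal(fit1$components$mu, 6, tolerance = 1e-4)
  fit2 <- fit_crowding_mixture(hist, k = 2)
  expect_identical(fit2$model_preferred, "single")
})

test_that("two-component decomposition recovers the crowded area fraction", {
  set.seed(17)
  counts <- mixture_counts(5000)
  fit <- fit_crowding_mixture(counts, k = 2)
  comp <- fit$components
  expect_identical(nrow(comp), 2L)
  expect_lt(comp$mu[1], comp$mu[2])          # ordered means
  expect_equal(sum(comp$area_fraction), 1, tolerance = 1e-9)
  expect_lt(abs(comp$area_fraction[2] - 0.32), 0.05)
  expect_equal(comp$mu[2], 12, tolerance = 0.1 * 12)
  expect_identical(fit$model_preferred, "double")
  # residuals/predict consistency
  expect_equal(predict(fit) + residuals(fit), fit$hist$percent,
               tolerance = 1e-12)
})

test_that("mixture fitting is deterministic and demands enough bins", {
  set.seed(23)
  counts <- mixture_counts(2000)
  f1 <- fit_crowding_mixture(counts, k = 2)
  f2 <- fit_crowding_mixture(counts, k = 2)
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_crowding_mixture(c(1, 1, 2, 2, 3), k = 2),
               "non-empty bins")
})

test_that("crowded-fraction recovery error shrinks with sample size", {
  med_err <- vapply(c(500, 5000), function(n) {
    errs <- vapply(1:20, function(s) {
      set.seed(s)
      f <- fit_crowding_mixture(mixture_counts(n), k = 2)
      abs(f$components$area_fraction[2] - 0.32)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1] + 1e-12)
})

test_that("through-origin regression equals its closed form", {
  x <- c(1, 2, 3, 4); y <- 2 * x
  r <- origin_regression(x, y)
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  expect_equal(unname(coef(r)), 2)
  expect_equal(predict(r, 10), 20)
  # closed form on arbitrary data
  set.seed(5)
  x <- runif(200, 0, 30); y <- runif(200, 0, 30)
  r <- origin_regression(x, y)
  expect_equal(r$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_equal(r$r2, 1 - sum((y - r$slope * x)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("anti-correlated point clouds produce negative R2", {
  set.seed(6)
  x <- c(runif(100, 20, 30), runif(100, 0, 2))
  y <- c(runif(100, 0, 2), runif(100, 20, 30))
  r <- origin_regression(x, y)
  expect_lt(r$r2, 0)
})

test_that("the 2 a.u. noise gate partitions maxima into three fractions", {
  x <- c(5, 5, 5, 1)
  y <- c(5, 1, 2, 9)
  r <- origin_regression(x, y, noise_level = 2)
  # x>2&y>2: 1; x>2&y<=2: 2; x<=2: 1
  expect_equal(r$frac_both, 0.25)
  expect_equal(r$frac_self_only, 0.5)
  expect_equal(r$frac_below_noise, 0.25)
  expect_equal(r$frac_both + r$frac_self_only + r$frac_below_noise, 1)
  # all y at/below noise, all x above
  r2 <- origin_regression(c(3, 4, 5), c(2, 1, 0))
  expect_equal(r2$frac_both, 0)
  expect_equal(r2$frac_self_only, 1)
  # degenerate x
  r3 <- origin_regression(c(0, 0), c(1, 2))
  expect_equal(r3$slope, 0)
  expect_true(is.na(r3$r2))
})

test_that("replicate aggregation reproduces the textbook t-test", {
  vals <- c(1, 2, 3, 4, 5, 6)
  reps <- c("r1", "r2", "r3", "r1", "r2", "r3")
  cond <- rep(c("ctrl", "treated"), each = 3)
  s <- aggregate_replicates(vals, reps, cond)
  expect_equal(abs(s$t), 3.674, tolerance = 1e-3)
  expect_equal(s$p, 0.0214, tolerance = 0.005)
  expect_identical(s$stars, "*")
  expect_equal(s$conditions$ctrl$grand_mean, 2)
  # identical means: t = 0, p = 1, no star
  s0 <- aggregate_replicates(c(1, 2, 3, 1, 2, 3), reps, cond)
  expect_equal(s0$t, 0)
  expect_equal(s0$p, 1)
  expect_identical(s0$stars, "")
  # zero spread
  s4 <- aggregate_replicates(c(4, 4, 4, 5, 5, 5), reps, cond)
  expect_equal(s4$conditions$ctrl$sd, 0)
  # single replicate is an error
  expect_error(aggregate_replicates(c(1, 2), c("r1", "r1"),
                                    c("a", "b")), "single replicate")
})

test_that("per-sheet metrics average within replicate before testing", {
  # two sheets in r1 with values 0 and 4 must count as one mean of 2
  vals <- c(0, 4, 3, 1, 6, 5, 7)
  reps <- c("r1", "r1", "r2", "r3", "r1", "r2", "r3")
  cond <- c("a", "a", "a", "a", "b", "b", "b")
  s <- aggregate_replicates(vals, reps, cond)
  expect_equal(as.vector(sort(s$conditions$a$replicate_means)), c(1, 2, 3))
  expect_equal(s$conditions$b$grand_mean, 6)
})
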