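test_that("crosstalk correction inverts its construction and clips at zero", {
  set.seed(1)
  a <- matrix(runif(400, 0, 100), 20, 20)
  b <- matrix(runif(400, 0, 100), 20, 20)
  long_red <- b + 0.5 * a
  out <- correct_crosstalk(long_red, a, factor = 0.5)
  expect_equal(out$values, b, tolerance = 1e-12)
  # factor 0 is the identity
  expect_equal(correct_crosstalk(long_red, a, factor = 0)$values, long_red)
  # over-subtraction clips at zero
  hot <- matrix(0, 20, 20); hot[5, 5] <- 100
  out2 <- correct_crosstalk(matrix(10, 20, 20), hot, factor = 0.5)
  expect_identical(out2$values[5, 5], 0)
  expect_error(correct_crosstalk(a, matrix(0, 5, 5)), "shape")
  expect_error(correct_crosstalk(a, b, factor = 2), "factor")
})

test_that("gaussian blur preserves constants, mass, and matches the dense
           convolution oracle", {
  const <- matrix(7, 16, 16)
  expect_equal(gaussian_blur(const, 0.5)$values, const, tolerance = 1e-9)
  # sigma 0 returns the input untouched
  set.seed(2)
  m <- matrix(runif(256), 16, 16)
  expect_identical(gaussian_blur(m, 0)$values, m)
  expect_error(gaussian_blur(m, -1), "sigma")
  # interior delta: total conserved
  delta <- matrix(0, 21, 21); delta[11, 11] <- 100
  expect_lt(abs(sum(gaussian_blur(delta, 0.5)$values) - 100) / 100, 1e-6)
  # oracle equivalence (delta and a random image, two sigmas)
  for (sigma in c(0.5, 1.3)) {
    expect_lt(max(abs(gaussian_blur(delta, sigma)$values -
                        blur_oracle(delta, sigma))), 1e-9)
    expect_lt(max(abs(gaussian_blur(m, sigma)$values -
                        blur_oracle(m, sigma))), 1e-9)
  }
})

test_that("find_maxima honors the prominence contract on hand-built cases", {
  # constant image: nothing stands out
  expect_identical(nrow(find_maxima(matrix(5, 10, 10), 2)), 0L)
  # single bright pixel
  m <- matrix(0, 20, 20); m[10, 10] <- 100
  mx <- find_maxima(m, 4)
  expect_identical(nrow(mx), 1L)
  expect_identical(c(mx$row, mx$col), c(10L, 10L))
  # two peaks joined by a saddle: merged below tolerance, split above
  m <- matrix(0, 20, 40)
  m[10, 10] <- 10; m[10, 30] <- 10; m[10, 11:29] <- 8
  expect_identical(nrow(find_maxima(m, 4)), 1L)   # prominence 2 < 4
  expect_identical(nrow(find_maxima(m, 1)), 2L)
  # plateau: exactly one representative near the centroid
  m <- matrix(0, 20, 20); m[8:11, 8:11] <- 5
  mx <- find_maxima(m, 2)
  expect_identical(nrow(mx), 1L)
  expect_true(mx$row %in% 9:10 && mx$col %in% 9:10)
})

test_that("find_maxima is set-identical to the brute-force flood oracle", {
  for (s in 1:40) {
    set.seed(s)
    img <- matrix(sample(0:50, 64 * 64, replace = TRUE), 64, 64)
    tol <- sample(c(2, 5, 10), 1)
    expect_setequal_maxima(find_maxima(img, tol),
                           find_maxima_reference(img, tol))
  }
  # also on smooth (blurred) images where plateaus are rare but floods large
  for (s in 1:10) {
    set.seed(100 + s)
    img <- gaussian_blur(matrix(rpois(64 * 64, 20), 64, 64), 1)$values
    expect_setequal_maxima(find_maxima(img, 1),
                           find_maxima_reference(img, 1))
  }
})

test_that("raising the noise tolerance never adds maxima", {
  for (s in 1:10) {
    set.seed(s)
    img <- gaussian_blur(matrix(rpois(48 * 48, 30), 48, 48), 0.5)$values
    counts <- vapply(c(0.5, 1, 2, 4, 8), function(tol)
      nrow(find_maxima(img, tol)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("maxima positions are translation-equivariant", {
  set.seed(7)
  big <- gaussian_blur(matrix(rpois(80 * 80, 15), 80, 80), 1)$values
  a <- big[1:60, 1:60]
  b <- big[6:65, 4:63]  # shifted crop: rows +5, cols +3
  ma <- find_maxima(a, 2)
  mb <- find_maxima(b, 2)
  # compare interior maxima only (floods near crop borders may differ)
  inner_a <- ma[ma$row > 15 & ma$row <= 50 & ma$col > 13 & ma$col <= 50, ]
  shifted <- paste(inner_a$row - 5, inner_a$col - 3)
  expect_true(all(shifted %in% paste(mb$row, mb$col)))
})

test_that("border handling flags and optionally drops edge maxima", {
  m <- matrix(0, 40, 40)
  m[1, 1] <- 50    # corner maximum
  m[20, 20] <- 50  # interior maximum
  mx <- find_maxima(m, 4)
  expect_identical(nrow(mx), 2L)
  expect_true(mx$border_flag[mx$row == 1])
  expect_false(mx$border_flag[mx$row == 20])
  mx2 <- find_maxima(m, 4, exclude_edge = TRUE)
  expect_identical(nrow(mx2), 1L)
  expect_identical(mx2$row, 20L)
})
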