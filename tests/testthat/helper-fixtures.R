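# shared fixture builders (all generated in code, no stored data)

# a 64x64 config with a single isolated spot field, handy for rendering tests
spot_config <- function(..., seed = 1L) {
  sim_config(image_size_px = c(64L, 64L), density_per_um2 = 1,
             frac_both = 1, frac_a_only = 0, frac_b_only = 0,
             ..., seed = seed)
}

# hand-built truth table with one channel-A spot at (x_nm, y_nm)
single_spot_truth <- function(x_nm, y_nm, amp = 800) {
  data.frame(id = 1L, x_nm = x_nm, y_nm = y_nm, membership = "A",
             amp_a = amp, amp_b = NA_real_, crowd_id = NA_integer_,
             det_a = TRUE, det_b = FALSE)
}

# uniform random points on a [0, w] x [0, h] nm field
csr_points <- function(n, w_nm, h_nm = w_nm) {
  cbind(x_nm = stats::runif(n, 0, w_nm), y_nm = stats::runif(n, 0, h_nm))
}

# noiseless Gaussian linescan profile evaluated at x = 0..30
gauss_profile <- function(A, mu, sigma, b = 0, n = 31) {
  x <- seq_len(n) - 1
  b + A * exp(-(x - mu)^2 / (2 * sigma^2))
}

# dense brute-force 2D convolution of a matrix with a truncated Gaussian
# kernel, reflective boundary; independent oracle for gaussian_blur
blur_oracle <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    period <- 2L * n - 2L
    j <- (i - 1L) %% period
    ifelse(j < n, j + 1L, period - j + 1L)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- refl(i + di, nr); jj <- refl(j + dj, nc)
      acc <- acc + k2[di + r + 1, dj + r + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# draw integer neighbored-maxima counts from a two-Gaussian mixture
mixture_counts <- function(n, w2 = 0.32, mu1 = 3.5, sd1 = 1.8,
                           mu2 = 12, sd2 = 3) {
  n2 <- round(w2 * n)
  pmax(round(c(stats::rnorm(n - n2, mu1, sd1), stats::rnorm(n2, mu2, sd2))),
       0)
}

expect_setequal_maxima <- function(a, b) {
  expect_setequal(paste(a$row, a$col), paste(b[, "row"], b[, "col"]))
}
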