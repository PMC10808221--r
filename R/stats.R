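#' Decompose a neighbored-maxima histogram into Gaussian components
#'
#' Fits `sum_i A_i * exp(-(x - mu_i)^2 / (2 * sigma_i^2))` (k = 1 or 2) by
#' nonlinear least squares to the percentage histogram of neighbor counts,
#' the decomposition that separates unorganized maxima from those
#' agglomerated into arranged crowds. Constraints: `A_i >= 0`,
#' `sigma_i >= 0.5` bins; components are reported with `mu_1 < mu_2`. The
#' two-component fit uses deterministic multi-start initialization (means at
#' the weighted 25th/75th percentiles plus perturbed variants) and keeps the
#' lowest-SSE solution. The area fraction of component i is
#' `A_i * sigma_i / sum_j A_j * sigma_j` (proportional to the area under an
#' unnormalized Gaussian). When both models are fitted, the two-component
#' model is preferred iff an F-test on the SSE reduction (3 extra
#' parameters) passes at `alpha = 0.05`.
#'
#' @param hist a [percent_histogram()] over integer neighbor counts, or an
#'   integer vector of raw counts (then histogrammed with bin width 1).
#' @param k number of Gaussian components, 1 or 2. `k = 2` additionally fits
#'   the single-Gaussian model for the F-test.
#' @return Object of class `crowding_mixture`: list with `components`
#'   (data frame `A`, `mu`, `sigma`, `area_fraction`), `r2`, `sse`,
#'   `model_preferred` (`"single"`/`"double"`), `f_test` (statistic, df, p),
#'   `hist`, `k`.
#' @examples
#' counts <- c(rnorm(3400, 3.5, 1.8), rnorm(1600, 12, 3))
#' counts <- pmax(0, round(counts))
#' fit <- fit_crowding_mixture(counts, k = 2)
#' fit$components
#' @export
fit_crowding_mixture <- function(hist, k = 2) {
  if (!inherits(hist, "percent_histogram")) {
    if (!is.numeric(hist))
      stop("`hist` must be a percent_histogram or numeric counts",
           call. = FALSE)
    hist <- percent_histogram(round(hist), bin_width = 1, origin = -0.5)
  }
  if (!k %in% c(1, 2)) stop("`k` must be 1 or 2", call. = FALSE)
  x <- hist$bin_center
  y <- hist$percent
  nonempty <- sum(y > 0)
  if (k == 2 && nonempty < 6)
    stop("two-component decomposition needs at least 6 non-empty bins",
         call. = FALSE)
  if (k == 1 && nonempty < 3)
    stop("single-component fit needs at least 3 non-empty bins",
         call. = FALSE)

  single <- fit_gauss_sum(x, y, starts_single(x, y))
  if (k == 1) {
    return(new_crowding_mixture(single, NULL, hist, k = 1))
  }
  double <- fit_gauss_sum(x, y, starts_double(x, y))
  new_crowding_mixture(single, double, hist, k = 2)
}

# weighted quantile of histogram bin centers
whist_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

starts_single <- function(x, y) {
  mu <- sum(x * y) / sum(y)
  sd0 <- sqrt(max(sum(y * (x - mu)^2) / sum(y), 0.25))
  list(list(A1 = max(y), mu1 = mu, s1 = sd0))
}

starts_double <- function(x, y) {
  q25 <- whist_quantile(x, y, 0.25)
  q75 <- whist_quantile(x, y, 0.75)
  mu <- sum(x * y) / sum(y)
  sd0 <- sqrt(max(sum(y * (x - mu)^2) / sum(y), 0.25))
  span <- max(diff(range(x)), 1)
  base <- list(A1 = max(y), mu1 = q25, s1 = max(sd0 / 2, 0.6),
               A2 = max(y) / 3, mu2 = q75, s2 = max(sd0 / 2, 0.6))
  jitter1 <- base; jitter1$mu2 <- min(q75 + span / 4, max(x))
  jitter2 <- base; jitter2$mu1 <- max(q25 - span / 8, min(x))
  jitter3 <- base; jitter3$A2 <- max(y); jitter3$s2 <- max(sd0, 0.6)
  list(base, jitter1, jitter2, jitter3)
}

# bounded LM fit of a 1- or 2-Gaussian sum; returns best (lowest SSE) start
fit_gauss_sum <- function(x, y, starts) {
  two <- length(starts[[1]]) == 6
  model <- function(par) {
    out <- par[1] * exp(-(x - par[2])^2 / (2 * par[3]^2))
    if (two) out <- out + par[4] * exp(-(x - par[5])^2 / (2 * par[6]^2))
    out
  }
  lower <- if (two) c(0, min(x), 0.5, 0, min(x), 0.5) else c(0, min(x), 0.5)
  upper <- if (two) c(Inf, max(x), Inf, Inf, max(x), Inf) else
    c(Inf, max(x), Inf)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st),
                         fn = function(par) y - model(par),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(coef = fit$par, sse = sse)
  }
  if (is.null(best))
    stop("mixture fit failed to converge from every start", call. = FALSE)
  cf <- best$coef
  names(cf) <- if (two) c("A1", "mu1", "s1", "A2", "mu2", "s2") else
    c("A1", "mu1", "s1")
  comp <- if (two)
    data.frame(A = c(cf[["A1"]], cf[["A2"]]),
               mu = c(cf[["mu1"]], cf[["mu2"]]),
               sigma = c(cf[["s1"]], cf[["s2"]]))
  else
    data.frame(A = cf[["A1"]], mu = cf[["mu1"]], sigma = cf[["s1"]])
  comp <- comp[order(comp$mu), , drop = FALSE]
  rownames(comp) <- NULL
  comp$area_fraction <- comp$A * comp$sigma / sum(comp$A * comp$sigma)
  sstot <- sum((y - mean(y))^2)
  list(components = comp, sse = best$sse,
       r2 = if (sstot > 0) 1 - best$sse / sstot else NA_real_,
       npar = if (two) 6L else 3L)
}

new_crowding_mixture <- function(single, double, hist, k) {
  nbin <- nrow(hist)
  f_test <- NULL
  preferred <- "single"
  chosen <- single
  if (!is.null(double)) {
    df2 <- nbin - double$npar
    # a numerically perfect single fit cannot be improved meaningfully;
    # guard against F-statistics built from rounding noise
    single_perfect <- single$sse <= 1e-10 * sum(hist$percent^2)
    if (!single_perfect && df2 > 0 && double$sse > 0) {
      f_stat <- ((single$sse - double$sse) / 3) / (double$sse / df2)
      p <- stats::pf(f_stat, 3, df2, lower.tail = FALSE)
      f_test <- list(statistic = f_stat, df = c(3L, df2), p_value = p)
      if (is.finite(p) && p < 0.05) preferred <- "double"
    } else if (!single_perfect) {
      # saturated/perfect double fit: preferred only if it actually improves
      f_test <- list(statistic = Inf, df = c(3L, df2), p_value = 0)
      if (double$sse < single$sse) preferred <- "double"
    }
    chosen <- if (preferred == "double") double else single
    if (k == 2) chosen <- double  # requested model is reported
  }
  structure(list(components = chosen$components, r2 = chosen$r2,
                 sse = chosen$sse, model_preferred = preferred,
                 f_test = f_test, single = single, double = double,
                 hist = hist, k = k),
            class = "crowding_mixture")
}

#' @export
print.crowding_mixture <- function(x, ...) {
  cat(sprintf("<crowding_mixture> %d-component fit, R^2 = %.4f\n",
              nrow(x$components), x$r2))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  component %d: mean %.2f neighbors, sd %.2f, %.1f%% of area\n",
                i, comp$mu[i], comp$sigma[i], 100 * comp$area_fraction[i]))
  if (!is.null(x$f_test))
    cat(sprintf("  model preferred: %s (F = %.3g, p = %.3g)\n",
                x$model_preferred, x$f_test$statistic, x$f_test$p_value))
  invisible(x)
}

#' @export
coef.crowding_mixture <- function(object, ...) {
  comp <- object$components
  out <- unlist(lapply(seq_len(nrow(comp)), function(i)
    stats::setNames(c(comp$A[i], comp$mu[i], comp$sigma[i]),
                    paste0(c("A", "mu", "sigma"), i))))
  out
}

#' @export
predict.crowding_mixture <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$hist$bin_center else as.numeric(newdata)
  comp <- object$components
  rowSums(sapply(seq_len(nrow(comp)), function(i)
    comp$A[i] * exp(-(x - comp$mu[i])^2 / (2 * comp$sigma[i]^2))))
}

#' @export
residuals.crowding_mixture <- function(object, ...)
  object$hist$percent - predict(object)

#' @export
plot.crowding_mixture <- function(x, ...) {
  h <- x$hist
  graphics::plot(h$bin_center, h$percent, type = "s", lwd = 2,
                 xlab = "neighbored maxima", ylab = "% of maxima", ...)
  xx <- seq(min(h$bin_center), max(h$bin_center), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = "purple", lwd = 2, lty = 2)
  comp <- x$components
  cols <- c("darkgreen", "orange")
  for (i in seq_len(nrow(comp)))
    graphics::lines(xx, comp$A[i] *
                      exp(-(xx - comp$mu[i])^2 / (2 * comp$sigma[i]^2)),
                    col = cols[(i - 1) %% 2 + 1], lwd = 1.5)
  invisible(x)
}

#' Through-origin inter-channel intensity regression
#'
#' Linear regression through the origin of the other-channel intensity on
#' the own-channel intensity across all maxima: `slope = sum(xy)/sum(x^2)`,
#' closed form, with `r2 = 1 - sum((y - slope*x)^2) / sum((y - mean(y))^2)`
#' (the about-mean definition, so `r2` can be negative for a through-origin
#' line). Also reports the fractions of maxima partitioned by the intensity
#' noise gate (`<= noise_level` counts as below noise): `frac_both` (both
#' channels above noise), `frac_self_only` (own channel above, other below)
#' and `frac_below_noise` (own channel at or below noise). The three
#' fractions sum to 1.
#'
#' @param x own-channel background-corrected intensities (a.u.).
#' @param y other-channel intensities at the same positions (a.u.).
#' @param noise_level intensity noise gate (a.u., default 2, inclusive).
#' @return Object of class `origin_regression`: `slope`, `r2`, `n`,
#'   `frac_both`, `frac_self_only`, `frac_below_noise`, `noise_level`,
#'   plus the data.
#' @export
origin_regression <- function(x, y, noise_level = 2) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 paired intensities", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) {
    slope <- 0
    r2 <- NA_real_
  } else {
    slope <- sum(x * y) / sxx
    sstot <- sum((y - mean(y))^2)
    r2 <- if (sstot > 0) 1 - sum((y - slope * x)^2) / sstot else NA_real_
  }
  below <- x <= noise_level
  both <- !below & y > noise_level
  self_only <- !below & y <= noise_level
  structure(list(slope = slope, r2 = r2, n = n,
                 frac_both = mean(both),
                 frac_self_only = mean(self_only),
                 frac_below_noise = mean(below),
                 noise_level = noise_level, x = x, y = y),
            class = "origin_regression")
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf(
    "<origin_regression> n = %d: slope %.4g, R^2 = %s\n", x$n, x$slope,
    if (is.na(x$r2)) "undefined" else sprintf("%.3f", x$r2)))
  cat(sprintf(
    "  noise gate %.3g a.u.: %.1f%% both channels, %.1f%% self only, %.1f%% below noise\n",
    x$noise_level, 100 * x$frac_both, 100 * x$frac_self_only,
    100 * x$frac_below_noise))
  invisible(x)
}

#' @export
coef.origin_regression <- function(object, ...) c(slope = object$slope)

#' @export
predict.origin_regression <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$slope * x
}

#' @export
residuals.origin_regression <- function(object, ...)
  object$y - object$slope * object$x

#' @export
plot.origin_regression <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4,
                 xlab = "intensity self (a.u.)",
                 ylab = "intensity other (a.u.)", ...)
  graphics::abline(0, x$slope, lty = 3)
  graphics::abline(v = x$noise_level, h = x$noise_level, lty = 3,
                   col = "gray")
  invisible(x)
}

#' Aggregate per-sheet metrics across biological replicates
#'
#' Averages a per-sheet metric within each biological replicate, then
#' summarizes replicate means per condition as grand mean +/- SD, and tests
#' two conditions against each other with a two-sided, unpaired,
#' equal-variance Student's t-test on the replicate means (Welch available
#' via `welch = TRUE`). Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param values numeric per-sheet metric.
#' @param replicate replicate identifier per sheet.
#' @param condition condition label per sheet (exactly 2 levels for the
#'   test; a single condition summarizes without a test).
#' @param welch use Welch's unequal-variance t-test instead.
#' @return Object of class `replicate_summary`: per-condition tables of
#'   replicate means, grand means, SDs, and (for two conditions) `t`, `p`,
#'   `stars`.
#' @export
aggregate_replicates <- function(values, replicate, condition, welch = FALSE) {
  df <- data.frame(value = as.numeric(values),
                   replicate = as.character(replicate),
                   condition = as.character(condition))
  df <- df[is.finite(df$value), , drop = FALSE]
  conds <- unique(df$condition)
  per_cond <- lapply(conds, function(cc) {
    sub <- df[df$condition == cc, , drop = FALSE]
    means <- tapply(sub$value, sub$replicate, mean)
    if (length(means) < 2)
      stop(sprintf(
        "condition '%s' has a single replicate: SD undefined", cc),
        call. = FALSE)
    list(replicate_means = means, grand_mean = mean(means),
         sd = stats::sd(means))
  })
  names(per_cond) <- conds
  tt <- NULL
  if (length(conds) == 2) {
    a <- per_cond[[1]]$replicate_means
    b <- per_cond[[2]]$replicate_means
    tt <- tryCatch(
      stats::t.test(a, b, var.equal = !welch, alternative = "two.sided"),
      error = function(e) {
        # zero within-group variance: the statistic degenerates to 0 (equal
        # means) or +-Inf (different means)
        d <- mean(a) - mean(b)
        list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
             p.value = if (d == 0) 1 else 0)
      })
  }
  structure(list(conditions = per_cond,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 stars = if (is.null(tt)) "" else p_stars(tt$p.value),
                 welch = welch),
            class = "replicate_summary")
}

p_stars <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary>\n")
  for (cc in names(x$conditions)) {
    s <- x$conditions[[cc]]
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d replicates)\n",
                cc, s$grand_mean, s$sd, length(s$replicate_means)))
  }
  if (is.finite(x$p))
    cat(sprintf("  %s t-test: t = %.4g, p = %.4g %s\n",
                if (x$welch) "Welch" else "Student", x$t, x$p,
                x$stars))
  invisible(x)
}
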