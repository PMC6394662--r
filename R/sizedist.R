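#' Build a colony-size histogram
#'
#' Bins positive sizes into equal-width bins spanning `[0, max(size) *
#' 1.001]`. With `n_bins = "auto"` the bin count follows the
#' Freedman-Diaconis rule clamped to \[5, 100\]. Densities are counts
#' normalised so that `sum(density * bin_width) == 1`, making the
#' histogram directly comparable to a probability density.
#'
#' @param sizes numeric vector of positive colony sizes (any consistent
#'   unit).
#' @param n_bins number of bins (>= 2) or `"auto"`.
#' @return Object of class `size_histogram`: `bin_edges` (length B + 1),
#'   `counts`, `densities`, `mids`, `n_total`, `unit`.
#' @param unit optional unit label carried through to plots.
#' @export
build_histogram <- function(sizes, n_bins = "auto", unit = "pixel^2") {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) abort_validation("no sizes to bin")
  if (anyNA(sizes) || any(sizes <= 0))
    abort_validation("all sizes must be positive")
  if (identical(n_bins, "auto")) {
    iqr <- stats::IQR(sizes)
    if (iqr > 0) {
      width <- 2 * iqr / length(sizes)^(1 / 3)
      n_bins <- ceiling(max(sizes) * 1.001 / width)
    } else {
      n_bins <- 5
    }
    n_bins <- min(max(n_bins, 5), 100)
  }
  check_number(n_bins, "n_bins", lower = 2)
  n_bins <- as.integer(n_bins)
  edges <- seq(0, max(sizes) * 1.001, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(sizes, edges, rightmost.closed = FALSE),
                     nbins = n_bins)
  width <- diff(edges)
  structure(list(bin_edges = edges, counts = counts,
                 densities = counts / (sum(counts) * width),
                 mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 n_total = length(sizes), unit = unit),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %d sizes in %d bins over [0, %.4g] %s\n",
              x$n_total, length(x$counts), max(x$bin_edges), x$unit))
  invisible(x)
}

#' Weibull model density
#'
#' The three-parameter form fitted to colony-size histograms:
#' `f(x) = c * (a / b^a) * x^(a-1) * exp(-(x/b)^a)`, i.e. a Weibull density
#' with shape `a` and scale `b` times an amplitude `c`. With `c = 1` it
#' integrates to 1; `a = 1` reduces to the exponential `c/b * exp(-x/b)`.
#'
#' @param x size values (>= 0).
#' @param a shape (> 0).
#' @param b scale (> 0), in size units.
#' @param c amplitude (> 0).
#' @return Density values at `x`.
#' @export
weibull_density <- function(x, a, b, c = 1) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  check_number(c, "c", lower = 0, strict_lower = TRUE)
  if (any(x < 0)) abort_validation("`x` must be >= 0")
  ifelse(x == 0 & a < 1, Inf,
         ifelse(x == 0, c * (a / b^a) * (if (a == 1) 1 else 0),
                c * (a / b^a) * x^(a - 1) * exp(-(x / b)^a)))
}

#' Gaussian model density
#'
#' `f(x) = A * 1/(sqrt(2*pi)*sigma) * exp(-((x - mu)/(sqrt(2)*sigma))^2)`;
#' with amplitude `A = 1` this is the normal density.
#'
#' @param x values.
#' @param mu mean.
#' @param sigma standard deviation (> 0).
#' @param amplitude scale factor (> 0).
#' @return Density values at `x`.
#' @export
gaussian_density <- function(x, mu, sigma, amplitude = 1) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  amplitude / (sqrt(2 * pi) * sigma) * exp(-((x - mu) / (sqrt(2) * sigma))^2)
}

#' Weibull mean and variance from shape and scale
#'
#' `mu = b * Gamma(1 + 1/a)` and
#' `V = b^2 * (Gamma(1 + 2/a) - Gamma(1 + 1/a)^2)`, with `sigma = sqrt(V)`.
#' These are the quantities reported alongside a fitted colony-size
#' distribution.
#'
#' @param a shape (> 0).
#' @param b scale (> 0).
#' @return List with `mu`, `V`, `sigma`.
#' @export
weibull_moments <- function(a, b) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  g1 <- gamma(1 + 1 / a)
  g2 <- gamma(1 + 2 / a)
  V <- b^2 * (g2 - g1^2)
  list(mu = b * g1, V = V, sigma = sqrt(V))
}

#' Area of a circular colony from its diameter
#'
#' Converts a manually measured colony diameter (e.g. ruler measurements
#' on a scan) to an area under the circular-colony assumption:
#' `pi * (d / 2)^2`.
#'
#' @param d diameter (>= 0).
#' @return Area in squared diameter units.
#' @export
area_from_diameter <- function(d) {
  if (any(d < 0)) abort_validation("diameter must be >= 0")
  pi * (d / 2)^2
}

## Moment summaries of a histogram (counts at bin mids); used to
## initialise the nonlinear fits.
hist_moments <- function(hist) {
  w <- hist$counts / sum(hist$counts)
  m <- sum(w * hist$mids)
  v <- sum(w * (hist$mids - m)^2)
  list(mean = m, sd = sqrt(max(v, .Machine$double.eps)))
}

## Solve Gamma(1+2/a)/Gamma(1+1/a)^2 = 1 + cv^2 for the Weibull shape.
shape_from_cv <- function(cv) {
  cv <- min(max(cv, 1e-3), 10)
  f <- function(a) gamma(1 + 2 / a) / gamma(1 + 1 / a)^2 - 1 - cv^2
  tryCatch(stats::uniroot(f, lower = 0.12, upper = 50, tol = 1e-10)$root,
           error = function(e) 1.5)
}

n_nonempty <- function(hist) sum(hist$counts > 0)

lm_fit <- function(residual_fun, start, lower) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                     ptol = 1e-10)
  fit <- minpack.lm::nls.lm(par = start, fn = residual_fun,
                            lower = lower, control = ctrl)
  list(par = fit$par,
       residual_ss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

#' Fit the Weibull model to a size histogram
#'
#' Levenberg-Marquardt least squares of the Weibull model density (shape
#' `a`, scale `b`, amplitude `c`) against the normalised bin densities at
#' bin centres. Initialisation is by method of moments on the binned data:
#' the shape is solved from the coefficient of variation by root finding,
#' the scale from the mean, `c` starts at 1. On a proper density `c`
#' converges near 1; leaving it free absorbs binning artefacts, while
#' `fix_c = TRUE` pins it to 1 for a strict two-parameter fit. The derived
#' mean and spread come from [weibull_moments()].
#'
#' @param hist a [build_histogram()] result with at least 5 non-empty bins.
#' @param fix_c logical; fit with amplitude fixed at 1.
#' @return Object of class `weibull_fit`: `a`, `b`, `c`, `mu`, `sigma`,
#'   `V`, `residual_ss`, `converged`, `n`.
#' @export
fit_weibull <- function(hist, fix_c = FALSE) {
  stopifnot(inherits(hist, "size_histogram"))
  if (n_nonempty(hist) < 5)
    abort_input("need at least 5 non-empty bins to fit", class = "colonysizer_insufficient_data")
  mo <- hist_moments(hist)
  a0 <- shape_from_cv(mo$sd / mo$mean)
  b0 <- mo$mean / gamma(1 + 1 / a0)
  x <- hist$mids; y <- hist$densities
  model <- function(a, b, cc) cc * (a / b^a) * x^(a - 1) * exp(-(x / b)^a)
  if (fix_c) {
    resid <- function(p) y - model(p[["a"]], p[["b"]], 1)
    res <- lm_fit(resid, c(a = a0, b = b0), lower = c(1e-3, 1e-9))
  } else {
    resid <- function(p) y - model(p[["a"]], p[["b"]], p[["c0"]])
    res <- lm_fit(resid, c(a = a0, b = b0, c0 = 1), lower = c(1e-3, 1e-9, 1e-9))
  }
  a <- res$par[["a"]]; b <- res$par[["b"]]
  cc <- if (fix_c) 1 else res$par[["c0"]]
  mom <- weibull_moments(a, b)
  structure(list(a = a, b = b, c = cc, mu = mom$mu, sigma = mom$sigma,
                 V = mom$V, residual_ss = res$residual_ss,
                 converged = res$converged, n = hist$n_total),
            class = "weibull_fit")
}

#' Fit the Gaussian model to a size histogram
#'
#' Least-squares fit of the amplitude-scaled normal density to the bin
#' densities at bin centres, initialised at the binned sample mean and
#' standard deviation.
#'
#' @inheritParams fit_weibull
#' @param fix_amplitude logical; fit with amplitude fixed at 1.
#' @return Object of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `residual_ss`, `converged`, `n`.
#' @export
fit_gaussian <- function(hist, fix_amplitude = FALSE) {
  stopifnot(inherits(hist, "size_histogram"))
  if (n_nonempty(hist) < 5)
    abort_input("need at least 5 non-empty bins to fit", class = "colonysizer_insufficient_data")
  mo <- hist_moments(hist)
  x <- hist$mids; y <- hist$densities
  resid <- if (fix_amplitude) {
    function(p) y - 1 / (sqrt(2 * pi) * p[["s"]]) *
      exp(-((x - p[["m"]]) / (sqrt(2) * p[["s"]]))^2)
  } else {
    function(p) y - p[["A"]] / (sqrt(2 * pi) * p[["s"]]) *
      exp(-((x - p[["m"]]) / (sqrt(2) * p[["s"]]))^2)
  }
  start <- if (fix_amplitude) c(m = mo$mean, s = mo$sd)
           else c(m = mo$mean, s = mo$sd, A = 1)
  res <- lm_fit(resid, start,
                lower = if (fix_amplitude) c(-Inf, 1e-9) else c(-Inf, 1e-9, 1e-9))
  structure(list(mu = res$par[["m"]], sigma = res$par[["s"]],
                 amplitude = if (fix_amplitude) 1 else res$par[["A"]],
                 residual_ss = res$residual_ss, converged = res$converged,
                 n = hist$n_total),
            class = "gaussian_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> a = %.4g, b = %.4g, c = %.4g | mu = %.4g, sigma = %.4g (%s)\n",
    x$a, x$b, x$c, x$mu, x$sigma,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.4g, sigma = %.4g, A = %.4g (%s)\n",
              x$mu, x$sigma, x$amplitude,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Compare colony-size distributions between groups
#'
#' Fits the Weibull model to each group's sizes and tabulates, per group,
#' the sample size, fitted mean and spread, and the raw sample mean,
#' together with pairwise differences of the fitted means. Groups whose
#' fit did not converge are flagged and excluded from the pairwise table.
#'
#' @param size_groups named list of numeric size vectors (>= 2 groups).
#' @param n_bins bins per histogram, or `"auto"`.
#' @param fix_c passed to [fit_weibull()].
#' @return Object of class `group_comparison`: `table` (per-group data
#'   frame), `pairwise` (data frame of mean differences), `fits` (list of
#'   `weibull_fit`), `histograms`.
#' @export
compare_groups <- function(size_groups, n_bins = "auto", fix_c = FALSE) {
  if (!is.list(size_groups) || length(size_groups) < 2L)
    abort_validation("need at least 2 groups")
  if (is.null(names(size_groups)) || any(!nzchar(names(size_groups))))
    names(size_groups) <- paste0("group", seq_along(size_groups))
  hists <- lapply(size_groups, build_histogram, n_bins = n_bins)
  fits <- lapply(hists, function(h)
    tryCatch(fit_weibull(h, fix_c = fix_c),
             colonysizer_insufficient_data = function(e) NULL))
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  tab <- data.frame(
    group = names(size_groups),
    n = vapply(size_groups, length, integer(1)),
    mu = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$mu, numeric(1)),
    sigma = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$sigma, numeric(1)),
    sample_mean = vapply(size_groups, mean, numeric(1)),
    converged = ok,
    row.names = NULL
  )
  pairs <- utils::combn(which(ok), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(group_a = tab$group[p[1L]], group_b = tab$group[p[2L]],
               mu_diff = tab$mu[p[1L]] - tab$mu[p[2L]])
  }))
  if (is.null(pairwise))
    pairwise <- data.frame(group_a = character(0), group_b = character(0),
                           mu_diff = numeric(0))
  structure(list(table = tab, pairwise = pairwise, fits = fits,
                 histograms = hists),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$table)
  invisible(x)
}

#' Plot a size histogram with fitted curves
#'
#' Draws the normalised colony-size histogram and overlays fitted Weibull
#' and/or Gaussian model curves, annotating the Weibull-derived mean and
#' spread.
#'
#' @param x a `size_histogram`.
#' @param weibull optional `weibull_fit` to overlay.
#' @param gaussian optional `gaussian_fit` to overlay.
#' @param main plot title.
#' @param ... passed to [graphics::plot.default()] via barplot setup.
#' @return Invisibly, `x`.
#' @export
plot.size_histogram <- function(x, weibull = NULL, gaussian = NULL,
                                main = "Colony size distribution", ...) {
  edges <- x$bin_edges
  graphics::plot(NA, xlim = range(edges), ylim = c(0, max(x$densities) * 1.15),
                 xlab = sprintf("colony size [%s]", x$unit),
                 ylab = "density", main = main, ...)
  graphics::rect(edges[-length(edges)], 0, edges[-1L], x$densities,
                 col = "grey85", border = "grey40")
  xx <- seq(min(edges), max(edges), length.out = 400)
  leg <- character(0); cols <- character(0)
  if (!is.null(weibull)) {
    graphics::lines(xx, weibull_density(xx, weibull$a, weibull$b, weibull$c),
                    col = "firebrick", lwd = 2)
    leg <- c(leg, sprintf("Weibull: mu = %.3g, sigma = %.3g",
                          weibull$mu, weibull$sigma))
    cols <- c(cols, "firebrick")
  }
  if (!is.null(gaussian)) {
    graphics::lines(xx, gaussian_density(xx, gaussian$mu, gaussian$sigma,
                                         gaussian$amplitude),
                    col = "steelblue", lwd = 2, lty = 2)
    leg <- c(leg, sprintf("Gaussian: mu = %.3g, sigma = %.3g",
                          gaussian$mu, gaussian$sigma))
    cols <- c(cols, "steelblue")
  }
  if (length(leg))
    graphics::legend("topright", legend = leg, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Plot group means with error bars
#'
#' Bar summary of fitted mean colony size per group with +/- one fitted
#' standard deviation whiskers.
#'
#' @param cmp a [compare_groups()] result.
#' @param main plot title.
#' @return Invisibly, `cmp`.
#' @export
plot_group_means <- function(cmp, main = "Mean colony size by group") {
  stopifnot(inherits(cmp, "group_comparison"))
  tab <- cmp$table
  ylim <- c(0, max(tab$mu + tab$sigma, na.rm = TRUE) * 1.1)
  bp <- graphics::barplot(tab$mu, names.arg = tab$group, ylim = ylim,
                          ylab = "fitted mean size", main = main,
                          col = "grey80")
  graphics::arrows(bp, tab$mu - tab$sigma, bp, tab$mu + tab$sigma,
                   angle = 90, code = 3, length = 0.06)
  invisible(cmp)
}
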