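# helper: a size_histogram whose densities are an exact model curve,
# with counts consistent enough for moment-based initialisation
exact_histogram <- function(edges, density_fun, n_total = 10000) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- density_fun(mids)
  width <- diff(edges)
  counts <- round(dens * width * n_total)
  structure(list(bin_edges = edges, counts = counts, densities = dens,
                 mids = mids, n_total = sum(counts), unit = "pixel^2"),
            class = "size_histogram")
}

test_that("histograms bin correctly and normalise to unit area", {
  h <- build_histogram(c(10, 10, 10, 10), n_bins = 5)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$counts), 4L)
  expect_equal(sum(h$counts), 4L)

  set.seed(2)
  bin_choices <- list(5, 12, 23, 40, "auto")
  for (i in 1:5) {
    sizes <- rlnorm(200, 4, 0.7)
    h <- build_histogram(sizes, n_bins = bin_choices[[i]])
    expect_equal(sum(h$densities * diff(h$bin_edges)), 1, tolerance = 1e-12)
    expect_equal(sum(h$counts), length(sizes))
    expect_true(all(diff(h$bin_edges) > 0))
  }
  expect_error(build_histogram(numeric(0)), class = "colonysizer_validation_error")
  expect_error(build_histogram(c(1, -2)), class = "colonysizer_validation_error")
  expect_error(build_histogram(1:10, n_bins = 1), class = "colonysizer_validation_error")
})

test_that("uniform draws fill bins within binomial sampling bounds", {
  set.seed(123)
  x <- runif(10000, 0, 100)
  h <- build_histogram(x, n_bins = 10)
  sd_bin <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(h$counts - 1000) < 4 * sd_bin))
})

test_that("the Weibull density matches its closed forms and integrates to 1", {
  expect_equal(weibull_density(0, a = 1, b = 1, c = 1), 1)
  expect_equal(weibull_density(1, a = 2, b = 1, c = 1), 2 * exp(-1))
  for (ab in list(c(0.5, 2), c(1.5, 300), c(3, 50))) {
    int <- integrate(function(x) weibull_density(x, ab[1], ab[2], 1),
                     0, Inf, rel.tol = 1e-10)
    expect_equal(int$value, 1, tolerance = 1e-6)
    # agrees with the standard Weibull density
    xs <- seq(0.01, 5 * ab[2], length.out = 50)
    expect_equal(weibull_density(xs, ab[1], ab[2], 1),
                 dweibull(xs, shape = ab[1], scale = ab[2]), tolerance = 1e-12)
  }
  expect_error(weibull_density(1, a = -1, b = 1), class = "colonysizer_validation_error")
})

test_that("Weibull moments match closed forms and quadrature", {
  m <- weibull_moments(1, 7)
  expect_identical(m$mu, 7)
  expect_identical(m$sigma, 7)

  m2 <- weibull_moments(2, 1)
  expect_equal(m2$mu, sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(m2$V, 1 - pi / 4, tolerance = 1e-12)

  for (a in c(0.5, 1, 2, 5)) {
    b <- 300
    m <- weibull_moments(a, b)
    mu_q <- integrate(function(x) x * dweibull(x, a, b), 0, Inf,
                      rel.tol = 1e-12)$value
    V_q <- integrate(function(x) (x - mu_q)^2 * dweibull(x, a, b), 0, Inf,
                     rel.tol = 1e-12)$value
    expect_equal(m$mu, mu_q, tolerance = 1e-6)
    expect_equal(m$V, V_q, tolerance = 1e-6)
  }
})

test_that("area_from_diameter applies the circle formula", {
  expect_equal(area_from_diameter(2), pi)
  expect_identical(area_from_diameter(0), 0)
  expect_equal(area_from_diameter(10), 25 * pi)
  expect_error(area_from_diameter(-1), class = "colonysizer_validation_error")
})

test_that("noiseless model histograms are recovered to 1e-4", {
  edges <- seq(0, 1200, length.out = 41)
  h <- exact_histogram(edges, function(x) weibull_density(x, 2, 400, 1))
  fit <- fit_weibull(h)
  expect_true(fit$converged)
  expect_rel_equal(c(fit$a, fit$b, fit$c), c(2, 400, 1), 1e-4)

  hg <- exact_histogram(seq(-5, 5, length.out = 41),
                        function(x) gaussian_density(x, 0, 1))
  fg <- fit_gaussian(hg)
  expect_true(fg$converged)
  expect_lt(abs(fg$mu), 1e-6)
  expect_lt(abs(fg$sigma - 1), 1e-6)
})

test_that("sampled Weibull data recover parameters within 10%", {
  set.seed(77)
  x <- rweibull(5000, shape = 1.8, scale = 300)
  fit <- fit_weibull(build_histogram(x, n_bins = 30))
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 1.8) / 1.8, 0.10)
  expect_lt(abs(fit$b - 300) / 300, 0.10)
  expect_lt(abs(fit$mu - mean(x)) / mean(x), 0.05)
})

test_that("exponential-limit fits report mu = sigma = b exactly", {
  edges <- seq(0, 2000, length.out = 31)
  h <- exact_histogram(edges, function(x) weibull_density(x, 1, 250, 1))
  fit <- fit_weibull(h)
  # Gamma(2) = 1 and Gamma(3) = 2, so at shape 1 the moments are the scale
  mom <- weibull_moments(1, fit$b)
  expect_identical(mom$mu, fit$b)
  expect_equal(mom$sigma, fit$b, tolerance = 1e-15)
  # and the fit itself sits at the exponential limit
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$mu, fit$b, tolerance = 1e-9)
  expect_equal(fit$sigma, fit$b, tolerance = 1e-9)
})

test_that("sampled Gaussian data recover mean and spread", {
  set.seed(88)
  x <- rnorm(5000, 500, 80)
  fit <- fit_gaussian(build_histogram(x, n_bins = 30))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 500) / 500, 0.02)
  expect_lt(abs(fit$sigma - 80) / 80, 0.05)
})

test_that("symmetric histograms fit a centred Gaussian", {
  edges <- seq(-3, 3, length.out = 7)
  mids <- (edges[-1] + edges[-7]) / 2
  dens <- c(0.05, 0.15, 0.3, 0.3, 0.15, 0.05)
  h <- structure(list(bin_edges = edges, counts = round(dens * 1000),
                      densities = dens / sum(dens * diff(edges)),
                      mids = mids, n_total = 1000, unit = "pixel^2"),
                 class = "size_histogram")
  fit <- fit_gaussian(h)
  expect_lt(abs(fit$mu), 1e-8)
})

test_that("too few populated bins raise an insufficient-data error", {
  h <- build_histogram(c(10, 10.1, 9.9), n_bins = 8)
  expect_error(fit_weibull(h), class = "colonysizer_insufficient_data")
  expect_error(fit_gaussian(h), class = "colonysizer_insufficient_data")
})

test_that("fits are scale-equivariant", {
  set.seed(55)
  x <- rweibull(3000, shape = 2.2, scale = 150)
  f1 <- fit_weibull(build_histogram(x, n_bins = 25))
  k <- 7.5
  f2 <- fit_weibull(build_histogram(k * x, n_bins = 25))
  expect_lt(abs(f2$a - f1$a) / f1$a, 0.01)
  expect_lt(abs(f2$b - k * f1$b) / (k * f1$b), 0.01)
  expect_lt(abs(f2$mu - k * f1$mu) / (k * f1$mu), 0.01)
})

test_that("group comparison orders means and excludes failed groups", {
  set.seed(99)
  grp <- list(hi = rweibull(2000, 2, 400),
              lo = rweibull(2000, 2, 200))
  cmp <- compare_groups(grp)
  expect_true(cmp$table$mu[1] > cmp$table$mu[2])
  expect_lt(abs(cmp$table$mu[1] / cmp$table$mu[2] - 2), 0.15 * 2)
  expect_equal(nrow(cmp$pairwise), 1L)

  # identical groups: zero difference
  set.seed(1); a <- rweibull(1000, 1.8, 300)
  cmp2 <- compare_groups(list(g1 = a, g2 = a))
  expect_equal(cmp2$pairwise$mu_diff, 0, tolerance = 1e-9)

  # a 3-observation group cannot be fitted and drops out of the pairwise table
  set.seed(2)
  cmp3 <- compare_groups(list(a = rweibull(1000, 2, 300),
                              b = rweibull(1000, 2, 300),
                              tiny = c(10, 20, 30)))
  expect_false(cmp3$table$converged[cmp3$table$group == "tiny"])
  expect_equal(nrow(cmp3$pairwise), 1L)
  expect_false(any(cmp3$pairwise$group_a == "tiny" | cmp3$pairwise$group_b == "tiny"))
})
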