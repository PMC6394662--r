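#' Specification of a synthetic scanned plate
#'
#' Describes everything needed to render a reproducible scan of a stained
#' culture dish: a light dish on a darker surround with an optional dark
#' rim annulus, purple-blue stained colonies as soft-edged discs, a linear
#' illumination gradient, and per-pixel Gaussian sensor noise. Colony
#' radii are drawn from a configurable law; a fraction of colonies is
#' placed as touching pairs to exercise watershed splitting. The same spec
#' and seed always render bit-identical images.
#'
#' @param image_size `(H, W)` in pixels.
#' @param dpi nominal resolution written to the output metadata and used
#'   by the automatic pipeline parameters.
#' @param n_colonies target colony count (>= 0).
#' @param radius_law list with `family` in `{"weibull", "lognormal",
#'   "fixed"}` and its parameters (`shape`/`scale`, `meanlog`/`sdlog`, or
#'   `value`), in pixels.
#' @param overlap_fraction fraction of colonies placed as equal-radius
#'   touching pairs (centre distance 1.5 x radius), in \[0, 1\].
#' @param contrast mean intensity gap (gray levels) between background and
#'   colony, averaged over channels.
#' @param gradient_amplitude peak-to-peak amplitude (gray levels) of a
#'   linear illumination tilt across the dish.
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param stain_color RGB triple of the fully stained colony tint;
#'   default is a Giemsa-like purple-blue, which makes the green channel
#'   the highest-contrast one.
#' @param rim draw a dark rim annulus at the dish border.
#' @param seed pseudo-random seed for placement, radii and noise.
#' @return Object of class `synthetic_plate_spec`.
#' @export
synthetic_plate_spec <- function(image_size = c(512, 512),
                                 dpi = 800,
                                 n_colonies = 50,
                                 radius_law = list(family = "lognormal",
                                                   meanlog = log(8), sdlog = 0.2),
                                 overlap_fraction = 0,
                                 contrast = 120,
                                 gradient_amplitude = 8,
                                 noise_sd = 3,
                                 stain_color = c(95, 70, 160),
                                 rim = TRUE,
                                 seed = 1) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32))
  check_number(dpi, "dpi", lower = 0, strict_lower = TRUE)
  check_number(n_colonies, "n_colonies", lower = 0)
  check_number(overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
  check_number(contrast, "contrast", lower = 0)
  check_number(gradient_amplitude, "gradient_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(stain_color) == 3L, all(stain_color >= 0 & stain_color <= 255))
  validate_radius_law(radius_law)
  structure(list(image_size = as.integer(image_size), dpi = dpi,
                 n_colonies = as.integer(n_colonies),
                 radius_law = radius_law,
                 overlap_fraction = overlap_fraction, contrast = contrast,
                 gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
                 stain_color = stain_color, rim = isTRUE(rim),
                 seed = as.integer(seed)),
            class = "synthetic_plate_spec")
}

validate_radius_law <- function(law) {
  if (!is.list(law) || is.null(law$family))
    abort_validation("`radius_law` must be a list with a `family` element")
  switch(law$family,
         weibull = {
           check_number(law$shape, "radius_law$shape", lower = 0, strict_lower = TRUE)
           check_number(law$scale, "radius_law$scale", lower = 0, strict_lower = TRUE)
         },
         lognormal = {
           check_number(law$meanlog, "radius_law$meanlog")
           check_number(law$sdlog, "radius_law$sdlog", lower = 0)
         },
         fixed = check_number(law$value, "radius_law$value", lower = 0,
                              strict_lower = TRUE),
         abort_validation(sprintf("unknown radius law family '%s'", law$family)))
  invisible(law)
}

draw_radii <- function(law, n) {
  switch(law$family,
         weibull = stats::rweibull(n, shape = law$shape, scale = law$scale),
         lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
         fixed = rep(law$value, n))
}

#' Sample colony areas from a radius law
#'
#' Draws `n` colony radii from the given law and returns the corresponding
#' circular areas `pi * r^2`. Deterministic under a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param law radius law as in [synthetic_plate_spec()].
#' @param n number of colonies (>= 1).
#' @param seed pseudo-random seed.
#' @return Numeric vector of `n` areas (pixel^2).
#' @export
sample_sizes <- function(law, n, seed = 1) {
  check_number(n, "n", lower = 1)
  validate_radius_law(law)
  with_seed(seed, pi * draw_radii(law, n)^2)
}

## Place colony centres inside the usable dish interior: singles by
## rejection sampling with a clearance margin, pairs as touching twins at
## centre distance 1.5 x mean pair radius.
place_colonies <- function(spec, dish_center, dish_radius) {
  n <- spec$n_colonies
  if (n == 0L)
    return(data.frame(center_r = numeric(0), center_c = numeric(0),
                      radius = numeric(0)))
  radii <- pmax(draw_radii(spec$radius_law, n), 2)
  n_pairs <- floor(round(spec$overlap_fraction * n) / 2)
  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  max_tries <- 8000L; tries <- 0L
  usable <- 0.82 * dish_radius
  ri <- 1L
  too_close <- function(r0, c0, rad, skip_last = 0L) {
    if (length(placed_r) <= skip_last) return(FALSE)
    keep <- seq_len(length(placed_r) - skip_last)
    any(sqrt((placed_r[keep] - r0)^2 + (placed_c[keep] - c0)^2) <
          placed_rad[keep] + rad + 8)
  }
  sample_center <- function(rad) {
    repeat {
      tries <<- tries + 1L
      if (tries > max_tries)
        abort_input("cannot place all colonies: dish too crowded, reduce n_colonies",
                    class = "colonysizer_generation_error")
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * max(usable - rad, 1)
      r0 <- dish_center[1L] + rr * sin(ang)
      c0 <- dish_center[2L] + rr * cos(ang)
      if (!too_close(r0, c0, rad)) return(c(r0, c0))
    }
  }
  for (p in seq_len(n_pairs)) {
    # touching twins share one radius: centre distance 1.5 r fuses them
    # into a single component whose distance transform keeps two peaks
    r1 <- r2 <- radii[ri]
    d <- 1.5 * r1
    ctr <- sample_center(max(r1, r2) + d)
    ang <- stats::runif(1, 0, 2 * pi)
    placed_r <- c(placed_r, ctr[1L] - d / 2 * sin(ang), ctr[1L] + d / 2 * sin(ang))
    placed_c <- c(placed_c, ctr[2L] - d / 2 * cos(ang), ctr[2L] + d / 2 * cos(ang))
    placed_rad <- c(placed_rad, r1, r2)
    ri <- ri + 2L
  }
  while (ri <= n) {
    ctr <- sample_center(radii[ri])
    placed_r <- c(placed_r, ctr[1L]); placed_c <- c(placed_c, ctr[2L])
    placed_rad <- c(placed_rad, radii[ri])
    ri <- ri + 1L
  }
  data.frame(center_r = placed_r, center_c = placed_c, radius = placed_rad)
}

#' Render a synthetic scanned plate with known ground truth
#'
#' Renders the dish described by a [synthetic_plate_spec()]: light dish
#' interior on a darker surround, optional rim annulus, anti-aliased
#' (soft-edged) stained colony discs, linear illumination gradient,
#' Gaussian sensor noise, clipped to \[0, 255\]. The ground truth lists
#' every colony's centre, radius and ideal area `pi * r^2`, so pipeline
#' accuracy can be scored exactly.
#'
#' @param spec a [synthetic_plate_spec()].
#' @return List with `image` (a [plate_image()]) and `truth` (list with
#'   `colonies` data frame, `n_true`, `category`).
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plate_spec"))
  with_seed(spec$seed, {
    h <- spec$image_size[1L]; w <- spec$image_size[2L]
    dish_center <- c((h + 1) / 2, (w + 1) / 2)
    dish_radius <- min(h, w) / 2 - 2
    colonies <- place_colonies(spec, dish_center, dish_radius)

    rows <- matrix(rep(seq_len(h), w), h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    dist_center <- sqrt((rows - dish_center[1L])^2 + (cols - dish_center[2L])^2)

    bg_rgb <- c(232, 230, 235)      # lightly tinted dish interior
    surround_rgb <- c(70, 70, 72)   # scanner bed outside the dish
    rim_rgb <- c(110, 110, 112)
    # per-channel stain weights: unit mean so `contrast` is the mean gap
    wgt <- (255 - spec$stain_color) / mean(255 - spec$stain_color)

    inside <- dist_center <= dish_radius
    rim_band <- spec$rim & dist_center > dish_radius - 3 & inside

    # colony coverage in [0,1]: soft edge of ~1.5 px, max over colonies
    coverage <- matrix(0, h, w)
    for (i in seq_len(nrow(colonies))) {
      r0 <- colonies$center_r[i]; c0 <- colonies$center_c[i]
      rad <- colonies$radius[i]
      rs <- max(1L, floor(r0 - rad - 2)):min(h, ceiling(r0 + rad + 2))
      cs <- max(1L, floor(c0 - rad - 2)):min(w, ceiling(c0 + rad + 2))
      d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, `+`))
      cov <- pmin(pmax((rad + 0.75 - d) / 1.5, 0), 1)
      coverage[rs, cs] <- pmax(coverage[rs, cs], cov)
    }
    coverage[!inside] <- 0

    gradient <- spec$gradient_amplitude * ((cols - 1) / max(w - 1, 1) - 0.5)
    pixels <- array(0, dim = c(h, w, 3L))
    for (k in 1:3) {
      ch <- matrix(surround_rgb[k], h, w)
      ch[inside] <- bg_rgb[k]
      ch[rim_band] <- rim_rgb[k]
      drop_k <- spec$contrast * wgt[k]
      ch <- ch - coverage * drop_k
      ch <- ch + gradient
      if (spec$noise_sd > 0) ch <- ch + stats::rnorm(h * w, sd = spec$noise_sd)
      pixels[, , k] <- pmin(pmax(round(ch), 0), 255)
    }
    img <- plate_image(pixels, dpi = spec$dpi,
                       source_id = sprintf("synthetic_seed%d", spec$seed))
    truth <- list(
      colonies = transform(colonies, true_area = pi * colonies$radius^2),
      n_true = nrow(colonies),
      category = attr(spec, "category") %||% NA_character_
    )
    list(image = img, truth = truth)
  })
}

#' Quality-category presets for synthetic plates
#'
#' Four presets emulating commonly encountered plate qualities, ordered
#' from easiest to hardest for automated counting:
#' \describe{
#'   \item{`"#1"`}{optimal distinguishability, high contrast: no touching
#'     colonies, contrast 120.}
#'   \item{`"#2"`}{intermediate distinguishability, high contrast: 30%
#'     of colonies in touching pairs.}
#'   \item{`"#3"`}{intermediate distinguishability, low contrast
#'     (38 gray levels): the same 30% touching pairs as #2, more noise.}
#'   \item{`"#4"`}{poor distinguishability, low contrast (32), 50%
#'     touching pairs, strong illumination gradient.}
#' }
#' The numeric operationalisation (contrast levels, overlap fractions,
#' noise, gradient) is this package's own; the categories preserve a
#' qualitative easy-to-hard ordering.
#'
#' @param name one of `"#1"`, `"#2"`, `"#3"`, `"#4"`.
#' @param n_colonies colony count for the preset.
#' @param seed pseudo-random seed.
#' @return A [synthetic_plate_spec()] with attribute `category`.
#' @export
category_preset <- function(name, n_colonies = 50, seed = 1) {
  presets <- list(
    "#1" = list(contrast = 120, overlap_fraction = 0,    noise_sd = 3, gradient_amplitude = 8),
    "#2" = list(contrast = 120, overlap_fraction = 0.30, noise_sd = 3, gradient_amplitude = 8),
    "#3" = list(contrast = 38,  overlap_fraction = 0.30, noise_sd = 5, gradient_amplitude = 15),
    "#4" = list(contrast = 32,  overlap_fraction = 0.50, noise_sd = 6, gradient_amplitude = 30)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    abort_validation(sprintf("unknown category preset '%s' (use \"#1\"..\"#4\")",
                             paste(name, collapse = ",")))
  p <- presets[[name]]
  spec <- synthetic_plate_spec(
    n_colonies = n_colonies, seed = seed,
    contrast = p$contrast, overlap_fraction = p$overlap_fraction,
    noise_sd = p$noise_sd, gradient_amplitude = p$gradient_amplitude
  )
  attr(spec, "category") <- name
  spec
}
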