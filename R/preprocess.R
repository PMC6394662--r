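#' Counting pipeline parameters
#'
#' All tunables of the colony-counting pipeline. Once chosen for a batch of
#' plates the same parameters must be applied to every image, so that
#' counting errors propagate identically across samples.
#'
#' @param sigma standard deviation (pixels) of the Gaussian blurring
#'   filter, or `"auto"` to derive it from the scan resolution with
#'   [default_sigma()].
#' @param rolling_radius rolling-ball radius (pixels) for background
#'   subtraction, or `"auto"` for [default_rolling_radius()]. Should be at
#'   least as large as the largest colony diameter.
#' @param threshold binarisation cut in \[0, 255\], or `"auto"` for the
#'   iterative intermeans (IsoData) threshold.
#' @param roi_margin fraction of the dish radius (in \[0, 1)) trimmed from
#'   the dish border so the rim is never counted as a colony.
#' @param min_area,max_area colony area limits in pixel^2. The default
#'   `min_area = "auto"` means 20 px^2 at 600 DPI rescaled by
#'   `(dpi/600)^2` for the actual resolution.
#' @param circ_min,circ_max circularity limits; circularity is
#'   `4*pi*area/perimeter^2`, 1 for an ideal circle.
#' @param min_peak_distance minimum separation (pixels) between watershed
#'   seed maxima; larger values resist over-segmentation of single colonies.
#' @param auto_threshold_method `"isodata"` (intermeans, the default) or
#'   `"otsu"`.
#' @param auto_threshold_floor lower clamp (gray levels) on the automatic
#'   threshold. On a plate without any stained signal the intermeans
#'   iteration converges inside the residual noise and would binarise
#'   noise; a cut below this floor is treated as "no signal present".
#'   Only applied to automatic thresholds, never to user-set ones.
#'
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(sigma = "auto",
                            rolling_radius = "auto",
                            threshold = "auto",
                            roi_margin = 0.05,
                            min_area = "auto",
                            max_area = Inf,
                            circ_min = 0.3,
                            circ_max = 1.2,
                            min_peak_distance = 3,
                            auto_threshold_method = c("isodata", "otsu"),
                            auto_threshold_floor = 8) {
  if (!identical(sigma, "auto")) check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (!identical(rolling_radius, "auto"))
    check_number(rolling_radius, "rolling_radius", lower = 1)
  if (!identical(threshold, "auto"))
    check_number(threshold, "threshold", lower = 0, upper = 255)
  check_number(roi_margin, "roi_margin", lower = 0, upper = 1)
  if (roi_margin >= 1) abort_validation("`roi_margin` must be < 1")
  if (!identical(min_area, "auto")) {
    check_number(min_area, "min_area", lower = 0)
    if (min_area >= max_area) abort_validation("`min_area` must be < `max_area`")
  }
  if (!identical(max_area, Inf)) check_number(max_area, "max_area", lower = 0)
  check_number(circ_min, "circ_min", lower = 0)
  check_number(circ_max, "circ_max", lower = 0, upper = 1.2)
  if (circ_min >= circ_max) abort_validation("`circ_min` must be < `circ_max`")
  check_number(min_peak_distance, "min_peak_distance", lower = 1)
  check_number(auto_threshold_floor, "auto_threshold_floor", lower = 0,
               upper = 255)
  structure(list(sigma = sigma, rolling_radius = rolling_radius,
                 threshold = threshold, roi_margin = roi_margin,
                 min_area = min_area, max_area = max_area,
                 circ_min = circ_min, circ_max = circ_max,
                 min_peak_distance = min_peak_distance,
                 auto_threshold_method = match.arg(auto_threshold_method),
                 auto_threshold_floor = auto_threshold_floor),
            class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

gray_image <- function(pixels, channel = "synthetic") {
  stopifnot(is.matrix(pixels))
  attr(pixels, "channel_origin") <- channel
  pixels
}

#' Select the highest-contrast RGB channel
#'
#' The scan is split into its red, green and blue channels and the channel
#' with the largest pixel-intensity standard deviation -- i.e. the one in
#' which the stained colonies contrast most with the background -- is kept
#' for all further analysis. Ties are broken in fixed R, G, B order. For
#' the purple-blue Giemsa stain on a light dish this is typically the green
#' channel.
#'
#' @param img a [plate_image()].
#' @return A numeric matrix of intensities with attribute `channel_origin`
#'   in `{"R","G","B"}`.
#' @export
select_channel <- function(img) {
  stopifnot(inherits(img, "plate_image"))
  sds <- vapply(1:3, function(k) stats::sd(as.numeric(img$pixels[, , k])), numeric(1))
  sds[is.na(sds)] <- 0  # single-pixel image
  k <- which.max(sds)   # first max: R before G before B
  gray_image(img$pixels[, , k] + 0, channel = c("R", "G", "B")[k])
}

#' Resolution-calibrated default blur width
#'
#' The default Gaussian blur standard deviation as a function of scan
#' resolution, from a polynomial calibrated so that automatic counts agree
#' with manual counts across resolutions:
#' `sigma = 1.9e-6 * dpi^2 + 6.3e-4 * dpi + 1.3`.
#'
#' @param dpi image resolution in dots per inch (>= 0; 0 returns the
#'   polynomial's constant term 1.3, the limiting low-resolution value).
#' @return Blur standard deviation in pixels.
#' @export
default_sigma <- function(dpi) {
  check_number(dpi, "dpi", lower = 0)
  1.9e-6 * dpi^2 + 6.3e-4 * dpi + 1.3
}

#' Resolution-calibrated default rolling-ball radius
#'
#' The rolling-ball radius for background subtraction scales approximately
#' proportionally with scan resolution, with coefficient 0.025 pixels per
#' DPI. The result is rounded half-up to an integer and never falls below
#' 1 pixel.
#'
#' @param dpi image resolution in dots per inch (> 0).
#' @return Integer radius in pixels, >= 1.
#' @export
default_rolling_radius <- function(dpi) {
  check_number(dpi, "dpi", lower = 0, strict_lower = TRUE)
  max(1L, as.integer(floor(0.025 * dpi + 0.5)))
}

## Reflected (half-sample symmetric) index into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Banded convolution matrix with symmetric-reflection boundaries; with a
## symmetric unit-mass kernel this conserves the image's total intensity.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    j <- reflect_index(seq_len(n) + off, n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[off + r + 1L]
  }
  K
}

#' Gaussian blur
#'
#' Isotropic Gaussian smoothing by separable convolution with a truncated
#' (3.5 sigma), unit-mass discrete kernel and symmetric-reflection boundary
#' handling, which conserves total image intensity. Blurring homogenises
#' colony interiors and suppresses sensor noise so that thresholding and
#' watershed splitting behave stably.
#'
#' @param img numeric matrix of intensities.
#' @param sigma blur standard deviation in pixels; 0 returns the input
#'   unchanged.
#' @return Blurred matrix, same size, `channel_origin` preserved.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  Kr <- conv_matrix(nrow(img), k)
  Kc <- conv_matrix(ncol(img), k)
  out <- Kr %*% img %*% t(Kc)
  gray_image(out, channel = attr(img, "channel_origin") %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rolling-ball background subtraction
#'
#' Estimates the smooth, slowly varying background (uneven illumination,
#' staining haze) as the surface traced by a ball of the given radius
#' rolled under the intensity landscape -- computed as a grayscale
#' morphological opening with a disc-shaped structuring element -- and
#' subtracts it, clipping at zero. Colonies must be bright relative to the
#' background (the pipeline inverts dark-colony channels beforehand). A
#' radius smaller than the largest colony diameter erodes colony signal,
#' the documented failure mode of an under-sized ball.
#'
#' @param img numeric matrix, colonies bright.
#' @param radius ball radius in pixels (>= 1).
#' @return Background-subtracted matrix, everywhere `>= 0` and `<=` input.
#' @export
subtract_background <- function(img, radius) {
  stopifnot(is.matrix(img))
  check_number(radius, "radius", lower = 1)
  brush <- EBImage::makeBrush(2L * as.integer(round(radius)) + 1L, shape = "disc")
  # EBImage grayscale morphology works on [0, 1]; rescale around it
  scale <- max(abs(img), 1)
  bg <- EBImage::opening(img / scale, brush) * scale
  out <- pmax(img - bg, 0)
  gray_image(matrix(out, nrow(img), ncol(img)),
             channel = attr(img, "channel_origin") %||% "synthetic")
}

#' Iterative intermeans (IsoData) threshold
#'
#' Classic automatic threshold: starting from the overall mean, the cut is
#' repeatedly replaced by the average of the mean intensities below and
#' above it until it stabilises. Operates on the 256-bin integer histogram.
#'
#' @param img numeric matrix with values in \[0, 255\].
#' @return A single numeric threshold in \[0, 255\].
#' @export
isodata_threshold <- function(img) {
  v <- pmin(pmax(round(as.numeric(img)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  t_old <- sum(h * lev) / sum(h)
  for (i in 1:200) {
    lo <- lev <= t_old
    m_lo <- if (any(h[lo] > 0)) sum(h[lo] * lev[lo]) / sum(h[lo]) else t_old
    m_hi <- if (any(h[!lo] > 0)) sum(h[!lo] * lev[!lo]) / sum(h[!lo]) else t_old
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_old) < 0.5) break
    t_old <- t_new
  }
  t_new
}

otsu_threshold <- function(img) {
  v <- as.numeric(img)
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1) / 255), range = c(0, 1)) * 255
}

auto_threshold <- function(values, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  if (method == "otsu") otsu_threshold(values) else isodata_threshold(values)
}

#' Threshold to a binary colony mask
#'
#' Pixels strictly above the threshold become foreground (candidate
#' colony), the rest background. With `threshold = "auto"` the cut is
#' computed by the iterative intermeans (IsoData) method (or Otsu); the
#' numeric value used is attached as attribute `threshold` so one value can
#' be frozen and reused across a whole batch of plates.
#'
#' @param img background-subtracted matrix, colonies bright.
#' @param threshold numeric cut in \[0, 255\] or `"auto"`.
#' @param method automatic thresholder, `"isodata"` or `"otsu"`.
#' @return Integer 0/1 matrix of class `binary_mask` with attribute
#'   `threshold`.
#' @export
binarize <- function(img, threshold = "auto", method = c("isodata", "otsu")) {
  stopifnot(is.matrix(img))
  method <- match.arg(method)
  if (identical(threshold, "auto")) {
    threshold <- if (method == "otsu") otsu_threshold(img) else isodata_threshold(img)
  } else {
    check_number(threshold, "threshold", lower = 0, upper = 255)
  }
  mask <- matrix(as.integer(img > threshold), nrow(img), ncol(img))
  attr(mask, "threshold") <- threshold
  class(mask) <- c("binary_mask", class(mask))
  mask
}

#' Restrict a mask to the dish region of interest
#'
#' Clears all foreground outside a circle inset from the dish border by
#' `roi_margin` times the dish radius, so the dish rim and anything beyond
#' it are never counted as colonies. By default the dish is taken as the
#' largest circle fitting the image (centre = image centre, radius =
#' `min(H, W) / 2`).
#'
#' @param mask binary 0/1 matrix.
#' @param dish_center numeric `(row, col)` of the dish centre; default
#'   image centre.
#' @param dish_radius dish radius in pixels; default `min(H, W) / 2`.
#' @param roi_margin fraction of the dish radius trimmed, in \[0, 1).
#' @return Mask of the same size with out-of-ROI foreground cleared.
#' @export
apply_roi <- function(mask, dish_center = NULL, dish_radius = NULL,
                      roi_margin = 0.05) {
  stopifnot(is.matrix(mask))
  keep <- roi_circle_mask(nrow(mask), ncol(mask), dish_center, dish_radius,
                          roi_margin)
  out <- mask
  out[!keep] <- 0L
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

## Logical H x W matrix: TRUE inside the analysis circle.
roi_circle_mask <- function(h, w, dish_center = NULL, dish_radius = NULL,
                            roi_margin = 0.05) {
  check_number(roi_margin, "roi_margin", lower = 0, upper = 1)
  if (roi_margin >= 1) abort_validation("`roi_margin` must be < 1")
  if (is.null(dish_center)) dish_center <- c((h + 1) / 2, (w + 1) / 2)
  if (is.null(dish_radius)) dish_radius <- min(h, w) / 2
  r2 <- ((1 - roi_margin) * dish_radius)^2
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  (rows - dish_center[1L])^2 + (cols - dish_center[2L])^2 <= r2
}

#' Orient a channel so colonies are bright
#'
#' Stained colonies are dark on a light dish in the raw scan; all later
#' stages assume the opposite polarity. The background is identified as the
#' modal intensity of the 256-level histogram: if the mode lies in the
#' upper half of the range the channel is inverted (`255 - x`).
#'
#' @param img numeric matrix in \[0, 255\].
#' @return List with `pixels` (possibly inverted matrix) and logical
#'   `inverted`.
#' @export
normalize_polarity <- function(img) {
  stopifnot(is.matrix(img))
  v <- pmin(pmax(round(as.numeric(img)), 0), 255)
  mode_level <- which.max(tabulate(v + 1L, nbins = 256L)) - 1L
  inverted <- mode_level > 127.5
  out <- if (inverted) 255 - img else img
  list(pixels = gray_image(matrix(out, nrow(img), ncol(img)),
                           channel = attr(img, "channel_origin") %||% "synthetic"),
       inverted = inverted)
}
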