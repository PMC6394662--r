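#' Split merged colonies by watershed segmentation
#'
#' Computes the Euclidean distance transform of the binary foreground,
#' takes its regional maxima as seeds (maxima closer than
#' `min_peak_distance` to a higher maximum of the same connected
#' component are suppressed), and assigns every foreground pixel to a
#' seed by marker-based propagation, so that touching colonies are cut
#' along the line between their distance peaks while single convex
#' colonies -- which contribute exactly one seed -- are never fragmented.
#' Labels are renumbered to consecutive integers in order of first
#' appearance.
#'
#' @param mask binary 0/1 matrix, colonies = 1.
#' @param min_peak_distance minimum seed separation in pixels (>= 1);
#'   larger values resist over-segmentation of irregular single colonies
#'   at the cost of merging very close pairs.
#' @param smooth_sigma standard deviation of a light Gaussian smoothing
#'   applied to the distance transform before maxima detection, so that
#'   ragged mask boundaries (noisy, low-contrast scans) do not break one
#'   colony's distance ridge into several spurious peaks. 0 disables.
#' @return Integer label matrix of class `label_image` (0 = background)
#'   with attribute `n_labels`; labels partition the foreground exactly.
#' @export
watershed_split <- function(mask, min_peak_distance = 3, smooth_sigma = 1) {
  stopifnot(is.matrix(mask))
  check_number(min_peak_distance, "min_peak_distance", lower = 1)
  check_number(smooth_sigma, "smooth_sigma", lower = 0)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(label_matrix(matrix(0L, nrow(m), ncol(m))))
  dm <- matrix(EBImage::distmap(m), nrow(m), ncol(m))
  if (smooth_sigma > 0) dm <- gaussian_blur(dm, smooth_sigma)
  comp <- label_components(m)

  # regional maxima: pixels equal to the local max of their neighbourhood
  win <- 2L * as.integer(floor(min_peak_distance)) + 1L
  dil <- EBImage::dilate(dm, EBImage::makeBrush(win, shape = "box"))
  peaks <- label_components(matrix(as.integer(m == 1L & dm >= dil), nrow(m), ncol(m)))

  n_pk <- attr(peaks, "n_labels")
  idx <- which(peaks > 0L)
  pk <- as.integer(peaks[idx])
  rr <- ((idx - 1L) %% nrow(m)) + 1L
  cc <- ((idx - 1L) %/% nrow(m)) + 1L
  height <- as.numeric(tapply(dm[idx], pk, max))
  cen_r <- as.numeric(tapply(rr, pk, mean))
  cen_c <- as.numeric(tapply(cc, pk, mean))
  parent <- comp[cbind(round(cen_r), round(cen_c))]
  # some plateau centroids fall outside the blob (concave); snap to a member
  bad <- parent == 0L
  if (any(bad)) {
    first <- match(unique(pk), pk)
    parent[bad] <- comp[idx[first[bad]]]
  }

  # greedy suppression, highest peak first, within each parent component
  ord <- order(-height, cen_r, cen_c)
  keep <- logical(n_pk)
  for (i in ord) {
    prev <- which(keep & parent == parent[i])
    if (!length(prev) ||
        all((cen_r[prev] - cen_r[i])^2 + (cen_c[prev] - cen_c[i])^2 >=
              min_peak_distance^2))
      keep[i] <- TRUE
  }
  seed_id <- integer(n_pk)
  seed_id[keep] <- seq_len(sum(keep))
  seeds <- matrix(0L, nrow(m), ncol(m))
  sel <- seed_id[pk] > 0L
  seeds[idx[sel]] <- seed_id[pk[sel]]

  ws <- EBImage::propagate(dm, seeds, mask = m > 0, lambda = 1e4)
  label_matrix(relabel_consecutive(matrix(as.integer(ws), nrow(m), ncol(m))))
}

label_matrix <- function(m) {
  attr(m, "n_labels") <- if (any(m > 0L)) max(m) else 0L
  class(m) <- c("label_image", class(m))
  m
}

## Renumber positive labels 1..n in order of first (column-major) occurrence.
relabel_consecutive <- function(lab) {
  pos <- lab > 0L
  u <- unique(lab[pos])
  lab[pos] <- match(lab[pos], u)
  lab
}

#' Label connected components (8-connectivity)
#'
#' Plain connected-component labelling with 8-connected foreground,
#' matching the convention that diagonally touching colony pixels belong
#' to one object. Used as the non-splitting counterpart of
#' [watershed_split()] and by its tests.
#'
#' @param mask binary 0/1 matrix.
#' @return Integer `label_image` with consecutive labels.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(label_matrix(matrix(0L, nrow(m), ncol(m))))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  h <- nrow(lab); w <- ncol(lab)
  pairs <- NULL
  if (h > 1L && w > 1L) {
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # \ diagonal
    a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # / diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  }
  if (!is.null(pairs) && nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  label_matrix(relabel_consecutive(lab))
}

#' Circularity shape descriptor
#'
#' `4 * pi * area / perimeter^2`: 1 for an ideal circle, approaching 0 for
#' elongated or ragged shapes. Colonies that are "not round enough" (rim
#' fragments, scratches, debris) score low and can be filtered out.
#'
#' @param area object area.
#' @param perimeter object perimeter, same length unit.
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    abort_validation("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

## Moore boundary tracing on a 0/1 submask (object must be 8-connected and
## not touch the matrix border). Returns the chain codes (0..7) of the
## outer boundary walk, or integer(0) for a single-pixel object.
moore_chain <- function(sub) {
  drc <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  start <- which(sub == 1L, arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  # scanning clockwise from just past the backtrack pixel traces the outer
  # boundary; the walk starts as if entered from the west
  cur <- start; back <- 6L  # direction from current to the backtrack pixel
  chain <- integer(0)
  max_steps <- 4L * sum(sub) + 8L
  repeat {
    found <- FALSE
    scan <- (back + 1L + 0:7) %% 8L
    for (d in scan) {
      nr <- cur[1L] + drc[d + 1L, 1L]; nc <- cur[2L] + drc[d + 1L, 2L]
      if (sub[nr, nc] == 1L) {
        chain <- c(chain, d)
        cur <- c(nr, nc)
        back <- (d + 4L) %% 8L
        found <- TRUE
        break
      }
    }
    if (!found) return(integer(0))  # isolated pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L]) break
    if (length(chain) >= max_steps) break
  }
  chain
}

## Perimeter from the boundary chain: straight steps weighted 0.980,
## diagonal steps 1.406, minus 0.091 per corner (direction change) -- the
## Vossepoel-Smeulders estimator, i.e. "1 per straight step, sqrt(2) per
## diagonal, with corner correction". The chain runs through pixel
## centres, half a pixel inside the region outline, so pi (the Minkowski
## offset of a convex contour by 1/2 px) is added back. Never allowed to
## undershoot the isoperimetric bound 2*sqrt(pi*area), which also supplies
## the perimeter of 1-2 pixel objects whose chain is degenerate.
perimeter_from_chain <- function(chain, area) {
  floor_p <- 2 * sqrt(pi * area)
  if (length(chain) == 0L) return(floor_p)
  n_diag <- sum(chain %% 2L == 1L)
  n_straight <- length(chain) - n_diag
  n_corner <- sum(chain != c(chain[-1L], chain[1L]))
  max(0.980 * n_straight + 1.406 * n_diag - 0.091 * n_corner + pi, floor_p)
}

#' Measure labelled colonies
#'
#' Computes, per label: area (pixel count, plus mm^2 via `(25.4/dpi)^2`
#' when the resolution is known), perimeter (weighted boundary-crack
#' estimator on the traced outer contour), circularity
#' `4*pi*area/perimeter^2`, and the centroid in (row, col) pixel
#' coordinates.
#'
#' @param labels a `label_image` from [watershed_split()] or
#'   [label_components()].
#' @param dpi scan resolution for physical units, or `NA` if unknown.
#' @return Data frame with one row per colony: `label`, `area_px`,
#'   `area_mm2` (`NA` without resolution), `perimeter`, `circularity`,
#'   `centroid_r`, `centroid_c`.
#' @export
measure_colonies <- function(labels, dpi = NA_real_) {
  stopifnot(is.matrix(labels))
  n <- if (any(labels > 0L)) max(labels) else 0L
  empty <- data.frame(label = integer(0), area_px = numeric(0),
                      area_mm2 = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), centroid_r = numeric(0),
                      centroid_c = numeric(0))
  if (n == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- as.integer(labels[idx])
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab, nbins = n)
  cen_r <- as.numeric(rowsum(rr, lab)) / area
  cen_c <- as.numeric(rowsum(cc, lab)) / area
  rmin <- tapply(rr, lab, min); rmax <- tapply(rr, lab, max)
  cmin <- tapply(cc, lab, min); cmax <- tapply(cc, lab, max)
  perim <- numeric(n)
  for (k in seq_len(n)) {
    sel <- lab == k
    h <- rmax[k] - rmin[k] + 3L
    w <- cmax[k] - cmin[k] + 3L
    sub <- matrix(0L, h, w)
    sub[cbind(rr[sel] - rmin[k] + 2L, cc[sel] - cmin[k] + 2L)] <- 1L
    perim[k] <- perimeter_from_chain(moore_chain(sub), area[k])
  }
  px_mm2 <- if (is_unknown_dpi(dpi)) NA_real_ else (25.4 / dpi)^2
  data.frame(label = seq_len(n),
             area_px = as.numeric(area),
             area_mm2 = as.numeric(area) * px_mm2,
             perimeter = perim,
             circularity = circularity(as.numeric(area), perim),
             centroid_r = cen_r,
             centroid_c = cen_c)
}

#' Filter colonies by area and circularity
#'
#' Keeps detections whose area lies in `[min_area, max_area]` (pixel^2)
#' and whose circularity lies in `[circ_min, circ_max]`, preserving
#' detection order. Raising `circ_min` discards objects that are not round
#' enough; the area window removes debris and merged super-objects.
#'
#' @param records data frame from [measure_colonies()].
#' @param params a [pipeline_params()] (numeric `min_area`; use
#'   [resolve_pipeline_params()] first if it is `"auto"`).
#' @return The accepted subset of `records`, order preserved.
#' @export
filter_colonies <- function(records, params) {
  stopifnot(is.data.frame(records), inherits(params, "pipeline_params"))
  min_area <- params$min_area
  if (identical(min_area, "auto")) min_area <- 20
  keep <- records$area_px >= min_area & records$area_px <= params$max_area &
    records$circularity >= params$circ_min & records$circularity <= params$circ_max
  records[keep, , drop = FALSE]
}

#' Resolve automatic pipeline parameters for a given resolution
#'
#' Replaces every `"auto"` entry of a [pipeline_params()] with its
#' resolution-calibrated numeric value: `sigma` via [default_sigma()],
#' `rolling_radius` via [default_rolling_radius()], and `min_area` as
#' 20 px^2 at 600 DPI rescaled by `(dpi/600)^2`. The threshold stays
#' `"auto"` here because it is computed from image content (and should
#' then be frozen for the batch).
#'
#' @param params a [pipeline_params()].
#' @param dpi resolution used for the calibration formulas; `NA` falls
#'   back to 600 DPI with a warning.
#' @return A `pipeline_params` with numeric `sigma`, `rolling_radius`,
#'   `min_area`.
#' @export
resolve_pipeline_params <- function(params, dpi = NA_real_) {
  stopifnot(inherits(params, "pipeline_params"))
  if (is_unknown_dpi(dpi)) {
    if (identical(params$sigma, "auto") || identical(params$rolling_radius, "auto") ||
        identical(params$min_area, "auto"))
      warning("image resolution unknown; using 600 DPI for auto parameters",
              call. = FALSE)
    dpi <- 600
  }
  if (identical(params$sigma, "auto")) params$sigma <- default_sigma(dpi)
  if (identical(params$rolling_radius, "auto"))
    params$rolling_radius <- default_rolling_radius(dpi)
  if (identical(params$min_area, "auto")) params$min_area <- 20 * (dpi / 600)^2
  params
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage '%s': %s", stage, conditionMessage(e)),
      class = c("colonysizer_stage_error", "colonysizer_error")))
  })
}

#' Count and measure colonies on one plate
#'
#' Runs the full counting pipeline on a scanned dish: channel selection by
#' highest standard deviation, polarity normalisation (colonies bright),
#' Gaussian blur, rolling-ball background subtraction, thresholding, ROI
#' masking, watershed splitting of merged colonies, measurement, and
#' area/circularity filtering. All automatic parameters are resolved from
#' the image resolution (or `dpi`) and reported in the diagnostics so a
#' batch can reuse them unchanged.
#'
#' @param img a [plate_image()].
#' @param params a [pipeline_params()].
#' @param dpi resolution override when the image metadata lacks one.
#' @param dish_center,dish_radius dish geometry override for [apply_roi()].
#' @return List of class `plate_result`: `records` (accepted colonies),
#'   `count`, and `diagnostics` (resolved parameters, selected channel,
#'   inversion flag, threshold used, intermediate mask and label image,
#'   candidate count before filtering).
#' @export
process_plate <- function(img, params = pipeline_params(), dpi = NULL,
                          dish_center = NULL, dish_radius = NULL) {
  stopifnot(inherits(img, "plate_image"), inherits(params, "pipeline_params"))
  eff_dpi <- if (!is.null(dpi)) dpi else img$dpi
  rp <- run_stage("resolve_params", resolve_pipeline_params(params, eff_dpi))
  gray <- run_stage("select_channel", select_channel(img))
  pol <- run_stage("normalize_polarity", normalize_polarity(gray))
  blurred <- run_stage("gaussian_blur", gaussian_blur(pol$pixels, rp$sigma))
  flat <- run_stage("subtract_background",
                    subtract_background(blurred, rp$rolling_radius))
  # the automatic threshold is computed from dish-interior pixels only, so
  # rim remnants and the scanner bed cannot bias the intensity histogram
  thr <- rp$threshold
  if (identical(thr, "auto")) {
    keep <- roi_circle_mask(nrow(flat), ncol(flat), dish_center, dish_radius,
                            rp$roi_margin)
    thr <- run_stage("binarize",
                     max(auto_threshold(flat[keep], rp$auto_threshold_method),
                         rp$auto_threshold_floor))
  }
  mask <- run_stage("binarize", binarize(flat, thr))
  roi <- run_stage("apply_roi",
                   apply_roi(mask, dish_center = dish_center,
                             dish_radius = dish_radius,
                             roi_margin = rp$roi_margin))
  labels <- run_stage("watershed_split",
                      watershed_split(roi, min_peak_distance = rp$min_peak_distance))
  measured <- run_stage("measure_colonies", measure_colonies(labels, dpi = eff_dpi))
  accepted <- run_stage("filter_colonies", filter_colonies(measured, rp))
  rp$threshold <- attr(mask, "threshold")
  structure(list(
    records = accepted,
    count = nrow(accepted),
    diagnostics = list(
      source_id = img$source_id,
      dpi = if (is_unknown_dpi(eff_dpi)) NA_real_ else eff_dpi,
      channel = attr(gray, "channel_origin"),
      inverted = pol$inverted,
      resolved_params = rp,
      threshold = attr(mask, "threshold"),
      n_candidates = nrow(measured),
      mask = roi,
      labels = labels
    )
  ), class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("<plate_result> %s: %d colonies (channel %s, threshold %.1f)\n",
              x$diagnostics$source_id, x$count, x$diagnostics$channel,
              x$diagnostics$threshold))
  invisible(x)
}
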