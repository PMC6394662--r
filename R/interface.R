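## Batch entry points. These are the programmatic equivalents of the
## command-line interface in inst/cli/colonysizer; each writes its fully
## resolved configuration next to its outputs so a run can be reproduced.

params_to_list <- function(params) {
  lapply(unclass(params), function(v) if (identical(v, Inf)) "Inf" else v)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

expand_inputs <- function(inputs) {
  hits <- unlist(lapply(inputs, function(p) {
    if (file.exists(p)) return(p)
    Sys.glob(p)
  }))
  unique(hits[file.exists(hits)])
}

#' Count colonies on a batch of plate images
#'
#' Processes every image with the same pipeline parameters. Automatic
#' parameters (blur sigma, rolling-ball radius, threshold, minimum area)
#' are resolved once, on the first image of the batch, and then frozen for
#' all remaining images, so that any residual counting bias propagates
#' identically across samples. Per plate, a colony-size text file and a
#' diagnostics JSON are written; the batch summary lists every count and
#' the resolved parameters.
#'
#' @param inputs character vector of image paths and/or globs.
#' @param out_dir output directory (created if needed).
#' @param params a [pipeline_params()].
#' @param dpi resolution fallback for images without metadata.
#' @param unit area unit for the size files (`"pixel^2"` or `"mm^2"`).
#' @return Invisibly, the batch summary list (`plates`, `counts`,
#'   `failures`, `resolved_params`).
#' @export
run_count <- function(inputs, out_dir, params = pipeline_params(),
                      dpi = NULL, unit = "pixel^2") {
  paths <- expand_inputs(inputs)
  if (length(paths) == 0L)
    abort_input(sprintf("no input images match: %s", paste(inputs, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frozen <- NULL
  plates <- list(); failures <- character(0)
  for (p in paths) {
    res <- tryCatch({
      img <- load_plate_image(p)
      if (is.null(frozen)) {
        eff_dpi <- if (!is.null(dpi)) dpi else img$dpi
        frozen <- resolve_pipeline_params(params, eff_dpi)
        if (identical(frozen$threshold, "auto")) {
          # compute the automatic threshold once, on the first plate,
          # from dish-interior pixels only
          gray <- select_channel(img)
          pol <- normalize_polarity(gray)
          flat <- subtract_background(gaussian_blur(pol$pixels, frozen$sigma),
                                      frozen$rolling_radius)
          keep <- roi_circle_mask(nrow(flat), ncol(flat),
                                  roi_margin = frozen$roi_margin)
          frozen$threshold <- max(auto_threshold(flat[keep],
                                                 frozen$auto_threshold_method),
                                  frozen$auto_threshold_floor)
        }
      }
      pr <- process_plate(img, frozen, dpi = dpi)
      stem <- img$source_id
      write_colony_sizes(pr$records, file.path(out_dir, paste0(stem, "_sizes.txt")),
                         unit = if (unit == "mm^2" && !is.na(pr$diagnostics$dpi))
                           "mm^2" else "pixel^2",
                         plate_id = stem,
                         params = list(sigma = frozen$sigma,
                                       rolling_radius = frozen$rolling_radius,
                                       threshold = frozen$threshold))
      diag <- pr$diagnostics
      diag$mask <- NULL; diag$labels <- NULL
      diag$resolved_params <- params_to_list(diag$resolved_params)
      write_json(diag, file.path(out_dir, paste0(stem, "_diagnostics.json")))
      list(plate = stem, count = pr$count)
    }, error = function(e) {
      warning(sprintf("plate '%s' failed: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- c(failures, p) else plates[[length(plates) + 1L]] <- res
  }
  summary <- list(
    plates = vapply(plates, `[[`, character(1), "plate"),
    counts = vapply(plates, `[[`, numeric(1), "count"),
    failures = failures,
    resolved_params = params_to_list(frozen %||% params)
  )
  write_json(summary, file.path(out_dir, "batch_summary.json"))
  if (length(failures))
    abort_input(sprintf("%d plate(s) failed: %s", length(failures),
                        paste(failures, collapse = ", ")))
  invisible(summary)
}

#' Fit size-distribution models to colony-size files
#'
#' Reads one or more colony-size text files (optionally grouped into
#' replicate batches by a one-capture-group regex on the filename stem),
#' builds a histogram per group, fits the Weibull and/or Gaussian models,
#' and writes a JSON result and a plot per group, plus a comparison table
#' when there is more than one group. Files too small to fit still get
#' their histogram written.
#'
#' @param inputs character vector of size-file paths and/or globs.
#' @param out_dir output directory.
#' @param n_bins bins per histogram or `"auto"`.
#' @param model `"weibull"`, `"gaussian"` or `"both"`.
#' @param fix_c fix the Weibull amplitude at 1 (strict two-parameter fit).
#' @param group_regex optional regex with one capture group for grouping
#'   replicate files; default: one group per file.
#' @return Invisibly, a list with per-group `fits` and the `comparison`
#'   table (or `NULL` for a single group).
#' @export
run_fit <- function(inputs, out_dir, n_bins = "auto",
                    model = c("both", "weibull", "gaussian"),
                    fix_c = FALSE, group_regex = NULL) {
  model <- match.arg(model)
  paths <- expand_inputs(inputs)
  if (length(paths) == 0L)
    abort_input(sprintf("no input size files match: %s",
                        paste(inputs, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- group_plates(paths, group_regex)
  sizes <- lapply(groups, function(ps)
    unlist(lapply(ps, function(p) read_colony_sizes(p)$areas)))
  results <- list()
  for (g in names(groups)) {
    out <- list(group = g, n = length(sizes[[g]]), files = basename(groups[[g]]))
    hist <- tryCatch(build_histogram(sizes[[g]], n_bins = n_bins),
                     error = function(e) NULL)
    wfit <- gfit <- NULL
    if (!is.null(hist)) {
      out$histogram <- list(bin_edges = hist$bin_edges, counts = hist$counts,
                            densities = hist$densities)
      if (model %in% c("both", "weibull"))
        wfit <- tryCatch(fit_weibull(hist, fix_c = fix_c),
                         colonysizer_insufficient_data = function(e) NULL)
      if (model %in% c("both", "gaussian"))
        gfit <- tryCatch(fit_gaussian(hist),
                         colonysizer_insufficient_data = function(e) NULL)
      out$weibull <- if (!is.null(wfit)) unclass(wfit)
      out$gaussian <- if (!is.null(gfit)) unclass(gfit)
      if (is.null(wfit) && model %in% c("both", "weibull"))
        out$note <- "too few non-empty bins to fit"
      grDevices::png(file.path(out_dir, paste0(g, "_histogram.png")),
                     width = 800, height = 600)
      plot(hist, weibull = wfit, gaussian = gfit,
           main = sprintf("Colony size distribution: %s", g))
      grDevices::dev.off()
    }
    write_json(out, file.path(out_dir, paste0(g, "_fit.json")))
    results[[g]] <- list(histogram = hist, weibull = wfit, gaussian = gfit)
  }
  comparison <- NULL
  if (length(groups) > 1L) {
    comparison <- compare_groups(sizes, n_bins = n_bins, fix_c = fix_c)
    utils::write.csv(comparison$table,
                     file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$pairwise,
                     file.path(out_dir, "group_pairwise.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "group_means.png"), width = 800, height = 600)
    plot_group_means(comparison)
    grDevices::dev.off()
  }
  invisible(list(fits = results, comparison = comparison))
}

#' Simulate a synthetic plate scan to disk
#'
#' Renders a [synthetic_plate_spec()] (or a named [category_preset()]),
#' writes the image as a DPI-tagged PNG plus a ground-truth JSON sidecar
#' (colony centres, radii, true areas) and the fully resolved spec.
#' Bit-reproducible for a fixed spec and seed.
#'
#' @param spec a `synthetic_plate_spec`, or a preset name `"#1"`..`"#4"`.
#' @param out_dir output directory.
#' @param seed seed override (applied to the spec).
#' @param name output file stem; default derived from seed.
#' @return Invisibly, list with `image_path`, `truth_path` and the
#'   generated plate.
#' @export
run_simulate <- function(spec, out_dir, seed = NULL, name = NULL) {
  if (is.character(spec)) spec <- category_preset(spec, seed = seed %||% 1)
  stopifnot(inherits(spec, "synthetic_plate_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate <- generate_plate(spec)
  stem <- name %||% plate$image$source_id
  image_path <- file.path(out_dir, paste0(stem, ".png"))
  png::writePNG(plate$image$pixels / 255, image_path, dpi = spec$dpi)
  truth_path <- file.path(out_dir, paste0(stem, "_truth.json"))
  write_json(list(n_true = plate$truth$n_true,
                  category = plate$truth$category,
                  colonies = plate$truth$colonies),
             truth_path)
  spec_out <- unclass(spec)
  spec_out$category <- attr(spec, "category")
  write_json(spec_out, file.path(out_dir, paste0(stem, "_spec.json")))
  invisible(list(image_path = image_path, truth_path = truth_path,
                 plate = plate))
}
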