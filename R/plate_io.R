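#' Plate image container
#'
#' A `plate_image` bundles an 8-bit RGB raster of one scanned culture dish
#' with its resolution metadata. Pixel intensities are integers in
#' \[0, 255\], stored as an `H x W x 3` array in row/column order.
#'
#' @param pixels numeric or integer array `H x W x 3` with values in
#'   \[0, 255\]. A single-channel `H x W` matrix is promoted to three
#'   identical channels.
#' @param dpi scan resolution in dots per inch (> 0), or `NA` when unknown.
#' @param source_id text label for the plate, typically the filename stem.
#'
#' @return An object of class `plate_image` with elements `pixels`,
#'   `dpi` and `source_id`.
#' @seealso [load_plate_image()]
#' @export
plate_image <- function(pixels, dpi = NA_real_, source_id = "plate") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    abort_validation("`pixels` must be an H x W x 3 array or an H x W matrix")
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    abort_input("plate image has zero extent")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort_validation("pixel intensities must lie in [0, 255]")
  if (!is_unknown_dpi(dpi)) {
    check_number(dpi, "dpi", lower = 0, strict_lower = TRUE)
  } else {
    dpi <- NA_real_
  }
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = dim(pixels)),
         dpi = dpi, source_id = as.character(source_id)),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %s: %d x %d px, 3 channels, dpi = %s\n",
              x$source_id, d[1L], d[2L],
              if (is.na(x$dpi)) "unknown" else format(x$dpi)))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

## Collapse a decoded raster (values in [0,1], possibly with an alpha
## channel) to H x W x 3 in [0,255].
raster_to_rgb255 <- function(arr, path) {
  if (length(arr) == 0L) abort_input(sprintf("zero-sized image: '%s'", path))
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  nc <- dim(arr)[3L]
  if (nc == 2L) arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  if (nc >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3L] != 3L)
    abort_input(sprintf("unsupported channel layout in '%s'", path))
  arr * 255
}

read_png_plate <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  dpi <- NA_real_
  if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1L] > 0) {
    # pHYs stores integer pixels-per-metre; undo its rounding.
    dpi <- round(info$dpi[1L], 2)
  }
  list(arr = raster_to_rgb255(arr, path), dpi = dpi)
}

read_tiff_plate <- function(path) {
  arr <- tiff::readTIFF(path, info = TRUE)
  at <- attributes(arr)
  dpi <- NA_real_
  if (!is.null(at$x.resolution) && is.finite(at$x.resolution) &&
      at$x.resolution > 0) {
    unit <- if (is.null(at$resolution.unit)) "inch" else at$resolution.unit
    dpi <- switch(unit,
                  inch = at$x.resolution,
                  cm   = at$x.resolution * 2.54,
                  NA_real_)
    if (!is.na(dpi)) dpi <- round(dpi, 2)
  }
  list(arr = raster_to_rgb255(arr, path), dpi = dpi)
}

read_jpeg_plate <- function(path) {
  if (!requireNamespace("jpeg", quietly = TRUE))
    abort_input("reading JPEG requires the 'jpeg' package")
  # baseline JPEG carries no resolution tag readable here
  list(arr = raster_to_rgb255(jpeg::readJPEG(path), path), dpi = NA_real_)
}

#' Load a scanned plate image
#'
#' Reads a PNG, TIFF or JPEG scan of a culture dish into a [plate_image()].
#' Resolution metadata (DPI) is taken from the file's standard resolution
#' tags when present and reported as `NA` ("unknown") otherwise. Grayscale
#' images are promoted to three identical channels; alpha channels are
#' dropped.
#'
#' @param path path to an existing PNG/TIFF/JPEG file (8 bit per channel).
#' @return A [plate_image()] whose `source_id` is the filename stem.
#' @export
load_plate_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_input(sprintf("image file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  res <- tryCatch(
    switch(ext,
           png  = read_png_plate(path),
           tif  = ,
           tiff = read_tiff_plate(path),
           jpg  = ,
           jpeg = read_jpeg_plate(path),
           abort_input(sprintf("unsupported image format '.%s': '%s'", ext, path))),
    error = function(e) {
      if (inherits(e, "colonysizer_error")) stop(e)
      abort_input(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)))
    })
  plate_image(res$arr, dpi = res$dpi,
              source_id = tools::file_path_sans_ext(basename(path)))
}

unit_labels <- c("pixel^2", "mm^2")

#' Write per-colony areas to a plain-text size file
#'
#' One plate per file: comment-prefixed header lines (`# key: value`) record
#' the plate id, the area unit and an optional parameter summary, followed
#' by one colony area per line in detection order. The numeric format
#' preserves full double precision so that a write/read round-trip is exact.
#'
#' @param records a data frame of colony measurements (see
#'   [measure_colonies()]) or a numeric vector of areas.
#' @param path output file path.
#' @param unit `"pixel^2"` or `"mm^2"`; selects the area column when
#'   `records` is a data frame.
#' @param plate_id plate label written to the header.
#' @param params optional named list summarised in the header.
#' @return Invisibly, the `colony_size_file` object written.
#' @export
write_colony_sizes <- function(records, path, unit = c("pixel^2", "mm^2"),
                               plate_id = "plate", params = NULL) {
  unit <- match.arg(unit)
  if (is.data.frame(records)) {
    col <- if (unit == "mm^2") "area_mm2" else "area_px"
    if (!col %in% names(records))
      abort_validation(sprintf("records lack column '%s' for unit %s", col, unit))
    areas <- records[[col]]
  } else {
    areas <- as.numeric(records)
  }
  if (length(areas) && (anyNA(areas) || any(areas <= 0)))
    abort_validation("all colony areas must be positive")
  header <- c(
    sprintf("# plate_id: %s", plate_id),
    sprintf("# unit: %s", unit),
    sprintf("# n_colonies: %d", length(areas))
  )
  if (!is.null(params) && length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), character(1)), sep = "=")
    header <- c(header, sprintf("# params: %s", paste(kv, collapse = "; ")))
  }
  lines <- c(header, sprintf("%.17g", areas))
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    abort_input(sprintf("cannot open '%s' for writing: %s", path,
                        conditionMessage(e))))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(structure(list(plate_id = plate_id, unit = unit, areas = areas),
                      class = "colony_size_file"))
}

#' Read a colony size file
#'
#' Accepts files produced by [write_colony_sizes()] as well as bare
#' one-number-per-line lists (which get `unit = "pixel^2"` and a plate id
#' derived from the filename). LF and CRLF line endings are tolerated.
#'
#' @param path path to the size file.
#' @return A `colony_size_file`: list with `plate_id`, `unit` and the
#'   ordered numeric vector `areas`.
#' @export
read_colony_sizes <- function(path) {
  if (!file.exists(path))
    abort_input(sprintf("size file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  plate_id <- tools::file_path_sans_ext(basename(path))
  unit <- "pixel^2"
  areas <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl("^plate_id:", body)) plate_id <- trimws(sub("^plate_id:", "", body))
      if (grepl("^unit:", body)) {
        u <- trimws(sub("^unit:", "", body))
        if (!u %in% unit_labels)
          abort_parse(sprintf("line %d: unknown unit '%s'", i, u))
        unit <- u
      }
      next
    }
    val <- suppressWarnings(as.numeric(ln))
    if (is.na(val))
      abort_parse(sprintf("line %d: non-numeric colony area '%s'", i, ln))
    if (val <= 0)
      abort_validation(sprintf("line %d: colony area must be > 0, got %g", i, val))
    areas <- c(areas, val)
  }
  structure(list(plate_id = plate_id, unit = unit, areas = areas),
            class = "colony_size_file")
}

#' @export
print.colony_size_file <- function(x, ...) {
  cat(sprintf("<colony_size_file> %s: %d colonies [%s]\n",
              x$plate_id, length(x$areas), x$unit))
  invisible(x)
}

#' Group plate files into replicate batches
#'
#' Plates belonging to the same experimental group are matched by a regular
#' expression with exactly one capture group applied to the filename stem;
#' the captured text is the group label. Stems that do not match form their
#' own singleton groups.
#'
#' @param paths character vector of file paths.
#' @param group_regex regular expression with one capture group, or `NULL`
#'   to place every file in its own group.
#' @return Named list mapping group label to character vector of paths.
#' @export
group_plates <- function(paths, group_regex = NULL) {
  stems <- tools::file_path_sans_ext(basename(paths))
  if (is.null(group_regex)) {
    labels <- stems
  } else {
    m <- regmatches(stems, regexec(group_regex, stems))
    labels <- vapply(seq_along(stems), function(i) {
      if (length(m[[i]]) >= 2L) m[[i]][[2L]] else stems[[i]]
    }, character(1))
  }
  split(paths, factor(labels, levels = unique(labels)))
}
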