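#' Write a kymograph as 16-bit TIFF with a JSON calibration sidecar
#'
#' Intensities are stored as 16-bit unsigned counts (values must lie in
#' `[0, 65535]`; they are rounded to integers). Calibration
#' (`pixel_size_um`, `frame_interval_s`) goes to a JSON sidecar next to
#' the image.
#'
#' @param kymo a [kymograph()].
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- round(kymo$intensities)
  if (any(img < 0) || any(img > 65535)) {
    stop("intensities must fit 16-bit unsigned range [0, 65535]",
         call. = FALSE)
  }
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = kymo$pixel_size,
         frame_interval_s = kymo$frame_interval),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph from TIFF plus calibration
#'
#' Loads a grayscale TIFF (any bit depth; intensities are rescaled to
#' counts on the 16-bit scale) and attaches the calibration, taken from
#' the JSON sidecar when present or from the explicit arguments
#' otherwise. Missing calibration is an explicit error naming the
#' missing field; an unreadable file is an error, not a crash.
#'
#' @param path TIFF file.
#' @param sidecar JSON sidecar path; default `paste0(path, ".json")`
#'   when that file exists.
#' @param pixel_size,frame_interval calibration fallbacks used when no
#'   sidecar is found.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path, sidecar = NULL, pixel_size = NULL,
                           frame_interval = NULL) {
  img <- tryCatch(tiff::readTIFF(path, as.is = FALSE),
                  error = function(e) {
                    stop(sprintf("cannot read TIFF '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1L]
  img <- round(img * 65535)

  if (is.null(sidecar) && file.exists(paste0(path, ".json"))) {
    sidecar <- paste0(path, ".json")
  }
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  }
  if (is.null(pixel_size)) {
    stop("missing calibration field `pixel_size_um`: supply a sidecar or `pixel_size`",
         call. = FALSE)
  }
  if (is.null(frame_interval)) {
    stop("missing calibration field `frame_interval_s`: supply a sidecar or `frame_interval`",
         call. = FALSE)
  }
  kymograph(img, pixel_size, frame_interval)
}

#' Write / read a filament trace as CSV
#'
#' The interchange dialect is comma-separated UTF-8 with a header row:
#' columns `time_s`, `length_subunits` and optionally `phase` (ground
#' truth from the simulator).
#'
#' @param trace a `filament_trace` data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `filament_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  cols <- intersect(c("time_s", "length_subunits", "delta_length_subunits",
                      "phase"), names(trace))
  write.csv(as.data.frame(trace)[cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("trace CSV must have a `time_s` column", call. = FALSE)
  }
  structure(df, class = c("filament_trace", "data.frame"))
}

#' Write / read filament contours as CSV
#'
#' Columns `x_um`, `y_um` ordered along the filament, plus `filament_id`
#' when several contours share one file.
#'
#' @param contours a single contour or a named/unnamed list of contours.
#' @param path CSV path.
#' @return `path` invisibly (writer); a list of `filament_contour`
#'   data frames (reader).
#' @export
write_contours_csv <- function(contours, path) {
  if (is.data.frame(contours)) contours <- list(contours)
  df <- do.call(rbind, lapply(seq_along(contours), function(k) {
    ct <- as.data.frame(contours[[k]])
    data.frame(filament_id = k, x_um = ct$x_um, y_um = ct$y_um)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df))) {
    stop("contours CSV must have `x_um` and `y_um` columns", call. = FALSE)
  }
  if (!"filament_id" %in% names(df)) df$filament_id <- 1L
  lapply(split(df[c("x_um", "y_um")], df$filament_id), function(d) {
    structure(d, class = c("filament_contour", "data.frame"))
  })
}

#' Write / read a density-response table as CSV
#'
#' Columns `density_per_um2`, `occupancy`, `v_mean`, `v_std`, `n`.
#'
#' @param data a `density_response` data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `density_response` (reader).
#' @export
write_density_response_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_density_response_csv
#' @export
read_density_response_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("density_response", "data.frame"))
}

#' Write an analysis report as JSON
#'
#' Emits a self-describing JSON report: schema version, the seed and
#' configuration echo needed to reproduce every stochastic output, SHA-1
#' style input hashes (plain file sizes + mtimes are avoided so reports
#' of identical runs are byte-identical), and the results themselves.
#'
#' @param results named list of stage results (coerced via
#'   `unclass`-friendly structures).
#' @param path output JSON path.
#' @param config configuration echo, a named list.
#' @param seed the global seed used.
#' @param inputs named character vector of input files to hash.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list(), seed = NULL,
                         inputs = character(0)) {
  hashes <- if (length(inputs) > 0) {
    lapply(inputs, function(f) {
      if (file.exists(f)) {
        unname(unclass(sum(as.integer(readBin(f, "raw", file.size(f))))))
      } else NA
    })
  } else NULL
  report <- list(schema_version = "1.0",
                 seed = seed,
                 config = config,
                 input_hashes = hashes,
                 results = results)
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", force = TRUE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write report to '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}
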