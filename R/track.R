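#' Track both filament ends through a kymograph
#'
#' Fits the error-function edge model ([fit_edge()]) to both sides of the
#' filament segment in every kymograph row: the rising (left) and falling
#' (right) edge, each within a window around the row's steepest gradient
#' of that sign. Edge positions are converted to micrometres via the
#' pixel size and to subunits via 370 subunits/um; each end's change in
#' length is referenced to the first row where both fits succeeded. Rows
#' with failed fits are carried as `NA` gaps, never interpolated; the gap
#' fraction is reported as an attribute.
#'
#' @param kymo a [kymograph()].
#' @param barbed_end which image side is the barbed end, `"right"`
#'   (default) or `"left"`.
#' @param window_px half-width of the fitting window around each
#'   detected edge, pixels.
#' @param marker_trace optional fiduciary-marker position trace
#'   (um, one value per row) subtracted from both end positions to
#'   correct for whole-filament sliding.
#' @return A list with elements `barbed` and `pointed`, each a
#'   `filament_trace` data frame (`time_s`, `delta_length_subunits`,
#'   `delta_length_um`, `position_um`, `ok`), plus `gap_fraction`.
#'   Growth of either end is counted as positive `delta_length`.
#' @export
#' @examples
#' tr <- simulate_growth_trace(growth_params(duration = 20, seed = 1))
#' ky <- render_kymograph(tr, render_params())
#' ends <- track_ends(ky)
#' head(ends$barbed)
track_ends <- function(kymo, barbed_end = c("right", "left"),
                       window_px = 12, marker_trace = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  barbed_end <- match.arg(barbed_end)
  img <- kymo$intensities
  n_row <- nrow(img)
  n_col <- ncol(img)
  if (!is.null(marker_trace) && length(marker_trace) != n_row) {
    stop("`marker_trace` must have one value per kymograph row",
         call. = FALSE)
  }

  fit_row <- function(profile) {
    g <- diff(running_mean(profile, 3))
    windows <- function(i_edge) {
      lo <- max(1L, i_edge - window_px)
      hi <- min(n_col, i_edge + window_px)
      if (hi - lo + 1L < 8L) {  # widen tiny windows to the minimum length
        lo <- max(1L, hi - 7L)
        hi <- min(n_col, lo + 7L)
      }
      c(lo, hi)
    }
    w_r <- windows(which.max(g))
    w_f <- windows(which.min(g))
    rise <- fit_edge(profile[w_r[1]:w_r[2]], "rising")
    fall <- fit_edge(profile[w_f[1]:w_f[2]], "falling")
    c(left = if (rise$ok) rise$center + (w_r[1] - 1) else NA_real_,
      right = if (fall$ok) fall$center + (w_f[1] - 1) else NA_real_)
  }
  pos <- t(apply(img, 1, fit_row))
  ok <- stats::complete.cases(pos)
  if (sum(ok) < 2L) {
    stop("fewer than 2 kymograph rows with successful edge fits",
         call. = FALSE)
  }

  times <- (seq_len(n_row) - 1) * kymo$frame_interval
  left_um <- pos[, "left"] * kymo$pixel_size
  right_um <- pos[, "right"] * kymo$pixel_size
  if (!is.null(marker_trace)) {
    left_um <- left_um - marker_trace
    right_um <- right_um - marker_trace
  }
  first <- which(ok)[1L]

  make_trace <- function(position_um, sign, end) {
    d_um <- sign * (position_um - position_um[first])
    structure(
      data.frame(time_s = times,
                 delta_length_subunits =
                   d_um * filakin_constants$subunits_per_um,
                 delta_length_um = d_um,
                 position_um = position_um,
                 ok = ok),
      class = c("filament_trace", "data.frame"),
      end = end, pixel_size = kymo$pixel_size,
      pausing_probability = NA_real_
    )
  }
  # the right edge grows towards +x, the left edge towards -x
  right_trace <- make_trace(right_um, +1,
                            if (barbed_end == "right") "barbed" else "pointed")
  left_trace <- make_trace(left_um, -1,
                           if (barbed_end == "left") "barbed" else "pointed")
  res <- if (barbed_end == "right") {
    list(barbed = right_trace, pointed = left_trace)
  } else {
    list(barbed = left_trace, pointed = right_trace)
  }
  res$gap_fraction <- mean(!ok)
  res
}
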