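#' Rendering parameters for synthetic kymographs
#'
#' Optical and camera parameters used by [render_kymograph()]: pixel
#' calibration, Gaussian point-spread blur, intensity levels and the noise
#' model. The default noise model is Poisson shot noise on signal plus
#' background with additive Gaussian read noise, the standard camera model.
#'
#' @param pixel_size um per pixel.
#' @param frame_interval s per kymograph row.
#' @param psf_sigma Gaussian blur width, pixels; 0 renders hard edges.
#' @param amplitude filament intensity above background, counts.
#' @param background baseline intensity, counts.
#' @param noise_model one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param seed optional integer RNG seed for the noise draws.
#' @return An object of class `render_params`.
#' @export
render_params <- function(pixel_size = 0.1, frame_interval = 1,
                          psf_sigma = 2, amplitude = 100, background = 10,
                          noise_model = c("none", "gaussian", "poisson"),
                          read_noise_sd = 2, seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_scalar(pixel_size = pixel_size, frame_interval = frame_interval,
               psf_sigma = psf_sigma, amplitude = amplitude,
               background = background, read_noise_sd = read_noise_sd,
               .ge = c("psf_sigma", "amplitude", "background",
                       "read_noise_sd"),
               .gt = c("pixel_size", "frame_interval"))
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 psf_sigma = psf_sigma, amplitude = amplitude,
                 background = background, noise_model = noise_model,
                 read_noise_sd = read_noise_sd, seed = seed),
            class = "render_params")
}

#' Construct a kymograph object
#'
#' A kymograph is a time-by-position intensity grid: one row per movie
#' frame, one column per pixel along the filament axis.
#'
#' @param intensities numeric matrix, rows = time frames, columns =
#'   position; all values finite and non-negative; at least 2 rows and 8
#'   columns.
#' @param pixel_size um per pixel.
#' @param frame_interval s per row.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensities, pixel_size, frame_interval) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensities) < 2L || ncol(intensities) < 8L) {
    stop("kymograph needs at least 2 rows and 8 columns", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("kymograph intensities must be finite and >= 0", call. = FALSE)
  }
  check_scalar(pixel_size = pixel_size, frame_interval = frame_interval,
               .gt = c("pixel_size", "frame_interval"))
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px; %.4g um/px, %.4g s/frame\n",
              nrow(x$intensities), ncol(x$intensities),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

# one kymograph row: plateau [left_px, right_px] (0-based pixel-centre
# coordinates) convolved with a Gaussian of sd sigma -> difference of erfs
kymo_row_profile <- function(n_px, left_px, right_px, sigma,
                             amplitude, background) {
  x <- seq_len(n_px) - 1
  if (sigma > 0) {
    background + amplitude / 2 *
      (erf((x - left_px) / (sqrt(2) * sigma)) -
         erf((x - right_px) / (sqrt(2) * sigma)))
  } else {
    background + amplitude * as.numeric(x >= left_px & x <= right_px)
  }
}

#' Render a synthetic kymograph from a growth trace
#'
#' Draws one kymograph row per trace sample: a plateau of intensity
#' `amplitude + background` between the two filament ends, convolved with
#' a Gaussian point-spread function, plus optional camera noise. One end
#' is fixed; the other follows the trace (growing towards increasing
#' coordinates when `moving_end = "right"`, the default barbed-end
#' polarity).
#'
#' Pixel coordinates are 0-based and refer to pixel centres: column `j` of
#' the image covers position `(j - 1) * pixel_size` um.
#'
#' @param trace a `filament_trace` (lengths in subunits; converted to um
#'   via 370 subunits/um).
#' @param rp a [render_params()] object.
#' @param initial_length_um filament length at the first frame, um.
#' @param fixed_end_px 0-based pixel coordinate of the fixed end.
#' @param moving_end which image side grows, `"right"` or `"left"`.
#' @param width_px image width in pixels; by default wide enough to
#'   contain the filament plus a 6 sigma + 5 px margin. A user-supplied
#'   width too small for the trace is an error naming the required width.
#' @return A [kymograph()] whose attribute `"truth"` holds the generating
#'   per-row edge positions (0-based pixels).
#' @export
#' @examples
#' tr <- simulate_growth_trace(growth_params(duration = 20, seed = 1))
#' ky <- render_kymograph(tr, render_params())
render_kymograph <- function(trace, rp, initial_length_um = 2,
                             fixed_end_px = 10,
                             moving_end = c("right", "left"),
                             width_px = NULL) {
  stopifnot(inherits(trace, "filament_trace"), inherits(rp, "render_params"))
  moving_end <- match.arg(moving_end)
  check_scalar(initial_length_um = initial_length_um,
               fixed_end_px = fixed_end_px,
               .ge = c("initial_length_um", "fixed_end_px"))

  len_um <- initial_length_um +
    trace$length_subunits / filakin_constants$subunits_per_um
  len_px <- len_um / rp$pixel_size
  margin <- ceiling(6 * rp$psf_sigma + 5)
  need <- ceiling(fixed_end_px + max(len_px) + margin) + 1
  if (is.null(width_px)) {
    width_px <- max(need, 8)
  } else if (width_px < need) {
    stop(sprintf("trace exceeds the image: width_px must be >= %d", need),
         call. = FALSE)
  }

  if (moving_end == "right") {
    left <- rep(fixed_end_px, length(len_px))
    right <- fixed_end_px + len_px
  } else {
    if (fixed_end_px - max(len_px) < margin - 1) {
      stop(sprintf(
        "trace exceeds the image: fixed_end_px must be >= %d for a left-moving end",
        ceiling(max(len_px) + margin)), call. = FALSE)
    }
    right <- rep(fixed_end_px, length(len_px))
    left <- fixed_end_px - len_px
  }

  img <- t(vapply(seq_along(len_px), function(k) {
    kymo_row_profile(width_px, left[k], right[k], rp$psf_sigma,
                     rp$amplitude, rp$background)
  }, numeric(width_px)))

  img <- with_seed_or_current(rp$seed, {
    out <- switch(rp$noise_model,
      none = img,
      gaussian = img + matrix(rnorm(length(img), 0, rp$read_noise_sd),
                              nrow = nrow(img)),
      poisson = matrix(rpois(length(img), pmax(img, 0)), nrow = nrow(img)) +
        matrix(rnorm(length(img), 0, rp$read_noise_sd), nrow = nrow(img))
    )
    pmax(out, 0)
  })

  ky <- kymograph(img, rp$pixel_size, rp$frame_interval)
  attr(ky, "truth") <- data.frame(time_s = trace$time_s, left_px = left,
                                  right_px = right)
  attr(ky, "moving_end") <- moving_end
  ky
}
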