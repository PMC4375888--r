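#' Simulate a planar worm-like chain contour
#'
#' Builds an ordered 2D polyline of segment length `1/spacing` um whose
#' successive turning angles are drawn from a zero-mean Gaussian with
#' variance `segment / lp`. For a chain built this way the ensemble
#' tangent-angle correlation decays as `exp(-s / (2 * lp))`, the planar
#' worm-like-chain law for surface-adsorbed filaments, so `lp` is the
#' ground-truth apparent persistence length.
#'
#' @param lp persistence length, um (> 0; `Inf` gives a rigid rod).
#' @param contour_length total contour length, um.
#' @param spacing points per micron; 6--10 is the recommended band for
#'   downstream estimation.
#' @param seed optional integer RNG seed.
#' @param theta0 initial tangent angle (radians); by default drawn
#'   uniformly on `[0, 2*pi)`.
#' @return A `filament_contour` data frame with columns `x_um`, `y_um`,
#'   ordered along the filament; attribute `"spacing_um"` holds the
#'   segment length.
#' @export
#' @examples
#' ct <- simulate_wlc(lp = 18, contour_length = 10, spacing = 8, seed = 1)
#' nrow(ct)
simulate_wlc <- function(lp, contour_length, spacing = 8, seed = NULL,
                         theta0 = NULL) {
  if (!is.numeric(lp) || length(lp) != 1L || is.na(lp) || lp <= 0) {
    stop("`lp` must be a single number > 0", call. = FALSE)
  }
  check_scalar(contour_length = contour_length, spacing = spacing,
               .gt = c("contour_length", "spacing"))
  ds <- 1 / spacing
  n_seg <- max(2L, round(contour_length * spacing))
  with_seed_or_current(seed, {
    t0 <- if (is.null(theta0)) runif(1, 0, 2 * pi) else theta0
    dtheta <- if (is.finite(lp)) {
      rnorm(n_seg - 1L, mean = 0, sd = sqrt(ds / lp))
    } else {
      numeric(n_seg - 1L)
    }
    theta <- t0 + c(0, cumsum(dtheta))
    x <- c(0, cumsum(cos(theta) * ds))
    y <- c(0, cumsum(sin(theta) * ds))
    structure(data.frame(x_um = x, y_um = y),
              class = c("filament_contour", "data.frame"),
              spacing_um = ds, lp_true = lp)
  })
}

#' Closed-form mean squared end-to-end distance of a planar worm-like chain
#'
#' For a 2D chain whose tangent correlation decays as `exp(-s / xi)` with
#' `xi = 2 * lp`, the mean squared end-to-end distance of a contour of
#' length `L` is `2 * xi * L - 2 * xi^2 * (1 - exp(-L / xi))`. Used as an
#' independent check of the generator.
#'
#' @param lp persistence length, um.
#' @param contour_length contour length `L`, um.
#' @return Mean squared end-to-end distance, um^2.
#' @export
wlc_mean_square_ee <- function(lp, contour_length) {
  xi <- 2 * lp
  2 * xi * contour_length - 2 * xi^2 * (1 - exp(-contour_length / xi))
}
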