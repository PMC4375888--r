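#' Fit an error-function edge model to an intensity profile
#'
#' Estimates the subpixel position of a filament end from a 1D intensity
#' profile by least-squares fitting of the blurred-step model
#' `I(x) = B + (A / 2) * (1 + p * erf((x - mu) / (sqrt(2) * sigma)))`
#' with `p = +1` for a rising edge and `p = -1` for a falling edge.
#' `mu` is the edge centre in 0-based pixel-centre coordinates, `sigma`
#' the blur width, `A` the edge amplitude and `B` the low-side baseline.
#'
#' Initialisation places `mu` at the maximum-magnitude gradient position;
#' bounds constrain `mu` to the profile support, `sigma` to (0.3, 10]
#' pixels and `A >= 0`. The fit is flagged as failed (`ok = FALSE`) when
#' it does not converge or when the fitted amplitude is not
#' distinguishable from noise (`A < 3` times the robust noise SD of the
#' profile); an all-constant profile fails with reason `"no edge"`.
#'
#' @param profile numeric vector of intensities, length >= 8, finite.
#' @param polarity `"rising"` (dark to bright with increasing `x`) or
#'   `"falling"`.
#' @return An `edge_fit` list: `center`, `width`, `amplitude`,
#'   `background`, `polarity`, `rss`, `ok`, `reason`.
#' @export
#' @examples
#' x <- 0:39
#' prof <- 10 + 100 * erf_profile(x, 17.3, 2)
#' fit_edge(prof, "rising")$center
fit_edge <- function(profile, polarity = c("rising", "falling")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(profile) || length(profile) < 8L) {
    stop("`profile` must be numeric with length >= 8", call. = FALSE)
  }
  if (any(!is.finite(profile))) {
    stop("`profile` must be finite", call. = FALSE)
  }
  n <- length(profile)
  x <- seq_len(n) - 1
  p_sign <- if (polarity == "rising") 1 else -1

  failed <- function(reason) {
    structure(list(center = NA_real_, width = NA_real_,
                   amplitude = NA_real_, background = NA_real_,
                   polarity = polarity, rss = NA_real_, ok = FALSE,
                   reason = reason),
              class = "edge_fit")
  }
  g <- diff(profile)
  if (all(g == 0)) return(failed("no edge"))

  # robust noise level: scaled MAD of successive differences
  noise_sd <- mad(g) / sqrt(2)

  # initialise mu at the maximum-magnitude gradient; a lightly smoothed
  # gradient is tried as well, since shot noise on bright plateaus can
  # outgun the true edge slope in the raw differences
  g_smooth <- diff(running_mean(profile, 3))
  pick <- function(grad) {
    if (polarity == "rising") which.max(grad) else which.min(grad)
  }
  mu0s <- unique(pmin(pmax(c(pick(g), pick(g_smooth)) - 0.5, 0), n - 1))
  b0 <- min(profile)
  a0 <- max(diff(range(profile)), .Machine$double.eps)

  try_fit <- function(mu0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ B + A / 2 * (1 + p_sign * erf((x - mu) / (sqrt(2) * sigma))),
        data = list(y = profile, x = x, p_sign = p_sign),
        start = list(mu = mu0, sigma = 2, A = a0, B = b0),
        lower = c(mu = 0, sigma = 0.3 + 1e-9, A = 0, B = -Inf),
        upper = c(mu = n - 1, sigma = 10, A = Inf, B = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), lapply(mu0s, try_fit))
  if (length(fits) == 0L) return(failed("did not converge"))
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  cf <- coef(fit)
  if (cf[["A"]] < 3 * noise_sd) return(failed("amplitude below noise"))
  structure(list(center = unname(cf[["mu"]]), width = unname(cf[["sigma"]]),
                 amplitude = unname(cf[["A"]]),
                 background = unname(cf[["B"]]),
                 polarity = polarity,
                 rss = sum(residuals(fit)^2), ok = TRUE, reason = NULL),
            class = "edge_fit")
}

#' Error-function edge profile
#'
#' Helper evaluating `(1/2) * (1 + erf((x - mu) / (sqrt(2) * sigma)))`,
#' the unit-amplitude rising-edge model of [fit_edge()] (a hard step at
#' `mu` when `sigma = 0`).
#'
#' @param x positions (pixels).
#' @param mu edge centre.
#' @param sigma blur width.
#' @return Values in `[0, 1]`.
#' @export
erf_profile <- function(x, mu, sigma) {
  if (sigma > 0) (1 + erf((x - mu) / (sqrt(2) * sigma))) / 2
  else as.numeric(x >= mu)
}

#' @export
print.edge_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<edge_fit ok> %s edge at %.3f px (sigma %.2f, A %.3g, B %.3g)\n",
                x$polarity, x$center, x$width, x$amplitude, x$background))
  } else {
    cat(sprintf("<edge_fit failed> %s\n", x$reason))
  }
  invisible(x)
}
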