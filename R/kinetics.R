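# common accessor: length series in subunits from either trace flavour
trace_lengths <- function(trace) {
  if ("length_subunits" %in% names(trace)) trace$length_subunits
  else if ("delta_length_subunits" %in% names(trace)) {
    trace$delta_length_subunits
  } else {
    stop("trace has no `length_subunits` or `delta_length_subunits` column",
         call. = FALSE)
  }
}

#' Smoothed instantaneous elongation velocity
#'
#' Centred finite differences of the length series divided by the sample
#' interval, followed by a centred running mean of `window` samples
#' (shrunken at the edges). `window = 1` returns the raw finite
#' differences. The default window of 10 matches a 10-point running
#' average on 1 s sampling.
#'
#' @param trace a `filament_trace` (uniform time grid).
#' @param window running-mean length, samples.
#' @return Numeric velocity series, subunits/s, one value per sample.
#' @export
#' @examples
#' tr <- simulate_growth_trace(growth_params(duration = 60, seed = 2))
#' v <- smooth_velocity(tr)
smooth_velocity <- function(trace, window = 10) {
  len <- trace_lengths(trace)
  times <- trace$time_s
  n <- length(len)
  if (n < window + 1L) {
    stop("trace must have at least `window` + 1 samples", call. = FALSE)
  }
  if (!is_uniform_grid(times)) {
    stop("non-uniform time grid; resample the trace first", call. = FALSE)
  }
  dt <- times[2] - times[1]
  v <- numeric(n)
  v[1] <- (len[2] - len[1]) / dt
  v[n] <- (len[n] - len[n - 1]) / dt
  if (n > 2L) {
    i <- 2:(n - 1L)
    v[i] <- (len[i + 1L] - len[i - 1L]) / (2 * dt)
  }
  running_mean(v, window)
}

#' Classify samples into kinetically active and paused phases
#'
#' A sample is kinetically active when its (smoothed) velocity exceeds
#' the threshold -- 1.5 subunits/s by default, the cut separating
#' elongation from pauses -- and paused otherwise. Runs shorter than
#' `min_run` samples are merged into the surrounding phase to suppress
#' flicker. The pausing probability `P_p` is the fraction of samples
#' spent paused.
#'
#' @param velocities numeric velocity series, subunits/s.
#' @param threshold active/paused velocity cut, subunits/s.
#' @param min_run minimum run length kept as a distinct phase, samples.
#' @return A `phase_summary` list: `labels` (character vector,
#'   `"active"`/`"paused"`), `pausing_probability`,
#'   `active_mean_velocity`, `threshold`.
#' @export
#' @examples
#' classify_phases(c(9, 9, 0, 0, 9), min_run = 1)$pausing_probability
classify_phases <- function(velocities, threshold = 1.5, min_run = 3) {
  if (any(!is.finite(velocities))) {
    stop("`velocities` must be finite", call. = FALSE)
  }
  check_scalar(threshold = threshold, min_run = min_run,
               .gt = c("threshold", "min_run"))
  active <- velocities > threshold
  # debounce: flip the shortest sub-minimum run until none remain
  repeat {
    r <- rle(active)
    short <- which(r$lengths < min_run)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1L):ends[k]
    active[idx] <- !r$values[k]
  }
  labels <- ifelse(active, "active", "paused")
  structure(list(
    labels = labels,
    pausing_probability = mean(!active),
    active_mean_velocity = if (any(active)) mean(velocities[active])
                           else NA_real_,
    threshold = threshold
  ), class = "phase_summary")
}

#' Pause-free elongation velocity of a trace
#'
#' Mean elongation velocity over the kinetically active phases only: the
#' trace is smoothed and classified ([smooth_velocity()],
#' [classify_phases()]), a least-squares slope of length vs time is
#' fitted within every active run of at least 3 samples, and the slopes
#' are combined as a duration-weighted mean with the SEM taken across
#' runs.
#'
#' @param trace a `filament_trace`.
#' @param threshold active/paused velocity cut, subunits/s.
#' @param window smoothing window, samples.
#' @param min_run minimum phase run length, samples.
#' @return List with `e` (mean pause-free velocity, subunits/s), `sem`
#'   (`NA` for a single run), `n_runs`, `pausing_probability`.
#' @export
#' @examples
#' tr <- simulate_growth_trace(growth_params(duration = 200, seed = 3))
#' pause_free_velocity(tr)$e
pause_free_velocity <- function(trace, threshold = 1.5, window = 10,
                                min_run = 3) {
  len <- trace_lengths(trace)
  times <- trace$time_s
  v <- smooth_velocity(trace, window)
  phases <- classify_phases(v, threshold, min_run)
  r <- rle(phases$labels == "active")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  slopes <- numeric(0)
  durations <- numeric(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 3L) next
    slopes <- c(slopes, unname(coef(lm(len[idx] ~ times[idx]))[2]))
    durations <- c(durations, times[ends[k]] - times[starts[k]])
  }
  if (length(slopes) == 0L) {
    stop("fully paused trace: no active run of >= 3 samples", call. = FALSE)
  }
  list(e = weighted.mean(slopes, durations),
       sem = if (length(slopes) > 1L) sd(slopes) / sqrt(length(slopes))
             else NA_real_,
       n_runs = length(slopes),
       pausing_probability = phases$pausing_probability)
}

#' Fit association and dissociation rate constants
#'
#' Linear fit of pause-free elongation velocity `E` against free actin
#' concentration `c`: `E = kon * c - koff`, so the slope is the
#' association rate constant and the negative intercept the dissociation
#' rate (the extrapolation of `E` to zero actin). The ratio `koff / kon`
#' is the critical concentration. Weighted least squares (weights
#' `1 / sem^2`) when standard errors are supplied; 95% confidence
#' intervals from the t distribution with `n - 2` degrees of freedom (the
#' critical-concentration interval by the delta method). A negative
#' fitted `koff` is reported as-is, never clipped.
#'
#' @param points data frame with columns `conc` (uM), `e` (subunits/s)
#'   and optionally `sem`; at least 2 distinct concentrations.
#' @return A `kinetic_rates` list: `kon`, `koff`, `cc`, `ci95_kon`,
#'   `ci95_koff`, `ci95_cc`, `n_points`.
#' @export
#' @examples
#' pts <- data.frame(conc = c(0.3, 0.5, 1, 2), e = 11 * c(0.3, 0.5, 1, 2) - 1.6)
#' fit_rate_constants(pts)
fit_rate_constants <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("conc", "e") %in% names(points))) {
    stop("`points` needs columns `conc` and `e`", call. = FALSE)
  }
  if (length(unique(points$conc)) < 2L) {
    stop("at least 2 distinct concentrations are required", call. = FALSE)
  }
  w <- if ("sem" %in% names(points) && all(is.finite(points$sem)) &&
           all(points$sem > 0)) 1 / points$sem^2 else NULL
  fit <- if (is.null(w)) lm(e ~ conc, data = points)
         else lm(e ~ conc, data = points, weights = w)
  cf <- coef(fit)
  kon <- unname(cf[2])
  koff <- -unname(cf[1])
  cc <- if (kon != 0) koff / kon else NA_real_

  n <- nrow(points)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  ci95_kon <- unname(ci["conc", ])
  ci95_koff <- sort(-unname(ci["(Intercept)", ]))
  # delta method for cc = -b0 / b1 (suppress the "essentially perfect
  # fit" warning that exact collinear inputs trigger)
  V <- suppressWarnings(vcov(fit))
  grad <- c(-1 / kon, -koff / kon^2)  # d(-b0/b1)/d(b0, b1)
  se_cc <- sqrt(drop(t(grad) %*% V %*% grad))
  tq <- qt(0.975, df = n - 2)
  ci95_cc <- cc + c(-1, 1) * tq * se_cc

  structure(list(kon = kon, koff = koff, cc = cc,
                 ci95_kon = ci95_kon, ci95_koff = ci95_koff,
                 ci95_cc = ci95_cc, n_points = n),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf(
    "<kinetic_rates> kon = %.3g [%.3g, %.3g] sub/uM/s; koff = %.3g [%.3g, %.3g] sub/s; cc = %.2g uM (n = %d)\n",
    x$kon, x$ci95_kon[1], x$ci95_kon[2],
    x$koff, x$ci95_koff[1], x$ci95_koff[2], x$cc, x$n_points))
  invisible(x)
}

#' Critical concentration from rate constants
#'
#' The monomer concentration `koff / kon` at which net elongation at an
#' end is zero.
#'
#' @param kon association rate constant, subunits uM^-1 s^-1 (non-zero).
#' @param koff dissociation rate, subunits s^-1.
#' @return Critical concentration, uM.
#' @export
#' @examples
#' critical_concentration(11, 1.6) # ~0.15 uM
critical_concentration <- function(kon, koff) {
  check_scalar(kon = kon, koff = koff)
  if (kon == 0) {
    stop("critical concentration is undefined for kon = 0", call. = FALSE)
  }
  koff / kon
}
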