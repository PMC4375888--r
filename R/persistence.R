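#' Resample a contour to uniform arc-length spacing
#'
#' Linear interpolation of the contour at equally spaced arc-length
#' positions. Uniform spacing is required before tangent angles are
#' compared along the contour, since irregular point spacing biases the
#' persistence-length estimate.
#'
#' @param contour data frame or matrix with ordered `x_um`, `y_um`
#'   columns (>= 10 points, consecutive points distinct).
#' @param spacing target inter-point arc length, um; defaults to the
#'   contour's mean segment length.
#' @return A `filament_contour` data frame with attribute `"spacing_um"`.
#' @export
resample_contour <- function(contour, spacing = NULL) {
  xy <- as.data.frame(contour)
  if (!all(c("x_um", "y_um") %in% names(xy))) {
    names(xy)[1:2] <- c("x_um", "y_um")
  }
  if (nrow(xy) < 10L) stop("contour needs >= 10 points", call. = FALSE)
  seg <- sqrt(diff(xy$x_um)^2 + diff(xy$y_um)^2)
  if (any(seg == 0)) {
    stop("consecutive contour points must be distinct", call. = FALSE)
  }
  s <- c(0, cumsum(seg))
  if (is.null(spacing)) spacing <- mean(seg)
  s_new <- seq(0, s[length(s)], by = spacing)
  structure(data.frame(
    x_um = approx(s, xy$x_um, xout = s_new)$y,
    y_um = approx(s, xy$y_um, xout = s_new)$y
  ), class = c("filament_contour", "data.frame"), spacing_um = spacing)
}

# tangent angles of a uniformly spaced contour: one angle per segment
# chord. Chord tangents keep the exponential tangent-correlation law
# exact at every lag on polygonal chains, whereas wider (e.g. central
# difference) stencils smooth the turning angles and bias the apparent
# persistence length upward.
contour_tangents <- function(contour) {
  atan2(diff(contour$y_um), diff(contour$x_um))
}

#' Tangent-angle correlation of filament contours
#'
#' For each arc-length separation `s` on a uniform grid, the mean of
#' `cos(theta(u + s) - theta(u))` over all admissible point pairs --
#' pooled across every contour by default (all-pairs averaging, not
#' anchored at one end). For a planar worm-like chain this correlation
#' decays as `exp(-s / (2 * Lp))`.
#'
#' @param contours a single contour or a list of contours (data frames
#'   with `x_um`, `y_um`); each is arc-length resampled to `spacing`
#'   before tangents are computed.
#' @param spacing resampling spacing, um; default: the first contour's
#'   mean segment length.
#' @param s_max largest separation evaluated, um; default: half the mean
#'   contour length (larger separations are pair-starved).
#' @param per_filament average the correlation within each filament
#'   first, then across filaments, instead of pooling all pairs.
#' @details Tangent angles are taken per segment chord of the resampled
#'   contour; on a polygonal chain this preserves the exponential
#'   correlation law exactly at every lag (wider difference stencils
#'   smooth the turning angles and inflate the apparent stiffness).
#' @return Data frame with columns `s` (um), `correlation`, `n_pairs`;
#'   attribute `"n_filaments"`.
#' @export
#' @examples
#' chains <- lapply(1:20, function(k)
#'   simulate_wlc(18, 10, 8, seed = k))
#' head(tangent_correlation(chains))
tangent_correlation <- function(contours, spacing = NULL, s_max = NULL,
                                per_filament = FALSE) {
  if (is.data.frame(contours) || is.matrix(contours)) {
    contours <- list(contours)
  }
  if (length(contours) == 0L) stop("no contours supplied", call. = FALSE)
  if (is.null(spacing)) {
    c1 <- as.data.frame(contours[[1L]])
    if (!all(c("x_um", "y_um") %in% names(c1))) {
      names(c1)[1:2] <- c("x_um", "y_um")
    }
    spacing <- mean(sqrt(diff(c1$x_um)^2 + diff(c1$y_um)^2))
  }
  resampled <- lapply(contours, resample_contour, spacing = spacing)
  thetas <- lapply(resampled, contour_tangents)
  mean_len <- mean(vapply(thetas, length, integer(1))) * spacing
  if (is.null(s_max)) s_max <- mean_len / 2
  k_max <- floor(s_max / spacing)
  if (k_max < 1L) {
    stop("`s_max` smaller than the contour spacing", call. = FALSE)
  }
  if (k_max * spacing > max(vapply(thetas, length, integer(1)) - 1) * spacing) {
    stop("`s_max` exceeds every contour length", call. = FALSE)
  }

  rows <- lapply(seq_len(k_max), function(k) {
    per <- vapply(thetas, function(th) {
      n <- length(th)
      if (n <= k) return(c(0, 0))
      dth <- th[(k + 1):n] - th[seq_len(n - k)]
      c(sum(cos(dth)), n - k)
    }, numeric(2))
    n_pairs <- sum(per[2, ])
    corr <- if (per_filament) {
      use <- per[2, ] > 0
      mean(per[1, use] / per[2, use])
    } else {
      sum(per[1, ]) / n_pairs
    }
    data.frame(s = k * spacing, correlation = corr, n_pairs = n_pairs)
  })
  structure(do.call(rbind, rows), n_filaments = length(contours),
            spacing_um = spacing)
}

#' Fit the apparent persistence length
#'
#' Single-parameter nonlinear least squares of the planar worm-like-chain
#' law `correlation = exp(-s / (2 * Lp))` to a tangent-correlation table.
#' The fit is performed on the cosine values directly (robust when
#' correlations approach zero); the starting value comes from a
#' log-linear regression. Correlations indistinguishable from 1
#' (effectively straight input) return `capped = TRUE` with `lp = Inf`;
#' non-positive correlations inside the range shrink it with a warning.
#'
#' @param corr_table data frame from [tangent_correlation()] (columns
#'   `s`, `correlation`).
#' @param s_max largest separation used in the fit, um; default: all
#'   rows. At least 5 separations must remain.
#' @return A `persistence_fit` list: `lp` (um), `s_max`, `n_filaments`,
#'   `capped`.
#' @export
#' @examples
#' tab <- data.frame(s = 1:20 / 2, correlation = exp(-(1:20) / 2 / 36))
#' fit_persistence_length(tab)$lp # 18
fit_persistence_length <- function(corr_table, s_max = NULL) {
  tab <- as.data.frame(corr_table)
  if (!all(c("s", "correlation") %in% names(tab))) {
    stop("`corr_table` needs columns `s` and `correlation`", call. = FALSE)
  }
  if (!is.null(s_max)) tab <- tab[tab$s <= s_max, , drop = FALSE]
  bad <- which(tab$correlation <= 0)
  if (length(bad) > 0L) {
    warning("non-positive correlations in range; shrinking the fit range")
    tab <- tab[seq_len(min(bad) - 1L), , drop = FALSE]
  }
  if (nrow(tab) < 5L) {
    stop("fewer than 5 usable separations in the fit range", call. = FALSE)
  }
  n_fil <- attr(corr_table, "n_filaments")
  if (all(tab$correlation > 1 - 1e-9)) {
    return(structure(list(lp = Inf, s_max = max(tab$s),
                          n_filaments = n_fil, capped = TRUE),
                     class = "persistence_fit"))
  }
  lp0 <- -mean(tab$s) / (2 * mean(log(pmax(tab$correlation, 1e-12))))
  lp0 <- min(max(lp0, 1e-3), 1e5)
  fit <- minpack.lm::nlsLM(
    correlation ~ exp(-s / (2 * lp)),
    data = tab, start = list(lp = lp0),
    lower = c(lp = 1e-6), upper = c(lp = 1e7),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  structure(list(lp = unname(coef(fit)[["lp"]]), s_max = max(tab$s),
                 n_filaments = n_fil, capped = FALSE),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  if (x$capped) {
    cat("<persistence_fit> effectively straight input (correlation ~ 1); no finite Lp\n")
  } else {
    cat(sprintf("<persistence_fit> Lp = %.3g um (s <= %.3g um%s)\n",
                x$lp, x$s_max,
                if (!is.null(x$n_filaments))
                  sprintf(", %d filaments", x$n_filaments) else ""))
  }
  invisible(x)
}

#' Estimate persistence length from raw contours
#'
#' Convenience wrapper: [tangent_correlation()] followed by
#' [fit_persistence_length()].
#'
#' @inheritParams tangent_correlation
#' @param s_max fit range, um; default half the mean contour length.
#' @return A `persistence_fit`.
#' @export
estimate_persistence_length <- function(contours, spacing = NULL,
                                        s_max = NULL,
                                        per_filament = FALSE) {
  tab <- tangent_correlation(contours, spacing = spacing, s_max = s_max,
                             per_filament = per_filament)
  fit_persistence_length(tab)
}
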