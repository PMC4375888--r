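# internal helpers shared across modules

# Gauss error function
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# stop() unless every argument is a finite scalar number
check_scalar <- function(..., .ge = NULL, .gt = NULL) {
  args <- list(...)
  nms <- names(args)
  for (k in seq_along(args)) {
    x <- args[[k]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nms[k]), call. = FALSE)
    }
  }
  if (!is.null(.ge)) {
    for (nm in .ge) {
      if (args[[nm]] < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    }
  }
  if (!is.null(.gt)) {
    for (nm in .gt) {
      if (args[[nm]] <= 0) stop(sprintf("`%s` must be > 0", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# run `expr` under a private RNG state seeded with `seed`; when seed is NULL
# draw from the session RNG unscoped (still reproducible via set.seed()).
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# centred running mean with shrunken windows at the edges
running_mean <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window == 1L || n == 0L) return(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# TRUE when a time grid is uniform to relative tolerance
is_uniform_grid <- function(times, tol = 1e-6) {
  dt <- diff(times)
  length(dt) > 0 && all(dt > 0) &&
    (max(dt) - min(dt)) <= tol * max(abs(dt))
}
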