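#' Estimate stage drift of a movie by image cross-correlation
#'
#' The offset of every frame relative to the first is located at the peak
#' of the 2D cross-correlation (computed by FFT), refined to subpixel
#' precision by a local parabolic interpolation of the correlation peak
#' in each axis.
#'
#' Offsets follow the convention `frame[i, j] ~ ref[i - dy, j - dx]`, i.e.
#' a frame whose content moved down/right relative to the first has
#' positive `(dy, dx)`.
#'
#' @param frames list of numeric matrices of identical dimensions (>= 2).
#' @return A data frame with one row per frame and columns `dy`, `dx`
#'   (pixels); the first row is `(0, 0)`.
#' @export
#' @examples
#' f <- matrix(rnorm(400), 20, 20)
#' estimate_drift(list(f, f))
estimate_drift <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("`frames` must be a list of >= 2 matrices", call. = FALSE)
  }
  dims <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be matrices of identical shape", call. = FALSE)
    }
  }
  ref <- frames[[1L]]
  fr <- stats::fft(ref)
  out <- t(vapply(frames, function(f) {
    cross_correlation_offset(fr, stats::fft(f), dims)
  }, numeric(2)))
  data.frame(dy = out[, 1], dx = out[, 2])
}

# subpixel offset from the cross-correlation of two FFTs
cross_correlation_offset <- function(fft_ref, fft_frame, dims) {
  cc <- Re(stats::fft(Conj(fft_ref) * fft_frame, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wraparound-safe neighbour lookup and signed shift
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  signed <- function(i, n) if (i - 1L > n %/% 2L) i - 1L - n else i - 1L
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  py <- peak[1]; px <- peak[2]
  dy <- signed(py, dims[1]) +
    refine(cc[wrap(py - 1L, dims[1]), px], cc[py, px],
           cc[wrap(py + 1L, dims[1]), px])
  dx <- signed(px, dims[2]) +
    refine(cc[py, wrap(px - 1L, dims[2])], cc[py, px],
           cc[py, wrap(px + 1L, dims[2])])
  c(dy, dx)
}

# Keys bicubic convolution kernel, a = -0.5
keys_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# translate one matrix by (dy, dx) using separable bicubic interpolation;
# pixels whose 4x4 support leaves the frame become NA
bicubic_translate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  if (fy == 0 && fx == 0) {
    offs_y <- 0L; wy <- 1
    offs_x <- 0L; wx <- 1
  } else {
    offs_y <- -1L:2L; wy <- keys_kernel(fy - offs_y)
    offs_x <- -1L:2L; wx <- keys_kernel(fx - offs_x)
    if (fy == 0) { offs_y <- 0L; wy <- 1 }
    if (fx == 0) { offs_x <- 0L; wx <- 1 }
  }
  out <- matrix(0, nr, nc)
  support <- matrix(TRUE, nr, nc)
  rows <- seq_len(nr); cols <- seq_len(nc)
  for (a in seq_along(offs_y)) {
    for (b in seq_along(offs_x)) {
      src_r <- rows + iy + offs_y[a]
      src_c <- cols + ix + offs_x[b]
      ok_r <- src_r >= 1L & src_r <= nr
      ok_c <- src_c >= 1L & src_c <= nc
      piece <- matrix(NA_real_, nr, nc)
      piece[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
      bad <- is.na(piece)
      piece[bad] <- 0
      support <- support & !bad
      out <- out + wy[a] * wx[b] * piece
    }
  }
  out[!support] <- NA_real_
  out
}

#' Correct stage drift by bicubic resampling
#'
#' Resamples every frame at coordinates shifted by its estimated offset
#' (bicubic convolution interpolation, Keys kernel), so the returned
#' frames are registered to the first. Integer offsets reduce to an exact
#' pixel relabeling. Border pixels whose interpolation support falls
#' outside the frame are flagged as `NA`.
#'
#' @param frames list of numeric matrices of identical dimensions.
#' @param offsets data frame with columns `dy`, `dx` (one row per frame),
#'   as from [estimate_drift()].
#' @return List of drift-corrected frames.
#' @export
correct_drift <- function(frames, offsets) {
  if (!is.list(frames)) stop("`frames` must be a list", call. = FALSE)
  offsets <- as.data.frame(offsets)
  if (nrow(offsets) != length(frames) ||
      !all(c("dy", "dx") %in% names(offsets))) {
    stop("`offsets` must have one (dy, dx) row per frame", call. = FALSE)
  }
  dims <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be matrices of identical shape", call. = FALSE)
    }
  }
  lapply(seq_along(frames), function(k) {
    if (offsets$dy[k] == 0 && offsets$dx[k] == 0) frames[[k]]
    else bicubic_translate(frames[[k]], offsets$dy[k], offsets$dx[k])
  })
}
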