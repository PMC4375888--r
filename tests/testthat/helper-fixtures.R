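# shared fixtures built in code

# a bare filament trace with prescribed length series (subunits)
make_trace <- function(times, lengths, phase = NULL) {
  df <- data.frame(time_s = times, length_subunits = lengths)
  if (!is.null(phase)) df$phase <- phase
  structure(df, class = c("filament_trace", "data.frame"),
            pausing_probability = if (is.null(phase)) NA_real_
                                  else mean(phase == "paused"),
            end = "barbed")
}

# an exactly linear trace of a given slope (subunits/s)
make_linear_trace <- function(slope, duration = 100, dt = 1) {
  times <- seq(0, duration, by = dt)
  make_trace(times, slope * times)
}

# independent brute-force evaluation of the allosteric per-site rate:
# literal double loop over sites and tethers, max over contributions
brute_force_kon <- function(n_sites, tethers, alpha, l_c, kon0) {
  out <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    best <- 0
    for (j in tethers) {
      d <- i - j
      if (d >= 0 && d < l_c) best <- max(best, 1 - d / l_c)
    }
    out[i] <- (1 + (alpha - 1) * best) * kon0
  }
  out
}

# points on a circle of radius r with uniform arc spacing (um)
make_arc_contour <- function(r, arc_length, spacing_um) {
  phi <- seq(0, arc_length / r, by = spacing_um / r)
  data.frame(x_um = r * cos(phi), y_um = r * sin(phi))
}
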