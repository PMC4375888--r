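#' Forward-simulate an elongation-vs-tether-density dataset
#'
#' Generates, with the allosteric Monte Carlo model as the forward model,
#' the mean and spread of elongation velocity at each requested surface
#' density: `reps` independent random tether placements per density, with
#' optional additional Gaussian measurement noise. This is the synthetic
#' counterpart of an elongation-velocity-vs-density experiment and is the
#' natural input of [grid_fit()].
#'
#' @param alpha,l_c generating allosteric parameters, see
#'   [effective_kon()].
#' @param cfg an [mc_config()]; its `seed` field governs all randomness
#'   here (the per-placement draws are taken from one seeded stream).
#' @param densities surface densities, molecules per um^2 (non-empty).
#' @param reps independent tether placements per density (>= 1).
#' @param noise_sd additional Gaussian measurement noise on each
#'   replicate velocity, subunits/s.
#' @return A `density_response` data frame with columns
#'   `density_per_um2`, `occupancy`, `v_mean`, `v_std`, `n`.
#' @export
#' @examples
#' dr <- simulate_density_response(5.1, 76, mc_config(n_sites = 1e4, seed = 1),
#'                                 densities = c(10, 1000, 10000), reps = 5)
simulate_density_response <- function(alpha, l_c, cfg, densities,
                                      reps = 20, noise_sd = 0) {
  stopifnot(inherits(cfg, "mc_config"))
  if (length(densities) == 0L) {
    stop("`densities` must be non-empty", call. = FALSE)
  }
  check_scalar(alpha = alpha, l_c = l_c, reps = reps, noise_sd = noise_sd,
               .gt = c("alpha", "reps"), .ge = "noise_sd")
  reps <- as.integer(reps)
  occ <- occupancy_from_density(densities)
  cfg_run <- cfg
  cfg_run$seed <- NULL
  with_seed_or_current(if (is.null(cfg$seed)) NULL else cfg$seed, {
    rows <- lapply(seq_along(densities), function(k) {
      v <- vapply(seq_len(reps), function(r) {
        tethers <- place_tethers(cfg$n_sites, occ[k])
        simulate_elongation(cfg_run, alpha, l_c, occ[k], tethers = tethers)
      }, numeric(1))
      if (noise_sd > 0) v <- v + rnorm(reps, 0, noise_sd)
      data.frame(density_per_um2 = densities[k], occupancy = occ[k],
                 v_mean = mean(v), v_std = if (reps > 1) sd(v) else 0,
                 n = reps)
    })
    structure(do.call(rbind, rows),
              class = c("density_response", "data.frame"),
              alpha = alpha, l_c = l_c, cfg = cfg)
  })
}
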