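#' Surface density of adsorbed protein from solution concentration
#'
#' Converts the concentration of side-binding protein introduced into a
#' flow cell to a surface density, assuming all protein in the sample
#' volume adsorbs to the glass. The default geometry is a 10 uL sample in
#' a 5 mm x 20 mm flow cell (100 mm^2 per face); with
#' `both_surfaces = TRUE` the protein distributes over the upper and
#' lower glass surfaces (200 mm^2 total).
#'
#' @param conc_nM protein concentration, nM.
#' @param volume_uL sample volume, uL.
#' @param area_mm2 adsorbing area of one face, mm^2.
#' @param both_surfaces adsorb to both faces (doubles the area)?
#' @return Surface density, molecules per um^2.
#' @export
#' @examples
#' surface_density_from_concentration(1) # ~30.1 molecules/um^2
surface_density_from_concentration <- function(conc_nM, volume_uL = 10,
                                               area_mm2 = 100,
                                               both_surfaces = TRUE) {
  check_scalar(volume_uL = volume_uL, area_mm2 = area_mm2,
               .gt = c("volume_uL", "area_mm2"))
  if (any(!is.finite(conc_nM)) || any(conc_nM < 0)) {
    stop("`conc_nM` must be finite and >= 0", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  molecules <- conc_nM * 1e-9 * volume_uL * 1e-6 * avogadro
  area_um2 <- area_mm2 * 1e6 * (if (both_surfaces) 2 else 1)
  molecules / area_um2
}

#' Tethers per micron of filament from surface density
#'
#' One micron of filament occupies 0.006 um^2 of surface, so a surface
#' density `rho` (molecules/um^2) corresponds to `rho * 0.006` molecules
#' per micron of filament.
#'
#' @param density surface density, molecules per um^2.
#' @return Molecules per um of filament.
#' @export
#' @examples
#' tethers_per_micron(5900) # ~35 molecules per micron
tethers_per_micron <- function(density) {
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be finite and >= 0", call. = FALSE)
  }
  density * filakin_constants$filament_footprint_um2
}

#' Fractional lattice occupancy from tethers per micron
#'
#' Converts molecules per micron of filament to a per-monomer-site
#' occupation probability using 370 subunits per micron, capped at 1
#' (one tether per subunit).
#'
#' @param per_micron molecules per um of filament.
#' @return Per-site occupancy in `[0, 1]`.
#' @export
#' @examples
#' fractional_occupancy(35.4) # ~0.096
fractional_occupancy <- function(per_micron) {
  if (any(!is.finite(per_micron)) || any(per_micron < 0)) {
    stop("`per_micron` must be finite and >= 0", call. = FALSE)
  }
  pmin(per_micron / filakin_constants$subunits_per_um, 1)
}

#' Per-site occupancy directly from surface density
#'
#' Convenience composition of [tethers_per_micron()] and
#' [fractional_occupancy()].
#'
#' @param density surface density, molecules per um^2.
#' @return Per-site occupancy in `[0, 1]`.
#' @export
occupancy_from_density <- function(density) {
  fractional_occupancy(tethers_per_micron(density))
}
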