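---
title: "Methods: single-filament elongation kinetics and lattice-binding modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-filament elongation kinetics and lattice-binding modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filakin)
```

## Scope and model

`filakin` analyses the growth of single actin filaments imaged by TIRF
microscopy, where filaments are tethered to a glass surface by a
side-binding protein (NEM-myosin, filamin, alpha-actinin, VASP, ...) and a
kymograph — one intensity row per movie frame along the filament axis —
records the motion of both ends. The package covers five linked
computations:

1. **End localisation.** The filament tip blurs into an error-function
   intensity step, $I(x) = B + \tfrac{A}{2}\left[1 + p\,
   \mathrm{erf}\!\left(\tfrac{x-\mu}{\sqrt{2}\sigma}\right)\right]$, and
   `fit_edge()` estimates the subpixel centre $\mu$ per kymograph row
   ($p = \pm 1$ selects a rising or falling edge). `track_ends()` applies
   this to both sides of every row and converts positions to micrometres
   and to subunits (370 subunits per micron of filament).
2. **Kinetics.** Instantaneous velocities are centred finite differences
   passed through a 10-sample running mean (`smooth_velocity()`); samples
   above 1.5 subunits/s are "kinetically active", the rest are paused,
   and the pausing probability $P_p$ is the paused time fraction
   (`classify_phases()`). Pause-free elongation velocities $E$ at several
   actin concentrations $c$ give the rate constants through the linear
   law $E = k_{on} c - k_{off}$ (`fit_rate_constants()`), with the
   critical concentration $k_{off}/k_{on}$.
3. **Allosteric Monte Carlo model.** A lattice-bound tether multiplies
   the basal association rate $k_{on}^0$ by $\alpha$ at its site, an
   effect that decays linearly to 1 over $L_C$ monomers
   (`effective_kon()`); the mean elongation velocity over an
   $N$-monomer lattice with random tether placement is compared to
   measured velocity-vs-density curves through
   $\chi^2(\alpha, L_C) = \sum_i \left[(v(x_i) -
   v_{sim}(x_i,\alpha,L_C))/\mathrm{std}(x_i)\right]^2$ and minimised on
   a coarse-then-refined grid (`grid_fit()`), with confidence intervals
   at $\Delta\chi^2 = 1$ (68%) and $\Delta\chi^2 = 4$ (95%).
4. **Local-concentration alternative.**
   $\langle E \rangle = k_{on} c_0 (1 + 4d) - k_{off}$
   (`local_concentration_velocity()`), the rejected model in which a
   tether merely concentrates monomers: it predicts a linear density
   dependence that measured curves do not show, and it cannot explain
   effects of constructs unable to bind monomers.
5. **Persistence length.** For surface-adsorbed (2D) filaments the
   tangent correlation decays as $\langle\cos[\theta(s) - \theta(0)]
   \rangle = e^{-s/2L_p}$; `tangent_correlation()` pools all point pairs
   across contours and `fit_persistence_length()` fits the single
   parameter $L_p$.

Every stage can be fed synthetic data with known ground truth:
`simulate_growth_trace()` (two-state growth traces),
`render_kymograph()` (PSF-blurred, optionally noisy images),
`simulate_wlc()` (planar worm-like chains) and
`simulate_density_response()` (the Monte Carlo forward model itself).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `subunits_per_um` | 370 | subunits/um | length calibration |
| `filament_footprint_um2` | 0.006 | um^2 | surface density -> tethers per micron |
| `pause_threshold` | 1.5 | subunits/s | active/paused cut |
| `smoothing_window` | 10 | samples | velocity running mean |
| `min_run` | 3 | samples | phase debouncing |
| `kon0` | 11 | subunits/uM/s | basal barbed-end association rate |
| `koff` | 2 | subunits/s | barbed-end dissociation rate |
| `lattice_size` | 1e5 | monomers | Monte Carlo lattice |

Surface densities convert to per-site occupancy as
`density * 0.006 / 370`, capped at one tether per subunit. The
concentration-based density estimate (all protein adsorbing to both flow
cell faces, 10 uL over 2 x 100 mm^2) is an upper bound; a swivel-based
estimate about a factor 2 lower exists for such assays, so the
density-to-occupancy conversion is kept configurable by passing
occupancies directly to `grid_fit()`.

## Design choices where the method was genuinely open

**Growth-trace microdynamics.** The two-state (elongating/paused)
alternation is modelled as a continuous-time Markov chain sampled at the
trace interval, with per-interval Poisson counts of association
(`kon*conc*dt`) and dissociation (`koff*dt`) events during active
phases. A deterministic mode applies exact expected increments for exact
tests. Pause entry/exit rates are fixture parameters: they shape test
data and are not estimates of the underlying biology.

**Phase debouncing.** The 1.5 subunits/s threshold is applied to the
smoothed velocity, and runs shorter than `min_run = 3` samples are
merged into their surroundings to suppress flicker at the threshold.

**Edge-fit failure.** A fit is rejected when the amplitude falls below
3x the robust noise SD of the profile (scaled MAD of successive
differences) or when the optimiser fails; rows with failed fits become
gaps in the trace, never silent interpolations, and the gap fraction is
reported. Initialisation places the centre at the maximum-magnitude
gradient; because shot noise on bright plateaus can exceed the true edge
slope, a second start from a lightly smoothed gradient is tried and the
lower-RSS solution kept.

**Expected vs stochastic elongation.** The default Monte Carlo mode
averages the instantaneous per-site rate
$k_{on}(i)\,c - k_{off}$ over the lattice (a space average). The
stochastic mode polymerizes event by event and reports length over
elapsed time — a time average, which weights slow stretches more and is
a harmonic-type mean of the per-site rates. The two agree when rate
heterogeneity is weak (low occupancy, $\alpha \approx 1$, or a saturated
lattice) but diverge systematically for strongly modulated lattices;
fits use the space average, matching how simulated rates are defined in
the model, and the stochastic mode exists for realism checks in the
homogeneous regime.

**Overlapping tethers.** The enhancement at a site is taken from the
nearest tether at or behind it (equivalently, the maximum of the linear
decay terms), so the rate never exceeds $\alpha k_{on}^0$; effects do
not compound. A tether influences only sites at or after its own
position, and `koff` is never modified. `L_C = 1` confines the effect to
the tether site itself.

**Grid refinement.** The chi-square valley in $(\alpha, L_C)$ is
typically narrow and curved: velocities at saturating occupancy pin
$\alpha$ to fractions of a percent while $L_C$ trades off against it.
The coarse stage (30 log-spaced $\alpha$ in [0.1, 20], 30 linear $L_C$
in [1, 400], spanning all plausible values with margin) therefore only
brackets the valley; the refined stage covers every coarse node within
an order of magnitude of the coarse minimum and then re-centres and
contracts (translating without contraction whenever the running minimum
sits on the window edge) until the spacing resolves the optimum.
Delta-chi-square intervals are read off all evaluated nodes. A coarse
optimum on the grid edge is flagged as a boundary solution with open
intervals. Zero-spread data rows are guarded by a small `std_floor`
(0.001 subunits/s) before weighting.

**Tangent stencil.** Contours are arc-length resampled to uniform
spacing before tangents are computed (6--10 points per micron is the
recommended band), and tangents are taken per segment chord. On a
polygonal chain a central-difference tangent is the bisector of adjacent
segments; it damps the turning-angle variance by half a step and
inflates $L_p$ by several percent, while chord tangents preserve
$e^{-s/2L_p}$ exactly at every lag and make the estimator exactly
invariant under point-order reversal. The fit range defaults to half the
mean contour length, since long-separation correlations are
pair-starved; correlations indistinguishable from 1 return a capped
(rigid-rod) result rather than a spurious finite $L_p$. All point pairs
are pooled across filaments by default; per-filament averaging is
available via `per_filament = TRUE`.

**Drift.** Frame offsets come from the FFT cross-correlation peak with
local parabolic interpolation (subpixel); correction resamples frames
with the Keys bicubic kernel ($a = -0.5$), reducing to exact relabeling
for integer offsets. Border pixels without full interpolation support
are flagged `NA`.

## What the synthetic data does and does not emulate

The generators reproduce the statistical structure the analysis relies
on: two-state growth with the correct mean active-phase slope,
error-function edges at known subpixel positions with Poisson + read
noise, exactly exponential tangent decorrelation, and density responses
drawn from the fitted model itself. They do not emulate photobleaching,
filament crossing or fragmentation, intensity variation along the
filament, non-Gaussian PSF tails, or tether detachment. Passing
round-trip tests therefore demonstrates that the estimators are
consistent and correctly calibrated, not that real images are free of
these artifacts.

## Numerical choices and problem sizes

Exact expectations (closed-form limits, collinear fits, brute-force
lattice oracles) are asserted to machine precision; stochastic checks
run at sizes chosen to keep the whole suite fast while leaving 3-sigma
margins: 50 seeds for trace slopes, 100 replicates for edge-fit bias,
200--500 worm-like chains, a 1e4-monomer lattice with 20 placements per
density for the round-trip fit (the full 1e5 default remains the
package's standard for analyses). The acceptance script reruns the
baseline velocity on the full 1e5-monomer lattice.

## Known limitations

- Kymograph extraction from movies (filament tracing/segmentation) is
  out of scope; kymographs or traced contours are consumed directly.
- The pause classifier is a threshold with debouncing, not a
  changepoint model; dwell-time distributions of pauses are not
  modelled.
- The stochastic elongation mode is not a fitting backend (see above).
- Densities entering the allosteric fit inherit the uncertainty of the
  adsorption-based surface-density estimate; fitted $L_C$ values are
  best read as lower bounds when tether loss is plausible.
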