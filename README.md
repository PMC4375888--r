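# filakin

Quantitative analysis of single actin-filament elongation from TIRF
microscopy, and of how proteins bound to the lateral filament surface
("side-binding" proteins: NEM-myosin, filamin, α-actinin, VASP, ...)
modulate that elongation.

In the underlying assay a filament is tethered to a glass surface by a
side-binding protein and imaged as it grows; a kymograph (time ×
position intensity image) records the motion of both ends. `filakin`
implements the full analysis chain, plus synthetic-data generators with
known ground truth so every stage is testable without any microscope
data:

- **Drift correction** — FFT cross-correlation offsets with subpixel
  parabolic refinement, bicubic (Keys) resampling
  (`estimate_drift()`, `correct_drift()`).
- **Subpixel end tracking** — per-row least-squares fits of the
  error-function edge model
  `I(x) = B + (A/2) [1 + p·erf((x − μ)/(√2 σ))]`
  (`fit_edge()`, `track_ends()`), calibrated with 370 subunits per
  micron of filament.
- **Elongation and pause kinetics** — smoothed velocities, the 1.5
  subunits/s active/paused threshold, pausing probability `P_p`,
  pause-free elongation velocity `E`
  (`smooth_velocity()`, `classify_phases()`, `pause_free_velocity()`).
- **Rate constants** — weighted linear fits of `E = kon·c − koff`
  across actin concentrations, 95% confidence intervals, critical
  concentration `koff/kon` (`fit_rate_constants()`,
  `critical_concentration()`), and surface-density unit conversions via
  the 0.006 μm² per-micron filament footprint
  (`tethers_per_micron()`, `fractional_occupancy()`).
- **Allosteric Monte Carlo model** — a lattice-bound tether multiplies
  the basal association rate `kon0` by `α` at its site, decaying
  linearly to 1 over `L_C` monomers; mean elongation velocities over a
  10⁵-monomer lattice are fitted to measured velocity-vs-density curves
  by a coarse-then-refined χ² grid search with Δχ² = 1/4 confidence
  intervals (`simulate_elongation()`, `grid_fit()`). The rejected
  local-concentration alternative `⟨E⟩ = kon·c0(1+4d) − koff` is
  provided for comparison (`local_concentration_velocity()`).
- **Persistence length** — tangent-angle correlations of filament
  contours fitted with the planar worm-like-chain law
  `⟨cos Δθ⟩ = e^(−s/2Lp)` (`tangent_correlation()`,
  `fit_persistence_length()`), with a matching chain generator
  (`simulate_wlc()`).

See the methods vignette
(`vignettes/filament-elongation-methods.Rmd`) for the models,
assumptions and numerical choices.

## Worked example

```r
library(filakin)

# 1. simulate a pausing filament and render its kymograph
gp <- growth_params(kon = 11, conc = 1, koff = 2,
                    pause_entry_rate = 0.01, pause_exit_rate = 0.05,
                    duration = 300, dt = 1, seed = 42)
trace <- simulate_growth_trace(gp)
trace
#> <filament_trace> 301 samples over 300 s; final dL = 2032 subunits; ground-truth P_p = 0.213

kymo <- render_kymograph(trace, render_params(pixel_size = 0.1, psf_sigma = 2,
                                              noise_model = "poisson", seed = 42))

# 2. recover the trace from the image and summarise its kinetics
ends <- track_ends(kymo)
pf <- pause_free_velocity(ends$barbed)
round(c(E = pf$e, P_p = pf$pausing_probability), 2)
#>    E  P_p
#> 8.36 0.15

# 3. rate constants from elongation velocity vs actin concentration
pts <- data.frame(conc = c(0.3, 0.5, 1, 2),
                  e = c(1.8, 3.8, 9.5, 20.3),
                  sem = c(0.3, 0.3, 0.4, 0.6))
fit_rate_constants(pts)
#> <kinetic_rates> kon = 10.9 [10.3, 11.5] sub/uM/s; koff = 1.55 [1.06, 2.05] sub/s; cc = 0.14 uM (n = 4)

# 4. round-trip the allosteric model through its chi-square grid fit
cfg <- mc_config(kon0 = 11, koff = 2, conc = 1, n_sites = 1e4, seed = 1)
dresp <- simulate_density_response(alpha = 5.1, l_c = 76, cfg = cfg,
                                   densities = c(5, 50, 200, 600, 2000,
                                                 5900, 12000, 18000),
                                   reps = 20)
grid_fit(dresp, cfg)
#> <allosteric_params> alpha = 5.1 (68%: 5.1-5.11), L_C = 75.99 monomers (68%: 73.78-76.33)
#>   chi2_min = 3.662e-05

# 5. persistence length of 200 simulated worm-like chains
chains <- lapply(1:200, function(k) simulate_wlc(18, 10, 8, seed = k))
estimate_persistence_length(chains)
#> <persistence_fit> Lp = 16.8 um (s <= 5 um, 200 filaments)
```

Reading the numbers: the tracked barbed end elongates at 8.4 subunits/s
during its kinetically active phases and spends 15% of the time paused
(the generator's ground truth is 9 subunits/s and `P_p` = 0.21; pause
edges blur under the 10-sample smoothing). The linear fit returns the
association rate as its slope and the dissociation rate as its negative
intercept, here a critical concentration of 0.14 μM. The χ² grid fit
recovers the generating allosteric parameters (α = 5.1, L_C = 76) to
within a refined-grid step, and the worm-like-chain ensemble returns
its generating 18 μm persistence length within the expected sampling
spread.

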