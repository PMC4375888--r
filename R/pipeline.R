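#' Default pipeline configuration
#'
#' Calibration, analysis and Monte Carlo defaults used by
#' [run_pipeline()]. The constants default to their standard values:
#' 370 subunits per micron of filament, a 0.006 um^2 surface footprint
#' per micron of filament, a 1.5 subunits/s pause threshold, a 10-sample
#' smoothing window and basal barbed-end rates kon0 = 11 subunits/uM/s,
#' koff = 2 subunits/s on a 1e5-monomer lattice.
#'
#' @param ... overrides of the default fields.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.1,
    frame_interval_s = 1,
    subunits_per_um = filakin_constants$subunits_per_um,
    filament_footprint_um2 = filakin_constants$filament_footprint_um2,
    pause_threshold = 1.5,
    smoothing_window = 10,
    min_run = 3,
    kon0 = filakin_constants$kon0,
    koff = filakin_constants$koff,
    conc = 1,
    lattice_size = 1e5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown pipeline_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(modifyList(cfg, over), class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in the analysis order -- end tracking on
#' a kymograph, velocity/pause kinetics on the resulting (or supplied)
#' traces, a rate-constant fit on an elongation-vs-concentration table,
#' the allosteric grid fit on a density-response table, and
#' persistence-length estimation on contours -- and returns one
#' consolidated report. Stages run only when their inputs are present
#' (and, optionally, when named in `stages`); per-stage wall time and
#' parameters are logged in the report. A stage failure aborts with the
#' failing stage named; results of completed stages are attached to the
#' error condition.
#'
#' @param config a [pipeline_config()].
#' @param kymo optional [kymograph()] (or TIFF path) for the tracking
#'   stage.
#' @param traces optional list of `filament_trace` objects (used directly
#'   when no kymograph is given).
#' @param e_vs_conc optional data frame (`conc`, `e`, `sem`) for
#'   [fit_rate_constants()].
#' @param density_response optional `density_response` data frame for
#'   [grid_fit()].
#' @param contours optional contour list for persistence estimation.
#' @param stages character vector restricting which stages run; default
#'   all stages whose inputs are present. Known names:
#'   `"track"`, `"kinetics"`, `"rates"`, `"mc_fit"`, `"persistence"`.
#' @param out optional path: when given the report is also written as
#'   JSON via [write_report()].
#' @return The report, a named list with one entry per executed stage
#'   plus `timings_s`.
#' @export
#' @examples
#' tr <- simulate_growth_trace(growth_params(duration = 100, seed = 1))
#' rep <- run_pipeline(pipeline_config(), traces = list(tr),
#'                     stages = "kinetics")
#' rep$kinetics[[1]]$e
run_pipeline <- function(config = pipeline_config(), kymo = NULL,
                         traces = NULL, e_vs_conc = NULL,
                         density_response = NULL, contours = NULL,
                         stages = NULL, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("track", "kinetics", "rates", "mc_fit", "persistence")
  if (is.null(stages)) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  report <- list()
  timings <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial_results <- report
      stop(cond)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    report[[name]] <<- res
  }

  if ("track" %in% stages && !is.null(kymo)) {
    if (is.character(kymo)) {
      kymo <- read_kymograph(kymo, pixel_size = config$pixel_size_um,
                             frame_interval = config$frame_interval_s)
    }
    run_stage("track", function() {
      ends <- track_ends(kymo)
      traces <<- list(barbed = ends$barbed, pointed = ends$pointed)
      list(gap_fraction = ends$gap_fraction,
           n_rows = nrow(kymo$intensities))
    })
  }
  if ("kinetics" %in% stages && !is.null(traces)) {
    run_stage("kinetics", function() {
      lapply(traces, function(tr) {
        # a fully paused trace (typical of pointed ends) is a result,
        # not a stage failure: report P_p = 1 with no velocity
        pf <- tryCatch(
          pause_free_velocity(tr, threshold = config$pause_threshold,
                              window = config$smoothing_window,
                              min_run = config$min_run),
          error = function(e) {
            if (!grepl("fully paused", conditionMessage(e))) stop(e)
            v <- smooth_velocity(tr, config$smoothing_window)
            ph <- classify_phases(v, config$pause_threshold,
                                  config$min_run)
            list(e = NA_real_, sem = NA_real_, n_runs = 0L,
                 pausing_probability = ph$pausing_probability)
          })
        list(e = pf$e, sem = pf$sem, n_runs = pf$n_runs,
             pausing_probability = pf$pausing_probability)
      })
    })
  }
  if ("rates" %in% stages && !is.null(e_vs_conc)) {
    run_stage("rates", function() {
      r <- fit_rate_constants(e_vs_conc)
      list(kon = r$kon, koff = r$koff, cc = r$cc,
           ci95_kon = r$ci95_kon, ci95_koff = r$ci95_koff,
           n_points = r$n_points)
    })
  }
  if ("mc_fit" %in% stages && !is.null(density_response)) {
    run_stage("mc_fit", function() {
      cfg <- mc_config(kon0 = config$kon0, koff = config$koff,
                       conc = config$conc, n_sites = config$lattice_size,
                       seed = config$seed)
      f <- grid_fit(density_response, cfg)
      list(alpha = f$alpha, lc = f$l_c, chi2_min = f$chi2_min,
           ci68_alpha = f$ci68$alpha, ci95_alpha = f$ci95$alpha,
           ci68_lc = f$ci68$l_c, ci95_lc = f$ci95$l_c,
           boundary_flag = f$boundary)
    })
  }
  if ("persistence" %in% stages && !is.null(contours)) {
    run_stage("persistence", function() {
      p <- estimate_persistence_length(contours)
      list(lp_um = p$lp, s_max_um = p$s_max,
           n_filaments = p$n_filaments, capped = p$capped)
    })
  }
  report$timings_s <- timings
  if (!is.null(out)) {
    write_report(report, out, config = unclass(config), seed = config$seed)
  }
  report
}
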