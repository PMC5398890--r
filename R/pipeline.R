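#' Pipeline run configuration
#'
#' Validated configuration for an end-to-end run: scheme and sensor panel,
#' pH series per stage, flux-assay settings, seed, and stage toggles.
#'
#' @param topology scheme topology (see [gating_scheme()]).
#' @param scheme_overrides passed to [gating_scheme()] as `steps`.
#' @param sensors sensor list; defaults to [default_sensors()].
#' @param pH_sf pH series for stopped-flow kinetics (besides the pH-8
#'   reference).
#' @param pH_curve pH series for steady-state dF, current and flux
#'   dose-response curves.
#' @param flux a [flux_config()].
#' @param flux_delay pre-mix delay used for the dIf curve (seconds).
#' @param comparison_sensor sensor whose dF curve is compared with the flux
#'   curve.
#' @param seed integer seed for every stochastic stage.
#' @param stages character subset of
#'   `c("stopped_flow", "phases", "dose_response", "flux")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(topology = "preactive",
                       scheme_overrides = NULL,
                       sensors = NULL,
                       pH_sf = c(6, 5, 4),
                       pH_curve = c(7.3, 7, 6.5, 6.2, 6, 5.7, 5.5, 5.2,
                                    5, 4.7, 4.5, 4.2, 4),
                       flux = flux_config(),
                       flux_delay = 0.015,
                       comparison_sensor = "136-101",
                       seed = 1L,
                       stages = c("stopped_flow", "phases",
                                  "dose_response", "flux")) {
  scheme <- gating_scheme(topology, steps = scheme_overrides)
  if (is.null(sensors)) sensors <- default_sensors(scheme)
  stopifnot(all(vapply(sensors, inherits, TRUE, "sensor_model")))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!comparison_sensor %in% names(sensors))
    stop("comparison_sensor not in the sensor panel")
  if (length(pH_curve) < 4) stop("pH_curve needs at least 4 points")
  structure(list(scheme = scheme, sensors = sensors, pH_sf = pH_sf,
                 pH_curve = pH_curve, flux = flux, flux_delay = flux_delay,
                 comparison_sensor = comparison_sensor,
                 seed = as.integer(seed), stages = stages),
            class = "run_config")
}

#' Steady-state fluorescence dose-response data
#'
#' Simulated steady-state (30 s) emission intensities of a sensor across a pH
#' series, with measurement noise, plus the denatured (SDS) reference
#' intensity (1 by construction of the brightness units).
#'
#' @param scheme a [gating_scheme()].
#' @param sensor a [sensor_model()].
#' @param pH_series pH values.
#' @param seed integer seed.
#' @param t_ss steady-state observation time (seconds).
#' @return data frame with columns pH, intensity; attribute `sds_reference`.
#' @export
steady_state_intensities <- function(scheme, sensor, pH_series, seed = 1L,
                                     t_ss = 30) {
  set.seed(derive_seed(as.integer(seed), 7L))
  f <- vapply(pH_series, function(ph) {
    occ <- simulate_occupancies(scheme, ph, t_ss)
    observable_fluorescence(occ, sensor)
  }, numeric(1))
  f <- f + stats::rnorm(length(f), 0, sensor$noise_sd)
  out <- data.frame(pH = pH_series, intensity = f)
  attr(out, "sds_reference") <- 1
  out
}

#' Write a reproducible synthetic dataset to disk
#'
#' Generates the full set of pipeline inputs -- stopped-flow traces with
#' pH-8 references, steady-state intensities, a peak-current table and
#' flux-assay traces -- as CSV files with JSON sidecars and a manifest,
#' deterministically under the configured seed.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
generate_fixtures <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  ok <- dir.exists(dir) ||
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    stop("output directory '", dir, "' is not writable")
  manifest <- list(seed = config$seed, topology = config$scheme$topology,
                   files = list())
  add <- function(name, meta) {
    manifest$files[[name]] <<- meta
  }
  write_trace <- function(tr, name) {
    utils::write.csv(data.frame(time_s = tr$time, intensity = tr$intensity),
                     file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    meta <- list(pH = tr$pH, sensor = tr$sensor_id, condition = tr$condition,
                 seed = tr$seed)
    jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE)
    add(paste0(name, ".csv"), meta)
  }
  k <- 0L
  for (sid in names(config$sensors)) {
    sens <- config$sensors[[sid]]
    ref_written <- FALSE
    for (ph in config$pH_sf) {
      k <- k + 1L
      tr <- simulate_sf_trace(config$scheme, sens, sf_protocol(), ph,
                              seed = derive_seed(config$seed, 100L + k))
      nm <- sprintf("sf_%s_pH%s", gsub("[^0-9A-Za-z]", "_", sid), ph)
      write_trace(tr, nm)
      if (!ref_written) {
        write_trace(tr$reference,
                    sprintf("sf_%s_ref_pH8", gsub("[^0-9A-Za-z]", "_", sid)))
        ref_written <- TRUE
      }
    }
    ss <- steady_state_intensities(config$scheme, sens, config$pH_curve,
                                   seed = derive_seed(config$seed, 200L + k))
    nm <- sprintf("steady_%s.csv", gsub("[^0-9A-Za-z]", "_", sid))
    utils::write.csv(ss, file.path(dir, nm), row.names = FALSE)
    add(nm, list(sensor = sid, sds_reference = attr(ss, "sds_reference")))
  }
  tevc <- simulate_tevc_current(config$scheme, config$pH_curve,
                                seed = derive_seed(config$seed, 300L))
  utils::write.csv(tevc$peak_table, file.path(dir, "peak_currents.csv"),
                   row.names = FALSE)
  add("peak_currents.csv", list(readout = "dI"))
  k <- 0L
  for (ph in config$pH_curve) {
    k <- k + 1L
    tr <- simulate_flux_assay(config$scheme, config$flux, ph,
                              config$flux_delay,
                              seed = derive_seed(config$seed, 400L + k))
    nm <- sprintf("flux_pH%s.csv", ph)
    utils::write.csv(data.frame(time_s = tr$time, intensity = tr$intensity),
                     file.path(dir, nm), row.names = FALSE)
    add(nm, list(pH = ph, delay = config$flux_delay))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the analysis pipeline end to end
#'
#' Simulate -> normalize -> fit -> bin -> dose-response -> compare.  Stages
#' can be toggled in the configuration; the dose-response stage is always
#' run, since the intermediate-state comparison is the pipeline's endpoint.
#'
#' The report contains, per stage: the per-sensor phase-amplitude table, the
#' tau histogram with its phase partition and per-phase amplitude summary,
#' Hill fits of the dF, dI and dIf readouts, and the dF-vs-dIf comparison
#' with the intermediate-state flag.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(stages = "dose_response", seed = 1))
#' rep$comparison
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scheme <- config$scheme
  report <- list(config = config)

  if ("stopped_flow" %in% config$stages) {
    fits <- list(); phases <- list(); k <- 0L
    for (sid in names(config$sensors)) {
      for (ph in config$pH_sf) {
        k <- k + 1L
        tr <- simulate_sf_trace(scheme, config$sensors[[sid]], sf_protocol(),
                                ph, seed = derive_seed(config$seed, 100L + k))
        ntr <- normalize_to_reference(tr)
        fit <- fit_multiexp(ntr)
        fits[[k]] <- fit
        phases[[k]] <- decompose_phases(fit)
      }
    }
    report$sf_fits <- fits
    report$phase_table <- do.call(rbind, lapply(phases, function(p)
      data.frame(sensor = p$sensor_id, pH = p$pH,
                 deadtime_dF_pct = p$deadtime_dF_pct,
                 max_dF_pct = p$max_dF_pct,
                 n_components = nrow(p$per_component),
                 no_variation = p$no_variation)))
    report$phases <- phases
    if ("phases" %in% config$stages) {
      ens <- tau_ensemble(fits, phases)
      hist <- log_bin_taus(ens)
      part <- identify_phases(hist)
      report$tau_histogram <- hist
      report$phase_partition <- part
      report$phase_dF <- aggregate_phase_dF(ens, part)
    }
  }

  # dose-response stage: dF per sensor, dI, dIf, comparison
  hill_dF <- list()
  for (sid in names(config$sensors)) {
    ss <- steady_state_intensities(scheme, config$sensors[[sid]],
                                   config$pH_curve,
                                   seed = derive_seed(config$seed, 500L +
                                                        match(sid, names(config$sensors))))
    crv <- build_dF_curve(ss$pH, ss$intensity, normalization = "ph7")
    hill_dF[[sid]] <- if (crv$na_flag) NULL else
      tryCatch(fit_hill(crv), error = function(e) NULL)
  }
  report$hill_dF <- hill_dF

  tevc <- simulate_tevc_current(scheme, config$pH_curve,
                                seed = derive_seed(config$seed, 300L))
  dI <- build_dI_curve(tevc$peak_table$pH, tevc$peak_table$current_uA,
                       exclude_submaximal_lowpH = TRUE)
  report$hill_dI <- tryCatch(fit_hill(dI), error = function(e) NULL)

  # flux stage always runs: the dF-vs-dIf comparison is the endpoint
  traces <- lapply(seq_along(config$pH_curve), function(i)
    simulate_flux_assay(scheme, config$flux, config$pH_curve[i],
                        config$flux_delay,
                        seed = derive_seed(config$seed, 400L + i)))
  rvd <- rate_vs_delay(traces)
  report$rate_vs_delay <- rvd
  dIf <- flux_dose_response(rvd, delay = config$flux_delay)
  report$hill_dIf <- tryCatch(fit_hill(dIf), error = function(e) NULL)

  fA <- report$hill_dF[[config$comparison_sensor]]
  fB <- report$hill_dIf
  if (is.null(fA) || is.null(fB))
    stop("comparison stage failed: missing dF or dIf Hill fit")
  report$comparison <- compare_curves(fA, fB)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Pipeline run report (topology:", x$config$scheme$topology,
      ", seed", x$config$seed, ") ==\n")
  if (!is.null(x$phase_table)) {
    cat("\nPhase amplitudes (dead-time % of maximal variation):\n")
    pt <- x$phase_table
    pt$deadtime_dF_pct <- round(pt$deadtime_dF_pct, 1)
    pt$max_dF_pct <- round(pt$max_dF_pct, 1)
    print(pt, row.names = FALSE)
  }
  if (!is.null(x$phase_partition)) {
    cat("\n"); print(x$phase_partition)
    cat("\nPer-phase fluorescence amplitudes:\n")
    pdf <- x$phase_dF
    pdf$mean_dF_pct <- signif(pdf$mean_dF_pct, 3)
    pdf$sd_dF_pct <- signif(pdf$sd_dF_pct, 3)
    print(pdf, row.names = FALSE)
  }
  cat("\nHill fits:\n")
  for (sid in names(x$hill_dF))
    if (!is.null(x$hill_dF[[sid]]))
      cat(sprintf("  dF  %-8s pH50 = %.2f, nH = %.2f\n", sid,
                  x$hill_dF[[sid]]$pH50, x$hill_dF[[sid]]$nH))
  if (!is.null(x$hill_dI))
    cat(sprintf("  dI  %-8s pH50 = %.2f, nH = %.2f\n", "(TEVC)",
                x$hill_dI$pH50, x$hill_dI$nH))
  if (!is.null(x$hill_dIf))
    cat(sprintf("  dIf %-8s pH50 = %.2f, nH = %.2f\n", "(flux)",
                x$hill_dIf$pH50, x$hill_dIf$nH))
  cat("\n"); print(x$comparison)
  invisible(x)
}
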