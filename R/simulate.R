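#' Simulate a stopped-flow fluorescence trace
#'
#' Propagates the gating scheme from the moment of mixing, maps occupancies
#' through the sensor brightness, truncates the observation before the mixing
#' dead time and adds multiplicative linear drift and additive Gaussian noise.
#' A matched reference trace recorded at pH 8 (same drift model, independent
#' noise) is returned alongside, mirroring the daily pH-8 normalization
#' recording.
#'
#' @param scheme a [gating_scheme()].
#' @param sensor a [sensor_model()].
#' @param protocol an [sf_protocol()].
#' @param pH final pH after mixing.
#' @param seed integer seed; traces are bit-reproducible given the seed.
#' @param reference logical; also simulate the paired pH-8 reference trace.
#' @return an object of class `sf_trace`: list with `time` (seconds, starting
#'   at the dead time), `intensity` (denatured-reference units), `pH`,
#'   `sensor_id`, `condition`, `seed`, `protocol`; when `reference = TRUE`
#'   the reference trace is attached as `$reference`.
#' @examples
#' tr <- simulate_sf_trace(gating_scheme(), default_sensors()[["33-160"]],
#'                         sf_protocol(), pH = 4, seed = 1)
#' head(tr$time)
#' @export
simulate_sf_trace <- function(scheme, sensor, protocol = sf_protocol(),
                              pH, seed = 1L, reference = TRUE) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(sensor, "sensor_model"),
            inherits(protocol, "sf_protocol"))
  seed <- as.integer(seed)
  tgrid <- protocol_grid(protocol)
  keep <- tgrid >= protocol$dead_time
  make_one <- function(ph, sub_seed, condition) {
    occ <- simulate_occupancies(scheme, ph, tgrid)
    f <- observable_fluorescence(occ, sensor)
    t <- tgrid[keep]
    y <- f[keep] * (1 + sensor$drift_rate * t)
    if (sensor$noise_sd > 0) {
      set.seed(sub_seed)
      y <- y + stats::rnorm(length(y), 0, sensor$noise_sd)
    }
    structure(list(time = t, intensity = y, pH = ph,
                   sensor_id = sensor$id, condition = condition,
                   seed = sub_seed, protocol = protocol),
              class = "sf_trace")
  }
  out <- make_one(pH, derive_seed(seed, 1L), "test")
  if (reference)
    out$reference <- make_one(8, derive_seed(seed, 2L), "reference_pH8")
  out
}

#' @export
print.sf_trace <- function(x, ...) {
  cat("Stopped-flow trace: sensor", x$sensor_id, "pH", x$pH,
      "(", x$condition, ")", length(x$time), "points,",
      signif(min(x$time) * 1000, 3), "ms -", max(x$time), "s\n")
  invisible(x)
}

#' @export
plot.sf_trace <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l", log = "x",
                 xlab = "time (s)", ylab = "fluorescence (SDS units)",
                 main = paste("sensor", x$sensor_id, "pH", x$pH), ...)
  invisible(x)
}

# deterministic per-stream seed derivation, kept within 32-bit range
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 10007) %%
               2147483629)
}

#' Simulate two-electrode voltage-clamp measurements
#'
#' Peak currents across a pH series follow the scheme's open-state occupancy
#' maximum over the recording window (the pre-desensitization quasi-steady
#' level), scaled to a maximal current.  Activation traces follow the
#' empirical double-exponential rise
#' `y(t) = A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2)) + C`.
#'
#' @param scheme a [gating_scheme()].
#' @param pH_series pH values for the peak-current table.
#' @param activation_params list with `tau1`, `tau2` (seconds), `frac1`
#'   (fraction of amplitude in the fast phase) and `C` (offset current, uA).
#' @param Imax maximal current (uA).
#' @param t_trace time grid for the activation traces (seconds).
#' @param noise_sd relative Gaussian noise on peak currents and traces.
#' @param seed integer seed.
#' @return list with `peak_table` (data frame: pH, current_uA) and `traces`
#'   (per-pH data frames: time_s, current_uA).
#' @export
simulate_tevc_current <- function(scheme, pH_series,
                                  activation_params = list(tau1 = 1.9,
                                                           tau2 = 7,
                                                           frac1 = 0.7,
                                                           C = 0),
                                  Imax = 7, t_trace = seq(0, 30, by = 0.05),
                                  noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(scheme, "gating_scheme"))
  ap <- activation_params
  if (ap$tau1 <= 0 || ap$tau2 <= 0) stop("activation tau must be positive")
  if (is.null(ap$C)) ap$C <- 0
  tg <- 10^seq(-4, log10(30), length.out = 200)
  peak_occ <- vapply(pH_series, function(ph) {
    max(simulate_occupancies(scheme, ph, tg)[, "O"])
  }, numeric(1))
  set.seed(derive_seed(as.integer(seed), 3L))
  peak <- Imax * peak_occ / max(peak_occ)
  peak_noisy <- peak * (1 + stats::rnorm(length(peak), 0, noise_sd))
  traces <- lapply(seq_along(pH_series), function(i) {
    A <- peak[i]
    y <- ap$frac1 * A * (1 - exp(-t_trace / ap$tau1)) +
      (1 - ap$frac1) * A * (1 - exp(-t_trace / ap$tau2)) + ap$C
    y <- y + stats::rnorm(length(y), 0, noise_sd * max(A, 1e-6))
    data.frame(time_s = t_trace, current_uA = y)
  })
  names(traces) <- as.character(pH_series)
  list(peak_table = data.frame(pH = pH_series, current_uA = peak_noisy),
       traces = traces,
       activation_params = ap)
}
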