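#' Liposome thallium-flux assay configuration
#'
#' Parameters of the sequential-mixing stopped-flow flux assay: a heterogeneous
#' liposome population (lognormal diameters, mean 150 nm; Poisson channel
#' loading), Tl+ quencher at 45 mM after 1:1 mixing of a 90 mM TlNO3 quenching
#' buffer, Stern-Volmer quenching of entrapped ANTS, and per-liposome Tl+
#' entry rates proportional to active channel count and open-state occupancy
#' and inversely proportional to liposome volume.
#'
#' `single_channel_rate` is a calibration constant (the per-open-channel quench
#' rate in a reference 150 nm liposome), not a physical conductance; its
#' default is chosen so that the assay defaults yield quenching rates of about
#' 80/s at pH 4.2 with a 15 ms delay.
#'
#' @param diameter_mean_nm mean liposome diameter (nm).
#' @param diameter_sdlog lognormal sd of the diameter on the log scale.
#' @param channels_per_liposome mean channel count per liposome.
#' @param channel_dispersion `"poisson"` (default) or `"fixed"` (every
#'   liposome carries exactly `channels_per_liposome` channels; with a single
#'   liposome size this is the homogeneous-population limit in which the
#'   ensemble decay is mono-exponential).
#' @param quencher_conc_M Tl+ concentration after mixing (mol/L).
#' @param stern_volmer_M Stern-Volmer constant (1/M); must be positive.
#' @param single_channel_rate reference per-channel quench rate (1/s).
#' @param delay_times pre-mix delay times (seconds), >= 0.015.
#' @param leak_rate background quench rate of protein-free liposomes (1/s).
#' @param blocker_active logical; a pore blocker (picrotoxinin-like) zeroes
#'   channel conductance.
#' @param n_liposomes liposomes drawn per simulated trace.
#' @param sample_rate_hz acquisition rate of the 1 s trace.
#' @param noise_sd additive Gaussian noise (fraction of initial intensity).
#' @return object of class `flux_config`.
#' @export
flux_config <- function(diameter_mean_nm = 150,
                        diameter_sdlog = 0.15,
                        channels_per_liposome = 4,
                        channel_dispersion = c("poisson", "fixed"),
                        quencher_conc_M = 0.045,
                        stern_volmer_M = 50,
                        single_channel_rate = 129,
                        delay_times = c(0.015, 0.025, 0.05, 0.1, 0.2),
                        leak_rate = 0.5,
                        blocker_active = FALSE,
                        n_liposomes = 300,
                        sample_rate_hz = 5000,
                        noise_sd = 0.005) {
  if (stern_volmer_M <= 0) stop("Stern-Volmer constant must be positive")
  if (any(delay_times < 0.015))
    stop("delay times below the 15 ms instrument minimum")
  if (diameter_mean_nm <= 0 || channels_per_liposome < 0 || leak_rate < 0 ||
      single_channel_rate < 0)
    stop("flux configuration rates and sizes must be non-negative")
  channel_dispersion <- match.arg(channel_dispersion)
  structure(as.list(environment()), class = "flux_config")
}

#' Simulate an ANTS quenching trace
#'
#' Draws a liposome population (lognormal radii, Poisson channel counts),
#' computes the per-liposome Tl+ entry rate
#' `k_i = leak + s * n_i * p_O(delay) * (V_ref / V_i)` (zero channel term for
#' protein-free or blocked preparations), and relaxes each liposome's ANTS
#' fluorescence exponentially toward its Stern-Volmer equilibrium
#' `F_eq = 1 / (1 + Ksv [Tl+])`.  The ensemble trace is the
#' volume(ANTS-content)-weighted average, sampled for 1 s with additive noise.
#' A no-Tl+ reference trace (no quenching) is attached.
#'
#' @param scheme a [gating_scheme()].
#' @param config a [flux_config()].
#' @param pH pH during the pre-mix (activation) step.
#' @param delay pre-mix delay time (seconds), >= 0.015.
#' @param seed integer seed.
#' @return object of class `flux_trace`: `time`, `intensity` (normalized to
#'   initial ANTS fluorescence), `reference`, `pH`, `delay`, `seed`, `config`.
#' @examples
#' tr <- simulate_flux_assay(gating_scheme(), flux_config(), pH = 4.2,
#'                           delay = 0.015, seed = 1)
#' @export
simulate_flux_assay <- function(scheme, config = flux_config(), pH, delay,
                                seed = 1L) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(config, "flux_config"))
  if (delay < 0.015)
    stop("delay must be >= 0.015 s (instrument minimum)")
  set.seed(derive_seed(as.integer(seed), 5L))
  n <- config$n_liposomes
  r_ref <- config$diameter_mean_nm / 2
  radii <- stats::rlnorm(n, log(r_ref), config$diameter_sdlog)
  channels <- if (identical(config$channel_dispersion, "fixed"))
    rep(config$channels_per_liposome, n)
  else stats::rpois(n, config$channels_per_liposome)
  pO <- simulate_occupancies(scheme, pH, delay)[1, "O"]
  eff_channels <- if (config$blocker_active) 0 else channels
  rates <- config$leak_rate +
    config$single_channel_rate * eff_channels * pO * (r_ref / radii)^3
  f_eq <- 1 / (1 + config$stern_volmer_M * config$quencher_conc_M)
  t <- seq(0, 1, by = 1 / config$sample_rate_hz)
  w <- radii^3 / sum(radii^3)
  decay <- exp(-outer(t, rates))          # time x liposome
  y <- as.vector(decay %*% w) * (1 - f_eq) + f_eq
  noise <- stats::rnorm(length(t), 0, config$noise_sd)
  ref <- 1 + stats::rnorm(length(t), 0, config$noise_sd)
  structure(list(time = t, intensity = y + noise, reference = ref,
                 pH = pH, delay = delay, seed = as.integer(seed),
                 config = config,
                 mean_rate = sum(w * rates)),
            class = "flux_trace")
}

#' @export
print.flux_trace <- function(x, ...) {
  cat("Flux-assay trace: pH", x$pH, "delay", x$delay * 1000, "ms,",
      length(x$time), "points, ensemble mean rate",
      signif(x$mean_rate, 3), "/s\n")
  invisible(x)
}
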