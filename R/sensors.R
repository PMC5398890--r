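#' Fluorescence sensor model
#'
#' A bimane/quencher pair is modelled by a per-state relative brightness
#' (in denatured-reference units, i.e. fluorescence normalized to the
#' intensity of the denatured protein in 1% SDS), plus instrument noise and
#' slow drift used when tracing through a stopped-flow protocol.
#'
#' @param id sensor label, e.g. `"136-101"`.
#' @param brightness named numeric vector of per-state brightness (> 0);
#'   names must match the scheme's states when the sensor is used.
#' @param noise_sd Gaussian noise standard deviation as a fraction of full
#'   scale (default 0.01).
#' @param drift_rate slow multiplicative drift per second (default 0.001,
#'   i.e. 0.1%/s).
#' @return object of class `sensor_model`.
#' @examples
#' sensor_model("136-101", c(R = 0.69, P = 0.40, O = 0.37, D = 0.35))
#' @export
sensor_model <- function(id, brightness, noise_sd = 0.01, drift_rate = 0.001) {
  if (any(!is.finite(brightness) | brightness <= 0))
    stop("brightness values must be positive")
  if (noise_sd < 0 || drift_rate < -1)
    stop("invalid noise_sd or drift_rate")
  structure(list(id = id, brightness = brightness,
                 noise_sd = noise_sd, drift_rate = drift_rate),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("Sensor", x$id, "- brightness per state:\n")
  print(x$brightness)
  cat("noise sd:", x$noise_sd, " drift:", x$drift_rate, "/s\n")
  invisible(x)
}

#' Default panel of fluorescence sensors
#'
#' Six bimane/quencher reporters spanning the receptor from the apex of the
#' extracellular domain to the top of the pore-lining M2 helix.  Brightness
#' values are in denatured-reference (SDS) units; the pre-active state carries
#' the compacted-ECD quenching signature, which the open and desensitized
#' states largely inherit with small additional offsets that generate the
#' minor fast/intermediate/slow fluorescence phases.
#'
#' For the concerted control topology (no pre-active state) the pre-active
#' brightness is mapped onto the open state, so the compaction signature and
#' channel opening are, by construction, a single concerted event.
#'
#' @param scheme a [gating_scheme()]; decides the state labels.
#' @param noise_sd,drift_rate passed to [sensor_model()].
#' @return named list of `sensor_model` objects.
#' @export
default_sensors <- function(scheme = gating_scheme(),
                            noise_sd = 0.01, drift_rate = 0.001) {
  b <- list(
    "136-101" = c(R = 0.69, P = 0.40, O = 0.37, D = 0.34),
    "135-72"  = c(R = 0.76, P = 0.53, O = 0.52, D = 0.58),
    "133-103" = c(R = 1.18, P = 0.80, O = 0.84, D = 0.78),
    "33-160"  = c(R = 1.09, P = 0.49, O = 0.47, D = 0.44),
    "250-197" = c(R = 0.60, P = 0.92, O = 0.96, D = 1.00),
    "243"     = c(R = 1.60, P = 1.48, O = 1.36, D = 1.31)
  )
  concerted <- identical(scheme$topology, "concerted")
  lapply(stats::setNames(names(b), names(b)), function(id) {
    v <- b[[id]]
    if (concerted) v <- c(R = unname(v["R"]), O = unname(v["P"]),
                          D = unname(v["D"]))
    sensor_model(id, v[scheme$states], noise_sd = noise_sd,
                 drift_rate = drift_rate)
  })
}

#' Noise-free fluorescence observable
#'
#' Per-time fluorescence F(t) = sum_s brightness_s p_s(t) in
#' denatured-reference units.  Deterministic; instrument noise and drift are
#' added only by [simulate_sf_trace()].
#'
#' @param occupancies matrix (time x states) as returned by
#'   [simulate_occupancies()].
#' @param sensor a [sensor_model()].
#' @return numeric vector of intensities.
#' @export
observable_fluorescence <- function(occupancies, sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  b <- sensor$brightness
  if (ncol(occupancies) != length(b))
    stop("brightness vector length (", length(b),
         ") does not match state count (", ncol(occupancies), ")")
  if (!is.null(colnames(occupancies)) && !is.null(names(b)))
    b <- b[colnames(occupancies)]
  as.vector(occupancies %*% b)
}
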