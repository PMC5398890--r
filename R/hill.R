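#' Dose-response curve container
#'
#' Stores a pH series and normalized responses for one readout: steady-state
#' fluorescence change (dF), peak clamp current (dI) or flux quench rate
#' (dIf), together with the normalization used and the detected direction.
#'
#' @param pH pH values (strictly monotone).
#' @param response normalized responses.
#' @param readout `"dF"`, `"dI"` or `"dIf"`.
#' @param normalization label, e.g. `"to-max"`, `"to-SDS"`, `"to-pH7.3"`.
#' @param na_flag logical; the readout showed no variation above threshold.
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(pH, response,
                                readout = c("dF", "dI", "dIf"),
                                normalization = "to-max",
                                na_flag = FALSE) {
  readout <- match.arg(readout)
  stopifnot(length(pH) == length(response))
  if (any(!is.finite(pH)) || any(!is.finite(response)))
    stop("pH and responses must be finite")
  o <- order(pH, decreasing = TRUE)
  pH <- pH[o]; response <- response[o]
  if (anyDuplicated(pH)) stop("pH values must be distinct")
  d <- diff(response)
  direction <- if (all(d <= 1e-9)) "decrease"
  else if (all(d >= -1e-9)) "increase"
  else {
    s <- sum(d)
    if (abs(s) > 0.5 * sum(abs(d))) {
      if (s > 0) "increase" else "decrease"
    } else "non-monotonic"
  }
  structure(list(pH = pH, response = response, readout = readout,
                 normalization = normalization, direction = direction,
                 na_flag = na_flag),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("Dose-response curve (", x$readout, ", ", x$normalization,
      ", ", x$direction, if (x$na_flag) ", flagged NA", ")\n", sep = "")
  print(data.frame(pH = x$pH, response = signif(x$response, 4)),
        row.names = FALSE)
  invisible(x)
}

hill_response <- function(x, a, nH, EC50) a * x^nH / (x^nH + EC50^nH)

#' Hill fit of a dose-response curve
#'
#' Least-squares fit of the Hill equation
#' `y(x) = a x^nH / (x^nH + EC50^nH)` performed in proton-concentration space
#' (`x = 10^-pH`).  Decreasing readouts are fitted on the response drop from
#' the most alkaline point, so one functional form serves both directions.
#' Non-monotonic curves are fitted on their dominant monotonic limb (from the
#' alkaline end to the global extremum) with a warning, and rejected when no
#' limb dominates.
#'
#' @param curve a [dose_response_curve()], or a pH vector.
#' @param response responses when `curve` is a pH vector.
#' @param floating_baseline also fit an additive baseline (default FALSE).
#' @return object of class `hill_fit` with `a`, `nH`, `EC50`, `pH50`
#'   (`= -log10(EC50)` exactly), `direction`, `fitted`, `curve`.
#' @examples
#' pH <- seq(7, 4, by = -0.5)
#' y <- 1 / (1 + (10^-5 / 10^-pH)^2)    # Hill with pH50 5, nH 2
#' f <- fit_hill(pH, y)
#' f$pH50
#' @export
fit_hill <- function(curve, response = NULL, floating_baseline = FALSE) {
  if (!inherits(curve, "dose_response_curve"))
    curve <- dose_response_curve(curve, response)
  if (length(unique(curve$pH)) < 4)
    stop("at least 4 distinct pH points are required")
  pH <- curve$pH; y <- curve$response
  if (curve$direction == "non-monotonic") {
    i_ext <- if (abs(max(y) - y[1]) >= abs(min(y) - y[1]))
      which.max(y) else which.min(y)
    limb <- seq_len(i_ext)
    span_limb <- abs(y[i_ext] - y[1])
    span_rest <- max(abs(y[i_ext:length(y)] - y[i_ext]))
    if (span_limb < 1.5 * span_rest || length(limb) < 4)
      stop("not Hill-fittable: non-monotonic curve with no dominant limb")
    warning("non-monotonic curve: fitting the dominant (alkaline-side) limb")
    pH <- pH[limb]; y <- y[limb]
  }
  x <- 10^(-pH)
  decreasing <- y[length(y)] < y[1]
  # decreasing readouts are fitted on the drop from the alkaline baseline;
  # increasing readouts are fitted directly when the alkaline response is
  # effectively zero, otherwise on the rise above the alkaline point
  yfit <- if (decreasing) y[1] - y
  else if (min(y) < 0.05 * max(y)) y
  else y - y[1]
  a0 <- max(yfit)
  if (a0 <= 0) stop("degenerate curve: no response variation")
  # coarse EC50 grid start + LM refinement
  half <- a0 / 2
  i_half <- which.min(abs(yfit - half))
  ec0 <- x[i_half]
  best <- NULL
  for (n0 in c(0.8, 1.3, 2)) for (e_mult in c(0.3, 1, 3)) {
    st <- if (floating_baseline)
      list(a = a0, lnE = log(ec0 * e_mult), nH = n0, b = 0)
    else list(a = a0, lnE = log(ec0 * e_mult), nH = n0)
    form <- if (floating_baseline)
      yfit ~ a * x^nH / (x^nH + exp(lnE)^nH) + b
    else yfit ~ a * x^nH / (x^nH + exp(lnE)^nH)
    f <- try(minpack.lm::nlsLM(
      form, start = st,
      lower = if (floating_baseline) c(1e-12, -60, 0.05, -Inf)
      else c(1e-12, -60, 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 300,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
  }
  if (is.null(best)) stop("Hill fit did not converge")
  cf <- stats::coef(best)
  EC50 <- unname(exp(cf["lnE"]))
  if (EC50 < min(x) || EC50 > max(x))
    warning("EC50 outside the sampled pH range")
  structure(list(a = unname(cf["a"]), nH = unname(cf["nH"]),
                 EC50 = EC50, pH50 = -log10(EC50),
                 baseline = if (floating_baseline) unname(cf["b"]) else 0,
                 direction = if (decreasing) "decrease" else "increase",
                 fitted = if (decreasing) y[1] - stats::fitted(best)
                 else y[1] + stats::fitted(best),
                 sigma = stats::sd(stats::residuals(best)),
                 curve = curve),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s, %s): a = %.4g, nH = %.3g, pH50 = %.3f (EC50 = %.3g M)\n",
              x$curve$readout, x$direction, x$a, x$nH, x$pH50, x$EC50))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(a = object$a, nH = object$nH, EC50 = object$EC50, pH50 = object$pH50)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  pH <- if (is.null(newdata)) object$curve$pH else
    if (is.list(newdata)) newdata$pH else newdata
  hill_response(10^(-pH), object$a, object$nH, object$EC50) + object$baseline
}

#' Build a fluorescence (dF) dose-response curve
#'
#' Normalizes steady-state emission intensities per pH to a denatured (SDS)
#' reference or to the intensity at the most alkaline pH, detects the
#' direction, and flags curves whose total variation is below 10% of the
#' alkaline intensity (the non-applicable convention).
#'
#' @param pH pH values.
#' @param intensity steady-state intensities (arbitrary units).
#' @param normalization `"sds"`, `"max"` or `"ph7"`.
#' @param reference_intensity the SDS-denatured intensity (same units);
#'   required for `normalization = "sds"`.
#' @return a [dose_response_curve()] with readout `"dF"`.
#' @export
build_dF_curve <- function(pH, intensity,
                           normalization = c("sds", "max", "ph7"),
                           reference_intensity = NULL) {
  normalization <- match.arg(normalization)
  ref <- switch(normalization,
                sds = {
                  if (is.null(reference_intensity))
                    stop("SDS reference intensity is missing")
                  reference_intensity
                },
                max = max(intensity),
                ph7 = intensity[which.max(pH)])
  resp <- intensity / ref
  alk <- resp[which.max(pH)]
  na_flag <- (max(resp) - min(resp)) < 0.10 * alk
  dose_response_curve(pH, resp, readout = "dF",
                      normalization = paste0("to-", normalization),
                      na_flag = na_flag)
}

#' Build a current (dI) dose-response curve
#'
#' Normalizes peak currents to their maximum.  Preparations whose maximal
#' current is below 0.5 uA are rejected as non-functional.  Optionally drops
#' trailing low-pH points that fall below the running maximum (systematically
#' sub-maximal currents at very low pH, e.g. from accumulated
#' desensitization) before fitting.
#'
#' @param pH pH values.
#' @param peak_current peak currents (uA), >= 0.
#' @param exclude_submaximal_lowpH drop sub-maximal acidic-side points.
#' @param tol relative tolerance defining "smaller than the maximum".
#' @return a [dose_response_curve()] with readout `"dI"`.
#' @export
build_dI_curve <- function(pH, peak_current,
                           exclude_submaximal_lowpH = FALSE, tol = 0.02) {
  stopifnot(all(peak_current >= 0))
  if (max(peak_current) < 0.5)
    stop("non-functional: maximal current below 0.5 uA")
  o <- order(pH, decreasing = TRUE)
  pH <- pH[o]; cur <- peak_current[o]
  if (exclude_submaximal_lowpH) {
    imax <- which.max(cur)
    drop <- seq_along(cur) > imax & cur < (1 - tol) * max(cur)
    pH <- pH[!drop]; cur <- cur[!drop]
  }
  dose_response_curve(pH, cur / max(cur), readout = "dI",
                      normalization = "to-max")
}

#' Compare two Hill fits for intermediate-state separation
#'
#' The pH50 separation between a conformational readout (dF) and a functional
#' readout (dIf or dI) of the same receptor diagnoses an intermediate state:
#' when the conformational change half-completes at a pH where the channel is
#' still mostly closed, the two curves separate by an order of magnitude or
#' more in proton concentration.
#'
#' @param fitA,fitB [fit_hill()] results (conventionally A = dF, B = dIf).
#' @param threshold pH-unit separation that flags an intermediate (default 1).
#' @return object of class `curve_comparison`: `delta_pH50`,
#'   `flag_intermediate`, `threshold`, `curves`.
#' @export
compare_curves <- function(fitA, fitB, threshold = 1.0) {
  stopifnot(inherits(fitA, "hill_fit"), inherits(fitB, "hill_fit"))
  delta <- fitA$pH50 - fitB$pH50
  structure(list(delta_pH50 = delta,
                 flag_intermediate = delta >= threshold,
                 threshold = threshold,
                 curves = c(fitA$curve$readout, fitB$curve$readout),
                 pH50 = c(A = fitA$pH50, B = fitB$pH50)),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("pH50 %s = %.3f vs %s = %.3f: delta = %.3f (threshold %.2f)\n",
              x$curves[1], x$pH50["A"], x$curves[2], x$pH50["B"],
              x$delta_pH50, x$threshold))
  cat(if (x$flag_intermediate)
    "-> separated: consistent with a pre-active intermediate state\n"
    else "-> not separated: concerted behaviour\n")
  invisible(x)
}
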