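#' Stretched-exponential fit of an ANTS quenching trace
#'
#' Fits the first part of a flux-assay trace with
#' `F(t) = F_inf + (F0 - F_inf) exp(-(t/tau0)^beta)`, the standard model for
#' quenching of a heterogeneous liposome population (liposome sizes and
#' channel counts disperse the per-liposome rates; beta < 1 measures that
#' dispersion).  The quench rate at 2 ms,
#' `k(2 ms) = (beta/tau0) (0.002/tau0)^(beta-1)`, summarizes channel
#' activity.
#'
#' @param trace a `flux_trace` (see [simulate_flux_assay()]) or a list/data
#'   frame with `time` and `intensity`.
#' @param window fit window (seconds, default first 0.1 s).
#' @param beta_max upper bound on beta (default 1.2: physically beta <= 1 for
#'   a mixture of exponential rates; the slack absorbs noise, and fits above
#'   1 warn).
#' @return object of class `stretchexp_fit`: `F0`, `F_inf`, `tau0`, `beta`,
#'   `k2ms`, `fit_window`, `no_activity`, `sigma`.
#' @examples
#' tr <- simulate_flux_assay(gating_scheme(), flux_config(), pH = 4.2,
#'                           delay = 0.015, seed = 1)
#' fit_stretchexp(tr)
#' @export
fit_stretchexp <- function(trace, window = 0.1, beta_max = 1.2) {
  t <- trace$time
  y <- trace$intensity
  sel <- t <= window
  if (sum(sel) < 20) stop("trace does not cover the fit window")
  F0_0 <- mean(y[seq_len(max(3, round(sum(sel) / 50)))])
  tail_n <- max(5, round(length(trace$time) / 10))
  F_inf_0 <- mean(utils::tail(trace$intensity, tail_n))
  # activity is judged on the standard window; rate fitting of near-flat
  # (leak-level) traces uses the whole recording, where a slow rate is
  # actually identifiable
  drop_window <- F0_0 - mean(y[sel][utils::tail(seq_len(sum(sel)), 10)])
  slow_trace <- drop_window < 0.08 * abs(F0_0)
  if (slow_trace) sel <- rep(TRUE, length(t))
  t <- t[sel]; y <- y[sel]
  drop <- F0_0 - F_inf_0
  # crude tau: time at 1/e of the drop
  i_e <- which(y <= F_inf_0 + drop * exp(-1))[1]
  tau0_0 <- if (!is.na(i_e) && t[i_e] > 0) t[i_e] else window / 3
  best <- NULL
  for (b0 in c(0.6, 0.85, 1)) for (tm in c(0.3, 1, 3)) {
    f <- try(minpack.lm::nlsLM(
      y ~ F_inf + (F0 - F_inf) * exp(-(t / tau0)^beta),
      start = list(F0 = F0_0, F_inf = F_inf_0,
                   tau0 = max(tau0_0 * tm, 1e-5), beta = b0),
      lower = c(-Inf, -Inf, 1e-7, 0.05),
      upper = c(Inf, Inf, Inf, beta_max),
      control = minpack.lm::nls.lm.control(maxiter = 300,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
  }
  if (is.null(best)) stop("stretched-exponential fit did not converge")
  cf <- stats::coef(best)
  fit <- structure(list(F0 = unname(cf["F0"]), F_inf = unname(cf["F_inf"]),
                        tau0 = unname(cf["tau0"]), beta = unname(cf["beta"]),
                        fit_window = if (slow_trace) max(t) else window,
                        sigma = stats::sd(stats::residuals(best)),
                        no_activity = FALSE),
                   class = "stretchexp_fit")
  fit$k2ms <- quench_rate_at(fit)
  # little decay within the activity window: leak-level / blocked trace
  if (slow_trace || drop_window < max(0.02, 5 * fit$sigma) * abs(F0_0))
    fit$no_activity <- TRUE
  if (fit$beta > 1.02 && !fit$no_activity)
    warning("fitted beta > 1 (", signif(fit$beta, 3),
            "): outside the physical range for rate mixtures")
  fit
}

#' @export
print.stretchexp_fit <- function(x, ...) {
  cat(sprintf("Stretched-exponential fit: F0 = %.4g, F_inf = %.4g, tau0 = %.4g s, beta = %.3f\n",
              x$F0, x$F_inf, x$tau0, x$beta))
  cat(sprintf("quench rate at 2 ms: %.4g /s%s\n", x$k2ms,
              if (x$no_activity) "  [no-activity flag]" else ""))
  invisible(x)
}

#' @export
coef.stretchexp_fit <- function(object, ...) {
  c(F0 = object$F0, F_inf = object$F_inf, tau0 = object$tau0,
    beta = object$beta, k2ms = object$k2ms)
}

#' @export
predict.stretchexp_fit <- function(object, newdata, ...) {
  t <- if (is.list(newdata)) newdata$time else newdata
  object$F_inf + (object$F0 - object$F_inf) *
    exp(-(t / object$tau0)^object$beta)
}

#' Instantaneous quench rate of a stretched exponential
#'
#' `k(t) = (beta/tau0) (t/tau0)^(beta-1)`, evaluated by default at 2 ms.
#' For beta = 1 this reduces to `1/tau0` independent of t.
#'
#' @param fit a [fit_stretchexp()] result, or a list with `tau0` and `beta`.
#' @param t evaluation time (seconds, default 0.002).
#' @return rate (1/s).
#' @examples
#' quench_rate_at(list(tau0 = 0.0125, beta = 1))   # 80
#' quench_rate_at(list(tau0 = 0.010, beta = 0.5))  # 111.80
#' @export
quench_rate_at <- function(fit, t = 0.002) {
  if (fit$tau0 <= 0) stop("tau0 must be positive")
  (fit$beta / fit$tau0) * (t / fit$tau0)^(fit$beta - 1)
}

#' Quench rates as a function of pre-mix delay
#'
#' Fits each trace of a (pH, delay)-grouped set, averages the 2 ms quench
#' rates across repeats within each cell, and summarizes the decline of
#' activity with prolonged pre-incubation (delays >= 25 ms), the signature of
#' entry into the desensitized state.
#'
#' @param traces list of `flux_trace` objects (repeats allowed).
#' @param window fit window passed to [fit_stretchexp()].
#' @return object of class `rate_vs_delay`: data frame `entries` (pH, delay,
#'   mean k2ms, sd, n) and data frame `decline` (per pH: relative rate loss
#'   from the earliest delay >= 25 ms to the longest delay; 0 when flat).
#' @export
rate_vs_delay <- function(traces, window = 0.1) {
  stopifnot(length(traces) >= 1)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    f <- fit_stretchexp(tr, window = window)
    data.frame(pH = tr$pH, delay = tr$delay, k2ms = f$k2ms)
  }))
  agg <- do.call(rbind, lapply(split(rows, list(rows$pH, rows$delay),
                                     drop = TRUE), function(d)
    data.frame(pH = d$pH[1], delay = d$delay[1],
               mean_k2ms = mean(d$k2ms),
               sd_k2ms = if (nrow(d) > 1) stats::sd(d$k2ms) else 0,
               n = nrow(d))))
  agg <- agg[order(agg$pH, agg$delay), ]
  rownames(agg) <- NULL
  decline <- do.call(rbind, lapply(split(agg, agg$pH), function(d) {
    d2 <- d[d$delay >= 0.025, ]
    rel <- if (nrow(d2) >= 2) {
      k0 <- d2$mean_k2ms[1]
      k1 <- d2$mean_k2ms[nrow(d2)]
      if (k0 > 0) (k0 - k1) / k0 else 0
    } else 0
    data.frame(pH = d$pH[1], relative_decline = rel)
  }))
  rownames(decline) <- NULL
  structure(list(entries = agg, decline = decline),
            class = "rate_vs_delay")
}

#' @export
print.rate_vs_delay <- function(x, ...) {
  cat("Quench rate vs pre-mix delay:\n")
  print(signif(x$entries, 4), row.names = FALSE)
  cat("relative decline of activity over delays >= 25 ms:\n")
  print(signif(x$decline, 3), row.names = FALSE)
  invisible(x)
}

#' Flux-rate (dIf) dose-response curve
#'
#' Extracts the quench rates at a fixed pre-mix delay across pH, normalizes
#' to the maximum and returns a dose-response curve for Hill fitting.  A flat
#' rate profile (variation below 10% of the maximum) is flagged NA.
#'
#' @param rvd a [rate_vs_delay()] result.
#' @param delay pre-mix delay to extract (seconds, default 0.015).
#' @return a [dose_response_curve()] with readout `"dIf"`.
#' @export
flux_dose_response <- function(rvd, delay = 0.015) {
  stopifnot(inherits(rvd, "rate_vs_delay"))
  d <- rvd$entries[abs(rvd$entries$delay - delay) < 1e-9, ]
  if (nrow(d) < 4) stop("need rates at >= 4 pH values for the fixed delay")
  r <- d$mean_k2ms / max(d$mean_k2ms)
  na_flag <- (max(r) - min(r)) < 0.10
  dose_response_curve(d$pH, r, readout = "dIf", normalization = "to-max",
                      na_flag = na_flag)
}
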