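#' Amplitude-weighted activation time constant
#'
#' `tau_w = A1/(A1+A2) tau1 + A2/(A1+A2) tau2`, the standard summary of
#' biphasic activation kinetics.
#'
#' @param A1,A2 phase amplitudes (same units).
#' @param tau1,tau2 time constants (seconds).
#' @return weighted time constant (seconds).
#' @examples
#' weighted_tau(1, 2, 1, 8)  # 5
#' @export
weighted_tau <- function(A1, tau1, A2, tau2) {
  if (A1 + A2 == 0) stop("A1 + A2 must be non-zero")
  (A1 * tau1 + A2 * tau2) / (A1 + A2)
}

#' Fit biphasic activation kinetics of a clamp current
#'
#' Fits `y(t) = A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2)) + C` to a
#' rising current trace; degrades gracefully to a single exponential when a
#' second phase is not supported by the data (then `tau_w = tau1`).  Time
#' constants are returned sorted ascending and the weighted constant is
#' computed by [weighted_tau()].
#'
#' @param time seconds, or a data frame with columns `time_s`/`current_uA`.
#' @param current current values (uA) when `time` is a vector.
#' @return object of class `activation_fit` with `A1`, `A2`, `tau1`, `tau2`,
#'   `C`, `tau_w`, `n_phases`, `sigma`.
#' @export
fit_activation_current <- function(time, current = NULL) {
  if (is.data.frame(time)) {
    current <- time$current_uA
    time <- time$time_s
  }
  stopifnot(length(time) == length(current), length(time) >= 8)
  amp0 <- max(current) - min(current)
  c0 <- min(current)
  one_exp <- function() {
    starts <- c(0.3, 1, 3) * max(time) / 5
    best <- NULL
    for (tau0 in starts) {
      f <- try(minpack.lm::nlsLM(
        current ~ A1 * (1 - exp(-time / tau1)) + C,
        start = list(A1 = amp0, tau1 = tau0, C = c0),
        lower = c(-Inf, 1e-9, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-14, ptol = 1e-14)),
        silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
    }
    best
  }
  two_exp <- function() {
    starts <- list(c(1, 5), c(0.5, 10), c(2, 8), c(0.2, 2))
    best <- NULL
    for (s in starts) {
      f <- try(minpack.lm::nlsLM(
        current ~ A1 * (1 - exp(-time / tau1)) + A2 * (1 - exp(-time / tau2)) + C,
        start = list(A1 = 0.7 * amp0, tau1 = s[1], A2 = 0.3 * amp0,
                     tau2 = s[2], C = c0),
        lower = c(-Inf, 1e-9, -Inf, 1e-9, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300,
                                             ftol = 1e-14, ptol = 1e-14)),
        silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
    }
    best
  }
  f1 <- one_exp(); f2 <- two_exp()
  if (is.null(f1) && is.null(f2))
    stop("activation fit did not converge")
  aicc <- function(f, k) {
    n <- length(current)
    n * log(stats::deviance(f) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  use2 <- !is.null(f2)
  if (use2) {
    cf <- stats::coef(f2)
    # degenerate second phase: near-zero amplitude or indistinct taus
    degenerate <- abs(cf["A2"]) < 1e-3 * abs(cf["A1"] + cf["A2"]) ||
      abs(log(cf["tau1"] / cf["tau2"])) < 0.05
    if (degenerate || (!is.null(f1) && aicc(f1, 4) <= aicc(f2, 6))) use2 <- FALSE
  }
  if (use2) {
    cf <- stats::coef(f2)
    if (cf["tau1"] > cf["tau2"])
      cf[c("A1", "tau1", "A2", "tau2")] <- cf[c("A2", "tau2", "A1", "tau1")]
    out <- list(A1 = unname(cf["A1"]), tau1 = unname(cf["tau1"]),
                A2 = unname(cf["A2"]), tau2 = unname(cf["tau2"]),
                C = unname(cf["C"]),
                tau_w = weighted_tau(cf[["A1"]], cf[["tau1"]],
                                     cf[["A2"]], cf[["tau2"]]),
                n_phases = 2L,
                sigma = stats::sd(stats::residuals(f2)))
  } else {
    if (is.null(f1)) stop("activation fit did not converge")
    cf <- stats::coef(f1)
    out <- list(A1 = unname(cf["A1"]), tau1 = unname(cf["tau1"]),
                A2 = 0, tau2 = NA_real_, C = unname(cf["C"]),
                tau_w = unname(cf["tau1"]), n_phases = 1L,
                sigma = stats::sd(stats::residuals(f1)))
  }
  structure(out, class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat("Activation fit (", x$n_phases, " phase",
      if (x$n_phases > 1) "s", ")\n", sep = "")
  cat(sprintf("A1 = %.3g uA, tau1 = %.3g s", x$A1, x$tau1))
  if (x$n_phases == 2)
    cat(sprintf("; A2 = %.3g uA, tau2 = %.3g s", x$A2, x$tau2))
  cat(sprintf("; C = %.3g uA; tau_w = %.3g s\n", x$C, x$tau_w))
  invisible(x)
}

#' @export
coef.activation_fit <- function(object, ...) {
  c(A1 = object$A1, tau1 = object$tau1, A2 = object$A2, tau2 = object$tau2,
    C = object$C, tau_w = object$tau_w)
}
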