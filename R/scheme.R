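#' pH-dependent allosteric gating scheme
#'
#' Builds a linear kinetic scheme for proton-gated channel gating.  The
#' default four-state topology is R (resting) <-> P (pre-active) <-> O (open)
#' <-> D (desensitized).  Forward rates carry a Hill-type proton dependence,
#' \deqn{k_f([H^+]) = k_{max} \frac{[H^+]^n}{[H^+]^n + K^n},}
#' backward rates are pH-independent.  The pre-active step is fast
#' (sub-millisecond relaxation at acidic pH), channel opening relaxes on the
#' tens-of-milliseconds scale and desensitization is quasi-absorbing on a 30 s
#' observation window.
#'
#' The `"concerted"` topology removes the pre-active state: a single fast
#' R <-> O transition (inheriting the pre-activation rate law) is followed by
#' desensitization.  It serves as the negative control in which conformational
#' (fluorescence) and functional (flux) dose-response curves coincide.
#'
#' @param topology `"preactive"` (default, states R, P, O, D) or
#'   `"concerted"` (states R, O, D).
#' @param steps optional list of per-transition overrides.  Each element is a
#'   list with fields `kmax` (maximal forward rate, 1/s), `pK` (-log10 of the
#'   half-activation proton concentration), `n` (Hill cooperativity) and
#'   `kback` (backward rate, 1/s), named after the transition
#'   (e.g. `"R-P"`, `"P-O"`, `"O-D"`).
#' @param initial_occupancy probability vector over states; defaults to all
#'   receptors resting.
#' @param modulator_shift multiplicative factor applied to the forward
#'   pre-activation and opening rates; values < 1 emulate a negative
#'   allosteric modulator (propofol-like right shift of activation).
#'
#' @return An object of class `gating_scheme` with elements `states`,
#'   `steps` (data frame of transition parameters), `initial_occupancy`,
#'   `topology` and `modulator_shift`.
#' @examples
#' sc <- gating_scheme()
#' rate_matrix(sc, pH = 4)
#' steady_state(sc, pH = 7.3)
#' @export
gating_scheme <- function(topology = c("preactive", "concerted"),
                          steps = NULL,
                          initial_occupancy = NULL,
                          modulator_shift = 1) {
  topology <- match.arg(topology)
  if (topology == "preactive") {
    states <- c("R", "P", "O", "D")
    def <- data.frame(
      from  = c("R", "P", "O"),
      to    = c("P", "O", "D"),
      kmax  = c(2500, 16, 1.3),
      pK    = c(5.0, 4.7, 4.9),
      n     = c(1.5, 1.8, 1.8),
      kback = c(50, 6.5, 0.005),
      stringsAsFactors = FALSE
    )
  } else {
    states <- c("R", "O", "D")
    def <- data.frame(
      from  = c("R", "O"),
      to    = c("O", "D"),
      kmax  = c(2500, 1.3),
      pK    = c(5.0, 4.9),
      n     = c(1.5, 1.8),
      kback = c(50, 0.005),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(steps)) {
    for (nm in names(steps)) {
      i <- match(nm, paste(def$from, def$to, sep = "-"))
      if (is.na(i)) stop("unknown transition '", nm, "'")
      for (f in names(steps[[nm]])) {
        if (!f %in% c("kmax", "pK", "n", "kback"))
          stop("unknown rate field '", f, "' in transition '", nm, "'")
        def[[f]][i] <- steps[[nm]][[f]]
      }
    }
  }
  for (f in c("kmax", "kback")) {
    bad <- !is.finite(def[[f]]) | def[[f]] < 0
    if (any(bad))
      stop("field '", f, "' must be finite and non-negative (transition ",
           paste(def$from[bad], def$to[bad], sep = "-")[1], ")")
  }
  if (any(!is.finite(def$n) | def$n <= 0))
    stop("field 'n' (cooperativity) must be positive")
  if (is.null(initial_occupancy)) {
    initial_occupancy <- stats::setNames(c(1, rep(0, length(states) - 1L)),
                                         states)
  }
  if (length(initial_occupancy) != length(states))
    stop("field 'initial_occupancy' must have one entry per state")
  if (any(initial_occupancy < 0) ||
      abs(sum(initial_occupancy) - 1) > 1e-9)
    stop("field 'initial_occupancy' must be a probability vector (non-negative, sum 1)")
  if (!is.finite(modulator_shift) || modulator_shift < 0)
    stop("field 'modulator_shift' must be a non-negative factor")
  structure(
    list(states = states, steps = def,
         initial_occupancy = stats::setNames(as.numeric(initial_occupancy), states),
         topology = topology, modulator_shift = modulator_shift),
    class = "gating_scheme"
  )
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("Gating scheme (", x$topology, "): ",
      paste(x$states, collapse = " <-> "), "\n", sep = "")
  print(x$steps, row.names = FALSE)
  if (x$modulator_shift != 1)
    cat("modulator shift on forward activation rates:", x$modulator_shift, "\n")
  invisible(x)
}

hill_activation <- function(H, K, n) {
  r <- (H / K)^n
  r / (1 + r)
}

#' Transition-rate matrix at a given pH
#'
#' Generator matrix Q of the scheme at proton concentration `10^-pH`, in the
#' column convention: `Q[j, i]` is the rate (1/s) from state i to state j and
#' every column sums to zero (probability conservation).
#'
#' @param scheme a [gating_scheme()].
#' @param pH unitless pH in `[2, 9]`.
#' @return square numeric matrix with `dimnames` the state labels.
#' @export
rate_matrix <- function(scheme, pH) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!is.finite(pH) || pH < 2 || pH > 9)
    stop("pH must lie in [2, 9]")
  H <- 10^(-pH)
  ns <- length(scheme$states)
  Q <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  st <- scheme$steps
  desens <- st$to == "D"
  for (i in seq_len(nrow(st))) {
    kf <- st$kmax[i] * hill_activation(H, 10^(-st$pK[i]), st$n[i])
    if (!desens[i]) kf <- kf * scheme$modulator_shift
    a <- match(st$from[i], scheme$states)
    b <- match(st$to[i], scheme$states)
    Q[b, a] <- Q[b, a] + kf
    Q[a, b] <- Q[a, b] + st$kback[i]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Steady-state occupancy of the scheme
#'
#' Null-space solution of the generator at a given pH, normalized to a
#' probability vector.
#'
#' @inheritParams rate_matrix
#' @return named occupancy vector.
#' @export
steady_state <- function(scheme, pH) {
  Q <- rate_matrix(scheme, pH)
  ns <- nrow(Q)
  A <- rbind(Q, rep(1, ns))
  b <- c(rep(0, ns), 1)
  p <- stats::setNames(as.vector(qr.solve(A, b)), rownames(Q))
  p[p < 0 & p > -1e-12] <- 0
  p
}

#' Propagate state occupancies in time
#'
#' Solves dp/dt = Q p for the time-homogeneous generator of the scheme at a
#' fixed pH by spectral (matrix-exponential) propagation; a scaling-and-squaring
#' matrix exponential (via the Matrix package) is used stepwise when the
#' generator is close to defective.
#'
#' @inheritParams rate_matrix
#' @param tgrid strictly increasing times (seconds), `>= 0`.
#' @param p0 initial occupancy; defaults to the scheme's `initial_occupancy`.
#' @return matrix (length(tgrid) x states) of occupancies; each row is a
#'   probability vector.
#' @examples
#' sc <- gating_scheme()
#' occ <- simulate_occupancies(sc, pH = 4, tgrid = c(0, 0.001, 0.01, 0.1, 1))
#' rowSums(occ)  # all 1
#' @export
simulate_occupancies <- function(scheme, pH, tgrid, p0 = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (length(tgrid) < 1L || any(!is.finite(tgrid)) || any(tgrid < 0))
    stop("tgrid must be non-negative and finite")
  if (is.unsorted(tgrid, strictly = TRUE))
    stop("tgrid must be strictly increasing")
  if (is.null(p0)) p0 <- scheme$initial_occupancy
  if (length(p0) != length(scheme$states))
    stop("p0 must have one entry per state")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability vector")
  Q <- rate_matrix(scheme, pH)
  occ <- propagate_generator(Q, p0, tgrid)
  dimnames(occ) <- list(NULL, scheme$states)
  occ
}

# spectral propagation with stepwise expm fallback for ill-conditioned
# eigenvector bases
propagate_generator <- function(Q, p0, tgrid) {
  e <- eigen(Q)
  ok <- !inherits(try(cV <- kappa(e$vectors), silent = TRUE), "try-error") &&
    is.finite(cV) && cV < 1e8
  if (ok) {
    a <- solve(e$vectors, p0)
    out <- Re(t(e$vectors %*% (a * exp(outer(e$values, tgrid)))))
  } else {
    out <- matrix(0, length(tgrid), length(p0))
    dt <- diff(c(0, tgrid))
    p <- p0
    ud <- unique(dt)
    mats <- lapply(ud, function(d) as.matrix(Matrix::expm(Q * d)))
    names(mats) <- format(ud, digits = 17)
    for (i in seq_along(tgrid)) {
      p <- mats[[format(dt[i], digits = 17)]] %*% p
      out[i, ] <- p
    }
  }
  # clip tiny negative round-off, renormalize at machine level
  out[out < 0 & out > -1e-10] <- 0
  out
}
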