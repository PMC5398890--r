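#' Collect fitted time constants into a tau ensemble
#'
#' Pools per-trace multi-exponential components (and the dead-time phase
#' fractions) across sensors and pH for kinetic-phase analysis.
#'
#' @param fits list of [fit_multiexp()] results.
#' @param phases optional list of matching [decompose_phases()] results; when
#'   given, relative amplitudes and dead-time entries are attached.
#' @return object of class `tau_ensemble`: data frame `entries`
#'   (sensor_id, pH, tau, rel_dF_pct, direction) and data frame `deadtime`
#'   (sensor_id, pH, rel_dF_pct).
#' @export
tau_ensemble <- function(fits, phases = NULL) {
  stopifnot(length(fits) >= 1)
  entries <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    stopifnot(inherits(f, "multiexp_fit"))
    if (!is.null(phases)) {
      ph <- phases[[i]]
      data.frame(sensor_id = f$sensor_id, pH = f$pH,
                 tau = f$components$tau,
                 rel_dF_pct = ph$per_component$rel_dF_pct,
                 direction = ph$per_component$direction)
    } else {
      data.frame(sensor_id = f$sensor_id, pH = f$pH,
                 tau = f$components$tau,
                 rel_dF_pct = NA_real_,
                 direction = ifelse(f$components$amplitude > 0,
                                    "decrease", "increase"))
    }
  }))
  deadtime <- if (!is.null(phases))
    do.call(rbind, lapply(phases, function(ph)
      data.frame(sensor_id = ph$sensor_id, pH = ph$pH,
                 rel_dF_pct = abs(ph$deadtime_dF_pct))))
  else NULL
  structure(list(entries = entries, deadtime = deadtime),
            class = "tau_ensemble")
}

#' Log-binned histogram of time constants
#'
#' Bins tau values on a log10 grid of fixed width anchored at the fit start
#' (5 ms), as used to separate kinetic phases.  Values faster than the anchor
#' are counted separately as "very fast" (they are unresolved within the
#' analysis window).
#'
#' @param ensemble a [tau_ensemble()] or numeric vector of tau (seconds).
#' @param bin_width log10 bin width (default 0.4).
#' @param anchor bin-grid origin (seconds; default 0.005).
#' @return object of class `tau_histogram`: `edges` (seconds), `counts`,
#'   `n_very_fast`, `taus`.
#' @export
log_bin_taus <- function(ensemble, bin_width = 0.4, anchor = 0.005) {
  taus <- if (inherits(ensemble, "tau_ensemble")) ensemble$entries$tau
  else as.numeric(ensemble)
  if (length(taus) == 0) stop("empty tau ensemble")
  if (any(!is.finite(taus) | taus <= 0)) stop("tau values must be positive")
  very_fast <- taus < anchor
  tin <- taus[!very_fast]
  if (length(tin)) {
    idx <- floor(log10(tin / anchor) / bin_width)
    nb <- max(idx) + 1L
    counts <- tabulate(idx + 1L, nbins = nb)
  } else {
    nb <- 0L; counts <- integer(0)
  }
  edges <- anchor * 10^(bin_width * (0:nb))
  structure(list(edges = edges, counts = counts,
                 n_very_fast = sum(very_fast), taus = taus,
                 bin_width = bin_width, anchor = anchor),
            class = "tau_histogram")
}

#' @export
print.tau_histogram <- function(x, ...) {
  cat("Tau histogram:", length(x$taus), "values,", x$n_very_fast,
      "below the", x$anchor * 1000, "ms anchor\n")
  if (length(x$counts))
    print(data.frame(t_low_ms = signif(1000 * x$edges[-length(x$edges)], 3),
                     t_high_ms = signif(1000 * x$edges[-1], 3),
                     count = x$counts), row.names = FALSE)
  invisible(x)
}

#' Identify kinetic-phase clusters in a tau histogram
#'
#' Cuts the histogram at runs of empty bins; when more than three clusters
#' result, the pair separated by the narrowest gap is merged (leftmost on
#' ties) until three remain; when a single occupied run spans four or more
#' bins and contains interior local count minima, it is split at the deepest
#' minima into at most three clusters.  Reported cluster intervals span the
#' occupied bins; partition boundaries additionally tile the whole
#' (fit start, end] axis so every tau is assigned to exactly one phase, with
#' the sub-anchor "very fast" phase preceding them.
#'
#' @param histogram a [log_bin_taus()] result.
#' @return object of class `phase_partition`: `cluster_intervals` (data frame
#'   label/t_low/t_high/count), `boundaries` (seconds, tiling the axis),
#'   `histogram`.
#' @export
identify_phases <- function(histogram) {
  stopifnot(inherits(histogram, "tau_histogram"))
  cnt <- histogram$counts
  if (!length(cnt) || sum(cnt) == 0) stop("empty histogram")
  occ <- which(cnt > 0)
  # maximal runs of occupied bins
  runs <- split(occ, cumsum(c(1, diff(occ) > 1)))
  clusters <- lapply(runs, function(r) c(first = min(r), last = max(r)))
  cl_count <- function(cl) sum(cnt[cl["first"]:cl["last"]])
  while (length(clusters) > 3) {
    gaps <- vapply(seq_len(length(clusters) - 1), function(i)
      clusters[[i + 1]]["first"] - clusters[[i]]["last"] - 1, numeric(1))
    # merge across the narrowest gap; among ties, the pair holding the fewest
    # tau values (slow components scatter widely on the log axis), then the
    # rightmost
    sums <- vapply(seq_len(length(clusters) - 1), function(i)
      cl_count(clusters[[i]]) + cl_count(clusters[[i + 1]]), numeric(1))
    cand <- which(gaps == min(gaps))
    cand <- cand[sums[cand] == min(sums[cand])]
    i <- cand[length(cand)]
    clusters[[i]] <- c(first = unname(clusters[[i]]["first"]),
                       last = unname(clusters[[i + 1]]["last"]))
    clusters[[i + 1]] <- NULL
  }
  if (length(clusters) == 1) {
    r <- clusters[[1]]
    if (r["last"] - r["first"] + 1 >= 4) {
      inner <- (r["first"] + 1):(r["last"] - 1)
      mins <- inner[vapply(inner, function(i)
        cnt[i] < cnt[i - 1] && cnt[i] <= cnt[i + 1], logical(1))]
      if (length(mins)) {
        mins <- mins[order(cnt[mins])][seq_len(min(2, length(mins)))]
        cuts <- sort(mins)
        bounds <- c(r["first"] - 1, cuts, r["last"])
        clusters <- lapply(seq_len(length(bounds) - 1), function(i)
          c(first = unname(bounds[i] + 1), last = unname(bounds[i + 1])))
      }
    }
  }
  edges <- histogram$edges
  labels <- c("fast", "intermediate", "slow")[seq_along(clusters)]
  ci <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    r <- clusters[[i]]
    sel <- histogram$taus >= edges[r["first"]] &
      histogram$taus < edges[r["last"] + 1]
    data.frame(label = labels[i],
               t_low = edges[r["first"]], t_high = edges[r["last"] + 1],
               count = sum(cnt[r["first"]:r["last"]]))
  }))
  # tiling boundaries: anchor, then left edge of each later cluster's span
  bnd <- c(histogram$anchor,
           if (nrow(ci) > 1) ci$t_low[-1],
           max(edges[length(edges)], max(histogram$taus)))
  structure(list(cluster_intervals = ci, boundaries = bnd,
                 histogram = histogram),
            class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat("Kinetic phase partition (very fast: tau <",
      x$histogram$anchor * 1000, "ms)\n")
  ci <- x$cluster_intervals
  ci$t_low_ms <- signif(ci$t_low * 1000, 4)
  ci$t_high_ms <- signif(ci$t_high * 1000, 4)
  print(ci[c("label", "t_low_ms", "t_high_ms", "count")], row.names = FALSE)
  invisible(x)
}

# phase label of each tau under a partition (very_fast below the anchor)
assign_phase <- function(taus, partition) {
  bnd <- partition$boundaries
  labs <- partition$cluster_intervals$label
  idx <- findInterval(taus, bnd, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 0L), length(labs))
  out <- ifelse(idx >= 1, labs[pmax(idx, 1L)], "very_fast")
  out[taus < partition$histogram$anchor] <- "very_fast"
  out
}

#' Aggregate per-phase fluorescence amplitudes
#'
#' Mean, standard deviation and count of the relative fluorescence amplitude
#' magnitudes in each kinetic phase of a partition; the very-fast (dead-time)
#' phase is aggregated from the ensemble's dead-time entries.
#'
#' @param ensemble a [tau_ensemble()] with amplitudes attached.
#' @param partition an [identify_phases()] result.
#' @return data frame with columns phase, mean_dF_pct, sd_dF_pct, n.
#' @export
aggregate_phase_dF <- function(ensemble, partition) {
  stopifnot(inherits(ensemble, "tau_ensemble"),
            inherits(partition, "phase_partition"))
  ent <- ensemble$entries
  ph <- assign_phase(ent$tau, partition)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                       n = length(v))
  rows <- list()
  if (!is.null(ensemble$deadtime) && nrow(ensemble$deadtime))
    rows[["very_fast"]] <- agg(abs(ensemble$deadtime$rel_dF_pct))
  for (lab in partition$cluster_intervals$label) {
    v <- abs(ent$rel_dF_pct[ph == lab])
    v <- v[is.finite(v)]
    if (length(v)) rows[[lab]] <- agg(v)
  }
  out <- data.frame(phase = names(rows),
                    mean_dF_pct = vapply(rows, `[[`, 0, "mean"),
                    sd_dF_pct = vapply(rows, `[[`, 0, "sd"),
                    n = vapply(rows, `[[`, 0, "n"))
  rownames(out) <- NULL
  out
}
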