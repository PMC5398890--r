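test_that("normalization maps a trace onto its reference baseline", {
  # linearly bleaching, noise-free reference (the regime the smoother is
  # exact for)
  ref <- synthetic_sf_trace(0.8, 0, 1)
  ref$intensity <- 0.8 * (1 - 0.002 * ref$time)
  ref$pH <- 8; ref$condition <- "reference_pH8"
  same <- ref
  same$condition <- "test"
  n1 <- normalize_to_reference(same, ref)
  expect_true(all(abs(n1$intensity - 1) < 1e-9))
  half <- same
  half$intensity <- ref$intensity * 0.5
  n2 <- normalize_to_reference(half, ref)
  expect_true(all(abs(n2$intensity - 0.5) < 1e-9))
  bad <- ref
  bad$time <- bad$time + 1
  expect_error(normalize_to_reference(same, bad), "grid")
  neg <- ref
  neg$intensity[1] <- -1
  expect_error(normalize_to_reference(same, neg), "positive")
})

test_that("normalization removes shared linear drift to within 0.5% RMS", {
  sc <- gating_scheme()
  s <- default_sensors(sc)[["136-101"]]
  s_drift <- sensor_model(s$id, s$brightness, noise_sd = 0,
                          drift_rate = 0.001)
  tr <- simulate_sf_trace(sc, s_drift, sf_protocol(), pH = 5, seed = 3)
  ntr <- normalize_to_reference(tr)
  occ <- simulate_occupancies(sc, 5, ntr$time)
  truth <- observable_fluorescence(occ, s_drift) / s$brightness[["R"]]
  expect_lt(sqrt(mean((ntr$intensity - truth)^2)), 0.005)
})

test_that("noiseless in-class traces are recovered to 1e-6 with the right order", {
  cases <- list(
    list(offset = 0.5, amp = 0.5, rate = 10),
    list(offset = 0.4, amp = c(0.3, 0.2), rate = c(50, 0.8)),
    list(offset = 0.46, amp = c(0.30, 0.10, 0.14),
         rate = c(1 / 0.009, 1 / 0.1, 1 / 2.9))
  )
  for (cs in cases) {
    tr <- synthetic_sf_trace(cs$offset, cs$amp, cs$rate)
    fit <- fit_multiexp(tr)
    expect_identical(fit$n_components, length(cs$amp))
    expect_equal(fit$offset, cs$offset, tolerance = 1e-6)
    expect_equal(fit$components$rate, sort(cs$rate, decreasing = TRUE),
                 tolerance = 1e-6)
    expect_equal(fit$components$amplitude,
                 cs$amp[order(cs$rate, decreasing = TRUE)],
                 tolerance = 1e-6)
    # rates reported fastest first
    expect_true(all(diff(fit$components$rate) <= 0))
  }
})

test_that("fit endpoint matches the trace endpoint within three residual sd", {
  tr <- synthetic_sf_trace(0.5, c(-0.2, -0.1), c(30, 0.5),
                           noise_sd = 0.01, seed = 2)
  fit <- fit_multiexp(tr)
  endm <- predict(fit, fit$fit_window["end"])
  endt <- mean(tail(tr$intensity, 20))
  expect_lt(abs(endm - endt), 3 * max(fit$sigma, 1e-3))
})

test_that("triple-exponential parameters survive 1% noise in most seeds", {
  taus <- c(0.009, 0.1, 2.9)
  ok <- vapply(1:12, function(sd) {
    tr <- synthetic_sf_trace(0.46, c(-0.30, -0.10, -0.14), 1 / taus,
                             noise_sd = 0.01, seed = 100 + sd)
    fit <- try(fit_multiexp(tr), silent = TRUE)
    if (inherits(fit, "try-error") || fit$n_components != 3) return(FALSE)
    all(abs(sort(fit$components$tau) / sort(taus) - 1) < 0.20)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("model selection does not hallucinate extra components at 2% noise", {
  n3 <- vapply(1:40, function(sd) {
    tr <- synthetic_sf_trace(0.6, -0.4, 2, noise_sd = 0.02, seed = 500 + sd)
    fit_multiexp(tr)$n_components
  }, numeric(1))
  expect_gte(mean(n3 < 3), 0.95)
})

test_that("window guard: too few points is an error", {
  tr <- synthetic_sf_trace(0.5, -0.3, 5)
  tr$time <- tr$time[1:30]; tr$intensity <- tr$intensity[1:30]
  expect_error(fit_multiexp(tr), "50 points")
})

test_that("phase accounting sums to 100% and flags flat traces", {
  tr <- synthetic_sf_trace(0.55, c(-0.2, -0.12), c(20, 0.4),
                           noise_sd = 0.01, seed = 9)
  fit <- fit_multiexp(tr)
  ph <- decompose_phases(fit)
  expect_equal(abs(ph$deadtime_dF_pct) + sum(ph$per_component$rel_dF_pct),
               100, tolerance = 1)
  expect_false(ph$no_variation)
  # trace fully equilibrated before the window start
  tr2 <- synthetic_sf_trace(0.7, -0.3, 5000)
  fit2 <- fit_multiexp(tr2)
  ph2 <- decompose_phases(fit2)
  expect_equal(abs(ph2$deadtime_dF_pct), 100, tolerance = 1)
  # no-variation flag below the 10% floor
  tr3 <- synthetic_sf_trace(0.97, -0.03, 20, noise_sd = 0.002, seed = 1)
  expect_true(decompose_phases(fit_multiexp(tr3))$no_variation)
})

test_that("bidirectional phase accounting sums absolute amplitudes", {
  # dead-time -60%, then -30% decrease and +10% increase of the max variation
  t0 <- 0.0051
  a1 <- 0.30 * exp(20 * t0)    # decays downward by 0.30 over the window
  a2 <- -0.10 * exp(0.5 * t0)  # rises by 0.10
  offset <- 1 - 0.60 - 0.30 + 0.10
  tr <- synthetic_sf_trace(offset, c(a1, a2), c(20, 0.5))
  fit <- fit_multiexp(tr)
  ph <- decompose_phases(fit)
  expect_true(ph$bidirectional)
  expect_equal(ph$max_dF_pct, 100, tolerance = 1)
  expect_equal(ph$deadtime_dF_pct, -60, tolerance = 1)
  expect_equal(sort(ph$per_component$rel_dF_pct), c(10, 30), tolerance = 1)
  expect_equal(abs(ph$deadtime_dF_pct) + sum(ph$per_component$rel_dF_pct),
               100, tolerance = 1)
})

test_that("single-exponential completion bound behaves as defined", {
  expect_equal(infer_tau_upper_bound(1 - exp(-1), 1), 1, tolerance = 1e-12)
  tb <- infer_tau_upper_bound(0.865, 0.002)
  expect_equal(tb, -0.002 / log(0.135), tolerance = 1e-12)
  expect_lt(tb, 1e-3)
  expect_lt(infer_tau_upper_bound(0.9, 0.002), 1e-3)
  expect_error(infer_tau_upper_bound(1, 1), "< 1")
  expect_error(infer_tau_upper_bound(-0.1, 1), "positive")
})

test_that("weighted activation constant is the amplitude-weighted mean", {
  expect_identical(weighted_tau(2, 1.5, 0, 7), 1.5)
  expect_identical(weighted_tau(1, 2, 1, 8), 5)
  expect_error(weighted_tau(0, 1, 0, 2), "non-zero")
  # published-style consistency: tau_w between tau1 and tau2 implies an
  # amplitude weight inside (0, 1)
  w <- (3.57 - 8.9) / (2.80 - 8.9)
  expect_gt(w, 0); expect_lt(w, 1)
  expect_equal(w, 0.874, tolerance = 1e-3)
})

test_that("activation fits recover noiseless parameters and degrade to one phase", {
  tt <- seq(0, 30, by = 0.05)
  cur <- 2 * (1 - exp(-tt / 1.5)) + 1 * (1 - exp(-tt / 7))
  fit <- fit_activation_current(tt, cur)
  expect_identical(fit$n_phases, 2L)
  expect_equal(c(fit$A1, fit$tau1, fit$A2, fit$tau2), c(2, 1.5, 1, 7),
               tolerance = 1e-6)
  expect_lte(fit$tau1, fit$tau2)
  expect_true(fit$tau_w >= fit$tau1 && fit$tau_w <= fit$tau2)
  single <- 2 * (1 - exp(-tt / 1.5))
  fs <- fit_activation_current(tt, single)
  expect_identical(fs$n_phases, 1L)
  expect_equal(fs$tau_w, fs$tau1, tolerance = 1e-9)
  expect_equal(fs$tau1, 1.5, tolerance = 1e-6)
})

test_that("simulated clamp traces are fit with biphasic kinetics in range", {
  sc <- gating_scheme()
  out <- simulate_tevc_current(sc, 4, noise_sd = 0.005, seed = 11)
  fit <- fit_activation_current(out$traces[["4"]])
  expect_identical(fit$n_phases, 2L)
  expect_gt(fit$tau1, 1); expect_lt(fit$tau1, 2.8)
  expect_gt(fit$tau2, 5); expect_lt(fit$tau2, 8.9)
})
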