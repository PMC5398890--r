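test_that("protein-free and blocked preparations quench at the leak rate", {
  sc <- gating_scheme()
  cfg0 <- flux_config(channels_per_liposome = 0)
  tr0 <- simulate_flux_assay(sc, cfg0, pH = 4.2, delay = 0.015, seed = 1)
  f0 <- fit_stretchexp(tr0)
  expect_lte(f0$k2ms, 2 * cfg0$leak_rate)
  expect_true(f0$no_activity)
  cfgB <- flux_config(blocker_active = TRUE)
  trB <- simulate_flux_assay(sc, cfgB, pH = 4.2, delay = 0.015, seed = 1)
  fB <- fit_stretchexp(trB)
  expect_lte(fB$k2ms, 2 * cfgB$leak_rate)
  # blocked trace is statistically indistinguishable from protein-free
  expect_lt(abs(mean(trB$intensity) - mean(tr0$intensity)), 0.01)
})

test_that("a homogeneous liposome population decays mono-exponentially", {
  sc <- gating_scheme()
  cfg <- flux_config(diameter_sdlog = 1e-9, channels_per_liposome = 4,
                     channel_dispersion = "fixed")
  ok <- vapply(1:5, function(sd) {
    tr <- simulate_flux_assay(sc, cfg, pH = 4.2, delay = 0.015, seed = sd)
    f <- suppressWarnings(fit_stretchexp(tr))
    abs(f$beta - 1) <= 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("stretched fit beats a single exponential on heterogeneous ensembles", {
  sc <- gating_scheme()
  cfg <- flux_config()
  wins <- vapply(1:50, function(sd) {
    tr <- simulate_flux_assay(sc, cfg, pH = 4.2, delay = 0.015, seed = sd)
    fs <- suppressWarnings(fit_stretchexp(tr))
    sel <- tr$time <= 0.1
    t <- tr$time[sel]; y <- tr$intensity[sel]
    f1 <- minpack.lm::nlsLM(y ~ A + B * exp(-t / tau),
                            start = list(A = 0.4, B = 0.6, tau = 0.02))
    sum((y - predict(fs, t))^2) < deviance(f1)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("flux configuration guards reject unphysical settings", {
  expect_error(flux_config(stern_volmer_M = 0), "Stern-Volmer")
  expect_error(flux_config(delay_times = 0.005), "15 ms")
  sc <- gating_scheme()
  expect_error(simulate_flux_assay(sc, flux_config(), pH = 4, delay = 0.01),
               "0.015")
})

test_that("flux traces are seed-reproducible", {
  sc <- gating_scheme()
  t1 <- simulate_flux_assay(sc, flux_config(), pH = 5, delay = 0.015, seed = 3)
  t2 <- simulate_flux_assay(sc, flux_config(), pH = 5, delay = 0.015, seed = 3)
  expect_identical(t1$intensity, t2$intensity)
})

test_that("default assay quenches at roughly 80/s under strong activation", {
  sc <- gating_scheme()
  k <- vapply(1:6, function(sd)
    fit_stretchexp(simulate_flux_assay(sc, flux_config(), pH = 4.2,
                                       delay = 0.015, seed = sd))$k2ms,
    numeric(1))
  expect_gt(mean(k), 80 / 1.5)
  expect_lt(mean(k), 80 * 1.5)
})

test_that("prolonged pre-incubation lowers activity only when desensitization is on", {
  sc <- gating_scheme()
  cfg <- flux_config()
  mk <- function(scheme, delays, seed0) {
    traces <- list()
    for (d in delays) for (r in 1:2)
      traces[[length(traces) + 1]] <-
        simulate_flux_assay(scheme, cfg, pH = 4.2, delay = d,
                            seed = seed0 + length(traces))
    rate_vs_delay(traces)
  }
  # activation is anchored on patch-clamp opening kinetics, so occupancy
  # peaks near 0.15 s; desensitization empties the open state beyond that
  rv <- mk(sc, c(0.2, 0.8, 2), 10)
  e <- rv$entries
  expect_lt(e$mean_k2ms[e$delay == 2], e$mean_k2ms[e$delay == 0.2])
  expect_gt(rv$decline$relative_decline, 0.2)
  sc0 <- gating_scheme(steps = list("O-D" = list(kmax = 0, kback = 0)))
  rv0 <- mk(sc0, c(0.2, 0.8, 2), 40)
  expect_lt(abs(rv0$decline$relative_decline), 0.15)
})

test_that("identical traces give a flat delay profile with zero decline", {
  sc <- gating_scheme()
  tr <- simulate_flux_assay(sc, flux_config(), pH = 4.2, delay = 0.015,
                            seed = 1)
  copies <- lapply(c(0.025, 0.05, 0.1), function(d) {
    x <- tr; x$delay <- d; x
  })
  rv <- rate_vs_delay(copies)
  expect_equal(rv$decline$relative_decline, 0, tolerance = 1e-9)
})
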