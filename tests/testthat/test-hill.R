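hill_y <- function(pH, a, nH, pH50) {
  x <- 10^(-pH); E <- 10^(-pH50)
  a * x^nH / (x^nH + E^nH)
}

test_that("exact Hill curves evaluate and round-trip to 1e-6", {
  expect_equal(hill_y(4.5, 1, 2, 5), 10 / 11, tolerance = 1e-9)  # 0.909
  pH <- seq(8, 3.5, by = -0.25)
  f <- fit_hill(pH, hill_y(pH, 1, 2, 5))
  expect_equal(c(f$a, f$nH, f$pH50), c(1, 2, 5), tolerance = 1e-6)
  expect_identical(f$pH50, -log10(f$EC50))
  # response at the half-activation point is a/2
  expect_equal(hill_y(5, 1, 2, 5), 0.5, tolerance = 1e-12)
  # decreasing (quenching-type) curve, alkaline-anchored
  fd <- fit_hill(pH, 0.9 - 0.9 * hill_y(pH, 1, 2, 4.5))
  expect_equal(c(fd$a, fd$nH, fd$pH50), c(0.9, 2, 4.5), tolerance = 1e-4)
  expect_identical(fd$direction, "decrease")
})

test_that("pH50 is invariant under positive rescaling of the response", {
  pH <- seq(8, 4, by = -0.25)
  y <- hill_y(pH, 0.8, 1.5, 5.2)
  f1 <- fit_hill(pH, y)
  f2 <- fit_hill(pH, y * 37.5)
  expect_lt(abs(f1$pH50 - f2$pH50), 1e-9)
  yd <- 1 - hill_y(pH, 0.7, 1.5, 5.2)
  g1 <- fit_hill(pH, yd)
  g2 <- fit_hill(pH, yd * 0.043)
  expect_lt(abs(g1$pH50 - g2$pH50), 1e-9)
})

test_that("noisy Hill curves recover pH50 within 0.1 in most seeds", {
  pH <- seq(7.3, 4, by = -0.3)
  ok <- vapply(1:12, function(sd) {
    set.seed(sd)
    y <- hill_y(pH, 1, 1.8, 5.3) + rnorm(length(pH), 0, 0.02)
    abs(fit_hill(pH, y)$pH50 - 5.3) <= 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("curve guards: point count, degenerate input, non-monotonic limbs", {
  expect_error(fit_hill(c(7, 6, 5), c(0, 0.5, 1)), "4 distinct")
  # symmetric V-shape has no dominant limb
  pH <- c(8, 7, 6, 5, 4, 3)
  y <- c(1, 0.7, 0.35, 0.35, 0.7, 1)
  expect_error(fit_hill(pH, y), "not Hill-fittable")
  # inverted-bell with a dominant alkaline limb fits with a warning
  y2 <- c(0.7, 0.5, 0.32, 0.30, 0.45, 0.55)
  expect_warning(f <- fit_hill(pH, y2), "limb")
  expect_identical(f$curve$direction, "non-monotonic")
})

test_that("fluorescence curves are normalized and flat ones flagged NA", {
  crv <- build_dF_curve(c(7.3, 6, 5, 4), c(1, 1.001, 0.999, 1),
                        normalization = "sds", reference_intensity = 1)
  expect_true(crv$na_flag)
  crv2 <- build_dF_curve(c(7.3, 6.5, 6, 5, 4), c(1, 0.9, 0.8, 0.6, 0.5),
                         normalization = "sds", reference_intensity = 1)
  expect_false(crv2$na_flag)
  expect_identical(crv2$direction, "decrease")
  expect_equal(min(crv2$response), 0.5)
  expect_error(build_dF_curve(c(7, 6, 5, 4), 1:4, normalization = "sds"),
               "missing")
})

test_that("current curves drop trailing sub-maximal acidic points only when asked", {
  pH <- c(7, 6, 5, 4.5, 4, 3.7)
  cur <- c(0.1, 1.5, 5, 6.9, 7, 6)
  c_keep <- build_dI_curve(pH, cur)
  expect_identical(length(c_keep$pH), 6L)
  c_drop <- build_dI_curve(pH, cur, exclude_submaximal_lowpH = TRUE)
  expect_identical(length(c_drop$pH), 5L)
  expect_false(3.7 %in% c_drop$pH)
  # monotone saturating currents unchanged by the flag
  mono <- c(0.1, 1.5, 5, 6.5, 6.9, 7)
  expect_identical(length(build_dI_curve(pH, mono,
                                         exclude_submaximal_lowpH = TRUE)$pH),
                   6L)
  expect_error(build_dI_curve(pH, rep(0.2, 6)), "non-functional")
})

test_that("a desensitization droop does not bias the recovered current pH50", {
  pH <- c(7, 6.5, 6, 5.5, 5.2, 5, 4.7, 4.4, 4, 3.7)
  y <- hill_y(pH, 7, 1.8, 5.1)
  y[pH == 3.7] <- 0.8 * max(y)          # droop at the most acidic point
  fit <- fit_hill(build_dI_curve(pH, y, exclude_submaximal_lowpH = TRUE))
  expect_lt(abs(fit$pH50 - 5.1), 0.1)
})

test_that("simulated peak currents give a wild-type-like Hill fit", {
  sc <- gating_scheme()
  out <- simulate_tevc_current(sc, c(7.3, 7, 6.5, 6, 5.7, 5.4, 5.1, 4.8,
                                     4.5, 4.2, 4), seed = 5)
  fit <- fit_hill(build_dI_curve(out$peak_table$pH,
                                 out$peak_table$current_uA,
                                 exclude_submaximal_lowpH = TRUE))
  expect_gt(fit$pH50, 4.8); expect_lt(fit$pH50, 5.6)
  expect_gt(fit$nH, 1); expect_lt(fit$nH, 2.5)
})

test_that("pH50 separation flags intermediates exactly at the threshold rule", {
  pH <- seq(7.5, 4, by = -0.25)
  fA <- fit_hill(pH, hill_y(pH, 1, 1.5, 5.8))
  fB <- fit_hill(pH, hill_y(pH, 1, 1.5, 4.7))
  cmp <- compare_curves(fA, fB)
  expect_equal(cmp$delta_pH50, 1.1, tolerance = 1e-3)
  expect_true(cmp$flag_intermediate)
  same <- compare_curves(fA, fA)
  expect_equal(same$delta_pH50, 0, tolerance = 1e-12)
  expect_false(same$flag_intermediate)
})
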