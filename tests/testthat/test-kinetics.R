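test_that("weight loss converts to cumulative CO2 per litre", {
  r <- fermentation_record("v1", "S", "M", FALSE, 5, 1,
                           c(0, 10, 20, 30), c(20, 19.9, 19.8, 19.7))
  co2 <- weights_to_co2(r)
  expect_equal(co2$co2[1], 0)
  expect_equal(co2$co2[2], 20)       # 0.1 g over 0.005 L
  r3 <- fermentation_record("v2", "S", "M", FALSE, 3, 1,
                            c(0, 10, 20, 30), c(20, 19.94, 19.9, 19.88))
  expect_equal(weights_to_co2(r3)$co2[2], 20)  # volume scaling
})

test_that("record constructor enforces the weighing-log invariants", {
  expect_error(fermentation_record("v", "S", "M", FALSE, 5, 1,
                                   c(0, 10, 10, 20), c(20, 19, 18, 17)),
               "strictly increasing")
  expect_error(fermentation_record("v", "S", "M", FALSE, 0, 1,
                                   c(0, 10, 20, 30), c(20, 19, 18, 17)),
               "volume")
  expect_error(fermentation_record("v", "S", "M", FALSE, 5, 1,
                                   c(0, 10, 20), c(20, 19, 18)),
               "at least 4")
})

test_that("smoothing reproduces polynomial-exact inputs", {
  t <- seq(0, 50, by = 5)
  y <- 0.8 * t                       # noise-free line
  sc <- smooth_co2(t, y)
  expect_lt(max(abs(sc$co2 - 0.8 * sc$grid_times)), 1e-6)
  yc <- rep(5, length(t))            # constant series
  scc <- smooth_co2(t, yc)
  expect_lt(max(abs(scc$co2 - 5)), 1e-9)
  expect_true(all(diff(sc$co2) >= 0))
  expect_gte(sc$co2[1], 0)
})

test_that("smoothing a coarsely sampled logistic stays close to the truth", {
  A <- 93.508; k <- 0.1; tm <- 40
  t <- seq(0, 100, by = 8)
  y <- A / (1 + exp(-k * (t - tm)))
  sc <- smooth_co2(t, y)
  truth <- A / (1 + exp(-k * (sc$grid_times - tm)))
  expect_lt(max(abs(sc$co2 - truth)), 0.5)
})

test_that("kinetic parameters match closed-form logistic inversions", {
  A <- 93.508; k <- 0.1; tm <- 40
  g <- seq(0, 100, by = 0.1)
  curve <- as_smoothed_curve(g, A / (1 + exp(-k * (g - tm))))
  p <- extract_kinetic_params(curve, tco2max = A)
  truth <- logistic_truth()
  tol <- 2 * 0.1
  expect_lt(abs(p$lp - truth$lp), tol)            # 1.77 h
  expect_lt(abs(p$t35 - truth$t35), tol)
  expect_lt(abs(p$t50 - truth$t50), tol)          # 38.23 h
  expect_lt(abs(p$t80 - truth$t80), tol)          # 52.10 h
  expect_lt(abs(p$v50_80 - truth$v50_80) / truth$v50_80, 0.01)  # 4.20
  expect_lte(p$co2max, A * 1.001)
  expect_equal(p$flags, character(0))
})

test_that("v50_80 equals 0.30 * sugar / (t80 - t50) algebraically", {
  g <- seq(0, 100, by = 0.1)
  curve <- as_smoothed_curve(g, 93.5 / (1 + exp(-0.1 * (g - 40))))
  p <- extract_kinetic_params(curve, tco2max = theoretical_co2_max(194))
  expect_equal(p$v50_80, 0.30 * 194 / (p$t80 - p$t50))
})

test_that("time-shifting a record shifts lp and leaves the rest unchanged", {
  t0 <- seq(0, 100, by = 2.5)
  w <- 20 - (93.508 / (1 + exp(-0.1 * (t0 - 40)))) * 0.005
  rec1 <- fermentation_record("a", "S", "M", FALSE, 5, 1, t0, w)
  rec2 <- fermentation_record("b", "S", "M", FALSE, 5, 1, t0 + 7, w)
  f1 <- fit_fermentation(rec1, tco2max = 93.508)
  f2 <- fit_fermentation(rec2, tco2max = 93.508)
  tol <- 0.35    # grid + interpolation tolerance
  expect_lt(abs((coef(f2)[["lp"]] - coef(f1)[["lp"]]) - 7), tol)
  for (p in c("t35", "t50", "t80"))
    expect_lt(abs(coef(f2)[[p]] - coef(f1)[[p]]), tol)
  expect_lt(abs(coef(f2)[["v50_80"]] - coef(f1)[["v50_80"]]), 0.05)
})

test_that("threshold-unreachable curves are flagged, not errors", {
  # plateaus at 60% of tCO2max: stuck fermentation
  A <- 0.6 * 93.508
  rec <- make_logistic_record(A = A, times = seq(0, 150, by = 3))
  fit <- fit_fermentation(rec, tco2max = 93.508)
  expect_true(is.na(coef(fit)[["t80"]]))
  expect_true("STUCK" %in% fit$params$flags)
  expect_false(is.na(coef(fit)[["t50"]]))
  # never releases 2 g/L: no lag phase either
  recf <- fermentation_record("v", "S", "M", FALSE, 5, 1,
                              seq(0, 40, by = 4),
                              20 - seq(0, 0.004, length.out = 11))
  fitf <- fit_fermentation(recf, tco2max = 93.508)
  expect_true(all(c("NO_LAG_REACHED", "STUCK") %in% fitf$params$flags))
  expect_true(is.na(coef(fitf)[["lp"]]))
})

test_that("ferm_fit methods are coherent", {
  set.seed(42)
  rec <- make_logistic_record(times = seq(0, 100, by = 3), noise_sd = 0.002)
  fit <- fit_fermentation(rec, tco2max = 93.508)
  expect_named(coef(fit), c("lp", "t35", "t50", "t80", "v50_80", "co2max"))
  expect_length(residuals(fit), length(rec$time_h))
  expect_lt(sd(residuals(fit)), 1)
  # predict interpolates the monotone curve
  pr <- predict(fit, newdata = c(0, 40, 1000))
  expect_true(all(diff(pr) >= 0))
  expect_equal(pr[3], fit$params$co2max)
  s <- summary(fit)
  expect_s3_class(s, "summary.ferm_fit")
  expect_lt(abs(s$completion - 1), 0.02)
})
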