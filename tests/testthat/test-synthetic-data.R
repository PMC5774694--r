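test_that("the delayed logistic and its inverse are mutually consistent", {
  p <- list(onset = 8, t_infl = 40, rate = 0.09, co2max = 90)
  lv <- c(2, 20, 45, 72)
  t <- delayed_logistic_inverse(lv, p)
  expect_equal(delayed_logistic(t, p), lv, tolerance = 1e-10)
  expect_equal(delayed_logistic(c(0, 4, 7.99), p), c(0, 0, 0))
  expect_true(is.na(delayed_logistic_inverse(90, p)))
})

test_that("simulated weighing records are seed-reproducible", {
  p <- list(onset = 5, t_infl = 45, rate = 0.08, co2max = 88)
  r1 <- simulate_curve(p, tco2max = 93.5, seed = 11)
  r2 <- simulate_curve(p, tco2max = 93.5, seed = 11)
  expect_identical(r1, r2)
  r3 <- simulate_curve(p, tco2max = 93.5, seed = 12)
  expect_false(identical(r1$weight_g, r3$weight_g))
})

test_that("impossible stoichiometry is rejected", {
  p <- list(onset = 5, t_infl = 45, rate = 0.08, co2max = 95)
  expect_error(simulate_curve(p, tco2max = 93.5), "exceeds")
})

test_that("noise-free dense weighing recovers the generative kinetics", {
  p <- list(onset = 6, t_infl = 42, rate = 0.1, co2max = 90)
  rec <- simulate_curve(p, tco2max = 93.508, weighing_frequency = 12,
                        balance_noise_sd = 0, seed = 3)
  # span scaled down to keep the smoothing window comparable to the one
  # the default span spans at routine 2-3/day weighing density
  fit <- fit_fermentation(rec, tco2max = 93.508, span = 0.2)
  truth <- true_kinetic_params(p, 93.508)
  expect_lt(abs(coef(fit)[["t50"]] - truth$t50), 2 * fit$curve$grid_step)
  expect_lte(coef(fit)[["co2max"]], 93.508)
})

test_that("weighing counts track the configured frequency", {
  p <- list(onset = 5, t_infl = 45, rate = 0.08, co2max = 88)
  for (freq in c(2, 3)) {
    rec <- simulate_curve(p, tco2max = 93.5, weighing_frequency = freq,
                          seed = 21)
    horizon <- max(rec$time_h)
    expected <- freq * horizon / 24
    expect_lt(abs(length(rec$time_h) - expected),
              3 * sqrt(expected) + 2)
  }
})

test_that("effect vectors are centered and dimension mismatches refused", {
  em <- effect_model(list(x = list(mean = 5, sigma = 1,
                                   strain = c(1, 2, 6))),
                     strains = c("a", "b", "c"), must_codes = c("m1", "m2"))
  expect_equal(sum(em$traits$x$strain), 0)
  expect_equal(em$traits$x$must, c(0, 0))
  expect_error(effect_model(list(x = list(mean = 0, sigma = 1,
                                          strain = c(1, 2))),
                            strains = c("a", "b", "c"),
                            must_codes = "m1"),
               "length")
})

test_that("the reference factorial yields 160 vials and is reproducible", {
  des <- simulation_design(seed = 9)
  ex1 <- simulate_experiment(des, curves = FALSE)
  expect_equal(nrow(ex1$traits), 160)     # 4 strains x 2 musts x 2 mox x 10
  ex2 <- simulate_experiment(des, curves = FALSE)
  expect_identical(ex1$traits, ex2$traits)
  expect_true(all(ex1$true_params$co2max <= ex1$true_params$tco2max))
})

test_that("a null effect model with zero noise gives identical vials", {
  strains <- c("a", "b"); musts <- c("SB14", "M15")
  traits <- list(glycerol = list(mean = 6, sigma = 0),
                 onset = list(mean = 5, sigma = 0),
                 t_infl = list(mean = 45, sigma = 0),
                 rate = list(mean = 0.09, sigma = 0),
                 co2max_deficit = list(mean = 1, sigma = 0))
  em <- effect_model(traits, strains, musts)
  des <- simulation_design(strains = strains, replicates = 3, seed = 2)
  ex <- simulate_experiment(des, em, curves = FALSE)
  expect_equal(var(ex$traits$glycerol), 0)
})

test_that("a pure must effect lands entirely in the Must term downstream", {
  strains <- paste0("s", 1:3); musts <- c("SB14", "M15")
  em <- effect_model(list(glycerol = list(mean = 6, sigma = 0,
                                          must = c(-1, 1))),
                     strains, musts)
  des <- simulation_design(strains = strains, replicates = 2, seed = 4)
  ex <- simulate_experiment(des, em, curves = FALSE)
  dec <- fit_lm1(ex$traits, response = "glycerol")
  expect_equal(dec$percent[dec$terms == "Must"], 100)
  expect_lt(sum(dec$percent[dec$terms != "Must"]), 1e-9)
})

test_that("mismatched factor labels between design and effects error", {
  em <- default_effect_model(strains = c("x", "y"))
  expect_error(simulate_experiment(simulation_design(), em),
               "factor labels")
})
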