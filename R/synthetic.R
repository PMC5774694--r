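#' Delayed-logistic CO2 trajectory
#'
#' The generative curve family of the experiment simulator: cumulative CO2
#' is 0 until fermentation onset, then rises along a logistic rescaled to
#' start at exactly 0 at onset and plateau at `co2max`:
#' \deqn{CO2(t) = co2max \frac{s(t - onset) - s(0)}{1 - s(0)}, \quad
#'       s(u) = \frac{1}{1 + e^{-rate (u - t_{infl})}}}
#' for `t >= onset`, 0 before. This is the simplest family reproducing the
#' lag + sigmoidal shape of observed vial fermentations; the analysis
#' pipeline itself never assumes it.
#'
#' @param t Times, hours.
#' @param params List with `onset` (h), `t_infl` (h after onset, the
#'   inflection point), `rate` (/h), `co2max` (g/L plateau).
#' @return Cumulative CO2 (g/L) at each `t`.
#' @seealso [delayed_logistic_inverse()] for the closed-form time at which a
#'   CO2 level is reached, [true_kinetic_params()] for oracle kinetic traits.
#' @export
delayed_logistic <- function(t, params) {
  with(params, {
    stopifnot(rate > 0, co2max > 0)
    s0 <- 1 / (1 + exp(rate * t_infl))
    u <- t - onset
    s <- 1 / (1 + exp(-rate * (u - t_infl)))
    ifelse(u < 0, 0, co2max * (s - s0) / (1 - s0))
  })
}

#' @param level CO2 level(s), g/L, strictly between 0 and `params$co2max`.
#' @return `delayed_logistic_inverse`: the time (h) at which the trajectory
#'   first reaches `level`; `NA` for unreachable levels.
#' @rdname delayed_logistic
#' @export
delayed_logistic_inverse <- function(level, params) {
  with(params, {
    s0 <- 1 / (1 + exp(rate * t_infl))
    sig <- level / co2max * (1 - s0) + s0
    out <- ifelse(level <= 0, onset,
                  onset + t_infl - log(1 / sig - 1) / rate)
    out[level >= co2max] <- NA_real_
    out
  })
}

#' Closed-form kinetic parameters of a delayed-logistic trajectory
#'
#' The analytic oracle for parameter-recovery tests: inverts the generative
#' curve exactly, using the same trait definitions as
#' [extract_kinetic_params()].
#'
#' @inheritParams delayed_logistic
#' @param tco2max Theoretical CO2 maximum of the must, g/L.
#' @param lag_threshold Lag-phase level, g/L. Default 2.
#' @return List with `lp`, `t35`, `t50`, `t80`, `v50_80`, `co2max`.
#' @export
true_kinetic_params <- function(params, tco2max, lag_threshold = 2) {
  lp <- delayed_logistic_inverse(lag_threshold, params)
  tx <- delayed_logistic_inverse(c(0.35, 0.5, 0.8) * tco2max, params) - lp
  v <- if (any(is.na(tx[2:3]))) NA_real_ else
    (0.30 * tco2max / 0.482) / (tx[3L] - tx[2L])
  list(lp = lp, t35 = tx[1L], t50 = tx[2L], t80 = tx[3L], v50_80 = v,
       co2max = params$co2max)
}

#' Simulate one vial's weighing record
#'
#' Draws manual weighing times at the configured mean frequency (gaps
#' jittered uniformly within +/-40\% of the mean gap) over a horizon long
#' enough for the trajectory to pass 95\% of its plateau, then converts the
#' true CO2 trajectory to vial weights and adds Gaussian balance noise.
#'
#' @inheritParams delayed_logistic
#' @inheritParams true_kinetic_params
#' @param design_cell List of design labels for the record: `vial_id`,
#'   `strain`, `must_code`, `shaking`, `replicate` (all optional, with
#'   placeholder defaults).
#' @param volume_ml Fermented volume, mL. Default 5.
#' @param initial_weight_g Vial weight at inoculation, g. Default 20.
#' @param weighing_frequency Mean weighings per day. Default 2.5.
#' @param balance_noise_sd Balance noise sd, grams. Default 0.002.
#' @param seed Integer seed; same seed, same record.
#' @return A [fermentation_record()].
#' @export
simulate_curve <- function(params, tco2max, design_cell = list(),
                           volume_ml = 5, initial_weight_g = 20,
                           weighing_frequency = 2.5,
                           balance_noise_sd = 0.002, seed = NULL) {
  stopifnot(params$rate > 0)
  if (params$co2max > tco2max)
    stop("co2max (", params$co2max, " g/L) exceeds the stoichiometric tCO2max (",
         tco2max, " g/L)")
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  t95 <- delayed_logistic_inverse(0.95 * params$co2max, params)
  horizon <- t95 + max(24, 0.15 * t95)
  gap <- 24 / weighing_frequency
  times <- 0
  while (times[length(times)] < horizon)
    times <- c(times, times[length(times)] + gap * stats::runif(1, 0.6, 1.4))
  co2 <- delayed_logistic(times, params)
  weights <- initial_weight_g - co2 * volume_ml / 1000 +
    stats::rnorm(length(times), 0, balance_noise_sd)
  cell <- utils::modifyList(list(vial_id = "sim", strain = "S1",
                                 must_code = "M1", shaking = FALSE,
                                 replicate = 1L), design_cell)
  fermentation_record(cell$vial_id, cell$strain, cell$must_code,
                      cell$shaking, volume_ml, cell$replicate,
                      times, weights)
}

#' Factorial simulation design
#'
#' Describes a complete strain x must x micro-oxygenation factorial with
#' replicate vials. The default is the reference G-by-E layout of the
#' package's validation studies: 4 strains x 2 musts x 2 oxygenation
#' levels x 10 replicates = 160 fermentations, weighed on average 2.5
#' times per day on a balance with 2 mg noise.
#'
#' @param strains Character vector of strain labels.
#' @param musts List of [must_composition()]s (default: SB14 and M15 from
#'   the packaged must panel).
#' @param shaking_levels Logical vector of micro-oxygenation levels.
#' @param replicates Replicates per cell (>= 1).
#' @param weighing_frequency Mean weighings/day. Default 2.5.
#' @param balance_noise_sd Balance noise sd, g. Default 0.002.
#' @param volume_ml Vial volume, mL. Default 5.
#' @param seed Master integer seed; per-vial seeds are derived from it
#'   deterministically so any subset of vials is reproducible.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(strains = c("M2", "GN", "F15", "SB"),
                              musts = NULL,
                              shaking_levels = c(FALSE, TRUE),
                              replicates = 10, weighing_frequency = 2.5,
                              balance_noise_sd = 0.002, volume_ml = 5,
                              seed = 1L) {
  if (is.null(musts)) {
    panel <- read_must_table(system.file("extdata", "grape_musts.csv",
                                         package = "fermphen"))
    musts <- panel[c("SB14", "M15")]
  }
  stopifnot(length(strains) >= 1, length(musts) >= 1, replicates >= 1,
            weighing_frequency > 0, balance_noise_sd >= 0, volume_ml > 0)
  if (is.null(names(musts)))
    names(musts) <- vapply(musts, `[[`, "", "code")
  structure(list(strains = strains, musts = musts,
                 shaking_levels = shaking_levels,
                 replicates = as.integer(replicates),
                 weighing_frequency = weighing_frequency,
                 balance_noise_sd = balance_noise_sd,
                 volume_ml = volume_ml, seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  n <- length(x$strains) * length(x$musts) * length(x$shaking_levels) *
    x$replicates
  cat(sprintf("Simulation design: %d strains x %d musts x %d oxygenation x %d reps = %d vials\n",
              length(x$strains), length(x$musts), length(x$shaking_levels),
              x$replicates, n))
  invisible(x)
}

# evenly spaced, centered effect vector (sums to zero exactly)
.spread <- function(n, scale) {
  if (n == 1L) return(0)
  v <- seq(-1, 1, length.out = n) * scale
  v - mean(v)
}

.center_vec <- function(v) v - mean(v)
.center_mat <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  sweep(m, 2, colMeans(m))
}

#' Additive trait effect model
#'
#' The generative statistical structure of the simulator: for every trait,
#' a vial's value is
#' `mean + strain_i + must_j + mox_k + strain_must_ij + strain_mox_ik + N(0, sigma)`
#' -- the same two-way-interaction linear model the variance-decomposition
#' stage ([fit_lm1()]) estimates. Effect vectors are centered (and
#' interaction matrices doubly centered) so the parameterization is
#' identifiable; inputs that are not centered are centered silently.
#'
#' @param traits Named list; each element a list with numeric `mean`,
#'   `sigma` (>= 0) and optional `strain`, `must`, `mox` (vectors over
#'   factor levels), `strain_must`, `strain_mox` (matrices strains x musts
#'   / strains x mox levels). Missing effects default to zero.
#' @param strains,must_codes,mox_levels Factor level labels the effect
#'   vectors refer to.
#' @return An object of class `effect_model`.
#' @seealso [default_effect_model()] for the package's reference settings.
#' @export
effect_model <- function(traits, strains, must_codes,
                         mox_levels = c(FALSE, TRUE)) {
  nS <- length(strains); nM <- length(must_codes); nO <- length(mox_levels)
  fix <- function(tr, nm) {
    stopifnot(is.numeric(tr$mean), is.numeric(tr$sigma), tr$sigma >= 0)
    get0v <- function(f, n) {
      v <- tr[[f]]
      if (is.null(v)) return(rep(0, n))
      if (length(v) != n)
        stop("trait '", nm, "': effect '", f, "' has length ", length(v),
             ", expected ", n)
      .center_vec(v)
    }
    get0m <- function(f, nr, nc) {
      m <- tr[[f]]
      if (is.null(m)) return(matrix(0, nr, nc))
      if (!all(dim(m) == c(nr, nc)))
        stop("trait '", nm, "': effect '", f, "' has wrong dimensions")
      .center_mat(m)
    }
    list(mean = tr$mean, sigma = tr$sigma,
         strain = get0v("strain", nS), must = get0v("must", nM),
         mox = get0v("mox", nO),
         strain_must = get0m("strain_must", nS, nM),
         strain_mox = get0m("strain_mox", nS, nO))
  }
  traits <- Map(fix, traits, names(traits))
  structure(list(traits = traits, strains = strains,
                 must_codes = must_codes, mox_levels = mox_levels),
            class = "effect_model")
}

#' Reference effect model for simulated experiments
#'
#' Plausible-by-default generative settings for a wine-fermentation
#' factorial: the kinetic-generative traits `onset` (lag onset, h),
#' `t_infl` (inflection time after onset, h), `rate` (logistic rate, /h)
#' and `co2max_deficit` (g/L of CO2 short of the must's `tCO2max`, keeping
#' every simulated fermentation essentially complete), plus an end-point
#' metabolite panel (`glycerol`, `acetic_acid`, `malic_acid`, `so2`,
#' `pyruvate`). Deterministic, evenly spaced strain/must effects of
#' realistic magnitude are used; micro-oxygenation shortens `t_infl`,
#' raises glycerol by about 15\% and lowers acetic acid, as observed in
#' shaken-vial fermentations. Interactions are present but small relative
#' to main effects.
#'
#' @inheritParams effect_model
#' @param interaction_scale Multiplier on the built-in interaction
#'   patterns; 0 switches interactions off.
#' @return An [effect_model()].
#' @export
default_effect_model <- function(strains = c("M2", "GN", "F15", "SB"),
                                 must_codes = c("SB14", "M15"),
                                 mox_levels = c(FALSE, TRUE),
                                 interaction_scale = 1) {
  nS <- length(strains); nM <- length(must_codes); nO <- length(mox_levels)
  inter <- function(scale) {
    m <- interaction_scale * scale *
      outer(.spread(nS, 1), .spread(nM, 1))
    m
  }
  interO <- function(scale)
    interaction_scale * scale * outer(.spread(nS, 1), .spread(nO, 1))
  mox_eff <- function(delta) {        # on-minus-off difference 'delta'
    v <- rep(0, nO)
    if (nO == 2L) v <- c(-delta / 2, delta / 2)
    v
  }
  traits <- list(
    onset = list(mean = 6, sigma = 0.8, strain = .spread(nS, 3),
                 must = .spread(nM, 1.5), mox = mox_eff(-1),
                 strain_must = inter(1.2), strain_mox = interO(0.6)),
    t_infl = list(mean = 48, sigma = 2, strain = .spread(nS, 6),
                  must = .spread(nM, 8), mox = mox_eff(-8),
                  strain_must = inter(1.5), strain_mox = interO(1)),
    rate = list(mean = 0.085, sigma = 0.003, strain = .spread(nS, 0.012),
                must = .spread(nM, 0.008), mox = mox_eff(0.012)),
    co2max_deficit = list(mean = 1.0, sigma = 0.3,
                          strain = .spread(nS, 0.2), must = .spread(nM, 0.1)),
    glycerol = list(mean = 6.5, sigma = 0.15, strain = .spread(nS, 0.6),
                    must = .spread(nM, 0.25), mox = mox_eff(1.0),
                    strain_mox = interO(0.1)),
    acetic_acid = list(mean = 0.35, sigma = 0.05, strain = .spread(nS, 0.05),
                       must = .spread(nM, 0.08), mox = mox_eff(-0.1),
                       strain_must = inter(0.02), strain_mox = interO(0.02)),
    malic_acid = list(mean = 1.6, sigma = 0.12, strain = .spread(nS, 0.25),
                      must = .spread(nM, 1.6), strain_must = inter(0.05)),
    so2 = list(mean = 20, sigma = 2.5, strain = .spread(nS, 2),
               must = .spread(nM, 4), mox = mox_eff(8)),
    pyruvate = list(mean = 150, sigma = 35, strain = .spread(nS, 25),
                    must = .spread(nM, 15), mox = mox_eff(15),
                    strain_must = inter(12))
  )
  effect_model(traits, strains, must_codes, mox_levels)
}

.kinetic_gen_traits <- c("onset", "t_infl", "rate", "co2max_deficit")

#' Simulate a complete factorial fermentation experiment
#'
#' Builds, for every vial of the design, generative kinetic parameters and
#' end-point metabolite values from the additive [effect_model()] (Gaussian
#' residuals), then optionally simulates the weighing log of each vial with
#' [simulate_curve()]. The returned true-parameter table carries the
#' closed-form kinetic traits of every vial so that recovery of the
#' curve-fitting stage can be measured exactly.
#'
#' @param design A [simulation_design()].
#' @param effects An [effect_model()]; default [default_effect_model()] on
#'   the design's factor levels.
#' @param curves Logical; simulate weighing logs (TRUE, default) or only
#'   the trait and true-parameter tables (fast path for statistical
#'   studies).
#' @return An object of class `ferm_experiment`: list with `records`
#'   (weighing log, `NULL` when `curves = FALSE`), `traits` (data frame:
#'   design columns + metabolite traits + extracted-from-truth kinetic
#'   traits), `true_params` (per-vial generative parameters and closed-form
#'   kinetic traits), `design`, `effects`.
#' @examples
#' des <- simulation_design(replicates = 2)
#' ex <- simulate_experiment(des, curves = FALSE)
#' head(ex$traits)
#' @export
simulate_experiment <- function(design, effects = NULL, curves = TRUE) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(effects))
    effects <- default_effect_model(design$strains, names(design$musts),
                                    design$shaking_levels)
  stopifnot(inherits(effects, "effect_model"))
  if (!identical(effects$strains, design$strains) ||
      !identical(effects$must_codes, names(design$musts)) ||
      !identical(effects$mox_levels, design$shaking_levels))
    stop("factor labels of 'effects' do not match 'design'")
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      shaking = design$shaking_levels,
                      must = names(design$musts),
                      strain = design$strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "must", "shaking", "replicate")]
  nV <- nrow(grid)
  si <- match(grid$strain, design$strains)
  mj <- match(grid$must, names(design$musts))
  ok <- match(grid$shaking, design$shaking_levels)

  set.seed(design$seed)
  vals <- sapply(effects$traits, function(tr)
    tr$mean + tr$strain[si] + tr$must[mj] + tr$mox[ok] +
      tr$strain_must[cbind(si, mj)] + tr$strain_mox[cbind(si, ok)] +
      stats::rnorm(nV, 0, tr$sigma))
  vals <- as.data.frame(vals)
  # kinetic-generative traits absent from the effect model fall back to
  # fixed reference values so curves can still be simulated
  gen_defaults <- c(onset = 5, t_infl = 45, rate = 0.085,
                    co2max_deficit = 1)
  for (nm in names(gen_defaults))
    if (is.null(vals[[nm]])) vals[[nm]] <- rep(gen_defaults[[nm]], nV)

  tco2 <- vapply(design$musts, function(m) theoretical_co2_max(m$sugar),
                 numeric(1))[mj]
  # clamp generative parameters to physically admissible ranges
  onset <- pmax(vals$onset, 0)
  t_infl <- pmax(vals$t_infl, 5)
  rate <- pmax(vals$rate, 0.02)
  co2max <- pmin(pmax(tco2 - pmax(vals$co2max_deficit, 0.2), 0.5 * tco2),
                 tco2)
  true_params <- data.frame(grid, onset = onset, t_infl = t_infl,
                            rate = rate, co2max = co2max, tco2max = tco2,
                            stringsAsFactors = FALSE)
  true_params$vial_id <- sprintf("V%03d", seq_len(nV))
  tk <- t(mapply(function(i) {
    p <- list(onset = onset[i], t_infl = t_infl[i], rate = rate[i],
              co2max = co2max[i])
    unlist(true_kinetic_params(p, tco2[i]))
  }, seq_len(nV)))
  true_params <- cbind(true_params, as.data.frame(tk))

  traits <- data.frame(vial_id = true_params$vial_id, grid,
                       vals[, setdiff(names(vals), .kinetic_gen_traits),
                            drop = FALSE],
                       stringsAsFactors = FALSE)

  records <- NULL
  if (curves) {
    records <- lapply(seq_len(nV), function(i) {
      p <- list(onset = onset[i], t_infl = t_infl[i], rate = rate[i],
                co2max = co2max[i])
      simulate_curve(p, tco2[i],
                     design_cell = list(vial_id = true_params$vial_id[i],
                                        strain = grid$strain[i],
                                        must_code = grid$must[i],
                                        shaking = grid$shaking[i],
                                        replicate = grid$replicate[i]),
                     volume_ml = design$volume_ml,
                     weighing_frequency = design$weighing_frequency,
                     balance_noise_sd = design$balance_noise_sd,
                     seed = (design$seed + 77003 * i) %% 2147483647)
    })
    names(records) <- true_params$vial_id
  }
  structure(list(records = records, traits = traits,
                 true_params = true_params, design = design,
                 effects = effects),
            class = "ferm_experiment")
}

#' @export
print.ferm_experiment <- function(x, ...) {
  print(x$design)
  cat(sprintf("  traits: %s\n",
              paste(setdiff(names(x$traits),
                            c("vial_id", "strain", "must", "shaking",
                              "replicate")), collapse = ", ")))
  cat(if (is.null(x$records)) "  no weighing logs simulated\n" else
    sprintf("  %d weighing logs\n", length(x$records)))
  invisible(x)
}
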