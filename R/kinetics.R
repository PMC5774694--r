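#' A single vial's fermentation weighing record
#'
#' One fermenting vial, tracked by manual weighing on a precision balance
#' 2--3 times a day: CO2 escaping through the needle makes the vial lose
#' weight, and that loss, scaled by the fermented volume, is the cumulative
#' CO2 released per litre of must.
#'
#' @param vial_id Unique vial label.
#' @param strain Yeast strain label.
#' @param must_code Must label (matches a [must_composition()] code).
#' @param shaking Logical; whether the vial is shaken (the micro-oxygenation
#'   proxy: orbital shaking transfers 2--4 mg/L/day of oxygen).
#' @param volume_ml Fermented volume in mL (> 0).
#' @param replicate Replicate index.
#' @param time_h Weighing times in hours since inoculation; strictly
#'   increasing, first value >= 0, at least 4 points.
#' @param weight_g Vial weight in grams at each time.
#' @return An object of class `fermentation_record`.
#' @export
fermentation_record <- function(vial_id, strain, must_code, shaking,
                                volume_ml, replicate, time_h, weight_g) {
  time_h <- as.numeric(time_h)
  weight_g <- as.numeric(weight_g)
  if (length(time_h) != length(weight_g))
    stop("time_h and weight_g differ in length for vial ", vial_id)
  if (length(time_h) < 4L)
    stop("vial ", vial_id, ": at least 4 weighings are required")
  if (any(!is.finite(time_h)) || any(!is.finite(weight_g)))
    stop("vial ", vial_id, ": non-finite time or weight")
  if (time_h[1L] < 0) stop("vial ", vial_id, ": times must start at >= 0")
  if (any(diff(time_h) <= 0))
    stop("vial ", vial_id, ": weighing times must be strictly increasing")
  volume_ml <- as.numeric(volume_ml)
  if (!is.finite(volume_ml) || volume_ml <= 0)
    stop("vial ", vial_id, ": volume must be positive (mL)")
  structure(list(vial_id = as.character(vial_id), strain = as.character(strain),
                 must_code = as.character(must_code), shaking = isTRUE(shaking),
                 volume_ml = volume_ml, replicate = as.integer(replicate),
                 time_h = time_h, weight_g = weight_g),
            class = "fermentation_record")
}

#' @export
print.fermentation_record <- function(x, ...) {
  cat(sprintf("Vial %s: strain %s in %s (%s, %.0f mL, rep %d), %d weighings over %.0f h\n",
              x$vial_id, x$strain, x$must_code,
              if (x$shaking) "shaken" else "static",
              x$volume_ml, x$replicate, length(x$time_h), max(x$time_h)))
  invisible(x)
}

#' Convert vial weights to cumulative CO2 release
#'
#' `co2(t_i) = (weight(t_0) - weight(t_i)) / volume_L`: grams of CO2 lost
#' per litre of must. The series is returned as observed -- balance noise
#' can make it locally decrease; monotonization happens on the smoothed
#' curve, not here.
#'
#' @param record A [fermentation_record()].
#' @return A data frame with columns `time_h` and `co2` (g/L); the first
#'   `co2` value is 0 by construction.
#' @examples
#' r <- fermentation_record("v1", "GN", "SB14", FALSE, 5, 1,
#'                          c(0, 24, 48, 72), c(20, 19.95, 19.8, 19.6))
#' weights_to_co2(r)
#' @export
weights_to_co2 <- function(record) {
  stopifnot(inherits(record, "fermentation_record"))
  data.frame(time_h = record$time_h,
             co2 = (record$weight_g[1L] - record$weight_g) /
                   (record$volume_ml / 1000))
}

#' Smooth a CO2-release series by local polynomial regression
#'
#' Fits a loess smoother (locally weighted quadratic regression, tricube
#' weights) to the observed cumulative CO2 series and evaluates it on a
#' regular time grid covering `[0, last observation]`. The evaluated curve
#' is clipped at zero and made non-decreasing by running maximum, because
#' kinetic thresholds are defined on cumulative release while balance drift
#' can make the raw fit dip locally.
#'
#' @param time_h Observation times, hours (strictly increasing, >= 4 points).
#' @param co2 Observed cumulative CO2, g/L.
#' @param span Loess span: the fraction of points in each local
#'   neighbourhood. Default 0.45.
#' @param grid_step Evaluation grid step, hours. Default 0.1.
#' @return An object of class `smoothed_curve`: list with `grid_times`,
#'   `co2` (monotone, clipped), `fitted` (raw loess fit at the observation
#'   times), `time_h`, `observed`, `span`, `grid_step`.
#' @export
smooth_co2 <- function(time_h, co2, span = 0.45, grid_step = 0.1) {
  time_h <- as.numeric(time_h); co2 <- as.numeric(co2)
  n <- length(time_h)
  if (n < 4L) stop("at least 4 points are required to smooth")
  if (length(co2) != n) stop("time_h and co2 differ in length")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(span) || span <= 0 || span > 1)
    stop("'span' must lie in (0, 1]")
  if (!is.finite(grid_step) || grid_step <= 0) stop("'grid_step' must be > 0")
  # a tricube-weighted local quadratic is numerically stable from 5 points up
  span_eff <- max(span, min(1, 5 / n))
  fit <- stats::loess(co2 ~ time_h, span = span_eff, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, max(time_h), by = grid_step)
  if (grid[length(grid)] < max(time_h)) grid <- c(grid, max(time_h))
  pred <- unname(stats::predict(fit, newdata = data.frame(time_h = grid)))
  # before the first weighing nothing is measured: extend flat rather than
  # extrapolate the polynomial backwards
  if (time_h[1L] > 0) {
    p0 <- unname(stats::predict(fit,
                                newdata = data.frame(time_h = time_h[1L])))
    pred[grid < time_h[1L]] <- p0
  }
  mono <- cummax(pmax(pred, 0))
  structure(list(grid_times = grid, co2 = mono,
                 fitted = unname(stats::predict(fit,
                                 newdata = data.frame(time_h = time_h))),
                 time_h = time_h, observed = co2,
                 span = span_eff, grid_step = grid_step),
            class = "smoothed_curve")
}

#' Wrap an already-modeled CO2 trajectory as a smoothed curve
#'
#' Builds a `smoothed_curve` directly from curve values on a regular grid,
#' skipping the loess stage -- for trajectories that are already noise-free
#' model output (simulator truth, externally fitted curves). Values are
#' clipped at zero and monotonized exactly as in [smooth_co2()].
#'
#' @param grid_times Regular time grid, hours, starting at 0.
#' @param co2 Curve values, g/L, same length.
#' @return A `smoothed_curve`.
#' @export
as_smoothed_curve <- function(grid_times, co2) {
  grid_times <- as.numeric(grid_times); co2 <- as.numeric(co2)
  stopifnot(length(grid_times) == length(co2), length(grid_times) >= 2L)
  if (any(diff(grid_times) <= 0)) stop("grid times must be increasing")
  mono <- cummax(pmax(co2, 0))
  structure(list(grid_times = grid_times, co2 = mono, fitted = mono,
                 time_h = grid_times, observed = co2, span = NA_real_,
                 grid_step = stats::median(diff(grid_times))),
            class = "smoothed_curve")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("Smoothed CO2 curve: %d grid points over [0, %.1f] h (step %.2g h, span %.2f)\n",
              length(x$grid_times), max(x$grid_times), x$grid_step, x$span))
  cat(sprintf("  final CO2 %.1f g/L\n", x$co2[length(x$co2)]))
  invisible(x)
}

# first time the monotone curve reaches `level`, linearly interpolated
# between bracketing grid points; NA if never reached
.crossing_time <- function(grid, co2, level) {
  idx <- which(co2 >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(grid[1L])
  t0 <- grid[i - 1L]; t1 <- grid[i]
  y0 <- co2[i - 1L]; y1 <- co2[i]
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Extract kinetic parameters from a smoothed CO2 curve
#'
#' Computes the six standard fermentation kinetic traits from a smoothed,
#' monotone CO2-release curve and the must's stoichiometric ceiling:
#' \describe{
#'   \item{lp}{lag phase (h): time to release the first 2 g/L of CO2.}
#'   \item{t35, t50, t80}{time (h) to release 35/50/80\% of `tco2max`,
#'     counted after subtracting `lp`.}
#'   \item{v50_80}{average hexose consumption rate (g/L/h) over the
#'     50--80\% interval, `(0.30 * tco2max / 0.482) / (t80 - t50)` -- the
#'     0.482 factor converts CO2 back to consumed sugar.}
#'   \item{co2max}{maximal CO2 released (g/L), read from the end of the
#'     monotonized smoothed curve.}
#' }
#' Threshold times are linearly interpolated between grid points. A curve
#' that never reaches a threshold yields `NA` for that trait plus a quality
#' flag: `"STUCK"` when 80\% of `tco2max` is not reached (the enological
#' stuck-fermentation situation), `"NO_LAG_REACHED"` when even 2 g/L is not.
#'
#' @param curve A `smoothed_curve` from [smooth_co2()].
#' @param tco2max Theoretical CO2 maximum of the must, g/L
#'   (see [theoretical_co2_max()]).
#' @param lag_threshold CO2 level defining the lag phase, g/L. Default 2.
#' @return An object of class `kinetic_params`: list with `lp`, `t35`,
#'   `t50`, `t80`, `v50_80`, `co2max`, `tco2max` and `flags` (character).
#' @export
extract_kinetic_params <- function(curve, tco2max, lag_threshold = 2) {
  stopifnot(inherits(curve, "smoothed_curve"))
  tco2max <- as.numeric(tco2max)
  if (!is.finite(tco2max) || tco2max <= 0) stop("'tco2max' must be > 0")
  g <- curve$grid_times; y <- curve$co2
  flags <- character(0)
  lp <- .crossing_time(g, y, lag_threshold)
  if (is.na(lp)) flags <- c(flags, "NO_LAG_REACHED")
  tx <- vapply(c(0.35, 0.50, 0.80), function(f)
    .crossing_time(g, y, f * tco2max), numeric(1))
  if (is.na(tx[3L])) flags <- c(flags, "STUCK")
  rel <- if (is.na(lp)) rep(NA_real_, 3L) else tx - lp
  v50_80 <- if (any(is.na(tx[2:3]))) NA_real_ else
    (0.30 * tco2max / 0.482) / (tx[3L] - tx[2L])
  structure(list(lp = lp, t35 = rel[1L], t50 = rel[2L], t80 = rel[3L],
                 v50_80 = v50_80, co2max = y[length(y)], tco2max = tco2max,
                 flags = flags),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, digits = 2, ...) {
  v <- unlist(x[c("lp", "t35", "t50", "t80", "v50_80", "co2max")])
  print(round(v, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a fermentation kinetic model to a vial's weighing record
#'
#' The main per-vial fitting function: converts the weighing record to a
#' cumulative CO2 series ([weights_to_co2()]), smooths it by local
#' polynomial regression ([smooth_co2()]) and extracts the six kinetic
#' parameters ([extract_kinetic_params()]). The must can be given either as
#' a [must_composition()] (its sugar sets `tco2max`) or as an explicit
#' `tco2max`.
#'
#' @param record A [fermentation_record()].
#' @param must Optional [must_composition()] supplying the sugar content.
#' @param tco2max Theoretical CO2 maximum, g/L; required when `must` is not
#'   given.
#' @param span,grid_step Smoothing controls, see [smooth_co2()].
#' @param lag_threshold Lag-phase CO2 level, g/L. Default 2.
#' @return An object of class `ferm_fit` with components `record`, `curve`
#'   (the `smoothed_curve`), `params` (the `kinetic_params`) and `call`.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`
#'   and `plot`.
#' @examples
#' set.seed(1)
#' rec <- simulate_curve(list(onset = 5, t_infl = 45, rate = 0.09,
#'                            co2max = 90), tco2max = 93.5, seed = 1)
#' fit <- fit_fermentation(rec, tco2max = 93.5)
#' coef(fit)
#' @export
fit_fermentation <- function(record, must = NULL, tco2max = NULL,
                             span = 0.45, grid_step = 0.1, lag_threshold = 2) {
  stopifnot(inherits(record, "fermentation_record"))
  if (is.null(tco2max)) {
    if (is.null(must)) stop("supply either 'must' or 'tco2max'")
    stopifnot(inherits(must, "must_composition"))
    tco2max <- theoretical_co2_max(must$sugar)
  }
  obs <- weights_to_co2(record)
  curve <- smooth_co2(obs$time_h, obs$co2, span = span, grid_step = grid_step)
  params <- extract_kinetic_params(curve, tco2max, lag_threshold = lag_threshold)
  structure(list(record = record, curve = curve, params = params,
                 call = match.call()),
            class = "ferm_fit")
}

#' @export
print.ferm_fit <- function(x, ...) {
  print(x$record)
  print(x$params)
  invisible(x)
}

#' @export
coef.ferm_fit <- function(object, ...) {
  unlist(object$params[c("lp", "t35", "t50", "t80", "v50_80", "co2max")])
}

#' @export
fitted.ferm_fit <- function(object, ...) object$curve$fitted

#' @export
residuals.ferm_fit <- function(object, ...)
  object$curve$observed - object$curve$fitted

#' @param newdata Optional numeric vector of times (h) at which to evaluate
#'   the smoothed CO2 curve; defaults to the observation times. Values
#'   outside the fitted range are held at the boundary values.
#' @rdname fit_fermentation
#' @export
predict.ferm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$curve$time_h
  stats::approx(object$curve$grid_times, object$curve$co2,
                xout = as.numeric(newdata), rule = 2)$y
}

#' @export
summary.ferm_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(params = object$params, record = object$record,
              sigma = stats::sd(res), n = length(res),
              completion = object$params$co2max / object$params$tco2max)
  class(out) <- "summary.ferm_fit"
  out
}

#' @export
print.summary.ferm_fit <- function(x, ...) {
  print(x$record)
  print(x$params)
  cat(sprintf("completion %.1f%% of tCO2max; residual sd %.3f g/L over %d weighings\n",
              100 * x$completion, x$sigma, x$n))
  invisible(x)
}

#' @param x,y A `ferm_fit` object (for `plot`).
#' @param ... Passed on to the underlying plot.
#' @rdname fit_fermentation
#' @export
plot.ferm_fit <- function(x, y, ...) {
  cv <- x$curve; p <- x$params
  graphics::plot(cv$time_h, cv$observed, xlab = "time (h)",
                 ylab = expression(CO[2] ~ "released (g/L)"),
                 main = sprintf("Vial %s (%s, %s)", x$record$vial_id,
                                x$record$strain, x$record$must_code), ...)
  graphics::lines(cv$grid_times, cv$co2, col = "steelblue", lwd = 2)
  graphics::abline(h = p$tco2max, lty = 3)
  for (f in c(0.35, 0.5, 0.8))
    graphics::abline(h = f * p$tco2max, lty = 3, col = "grey70")
  if (!is.na(p$lp)) graphics::abline(v = p$lp, lty = 2, col = "firebrick")
  invisible(x)
}

#' Fit kinetics for a batch of vials
#'
#' Applies [fit_fermentation()] to every record in a weighing log and
#' assembles the kinetic parameters into a tidy table, one row per vial.
#'
#' @param records List of [fermentation_record()]s
#'   (e.g. from [read_weighing_log()]).
#' @param musts Named list of [must_composition()]s keyed by must code, used
#'   to look up each vial's `tco2max`; alternatively supply a single
#'   `tco2max` applied to all vials.
#' @param tco2max Optional scalar override, g/L.
#' @inheritParams fit_fermentation
#' @return A data frame with design columns (`vial_id`, `strain`, `must`,
#'   `shaking`, `replicate`), the six kinetic parameters and a
#'   semicolon-separated `flags` column.
#' @export
fit_kinetics_batch <- function(records, musts = NULL, tco2max = NULL,
                               span = 0.45, grid_step = 0.1,
                               lag_threshold = 2) {
  rows <- lapply(records, function(r) {
    tc <- tco2max
    if (is.null(tc)) {
      if (is.null(musts) || is.null(musts[[r$must_code]]))
        stop("no must composition for code ", r$must_code)
      tc <- theoretical_co2_max(musts[[r$must_code]]$sugar)
    }
    fit <- fit_fermentation(r, tco2max = tc, span = span,
                            grid_step = grid_step,
                            lag_threshold = lag_threshold)
    p <- fit$params
    data.frame(vial_id = r$vial_id, strain = r$strain, must = r$must_code,
               shaking = r$shaking, replicate = r$replicate,
               lp = p$lp, t35 = p$t35, t50 = p$t50, t80 = p$t80,
               v50_80 = p$v50_80, co2max = p$co2max, tco2max = p$tco2max,
               flags = paste(p$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
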