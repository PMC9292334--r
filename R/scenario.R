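#' Analysis windows on the model calendar
#'
#' Model year `y` maps to calendar year `1800 + y`, so a 300-year run spans
#' 1801-2100. The analysis windows are PRESENT (calendar 1991-2000, model
#' years 191-200), FUTURE (2091-2100, years 291-300) and the preindustrial
#' reference PI_REF (1801-1900, years 1-100).
#'
#' @return Named list of `c(first_year, last_year)` model-year ranges.
#' @export
mn_windows <- function() {
  list(PRESENT = c(191, 200), FUTURE = c(291, 300), PI_REF = c(1, 100))
}

#' Climate scenario specification
#'
#' Describes a control/climate forcing pair: the control keeps temperature
#' and deep-exchange mixing constant; the climate variant ramps temperature
#' up by `delta_t` degC and reduces mixing by the fraction `delta_kappa`
#' (the stratification proxy) between `ramp_start_year` and the end of the
#' run. Defaults: 300 years total, ramp from year 50 (calendar 1851), linear
#' ramp, `delta_t` = 4 degC, `delta_kappa` = 0.4.
#'
#' @param years_total run length in model years.
#' @param delta_t warming reached at end of run, degC.
#' @param delta_kappa fractional mixing reduction at end of run, in `[0, 1)`.
#' @param ramp_start_year model year at which the ramps (and the branch from
#'   the control) begin.
#' @param ramp_shape `"linear"` or `"quadratic"`.
#' @param base_temp control surface temperature, degC.
#' @param temp_amp amplitude of a sinusoidal temperature cycle, degC
#'   (applies to both members of the pair).
#' @param temp_period period of the temperature cycle in days (default one
#'   model year, i.e. a seasonal cycle; shorter periods emulate weather-band
#'   variability).
#' @param seed integer seed recorded with the scenario (the model itself is
#'   deterministic; the seed feeds ensemble perturbations).
#' @return A list of class `mn_scenario`.
#' @export
scenario_spec <- function(years_total = 300, delta_t = 4, delta_kappa = 0.4,
                          ramp_start_year = 50, ramp_shape = "linear",
                          base_temp = 18, temp_amp = 0,
                          temp_period = MN_YEAR_DAYS, seed = 1L) {
  stopifnot(years_total >= 1, delta_kappa >= 0, delta_kappa < 1,
            ramp_start_year >= 1, ramp_start_year < years_total,
            ramp_shape %in% c("linear", "quadratic"))
  stopifnot(temp_period > 0)
  structure(list(years_total = years_total, delta_t = delta_t,
                 delta_kappa = delta_kappa,
                 ramp_start_year = ramp_start_year, ramp_shape = ramp_shape,
                 base_temp = base_temp, temp_amp = temp_amp,
                 temp_period = temp_period, seed = as.integer(seed)),
            class = "mn_scenario")
}

#' Build the control and climate forcings of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param params [ecosystem_params()] (supplies the base mixing rate).
#' @return List with elements `control` and `climate`, each a forcing list
#'   usable by [run_simulation()].
#' @export
build_forcing <- function(spec, params) {
  stopifnot(inherits(spec, "mn_scenario"))
  total <- spec$years_total * MN_YEAR_DAYS
  ramp0 <- spec$ramp_start_year * MN_YEAR_DAYS
  k0 <- params$kappa0
  control <- list(time = c(0, total), temp = rep(spec$base_temp, 2),
                  kappa = rep(k0, 2), temp_amp = spec$temp_amp,
                  temp_period = spec$temp_period)
  if (spec$ramp_shape == "linear") {
    tt <- c(0, ramp0, total)
    frac <- c(0, 0, 1)
  } else {
    ramp_years <- spec$ramp_start_year:spec$years_total
    tt <- c(0, ramp_years * MN_YEAR_DAYS)
    frac <- c(0, ((ramp_years - spec$ramp_start_year) /
                    (spec$years_total - spec$ramp_start_year))^2)
  }
  climate <- list(time = tt, temp = spec$base_temp + spec$delta_t * frac,
                  kappa = k0 * (1 - spec$delta_kappa * frac),
                  temp_amp = spec$temp_amp, temp_period = spec$temp_period)
  list(control = control, climate = climate)
}

# stitch two trajectory segments that share the branch save point
.stitch_traj <- function(seg1, seg2, keep_rows1 = NULL) {
  i1 <- if (is.null(keep_rows1)) seq_len(nrow(seg1$state) - 1L) else keep_rows1
  out <- seg1
  out$time <- c(seg1$time[i1], seg2$time)
  out$year <- out$time / MN_YEAR_DAYS
  out$state <- rbind(seg1$state[i1, , drop = FALSE], seg2$state)
  out$diag <- rbind(seg1$diag[i1, , drop = FALSE], seg2$diag)
  rownames(out$diag) <- NULL
  out$forcing <- seg2$forcing
  out$fq_fixed <- seg2$fq_fixed
  out
}

#' Run a control/climate scenario pair
#'
#' The control runs for the whole period under constant forcing; the climate
#' run branches from the control state at `ramp_start_year` and then follows
#' the ramped forcing. Both trajectories therefore share the identical
#' pre-ramp history (same integrator path).
#'
#' @param params [ecosystem_params()].
#' @param spec a [scenario_spec()].
#' @param dt RK4 step, days.
#' @param save_every save interval, days (must divide the ramp start).
#' @param init optional initial state.
#' @return List of class `mn_scenario_pair` with `control` and `climate`
#'   trajectories, the branch state/time, and the run settings.
#' @export
run_pair <- function(params, spec, dt = 0.25, save_every = 30, init = NULL) {
  f <- build_forcing(spec, params)
  total <- spec$years_total * MN_YEAR_DAYS
  ramp0 <- spec$ramp_start_year * MN_YEAR_DAYS
  seg1 <- run_simulation(params, f$control, t_end = ramp0, dt = dt,
                         save_every = save_every, init = init)
  branch <- seg1$state[nrow(seg1$state), ]
  seg2c <- run_simulation(params, f$control, t_end = total, dt = dt,
                          save_every = save_every, init = branch, t0 = ramp0)
  seg2k <- run_simulation(params, f$climate, t_end = total, dt = dt,
                          save_every = save_every, init = branch, t0 = ramp0)
  structure(list(control = .stitch_traj(seg1, seg2c),
                 climate = .stitch_traj(seg1, seg2k),
                 branch_state = branch, branch_time = ramp0, spec = spec,
                 params = params, dt = dt, save_every = save_every,
                 forcing = f),
            class = "mn_scenario_pair")
}

#' Time-mean diagnostics over an analysis window
#'
#' Arithmetic mean of every flux diagnostic over the save points falling in
#' the window (save times `t` with `(y0 - 1) * 360 < t <= y1 * 360`).
#'
#' @param traj an `mn_trajectory`.
#' @param window a window label (`"PRESENT"`, `"FUTURE"`, `"PI_REF"`) or a
#'   numeric `c(first_year, last_year)` in model years.
#' @return List of class `mn_window_average` with `window`, `years` and the
#'   named vector `means`.
#' @export
window_mean <- function(traj, window = "PRESENT") {
  if (is.character(window)) {
    label <- window
    window <- mn_windows()[[window]]
    if (is.null(window)) stop("unknown window label: ", label, call. = FALSE)
  } else {
    label <- paste(window, collapse = "-")
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  lo <- (window[1] - 1) * MN_YEAR_DAYS
  hi <- window[2] * MN_YEAR_DAYS
  if (min(traj$time) > lo + traj$save_every + 1e-9 || max(traj$time) < hi - 1e-9) {
    stop("window [", window[1], ", ", window[2],
         "] model years is not covered by the trajectory", call. = FALSE)
  }
  sel <- traj$time > lo + 1e-9 & traj$time <= hi + 1e-9
  means <- colMeans(traj$diag[sel, , drop = FALSE], na.rm = TRUE)
  structure(list(window = label, years = window, n = sum(sel),
                 means = means),
            class = "mn_window_average")
}

#' @export
print.mn_window_average <- function(x, ...) {
  cat("<window ", x$window, "> model years ", x$years[1], "-", x$years[2],
      " (", x$n, " save points)\n", sep = "")
  print(utils::head(x$means, 10))
  invisible(x)
}

#' Fixed-food-quality counterfactual run
#'
#' Repeats the climate run of a scenario pair with the per-element food
#' quality inside the assimilation-efficiency term frozen to its
#' preindustrial climatology (the PI_REF 1801-1900 time-mean of the control
#' run). All other couplings - biomass, prey quantity, temperature - evolve
#' freely, which isolates the food-quality feedback on recycling.
#'
#' @param pair an `mn_scenario_pair` from [run_pair()].
#' @return An `mn_trajectory` matching the climate run's time base, with the
#'   frozen food-quality vector attached as `fq_fixed`.
#' @export
fixed_fq_counterfactual <- function(pair) {
  stopifnot(inherits(pair, "mn_scenario_pair"))
  pi_ref <- window_mean(pair$control, "PI_REF")
  fq_ref <- pi_ref$means[paste0("fq.", MN_ELEMENTS)]
  if (any(!is.finite(fq_ref))) {
    stop("control run has undefined food quality over PI_REF; ",
         "cannot build the frozen climatology", call. = FALSE)
  }
  names(fq_ref) <- MN_ELEMENTS
  total <- pair$spec$years_total * MN_YEAR_DAYS
  seg2 <- run_simulation(pair$params, pair$forcing$climate, t_end = total,
                         dt = pair$dt, save_every = pair$save_every,
                         init = pair$branch_state, t0 = pair$branch_time,
                         fq_fixed = fq_ref)
  pre <- which(pair$control$time < pair$branch_time - 1e-9)
  out <- .stitch_traj(pair$control, seg2, keep_rows1 = pre)
  out$fq_fixed <- fq_ref
  out
}

#' Normalize a series against a reference mean
#'
#' Dimensionless trend series `x(t) / reference`, the form used to compare
#' control, climate and counterfactual runs against the preindustrial
#' (1801-1900) control average. Normalizing the control's own reference
#' window returns a series with mean 1.
#'
#' @param x numeric series (or matrix/data.frame of series).
#' @param reference reference mean(s), strictly positive; recycled across
#'   columns when `x` has several.
#' @return `x / reference`, same shape as `x`.
#' @export
normalized_trend <- function(x, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference mean must be finite and > 0", call. = FALSE)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    stopifnot(length(reference) %in% c(1L, ncol(x)))
    return(sweep(x, 2, reference, "/"))
  }
  x / reference
}

#' Annual means of trajectory diagnostics
#'
#' @param traj an `mn_trajectory`.
#' @param variables diagnostic columns to average (default all).
#' @return data.frame with `year` (integer model year) and one column per
#'   variable.
#' @export
annual_means <- function(traj, variables = names(traj$diag)) {
  yr <- ceiling((traj$time - 1e-9) / MN_YEAR_DAYS)
  keep <- yr >= 1
  agg <- stats::aggregate(traj$diag[keep, variables, drop = FALSE],
                          by = list(year = yr[keep]), FUN = mean,
                          na.rm = TRUE)
  agg
}
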