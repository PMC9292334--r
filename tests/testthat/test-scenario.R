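test_that("forcing ramps follow the scenario specification", {
  p <- ecosystem_params()
  # null scenario: climate forcing identical to the control
  f0 <- build_forcing(scenario_spec(delta_t = 0, delta_kappa = 0), p)
  tt <- seq(0, 300 * MN_YEAR_DAYS, by = 360)
  expect_equal(stats::approx(f0$climate$time, f0$climate$temp, tt)$y,
               stats::approx(f0$control$time, f0$control$temp, tt)$y)
  expect_equal(stats::approx(f0$climate$time, f0$climate$kappa, tt)$y,
               stats::approx(f0$control$time, f0$control$kappa, tt)$y)

  sp <- scenario_spec(delta_t = 4, delta_kappa = 0.4)
  f <- build_forcing(sp, p)
  mid <- (sp$ramp_start_year + sp$years_total) / 2 * MN_YEAR_DAYS
  expect_equal(stats::approx(f$climate$time, f$climate$temp, mid)$y,
               sp$base_temp + 2)
  expect_equal(f$climate$kappa[length(f$climate$kappa)],
               p$kappa0 * (1 - 0.4))
  # control stays flat
  expect_equal(unique(f$control$temp), sp$base_temp)

  # quadratic ramp reaches a quarter of the change at mid-ramp
  fq <- build_forcing(scenario_spec(delta_t = 4, ramp_shape = "quadratic"), p)
  expect_equal(stats::approx(fq$climate$time, fq$climate$temp, mid)$y,
               18 + 4 * 0.25, tolerance = 1e-6)
})

test_that("analysis windows map model years onto the 1801-2100 calendar", {
  w <- mn_windows()
  expect_equal(w$PRESENT, c(191, 200))  # calendar 1991-2000
  expect_equal(w$FUTURE, c(291, 300))   # calendar 2091-2100
  expect_equal(w$PI_REF, c(1, 100))     # calendar 1801-1900

  time <- seq(30, 300 * MN_YEAR_DAYS, by = 30)
  const <- fake_trajectory(time, data.frame(npp = rep(2.5, length(time))))
  expect_equal(window_mean(const, "PRESENT")$means[["npp"]], 2.5)

  lin <- fake_trajectory(time, data.frame(npp = time))
  wm <- window_mean(lin, c(191, 200))
  expect_equal(wm$means[["npp"]], (190 * 360 + 30 + 200 * 360) / 2)
  expect_equal(wm$n, 120L)  # ten years of monthly saves

  short <- fake_trajectory(time[time <= 50 * 360],
                           data.frame(npp = time[time <= 50 * 360]))
  expect_error(window_mean(short, "PRESENT"), "not covered")
  expect_error(window_mean(const, "NOPE"), "unknown window")
})

test_that("climate runs branch bitwise from the control at the ramp start", {
  p <- ecosystem_params()
  sp <- scenario_spec(years_total = 6, ramp_start_year = 3, delta_t = 3,
                      delta_kappa = 0.3)
  pair <- run_pair(p, sp, dt = 0.5)
  pre <- pair$control$time <= pair$branch_time
  expect_identical(pair$control$state[pre, ], pair$climate$state[pre, ])
  # and they diverge afterwards
  post <- which(!pre)
  expect_false(identical(pair$control$state[post, ],
                         pair$climate$state[post, ]))

  null <- run_pair(p, scenario_spec(years_total = 6, ramp_start_year = 3,
                                    delta_t = 0, delta_kappa = 0), dt = 0.5)
  expect_equal(null$control$state, null$climate$state, tolerance = 0)
})

test_that("ramp effects show up in the window means with the scheduled sign", {
  p <- ecosystem_params()
  warm <- run_pair(p, scenario_spec(years_total = 20, ramp_start_year = 5,
                                    delta_t = 2, delta_kappa = 0), dt = 0.5)
  early <- window_mean(warm$climate, c(8, 10))$means
  late <- window_mean(warm$climate, c(18, 20))$means
  # scheduled warming between the two windows under the linear ramp
  frac <- function(y) (y - 5) / (20 - 5)
  sched <- 2 * (mean(frac(c(17, 20))) - mean(frac(c(7, 10))))
  expect_equal(late[["sst"]] - early[["sst"]], sched, tolerance = 0.02)

  strat <- run_pair(p, scenario_spec(years_total = 20, ramp_start_year = 5,
                                     delta_t = 0, delta_kappa = 0.5),
                    dt = 0.5)
  expect_lt(window_mean(strat$climate, c(18, 20))$means[["npp"]],
            window_mean(strat$climate, c(8, 10))$means[["npp"]])
})

test_that("the counterfactual differs only through the AE(FQ) argument", {
  # with AE independent of food quality the frozen run must be identical
  p <- ecosystem_params(elements = element_params(
    list(Fe = list(ae_shape = 0), Zn = list(ae_shape = 0),
         Cu = list(ae_shape = 0), Co = list(ae_shape = 0),
         Mn = list(ae_shape = 0))))
  sp <- scenario_spec(years_total = 110, ramp_start_year = 102, delta_t = 3,
                      delta_kappa = 0.3)
  pair <- run_pair(p, sp, dt = 0.5)
  cf <- fixed_fq_counterfactual(pair)
  expect_equal(cf$state, pair$climate$state, tolerance = 0)
  expect_equal(cf$time, pair$climate$time)
})

test_that("a null scenario's counterfactual reproduces the control", {
  p <- ecosystem_params()
  spin <- run_simulation(p, t_end = 30 * MN_YEAR_DAYS, dt = 0.5)
  eq <- spin$state[nrow(spin$state), ]
  eq[26:37] <- 0  # reset boundary-flux accumulators
  sp <- scenario_spec(years_total = 110, ramp_start_year = 102,
                      delta_t = 0, delta_kappa = 0)
  pair <- run_pair(p, sp, dt = 0.5, init = eq)
  cf <- fixed_fq_counterfactual(pair)
  expect_equal(cf$state[, 1:25], pair$control$state[, 1:25],
               tolerance = 1e-5)
})

test_that("normalized trends are reference-relative and idempotent", {
  expect_equal(normalized_trend(c(2, 2, 2), 2), c(1, 1, 1))
  expect_equal(normalized_trend(c(4, 6), 2), c(2, 3))
  expect_equal(normalized_trend(normalized_trend(c(4, 6), 2), 1), c(2, 3))
  expect_error(normalized_trend(1:3, 0), "reference")
  m <- cbind(a = c(2, 4), b = c(10, 30))
  expect_equal(normalized_trend(m, c(2, 10)), cbind(a = c(1, 2), b = c(1, 3)))

  # self-normalization: the control's own reference window averages to 1
  p <- ecosystem_params()
  traj <- run_simulation(p, t_end = 100 * MN_YEAR_DAYS, dt = 0.5)
  ref <- window_mean(traj, "PI_REF")$means[["recycle_c"]]
  sel <- traj$time > 0 & traj$time <= 100 * MN_YEAR_DAYS
  expect_equal(mean(normalized_trend(traj$diag$recycle_c[sel], ref)), 1,
               tolerance = 1e-12)
})
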