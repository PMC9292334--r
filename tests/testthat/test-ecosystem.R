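test_that("temperature factor follows the Q10 law around 20 degC", {
  expect_equal(temperature_factor(20, 2), 1)
  expect_equal(temperature_factor(30, 2), 2)
  expect_equal(temperature_factor(10, 1.88), 1 / 1.88)
})

test_that("growth rate combines macronutrient and Droop Fe limitation", {
  p <- ecosystem_params()
  y <- initial_state(p)
  tf <- temperature_factor(18, p$q10)

  # nutrient-replete, quota at maximum: growth at the temperature-scaled max
  y["n"] <- 100 * p$k_n[["nano"]]
  y["pm.nano.Fe"] <- y[["pc.nano"]] * p$elements["Fe", "q_max_nano"]
  mu <- growth_rate(y, p, 18, "nano")
  expect_equal(mu, p$mu_max[["nano"]] * tf * (100 / 101), tolerance = 1e-12)

  # Droop floor: growth stops at the minimum Fe quota
  y["pm.nano.Fe"] <- y[["pc.nano"]] * p$fe_q_min
  expect_equal(growth_rate(y, p, 18, "nano"), 0)

  # macronutrient half-saturation
  y["pm.nano.Fe"] <- y[["pc.nano"]] * p$elements["Fe", "q_max_nano"]
  y["n"] <- p$k_n[["nano"]]
  expect_equal(growth_rate(y, p, 18, "nano"),
               0.5 * p$mu_max[["nano"]] * tf)
})

test_that("metal uptake saturates in substrate and shuts off at the quota cap", {
  p <- ecosystem_params()
  y <- initial_state(p)
  # quota at the cap
  y["pm.nano.Fe"] <- y[["pc.nano"]] * p$elements["Fe", "q_max_nano"]
  expect_equal(metal_uptake(y, p, "nano", "Fe"), 0)
  # no substrate
  y["pm.nano.Fe"] <- 0
  y["d.Fe"] <- 0
  expect_equal(metal_uptake(y, p, "nano", "Fe"), 0)
  # half substrate saturation at half quota: v_max / 4
  y["d.Fe"] <- p$elements["Fe", "k_uptake"]
  y["pm.nano.Fe"] <- y[["pc.nano"]] * p$elements["Fe", "q_max_nano"] / 2
  expect_equal(metal_uptake(y, p, "nano", "Fe"),
               p$v_max["nano", "Fe"] / 4)
})

test_that("grazing follows the shared-saturation multi-prey response", {
  p <- ecosystem_params()
  y <- initial_state(p)
  tf <- temperature_factor(18, p$q10)

  y[c("pc.nano", "pc.diatom", "poc")] <- 0
  expect_equal(unname(grazing_fluxes(y, p, 18)), c(0, 0, 0))

  # single prey far above half-saturation: total rate saturates
  y <- initial_state(p)
  y["pc.nano"] <- 1000 * p$k_g
  y[c("pc.diatom", "poc")] <- 0
  g <- grazing_fluxes(y, p, 18)
  expect_equal(g[["nano"]], p$g_max * tf * y[["zc"]], tolerance = 1e-2)
  expect_equal(g[["diatom"]], 0)

  # zero preference excludes a prey even when abundant
  p0 <- ecosystem_params(preference = c(nano = 1, diatom = 0, particle = 0))
  y <- initial_state(p0)
  y["pc.diatom"] <- y[["pc.nano"]]
  g <- grazing_fluxes(y, p0, 18)
  expect_gt(g[["nano"]], 0)
  expect_equal(g[["diatom"]], 0)
})

test_that("zooplankton budget partitions metal among growth, excretion, egestion", {
  # balanced diet with surplus capacity: assimilation meets demand exactly
  p <- ecosystem_params()
  q_fe <- p$elements["Fe", "q_zoo"]
  quotas <- matrix(0, 3, 5, dimnames = list(c("nano", "diatom", "particle"),
                                            MN_ELEMENTS))
  quotas["nano", "Fe"] <- q_fe  # FQ = 1
  gr <- c(nano = 1e-3, diatom = 0, particle = 0)
  zb <- zoo_budget(gr, quotas, p)
  demand <- p$ae_c * 1e-3 * q_fe
  expect_equal(zb$assimilated[["Fe"]], demand)
  expect_equal(zb$draw_dissolved[["Fe"]], 0)
  expect_equal(zb$fq[["Fe"]], 1)

  # metal-free diet: nothing assimilated, nothing recycled
  quotas["nano", "Fe"] <- 0
  zb <- zoo_budget(gr, quotas, p)
  expect_equal(zb$assimilated[["Fe"]], 0)
  expect_equal(zb$recycle_m[["Fe"]], 0)

  # hand-evaluated min() budget: AE = 0.9 * (10/30) = 0.3 on a 30e-6 diet
  pe <- ecosystem_params(
    ae_c = 0.6,
    elements = element_params(list(Fe = list(ae_max = 0.9, ae_shape = 1))))
  quotas["nano", "Fe"] <- 30e-6
  zb <- zoo_budget(gr, quotas, pe)
  expect_equal(zb$ingested_m[["Fe"]], 3e-8)
  expect_equal(zb$assimilated[["Fe"]], 6e-9)  # demand-capped below 9e-9
  unassim <- 3e-8 - 6e-9
  expect_equal(zb$recycle_m[["Fe"]] + zb$egest_m[["Fe"]], unassim)
  expect_equal(zb$recycle_m[["Fe"]], pe$sigma_diss * unassim)
  # metal ingestion fully partitioned
  expect_equal(zb$assimilated[["Fe"]] + zb$recycle_m[["Fe"]] +
                 zb$egest_m[["Fe"]], zb$ingested_m[["Fe"]])

  # zero ingestion: all-zero budget
  zb0 <- zoo_budget(c(nano = 0, diatom = 0, particle = 0), quotas, p)
  expect_equal(zb0$growth_c, 0)
  expect_equal(unname(zb0$recycle_m), rep(0, 5))
})

test_that("R operator assembly matches the compiled right-hand side", {
  p <- ecosystem_params()
  traj <- run_simulation(p, t_end = 2 * MN_YEAR_DAYS, dt = 0.5)
  y <- traj$state[nrow(traj$state), ]
  for (fqf in list(NULL, c(Fe = 0.8, Zn = 1.1, Cu = 0.5, Co = 2, Mn = 0.9))) {
    d_r <- ecosystem_derivatives(y, p, temp = 18, kappa = p$kappa0,
                                 fq_fixed = fqf)
    d_c <- mnrecycle:::deriv_core(unname(y), mnrecycle:::.sim_pars(p), 18,
                                  p$kappa0,
                                  if (is.null(fqf)) NULL else unname(fqf))$dy
    # absolute comparison at the scale of the dominant derivatives (moribund
    # pools carry denormal-scale values where relative error is meaningless)
    expect_lt(max(abs(unname(d_r) - d_c)), 1e-12 * max(abs(d_c)))
  }
})

test_that("an empty closed box is a fixed point of the integrator", {
  p <- closed_box_params()
  y0 <- stats::setNames(numeric(37), state_names())
  out <- step_model(y0, p, closed_box_forcing(10), dt = 0.25, n_steps = 4)
  expect_equal(unname(out$state), numeric(37))
})

test_that("pure sinking decays particulate carbon exponentially", {
  p <- closed_box_params(lambda_rem = 0, m_p = 0, lambda_sink = 0.1)
  y0 <- stats::setNames(numeric(37), state_names())
  y0["poc"] <- 1e-3
  dt <- 0.25
  out <- step_model(y0, p, closed_box_forcing(10), dt = dt, n_steps = 1)
  expect_equal(out$state[["poc"]], 1e-3 * exp(-0.1 * dt), tolerance = 1e-9)
})

test_that("closed-box runs conserve every element and carbon", {
  p <- closed_box_params()
  traj <- run_simulation(p, closed_box_forcing(2 * MN_YEAR_DAYS),
                         t_end = 2 * MN_YEAR_DAYS)
  expect_lt(max(budget_check(traj)), 1e-10)
  # inventories genuinely constant, not just consistent with zero boundary
  inv <- inventories(traj)
  rel_drift <- apply(inv, 2, function(x) diff(range(x)) / max(x))
  expect_lt(max(rel_drift), 1e-10)
})

test_that("open runs close the source/mixing/export budget", {
  traj <- run_simulation(ecosystem_params(), t_end = 10 * MN_YEAR_DAYS)
  expect_lt(max(budget_check(traj)), 1e-8)
})

test_that("phytoplankton quotas never exceed their caps", {
  p <- ecosystem_params()
  traj <- run_simulation(p, t_end = 5 * MN_YEAR_DAYS)
  el <- p$elements
  for (g in MN_GROUPS) {
    pc <- traj$state[, paste0("pc.", g)]
    live <- pc > 1e-12
    for (e in MN_ELEMENTS) {
      q <- traj$state[live, paste0("pm.", g, ".", e)] / pc[live]
      expect_lt(max(q / el[e, paste0("q_max_", g)]), 1 + 1e-9)
    }
  }
})

test_that("instantaneous recycling scales linearly with zooplankton biomass", {
  p <- ecosystem_params()
  traj <- run_simulation(p, t_end = 2 * MN_YEAR_DAYS)
  y <- traj$state[nrow(traj$state), ]
  dn <- mnrecycle:::.diag_names()
  base <- mnrecycle:::deriv_core(unname(y), mnrecycle:::.sim_pars(p), 18,
                                 p$kappa0, NULL)$diag
  y2 <- y; y2["zc"] <- 3 * y[["zc"]]
  scaled <- mnrecycle:::deriv_core(unname(y2), mnrecycle:::.sim_pars(p), 18,
                                   p$kappa0, NULL)$diag
  names(base) <- names(scaled) <- dn
  for (e in MN_ELEMENTS) {
    expect_equal(scaled[[paste0("recycle_m.", e)]],
                 3 * base[[paste0("recycle_m.", e)]], tolerance = 1e-12)
  }
  expect_equal(scaled[["recycle_c"]], 3 * base[["recycle_c"]],
               tolerance = 1e-12)
})

test_that("steady state under constant forcing is independent of the start", {
  p <- ecosystem_params()
  t_end <- 30 * MN_YEAR_DAYS
  a <- run_simulation(p, t_end = t_end, init = initial_state(p, scale = 0.5))
  b <- run_simulation(p, t_end = t_end, init = initial_state(p, scale = 2))
  ya <- a$state[nrow(a$state), 1:25]
  yb <- b$state[nrow(b$state), 1:25]
  keep <- pmax(abs(ya), abs(yb)) > 1e-15
  expect_lt(max(abs(ya[keep] - yb[keep]) / pmax(abs(ya[keep]), abs(yb[keep]))),
            1e-6)
})

test_that("trajectories are deterministic and integration failures are named", {
  p <- ecosystem_params()
  t1 <- run_simulation(p, t_end = MN_YEAR_DAYS)
  t2 <- run_simulation(p, t_end = MN_YEAR_DAYS)
  expect_identical(t1$state, t2$state)

  bad <- initial_state(p)
  bad["zc"] <- -1e-3
  expect_error(run_simulation(p, t_end = 30, init = bad), "zc")
})
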