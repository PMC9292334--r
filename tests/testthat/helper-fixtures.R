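# shared fixtures: all built in code, nothing stored on disk

# a closed box: no external sources, no sinking export, no deep exchange
closed_box_params <- function(...) {
  args <- utils::modifyList(
    list(source_d = c(Fe = 0, Zn = 0, Cu = 0, Co = 0, Mn = 0),
         source_n = 0, lambda_sink = 0, kappa0 = 0),
    list(...))
  do.call(ecosystem_params, args)
}

closed_box_forcing <- function(t_end, temp = 18) {
  forcing_constant(temp = temp, kappa = 0, t_end = t_end)
}

# random symmetric positive definite 4x4 covariance
random_spd4 <- function() {
  a <- matrix(stats::rnorm(16), 4)
  crossprod(a) + diag(4) * 0.5
}

# small random driver panel with correlated predictors
random_panel <- function(seed, n = 60) {
  set.seed(seed)
  sigma <- random_spd4()
  beta <- stats::rnorm(4)
  x <- matrix(stats::rnorm(n * 4), n) %*% chol(sigma)
  colnames(x) <- MN_PREDICTORS
  data.frame(response = as.numeric(x %*% beta) + stats::rnorm(n),
             x, stringsAsFactors = FALSE)
}

# minimal trajectory object with a prescribed diagnostic series
fake_trajectory <- function(time, diag_df, save_every = 30) {
  structure(list(time = time, year = time / MN_YEAR_DAYS,
                 state = matrix(0, length(time), 37,
                                dimnames = list(NULL, state_names())),
                 diag = diag_df, save_every = save_every, dt = 0.25),
            class = "mn_trajectory")
}

# engineered metal-poor-Fe-diet setup for the counterfactual experiment:
# preindustrial food quality starts above 1, already inside the regime where
# the AE limit (not the fixed-quota demand cap) bounds assimilation, and the
# climate ramp pushes it monotonically further away from 1
fq_drift_params <- function() {
  ecosystem_params(elements = element_params(list(Fe = list(q_zoo = 50e-6))))
}

# quota-regulated uptake slowed so that no quota reaches its cap: the
# right-hand side stays smooth (no clamp kinks), which a convergence-order
# measurement requires
smooth_params <- function() {
  el <- element_params()
  qm <- rbind(nano = el$q_max_nano, diatom = el$q_max_diatom)
  colnames(qm) <- MN_ELEMENTS
  ecosystem_params(v_max = qm * 0.3)
}
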