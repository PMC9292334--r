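# Default run configuration for mnrecycle.
# Every entry shown here equals the package default; omitted entries are
# filled in by load_config(). Quotas are absolute mol metal per mol C,
# concentrations mol m^-3, rates per day.
seed: 1
output_dir: mnrecycle-out
integrator:
  dt: 0.25
  save_every: 30
elements:
  Fe: {q_max_nano: 80.0e-6, q_max_diatom: 80.0e-6, q_zoo: 10.0e-6, k_uptake: 0.5e-6, ae_max: 0.8, ae_shape: 2}
  Zn: {q_max_nano: 40.0e-6, q_max_diatom: 123.0e-6, q_zoo: 10.0e-6, k_uptake: 1.0e-6, ae_max: 0.8, ae_shape: 2}
  Cu: {q_max_nano: 16.0e-6, q_max_diatom: 16.0e-6, q_zoo: 10.0e-6, k_uptake: 1.0e-6, ae_max: 0.8, ae_shape: 2}
  Co: {q_max_nano: 1.2e-6, q_max_diatom: 1.2e-6, q_zoo: 0.16e-6, k_uptake: 0.03e-6, ae_max: 0.8, ae_shape: 2}
  Mn: {q_max_nano: 8.0e-6, q_max_diatom: 8.0e-6, q_zoo: 1.0e-6, k_uptake: 0.5e-6, ae_max: 0.8, ae_shape: 2}
ecosystem:
  mu_max: {nano: 1.2, diatom: 1.5}
  k_n: {nano: 8.0e-4, diatom: 7.6e-3}
  q10: 1.88
  g_max: 3
  k_g: 0.02
  preference: {nano: 1.0, diatom: 0.5, particle: 0.3}
  ae_c: 0.3
  sigma_diss: 0.5
  m_z: 20
  m_p: 0.05
  lambda_sink: 0.1
  lambda_rem: 0.05
  kappa0: 0.02
  n_deep: 0.076
  d_deep: {Fe: 0.8e-6, Zn: 6.0e-6, Cu: 2.0e-6, Co: 0.05e-6, Mn: 0.3e-6}
  source_n: 0
  source_d: {Fe: 1.0e-10, Zn: 2.0e-10, Cu: 5.0e-11, Co: 2.0e-12, Mn: 5.0e-11}
  fe_q_min: 4.0e-6
scenario:
  years_total: 300
  delta_t: 4
  delta_kappa: 0.4
  ramp_start_year: 50
  ramp_shape: linear
  base_temp: 18
  temp_amp: 0
  seed: 1
attribution:
  threshold: 0.5
  grouping: [region, element, response_kind, period]
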