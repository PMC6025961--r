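# Default rate constants for the two-reporter metabolic switching model.
# Units package-wide: time min, length um, concentration mM, fluorescence AU.
# Calibration anchors: mean sucC+ episode length 252 min; sucC+/sucC- elongation
# 47.4/67.7 %/hr; alsS+/alsS- elongation 63/74 %/hr; batch medium 22 mM glucose
# + 50 mM malate; pad acetate 20 mM.
version: 1
params:
  # sucC+/competent state entry and exit (1/min)
  k_on_sucC: 2.5e-4
  k_off_sucC: 3.968254e-3      # 1/252
  # alsS+ state: basal + Hill-type acetate induction (1/min), exit (1/min)
  k0_alsS: 1.0e-4
  kmax_alsS: 1.0e-3
  K_alsS: 10.0                  # mM, half-activation acetate
  h_alsS: 2.0
  k_off_alsS: 5.555556e-3      # 1/180
  # growth
  r_base: 9.240246e-3          # 1/min; 100*(exp(60*r)-1) = 74 %/hr
  # penalties multiply the specific (exponential) elongation rate; the
  # ratios are converted from the %/hr anchors via log(1 + pct/100), so
  # on-cells grow at 47.4 vs 67.7 %/hr (sucC+) and 63 vs 74 %/hr (alsS+)
  penalty_sucC: 0.7504351      # log(1.474)/log(1.677)
  penalty_alsS: 0.8820963      # log(1.63)/log(1.74)
  K_tox: 25.0                  # mM acetate halving growth
  r_cv: 0.10                   # per-cell lognormal growth-rate variability
  # reporters (AU/min); dilution by growth only, no degradation
  beta_on: 50.0
  beta_off: 1.0
  # division
  L_div: 6.0                   # um
  div_cv: 0.05
  length_noise_cv: 0.02        # multiplicative measurement noise on recorded length
  # environment coupling (per unit biomass, OD-equivalents)
  p_A: 3.2                     # mM/min acetate secretion per OD of sucC+ cells
  p_A_basal: 0.05             # mM/min basal acetate leak per OD of all cells
  c_A: 1.5                     # mM/min acetate uptake per OD of alsS+ cells
  y_acetoin: 0.5               # mol acetoin per mol acetate consumed
  # batch carbon model
  yield_od_per_mM: 0.0375      # biomass yield on glucose+malate
  K_C: 0.5                     # mM, carbon half-saturation for growth
  quorum: 1.0                  # dimensionless scale on k_on_sucC
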