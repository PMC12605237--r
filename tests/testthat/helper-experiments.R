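# Cohort-level experiment helpers shared by the acceptance tests.

# p-values of the group-by-phase analysis of the combined social Z-score
social_phase_p <- function(measures) {
  pt <- combined_social_phase_test(measures)
  ph <- pt$posthoc
  c(drug = pt$anova$table$p[1],
    interaction = pt$anova$table$p[3],
    early = ph$p[ph$scope == "between_at_level" & ph$level == "early"],
    late = ph$p[ph$scope == "between_at_level" & ph$level == "late"])
}

# Null cohort at the calibration scale: 6 + 6 mice, 6 sessions, 2-minute
# interaction sessions at 10 Hz.
null_cohort_p <- function(seed) {
  des <- cohort_design(n_morphine = 6, n_saline = 6,
                       habituation_duration = 120,
                       interaction_duration = 120, frame_rate = 10,
                       effects = null_schedule(), master_seed = seed)
  cm <- simulate_cohort_measures(des, phases = "interaction")
  social_phase_p(cm$measures)
}

# Incubation cohort: study-sized groups (11 + 10), 150-second interaction
# sessions at 10 Hz; social multipliers 1.0 in S1-S2 and `late_mult` in
# S3-S5 on both approach_rate and contact_dwell.
incubation_cohort_p <- function(seed, late_mult) {
  eff <- effect_schedule(motor_multipliers = rep(1, 6),
                         social_multipliers = c(1, 1, 1, rep(late_mult, 3)),
                         coupling_lambda = 0, weight_base = 0,
                         weight_slope = 0)
  des <- cohort_design(n_morphine = 11, n_saline = 10,
                       habituation_duration = 150,
                       interaction_duration = 150, frame_rate = 10,
                       effects = eff, master_seed = seed)
  cm <- simulate_cohort_measures(des, phases = "interaction")
  social_phase_p(cm$measures)
}

# Prediction cohort: 20 treated + 10 control mice, 90-second sessions at
# 10 Hz; habituation simulated for S0-S2 only (baseline reference and early
# motor composites are all that the prediction analysis consumes).
prediction_cohort <- function(seed, lambda) {
  eff <- effect_schedule(coupling_lambda = lambda)
  des <- cohort_design(n_morphine = 20, n_saline = 10,
                       habituation_duration = 90, interaction_duration = 90,
                       frame_rate = 10, effects = eff, master_seed = seed)
  cm <- simulate_cohort_measures(des, hab_sessions = c("S0", "S1", "S2"),
                                 saline_sessions = "S0")
  zt <- zscore_normalize(cm$measures)
  comp <- phase_composites(zt)
  soc <- combined_zscore(comp, "social", by = c("group", "phase"))
  mot <- combined_zscore(comp, "motor", by = c("group", "phase"))
  msoc <- soc[soc$group == "morphine", ]
  mmot <- mot[mot$group == "morphine", ]
  sw <- dyadtrack:::long_to_wide(msoc, "phase")$values
  mw <- dyadtrack:::long_to_wide(mmot, "phase")$values
  wl <- cm$weights[rownames(sw)]
  motor_social <- linear_fit(mw[, "early"], sw[, "late"])
  wl_late <- linear_fit(wl, sw[, "late"])
  wl_early <- linear_fit(wl, sw[, "early"])
  c(slope = motor_social$slope, r2 = motor_social$r_squared,
    wl_late_slope = wl_late$slope, wl_late_r2 = wl_late$r_squared,
    wl_early_r2 = wl_early$r_squared)
}
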