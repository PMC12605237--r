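test_that("simulation is deterministic under the seed", {
  a <- simulate_session(motion_params(), social_params(), 30, seed = 42,
                        frame_rate = 15)
  b <- simulate_session(motion_params(), social_params(), 30, seed = 42,
                        frame_rate = 15)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_session(motion_params(), social_params(), 30, seed = 43,
                        frame_rate = 15)
  expect_false(identical(a$tracks[[1]]$cx, c$tracks[[1]]$cx))
})

test_that("stationary limit: zero mean speed gives negligible path length", {
  rec <- simulate_session(motion_params(mean_speed = 0), NULL, 60, seed = 1,
                          frame_rate = 30)
  kin <- compute_kinematics(rec)
  expect_lt(total_distance(kin), 1)
})

test_that("empirical mean speed tracks mean_speed within 15%", {
  rec <- simulate_session(motion_params(mean_speed = 8), NULL, 600,
                          seed = 7, frame_rate = 30)
  kin <- compute_kinematics(rec)
  ms <- mean(kin$mice[[1]]$speed, na.rm = TRUE)
  expect_gt(ms, 6.8)
  expect_lt(ms, 9.2)
})

test_that("poses respect arena bounds and rearing modulates the posture channel", {
  rec <- simulate_session(motion_params(rear_rate = 6), NULL, 120, seed = 3,
                          frame_rate = 20)
  tr <- rec$tracks[[1]]
  expect_true(all(tr$cx >= 0 & tr$cx <= 50 & tr$cy >= 0 & tr$cy <= 50))
  expect_true(any(tr$posture > 0.5))
  # rearing compresses the nose to tail-base distance
  bl <- sqrt((tr$nx - tr$tx)^2 + (tr$ny - tr$ty)^2)
  expect_lt(median(bl[tr$posture > 0.5]), 0.6 * median(bl[tr$posture < 0.5]))
})

test_that("approach state points the focal at the partner", {
  rec <- simulate_session(motion_params(), social_params(approach_rate = 8),
                          300, seed = 11, frame_rate = 30)
  st <- attr(rec, "social_state")[[rec$focal_id]]
  tr <- rec$tracks[[rec$focal_id]]
  pt <- rec$tracks[[rec$partner_id]]
  idx <- which(st == 1L)
  # skip the steering transient at each approach onset
  idx <- idx[c(FALSE, diff(idx) == 1L)]
  idx <- idx[idx > 5]
  skip_if(length(idx) < 20)
  axis <- atan2(tr$ny[idx] - tr$ty[idx], tr$nx[idx] - tr$tx[idx])
  bearing <- atan2(pt$cy[idx] - tr$cy[idx], pt$cx[idx] - tr$cx[idx])
  err <- abs(atan2(sin(axis - bearing), cos(axis - bearing)))
  expect_gt(mean(err < 30 * pi / 180), 0.9)
})

test_that("silencing the social automaton removes directed social behavior", {
  n_social <- function(ar, fp, seeds) {
    out <- c(approach = 0, follow = 0, states = 0)
    for (s in seeds) {
      rec <- simulate_session(motion_params(center_bias = 0),
                              social_params(approach_rate = ar,
                                            follow_propensity = fp),
                              120, seed = s, frame_rate = 10,
                              partner_motion = motion_params(mean_speed = 0,
                                                             rear_rate = 0))
      st <- attr(rec, "social_state")[[rec$focal_id]]
      p <- profile_recording(rec)
      out <- out + c(p$value[p$measure == "int_approach_count"],
                     p$value[p$measure == "int_follow_count"],
                     sum(st %in% c(1L, 4L)))
    }
    out
  }
  off <- n_social(0, 0, 1:6)
  on <- n_social(5, 0.3, 101:106)
  # the automaton never enters the approach or follow state
  expect_equal(unname(off["states"]), 0)
  # a stationary partner can never be followed (speed gate)
  expect_equal(unname(off["follow"]), 0)
  # only incidental zone passages remain: approaches collapse
  expect_lt(off["approach"], 0.5 * on["approach"])
})

test_that("effect schedule follows the design rules", {
  # null schedule: every row equals baseline
  des <- cohort_design(n_morphine = 4, n_saline = 3,
                       effects = null_schedule(), master_seed = 2)
  sched <- build_effect_schedule(des)
  expect_equal(nrow(sched), 7 * 6)
  expect_true(all(sched$mean_speed == des$baseline_motion$mean_speed))
  expect_true(all(sched$approach_rate == des$baseline_social$approach_rate))
  # saline rows always exactly baseline, even with effects on
  eff <- effect_schedule(motor_multipliers = c(1, 0.6, 0.6, 1, 1, 1),
                         social_multipliers = rep(1, 6),
                         coupling_lambda = 0)
  des2 <- cohort_design(n_morphine = 4, n_saline = 3, effects = eff,
                        master_seed = 2)
  s2 <- build_effect_schedule(des2)
  sal <- s2[s2$group == "saline", ]
  expect_true(all(sal$motor_multiplier == 1))
  mor <- s2[s2$group == "morphine", ]
  expect_equal(mor$mean_speed[mor$session %in% c("S1", "S2")],
               rep(0.6 * des2$baseline_motion$mean_speed, 8))
  expect_equal(mor$mean_speed[mor$session == "S0"],
               rep(des2$baseline_motion$mean_speed, 4))
  # latents drawn once per mouse and reused across sessions
  expect_equal(as.vector(tapply(s2$s_i, s2$mouse_id,
                              function(x) length(unique(x)))),
               rep(1L, 7))
})

test_that("latent coupling correlates early motor and late social multipliers", {
  eff <- effect_schedule(coupling_lambda = 0.5)
  des <- cohort_design(n_morphine = 200, n_saline = 2, effects = eff,
                       master_seed = 8)
  sched <- build_effect_schedule(des)
  mor <- sched[sched$group == "morphine", ]
  early <- mor$motor_multiplier[mor$session == "S1"]
  late <- mor$social_multiplier[mor$session == "S3"]
  expect_gt(cor(early, late), 0.5)
  # lambda = 0 removes the coupling variance entirely
  eff0 <- effect_schedule(coupling_lambda = 0)
  des0 <- cohort_design(n_morphine = 50, n_saline = 2, effects = eff0,
                        master_seed = 8)
  s0 <- build_effect_schedule(des0)
  expect_equal(var(s0$motor_multiplier[s0$group == "morphine" &
                                         s0$session == "S1"]), 0)
})

test_that("weight loss sampling matches the model", {
  des <- cohort_design(n_morphine = 500, n_saline = 500,
                       effects = effect_schedule(coupling_lambda = 0.5,
                                                 weight_base = 3,
                                                 weight_slope = 1,
                                                 weight_noise_sd = 0.1),
                       master_seed = 4)
  sched <- build_effect_schedule(des)
  lat <- setNames(sched$s_i[!duplicated(sched$mouse_id)],
                  sched$mouse_id[!duplicated(sched$mouse_id)])
  wl <- sample_weight_loss(des, lat)
  groups <- c(rep("morphine", 500), rep("saline", 500))
  m <- wl[groups == "morphine"]
  expect_gt(mean(m), 2.8)
  expect_lt(mean(m), 3.2)
  expect_gt(cor(m, lat[names(m)]), 0.9)
  expect_lt(mean(abs(wl[groups == "saline"])), 0.2)
  # slope 0 ablates the correlation
  des0 <- cohort_design(n_morphine = 500, n_saline = 2,
                        effects = effect_schedule(weight_slope = 0,
                                                  weight_noise_sd = 0.5),
                        master_seed = 4)
  wl0 <- sample_weight_loss(des0, lat)
  expect_lt(abs(cor(wl0[names(m)], lat[names(m)])), 0.15)
})

test_that("generate_cohort produces the full grid with per-recording seeds", {
  des <- cohort_design(n_morphine = 2, n_saline = 2,
                       habituation_duration = 12, interaction_duration = 12,
                       frame_rate = 10, master_seed = 6)
  coh <- generate_cohort(des)
  expect_length(coh$recordings, 4 * 6 * 2)
  expect_equal(nrow(coh$manifest$mice), 4)
  # a recording is reproducible from its derived seed alone
  sched <- coh$truth
  row <- sched[sched$mouse_id == "m02" & sched$session == "S3", ]
  pr <- dyadtrack:::params_for_row(des, row)
  seed <- dyadtrack:::derive_seed(des$master_seed, 2L, 4L, 1L)
  solo <- simulate_session(pr$motion, NULL, 12, des$arena, seed = seed,
                           frame_rate = 10, session = "S3",
                           focal_id = "m02")
  expect_identical(solo$tracks,
                   coh$recordings[["m02_S3_habituation"]]$tracks)
  # newcomers are fresh per session
  expect_match(coh$recordings[["m01_S2_interaction"]]$partner_id, "nc_S2")
})

test_that("streamed cohort measures equal profiling the generated recordings", {
  des <- cohort_design(n_morphine = 2, n_saline = 2,
                       habituation_duration = 12, interaction_duration = 12,
                       frame_rate = 10, master_seed = 13)
  cm <- simulate_cohort_measures(des)
  coh <- generate_cohort(des)
  rows <- do.call(rbind, lapply(coh$recordings, profile_recording))
  ref <- build_measures_table(rows, coh$manifest)
  expect_equal(cm$measures, ref)
  # determinism end to end
  cm2 <- simulate_cohort_measures(des)
  expect_identical(cm$measures, cm2$measures)
})

test_that("lowering approach_rate lowers detected approach counts monotonically", {
  mean_ct <- function(ar) {
    mean(sapply(1:8, function(i) {
      rec <- simulate_session(motion_params(),
                              social_params(approach_rate = ar), 120,
                              seed = 100 + i, frame_rate = 10)
      sum(profile_recording(rec)$value[
        profile_recording(rec)$measure == "int_approach_count"])
    }))
  }
  counts <- sapply(c(1, 5, 10), mean_ct)
  expect_true(all(diff(counts) > 0))
})
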