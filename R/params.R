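#' Event-detector parameters
#'
#' Thresholds and post-processing rules shared by all event classifiers.
#' All distance thresholds expressed in body lengths are scaled by the
#' per-session dyad body length (mean of the two animals' median nose to
#' tail-base distances). All inequalities in the per-frame predicates are
#' strict, so values exactly at a threshold fail the predicate.
#'
#' @param speed_threshold Speed gate in cm/s for movement bouts and follows
#'   (strict \code{>}; default 5).
#' @param approach_radius_bl Radius of the approach zone in body lengths
#'   (default 2).
#' @param follow_heading_max_deg Maximal heading difference between the two
#'   animals during a follow, in degrees (default 45, must be < 90).
#' @param follow_zone_w_bl,follow_zone_l_bl Width and length of the follow
#'   zone behind the leader, in body lengths (defaults 1 and 2).
#' @param contact_dist_cm Contact threshold on the minimum distance among the
#'   nine point pairs of the two three-point skeletons (nose, mass center,
#'   tail base), in cm (default 2).
#' @param min_event_frames Minimum event duration in frames; shorter runs are
#'   dropped (default 3).
#' @param merge_gap_frames Gaps of at most this many frames between
#'   consecutive surviving runs of the same predicate are merged, after the
#'   minimum-duration filter (default 2).
#' @param smoothing_window_frames Centered moving-average window applied to
#'   the mass center before differentiation (default 5).
#' @param rear_posture_threshold Threshold on the posture channel above which
#'   a frame counts as rearing (default 0.5).
#' @param side_by_side_angle_max_deg Maximal angle between body axes
#'   (parallel or antiparallel) for the side-by-side contact subtype
#'   (default 30).
#' @param heading_min_disp_cm Displacement per frame below which the heading
#'   falls back to the tail-to-nose body axis (default 0.1 cm).
#' @return An object of class \code{"detector_params"}.
#' @export
detector_params <- function(speed_threshold = 5,
                            approach_radius_bl = 2,
                            follow_heading_max_deg = 45,
                            follow_zone_w_bl = 1,
                            follow_zone_l_bl = 2,
                            contact_dist_cm = 2,
                            min_event_frames = 3,
                            merge_gap_frames = 2,
                            smoothing_window_frames = 5,
                            rear_posture_threshold = 0.5,
                            side_by_side_angle_max_deg = 30,
                            heading_min_disp_cm = 0.1) {
  p <- list(speed_threshold = speed_threshold,
            approach_radius_bl = approach_radius_bl,
            follow_heading_max_deg = follow_heading_max_deg,
            follow_zone_w_bl = follow_zone_w_bl,
            follow_zone_l_bl = follow_zone_l_bl,
            contact_dist_cm = contact_dist_cm,
            min_event_frames = as.integer(min_event_frames),
            merge_gap_frames = as.integer(merge_gap_frames),
            smoothing_window_frames = as.integer(smoothing_window_frames),
            rear_posture_threshold = rear_posture_threshold,
            side_by_side_angle_max_deg = side_by_side_angle_max_deg,
            heading_min_disp_cm = heading_min_disp_cm)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || !all(vapply(p, function(v) length(v) == 1L && is.finite(v), logical(1))))
    stop("all detector parameters must be finite scalars")
  if (any(unlist(p[c("speed_threshold", "approach_radius_bl", "contact_dist_cm",
                     "follow_zone_w_bl", "follow_zone_l_bl",
                     "rear_posture_threshold")]) <= 0))
    stop("detector thresholds must be > 0")
  if (p$follow_heading_max_deg <= 0 || p$follow_heading_max_deg >= 90)
    stop("follow_heading_max_deg must lie in (0, 90)")
  if (p$min_event_frames < 1L || p$merge_gap_frames < 0L ||
      p$smoothing_window_frames < 1L)
    stop("invalid frame-count parameter")
  structure(p, class = "detector_params")
}

#' Single-animal locomotion parameters
#'
#' Parameters of the agent motion model: an Ornstein-Uhlenbeck speed process
#' with wrapped-normal heading noise, wall steering, an optional center-zone
#' bias, and explicit rearing episodes that raise the posture channel and
#' compress the body axis.
#'
#' @param mean_speed Long-run mean of the speed process, cm/s (default 6, a
#'   realistic open-field average for an adult C57BL/6 mouse).
#' @param speed_relaxation Mean-reversion rate of the speed process, 1/s
#'   (default 1).
#' @param turn_noise Heading diffusion, rad/sqrt(s) (default 2.5).
#' @param wall_avoidance_range Distance from a wall at which steering toward
#'   the interior begins, cm (default 5).
#' @param rear_rate Rearing initiation rate, events/min (default 2).
#' @param rear_mean_duration Mean rearing duration, s (default 3).
#' @param center_bias Steering weight toward (> 0) or away from (< 0) the
#'   arena center (default -0.2, mild thigmotaxis).
#' @param body_length_cm Nose to tail-base length of the animal, cm
#'   (default 7).
#' @return An object of class \code{"motion_params"}.
#' @export
motion_params <- function(mean_speed = 6,
                          speed_relaxation = 1,
                          turn_noise = 2.5,
                          wall_avoidance_range = 5,
                          rear_rate = 2,
                          rear_mean_duration = 3,
                          center_bias = -0.2,
                          body_length_cm = 7) {
  p <- list(mean_speed = mean_speed, speed_relaxation = speed_relaxation,
            turn_noise = turn_noise,
            wall_avoidance_range = wall_avoidance_range,
            rear_rate = rear_rate, rear_mean_duration = rear_mean_duration,
            center_bias = center_bias, body_length_cm = body_length_cm)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all motion parameters must be finite scalars")
  if (p$mean_speed < 0 || p$rear_rate < 0) stop("rates must be >= 0")
  if (p$rear_mean_duration <= 0 || p$body_length_cm <= 0 ||
      p$speed_relaxation <= 0)
    stop("durations, lengths and relaxation rates must be > 0")
  structure(p, class = "motion_params")
}

#' Social-interaction parameters
#'
#' Parameters of the social behavioral automaton (roam / approach-and-
#' contact / disengage-or-avoid) layered on top of the motion model. The
#' approach drive also governs whether an encounter initiated by the
#' partner is accepted or avoided, and the sign of the roaming proximity
#' bias.
#'
#' @param approach_rate Hazard of initiating a directed approach,
#'   initiations/min (default 5, the species-typical drive at which the
#'   roaming proximity bias is neutral: lower values produce active social
#'   avoidance, higher values net attraction).
#' @param contact_dwell Mean duration of a contact bout, s (default 3).
#' @param follow_propensity Probability in [0, 1] of entering a follow bout
#'   when the opportunity arises (default 0.3).
#' @param break_assertiveness Relative speed surplus of the focal animal when
#'   disengaging from a contact (default 1, i.e. it leaves at twice its mean
#'   speed).
#' @return An object of class \code{"social_params"}.
#' @export
social_params <- function(approach_rate = 5,
                          contact_dwell = 3,
                          follow_propensity = 0.3,
                          break_assertiveness = 1) {
  p <- list(approach_rate = approach_rate, contact_dwell = contact_dwell,
            follow_propensity = follow_propensity,
            break_assertiveness = break_assertiveness)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all social parameters must be finite scalars")
  if (any(unlist(p) < 0)) stop("social parameters must be >= 0")
  if (p$follow_propensity > 1) stop("follow_propensity must be <= 1")
  structure(p, class = "social_params")
}

SESSION_LABELS <- paste0("S", 0:5)
SESSION_PHASE_TAGS <- c(S0 = "baseline", S1 = "early", S2 = "early",
                        S3 = "late", S4 = "late", S5 = "late")

#' Treatment effect schedule
#'
#' Per-session multipliers applied to the treated group's motion and social
#' parameters, plus a latent-severity coupling and a weight-loss model.
#' Control-group multipliers are identically 1 for every session.
#'
#' The per-mouse latent severity \eqn{s_i ~ N(0, 1)} couples the early motor
#' and late social deficits: a base multiplier \eqn{m < 1} becomes
#' \eqn{m^{exp(\lambda s_i)}}, so a more severe mouse (larger \eqn{s_i})
#' shows a proportionally stronger deficit wherever a deficit is programmed,
#' while null multipliers (\eqn{m = 1}) are unaffected. Weight loss is
#' \code{weight_base + weight_slope * s_i + noise} for treated mice and pure
#' noise for controls.
#'
#' The defaults encode the study conditions the package is built around: a
#' transient motor suppression in the two sessions immediately after
#' treatment, a social suppression confined to the three late sessions, and
#' a positive coupling between the two.
#'
#' @param motor_multipliers Named numeric vector over sessions S0..S5
#'   multiplying \code{mean_speed} of treated mice (default 1, 0.5, 0.7, 1,
#'   1, 1: early suppression only).
#' @param social_multipliers Named numeric vector over sessions S0..S5
#'   multiplying \code{approach_rate} and \code{contact_dwell} of treated
#'   mice (default 1, 1, 1, 0.5, 0.5, 0.5: late suppression only).
#' @param coupling_lambda Weight (>= 0) of the shared latent severity
#'   (default 0.5).
#' @param weight_base Mean treatment-induced weight loss, g (default 3).
#' @param weight_slope Weight-loss increase per unit of latent severity,
#'   g (default 1).
#' @param weight_noise_sd Residual weight-loss standard deviation, g
#'   (default 0.1).
#' @return An object of class \code{"effect_schedule"}.
#' @export
effect_schedule <- function(motor_multipliers = c(S0 = 1, S1 = 0.5, S2 = 0.7,
                                                  S3 = 1, S4 = 1, S5 = 1),
                            social_multipliers = c(S0 = 1, S1 = 1, S2 = 1,
                                                   S3 = 0.5, S4 = 0.5, S5 = 0.5),
                            coupling_lambda = 0.5,
                            weight_base = 3,
                            weight_slope = 1,
                            weight_noise_sd = 0.1) {
  motor_multipliers <- expand_multipliers(motor_multipliers, "motor_multipliers")
  social_multipliers <- expand_multipliers(social_multipliers, "social_multipliers")
  if (any(motor_multipliers <= 0) || any(social_multipliers <= 0))
    stop("multipliers must be > 0")
  stopifnot(coupling_lambda >= 0, weight_noise_sd >= 0)
  structure(list(motor_multipliers = motor_multipliers,
                 social_multipliers = social_multipliers,
                 coupling_lambda = coupling_lambda,
                 weight_base = weight_base,
                 weight_slope = weight_slope,
                 weight_noise_sd = weight_noise_sd),
            class = "effect_schedule")
}

expand_multipliers <- function(m, what) {
  if (length(m) == 1L) m <- rep(m, 6L)
  if (is.null(names(m))) names(m) <- SESSION_LABELS
  if (length(m) != 6L || !identical(sort(names(m)), sort(SESSION_LABELS)))
    stop(what, " must be a scalar or a vector named S0..S5")
  m[SESSION_LABELS]
}

#' Null effect schedule
#'
#' All multipliers 1, no coupling, no treatment weight loss: the two groups
#' are exchangeable by construction.
#' @return An \code{\link{effect_schedule}}.
#' @export
null_schedule <- function() {
  effect_schedule(motor_multipliers = rep(1, 6), social_multipliers = rep(1, 6),
                  coupling_lambda = 0, weight_base = 0, weight_slope = 0,
                  weight_noise_sd = 0.1)
}

#' Longitudinal cohort design
#'
#' Describes a two-group longitudinal cohort: group sizes, the six-session
#' schedule (baseline, 24 h, weeks 1-4 post-treatment), session durations
#' for the solo habituation and dyadic interaction phases, acquisition frame
#' rate, the treatment \code{\link{effect_schedule}}, and the master seed
#' governing all randomness.
#'
#' @param n_morphine Number of treated mice (default 11).
#' @param n_saline Number of control mice (default 10).
#' @param habituation_duration Solo phase duration, s (default 900).
#' @param interaction_duration Dyadic phase duration, s (default 1500).
#' @param frame_rate Acquisition rate, Hz (default 30).
#' @param effects An \code{\link{effect_schedule}}.
#' @param baseline_motion A \code{\link{motion_params}} object giving the
#'   untreated phenotype.
#' @param baseline_social A \code{\link{social_params}} object giving the
#'   untreated phenotype.
#' @param arena An \code{\link{arena}}.
#' @param master_seed Integer master seed (default 1).
#' @return An object of class \code{"cohort_design"}.
#' @export
cohort_design <- function(n_morphine = 11, n_saline = 10,
                          habituation_duration = 900,
                          interaction_duration = 1500,
                          frame_rate = 30,
                          effects = effect_schedule(),
                          baseline_motion = motion_params(),
                          baseline_social = social_params(),
                          arena = dyadtrack::arena(),
                          master_seed = 1L) {
  stopifnot(n_morphine >= 2, n_saline >= 2,
            habituation_duration > 0, interaction_duration > 0,
            frame_rate > 0,
            inherits(effects, "effect_schedule"),
            inherits(baseline_motion, "motion_params"),
            inherits(baseline_social, "social_params"),
            inherits(arena, "arena"))
  structure(list(n_morphine = as.integer(n_morphine),
                 n_saline = as.integer(n_saline),
                 sessions = SESSION_LABELS,
                 habituation_duration = habituation_duration,
                 interaction_duration = interaction_duration,
                 frame_rate = frame_rate,
                 effects = effects,
                 baseline_motion = baseline_motion,
                 baseline_social = baseline_social,
                 arena = arena,
                 master_seed = as.integer(master_seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(paste0("Cohort design: %d treated + %d control mice, ",
                     "%d sessions (%s)\n"),
              x$n_morphine, x$n_saline, length(x$sessions),
              paste(x$sessions, collapse = " ")),
      sprintf("  habituation %g s, interaction %g s at %g Hz, seed %d\n",
              x$habituation_duration, x$interaction_duration, x$frame_rate,
              x$master_seed))
  invisible(x)
}
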