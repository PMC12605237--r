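#' Simulate one open-field session
#'
#' Generates a solo (habituation) or dyadic (interaction) session from the
#' agent motion model: an Ornstein-Uhlenbeck speed process with
#' wrapped-normal heading noise, wall steering, an optional center bias,
#' explicit rearing episodes driving the posture channel, and (for dyads) a
#' three-state social automaton per animal whose approach, contact, break
#' and follow bouts are detectable by the geometric event classifiers.
#'
#' @param motion \code{\link{motion_params}} of the focal animal.
#' @param social \code{\link{social_params}} of the focal animal, or
#'   \code{NULL} for a solo session.
#' @param duration Session duration in seconds (>= 10).
#' @param arena An \code{\link{arena}}.
#' @param seed Integer seed; identical seeds and parameters give identical
#'   recordings.
#' @param frame_rate Acquisition rate, Hz (default 30).
#' @param partner_motion,partner_social Parameters of the newcomer (defaults:
#'   baseline \code{motion_params()} / \code{social_params()}); ignored for
#'   solo sessions.
#' @param session Session label (default "S0").
#' @param focal_id,partner_id Animal identifiers.
#' @param noise_sd Tracking noise added to recorded coordinates, cm
#'   (default 0).
#' @return A \code{\link{session_recording}}. The per-frame behavioral state
#'   of the automaton (0 roam, 1 approach, 2 contact, 3 break, 4 follow) is
#'   attached as attribute \code{"social_state"} for introspection.
#' @export
simulate_session <- function(motion, social = NULL, duration, arena = dyadtrack::arena(),
                             seed = 1L, frame_rate = 30,
                             partner_motion = motion_params(),
                             partner_social = social_params(),
                             session = "S0", focal_id = "F1",
                             partner_id = "N1", noise_sd = 0) {
  stopifnot(inherits(motion, "motion_params"))
  if (!is.null(social)) stopifnot(inherits(social, "social_params"))
  if (!is.numeric(duration) || !is.finite(duration) || duration < 10)
    stop("duration must be a finite number >= 10 s")
  dyad <- !is.null(social)
  n <- as.integer(round(duration * frame_rate))
  mf <- unlist(motion[c("mean_speed", "speed_relaxation", "turn_noise",
                        "wall_avoidance_range", "rear_rate",
                        "rear_mean_duration", "center_bias",
                        "body_length_cm")])
  mp <- if (dyad)
    unlist(partner_motion[c("mean_speed", "speed_relaxation", "turn_noise",
                            "wall_avoidance_range", "rear_rate",
                            "rear_mean_duration", "center_bias",
                            "body_length_cm")]) else numeric(8)
  sf <- if (dyad) unlist(social) else numeric(4)
  sp <- if (dyad) unlist(partner_social) else numeric(4)
  set.seed(as.integer(seed))
  res <- sim_session_cpp(mf, mp, sf, sp, n, 1 / frame_rate,
                         arena$side_cm, dyad, noise_sd)
  as_track <- function(m) {
    data.frame(frame = seq_len(nrow(m)) - 1L, t = m[, "t"], cx = m[, "cx"],
               cy = m[, "cy"], nx = m[, "nx"], ny = m[, "ny"],
               tx = m[, "tx"], ty = m[, "ty"], posture = m[, "posture"])
  }
  tracks <- stats::setNames(list(as_track(res$focal)), focal_id)
  if (dyad) tracks[[partner_id]] <- as_track(res$partner)
  rec <- session_recording(session, if (dyad) "interaction" else "habituation",
                           frame_rate, arena, tracks, focal_id,
                           if (dyad) partner_id else NULL)
  attr(rec, "social_state") <-
    stats::setNames(list(res$state_focal,
                         if (dyad) res$state_partner else NULL),
                    c(focal_id, if (dyad) partner_id else "none"))[
                      seq_len(1L + dyad)]
  rec
}

# Deterministic sub-seed derivation: mixes the master seed with small
# indices, exact in double arithmetic, result < 2^31.
derive_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  as.integer((as.numeric(master) * 1000003 + a * 10007 + b * 101 + c) %%
               2147483629)
}

cohort_mouse_ids <- function(design) {
  c(sprintf("m%02d", seq_len(design$n_morphine)),
    sprintf("s%02d", seq_len(design$n_saline)))
}

cohort_groups <- function(design) {
  c(rep("morphine", design$n_morphine), rep("saline", design$n_saline))
}

#' Expand a cohort design into per-mouse, per-session true parameters
#'
#' Draws the per-mouse latent severity \eqn{s_i} once per mouse from its own
#' seeded substream and applies the effect schedule: treated rows carry the
#' session multipliers (raised to \eqn{exp(\lambda s_i)}), control rows equal
#' the baseline parameters exactly.
#'
#' @param design A \code{\link{cohort_design}}.
#' @return Data frame with one row per mouse x session: ids, group, session,
#'   latent \code{s_i}, effective multipliers, and the resulting
#'   \code{mean_speed}, \code{approach_rate} and \code{contact_dwell}.
#' @export
build_effect_schedule <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  eff <- design$effects
  ids <- cohort_mouse_ids(design)
  groups <- cohort_groups(design)
  s_i <- vapply(seq_along(ids), function(i) {
    set.seed(derive_seed(design$master_seed, i, 0L, 99L))
    stats::rnorm(1)
  }, numeric(1))
  rows <- vector("list", length(ids) * 6L)
  k <- 0L
  for (i in seq_along(ids)) {
    sev <- exp(eff$coupling_lambda * s_i[i])
    for (s in SESSION_LABELS) {
      k <- k + 1L
      treated <- groups[i] == "morphine"
      mm <- if (treated) eff$motor_multipliers[[s]]^sev else 1
      sm <- if (treated) eff$social_multipliers[[s]]^sev else 1
      rows[[k]] <- data.frame(
        mouse_id = ids[i], group = groups[i], session = s, s_i = s_i[i],
        motor_multiplier = mm, social_multiplier = sm,
        mean_speed = design$baseline_motion$mean_speed * mm,
        approach_rate = design$baseline_social$approach_rate * sm,
        contact_dwell = design$baseline_social$contact_dwell * sm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Effective per-session parameters for one mouse from a schedule row.
params_for_row <- function(design, row) {
  m <- design$baseline_motion
  m$mean_speed <- row$mean_speed
  s <- design$baseline_social
  s$approach_rate <- row$approach_rate
  s$contact_dwell <- row$contact_dwell
  list(motion = m, social = s)
}

#' Sample per-mouse treatment weight loss
#'
#' Treated mice lose \code{weight_base + weight_slope * s_i} grams on
#' average; control losses are centered at zero. Residual noise has standard
#' deviation \code{weight_noise_sd}.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param latents Named numeric vector of per-mouse latent severities (as in
#'   the schedule from \code{\link{build_effect_schedule}}); required for
#'   treated mice.
#' @param seed Integer seed (default derived from the design master seed).
#' @return Named numeric vector of weight losses in grams (pre minus post).
#' @export
sample_weight_loss <- function(design, latents,
                               seed = derive_seed(design$master_seed,
                                                  0L, 0L, 7L)) {
  ids <- cohort_mouse_ids(design)
  groups <- cohort_groups(design)
  if (!all(ids[groups == "morphine"] %in% names(latents)))
    stop("latents must be provided for every treated mouse")
  eff <- design$effects
  set.seed(seed)
  loss <- vapply(seq_along(ids), function(i) {
    if (groups[i] == "morphine")
      eff$weight_base + eff$weight_slope * latents[[ids[i]]] +
        stats::rnorm(1, 0, eff$weight_noise_sd)
    else stats::rnorm(1, 0, eff$weight_noise_sd)
  }, numeric(1))
  stats::setNames(loss, ids)
}

#' Generate a full longitudinal cohort of recordings
#'
#' Simulates every mouse over the six-session schedule, each session
#' comprising a solo habituation phase and a dyadic interaction phase with a
#' freshly generated, untreated newcomer. Each recording is driven by its
#' own seed derived from the master seed, so changing one mouse's stream
#' leaves all others unchanged.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param phases Which phases to simulate (default both).
#' @return A list with elements \code{manifest} (a
#'   \code{\link{cohort_manifest}}), \code{recordings} (named list of
#'   \code{\link{session_recording}}s, names \code{<mouse>_<session>_<phase>}),
#'   \code{truth} (the true-parameter table from
#'   \code{\link{build_effect_schedule}}) and \code{weights} (per-mouse
#'   weight loss, g).
#' @export
generate_cohort <- function(design,
                            phases = c("habituation", "interaction")) {
  stopifnot(inherits(design, "cohort_design"))
  phases <- match.arg(phases, several.ok = TRUE)
  sched <- build_effect_schedule(design)
  latents <- stats::setNames(
    sched$s_i[!duplicated(sched$mouse_id)],
    sched$mouse_id[!duplicated(sched$mouse_id)])
  wl <- sample_weight_loss(design, latents)
  recs <- list()
  for (i in seq_len(nrow(sched))) {
    row <- sched[i, ]
    mi <- match(row$mouse_id, cohort_mouse_ids(design))
    si <- match(row$session, SESSION_LABELS)
    pr <- params_for_row(design, row)
    if ("habituation" %in% phases) {
      recs[[paste(row$mouse_id, row$session, "habituation", sep = "_")]] <-
        simulate_session(pr$motion, NULL, design$habituation_duration,
                         design$arena,
                         seed = derive_seed(design$master_seed, mi, si, 1L),
                         frame_rate = design$frame_rate,
                         session = row$session, focal_id = row$mouse_id)
    }
    if ("interaction" %in% phases) {
      newcomer <- sprintf("nc_%s_%s", row$session, row$mouse_id)
      recs[[paste(row$mouse_id, row$session, "interaction", sep = "_")]] <-
        simulate_session(pr$motion, pr$social, design$interaction_duration,
                         design$arena,
                         seed = derive_seed(design$master_seed, mi, si, 2L),
                         frame_rate = design$frame_rate,
                         session = row$session, focal_id = row$mouse_id,
                         partner_id = newcomer)
    }
  }
  manifest <- cohort_manifest(data.frame(
    mouse_id = cohort_mouse_ids(design), group = cohort_groups(design),
    weight_pre_g = 25, weight_post_g = 25 - unname(wl)))
  list(manifest = manifest, recordings = recs, truth = sched, weights = wl)
}
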