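#' Simulate a cohort and compute its measures table in one pass
#'
#' Streams over the cohort: each recording is simulated (with the same
#' derived seeds as \code{\link{generate_cohort}}), run through the event
#' detectors, summarized, and discarded, so full-length cohorts fit in
#' memory. Returns the long measures table plus the manifest and the
#' true-parameter table for recovery analyses.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param params A \code{\link{detector_params}}.
#' @param phases Phases to simulate and measure (default both; use
#'   \code{"interaction"} for social-only analyses).
#' @param hab_sessions Sessions whose habituation phase is simulated
#'   (default all; restrict to e.g. S0-S2 when only baseline and early
#'   motor measures are needed).
#' @param saline_sessions Sessions simulated for the control group (default
#'   all; restrict to "S0" when controls only provide the standardization
#'   reference).
#' @return List: \code{measures}, \code{manifest}, \code{truth},
#'   \code{weights}.
#' @export
simulate_cohort_measures <- function(design, params = detector_params(),
                                     phases = c("habituation",
                                                "interaction"),
                                     hab_sessions = SESSION_LABELS,
                                     saline_sessions = SESSION_LABELS) {
  stopifnot(inherits(design, "cohort_design"))
  phases <- match.arg(phases, several.ok = TRUE)
  sched <- build_effect_schedule(design)
  latents <- stats::setNames(sched$s_i[!duplicated(sched$mouse_id)],
                             sched$mouse_id[!duplicated(sched$mouse_id)])
  wl <- sample_weight_loss(design, latents)
  ids <- cohort_mouse_ids(design)
  rows <- vector("list", nrow(sched) * length(phases))
  k <- 0L
  for (i in seq_len(nrow(sched))) {
    row <- sched[i, ]
    if (row$group == "saline" && !row$session %in% saline_sessions) next
    mi <- match(row$mouse_id, ids)
    si <- match(row$session, SESSION_LABELS)
    pr <- params_for_row(design, row)
    if ("habituation" %in% phases && row$session %in% hab_sessions) {
      rec <- simulate_session(pr$motion, NULL, design$habituation_duration,
                              design$arena,
                              seed = derive_seed(design$master_seed, mi, si, 1L),
                              frame_rate = design$frame_rate,
                              session = row$session, focal_id = row$mouse_id)
      k <- k + 1L
      rows[[k]] <- profile_recording(rec, params)
    }
    if ("interaction" %in% phases) {
      rec <- simulate_session(pr$motion, pr$social,
                              design$interaction_duration, design$arena,
                              seed = derive_seed(design$master_seed, mi, si, 2L),
                              frame_rate = design$frame_rate,
                              session = row$session, focal_id = row$mouse_id,
                              partner_id = sprintf("nc_%s_%s", row$session,
                                                   row$mouse_id))
      k <- k + 1L
      rows[[k]] <- profile_recording(rec, params)
    }
  }
  manifest <- cohort_manifest(data.frame(
    mouse_id = ids, group = cohort_groups(design),
    weight_pre_g = 25, weight_post_g = 25 - unname(wl)))
  measures <- build_measures_table(
    do.call(rbind, rows[seq_len(k)]), manifest, phases,
    check_complete = identical(hab_sessions, SESSION_LABELS) &&
      identical(saline_sessions, SESSION_LABELS))
  list(measures = measures, manifest = manifest, truth = sched,
       weights = wl)
}
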