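# Per-session behavioral profiles and the long cohort measures table.

HAB_MEASURES <- c("hab_distance_cm", "hab_center_distance_cm",
                  "hab_pct_time_center", "hab_rear_count", "hab_rear_total_s",
                  "hab_rear_mean_s")
INT_MEASURES <- c("int_distance_cm", "int_move_count",
                  "int_move_isolated_count", "int_move_in_contact_count",
                  "int_contact_count", "int_approach_count",
                  "int_follow_count", "int_break_count",
                  "int_static_dyadic_count", "int_dynamic_dyadic_count",
                  "int_total_dyadic_count")

#' Measures entering the combined social and motor Z-scores
#'
#' The combined social score averages the Z-scores of the number of
#' contacts, social approaches and total dyadic events; the combined motor
#' score averages the Z-scores of the habituation total distance, center
#' distance and rearing count.
#' @name composite_measures
#' @export
SOCIAL_MEASURES <- c("int_contact_count", "int_approach_count",
                     "int_total_dyadic_count")

#' @rdname composite_measures
#' @export
MOTOR_MEASURES <- c("hab_distance_cm", "hab_center_distance_cm",
                    "hab_rear_count")

#' Summarize a habituation session
#'
#' @param rec A habituation \code{\link{session_recording}}.
#' @param kin Its \code{"kinematics"}.
#' @param events Event table including the focal animal's rears.
#' @param arena An \code{\link{arena}} (defaults to the recording's).
#' @return Named list: total distance, center-zone distance and time
#'   percentage, rearing count, total and mean rearing durations. The
#'   identity \code{rear_mean_s * rear_count == rear_total_s} holds.
#' @export
summarize_habituation <- function(rec, kin, events, arena = rec$arena) {
  if (rec$phase != "habituation")
    stop("summarize_habituation requires a habituation recording")
  cz <- center_zone_metrics(kin, arena)
  rears <- events[events$kind == "rear" & events$focal == rec$focal_id, ]
  n <- nrow(rears)
  tot <- sum(rears$duration_s)
  list(hab_distance_cm = total_distance(kin),
       hab_center_distance_cm = cz$distance_in_center_cm,
       hab_pct_time_center = cz$pct_time_center,
       hab_rear_count = n,
       hab_rear_total_s = tot,
       hab_rear_mean_s = if (n > 0) tot / n else 0)
}

#' Summarize an interaction session
#'
#' Counts are for the given focal animal. Static dyadic events are the
#' moves in contact, stops in contact and contacts; dynamic dyadic events
#' are approaches, breaks and follows; the total is their sum, each event
#' counted once regardless of subtype.
#'
#' @param rec An interaction \code{\link{session_recording}}.
#' @param kin Its \code{"kinematics"}.
#' @param events Event table with all detectors run (moves, stops,
#'   contacts, approaches, breaks, follows).
#' @param params A \code{\link{detector_params}} (for the move-splitting
#'   minimum duration).
#' @param focal Animal to summarize (default the recording's focal).
#' @return Named list of the 11 interaction measures.
#' @export
summarize_interaction <- function(rec, kin, events,
                                  params = detector_params(),
                                  focal = rec$focal_id) {
  if (rec$phase != "interaction")
    stop("summarize_interaction requires an interaction recording")
  # moves/stops partition every frame, so a recording whose event table has
  # neither was never run through the detectors; other kinds may
  # legitimately be absent (zero events found)
  if (!any(events$kind %in% c("move", "stop")))
    stop("missing detector output: ",
         paste(setdiff(c("move", "stop", "contact", "approach", "break",
                         "follow"), unique(events$kind)), collapse = ", "))
  fm <- events$focal == focal
  ek <- events$kind
  ev <- events[fm, , drop = FALSE]
  contacts <- events[fm & ek == "contact", , drop = FALSE]
  cnt <- function(kind) sum(ek[fm] == kind)
  moves_split <- partition_moves_by_contact(events[fm & ek == "move", ],
                                            contacts, params)
  stops_split <- partition_moves_by_contact(events[fm & ek == "stop", ],
                                            contacts, params, kind = "stop")
  move_iso <- sum(moves_split$subtype == "isolated")
  move_inc <- sum(moves_split$subtype == "in_contact")
  stop_inc <- sum(stops_split$subtype == "in_contact")
  static_n <- move_inc + stop_inc + cnt("contact")
  dynamic_n <- cnt("approach") + cnt("break") + cnt("follow")
  list(int_distance_cm = total_distance(kin, focal),
       int_move_count = cnt("move"),
       int_move_isolated_count = move_iso,
       int_move_in_contact_count = move_inc,
       int_contact_count = cnt("contact"),
       int_approach_count = cnt("approach"),
       int_follow_count = cnt("follow"),
       int_break_count = cnt("break"),
       int_static_dyadic_count = static_n,
       int_dynamic_dyadic_count = dynamic_n,
       int_total_dyadic_count = static_n + dynamic_n)
}

#' Build the long cohort measures table
#'
#' Stacks per-mouse, per-session profiles into the long format
#' \code{(mouse_id, group, session, measure, value)} with deterministic
#' ordering, and checks completeness: every mouse must have every session
#' and every expected measure.
#'
#' @param rows Data frame with columns \code{mouse_id}, \code{session},
#'   \code{measure}, \code{value} (e.g. stacked profiles).
#' @param manifest A \code{\link{cohort_manifest}} supplying groups.
#' @param phases Phases whose measures are expected (default both).
#' @param check_complete Verify that every mouse x session carries every
#'   expected measure (default TRUE; disable for deliberately restricted
#'   designs).
#' @return Measures data frame ordered by (mouse, session, measure).
#' @export
build_measures_table <- function(rows, manifest,
                                 phases = c("habituation", "interaction"),
                                 check_complete = TRUE) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  expected <- c(if ("habituation" %in% phases) HAB_MEASURES,
                if ("interaction" %in% phases) INT_MEASURES)
  mice <- manifest$mice$mouse_id
  sessions <- as.character(manifest$sessions$label)
  if (check_complete) for (m in mice) for (s in sessions) {
    got <- rows$measure[rows$mouse_id == m & rows$session == s]
    miss <- setdiff(expected, got)
    if (length(miss))
      stop(sprintf("missing measures for mouse %s session %s: %s",
                   m, s, paste(miss, collapse = ", ")))
  }
  rows <- rows[rows$measure %in% expected, , drop = FALSE]
  out <- data.frame(mouse_id = rows$mouse_id,
                    group = manifest$mice$group[match(rows$mouse_id, mice)],
                    session = rows$session, measure = rows$measure,
                    value = rows$value)
  out <- out[order(out$mouse_id, out$session, out$measure), ]
  rownames(out) <- NULL
  out
}

#' Profile of one recording as long-format rows
#'
#' Runs all detectors on a recording and returns its per-session profile as
#' rows of the long measures table.
#'
#' @param rec A \code{\link{session_recording}}.
#' @param params A \code{\link{detector_params}}.
#' @param events Precomputed event table for this recording; if \code{NULL}
#'   all detectors are run.
#' @return Data frame with columns \code{mouse_id, session, measure, value}.
#' @export
profile_recording <- function(rec, params = detector_params(),
                              events = NULL) {
  if (is.null(events)) {
    det <- detect_all(rec, params, mice = rec$focal_id,
                      rears = rec$phase == "habituation")
    kin <- det$kinematics
    events <- det$events
  } else {
    kin <- compute_kinematics(rec, params)
    events <- events[events$session == rec$session &
                       events$phase == rec$phase &
                       events$focal %in% names(rec$tracks), , drop = FALSE]
  }
  prof <- if (rec$phase == "habituation")
    summarize_habituation(rec, kin, events)
  else summarize_interaction(rec, kin, events, params)
  data.frame(mouse_id = rec$focal_id, session = rec$session,
             measure = names(prof), value = unlist(prof, use.names = FALSE))
}
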