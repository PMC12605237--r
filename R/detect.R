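# Event classifiers: deterministic geometric predicates over session
# recordings, run-length encoded with shared post-processing: maximal true
# runs are encoded, runs shorter than min_event_frames are dropped, and
# surviving runs separated by at most merge_gap_frames are merged. Tracking
# gaps (NA frames) are never merged across: an event cannot span a gap.


# Fast data-frame assembly for hot paths (columns already validated).
fast_df <- function(lst) {
  n <- length(lst[[1L]])
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

# rbind for event tables sharing the canonical columns.
rbind_events <- function(lst) {
  lst <- lst[vapply(lst, nrow, integer(1)) > 0L]
  if (!length(lst)) return(empty_events())
  cols <- names(lst[[1L]])
  fast_df(stats::setNames(lapply(cols, function(cl)
    unlist(lapply(lst, `[[`, cl), use.names = FALSE)), cols))
}

# Post-process a per-frame logical predicate (NA = tracking gap) into
# half-open 0-based [start, end) runs.
predicate_runs <- function(pred, min_frames, merge_gap) {
  v <- as.integer(pred)
  v[is.na(v)] <- 2L
  m <- runs_encode_cpp(v, min_frames, merge_gap)
  fast_df(list(start = m[, 1L], end = m[, 2L]))
}

make_events <- function(kin, kind, focal, partner, runs,
                        subtype = "none") {
  n <- nrow(runs)
  if (!n) return(empty_events())
  if (length(subtype) == 1L) subtype <- rep(subtype, n)
  fast_df(list(session = rep(kin$session, n), phase = rep(kin$phase, n),
               focal = rep(focal, n), partner = rep(partner, n),
               kind = rep(kind, n), subtype = subtype,
               start_frame = as.integer(runs$start),
               end_frame = as.integer(runs$end),
               duration_s = (runs$end - runs$start) / kin$frame_rate))
}

#' Detect movement bouts and stops
#'
#' A frame belongs to a move when the smoothed speed strictly exceeds
#' \code{speed_threshold}; stops are the complement among valid frames.
#' Both are run-length encoded with the standard post-processing.
#'
#' @param kin A \code{"kinematics"} object from
#'   \code{\link{compute_kinematics}}.
#' @param params A \code{\link{detector_params}}.
#' @param mice Which animals to score (default: all tracked).
#' @return Event data frame with kinds \code{move} and \code{stop}.
#' @export
detect_movement_bouts <- function(kin, params = detector_params(),
                                  mice = names(kin$mice)) {
  out <- lapply(mice, function(id) {
    spd <- kin$mice[[id]]$speed
    moving <- spd > params$speed_threshold
    rbind_events(list(
      make_events(kin, "move", id, "",
                  predicate_runs(moving, params$min_event_frames,
                                 params$merge_gap_frames)),
      make_events(kin, "stop", id, "",
                  predicate_runs(!moving, params$min_event_frames,
                                 params$merge_gap_frames))))
  })
  rbind_events(out)
}

# Raw 3x3 skeleton distances between two mice on the grid.
# Returns list(dmin, argmin (1..9, column-major pairs focal x partner in
# order nose, center, tail)).
skeleton_distances <- function(a, b) {
  skeleton_min_cpp(cbind(a$nx, a$ny, a$cx, a$cy, a$tx, a$ty),
                   cbind(b$nx, b$ny, b$cx, b$cy, b$tx, b$ty))
}

# Decode a column-major pair index into focal / partner skeleton points.
pair_points <- function(k) {
  pts <- c("nose", "center", "tail")
  list(focal = pts[(k - 1L) %% 3L + 1L], partner = pts[(k - 1L) %/% 3L + 1L])
}

#' Detect contacts between the two animals
#'
#' A contact frame is one where the minimum distance among the nine point
#' pairs of the two three-point skeletons (nose, mass center, tail base) is
#' strictly below \code{contact_dist_cm}. Bouts are post-processed as usual
#' and labeled with their modal frame subtype: \code{nose_nose} when the
#' nose-nose pair is minimal, \code{nose_anogenital} when the focal nose to
#' partner tail-base pair is minimal, \code{side_by_side} when neither nose
#' pair is minimal and the body axes are within
#' \code{side_by_side_angle_max_deg} of parallel or antiparallel (flank
#' contact), otherwise \code{other_contact}; modal ties resolve in that
#' order. Events are emitted for both animals as focal.
#'
#' @param rec An interaction \code{\link{session_recording}}.
#' @param kin Its \code{"kinematics"}.
#' @param params A \code{\link{detector_params}}.
#' @param mice Animals to score as focal (default both).
#' @return Event data frame with kind \code{contact}.
#' @export
detect_contacts <- function(rec, kin, params = detector_params(),
                            mice = names(kin$mice)) {
  if (rec$phase != "interaction" || length(kin$mice) != 2L)
    stop("contact detection requires 2 animals")
  ids <- names(kin$mice)
  a <- kin$mice[[ids[1]]]; b <- kin$mice[[ids[2]]]
  sk <- skeleton_distances(a, b)
  pred <- sk$dmin < params$contact_dist_cm
  runs <- predicate_runs(pred, params$min_event_frames,
                         params$merge_gap_frames)
  # frame subtypes, per direction
  ang <- abs(wrap_angle(a$axis - b$axis))
  amax <- params$side_by_side_angle_max_deg * pi / 180
  parallelish <- !is.na(ang) & (ang < amax | ang > pi - amax)
  frame_subtype <- function(focal_first) {
    k <- sk$argmin
    fp <- if (focal_first) (k - 1L) %% 3L + 1L else (k - 1L) %/% 3L + 1L
    pp <- if (focal_first) (k - 1L) %/% 3L + 1L else (k - 1L) %% 3L + 1L
    st <- ifelse(parallelish, "side_by_side", "other_contact")
    st[fp == 1L & pp == 1L] <- "nose_nose"
    st[fp == 1L & pp == 3L] <- "nose_anogenital"
    st[is.na(k)] <- NA_character_
    st
  }
  modal <- function(st, runs, pred) {
    vapply(seq_len(nrow(runs)), function(i) {
      idx <- (runs$start[i] + 1L):runs$end[i]
      sub <- st[idx][!is.na(pred[idx]) & pred[idx]]
      if (!length(sub)) return("other_contact")
      lev <- c("nose_nose", "nose_anogenital", "side_by_side",
               "other_contact")
      lev[which.max(tabulate(match(sub, lev), 4L))]
    }, character(1))
  }
  out <- list()
  if (ids[1] %in% mice)
    out <- c(out, list(make_events(kin, "contact", ids[1], ids[2], runs,
                                   modal(frame_subtype(TRUE), runs, pred))))
  if (ids[2] %in% mice)
    out <- c(out, list(make_events(kin, "contact", ids[2], ids[1], runs,
                                   modal(frame_subtype(FALSE), runs, pred))))
  rbind_events(out)
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

# Per-frame logical: is `id` inside one of its own events of kind `kind`?
frames_in_events <- function(events, id, kind, nf) {
  x <- logical(nf)
  e <- events[events$focal == id & events$kind == kind, , drop = FALSE]
  for (i in seq_len(nrow(e)))
    x[(e$start_frame[i] + 1L):e$end_frame[i]] <- TRUE
  x
}

#' Detect social approaches
#'
#' An approach by the focal animal starts at the first frame where the
#' center-center distance is strictly below \code{approach_radius_bl} dyad
#' body lengths, strictly decreasing, the focal is strictly faster than the
#' partner, and the pair is not in contact. It ends at contact onset
#' (subtype \code{with_contact}), on zone exit, or once the distance has
#' stopped decreasing for \code{merge_gap_frames} consecutive frames, the
#' event then ending at the first non-decreasing frame (subtype
#' \code{without_contact}). An approach truncated by a tracking gap or by
#' the end of the recording ends there, \code{without_contact}. Both
#' animals are scored as focal independently.
#'
#' @param rec An interaction \code{\link{session_recording}}.
#' @param kin Its \code{"kinematics"}.
#' @param contacts Contact events from \code{\link{detect_contacts}}.
#' @param params A \code{\link{detector_params}}.
#' @return Event data frame with kind \code{approach}.
#' @export
detect_approaches <- function(rec, kin, contacts, params = detector_params(),
                              mice = names(kin$mice)) {
  if (rec$phase != "interaction" || length(kin$mice) != 2L)
    stop("approach detection requires 2 animals")
  if (missing(contacts) || is.null(contacts))
    stop("approach detection requires the contact events")
  ids <- names(kin$mice)
  a <- kin$mice[[ids[1]]]; b <- kin$mice[[ids[2]]]
  d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
  radius <- params$approach_radius_bl * dyad_body_length(kin)
  out <- lapply(intersect(ids, mice), function(id) {
    other <- setdiff(ids, id)
    inc <- frames_in_events(contacts, id, "contact", kin$n_frames)
    m <- scan_approaches_cpp(d, inc, kin$mice[[id]]$speed,
                             kin$mice[[other]]$speed, radius,
                             params$merge_gap_frames,
                             params$min_event_frames)
    make_events(kin, "approach", id, other,
                data.frame(start = m[, "start"], end = m[, "end"]),
                ifelse(m[, "with_contact"] == 1L, "with_contact",
                       "without_contact"))
  })
  rbind_events(out)
}

#' Detect contact breaks
#'
#' A break by the focal animal starts at a contact end frame if, over the
#' following \code{min_event_frames} frames, the center-center distance is
#' strictly increasing and the focal is strictly faster than the partner at
#' every frame; it then extends while both conditions hold. At most one
#' break per contact end per focal.
#'
#' @inheritParams detect_approaches
#' @return Event data frame with kind \code{break}.
#' @export
detect_breaks <- function(rec, kin, contacts, params = detector_params(),
                          mice = names(kin$mice)) {
  if (rec$phase != "interaction" || length(kin$mice) != 2L)
    stop("break detection requires 2 animals")
  ids <- names(kin$mice)
  a <- kin$mice[[ids[1]]]; b <- kin$mice[[ids[2]]]
  d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
  nf <- kin$n_frames
  out <- lapply(intersect(ids, mice), function(id) {
    other <- setdiff(ids, id)
    sf <- kin$mice[[id]]$speed
    sp <- kin$mice[[other]]$speed
    # per-frame departure condition (0-based frame t at index t + 1)
    ok <- c(FALSE, d[-1L] > d[-nf] & sf[-1L] > sp[-1L])
    ok[is.na(ok)] <- FALSE
    ce <- contacts[contacts$focal == id & contacts$kind == "contact", ]
    runs <- list()
    for (e in ce$end_frame) {
      if (e + params$min_event_frames > nf) next
      if (!all(ok[(e + 1L):(e + params$min_event_frames)])) next
      t <- e + params$min_event_frames
      while (t < nf && ok[t + 1L]) t <- t + 1L
      runs[[length(runs) + 1L]] <- fast_df(list(start = e, end = t))
    }
    make_events(kin, "break", id, other,
                if (length(runs)) do.call(rbind, runs)
                else fast_df(list(start = integer(), end = integer())))
  })
  rbind_events(out)
}

#' Detect follows
#'
#' A follow frame requires both animals strictly faster than
#' \code{speed_threshold}, headings strictly less than
#' \code{follow_heading_max_deg} apart, and the focal mass center strictly
#' inside the follow zone: a rectangle of width \code{follow_zone_w_bl} and
#' length \code{follow_zone_l_bl} dyad body lengths anchored at the leader's
#' mass center and extending backward along the leader's heading. Runs are
#' post-processed as usual; both animals are scored as focal.
#'
#' @inheritParams detect_approaches
#' @return Event data frame with kind \code{follow}.
#' @export
detect_follows <- function(rec, kin, params = detector_params(),
                           mice = names(kin$mice)) {
  if (rec$phase != "interaction" || length(kin$mice) != 2L)
    stop("follow detection requires 2 animals")
  ids <- names(kin$mice)
  L <- dyad_body_length(kin)
  hmax <- params$follow_heading_max_deg * pi / 180
  out <- lapply(intersect(ids, mice), function(id) {
    other <- setdiff(ids, id)
    f <- kin$mice[[id]]; l <- kin$mice[[other]]
    rx <- f$cx - l$cx; ry <- f$cy - l$cy
    ux <- cos(l$heading); uy <- sin(l$heading)
    along <- -(rx * ux + ry * uy)
    across <- rx * (-uy) + ry * ux
    pred <- f$speed > params$speed_threshold &
      l$speed > params$speed_threshold &
      abs(wrap_angle(f$heading - l$heading)) < hmax &
      along > 0 & along < params$follow_zone_l_bl * L &
      abs(across) < params$follow_zone_w_bl * L / 2
    make_events(kin, "follow", id, other,
                predicate_runs(pred, params$min_event_frames,
                               params$merge_gap_frames))
  })
  rbind_events(out)
}

#' Detect rearing episodes
#'
#' Frames whose posture channel strictly exceeds
#' \code{rear_posture_threshold}, run-length encoded with the standard
#' post-processing.
#'
#' @param rec A \code{\link{session_recording}} whose tracks carry a posture
#'   channel.
#' @param params A \code{\link{detector_params}}.
#' @param mice Which animals to score (default all).
#' @return Event data frame with kind \code{rear}.
#' @export
detect_rearings <- function(rec, params = detector_params(),
                            mice = names(rec$tracks)) {
  kinless <- lapply(mice, function(id) {
    tr <- rec$tracks[[id]]
    if (all(is.na(tr$posture)))
      stop("posture channel absent for '", id,
           "'; supply a synthetic posture channel or external rear labels")
    g <- track_on_grid(rec, id)
    pred <- g[, "posture"] > params$rear_posture_threshold
    runs <- predicate_runs(pred, params$min_event_frames,
                           params$merge_gap_frames)
    n <- nrow(runs)
    if (!n) return(empty_events())
    fast_df(list(session = rep(rec$session, n), phase = rep(rec$phase, n),
                 focal = rep(id, n), partner = rep("", n),
                 kind = rep("rear", n), subtype = rep("none", n),
                 start_frame = as.integer(runs$start),
                 end_frame = as.integer(runs$end),
                 duration_s = (runs$end - runs$start) / rec$frame_rate))
  })
  rbind_events(kinless)
}

#' Split movement bouts by contact intervals
#'
#' Each move event is split at the boundaries of the focal's contact
#' intervals; a fragment is \code{in_contact} iff every frame lies inside
#' some contact interval, otherwise \code{isolated}. Fragments shorter than
#' \code{min_event_frames} are dropped.
#'
#' @param moves Move events (kind \code{move}; \code{kind} below selects
#'   another kind, e.g. stops).
#' @param contacts Contact events from the same recording.
#' @param params A \code{\link{detector_params}}.
#' @param kind Event kind to split (default \code{"move"}).
#' @return Event data frame of the selected kind with subtypes
#'   \code{isolated} / \code{in_contact}.
#' @export
partition_moves_by_contact <- function(moves, contacts,
                                       params = detector_params(),
                                       kind = "move") {
  moves <- moves[moves$kind == kind, , drop = FALSE]
  contacts <- contacts[contacts$kind == "contact", , drop = FALSE]
  for (ev in list(moves, contacts)) {
    for (id in unique(ev$focal)) {
      e <- ev[ev$focal == id, , drop = FALSE]
      o <- order(e$start_frame)
      if (nrow(e) > 1L &&
          any(e$start_frame[o][-1L] < e$end_frame[o][-nrow(e)]))
        stop("overlapping events of one kind for '", id,
             "': upstream invariant violated")
    }
  }
  if (!nrow(moves)) return(empty_events())
  out <- list()
  for (id in unique(moves$focal)) {
    mv <- moves[moves$focal == id, , drop = FALSE]
    cc <- contacts[contacts$focal == id, , drop = FALSE]
    nf <- max(mv$end_frame, cc$end_frame, 0L)
    inc <- integer(nf)
    for (j in seq_len(nrow(cc)))
      inc[(cc$start_frame[j] + 1L):cc$end_frame[j]] <- 1L
    lab <- integer(nf)
    for (i in seq_len(nrow(mv)))
      lab[(mv$start_frame[i] + 1L):mv$end_frame[i]] <- i
    fr <- (mv$end_frame[1] - mv$start_frame[1]) / mv$duration_s[1]
    # one run-length pass over (move index, in-contact) fragments
    r <- rle(lab * 2L + inc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values >= 2L & r$lengths >= params$min_event_frames
    if (!any(keep)) next
    src <- r$values[keep] %/% 2L
    in_all <- r$values[keep] %% 2L == 1L
    out[[length(out) + 1L]] <- fast_df(list(
      session = mv$session[src], phase = mv$phase[src],
      focal = rep(id, sum(keep)), partner = mv$partner[src],
      kind = rep(kind, sum(keep)),
      subtype = ifelse(in_all, "in_contact", "isolated"),
      start_frame = as.integer(starts[keep]),
      end_frame = as.integer(ends[keep]),
      duration_s = (ends[keep] - starts[keep]) / fr))
  }
  rbind_events(out)
}

#' Center-zone occupancy metrics
#'
#' Per-frame membership of the smoothed mass center in the arena center
#' zone. Distance accumulates only displacement between consecutive
#' in-center frames; the percentage uses all valid (tracked, speed-bearing)
#' frames.
#'
#' @param kin A \code{"kinematics"} object.
#' @param arena An \code{\link{arena}}.
#' @param mouse Animal id (default the focal).
#' @return List with \code{distance_in_center_cm}, \code{time_in_center_s},
#'   \code{pct_time_center}.
#' @export
center_zone_metrics <- function(kin, arena, mouse = kin$focal_id) {
  m <- kin$mice[[mouse]]
  if (is.null(m)) stop("no such track: ", mouse)
  inc <- in_center(m$sx, m$sy, arena)
  valid <- !is.na(m$sx)
  n <- kin$n_frames
  disp <- sqrt(diff(m$sx)^2 + diff(m$sy)^2)
  both_in <- inc[-n] & inc[-1L]
  dist_c <- sum(disp[which(both_in)], na.rm = TRUE)
  list(distance_in_center_cm = dist_c,
       time_in_center_s = sum(inc, na.rm = TRUE) / kin$frame_rate,
       pct_time_center = 100 * sum(inc, na.rm = TRUE) / sum(valid))
}

#' Total path length of an animal
#'
#' Sum of smoothed per-frame displacements over valid consecutive frames.
#' @param kin A \code{"kinematics"} object.
#' @param mouse Animal id (default the focal).
#' @return Distance in cm.
#' @export
total_distance <- function(kin, mouse = kin$focal_id) {
  m <- kin$mice[[mouse]]
  sum(sqrt(diff(m$sx)^2 + diff(m$sy)^2), na.rm = TRUE)
}

#' Run every detector applicable to a recording
#'
#' @param rec A \code{\link{session_recording}}.
#' @param params A \code{\link{detector_params}}.
#' @param mice Animals to score as focal (default all tracked).
#' @param rears Include rearing detection (default TRUE).
#' @return List with the \code{"kinematics"} object and the combined event
#'   data frame (moves, stops and rears per scored animal; contacts,
#'   approaches, breaks and follows for interaction recordings).
#' @export
detect_all <- function(rec, params = detector_params(),
                       mice = names(rec$tracks), rears = TRUE) {
  kin <- compute_kinematics(rec, params)
  ev <- list(detect_movement_bouts(kin, params, mice))
  if (rears) ev <- c(ev, list(detect_rearings(rec, params, mice)))
  if (rec$phase == "interaction") {
    contacts <- detect_contacts(rec, kin, params, mice)
    ev <- c(ev, list(contacts,
                     detect_approaches(rec, kin, contacts, params, mice),
                     detect_breaks(rec, kin, contacts, params, mice),
                     detect_follows(rec, kin, params, mice)))
  }
  events <- rbind_events(ev)
  list(kinematics = kin, events = events)
}
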