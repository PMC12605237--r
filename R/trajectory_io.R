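TRAJ_HEADER <- c("session", "phase", "frame", "t_s", "mouse_id",
                 "cx", "cy", "nx", "ny", "tx", "ty", "posture")
EVENT_HEADER <- c("session", "phase", "focal", "partner", "kind", "subtype",
                  "start_frame", "end_frame", "duration_s")
MEASURE_HEADER <- c("mouse_id", "group", "session", "measure", "value")

#' Read a trajectory file into a session recording
#'
#' Reads the tabular trajectory dialect (columns \code{session, phase,
#' frame, t_s, mouse_id, cx, cy, nx, ny, tx, ty, posture}; one row per mouse
#' per frame) for a single session. Rows may appear in any order; they are
#' canonicalized by (mouse, frame). Gaps in a track are recorded as missing
#' frames, never interpolated.
#'
#' @param path Path to the CSV file.
#' @param arena An \code{\link{arena}}.
#' @param focal_id Focal mouse id; defaults to the first id in the file.
#' @param frame_rate Acquisition rate in Hz; if \code{NULL}, recovered from
#'   the \code{frame}/\code{t_s} columns.
#' @param max_missing Maximal tolerated fraction of missing frames per track
#'   (default 0.1); beyond it reading fails naming the track.
#' @return A \code{\link{session_recording}}.
#' @export
read_trajectories <- function(path, arena = dyadtrack::arena(),
                              focal_id = NULL, frame_rate = NULL,
                              max_missing = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), TRAJ_HEADER))
    stop("malformed trajectory header in ", path, "; expected: ",
         paste(TRAJ_HEADER, collapse = ","))
  if (!nrow(df)) stop("empty trajectory file: ", path)
  session <- unique(df$session)
  phase <- unique(df$phase)
  if (length(session) != 1L || length(phase) != 1L)
    stop("a trajectory file must contain exactly one session and phase")
  df <- df[order(df$mouse_id, df$frame), ]
  ids <- unique(df$mouse_id)
  if (is.null(frame_rate)) {
    d <- df[df$mouse_id == ids[1], ]
    if (nrow(d) < 2L) stop("cannot recover frame rate from a 1-frame track")
    frame_rate <- 1 / stats::median(diff(d$t_s) / diff(d$frame))
  }
  tracks <- lapply(ids, function(id) {
    d <- df[df$mouse_id == id, ]
    data.frame(frame = as.integer(d$frame), t = d$t_s, cx = d$cx, cy = d$cy,
               nx = d$nx, ny = d$ny, tx = d$tx, ty = d$ty,
               posture = d$posture)
  })
  names(tracks) <- ids
  nf <- max(df$frame) + 1L
  for (id in ids) {
    miss <- 1 - nrow(tracks[[id]]) / nf
    if (miss > max_missing)
      stop(sprintf("track '%s' has %.1f%% missing frames (limit %.0f%%)",
                   id, 100 * miss, 100 * max_missing))
  }
  if (is.null(focal_id)) focal_id <- ids[1]
  session_recording(session, phase, frame_rate, arena, tracks, focal_id)
}

#' Write a session recording to the trajectory dialect
#'
#' @param rec A \code{\link{session_recording}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  rows <- lapply(names(rec$tracks), function(id) {
    tr <- rec$tracks[[id]]
    data.frame(session = rec$session, phase = rec$phase, frame = tr$frame,
               t_s = tr$t, mouse_id = id, cx = tr$cx, cy = tr$cy,
               nx = tr$nx, ny = tr$ny, tx = tr$tx, ty = tr$ty,
               posture = tr$posture)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$mouse_id, df$frame), ]
  write_csv_checked(df, path)
  invisible(path)
}

#' An empty event table
#'
#' @return Zero-row data frame with the canonical event columns.
#' @export
empty_events <- function() {
  data.frame(session = character(), phase = character(), focal = character(),
             partner = character(), kind = character(), subtype = character(),
             start_frame = integer(), end_frame = integer(),
             duration_s = numeric())
}

#' Write an event or measures table
#'
#' Writes either an event table (columns \code{session, phase, focal,
#' partner, kind, subtype, start_frame, end_frame, duration_s}) or a long
#' measures table (columns \code{mouse_id, group, session, measure, value})
#' with a deterministic column and row order, so that re-reading reproduces
#' the records exactly.
#'
#' @param records Event or measures data frame.
#' @param path Output path.
#' @param allow_empty Permit writing a zero-row table (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (!nrow(records) && !allow_empty)
    stop("refusing to write an empty table without allow_empty = TRUE")
  if (all(EVENT_HEADER %in% names(records))) {
    records <- records[EVENT_HEADER]
    o <- order(records$focal, records$session, records$start_frame,
               records$kind, records$end_frame, records$subtype)
  } else if (all(MEASURE_HEADER %in% names(records))) {
    records <- records[MEASURE_HEADER]
    o <- order(records$mouse_id, records$session, records$measure)
  } else stop("records are neither an event nor a measures table")
  write_csv_checked(records[o, , drop = FALSE], path)
  invisible(path)
}

#' Read an event table
#' @param path Path to an events CSV.
#' @return Event data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(partner = "character"))
  if (!identical(names(df), EVENT_HEADER))
    stop("malformed event header in ", path)
  df$partner[is.na(df$partner)] <- ""
  df
}

#' Read a long measures table
#' @param path Path to a measures CSV.
#' @return Measures data frame.
#' @export
read_measures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), MEASURE_HEADER))
    stop("malformed measures header in ", path)
  df
}

write_csv_checked <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort manifest
#'
#' The manifest lists the mice (id, group, pre- and post-treatment weights)
#' and the ordered session schedule with phase tags, as a YAML key-value
#' file.
#'
#' @param manifest A \code{"cohort_manifest"} object (see
#'   \code{\link{cohort_manifest}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  obj <- list(mice = lapply(seq_len(nrow(manifest$mice)), function(i)
                as.list(manifest$mice[i, ])),
              sessions = lapply(seq_len(nrow(manifest$sessions)), function(i)
                as.list(manifest$sessions[i, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a cohort manifest
#' @param path Path to a manifest YAML file.
#' @return A \code{"cohort_manifest"} object.
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  mice <- do.call(rbind, lapply(obj$mice, as.data.frame))
  sessions <- do.call(rbind, lapply(obj$sessions, as.data.frame))
  cohort_manifest(mice, sessions)
}

#' Cohort manifest
#'
#' @param mice Data frame with columns \code{mouse_id}, \code{group} (one of
#'   "saline", "morphine"), \code{weight_pre_g}, \code{weight_post_g}.
#' @param sessions Data frame with columns \code{label} (S0..S5) and
#'   \code{phase_tag} (baseline/early/late); defaults to the canonical
#'   schedule.
#' @return An object of class \code{"cohort_manifest"}. Weight loss per
#'   mouse is defined as \code{weight_pre_g - weight_post_g}.
#' @export
cohort_manifest <- function(mice,
                            sessions = data.frame(
                              label = SESSION_LABELS,
                              phase_tag = unname(SESSION_PHASE_TAGS))) {
  stopifnot(is.data.frame(mice),
            all(c("mouse_id", "group", "weight_pre_g", "weight_post_g") %in%
                  names(mice)))
  if (!all(mice$group %in% c("saline", "morphine")))
    stop("groups must be 'saline' or 'morphine'")
  if (!any(mice$group == "saline") || !any(mice$group == "morphine"))
    stop("both groups must be nonempty")
  if (!identical(as.character(sessions$label), SESSION_LABELS))
    stop("sessions must be S0..S5 in order")
  rownames(mice) <- NULL
  rownames(sessions) <- NULL
  structure(list(mice = mice, sessions = sessions),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("Cohort manifest: %d mice (%d morphine, %d saline), %d sessions\n",
              nrow(x$mice), sum(x$mice$group == "morphine"),
              sum(x$mice$group == "saline"), nrow(x$sessions)))
  invisible(x)
}

#' Per-mouse weight loss from a manifest
#' @param manifest A \code{"cohort_manifest"}.
#' @return Named numeric vector, \code{weight_pre_g - weight_post_g} per
#'   mouse (grams).
#' @export
weight_loss <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  stats::setNames(manifest$mice$weight_pre_g - manifest$mice$weight_post_g,
                  manifest$mice$mouse_id)
}
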