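#' Session recording of one or two tracked mice
#'
#' Container for the per-frame poses of one (habituation phase) or two
#' (interaction phase) identified animals in a bounded arena. Each track is a
#' data frame with columns \code{frame} (0-based), \code{t} (s), \code{cx},
#' \code{cy} (mass center), \code{nx}, \code{ny} (nose), \code{tx}, \code{ty}
#' (tail base), all in cm, and \code{posture} (unitless posture-height
#' channel, >= 0). Frames must be strictly increasing within a track; missing
#' frames are allowed and are treated as gaps that no event may span.
#'
#' @param session Session label, one of "S0".."S5".
#' @param phase Either "habituation" or "interaction".
#' @param frame_rate Acquisition rate in Hz.
#' @param arena An \code{\link{arena}}.
#' @param tracks Named list (by mouse id) of track data frames.
#' @param focal_id Id of the focal animal; must name a track.
#' @param partner_id Id of the partner, or \code{NULL} for habituation.
#' @return An object of class \code{"session_recording"}.
#' @export
session_recording <- function(session, phase, frame_rate, arena, tracks,
                              focal_id, partner_id = NULL) {
  phase <- match.arg(phase, c("habituation", "interaction"))
  if (!inherits(arena, "arena")) stop("arena must be an 'arena' object")
  if (!is.list(tracks) || is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list")
  n_expected <- if (phase == "habituation") 1L else 2L
  if (length(tracks) != n_expected)
    stop(sprintf("%s recordings must have exactly %d track(s), got %d",
                 phase, n_expected, length(tracks)))
  needed <- c("frame", "t", "cx", "cy", "nx", "ny", "tx", "ty", "posture")
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    if (!is.data.frame(tr) || !all(needed %in% names(tr)))
      stop("track '", id, "' lacks required columns")
    if (anyDuplicated(tr$frame))
      stop(sprintf("track '%s': duplicated frame_index %d", id,
                   tr$frame[anyDuplicated(tr$frame)]))
    if (is.unsorted(tr$frame, strictly = TRUE))
      stop("track '", id, "': frames must be strictly increasing")
    if (nrow(tr) > 1L && any(diff(tr$t) <= 0)) {
      bad <- tr$frame[which(diff(tr$t) <= 0)[1] + 1L]
      stop(sprintf("track '%s': non-monotone timestamps at frame %d", id, bad))
    }
    tracks[[id]] <- tr[needed]
  }
  if (!focal_id %in% names(tracks)) stop("focal_id must name a track")
  if (phase == "interaction") {
    if (is.null(partner_id)) partner_id <- setdiff(names(tracks), focal_id)[1]
    if (!partner_id %in% names(tracks)) stop("partner_id must name a track")
  } else partner_id <- NULL
  structure(list(session = as.character(session), phase = phase,
                 frame_rate = as.numeric(frame_rate), arena = arena,
                 tracks = tracks, focal_id = as.character(focal_id),
                 partner_id = if (is.null(partner_id)) NULL else
                   as.character(partner_id)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("Session recording %s (%s), %g Hz, %d frame grid\n",
              x$session, x$phase, x$frame_rate, n_frames(x)))
  for (id in names(x$tracks))
    cat(sprintf("  track %s%s: %d samples\n", id,
                if (identical(id, x$focal_id)) " (focal)" else "",
                nrow(x$tracks[[id]])))
  invisible(x)
}

#' Number of frames on the session frame grid
#'
#' The frame grid spans 0 .. max(frame) over all tracks.
#' @param rec A \code{\link{session_recording}}.
#' @return Integer grid length.
#' @export
n_frames <- function(rec) {
  max(vapply(rec$tracks, function(tr) max(tr$frame), numeric(1))) + 1L
}

# A track aligned on the session frame grid: matrix n_frames x 9 with columns
# t, cx, cy, nx, ny, tx, ty, posture, present; NA rows at missing frames.
track_on_grid <- function(rec, id) {
  tr <- rec$tracks[[id]]
  if (is.null(tr)) stop("no track '", id, "'")
  nf <- n_frames(rec)
  m <- matrix(NA_real_, nrow = nf, ncol = 8,
              dimnames = list(NULL, c("t", "cx", "cy", "nx", "ny", "tx",
                                      "ty", "posture")))
  m[tr$frame + 1L, ] <- as.matrix(tr[c("t", "cx", "cy", "nx", "ny", "tx",
                                       "ty", "posture")])
  m
}

#' Validate a session recording
#'
#' Reports out-of-arena excursions (beyond a 1 cm tolerance), gaps in the
#' frame grid, and degenerate poses (nose coinciding with tail base). A
#' recording is clean iff the report has zero rows.
#'
#' @param rec A \code{\link{session_recording}}.
#' @return A data frame with columns \code{finding}, \code{mouse_id},
#'   \code{start_frame}, \code{end_frame} (half-open), \code{detail}.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  tol <- 1
  side <- rec$arena$side_cm
  out <- list()
  nf <- n_frames(rec)
  for (id in names(rec$tracks)) {
    tr <- rec$tracks[[id]]
    xy <- as.matrix(tr[c("cx", "cy", "nx", "ny", "tx", "ty")])
    oob <- which(apply(xy < -tol | xy > side + tol, 1, any))
    for (i in oob)
      out[[length(out) + 1L]] <- data.frame(
        finding = "out_of_bounds", mouse_id = id,
        start_frame = tr$frame[i], end_frame = tr$frame[i] + 1L,
        detail = sprintf("coordinate outside [%g, %g]", -tol, side + tol))
    present <- logical(nf)
    present[tr$frame + 1L] <- TRUE
    gaps <- runs_of(!present)
    for (k in seq_len(nrow(gaps)))
      out[[length(out) + 1L]] <- data.frame(
        finding = "gap", mouse_id = id,
        start_frame = gaps$start[k], end_frame = gaps$end[k],
        detail = sprintf("%d missing frame(s)", gaps$end[k] - gaps$start[k]))
    degen <- which(tr$nx == tr$tx & tr$ny == tr$ty)
    for (i in degen)
      out[[length(out) + 1L]] <- data.frame(
        finding = "degenerate_pose", mouse_id = id,
        start_frame = tr$frame[i], end_frame = tr$frame[i] + 1L,
        detail = "nose coincides with tail base")
  }
  if (!length(out))
    return(data.frame(finding = character(), mouse_id = character(),
                      start_frame = integer(), end_frame = integer(),
                      detail = character()))
  do.call(rbind, out)
}

# Runs of TRUE in a logical vector, as half-open 0-based [start, end) frames.
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}
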