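#' Per-frame kinematics of a session recording
#'
#' Computes, for every animal on the session frame grid: the mass center
#' smoothed by a centered moving average (window truncated at the ends of
#' each contiguous tracked segment), the speed as the norm of the smoothed
#' per-frame displacement times the frame rate, the heading as the direction
#' of that displacement (falling back to the tail-to-nose body axis when the
#' displacement is below \code{heading_min_disp_cm}), and the session body
#' length as the median nose to tail-base distance. Frames adjacent to
#' tracking gaps carry no speed.
#'
#' @param rec A \code{\link{session_recording}}.
#' @param params A \code{\link{detector_params}}.
#' @return An object of class \code{"kinematics"}: per-mouse speed and
#'   heading vectors on the frame grid, smoothed coordinates, presence mask
#'   and body length, plus session metadata.
#' @export
compute_kinematics <- function(rec, params = detector_params()) {
  stopifnot(inherits(rec, "session_recording"),
            inherits(params, "detector_params"))
  nf <- n_frames(rec)
  w <- params$smoothing_window_frames
  mice <- lapply(names(rec$tracks), function(id) {
    g <- track_on_grid(rec, id)
    present <- !is.na(g[, "cx"])
    if (sum(present) < w)
      stop(sprintf("track '%s' is shorter than the smoothing window", id))
    sx <- rep(NA_real_, nf)
    sy <- rep(NA_real_, nf)
    segs <- runs_of(present)
    for (k in seq_len(nrow(segs))) {
      idx <- (segs$start[k] + 1L):segs$end[k]
      sx[idx] <- roll_mean_trunc(g[idx, "cx"], w)
      sy[idx] <- roll_mean_trunc(g[idx, "cy"], w)
    }
    dx <- c(NA_real_, diff(sx))
    dy <- c(NA_real_, diff(sy))
    disp <- sqrt(dx^2 + dy^2)
    speed <- disp * rec$frame_rate
    axis <- atan2(g[, "ny"] - g[, "ty"], g[, "nx"] - g[, "tx"])
    heading <- ifelse(!is.na(disp) & disp >= params$heading_min_disp_cm,
                      atan2(dy, dx), axis)
    bl <- stats::median(sqrt((g[, "nx"] - g[, "tx"])^2 +
                               (g[, "ny"] - g[, "ty"])^2), na.rm = TRUE)
    if (!is.finite(bl) || bl <= 0)
      stop(sprintf("track '%s' has no usable body-length samples", id))
    list(speed = speed, heading = heading, sx = sx, sy = sy,
         cx = g[, "cx"], cy = g[, "cy"], nx = g[, "nx"], ny = g[, "ny"],
         tx = g[, "tx"], ty = g[, "ty"], posture = g[, "posture"],
         axis = axis, present = present, body_length = bl)
  })
  names(mice) <- names(rec$tracks)
  structure(list(mice = mice, n_frames = nf, frame_rate = rec$frame_rate,
                 session = rec$session, phase = rec$phase,
                 focal_id = rec$focal_id, partner_id = rec$partner_id),
            class = "kinematics")
}

# Centered rolling mean with truncated windows at the vector ends.
# For window w the half-widths are floor((w-1)/2) left and floor(w/2) right.
roll_mean_trunc <- function(x, w) {
  roll_mean_cpp(x, as.integer(w))
}

#' Dyad mean body length
#'
#' Mean of the two animals' per-session median body lengths; the unit for
#' body-length-scaled detector thresholds.
#' @param kin A \code{"kinematics"} object from an interaction recording.
#' @return Length in cm.
#' @export
dyad_body_length <- function(kin) {
  stopifnot(inherits(kin, "kinematics"))
  if (length(kin$mice) != 2L)
    stop("dyad body length requires 2 animals")
  mean(vapply(kin$mice, `[[`, numeric(1), "body_length"))
}
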