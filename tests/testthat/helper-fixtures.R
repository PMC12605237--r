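# Fixture builders: recordings constructed analytically in code.

# A track data frame from coordinate vectors; nose/tail default to a body
# axis along +x of length 2 cm centered on the mass center.
make_track <- function(cx, cy, frame_rate = 30, frames = seq_along(cx) - 1L,
                       nx = cx + 1, ny = cy, tx = cx - 1, ty = cy,
                       posture = 0) {
  n <- length(cx)
  data.frame(frame = frames, t = frames / frame_rate,
             cx = cx, cy = cy, nx = nx, ny = ny, tx = tx, ty = ty,
             posture = rep_len(posture, n))
}

make_rec <- function(tracks, phase = if (length(tracks) == 1L)
                       "habituation" else "interaction",
                     frame_rate = 30, arena = dyadtrack::arena(),
                     session = "S0", focal_id = names(tracks)[1]) {
  session_recording(session, phase, frame_rate, arena, tracks, focal_id)
}

# Solo mouse moving in a straight line at constant speed (cm/s) along +x,
# bouncing is not handled: keep within the arena.
straight_rec <- function(speed, duration = 10, frame_rate = 30, y = 25,
                         x0 = 2, phase = "habituation") {
  n <- round(duration * frame_rate)
  cx <- x0 + speed * (seq_len(n) - 1L) / frame_rate
  make_rec(list(m1 = make_track(cx, rep(y, n), frame_rate)),
           phase = phase, frame_rate = frame_rate)
}

# Dyad recording from two coordinate paths (and optional axes).
dyad_rec <- function(t1, t2, frame_rate = 30,
                     arena = dyadtrack::arena()) {
  make_rec(list(A = t1, B = t2), phase = "interaction",
           frame_rate = frame_rate, arena = arena)
}

# Small measures table for the z-score layer: values indexed by mouse,
# session, measure through a deterministic function or explicit frame.
toy_measures <- function(n_m = 3, n_s = 3, measures = c("m1", "m2"),
                         fun = function(mouse, session, measure)
                           10 * measure + session + mouse / 10) {
  mice <- c(sprintf("mo%02d", seq_len(n_m)), sprintf("sa%02d", seq_len(n_s)))
  groups <- c(rep("morphine", n_m), rep("saline", n_s))
  rows <- expand.grid(mouse_id = mice, session = paste0("S", 0:5),
                      measure = measures, stringsAsFactors = FALSE)
  rows$group <- groups[match(rows$mouse_id, mice)]
  rows$value <- mapply(fun, match(rows$mouse_id, mice),
                       match(rows$session, paste0("S", 0:5)),
                       match(rows$measure, measures))
  rows[c("mouse_id", "group", "session", "measure", "value")]
}

toy_manifest <- function(n_m = 3, n_s = 3, loss_m = 3, loss_s = 0) {
  mice <- c(sprintf("mo%02d", seq_len(n_m)), sprintf("sa%02d", seq_len(n_s)))
  cohort_manifest(data.frame(
    mouse_id = mice,
    group = c(rep("morphine", n_m), rep("saline", n_s)),
    weight_pre_g = 25,
    weight_post_g = 25 - c(rep(loss_m, n_m), rep(loss_s, n_s))))
}

# Random event table for I/O round-trips.
random_events <- function(n, seed = 1) {
  set.seed(seed)
  kinds <- c("move", "stop", "contact", "approach", "break", "follow", "rear")
  start <- sort(sample.int(10000, n))
  len <- sample(3:50, n, replace = TRUE)
  data.frame(session = sample(paste0("S", 0:5), n, TRUE),
             phase = "interaction",
             focal = sample(c("A", "B"), n, TRUE),
             partner = sample(c("A", "B", ""), n, TRUE),
             kind = sample(kinds, n, TRUE),
             subtype = sample(c("none", "nose_nose", "with_contact"), n, TRUE),
             start_frame = start, end_frame = start + len,
             duration_s = len / 30)
}
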