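dp <- detector_params()

test_that("movement bouts respect the strict speed threshold", {
  # constant speed exactly at the threshold: the strict gate yields no moves
  kin5 <- structure(list(mice = list(m = list(speed = c(NA, rep(5, 99)))),
                         n_frames = 100L, frame_rate = 30, session = "S0",
                         phase = "habituation", focal_id = "m",
                         partner_id = NULL),
                    class = "kinematics")
  ev <- detect_movement_bouts(kin5)
  expect_equal(sum(ev$kind == "move"), 0L)
  expect_equal(sum(ev$kind == "stop"), 1L)
  # constant 8 cm/s for 300 frames: exactly one move over the valid frames
  rec <- straight_rec(8, duration = 10, frame_rate = 30, x0 = 2)
  ev <- detect_movement_bouts(compute_kinematics(rec))
  mv <- ev[ev$kind == "move", ]
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$start_frame, 3L)
  expect_equal(mv$end_frame, 298L)
  # alternating 10/0 every frame: all runs shorter than min duration
  x <- cumsum(c(0, rep(c(10 / 30, 0), 100)))
  rec <- make_rec(list(m = make_track(2 + x, rep(25, length(x)))))
  p1 <- detector_params(smoothing_window_frames = 1)
  ev <- detect_movement_bouts(compute_kinematics(rec, p1), p1)
  expect_equal(sum(ev$kind == "move"), 0L)
})

test_that("contact subtypes follow the minimal-pair geometry", {
  n <- 30
  # head-on, nose to nose 1 cm apart
  a <- make_track(rep(10, n), rep(10, n), nx = rep(11.5, n), ny = rep(10, n),
                  tx = rep(8.5, n), ty = rep(10, n))
  b <- make_track(rep(14, n), rep(10, n), nx = rep(12.5, n), ny = rep(10, n),
                  tx = rep(15.5, n), ty = rep(10, n))
  ev <- detect_contacts(r <- dyad_rec(a, b), compute_kinematics(r))
  expect_equal(nrow(ev), 2L)  # one per focal
  expect_true(all(ev$subtype == "nose_nose"))
  expect_equal(ev$start_frame, c(0L, 0L))
  expect_equal(ev$end_frame, c(n, n))
  # parallel, flank distance 1.5 cm, axes 10 degrees apart
  th <- 10 * pi / 180
  b2 <- make_track(rep(10, n), rep(11.5, n),
                   nx = 10 + cos(th), ny = 11.5 + sin(th),
                   tx = 10 - cos(th), ty = 11.5 - sin(th))
  ev2 <- detect_contacts(r2 <- dyad_rec(a, b2), compute_kinematics(r2))
  expect_true(all(ev2$subtype == "side_by_side"))
  # mice far apart: no contacts
  b3 <- make_track(rep(40, n), rep(40, n))
  ev3 <- detect_contacts(r3 <- dyad_rec(a, b3), compute_kinematics(r3))
  expect_equal(nrow(ev3), 0L)
  # habituation recordings are refused
  hab <- make_rec(list(m = a))
  expect_error(detect_contacts(hab, compute_kinematics(hab)), "2 animals")
})

test_that("nose-to-anogenital contacts are direction specific", {
  n <- 30
  # A's nose 1 cm from B's tail base; B faces away
  a <- make_track(rep(10, n), rep(10, n), nx = rep(11.5, n), ny = rep(10, n),
                  tx = rep(8.5, n), ty = rep(10, n))
  b <- make_track(rep(14, n), rep(10, n), nx = rep(15.5, n), ny = rep(10, n),
                  tx = rep(12.5, n), ty = rep(10, n))
  ev <- detect_contacts(r <- dyad_rec(a, b), compute_kinematics(r))
  expect_equal(ev$subtype[ev$focal == "A"], "nose_anogenital")
  expect_false(ev$subtype[ev$focal == "B"] == "nose_anogenital")
})

test_that("approach detection matches the worked radial geometry", {
  fr <- 30
  n <- 91
  # bodies of length 4 so the dyad body length L = 4, zone radius 2L = 8
  cx <- pmin(10 + 0.2 * (seq_len(n) - 1), 26)
  a <- make_track(cx, rep(25, n), nx = cx + 2, ny = rep(25, n),
                  tx = cx - 2, ty = rep(25, n), frame_rate = fr)
  b <- make_track(rep(30, n), rep(25, n), nx = rep(32, n), ny = rep(25, n),
                  tx = rep(28, n), ty = rep(25, n), frame_rate = fr)
  rec <- dyad_rec(a, b)
  kin <- compute_kinematics(rec)
  ctc <- detect_contacts(rec, kin)
  app <- detect_approaches(rec, kin, ctc)
  appA <- app[app$focal == "A", ]
  expect_equal(nrow(appA), 1L)
  expect_equal(appA$subtype, "with_contact")
  # first frame strictly inside the 8 cm zone: dist = 20 - 0.2 i < 8
  expect_equal(appA$start_frame, 61L)
  expect_equal(appA$end_frame,
               ctc$start_frame[ctc$focal == "A"][1])
  expect_equal(nrow(app[app$focal == "B", ]), 0L)
  # both mice stationary inside the zone: no approach
  n2 <- 40
  a2 <- make_track(rep(10, n2), rep(25, n2))
  b2 <- make_track(rep(12, n2), rep(25, n2))
  rec2 <- dyad_rec(a2, b2)
  kin2 <- compute_kinematics(rec2)
  app2 <- detect_approaches(rec2, kin2, detect_contacts(rec2, kin2))
  expect_equal(nrow(app2), 0L)
})

test_that("an aborted approach is scored without contact", {
  fr <- 30
  # in, then turn away before contact
  cx <- c(seq(15, 23.8, by = 0.2), seq(23.6, 15, by = -0.2))
  n <- length(cx)
  a <- make_track(cx, rep(25, n), nx = cx + 2, ny = rep(25, n),
                  tx = cx - 2, ty = rep(25, n), frame_rate = fr)
  b <- make_track(rep(30, n), rep(25, n), nx = rep(32, n), ny = rep(25, n),
                  tx = rep(28, n), ty = rep(25, n), frame_rate = fr)
  rec <- dyad_rec(a, b)
  kin <- compute_kinematics(rec)
  app <- detect_approaches(rec, kin, detect_contacts(rec, kin))
  appA <- app[app$focal == "A", ]
  expect_equal(nrow(appA), 1L)
  expect_equal(appA$subtype, "without_contact")
  expect_identical(o_sort(app), o_sort(o_approaches(rec, dp,
                                                    o_contacts(rec, dp))))
})

test_that("breaks require higher focal speed and increasing distance", {
  fr <- 30
  n <- 90
  move_after <- function(v_a, v_b) {
    cxa <- c(rep(10, 30), 10 - v_a / fr * seq_len(n - 30))
    cxb <- c(rep(13, 30), 13 + v_b / fr * seq_len(n - 30))
    a <- make_track(cxa, rep(25, n), frame_rate = fr)
    b <- make_track(cxb, rep(25, n), frame_rate = fr)
    rec <- dyad_rec(a, b)
    kin <- compute_kinematics(rec)
    ctc <- detect_contacts(rec, kin)
    detect_breaks(rec, kin, ctc)
  }
  br <- move_after(10, 2)
  expect_equal(unique(br$focal), "A")
  expect_equal(nrow(br), 1L)
  # equal departure speeds: the strict speed inequality fails
  expect_equal(nrow(move_after(8, 8)), 0L)
  # both freeze after contact: no break
  a <- make_track(rep(10, n), rep(25, n), frame_rate = fr)
  b <- make_track(rep(13, n), rep(25, n), frame_rate = fr)
  rec <- dyad_rec(a, b)
  kin <- compute_kinematics(rec)
  expect_equal(nrow(detect_breaks(rec, kin, detect_contacts(rec, kin))), 0L)
})

test_that("follow detection honors speed gate, heading gate and zone", {
  fr <- 30
  n <- 300
  circle_pair <- function(v, lag_cm = 3) {
    r <- 20
    om <- v / r
    tt <- (seq_len(n) - 1) / fr
    lead <- cbind(25 + r * cos(om * tt), 25 + r * sin(om * tt))
    lag <- lag_cm / r
    foll <- cbind(25 + r * cos(om * tt - lag), 25 + r * sin(om * tt - lag))
    axis_l <- om * tt + pi / 2
    axis_f <- om * tt - lag + pi / 2
    a <- make_track(foll[, 1], foll[, 2],
                    nx = foll[, 1] + cos(axis_f), ny = foll[, 2] + sin(axis_f),
                    tx = foll[, 1] - cos(axis_f), ty = foll[, 2] - sin(axis_f),
                    frame_rate = fr)
    b <- make_track(lead[, 1], lead[, 2],
                    nx = lead[, 1] + cos(axis_l), ny = lead[, 2] + sin(axis_l),
                    tx = lead[, 1] - cos(axis_l), ty = lead[, 2] - sin(axis_l),
                    frame_rate = fr)
    dyad_rec(a, b)
  }
  rec <- circle_pair(8)
  kin <- compute_kinematics(rec)
  fo <- detect_follows(rec, kin)
  foA <- fo[fo$focal == "A", ]
  expect_equal(nrow(foA), 1L)
  expect_gte(foA$end_frame - foA$start_frame, 290)
  expect_equal(nrow(fo[fo$focal == "B", ]), 0L)  # leader is not behind
  # both at 4 cm/s: the strict >5 cm/s gate fails
  rec4 <- circle_pair(4)
  expect_equal(nrow(detect_follows(rec4, compute_kinematics(rec4))), 0L)
  # headings 90 degrees apart with the zone satisfied
  m <- 40
  cxa <- rep(27, m)
  cya <- 25 + 6 * (seq_len(m) - 1) / fr  # focal moves +y at 6 cm/s
  cxb <- 30 + 8 * (seq_len(m) - 1) / fr  # leader moves +x at 8 cm/s
  a <- make_track(cxa, cya, nx = cxa, ny = cya + 1, tx = cxa, ty = cya - 1,
                  frame_rate = fr)
  b <- make_track(cxb, rep(25, m), frame_rate = fr)
  rec9 <- dyad_rec(a, b)
  expect_equal(nrow(detect_follows(rec9, compute_kinematics(rec9))), 0L)
})

test_that("rearing episodes are run-length encoded with merging", {
  fr <- 30
  posture <- rep(0, 200)
  posture[c(11:40, 81:110, 151:180)] <- 0.9
  tr <- make_track(rep(10, 200), rep(10, 200), frame_rate = fr,
                   posture = posture)
  rec <- make_rec(list(m = tr), frame_rate = fr)
  ev <- detect_rearings(rec)
  expect_equal(nrow(ev), 3L)
  expect_equal(sum(ev$duration_s), 3)
  # two plateaus separated by one sub-threshold frame merge into one
  posture2 <- rep(0, 100)
  posture2[c(11:40, 42:71)] <- 0.9
  tr2 <- make_track(rep(10, 100), rep(10, 100), frame_rate = fr,
                    posture = posture2)
  ev2 <- detect_rearings(make_rec(list(m = tr2), frame_rate = fr))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$start_frame, 10L)
  expect_equal(ev2$end_frame, 71L)
  # posture never above threshold: no rears
  ev0 <- detect_rearings(make_rec(list(m = make_track(rep(10, 50),
                                                      rep(10, 50)))))
  expect_equal(nrow(ev0), 0L)
})

test_that("moves split at contact boundaries by interval arithmetic", {
  mk <- function(kind, s, e, focal = "A") {
    data.frame(session = "S0", phase = "interaction", focal = focal,
               partner = "B", kind = kind, subtype = "none",
               start_frame = s, end_frame = e, duration_s = (e - s) / 30)
  }
  out <- partition_moves_by_contact(mk("move", 0, 100),
                                    mk("contact", 40, 60))
  expect_equal(out$start_frame, c(0L, 40L, 60L))
  expect_equal(out$end_frame, c(40L, 60L, 100L))
  expect_equal(out$subtype, c("isolated", "in_contact", "isolated"))
  # no contacts: everything isolated
  out2 <- partition_moves_by_contact(mk("move", 0, 100), empty_events())
  expect_equal(out2$subtype, "isolated")
  # move entirely inside a contact
  out3 <- partition_moves_by_contact(mk("move", 45, 55),
                                     mk("contact", 40, 60))
  expect_equal(out3$subtype, "in_contact")
  # fragments shorter than the minimum duration are dropped
  out4 <- partition_moves_by_contact(mk("move", 0, 42),
                                     mk("contact", 40, 60))
  expect_equal(nrow(out4), 1L)
  expect_equal(out4$end_frame, 40L)
  # overlapping inputs of one kind violate the upstream invariant
  expect_error(partition_moves_by_contact(rbind(mk("move", 0, 50),
                                                mk("move", 40, 80)),
                                          empty_events()),
               "overlapping")
})

test_that("center-zone metrics follow the geometry", {
  fr <- 10
  ar <- arena()
  # stationary in a corner
  rec <- make_rec(list(m = make_track(rep(2, 100), rep(2, 100),
                                      frame_rate = fr)), frame_rate = fr)
  cz <- center_zone_metrics(compute_kinematics(rec), ar)
  expect_equal(unlist(cz), c(distance_in_center_cm = 0, time_in_center_s = 0,
                             pct_time_center = 0))
  # stationary at the arena midpoint for 900 s
  rec2 <- make_rec(list(m = make_track(rep(25, 9000), rep(25, 9000),
                                       frame_rate = fr)), frame_rate = fr)
  cz2 <- center_zone_metrics(compute_kinematics(rec2), ar)
  expect_equal(cz2$distance_in_center_cm, 0)
  expect_equal(cz2$time_in_center_s, 900)
  expect_equal(cz2$pct_time_center, 100)
  # straight diagonal crossing of the 25 cm center square
  fr3 <- 30
  n3 <- 400
  s <- 5 + 40 * (seq_len(n3) - 1) / (n3 - 1)
  rec3 <- make_rec(list(m = make_track(s, s, frame_rate = fr3)),
                   frame_rate = fr3)
  cz3 <- center_zone_metrics(compute_kinematics(rec3), ar)
  expect_equal(cz3$distance_in_center_cm, 25 * sqrt(2), tolerance = 0.01)
  # distance decomposition: center + outside = total
  kin3 <- compute_kinematics(rec3)
  expect_equal(cz3$distance_in_center_cm +
                 (total_distance(kin3) - cz3$distance_in_center_cm),
               total_distance(kin3), tolerance = 1e-9)
})

test_that("relabeling the mice swaps attributions and nothing else", {
  rec <- simulate_session(motion_params(), social_params(), 60, seed = 21,
                          frame_rate = 15, focal_id = "A", partner_id = "B")
  renamed <- list(B = rec$tracks$A, A = rec$tracks$B)
  sw <- session_recording(rec$session, rec$phase, rec$frame_rate, rec$arena,
                          renamed, focal_id = "B", partner_id = "A")
  e1 <- detect_all(rec)$events
  e2 <- detect_all(sw)$events
  relab <- e2
  relab$focal <- chartr("AB", "BA", relab$focal)
  relab$partner <- chartr("AB", "BA", relab$partner)
  key <- function(d) {
    d <- d[order(d$focal, d$kind, d$start_frame, d$end_frame, d$subtype), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(e1), key(relab))
})

test_that("detector thresholds act monotonically", {
  rec <- simulate_session(motion_params(), social_params(), 90, seed = 31,
                          frame_rate = 15)
  kin <- compute_kinematics(rec)
  move_time <- sapply(c(3, 5, 8), function(th) {
    p <- detector_params(speed_threshold = th)
    ev <- detect_movement_bouts(kin, p)
    sum(ev$duration_s[ev$kind == "move"])
  })
  expect_true(all(diff(move_time) <= 0))
  contact_time <- sapply(c(1, 2, 4), function(cd) {
    p <- detector_params(contact_dist_cm = cd)
    ev <- detect_contacts(rec, kin, p)
    sum(ev$duration_s[ev$focal == rec$focal_id])
  })
  expect_true(all(diff(contact_time) >= 0))
})

test_that("every detector equals the frame-wise oracle on simulated dyads", {
  for (seed in 1:5) {
    rec <- simulate_session(motion_params(), social_params(), 40,
                            seed = seed, frame_rate = 15)
    expect_identical(o_sort(detect_all(rec)$events), o_detect_all(rec, dp),
                     label = paste("seed", seed))
  }
})
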