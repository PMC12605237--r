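# Independent frame-wise oracle for every detector: predicates evaluated
# per frame from the raw recording, then run-length encoded by an explicit
# loop (drop runs < min_event_frames first, then merge separations <=
# merge_gap_frames that contain no tracking gap). Shares no code with the
# package implementation.

o_grid <- function(rec, id) {
  tr <- rec$tracks[[id]]
  nf <- max(vapply(rec$tracks, function(x) max(x$frame), numeric(1))) + 1L
  g <- list()
  for (cl in c("cx", "cy", "nx", "ny", "tx", "ty", "posture")) {
    v <- rep(NA_real_, nf)
    v[tr$frame + 1L] <- tr[[cl]]
    g[[cl]] <- v
  }
  g$present <- !is.na(g$cx)
  g$nf <- nf
  g
}

o_smooth_vec <- function(x, w) {
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  out <- rep(NA_real_, n)
  # smooth within each contiguous non-NA segment, truncated at its ends
  i <- 1L
  while (i <= n) {
    if (is.na(x[i])) { i <- i + 1L; next }
    j <- i
    while (j <= n && !is.na(x[j])) j <- j + 1L
    seg <- x[i:(j - 1L)]
    m <- length(seg)
    for (k in seq_len(m))
      out[i + k - 1L] <- mean(seg[max(1L, k - hl):min(m, k + hr)])
    i <- j
  }
  out
}

o_kin <- function(rec, params) {
  w <- params$smoothing_window_frames
  lapply(rec$tracks, function(tr) NULL) -> dummy
  out <- list()
  for (id in names(rec$tracks)) {
    g <- o_grid(rec, id)
    sx <- o_smooth_vec(g$cx, w)
    sy <- o_smooth_vec(g$cy, w)
    n <- g$nf
    speed <- rep(NA_real_, n)
    heading <- rep(NA_real_, n)
    axis <- atan2(g$ny - g$ty, g$nx - g$tx)
    for (i in seq_len(n)) {
      if (i > 1L && !is.na(sx[i]) && !is.na(sx[i - 1L])) {
        dx <- sx[i] - sx[i - 1L]
        dy <- sy[i] - sy[i - 1L]
        disp <- sqrt(dx^2 + dy^2)
        speed[i] <- disp * rec$frame_rate
        heading[i] <- if (disp >= params$heading_min_disp_cm)
          atan2(dy, dx) else axis[i]
      } else heading[i] <- axis[i]
    }
    bl <- median(sqrt((g$nx - g$tx)^2 + (g$ny - g$ty)^2), na.rm = TRUE)
    out[[id]] <- list(g = g, sx = sx, sy = sy, speed = speed,
                      heading = heading, axis = axis, body_length = bl)
  }
  out
}

# run-length encoding with the documented post-processing; pred has NAs at
# tracking gaps; returns half-open 0-based intervals
o_runs <- function(pred, min_frames, merge_gap) {
  n <- length(pred)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (isTRUE(pred[i])) {
      s <- i
      while (i <= n && isTRUE(pred[i])) i <- i + 1L
      if (i - s >= min_frames)
        runs[[length(runs) + 1L]] <- c(s - 1L, i - 1L)  # [start, end) 0-based
    } else i <- i + 1L
  }
  merged <- list()
  for (r in runs) {
    if (length(merged)) {
      last <- merged[[length(merged)]]
      gap_frames <- if (r[1] > last[2]) pred[(last[2] + 1L):r[1]] else
        logical(0)
      if (r[1] - last[2] <= merge_gap && !anyNA(gap_frames)) {
        merged[[length(merged)]][2] <- r[2]
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  if (!length(merged)) return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(merged, `[`, numeric(1), 1),
             end = vapply(merged, `[`, numeric(1), 2))
}

o_wrap <- function(a) atan2(sin(a), cos(a))

o_event_df <- function(rec, kind, focal, partner, runs, subtype = "none") {
  if (!nrow(runs))
    return(empty_events())
  data.frame(session = rec$session, phase = rec$phase, focal = focal,
             partner = partner, kind = kind,
             subtype = rep_len(subtype, nrow(runs)),
             start_frame = as.integer(runs$start),
             end_frame = as.integer(runs$end),
             duration_s = (runs$end - runs$start) / rec$frame_rate)
}

o_moves <- function(rec, params, mice = names(rec$tracks)) {
  kin <- o_kin(rec, params)
  out <- list()
  for (id in mice) {
    spd <- kin[[id]]$speed
    mv <- spd > params$speed_threshold
    out[[length(out) + 1L]] <- o_event_df(rec, "move", id, "",
      o_runs(mv, params$min_event_frames, params$merge_gap_frames))
    out[[length(out) + 1L]] <- o_event_df(rec, "stop", id, "",
      o_runs(!mv, params$min_event_frames, params$merge_gap_frames))
  }
  do.call(rbind, out)
}

# per-frame minimum skeleton distance and subtype info
o_contact_frames <- function(rec, params) {
  ids <- names(rec$tracks)
  ga <- o_grid(rec, ids[1])
  gb <- o_grid(rec, ids[2])
  n <- ga$nf
  dmin <- rep(NA_real_, n)
  besta <- rep(NA_integer_, n)  # point index on A: 1 nose, 2 center, 3 tail
  bestb <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!ga$present[i] || !gb$present[i]) next
    pa <- rbind(c(ga$nx[i], ga$ny[i]), c(ga$cx[i], ga$cy[i]),
                c(ga$tx[i], ga$ty[i]))
    pb <- rbind(c(gb$nx[i], gb$ny[i]), c(gb$cx[i], gb$cy[i]),
                c(gb$tx[i], gb$ty[i]))
    best <- Inf
    for (jb in 1:3) for (ja in 1:3) {
      dd <- sqrt(sum((pa[ja, ] - pb[jb, ])^2))
      if (dd < best) { best <- dd; besta[i] <- ja; bestb[i] <- jb }
    }
    dmin[i] <- best
  }
  axis_a <- atan2(ga$ny - ga$ty, ga$nx - ga$tx)
  axis_b <- atan2(gb$ny - gb$ty, gb$nx - gb$tx)
  dang <- abs(o_wrap(axis_a - axis_b))
  amax <- params$side_by_side_angle_max_deg * pi / 180
  list(dmin = dmin, besta = besta, bestb = bestb,
       parallelish = !is.na(dang) & (dang < amax | dang > pi - amax))
}

o_contacts <- function(rec, params, mice = names(rec$tracks)) {
  ids <- names(rec$tracks)
  cf <- o_contact_frames(rec, params)
  pred <- cf$dmin < params$contact_dist_cm
  runs <- o_runs(pred, params$min_event_frames, params$merge_gap_frames)
  levs <- c("nose_nose", "nose_anogenital", "side_by_side", "other_contact")
  sub_for <- function(i, focal_first) {
    fp <- if (focal_first) cf$besta[i] else cf$bestb[i]
    pp <- if (focal_first) cf$bestb[i] else cf$besta[i]
    if (fp == 1 && pp == 1) "nose_nose"
    else if (fp == 1 && pp == 3) "nose_anogenital"
    else if (cf$parallelish[i]) "side_by_side"
    else "other_contact"
  }
  modal_sub <- function(run, focal_first) {
    subs <- character()
    for (i in (run[1] + 1L):run[2])
      if (isTRUE(pred[i])) subs <- c(subs, sub_for(i, focal_first))
    if (!length(subs)) return("other_contact")
    counts <- sapply(levs, function(l) sum(subs == l))
    levs[which.max(counts)]
  }
  out <- list()
  if (ids[1] %in% mice)
    out[[length(out) + 1L]] <- o_event_df(rec, "contact", ids[1], ids[2],
      runs, if (nrow(runs)) sapply(seq_len(nrow(runs)), function(k)
        modal_sub(c(runs$start[k], runs$end[k]), TRUE)) else character())
  if (ids[2] %in% mice)
    out[[length(out) + 1L]] <- o_event_df(rec, "contact", ids[2], ids[1],
      runs, if (nrow(runs)) sapply(seq_len(nrow(runs)), function(k)
        modal_sub(c(runs$start[k], runs$end[k]), FALSE)) else character())
  do.call(rbind, out)
}

# frames (1-based index) covered by an event list for a focal
o_cover <- function(events, id, kind, nf) {
  x <- rep(FALSE, nf)
  e <- events[events$focal == id & events$kind == kind, , drop = FALSE]
  for (k in seq_len(nrow(e)))
    for (i in (e$start_frame[k] + 1L):e$end_frame[k]) x[i] <- TRUE
  x
}

o_approaches <- function(rec, params, contacts, mice = names(rec$tracks)) {
  ids <- names(rec$tracks)
  kin <- o_kin(rec, params)
  ga <- o_grid(rec, ids[1]); gb <- o_grid(rec, ids[2])
  d <- sqrt((ga$cx - gb$cx)^2 + (ga$cy - gb$cy)^2)
  L <- mean(c(kin[[ids[1]]]$body_length, kin[[ids[2]]]$body_length))
  R <- params$approach_radius_bl * L
  n <- ga$nf
  g <- max(1L, params$merge_gap_frames)
  out <- list()
  for (id in mice) {
    other <- setdiff(ids, id)
    sf <- kin[[id]]$speed
    sp <- kin[[other]]$speed
    inc <- o_cover(contacts, id, "contact", n)
    open <- FALSE; start <- NA; nondec <- 0L
    ev <- list()
    i <- 2L
    while (i <= n) {
      valid <- !is.na(d[i]) && !is.na(d[i - 1L]) && !is.na(sf[i]) &&
        !is.na(sp[i])
      if (open) {
        fin <- NULL
        if (!valid) fin <- c(i - 1L, 0L)
        else if (inc[i]) fin <- c(i - 1L, 1L)
        else if (d[i] >= R) fin <- c(i - 1L, 0L)
        else if (d[i] < d[i - 1L]) nondec <- 0L
        else {
          nondec <- nondec + 1L
          if (nondec >= g) fin <- c(i - 1L - nondec + 1L, 0L)
        }
        if (!is.null(fin)) {
          if (fin[1] - start >= params$min_event_frames)
            ev[[length(ev) + 1L]] <- c(start, fin[1], fin[2])
          open <- FALSE
        }
      }
      if (!open && valid && d[i] < R && d[i] < d[i - 1L] && sf[i] > sp[i] &&
          !inc[i]) {
        open <- TRUE
        start <- i - 1L  # 0-based
        nondec <- 0L
      }
      i <- i + 1L
    }
    if (open && n - start >= params$min_event_frames)
      ev[[length(ev) + 1L]] <- c(start, n, 0L)
    runs <- if (length(ev))
      data.frame(start = sapply(ev, `[`, 1), end = sapply(ev, `[`, 2),
                 wc = sapply(ev, `[`, 3))
    else data.frame(start = integer(), end = integer(), wc = integer())
    out[[length(out) + 1L]] <- o_event_df(rec, "approach", id, other,
      runs[c("start", "end")],
      if (nrow(runs)) ifelse(runs$wc == 1, "with_contact", "without_contact")
      else character())
  }
  do.call(rbind, out)
}

o_breaks <- function(rec, params, contacts, mice = names(rec$tracks)) {
  ids <- names(rec$tracks)
  kin <- o_kin(rec, params)
  ga <- o_grid(rec, ids[1]); gb <- o_grid(rec, ids[2])
  d <- sqrt((ga$cx - gb$cx)^2 + (ga$cy - gb$cy)^2)
  n <- ga$nf
  out <- list()
  for (id in mice) {
    other <- setdiff(ids, id)
    sf <- kin[[id]]$speed
    sp <- kin[[other]]$speed
    cond <- function(t0) {  # 0-based frame t0
      i <- t0 + 1L
      i <= n && !is.na(d[i]) && !is.na(d[i - 1L]) && !is.na(sf[i]) &&
        !is.na(sp[i]) && d[i] > d[i - 1L] && sf[i] > sp[i]
    }
    ce <- contacts[contacts$focal == id & contacts$kind == "contact", ]
    ev <- list()
    for (e in ce$end_frame) {
      if (e + params$min_event_frames > n) next
      if (!all(sapply(e:(e + params$min_event_frames - 1L), cond))) next
      t <- e + params$min_event_frames
      while (cond(t)) t <- t + 1L
      ev[[length(ev) + 1L]] <- c(e, t)
    }
    runs <- if (length(ev))
      data.frame(start = sapply(ev, `[`, 1), end = sapply(ev, `[`, 2))
    else data.frame(start = integer(), end = integer())
    out[[length(out) + 1L]] <- o_event_df(rec, "break", id, other, runs)
  }
  do.call(rbind, out)
}

o_follows <- function(rec, params, mice = names(rec$tracks)) {
  ids <- names(rec$tracks)
  kin <- o_kin(rec, params)
  L <- mean(c(kin[[ids[1]]]$body_length, kin[[ids[2]]]$body_length))
  hmax <- params$follow_heading_max_deg * pi / 180
  out <- list()
  for (id in mice) {
    other <- setdiff(ids, id)
    gf <- o_grid(rec, id); gl <- o_grid(rec, other)
    kf <- kin[[id]]; kl <- kin[[other]]
    n <- gf$nf
    pred <- rep(NA, n)
    for (i in seq_len(n)) {
      if (is.na(kf$speed[i]) || is.na(kl$speed[i])) next
      ok <- kf$speed[i] > params$speed_threshold &&
        kl$speed[i] > params$speed_threshold &&
        abs(o_wrap(kf$heading[i] - kl$heading[i])) < hmax
      if (ok) {
        rx <- gf$cx[i] - gl$cx[i]
        ry <- gf$cy[i] - gl$cy[i]
        ux <- cos(kl$heading[i]); uy <- sin(kl$heading[i])
        along <- -(rx * ux + ry * uy)
        across <- -rx * uy + ry * ux
        ok <- along > 0 && along < params$follow_zone_l_bl * L &&
          abs(across) < params$follow_zone_w_bl * L / 2
      }
      pred[i] <- ok
    }
    out[[length(out) + 1L]] <- o_event_df(rec, "follow", id, other,
      o_runs(pred, params$min_event_frames, params$merge_gap_frames))
  }
  do.call(rbind, out)
}

o_rears <- function(rec, params, mice = names(rec$tracks)) {
  out <- list()
  for (id in mice) {
    g <- o_grid(rec, id)
    pred <- g$posture > params$rear_posture_threshold
    out[[length(out) + 1L]] <- o_event_df(rec, "rear", id, "",
      o_runs(pred, params$min_event_frames, params$merge_gap_frames))
  }
  do.call(rbind, out)
}

# sort events canonically for comparison
o_sort <- function(ev) {
  ev <- ev[order(ev$focal, ev$kind, ev$start_frame, ev$end_frame,
                 ev$subtype), ]
  rownames(ev) <- NULL
  ev
}

# oracle counterpart of detect_all on an interaction recording
o_detect_all <- function(rec, params, mice = names(rec$tracks)) {
  out <- list(o_moves(rec, params, mice), o_rears(rec, params, mice))
  if (rec$phase == "interaction") {
    ctc <- o_contacts(rec, params, mice)
    out <- c(out, list(ctc,
                       o_approaches(rec, params, ctc, mice),
                       o_breaks(rec, params, ctc, mice),
                       o_follows(rec, params, mice)))
  }
  o_sort(do.call(rbind, out))
}
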