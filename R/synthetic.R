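ring_half <- 20       # rubber ring box is 40 x 40 px
peg_half <- 8         # peg box 16 x 16 px
diss_half_w <- 30     # dissector box 60 x 24 px
diss_half_h <- 12
grab_half <- 15       # grab box 30 x 30 px
lift_frames <- 14L    # frames to lift a ring to transit height
fall_frames <- 12L    # frames for a dropped ring to reach the board
transit_y <- 40       # flight height, above all pegs

#' Template pegboard used by the simulator
#'
#' Twelve pegs in two 6-peg columns (left x = 160, right x = 480) on a
#' 640 x 480 image, numbered 1-6 left top-to-bottom and 7-12 right.
#'
#' @param image_size `c(width, height)` in pixels.
#' @return A `peg_geometry`.
#' @export
board_template <- function(image_size = c(640, 480)) {
  y <- 90 + 60 * (0:5)
  pegs <- tibble(
    peg = 1:12,
    x = rep(c(160, 480), each = 6),
    y = rep(y, 2),
    side = rep(c("left", "right"), each = 6)
  )
  pegs$x_min <- pegs$x - peg_half
  pegs$y_min <- pegs$y - peg_half
  pegs$x_max <- pegs$x + peg_half
  pegs$y_max <- pegs$y + peg_half
  pegs$object_id <- sprintf("peg_%02d", pegs$peg)
  structure(
    list(pegs = pegs[c("peg", "x", "y", "x_min", "y_min", "x_max", "y_max",
                       "side", "object_id")],
         midline_x = 320,
         image_size = as.integer(image_size)),
    class = "peg_geometry"
  )
}

#' Define a scripted peg-transfer scenario
#'
#' A scenario is a set of rings with initial peg assignments and an ordered
#' table of carries (`moves`), each describing one pickup-to-release
#' session: which instrument picks the ring up, an optional mid-air exchange
#' to the other instrument, and whether the carry ends in a placement on a
#' peg or a drop onto the board.
#'
#' @param name Scenario (and simulated video) id.
#' @param rings Named integer vector: initial peg of each ring, e.g.
#'   `c(r1 = 1, ..., r6 = 6)`.
#' @param moves Tibble with columns `ring`, `start`, `end` (frames),
#'   `inst1`, `inst2` (`NA` for no exchange), `switch_start`, `overlap`
#'   (frames both instruments hold the ring), `outcome` (`"place"`/`"drop"`),
#'   `dest_peg`, `drop_x`, `drop_y`.
#' @param fps Frames per second of the rendered stream.
#' @param frame_count Total frames; defaults to 45 frames past the last move.
#' @param image_size Rendered image size in pixels.
#' @return A `peg_scenario`.
#' @export
peg_scenario <- function(name, rings, moves, fps = 30,
                         frame_count = NULL, image_size = c(640, 480)) {
  defaults <- tibble(inst2 = NA_character_, switch_start = NA_integer_,
                     overlap = NA_integer_, dest_peg = NA_integer_,
                     drop_x = NA_real_, drop_y = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(moves)) moves[[col]] <- defaults[[col]]
  }
  moves <- dplyr::arrange(as_tibble(moves), .data$start, .data$ring)
  frame_count <- as.integer(frame_count %||% (max(moves$end) + 45L))
  sc <- structure(
    list(name = name, rings = rings, moves = moves, fps = fps,
         frame_count = frame_count, image_size = as.integer(image_size),
         board = board_template(image_size)),
    class = "peg_scenario"
  )
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  m <- sc$moves
  err <- function(msg) stop_pegtransfer(paste0("scenario '", sc$name, "': ", msg),
                                        "peg_scenario_error")
  if (any(!(m$ring %in% names(sc$rings)))) err("move references unknown ring")
  if (any(m$end <= m$start)) err("moves must have end > start")
  if (any(m$end - m$start < 2L * lift_frames + 1L)) {
    err("moves must be long enough to lift and lower the ring")
  }
  if (any(m$outcome == "place" & is.na(m$dest_peg))) {
    err("place moves need dest_peg")
  }
  if (any(m$outcome == "drop" & (is.na(m$drop_x) | is.na(m$drop_y)))) {
    err("drop moves need drop_x/drop_y")
  }
  sw <- !is.na(m$switch_start)
  if (any(sw & (is.na(m$overlap) | m$overlap < 1L))) {
    err("exchanges need overlap >= 1")
  }
  if (any(sw & (m$switch_start <= m$start | m$switch_start + m$overlap - 1L >= m$end))) {
    err("exchange must lie strictly inside the move")
  }
  for (r in unique(m$ring)) {
    mm <- m[m$ring == r, ]
    if (nrow(mm) > 1 && any(diff(mm$start) <= 0 |
                            mm$start[-1] <= mm$end[-nrow(mm)])) {
      err(paste0("ring ", r, " has overlapping moves"))
    }
  }
  occ <- scenario_occupancy(sc)
  conflict <- occ |>
    dplyr::inner_join(occ, by = "peg", relationship = "many-to-many") |>
    dplyr::filter(.data$ring.x < .data$ring.y,
                  .data$from.x <= .data$to.y, .data$from.y <= .data$to.x)
  if (nrow(conflict) > 0) {
    err(sprintf("peg %d would hold rings %s and %s at the same time",
                conflict$peg[1], conflict$ring.x[1], conflict$ring.y[1]))
  }
  invisible(sc)
}

# Rest intervals of each ring on each peg implied by the script (0-based
# frames, inclusive). Rings resting on the board (after a drop) have no row.
scenario_occupancy <- function(sc) {
  out <- list()
  n <- sc$frame_count
  for (r in names(sc$rings)) {
    peg <- sc$rings[[r]]
    t_prev <- 0L
    mm <- sc$moves[sc$moves$ring == r, ]
    for (j in seq_len(nrow(mm))) {
      if (!is.na(peg)) {
        out[[length(out) + 1L]] <- tibble(ring = r, peg = peg,
                                          from = t_prev, to = mm$start[j])
      }
      peg <- if (mm$outcome[j] == "place") mm$dest_peg[j] else NA_integer_
      t_prev <- mm$end[j]
    }
    if (!is.na(peg)) {
      out[[length(out) + 1L]] <- tibble(ring = r, peg = peg,
                                        from = t_prev, to = n - 1L)
    }
  }
  dplyr::bind_rows(out)
}

#' Render a scenario into a detection stream plus ground truth
#'
#' Object boxes are linearly interpolated between scripted keyframes; grab
#' detections are emitted exactly on held frames. The ground truth (sessions,
#' transfers, pitfalls, duration, verdict under the default rule set) is
#' computed from the script itself, not from the rendered stream.
#'
#' @param scenario A `peg_scenario`.
#' @param config Rule configuration used to derive the ground-truth verdict.
#' @return A list with `stream` (a `peg_stream`) and `truth` (list with
#'   `sessions`, `transfers`, `pitfalls`, `duration_s`, `verdict`).
#' @export
simulate_exercise <- function(scenario, config = eval_config()) {
  sc <- scenario
  n <- sc$frame_count
  frames <- 0:(n - 1L)
  board <- sc$board
  ring_pos <- lapply(names(sc$rings), function(r) render_ring_path(sc, r))
  names(ring_pos) <- names(sc$rings)

  det <- list()
  # pegs: static, every frame
  pg <- board$pegs
  det$pegs <- tibble(
    frame = rep(frames, times = nrow(pg)),
    cls = "peg",
    x_min = rep(pg$x_min, each = n), y_min = rep(pg$y_min, each = n),
    x_max = rep(pg$x_max, each = n), y_max = rep(pg$y_max, each = n),
    confidence = 0.98
  )
  det$rings <- purrr::map_dfr(names(ring_pos), function(r) {
    p <- ring_pos[[r]]
    tibble(frame = frames, cls = "rubber",
           x_min = p$x - ring_half, y_min = p$y - ring_half,
           x_max = p$x + ring_half, y_max = p$y + ring_half,
           confidence = 0.92)
  })
  eng <- scenario_engagements(sc)
  det$dissectors <- purrr::map_dfr(c("L", "R"), function(inst) {
    p <- render_dissector_path(sc, inst, eng, ring_pos)
    tibble(frame = frames, cls = "dissector",
           x_min = p$x - diss_half_w, y_min = p$y - diss_half_h,
           x_max = p$x + diss_half_w, y_max = p$y + diss_half_h,
           confidence = 0.94)
  })
  det$grabs <- purrr::map_dfr(seq_len(nrow(eng)), function(j) {
    e <- eng[j, ]
    f <- e$from:e$to
    p <- ring_pos[[e$ring]]
    gdx <- if (e$instrument == "L") -8 else 8
    tibble(frame = f, cls = "grab",
           x_min = p$x[f + 1L] + gdx - grab_half,
           y_min = p$y[f + 1L] - 8 - grab_half,
           x_max = p$x[f + 1L] + gdx + grab_half,
           y_max = p$y[f + 1L] - 8 + grab_half,
           confidence = 0.90)
  })
  stream <- detection_stream(dplyr::bind_rows(det), video_id = sc$name,
                             fps = sc$fps, frame_count = n,
                             image_size = sc$image_size)
  list(stream = stream, truth = scenario_truth(sc, config))
}

# Holding intervals per (move, instrument), inclusive 0-based frames.
scenario_engagements <- function(sc) {
  m <- sc$moves
  purrr::map_dfr(seq_len(nrow(m)), function(j) {
    mm <- m[j, ]
    sw_end <- if (!is.na(mm$switch_start)) mm$switch_start + mm$overlap - 1L else NA_integer_
    first <- tibble(ring = mm$ring, instrument = mm$inst1, move = j,
                    from = mm$start,
                    to = if (!is.na(sw_end)) sw_end else mm$end)
    if (!is.na(mm$inst2)) {
      dplyr::bind_rows(first,
                       tibble(ring = mm$ring, instrument = mm$inst2, move = j,
                              from = mm$switch_start, to = mm$end))
    } else {
      first
    }
  })
}

render_ring_path <- function(sc, r) {
  n <- sc$frame_count
  board <- sc$board
  peg_xy <- function(p) c(board$pegs$x[board$pegs$peg == p],
                          board$pegs$y[board$pegs$peg == p])
  pos <- peg_xy(sc$rings[[r]])
  kf <- list(c(0, pos))
  mm <- sc$moves[sc$moves$ring == r, ]
  for (j in seq_len(nrow(mm))) {
    m <- mm[j, ]
    kf[[length(kf) + 1L]] <- c(m$start, pos)
    kf[[length(kf) + 1L]] <- c(m$start + lift_frames, pos[1], transit_y)
    if (m$outcome == "place") {
      dest <- peg_xy(m$dest_peg)
      kf[[length(kf) + 1L]] <- c(m$end - lift_frames, dest[1], transit_y)
      kf[[length(kf) + 1L]] <- c(m$end, dest)
      pos <- dest
    } else {
      kf[[length(kf) + 1L]] <- c(m$end, m$drop_x, transit_y)
      kf[[length(kf) + 1L]] <- c(min(m$end + fall_frames, n - 1L),
                                 m$drop_x, m$drop_y)
      pos <- c(m$drop_x, m$drop_y)
    }
  }
  kf[[length(kf) + 1L]] <- c(n - 1L, pos)
  k <- do.call(rbind, kf)
  k <- k[!duplicated(k[, 1], fromLast = TRUE), , drop = FALSE]
  k <- k[order(k[, 1]), , drop = FALSE]
  frames <- 0:(n - 1L)
  list(x = stats::approx(k[, 1], k[, 2], xout = frames, rule = 2)$y,
       y = stats::approx(k[, 1], k[, 3], xout = frames, rule = 2)$y)
}

render_dissector_path <- function(sc, inst, eng, ring_pos) {
  n <- sc$frame_count
  home <- if (inst == "L") c(80, 445) else c(560, 445)
  dx <- if (inst == "L") -14 else 14
  ee <- eng[eng$instrument == inst, , drop = FALSE]
  ee <- ee[order(ee$from), , drop = FALSE]
  known_f <- integer(0); known_x <- numeric(0); known_y <- numeric(0)
  for (j in seq_len(nrow(ee))) {
    f <- ee$from[j]:ee$to[j]
    p <- ring_pos[[ee$ring[j]]]
    known_f <- c(known_f, f)
    known_x <- c(known_x, p$x[f + 1L] + dx)
    known_y <- c(known_y, p$y[f + 1L] - 8)
  }
  # idle behaviour: park at home during long gaps, otherwise drift directly
  # to the next engagement (keeps per-frame motion inside a tracking gate)
  gap_bounds <- rbind(
    c(0L, if (nrow(ee) > 0) ee$from[1] else n - 1L),
    if (nrow(ee) > 1) cbind(ee$to[-nrow(ee)], ee$from[-1]),
    c(if (nrow(ee) > 0) ee$to[nrow(ee)] else 0L, n - 1L)
  )
  anchors <- integer(0)
  for (j in seq_len(nrow(gap_bounds))) {
    lo <- gap_bounds[j, 1]; hi <- gap_bounds[j, 2]
    if (hi - lo >= 40L) anchors <- c(anchors, as.integer((lo + hi) %/% 2))
  }
  anchors <- setdiff(unique(c(0L, n - 1L, anchors)), known_f)
  known_f <- c(known_f, anchors)
  known_x <- c(known_x, rep(home[1], length(anchors)))
  known_y <- c(known_y, rep(home[2], length(anchors)))
  ord <- order(known_f)
  frames <- 0:(n - 1L)
  list(x = stats::approx(known_f[ord], known_x[ord], xout = frames, rule = 2)$y,
       y = stats::approx(known_f[ord], known_y[ord], xout = frames, rule = 2)$y)
}

# Ground truth computed from the script, using the same rule engine that
# scores evaluated streams (sessions themselves come from the script).
scenario_truth <- function(sc, config = eval_config()) {
  n <- sc$frame_count
  m <- sc$moves
  occ <- scenario_occupancy(sc)
  ring_contact <- lapply(stats::setNames(names(sc$rings), names(sc$rings)),
                         function(r) {
    v <- logical(n)
    oo <- occ[occ$ring == r, ]
    for (j in seq_len(nrow(oo))) v[(oo$from[j] + 1L):(oo$to[j] + 1L)] <- TRUE
    v
  })
  sessions <- purrr::map_dfr(seq_len(nrow(m)), function(j) {
    mm <- m[j, ]
    before <- occ[occ$ring == mm$ring & occ$to == mm$start, ]
    origin <- if (nrow(before) > 0) before$peg[1] else NA_integer_
    release <- if (!is.na(mm$inst2)) mm$inst2 else mm$inst1
    end_reason <- if (mm$end >= n - 1L) "stream_end"
      else if (mm$outcome == "place") "placed" else "dropped"
    sw <- !is.na(mm$switch_start)
    holders <- if (sw) {
      tibble(instrument = c(mm$inst1, mm$inst2),
             start = c(mm$start, mm$switch_start),
             end = c(mm$switch_start + mm$overlap - 1L, mm$end))
    } else {
      tibble(instrument = mm$inst1, start = mm$start, end = mm$end)
    }
    tibble(
      ring_id = mm$ring, start_frame = mm$start, end_frame = mm$end,
      pickup_instrument = mm$inst1, release_instrument = release,
      end_reason = end_reason, origin_peg = as.integer(origin),
      destination_peg = if (mm$outcome == "place") as.integer(mm$dest_peg)
        else NA_integer_,
      exchange_overlap = sw,
      holder_change = !is.na(mm$inst2) && mm$inst2 != mm$inst1,
      change_gap = 0L, change_contact = FALSE,
      dest_occupied_by_other = FALSE,
      holders = list(holders)
    )
  })
  sessions <- dplyr::arrange(sessions, .data$start_frame, .data$ring_id)
  attr(sessions, "ring_contact") <- ring_contact
  attr(sessions, "frame_count") <- n
  attr(sessions, "geometry") <- sc$board
  transfers <- assemble_transfers(sessions, sc$board, config)
  pitfalls <- detect_pitfalls(transfers, sessions, config)
  duration_s <- measure_duration(sessions, sc$fps)
  verdict <- score_exercise(transfers, pitfalls, duration_s, config,
                            rings = names(sc$rings))
  list(scenario = sc$name, fps = sc$fps, sessions = sessions,
       transfers = transfers, pitfalls = pitfalls, duration_s = duration_s,
       verdict = as.character(verdict), fail_reasons = attr(verdict, "reasons"))
}

#' Library of scripted scenarios
#'
#' Canonical exercises with documented ground truth: a perfect bidirectional
#' 6-ring run, each pitfall kind, an over-time run and a one-direction-only
#' run.
#'
#' @return Named list of `peg_scenario` objects.
#' @export
scenario_library <- function() {
  list(
    perfect_run = peg_scenario("perfect_run", default_rings(),
                               schedule_moves()),
    missed_handover = peg_scenario(
      "missed_handover", default_rings(),
      schedule_moves(alter = function(m) {
        i <- which(m$ring == "r3" & m$dest_peg == 10L)
        m$inst2[i] <- NA_character_
        m$switch_start[i] <- NA_integer_
        m$overlap[i] <- NA_integer_
        m
      })),
    invalid_handover_via_drop = peg_scenario(
      "invalid_handover_via_drop", default_rings(),
      schedule_moves(alter = function(m) {
        i <- which(m$ring == "r2" & m$dest_peg == 11L)
        s <- m$start[i]
        m <- delay_moves_after(m[-i, ], s)
        dplyr::bind_rows(m, tibble(
          ring = "r2", start = c(s, s + 60L), end = c(s + 35L, s + 130L),
          inst1 = c("L", "R"), inst2 = NA_character_,
          switch_start = NA_integer_, overlap = NA_integer_,
          outcome = c("drop", "place"), dest_peg = c(NA_integer_, 11L),
          drop_x = c(300, NA), drop_y = c(430, NA)))
      })),
    invalid_release_drop = peg_scenario(
      "invalid_release_drop", default_rings(),
      schedule_moves(alter = function(m) {
        i <- which(m$ring == "r5" & m$dest_peg == 8L)
        s <- m$start[i]
        m <- delay_moves_after(m[-i, ], s)
        dplyr::bind_rows(m, tibble(
          ring = "r5", start = c(s, s + 60L), end = c(s + 40L, s + 130L),
          inst1 = c("L", "R"), inst2 = c("R", NA),
          switch_start = c(s + 18L, NA), overlap = c(6L, NA),
          outcome = c("drop", "place"), dest_peg = c(NA_integer_, 8L),
          drop_x = c(440, NA), drop_y = c(430, NA)))
      })),
    invalid_pickup_return = peg_scenario(
      "invalid_pickup_return", default_rings(),
      schedule_moves(alter = function(m) {
        i <- which(m$ring == "r4" & m$dest_peg == 9L)
        s <- m$start[i]
        m <- delay_moves_after(m[-i, ], s)
        dplyr::bind_rows(m, tibble(
          ring = "r4", start = c(s, s + 72L), end = c(s + 60L, s + 142L),
          inst1 = c("L", "R"), inst2 = c("R", NA),
          switch_start = c(s + 27L, NA), overlap = c(6L, NA),
          outcome = "place", dest_peg = c(4L, 9L),
          drop_x = NA_real_, drop_y = NA_real_))
      })),
    slow_run_over_limit = peg_scenario(
      "slow_run_over_limit", default_rings(),
      schedule_moves(slot = 135L), fps = 5),
    single_direction_only = peg_scenario(
      "single_direction_only", default_rings(),
      schedule_moves(directions = 1L))
  )
}

default_rings <- function() stats::setNames(1:6, paste0("r", 1:6))

# Shift every move starting after frame s one slot later, opening room for
# a two-move recovery (drop + re-pickup) in the altered ring's schedule.
delay_moves_after <- function(m, s, by = 85L) {
  late <- m$start > s
  m$start[late] <- m$start[late] + by
  m$end[late] <- m$end[late] + by
  m$switch_start[late] <- m$switch_start[late] + by
  m
}

# Canonical move schedule: one 60-frame carry per ring per direction with a
# mid-air exchange, one carry per 'slot' frames. Rings are picked top-down
# and placed bottom-up (r1 -> peg 12, ..., r6 -> peg 7; then back r6 -> peg
# 6, ..., r1 -> peg 1), so a descending ring only crosses empty pegs of its
# destination column -- from a single top view a ring lowered across an
# occupied peg is indistinguishable from the resting ring there.
schedule_moves <- function(slot = 85L, t0 = 30L, dur = 60L,
                           switch_off = 27L, overlap = 6L,
                           directions = 2L, alter = NULL) {
  rows <- list()
  k <- 0L
  for (d in seq_len(directions)) {
    for (i in 1:6) {
      ring_no <- if (d == 1L) i else 7L - i
      s <- t0 + k * slot
      rows[[length(rows) + 1L]] <- tibble(
        ring = paste0("r", ring_no),
        start = s, end = s + dur,
        inst1 = if (d == 1L) "L" else "R",
        inst2 = if (d == 1L) "R" else "L",
        switch_start = s + switch_off, overlap = overlap,
        outcome = "place",
        dest_peg = if (d == 1L) 13L - ring_no else ring_no,
        drop_x = NA_real_, drop_y = NA_real_
      )
      k <- k + 1L
    }
  }
  m <- dplyr::bind_rows(rows)
  if (!is.null(alter)) m <- alter(m)
  m
}

#' Detector-noise specification
#'
#' @param fp_rate Probability of one spurious detection per class per frame.
#'   Scalar or named per class (`peg`, `rubber`, `dissector`, `grab`).
#' @param fn_rate Probability that a true detection is deleted. Scalar or
#'   named per class.
#' @param jitter_sigma_px Gaussian jitter (pixels) applied to box centres.
#' @param conf_range Confidence range of spurious detections.
#' @param burst If `TRUE`, deletions come in geometric run-length bursts
#'   (mean `burst_len`) instead of i.i.d. per frame, mimicking the bursty
#'   errors of real detectors.
#' @param burst_len Mean burst length in detections.
#' @return A `peg_noise_spec`.
#' @export
noise_spec <- function(fp_rate = 0, fn_rate = 0, jitter_sigma_px = 0,
                       conf_range = c(0.5, 0.99), burst = FALSE,
                       burst_len = 5) {
  expand <- function(r) {
    if (is.null(names(r))) {
      stats::setNames(rep(r[1], 4), det_classes)
    } else {
      out <- stats::setNames(rep(0, 4), det_classes)
      out[names(r)] <- r
      out
    }
  }
  fp <- expand(fp_rate); fn <- expand(fn_rate)
  if (any(fp < 0 | fp >= 1) || any(fn < 0 | fn > 1)) {
    stop_pegtransfer("noise rates must lie in [0, 1)", "peg_validation_error")
  }
  if (jitter_sigma_px < 0) {
    stop_pegtransfer("jitter sigma must be >= 0", "peg_validation_error")
  }
  structure(list(fp_rate = fp, fn_rate = fn,
                 jitter_sigma_px = jitter_sigma_px, conf_range = conf_range,
                 burst = isTRUE(burst), burst_len = burst_len),
            class = "peg_noise_spec")
}

#' Inject detector noise into a stream
#'
#' Seeded pseudo-random deletion of true detections, insertion of spurious
#' boxes (uniform position, class-typical size) and Gaussian box-centre
#' jitter. The same seed reproduces the same output exactly.
#'
#' @param stream A `peg_stream`.
#' @param spec A [noise_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A new `peg_stream`.
#' @export
inject_noise <- function(stream, spec = noise_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  meta <- stream_meta(stream)
  d <- as_tibble(stream)
  # deletions
  if (nrow(d) > 0) {
    keep <- rep(TRUE, nrow(d))
    for (cl in det_classes) {
      idx <- which(d$cls == cl)
      if (length(idx) == 0) next
      p <- spec$fn_rate[[cl]]
      if (p <= 0) next
      if (p >= 1) { keep[idx] <- FALSE; next }
      keep[idx] <- if (spec$burst) {
        !burst_mask(length(idx), p, spec$burst_len)
      } else {
        stats::runif(length(idx)) >= p
      }
    }
    d <- d[keep, , drop = FALSE]
  }
  # jitter
  if (spec$jitter_sigma_px > 0 && nrow(d) > 0) {
    dx <- stats::rnorm(nrow(d), 0, spec$jitter_sigma_px)
    dy <- stats::rnorm(nrow(d), 0, spec$jitter_sigma_px)
    d$x_min <- d$x_min + dx; d$x_max <- d$x_max + dx
    d$y_min <- d$y_min + dy; d$y_max <- d$y_max + dy
  }
  # spurious insertions
  half_sizes <- list(peg = c(peg_half, peg_half),
                     rubber = c(ring_half, ring_half),
                     dissector = c(diss_half_w, diss_half_h),
                     grab = c(grab_half, grab_half))
  fp <- list()
  for (cl in det_classes) {
    p <- spec$fp_rate[[cl]]
    if (p <= 0) next
    hit <- which(stats::runif(meta$frame_count) < p) - 1L
    if (length(hit) == 0) next
    h <- half_sizes[[cl]]
    cx <- stats::runif(length(hit), h[1], meta$image_size[1] - h[1])
    cy <- stats::runif(length(hit), h[2], meta$image_size[2] - h[2])
    fp[[cl]] <- tibble(
      frame = hit, cls = cl,
      x_min = cx - h[1], y_min = cy - h[2],
      x_max = cx + h[1], y_max = cy + h[2],
      confidence = stats::runif(length(hit), spec$conf_range[1],
                                spec$conf_range[2])
    )
  }
  d <- dplyr::bind_rows(c(list(d), fp))
  detection_stream(d, video_id = meta$video_id, fps = meta$fps,
                   frame_count = meta$frame_count,
                   image_size = meta$image_size)
}

# Two-state Markov deletion mask with marginal rate p and mean run length L.
burst_mask <- function(n, p, L) {
  p_exit <- 1 / L
  p_enter <- min(1, p * p_exit / (1 - p))
  state <- stats::runif(1) < p
  out <- logical(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    out[i] <- state
    state <- if (state) u[i] >= p_exit else u[i] < p_enter
  }
  out
}
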