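test_that("duration is measured from first pickup to last release", {
  s1 <- session_row("r1", 0, 299, "L", "R", origin = 1, dest = 7,
                    overlap = TRUE)
  expect_equal(measure_duration(board_sessions(s1), fps = 30), 10.00)

  s2 <- board_sessions(
    session_row("r1", 100, 200, "L", "R", origin = 1, dest = 7, overlap = TRUE),
    session_row("r2", 400, 700, "L", "R", origin = 2, dest = 8, overlap = TRUE)
  )
  expect_equal(measure_duration(s2, fps = 30), 20.03)

  expect_error(measure_duration(board_sessions(), fps = 30),
               class = "peg_undefined_duration")
})

test_that("segmentation recovers holds, exchanges and end reasons", {
  # single hold, ring rests on peg 1 before and peg 8 after
  tl <- make_timelines(400,
                       grab_l = list(list(from = 100, to = 300, ring = "a")),
                       contact = list(list(peg = 1, from = 0, to = 102, ring = "a"),
                                      list(peg = 8, from = 299, to = 399, ring = "a")))
  s <- segment_sessions(tl, gap_tol_frames = 2, handover_gap_max = 3)
  expect_equal(nrow(s), 1)
  expect_equal(s$start_frame, 100)
  expect_equal(s$end_frame, 300)
  expect_equal(s$pickup_instrument, "L")
  expect_equal(s$release_instrument, "L")
  expect_equal(s$end_reason, "placed")
  expect_equal(s$origin_peg, 1L)
  expect_equal(s$destination_peg, 8L)

  # mid-air exchange: overlapping holds become one two-holder session
  tl <- make_timelines(400,
                       grab_l = list(list(from = 100, to = 210, ring = "a")),
                       grab_r = list(list(from = 200, to = 300, ring = "a")),
                       contact = list(list(peg = 2, from = 0, to = 101, ring = "a"),
                                      list(peg = 9, from = 298, to = 399, ring = "a")))
  s <- segment_sessions(tl, gap_tol_frames = 2, handover_gap_max = 3)
  expect_equal(nrow(s), 1)
  expect_equal(s$pickup_instrument, "L")
  expect_equal(s$release_instrument, "R")
  expect_true(s$exchange_overlap)
  expect_equal(nrow(s$holders[[1]]), 2)

  # no grab frames at all -> no sessions
  tl <- make_timelines(50)
  expect_equal(nrow(segment_sessions(tl)), 0)

  # short flicker gaps are bridged; a mid-air end with no re-grab is a drop
  tl <- make_timelines(200,
                       grab_l = list(list(from = 10, to = 60, ring = "a"),
                                     list(from = 63, to = 100, ring = "a")))
  s <- segment_sessions(tl, gap_tol_frames = 2, handover_gap_max = 3)
  expect_equal(nrow(s), 1)
  expect_equal(s$end_reason, "dropped")
})

test_that("transfers group sessions and classify handovers", {
  geo <- board_template()
  cfg <- eval_config()

  # same-instrument carry across the board: completed but no exchange
  s <- board_sessions(session_row("r1", 10, 80, "L", "L", origin = 1, dest = 7))
  tr <- assemble_transfers(s, geo, cfg)
  expect_equal(nrow(tr), 1)
  expect_true(tr$completed)
  expect_false(tr$changed)
  expect_equal(tr$direction, "left_to_right")
  p <- detect_pitfalls(tr, s, cfg)
  expect_equal(p$kind, "missed_handover")

  # mid-air exchange -> valid handover, no pitfalls
  s <- board_sessions(session_row("r1", 10, 80, "L", "R", origin = 1,
                                  dest = 7, overlap = TRUE))
  tr <- assemble_transfers(s, geo, cfg)
  expect_true(tr$handover_valid)
  expect_equal(nrow(detect_pitfalls(tr, s, cfg)), 0)

  # drop, opposite-instrument re-pickup far beyond the handover gap
  s <- board_sessions(
    session_row("r1", 10, 50, "L", "L", end_reason = "dropped", origin = 1),
    session_row("r1", 80, 150, "R", "R", dest = 7)
  )
  tr <- assemble_transfers(s, geo, cfg)
  expect_true(tr$completed)
  expect_true(tr$changed)
  expect_false(tr$handover_valid)
  p <- detect_pitfalls(tr, s, cfg)
  expect_setequal(p$kind, c("invalid_release", "invalid_handover"))

  # placement back on the origin side keeps the transfer open
  s <- board_sessions(
    session_row("r1", 10, 50, "L", "R", origin = 1, dest = 2, overlap = TRUE),
    session_row("r1", 80, 150, "R", "R", origin = 2, dest = 7)
  )
  tr <- assemble_transfers(s, geo, cfg)
  expect_equal(nrow(tr), 1)
  expect_true(tr$completed)
  p <- detect_pitfalls(tr, s, cfg)
  expect_setequal(p$kind, c("invalid_release", "invalid_pickup"))

  # placement on an occupied peg
  s <- board_sessions(session_row("r1", 10, 80, "L", "R", origin = 1, dest = 7,
                                  overlap = TRUE, occupied = TRUE))
  tr <- assemble_transfers(s, geo, cfg)
  p <- detect_pitfalls(tr, s, cfg)
  expect_equal(p$kind, "invalid_release")
  expect_match(p$detail, "occupied")
})

test_that("pitfall rules honour their configuration toggles", {
  geo <- board_template()
  s <- board_sessions(session_row("r1", 10, 80, "L", "L", origin = 1, dest = 7))
  tr <- assemble_transfers(s, geo, eval_config())

  off <- eval_config(rule_missed_handover = FALSE)
  expect_equal(nrow(detect_pitfalls(tr, s, off)), 0)

  # literal-wording mode: differing pickup/release instruments flag the
  # transfer instead
  s2 <- board_sessions(session_row("r1", 10, 80, "L", "R", origin = 1,
                                   dest = 7, overlap = TRUE))
  tr2 <- assemble_transfers(s2, geo, eval_config())
  strict <- eval_config(strict_paper_wording = TRUE)
  expect_equal(detect_pitfalls(tr2, s2, strict)$kind, "missed_handover")
  expect_equal(nrow(detect_pitfalls(tr, s, strict)), 0)
})

test_that("scoring combines pitfalls, duration and completion", {
  geo <- board_template()
  mk <- function(ring, start, origin, dest) {
    session_row(ring, start, start + 70, if (origin <= 6) "L" else "R",
                if (origin <= 6) "R" else "L", origin = origin, dest = dest,
                overlap = TRUE)
  }
  rings <- paste0("r", 1:6)
  rows <- c(
    purrr::map(1:6, function(i) mk(rings[i], 100 * i, i, 13 - i)),
    purrr::map(1:6, function(i) mk(rings[i], 700 + 100 * i, 13 - i, i))
  )
  s <- do.call(board_sessions, rows)
  tr <- assemble_transfers(s, geo, eval_config())
  p <- detect_pitfalls(tr, s, eval_config())
  expect_equal(nrow(p), 0)

  v <- score_exercise(tr, p, duration_s = 180, eval_config(), rings = rings)
  expect_equal(as.character(v), "pass")

  v <- score_exercise(tr, p, duration_s = 301, eval_config(), rings = rings)
  expect_equal(as.character(v), "fail")

  fake_pitfall <- tibble::tibble(kind = "missed_handover", ring_id = "r1",
                                 frame = 1L, detail = "")
  v <- score_exercise(tr, fake_pitfall, duration_s = 180, eval_config(),
                      rings = rings)
  expect_equal(as.character(v), "fail")

  # a ring with only one direction fails the bidirectional requirement
  one_dir <- assemble_transfers(
    do.call(board_sessions, purrr::map(1:6, function(i) mk(rings[i], 100 * i, i, 13 - i))),
    geo, eval_config())
  v <- score_exercise(one_dir, p[0, ], duration_s = 100, eval_config(),
                      rings = rings)
  expect_equal(as.character(v), "fail")
  v <- score_exercise(one_dir, p[0, ], duration_s = 100,
                      eval_config(require_bidirectional = FALSE), rings = rings)
  expect_equal(as.character(v), "pass")
})

test_that("an empty stream fails with an undefined-duration error", {
  empty <- detection_stream(
    tibble::tibble(frame = integer(), cls = character(), x_min = double(),
                   y_min = double(), x_max = double(), y_max = double(),
                   confidence = double()),
    video_id = "e", fps = 30, frame_count = 10, image_size = c(640, 480))
  expect_error(evaluate_stream(empty), class = "pegtransfer_error")
})
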