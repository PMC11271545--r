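test_that("detection streams parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".jsonl")

  # header-only file -> empty stream
  writeLines('{"video_id":"v0","fps":30.000000,"frame_count":5,"image_size":[640,480]}',
             path)
  s <- read_detection_stream(path)
  expect_equal(nrow(s), 0)
  expect_equal(stream_meta(s)$frame_count, 5L)

  # minimal one-detection file
  writeLines(c(
    '{"video_id":"v1","fps":30.000000,"frame_count":3,"image_size":[640,480]}',
    '{"frame":0,"cls":"peg","box":[10,10,20,20],"confidence":0.9}'
  ), path)
  s <- read_detection_stream(path)
  expect_equal(nrow(s), 1)
  expect_equal(s$cls, "peg")
  expect_equal(s$x_max, 20)

  # canonical write -> read -> write is byte-identical
  sim <- simulate_exercise(scenario_library()$single_direction_only)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_detection_stream(sim$stream, p1)
  write_detection_stream(read_detection_stream(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("detection stream errors identify the offending record", {
  path <- withr::local_tempfile(fileext = ".jsonl")

  writeLines('{"frame":0,"cls":"peg","box":[1,1,2,2],"confidence":0.9}', path)
  expect_error(read_detection_stream(path), class = "peg_format_error")

  writeLines(c(
    '{"video_id":"v","fps":30.0,"frame_count":3,"image_size":[640,480]}',
    '{"frame":0,"cls":"peg","box":[1,1,2,2],"confidence":0.9}',
    'not json at all {'
  ), path)
  expect_error(read_detection_stream(path), "line 3",
               class = "peg_parse_error")

  writeLines(c(
    '{"video_id":"v","fps":30.0,"frame_count":3,"image_size":[640,480]}',
    '{"frame":0,"cls":"peg","box":[1,1,2,2],"confidence":1.5}'
  ), path)
  expect_error(read_detection_stream(path), class = "peg_validation_error")

  writeLines(c(
    '{"video_id":"v","fps":30.0,"frame_count":3,"image_size":[640,480]}',
    '{"frame":0,"cls":"scissors","box":[1,1,2,2],"confidence":0.5}'
  ), path)
  expect_error(read_detection_stream(path), "scissors",
               class = "peg_validation_error")

  # detection beyond the declared frame count
  expect_error(
    tiny_stream(det_row(9, "peg", 50, 50), frame_count = 5),
    class = "peg_validation_error"
  )
})

test_that("same-frame detections get a deterministic tie-broken order", {
  d <- dplyr::bind_rows(
    det_row(0, "rubber", 300, 100),
    det_row(0, "peg", 200, 100),
    det_row(0, "peg", 100, 100)
  )
  s <- tiny_stream(d)
  expect_equal(s$cls, c("peg", "peg", "rubber"))
  expect_equal(s$x_min, c(90, 190, 290))
})

test_that("manual assessment sheets are validated", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("video_id,evaluator_id,verdict,duration_s", path)
  expect_equal(nrow(read_manual_assessments(path)), 0)

  writeLines(c("video_id,evaluator_id,verdict,duration_s",
               "v1,e1,pass,120.5", "v1,e2,FAIL,"), path)
  m <- read_manual_assessments(path)
  expect_equal(m$verdict, c("pass", "fail"))
  expect_equal(m$duration_s, c(120.5, NA))

  writeLines(c("video_id,evaluator_id,verdict,duration_s",
               "v1,e1,Passed,10"), path)
  expect_error(read_manual_assessments(path), "Passed",
               class = "peg_validation_error")

  writeLines(c("video_id,evaluator_id,verdict,duration_s",
               "v1,e1,pass,10", "v1,e1,fail,12"), path)
  expect_error(read_manual_assessments(path),
               class = "peg_duplicate_record_error")
})

test_that("results CSV has the exact schema and rounding", {
  path <- withr::local_tempfile(fileext = ".csv")

  write_results_csv(list(), path)
  expect_equal(readLines(path),
               paste("video_id,duration_s,n_sessions,n_valid_transfers",
                     "missed_handover,invalid_handover,invalid_pickup",
                     "invalid_release,verdict", sep = ","))

  row <- tibble::tibble(video_id = "v1", duration_s = 123.456,
                        n_sessions = 12L, n_valid_transfers = 12L,
                        missed_handover = 0L, invalid_handover = 0L,
                        invalid_pickup = 0L, invalid_release = 0L,
                        verdict = "pass")
  write_results_csv(row, path)
  expect_equal(readLines(path)[2], "v1,123.46,12,12,0,0,0,0,pass")
})

test_that("configuration files parse with defaults and validation", {
  path <- withr::local_tempfile(fileext = ".cfg")

  writeLines(character(0), path)
  cfg <- load_config(path)
  expect_s3_class(cfg, "peg_config")
  expect_equal(cfg$window_frames, 15L)
  expect_equal(cfg$on_threshold, 0.5)
  expect_equal(cfg$contact_tau, 0.1)
  expect_equal(cfg$gap_tol_frames, 2L)
  expect_equal(cfg$handover_gap_max, 3L)
  expect_equal(cfg$time_limit_s, 300)
  expect_true(cfg$require_bidirectional)
  expect_equal(cfg$max_allowed_pitfalls, 0L)

  writeLines(c("window_frames = 21", "# a comment",
               "time_limit_s = 240"), path)
  cfg <- load_config(path)
  expect_equal(cfg$window_frames, 21L)
  expect_equal(cfg$time_limit_s, 240)
  expect_equal(cfg$on_threshold, 0.5)

  writeLines("window_frames = 10", path)
  expect_error(load_config(path), class = "peg_validation_error")

  writeLines("no_such_key = 4", path)
  expect_warning(cfg <- load_config(path), "no_such_key")
  expect_equal(cfg$window_frames, 15L)
})
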