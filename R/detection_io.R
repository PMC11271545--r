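#' Construct a detection stream
#'
#' A detection stream is the package's primary input: one row per detected
#' object instance on one frame of an exercise recording, plus recording
#' metadata. Boxes are in pixels, origin at the top-left corner, half-open on
#' the max edges; frames are 0-based.
#'
#' @param detections A data frame with columns `frame`, `cls`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `confidence`. `cls` must be one of
#'   `"peg"`, `"rubber"`, `"dissector"`, `"grab"`.
#' @param video_id Identifier of the recording.
#' @param fps Frames per second (> 0).
#' @param frame_count Total number of frames (> 0); all detection frames must
#'   be smaller.
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @return A tibble of detections in canonical order (frame, then class in
#'   the order peg, rubber, dissector, grab, then `x_min`), of class
#'   `peg_stream`, carrying `video_id`, `fps`, `frame_count` and `image_size`
#'   as attributes.
#' @examples
#' detection_stream(
#'   tibble::tibble(frame = 0L, cls = "peg", x_min = 10, y_min = 10,
#'                  x_max = 20, y_max = 20, confidence = 0.9),
#'   video_id = "v1", fps = 30, frame_count = 10, image_size = c(640, 480)
#' )
#' @export
detection_stream <- function(detections, video_id, fps, frame_count,
                             image_size) {
  detections <- as_tibble(detections)
  needed <- c("frame", "cls", "x_min", "y_min", "x_max", "y_max", "confidence")
  missing_cols <- setdiff(needed, names(detections))
  if (length(missing_cols) > 0) {
    stop_pegtransfer(
      paste0("detections lack column(s): ", paste(missing_cols, collapse = ", ")),
      "peg_validation_error"
    )
  }
  detections <- detections[needed]
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop_pegtransfer("fps must be a single positive number", "peg_validation_error")
  }
  frame_count <- as.integer(frame_count)
  if (is.na(frame_count) || frame_count <= 0) {
    stop_pegtransfer("frame_count must be a positive integer", "peg_validation_error")
  }
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(is.na(image_size)) || any(image_size <= 0)) {
    stop_pegtransfer("image_size must be two positive integers", "peg_validation_error")
  }
  detections$frame <- as.integer(detections$frame)
  validate_detections(detections, frame_count)
  ord <- order(detections$frame, match(detections$cls, det_classes),
               detections$x_min, detections$y_min, detections$x_max,
               detections$y_max, detections$confidence)
  detections <- detections[ord, ]
  structure(
    detections,
    video_id = as.character(video_id),
    fps = as.numeric(fps),
    frame_count = frame_count,
    image_size = image_size,
    class = c("peg_stream", class(tibble()))
  )
}

validate_detections <- function(d, frame_count) {
  bad <- function(which, why) {
    stop_pegtransfer(
      sprintf("invalid detection record %d: %s", which, why),
      "peg_validation_error"
    )
  }
  if (nrow(d) == 0) return(invisible(d))
  i <- which(!(d$cls %in% det_classes))
  if (length(i) > 0) bad(i[1], paste0("unknown class '", d$cls[i[1]], "'"))
  i <- which(is.na(d$frame) | d$frame < 0L)
  if (length(i) > 0) bad(i[1], "frame must be a non-negative integer")
  i <- which(d$frame >= frame_count)
  if (length(i) > 0) bad(i[1], sprintf("frame %d >= frame_count %d", d$frame[i[1]], frame_count))
  i <- which(!(d$x_min < d$x_max) | !(d$y_min < d$y_max))
  if (length(i) > 0) bad(i[1], "box must satisfy x_min < x_max and y_min < y_max")
  i <- which(is.na(d$confidence) | d$confidence < 0 | d$confidence > 1)
  if (length(i) > 0) bad(i[1], "confidence must lie in [0, 1]")
  invisible(d)
}

#' Stream metadata accessors
#'
#' @param stream A `peg_stream`.
#' @return `stream_meta()` returns a list with `video_id`, `fps`,
#'   `frame_count` and `image_size`.
#' @export
stream_meta <- function(stream) {
  list(
    video_id = attr(stream, "video_id"),
    fps = attr(stream, "fps"),
    frame_count = attr(stream, "frame_count"),
    image_size = attr(stream, "image_size")
  )
}

#' Read a detection stream from a JSON-Lines file
#'
#' The dialect is one JSON object per line: a header object with keys
#' `video_id`, `fps`, `frame_count` and `image_size` (`[width, height]`),
#' followed by one object per detection with keys `frame`, `cls`, `box`
#' (`[x_min, y_min, x_max, y_max]`) and `confidence`.
#'
#' @param path Path to the JSONL file.
#' @return A validated, canonically sorted [detection_stream()].
#' @export
read_detection_stream <- function(path) {
  if (!file.exists(path)) {
    stop_pegtransfer(paste0("no such file: ", path), "peg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_pegtransfer("empty file: missing header object", "peg_format_error")
  }
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) NULL)
  if (is.null(header) || !all(c("video_id", "fps", "frame_count", "image_size")
                              %in% names(header))) {
    stop_pegtransfer(
      "first line must be a header object with video_id, fps, frame_count, image_size",
      "peg_format_error"
    )
  }
  det <- parse_detection_lines(lines[-1])
  detection_stream(det,
                   video_id = header$video_id, fps = header$fps,
                   frame_count = header$frame_count,
                   image_size = header$image_size)
}

parse_detection_lines <- function(lines) {
  empty <- tibble(frame = integer(), cls = character(), x_min = double(),
                  y_min = double(), x_max = double(), y_max = double(),
                  confidence = double())
  if (length(lines) == 0) return(empty)
  parsed <- vector("list", length(lines))
  cls <- character(length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(obj)) {
      stop_pegtransfer(
        sprintf("parse error at line %d: malformed JSON", i + 1L),
        "peg_parse_error"
      )
    }
    if (!all(c("frame", "cls", "box", "confidence") %in% names(obj)) ||
        length(obj$box) != 4) {
      stop_pegtransfer(
        sprintf("parse error at line %d: expected keys frame, cls, box[4], confidence", i + 1L),
        "peg_parse_error"
      )
    }
    parsed[[i]] <- c(obj$frame, obj$box, obj$confidence)
    cls[i] <- as.character(obj$cls)
  }
  m <- do.call(rbind, parsed)
  tibble(
    frame = as.integer(m[, 1]),
    cls = cls,
    x_min = m[, 2], y_min = m[, 3], x_max = m[, 4], y_max = m[, 5],
    confidence = m[, 6]
  )
}

#' Write a detection stream as canonical JSON-Lines
#'
#' Writes the header object first, then detections in canonical sort order
#' with a fixed key order and reals at 6 decimals, so that
#' `write_detection_stream(read_detection_stream(p))` reproduces `p`
#' byte-identically for canonically formatted files.
#'
#' @param stream A `peg_stream`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_detection_stream <- function(stream, path) {
  meta <- stream_meta(stream)
  header <- sprintf('{"video_id":"%s","fps":%.6f,"frame_count":%d,"image_size":[%d,%d]}',
                    meta$video_id, meta$fps, meta$frame_count,
                    meta$image_size[1], meta$image_size[2])
  if (nrow(stream) > 0) {
    body <- sprintf('{"frame":%d,"cls":"%s","box":[%.6f,%.6f,%.6f,%.6f],"confidence":%.6f}',
                    stream$frame, stream$cls, stream$x_min, stream$y_min,
                    stream$x_max, stream$y_max, stream$confidence)
    out <- c(header, body)
  } else {
    out <- header
  }
  tryCatch(writeLines(out, path),
           error = function(e) stop_pegtransfer(
             paste0("cannot write ", path, ": ", conditionMessage(e)), "peg_io_error"))
  invisible(path)
}

#' Read manual assessment sheets
#'
#' @param path CSV file with header `video_id,evaluator_id,verdict,duration_s`.
#'   Verdicts are parsed case-insensitively from the strict vocabulary
#'   `pass`/`fail`; `duration_s` may be empty.
#' @return A tibble with one validated row per (video, evaluator) assessment.
#' @export
read_manual_assessments <- function(path) {
  if (!file.exists(path)) {
    stop_pegtransfer(paste0("no such file: ", path), "peg_io_error")
  }
  d <- readr::read_csv(path, col_types = readr::cols(
    video_id = readr::col_character(),
    evaluator_id = readr::col_character(),
    verdict = readr::col_character(),
    duration_s = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("video_id", "evaluator_id", "verdict", "duration_s"),
                          names(d))
  if (length(missing_cols) > 0) {
    stop_pegtransfer(
      paste0("assessment sheet lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "peg_format_error"
    )
  }
  if (nrow(d) == 0) return(as_tibble(d))
  v <- tolower(d$verdict)
  bad <- which(!(v %in% c("pass", "fail")))
  if (length(bad) > 0) {
    stop_pegtransfer(
      sprintf("row %d: unknown verdict token '%s' (expected pass/fail)",
              bad[1], d$verdict[bad[1]]),
      "peg_validation_error"
    )
  }
  d$verdict <- v
  dup <- duplicated(d[c("video_id", "evaluator_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_pegtransfer(
      sprintf("duplicate record for video '%s', evaluator '%s' (row %d)",
              d$video_id[i], d$evaluator_id[i], i),
      "peg_duplicate_record_error"
    )
  }
  bad <- which(!is.na(d$duration_s) & d$duration_s < 0)
  if (length(bad) > 0) {
    stop_pegtransfer(sprintf("row %d: negative duration", bad[1]),
                     "peg_validation_error")
  }
  d
}

results_csv_header <- c("video_id", "duration_s", "n_sessions",
                        "n_valid_transfers", "missed_handover",
                        "invalid_handover", "invalid_pickup",
                        "invalid_release", "verdict")

#' Write exercise results to CSV
#'
#' Writes one row per evaluated exercise under the fixed header
#' `video_id,duration_s,n_sessions,n_valid_transfers,missed_handover,`
#' `invalid_handover,invalid_pickup,invalid_release,verdict`, durations at
#' 2 decimals.
#'
#' @param results A `peg_result`, a list of them, or a tibble as returned by
#'   `glance()` on a `peg_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(results, path) {
  rows <- results_to_rows(results)
  lines <- paste(results_csv_header, collapse = ",")
  if (nrow(rows) > 0) {
    body <- sprintf("%s,%.2f,%d,%d,%d,%d,%d,%d,%s",
                    rows$video_id, round_half_up(rows$duration_s, 2),
                    rows$n_sessions, rows$n_valid_transfers,
                    rows$missed_handover, rows$invalid_handover,
                    rows$invalid_pickup, rows$invalid_release, rows$verdict)
    lines <- c(lines, body)
  }
  tryCatch(writeLines(lines, path),
           error = function(e) stop_pegtransfer(
             paste0("cannot write ", path, ": ", conditionMessage(e)), "peg_io_error"))
  invisible(path)
}

results_to_rows <- function(results) {
  if (inherits(results, "peg_result")) results <- list(results)
  if (is.data.frame(results)) {
    rows <- as_tibble(results)
  } else {
    rows <- purrr::map_dfr(results, glance)
  }
  if (nrow(rows) == 0) {
    rows <- tibble(video_id = character(), duration_s = double(),
                   n_sessions = integer(), n_valid_transfers = integer(),
                   missed_handover = integer(), invalid_handover = integer(),
                   invalid_pickup = integer(), invalid_release = integer(),
                   verdict = character())
  }
  rows[results_csv_header]
}
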