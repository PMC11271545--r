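#' Decide the pass/fail verdict
#'
#' An exercise passes when the pitfall count does not exceed
#' `max_allowed_pitfalls`, the duration is within `time_limit_s`, and every
#' ring has a completed, handover-valid transfer in each required direction
#' (both directions when `require_bidirectional`).
#'
#' @param transfers Transfer tibble.
#' @param pitfalls Pitfall tibble.
#' @param duration_s Measured duration in seconds.
#' @param config A `peg_config`.
#' @param rings Ring universe to check for completion; defaults to the rings
#'   appearing in `transfers`.
#' @return `"pass"` or `"fail"`, with attribute `reasons` (character vector,
#'   empty on pass).
#' @export
score_exercise <- function(transfers, pitfalls, duration_s,
                           config = eval_config(), rings = NULL) {
  rings <- rings %||% unique(transfers$ring_id)
  reasons <- character(0)
  if (nrow(pitfalls) > config$max_allowed_pitfalls) {
    reasons <- c(reasons, sprintf("%d pitfall(s) exceed allowance of %d",
                                  nrow(pitfalls), config$max_allowed_pitfalls))
  }
  if (is.na(duration_s) || duration_s > config$time_limit_s) {
    reasons <- c(reasons, sprintf("duration %.2f s exceeds limit %.2f s",
                                  duration_s, config$time_limit_s))
  }
  need <- if (config$require_bidirectional) {
    c("left_to_right", "right_to_left")
  } else {
    NA_character_
  }
  ok <- transfers$completed & transfers$handover_valid
  for (r in rings) {
    mine <- transfers[transfers$ring_id == r & ok, ]
    if (length(need) == 1 && is.na(need)) {
      if (nrow(mine) == 0) {
        reasons <- c(reasons, sprintf("ring %s has no completed valid transfer", r))
      }
    } else {
      for (d in need) {
        if (!any(mine$direction == d, na.rm = TRUE)) {
          reasons <- c(reasons,
                       sprintf("ring %s lacks a completed valid %s transfer", r, d))
        }
      }
    }
  }
  verdict <- if (length(reasons) == 0) "pass" else "fail"
  structure(verdict, reasons = reasons)
}

#' Evaluate a detection stream end to end
#'
#' Composes the full assessment pipeline: tracking, board-geometry
#' inference, raw grab/contact state derivation, sliding-average debouncing,
#' session segmentation, transfer assembly, pitfall detection, duration
#' measurement and the pass/fail verdict. Deterministic for fixed inputs and
#' configuration.
#'
#' @param stream A `peg_stream`.
#' @param config A `peg_config`.
#' @return A `peg_result` object; see [glance.peg_result()] for the summary
#'   row and [tidy.peg_result()] for the pitfall table.
#' @export
evaluate_stream <- function(stream, config = eval_config()) {
  meta <- stream_meta(stream)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "pegtransfer_stage_error")) stop(e)
      abort(sprintf("stage '%s' failed for video '%s': %s",
                    name, meta$video_id, conditionMessage(e)),
            class = c(setdiff(class(e)[1], "simpleError"),
                      "pegtransfer_stage_error", "pegtransfer_error"),
            parent = e)
    })
  }
  tracks <- stage("tracking",
                  track_objects(stream, max_jump_px = config$max_jump_px,
                                patience = config$track_patience))
  geometry <- stage("geometry", infer_board_geometry(tracks))
  grab_states <- stage("grab_states",
                       derive_grab_states(tracks, stream, geometry,
                                          min_track_support = config$min_track_support))
  contact_states <- stage("contact_states",
                          derive_contact_states(tracks, geometry,
                                                tau = config$contact_tau,
                                                min_track_support = config$min_track_support))
  raw <- peg_timelines(grab_states, contact_states, meta$frame_count, meta$fps)
  filtered <- stage("filter",
                    filter_timelines(raw, window = config$window_frames,
                                     threshold = config$on_threshold))
  sessions <- stage("sessions",
                    segment_sessions(filtered,
                                     gap_tol_frames = effective_gap_tol(config),
                                     handover_gap_max = effective_handover_gap(config)))
  sessions <- flag_occupied_destinations(sessions, filtered,
                                         effective_handover_gap(config))
  attr(sessions, "geometry") <- geometry
  transfers <- stage("transfers",
                     assemble_transfers(sessions, geometry, config))
  pitfalls <- stage("pitfalls", detect_pitfalls(transfers, sessions, config))
  duration_s <- stage("duration", measure_duration(sessions, meta$fps))
  rings <- ring_universe(filtered, config)
  verdict <- score_exercise(transfers, pitfalls, duration_s, config, rings)
  structure(
    list(
      video_id = meta$video_id,
      fps = meta$fps,
      duration_s = duration_s,
      sessions = sessions,
      transfers = transfers,
      pitfalls = pitfalls,
      verdict = as.character(verdict),
      fail_reasons = attr(verdict, "reasons"),
      rings = rings,
      filter_report = attr(filtered, "filter_report"),
      timelines = filtered,
      geometry = geometry,
      config = config
    ),
    class = "peg_result"
  )
}

# Rings taking part in the exercise: rubbers ever held, plus rubbers that
# rest on some peg for a substantial part of the stream (untouched rings).
# The resting criterion is deliberately coarse (20% of frames) so that
# short-lived ghost tracks spawned by detector noise do not enter the
# completion check.
ring_universe <- function(timelines, config) {
  held <- unique(stats::na.omit(c(timelines$grab_ring$L, timelines$grab_ring$R)))
  occ <- as.vector(timelines$contact_ring)
  occ <- occ[!is.na(occ)]
  tab <- table(occ)
  resting <- names(tab)[tab >= 0.2 * timelines$frame_count]
  sort(unique(c(held, resting)))
}

#' @export
print.peg_result <- function(x, ...) {
  cat(sprintf("<peg_result> video '%s': %s in %.2f s\n", x$video_id,
              toupper(x$verdict), x$duration_s))
  cat(sprintf("  %d sessions, %d transfers (%d valid), %d pitfall(s)\n",
              nrow(x$sessions), nrow(x$transfers),
              sum(x$transfers$completed & x$transfers$handover_valid),
              nrow(x$pitfalls)))
  if (nrow(x$pitfalls) > 0) {
    counts <- table(x$pitfalls$kind)
    cat("  pitfalls:", paste(names(counts), counts, sep = "=", collapse = ", "),
        "\n")
  }
  if (length(x$fail_reasons) > 0) {
    cat("  reasons:", paste(x$fail_reasons, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Summarise an exercise result as one row
#'
#' @param x A `peg_result`.
#' @param ... Unused.
#' @return A one-row tibble matching the results CSV schema.
#' @method glance peg_result
#' @export
glance.peg_result <- function(x, ...) {
  kinds <- c("missed_handover", "invalid_handover", "invalid_pickup",
             "invalid_release")
  counts <- vapply(kinds, function(k) sum(x$pitfalls$kind == k), integer(1))
  tibble(
    video_id = x$video_id,
    duration_s = x$duration_s,
    n_sessions = nrow(x$sessions),
    n_valid_transfers = sum(x$transfers$completed & x$transfers$handover_valid),
    missed_handover = counts[["missed_handover"]],
    invalid_handover = counts[["invalid_handover"]],
    invalid_pickup = counts[["invalid_pickup"]],
    invalid_release = counts[["invalid_release"]],
    verdict = x$verdict
  )
}

#' Tidy an exercise result into its pitfall records
#'
#' @param x A `peg_result`.
#' @param ... Unused.
#' @return The pitfall tibble (`kind`, `ring_id`, `frame`, `detail`) with a
#'   `video_id` column prepended.
#' @method tidy peg_result
#' @export
tidy.peg_result <- function(x, ...) {
  dplyr::bind_cols(tibble(video_id = rep(x$video_id, nrow(x$pitfalls))),
                   x$pitfalls)
}
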