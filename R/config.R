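#' Evaluation configuration
#'
#' Houses every tunable of the assessment pipeline. Defaults correspond to a
#' 30 fps top-view recording: a 15-frame (~0.5 s) centred debouncing window,
#' and flicker tolerances of a few frames.
#'
#' @param window_frames Sliding-average window width in frames; odd, >= 1.
#' @param on_threshold Windowed-mean threshold in (0, 1] above which a state
#'   counts as on.
#' @param contact_tau Minimum ratio of (rubber box \eqn{\cap} peg box) area to
#'   rubber box area for a ring-peg contact, in (0, 1].
#' @param gap_tol_frames Gaps up to this many frames inside a session are
#'   bridged.
#' @param handover_gap_max Maximum gap, in frames, across which an
#'   instrument change still counts as a mid-air handover.
#' @param time_limit_s Exercise time limit in seconds.
#' @param require_bidirectional Must every ring complete a valid transfer in
#'   both directions to pass?
#' @param max_allowed_pitfalls Number of pitfalls tolerated before failing.
#' @param seed Seed recorded into run manifests.
#' @param max_jump_px Tracking association gate in pixels per frame.
#' @param track_patience Frames a track survives without a detection.
#' @param min_track_support Minimum detections for a rubber/dissector track
#'   to take part in state derivation.
#' @param strict_paper_wording If `TRUE`, a completed transfer whose pickup
#'   and release instruments differ is flagged as a missed handover (the
#'   literal wording of the rule); the default treats an exchange between
#'   instruments with a mid-air handover as the valid execution.
#' @param strict_drop_pickup If `TRUE`, re-pickup of a dropped ring by the
#'   opposite instrument additionally raises `invalid_pickup`.
#' @param rule_missed_handover,rule_invalid_handover,rule_invalid_pickup,rule_invalid_release
#'   Individual pitfall-rule toggles.
#' @return A list of class `peg_config`.
#' @export
eval_config <- function(window_frames = 15L,
                        on_threshold = 0.5,
                        contact_tau = 0.1,
                        gap_tol_frames = 2L,
                        handover_gap_max = 3L,
                        time_limit_s = 300,
                        require_bidirectional = TRUE,
                        max_allowed_pitfalls = 0L,
                        seed = 0L,
                        max_jump_px = 40,
                        track_patience = 10L,
                        min_track_support = 3L,
                        strict_paper_wording = FALSE,
                        strict_drop_pickup = FALSE,
                        rule_missed_handover = TRUE,
                        rule_invalid_handover = TRUE,
                        rule_invalid_pickup = TRUE,
                        rule_invalid_release = TRUE) {
  cfg <- list(
    window_frames = as.integer(window_frames),
    on_threshold = as.numeric(on_threshold),
    contact_tau = as.numeric(contact_tau),
    gap_tol_frames = as.integer(gap_tol_frames),
    handover_gap_max = as.integer(handover_gap_max),
    time_limit_s = as.numeric(time_limit_s),
    require_bidirectional = isTRUE(require_bidirectional),
    max_allowed_pitfalls = as.integer(max_allowed_pitfalls),
    seed = as.integer(seed),
    max_jump_px = as.numeric(max_jump_px),
    track_patience = as.integer(track_patience),
    min_track_support = as.integer(min_track_support),
    strict_paper_wording = isTRUE(strict_paper_wording),
    strict_drop_pickup = isTRUE(strict_drop_pickup),
    rule_missed_handover = isTRUE(rule_missed_handover),
    rule_invalid_handover = isTRUE(rule_invalid_handover),
    rule_invalid_pickup = isTRUE(rule_invalid_pickup),
    rule_invalid_release = isTRUE(rule_invalid_release)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  w <- cfg$window_frames
  if (is.na(w) || w < 1L || w %% 2L == 0L) {
    stop_pegtransfer("window_frames must be an odd integer >= 1",
                     "peg_validation_error")
  }
  if (!(cfg$on_threshold > 0 && cfg$on_threshold <= 1)) {
    stop_pegtransfer("on_threshold must lie in (0, 1]", "peg_validation_error")
  }
  if (!(cfg$contact_tau > 0 && cfg$contact_tau <= 1)) {
    stop_pegtransfer("contact_tau must lie in (0, 1]", "peg_validation_error")
  }
  if (cfg$gap_tol_frames < 0L || cfg$handover_gap_max < 0L) {
    stop_pegtransfer("gap tolerances must be non-negative", "peg_validation_error")
  }
  if (!(cfg$time_limit_s > 0)) {
    stop_pegtransfer("time_limit_s must be positive", "peg_validation_error")
  }
  if (cfg$max_allowed_pitfalls < 0L) {
    stop_pegtransfer("max_allowed_pitfalls must be non-negative",
                     "peg_validation_error")
  }
  structure(cfg, class = "peg_config")
}

#' Load an evaluation configuration from a flat key-value file
#'
#' Lines are `key = value`; `#` starts a comment; unspecified keys take the
#' [eval_config()] defaults. Unknown keys produce a warning and are ignored.
#'
#' @param path Path to the config file.
#' @return A `peg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_pegtransfer(paste0("no such file: ", path), "peg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(eval_config)
  values <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop_pegtransfer(paste0("malformed config line: '", ln, "'"),
                       "peg_parse_error")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!(key %in% names(defaults))) {
      warn(paste0("unknown config key ignored: '", key, "'"))
      next
    }
    default <- eval(defaults[[key]])
    values[[key]] <- if (is.logical(default)) {
      tolower(val) %in% c("true", "t", "yes", "1")
    } else {
      suppressWarnings(as.numeric(val))
    }
    if (!is.logical(values[[key]]) && is.na(values[[key]])) {
      stop_pegtransfer(paste0("non-numeric value for key '", key, "': ", val),
                       "peg_parse_error")
    }
  }
  do.call(eval_config, values)
}

# Temporal resolution of the debouncer: a state edge can move by up to half
# the window, so gap tolerances below this cannot be honoured reliably.
filter_slack <- function(config) {
  config$window_frames %/% 2L + 1L
}

# Gap tolerances actually applied by the pipeline: at least the configured
# values, and never finer than the debouncer's edge resolution.
effective_gap_tol <- function(config) {
  max(config$gap_tol_frames, filter_slack(config))
}

effective_handover_gap <- function(config) {
  max(config$handover_gap_max, filter_slack(config))
}

#' @export
print.peg_config <- function(x, ...) {
  cat("<peg_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
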