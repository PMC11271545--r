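#' Sliding-average debouncing of a boolean state channel
#'
#' `out[i]` is `TRUE` when the mean of `x` over the centred window of width
#' `window` (truncated at the array edges) is at least `threshold`. This
#' suppresses isolated false positive/negative detections while preserving
#' runs of stable state.
#'
#' @param x Logical vector (a raw per-frame state channel).
#' @param window Odd window width >= 1, in frames.
#' @param threshold Mean threshold in (0, 1].
#' @return Logical vector of the same length.
#' @examples
#' sliding_average_filter(c(FALSE, TRUE, TRUE, FALSE, FALSE), 3, 0.5)
#' @export
sliding_average_filter <- function(x, window = 15L, threshold = 0.5) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_pegtransfer("window must be an odd integer >= 1", "peg_validation_error")
  }
  if (!(threshold > 0 && threshold <= 1)) {
    stop_pegtransfer("threshold must lie in (0, 1]", "peg_validation_error")
  }
  n <- length(x)
  if (n == 0) return(logical(0))
  h <- (window - 1L) %/% 2L
  cs <- c(0L, cumsum(as.integer(x)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  s <- cs[hi + 1L] - cs[lo]
  size <- hi - lo + 1L
  s >= threshold * size - 1e-9
}

# Resample a per-frame id attribute (held ring / occupying ring) after
# filtering: the modal id over the same centred window among frames where
# the raw channel was true. Frames turned on by the filter with no raw-true
# frame in the window inherit the nearest resolved id.
window_mode_ids <- function(ids, raw, filtered, window) {
  n <- length(ids)
  out <- rep(NA_character_, n)
  if (!any(filtered)) return(out)
  levels <- unique(ids[raw & !is.na(ids)])
  if (length(levels) == 0) return(out)
  h <- (as.integer(window) - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  counts <- vapply(levels, function(lv) {
    cs <- c(0L, cumsum(as.integer(raw & !is.na(ids) & ids == lv)))
    cs[hi + 1L] - cs[lo]
  }, integer(n))
  counts <- matrix(counts, nrow = n)
  best <- max.col(counts, ties.method = "first")
  any_support <- counts[cbind(i, best)] > 0L
  out[any_support] <- levels[best[any_support]]
  out <- fill_nearest(out)
  out[!filtered] <- NA_character_
  out
}

#' Debounce all channels of a timelines object
#'
#' Applies [sliding_average_filter()] to both grab channels and every peg
#' contact channel, re-samples the held-ring / occupying-ring attributes as
#' windowed modes, and attaches a per-group [filter_report()].
#'
#' @param timelines A `peg_timelines` (raw).
#' @param window,threshold See [sliding_average_filter()].
#' @return A filtered `peg_timelines` with attribute `filter_report` (a
#'   two-row tibble, groups `grab` and `contact`).
#' @export
filter_timelines <- function(timelines, window = 15L, threshold = 0.5) {
  tl <- timelines
  changed_grab <- 0L
  for (inst in names(tl$grab)) {
    raw <- timelines$grab[[inst]]
    filt <- sliding_average_filter(raw, window, threshold)
    changed_grab <- changed_grab + sum(raw != filt)
    tl$grab[[inst]] <- filt
    tl$grab_ring[[inst]] <- window_mode_ids(timelines$grab_ring[[inst]],
                                            raw, filt, window)
  }
  changed_contact <- 0L
  for (k in seq_len(ncol(tl$contact))) {
    raw <- timelines$contact[, k]
    filt <- sliding_average_filter(raw, window, threshold)
    changed_contact <- changed_contact + sum(raw != filt)
    tl$contact[, k] <- filt
    tl$contact_ring[, k] <- window_mode_ids(timelines$contact_ring[, k],
                                            raw, filt, window)
  }
  report <- dplyr::bind_rows(
    filter_report(frames_total = tl$frame_count, channels_max_per_frame = 2L,
                  changed = changed_grab, group = "grab"),
    filter_report(frames_total = tl$frame_count,
                  channels_max_per_frame = ncol(tl$contact),
                  changed = changed_contact, group = "contact")
  )
  attr(tl, "filter_report") <- report
  tl
}

#' Account for filtered-out detections
#'
#' Counts (frame, channel) cells whose state the debouncer changed — the
#' false positive/negative detections removed — and expresses them as a
#' percentage of all frame-channel cells. Aggregable across videos by
#' summing `frames_total x channels` and `changed` before computing the
#' percentage.
#'
#' @param raw,filtered Equal-shaped logical vectors/matrices (or lists of
#'   them), or `NULL` when `changed` is given directly.
#' @param frames_total Total frames accounted.
#' @param channels_max_per_frame Channels per frame (2 for grab, 12 for a
#'   full pegboard).
#' @param changed Pre-counted changed cells (alternative to `raw`/`filtered`).
#' @param group Label, `"grab"` or `"contact"`.
#' @return One-row tibble: `group`, `frames`, `channels`, `changed`,
#'   `percent` (round-half-up, 2 decimals).
#' @examples
#' filter_report(frames_total = 3038120, channels_max_per_frame = 12,
#'               changed = 1333781, group = "contact")
#' @export
filter_report <- function(raw = NULL, filtered = NULL, frames_total,
                          channels_max_per_frame, changed = NULL,
                          group = "grab") {
  if (is.null(changed)) {
    if (is.list(raw) && !is.data.frame(raw)) {
      raw <- unlist(raw, use.names = FALSE)
      filtered <- unlist(filtered, use.names = FALSE)
    }
    if (length(raw) != length(filtered)) {
      stop_pegtransfer("raw and filtered must have identical shape",
                       "peg_validation_error")
    }
    changed <- sum(raw != filtered)
  }
  cells <- as.numeric(frames_total) * as.numeric(channels_max_per_frame)
  if (changed > cells) {
    stop_pegtransfer("changed detections exceed frame-channel cells",
                     "peg_validation_error")
  }
  tibble(
    group = group,
    frames = as.numeric(frames_total),
    channels = as.integer(channels_max_per_frame),
    changed = as.numeric(changed),
    percent = round_half_up(100 * changed / cells, 2)
  )
}

#' Aggregate filter reports across videos
#'
#' @param reports A tibble of [filter_report()] rows.
#' @return One row per group with summed frames/changed counts and the
#'   recomputed percentage.
#' @export
aggregate_filter_reports <- function(reports) {
  reports |>
    dplyr::group_by(.data$group, .data$channels) |>
    dplyr::summarise(frames = sum(.data$frames),
                     changed = sum(.data$changed), .groups = "drop") |>
    dplyr::mutate(percent = round_half_up(
      100 * .data$changed / (.data$frames * .data$channels), 2)) |>
    dplyr::select("group", "frames", "channels", "changed", "percent")
}

#' Write a filter report CSV
#'
#' Columns: `group,frames,channels,changed,percent`.
#'
#' @param report Tibble of report rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  readr::write_csv(report[c("group", "frames", "channels", "changed",
                            "percent")], path, progress = FALSE)
  invisible(path)
}
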