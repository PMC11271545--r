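#' Segment filtered timelines into ring-holding sessions
#'
#' A session is a maximal interval during which some instrument continuously
#' holds one ring (gaps up to `gap_tol_frames` are bridged). Each session
#' records its pickup and release instruments, the ordered holder intervals,
#' how it ended (`placed` when the ring occupies a peg within
#' `handover_gap_max` frames of release, `stream_end` when held to the last
#' frame, otherwise `dropped`) and the origin/destination pegs.
#'
#' @param timelines A filtered `peg_timelines`.
#' @param gap_tol_frames Bridged gap length inside a session.
#' @param handover_gap_max Search window (frames) used to resolve the pegs
#'   at pickup/release.
#' @return A tibble with one row per session (0-based frames), sorted by
#'   `start_frame`, carrying per-ring contact vectors in attribute
#'   `ring_contact`.
#' @export
segment_sessions <- function(timelines, gap_tol_frames = 2L,
                             handover_gap_max = 3L) {
  tl <- timelines
  n <- tl$frame_count
  G <- as.integer(handover_gap_max)
  rings <- sort(unique(stats::na.omit(c(tl$grab_ring$L, tl$grab_ring$R))))
  ring_contact <- ring_contact_map(tl)
  out <- list()
  for (r in rings) {
    heldL <- tl$grab$L & !is.na(tl$grab_ring$L) & tl$grab_ring$L == r
    heldR <- tl$grab$R & !is.na(tl$grab_ring$R) & tl$grab_ring$R == r
    held <- heldL | heldR
    runs <- merge_runs(held, gap_tol_frames)
    if (nrow(runs) == 0) next
    occ <- ring_peg_occupancy(tl, r)
    for (j in seq_len(nrow(runs))) {
      s <- runs$start[j]; e <- runs$end[j]  # 1-based indices
      out[[length(out) + 1L]] <-
        build_session(r, s, e, heldL, heldR, occ,
                      ring_contact[[r]] %||% logical(n), n, G)
    }
  }
  sessions <- if (length(out) == 0) empty_sessions() else dplyr::bind_rows(out)
  sessions <- dplyr::arrange(sessions, .data$start_frame, .data$ring_id)
  attr(sessions, "ring_contact") <- ring_contact
  attr(sessions, "frame_count") <- n
  sessions
}

empty_sessions <- function() {
  tibble(ring_id = character(), start_frame = integer(), end_frame = integer(),
         pickup_instrument = character(), release_instrument = character(),
         end_reason = character(), origin_peg = integer(),
         destination_peg = integer(), exchange_overlap = logical(),
         holder_change = logical(), change_gap = integer(),
         change_contact = logical(), dest_occupied_by_other = logical(),
         holders = list())
}

# Any-peg contact vector per ring id.
ring_contact_map <- function(tl) {
  ids <- unique(stats::na.omit(as.vector(tl$contact_ring)))
  out <- lapply(ids, function(r) {
    m <- tl$contact & !is.na(tl$contact_ring) & tl$contact_ring == r
    rowSums(m) > 0
  })
  stats::setNames(out, ids)
}

# (frame index, peg) occupancy pairs for one ring.
ring_peg_occupancy <- function(tl, r) {
  m <- tl$contact & !is.na(tl$contact_ring) & tl$contact_ring == r
  idx <- which(m, arr.ind = TRUE)
  pegs <- as.integer(colnames(tl$contact))
  tibble(i = idx[, 1], peg = pegs[idx[, 2]])
}

merge_runs <- function(x, gap_tol) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) return(tibble(start = integer(), end = integer()))
  runs <- tibble(start = starts[on], end = ends[on])
  if (nrow(runs) > 1 && gap_tol > 0) {
    merged <- list(runs[1, ])
    for (j in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start[j] - last$end - 1L <= gap_tol) {
        merged[[length(merged)]]$end <- runs$end[j]
      } else {
        merged[[length(merged) + 1L]] <- runs[j, ]
      }
    }
    runs <- dplyr::bind_rows(merged)
  }
  runs
}

build_session <- function(r, s, e, heldL, heldR, occ, contact_any, n, G) {
  holder_runs <- function(h, inst) {
    rr <- merge_runs(h[s:e], 0L)
    if (nrow(rr) == 0) return(NULL)
    tibble(instrument = inst, start = rr$start + s - 2L, end = rr$end + s - 2L)
  }
  holders <- dplyr::bind_rows(holder_runs(heldL, "L"), holder_runs(heldR, "R"))
  holders <- dplyr::arrange(holders, .data$start, .data$end)
  pickup <- holders$instrument[1]
  release <- holders$instrument[which.max(holders$end)]
  exchange_overlap <- any(heldL[s:e] & heldR[s:e])
  insts <- unique(holders$instrument)
  holder_change <- length(insts) > 1
  change_gap <- 0L
  change_contact <- FALSE
  if (holder_change && !exchange_overlap && nrow(holders) > 1) {
    for (j in 2:nrow(holders)) {
      if (holders$instrument[j] != holders$instrument[j - 1]) {
        glen <- holders$start[j] - holders$end[j - 1] - 1L
        change_gap <- max(change_gap, glen)
        if (glen > 0) {
          gap_frames <- (holders$end[j - 1] + 2L):(holders$start[j])  # 1-based
          change_contact <- change_contact || any(contact_any[gap_frames])
        }
      }
    }
  }
  pre <- max(1L, s - G):s
  origin_hits <- occ[occ$i %in% pre, ]
  origin_peg <- if (nrow(origin_hits) == 0) NA_integer_ else
    origin_hits$peg[which.max(origin_hits$i)]
  post <- e:min(n, e + G)
  dest_hits <- occ[occ$i %in% post, ]
  if (nrow(dest_hits) > 0) {
    end_reason <- "placed"
    destination_peg <- dest_hits$peg[which.min(dest_hits$i)]
  } else if (e >= n) {
    end_reason <- "stream_end"
    destination_peg <- NA_integer_
  } else {
    end_reason <- "dropped"
    destination_peg <- NA_integer_
  }
  tibble(
    ring_id = r, start_frame = s - 1L, end_frame = e - 1L,
    pickup_instrument = pickup, release_instrument = release,
    end_reason = end_reason, origin_peg = origin_peg,
    destination_peg = as.integer(destination_peg),
    exchange_overlap = exchange_overlap, holder_change = holder_change,
    change_gap = change_gap, change_contact = change_contact,
    dest_occupied_by_other = FALSE,  # filled by caller with peg occupancy
    holders = list(holders)
  )
}

# Placement-on-occupied-peg flag: another ring occupies the destination peg
# in the approach window before release.
flag_occupied_destinations <- function(sessions, tl, handover_gap_max = 3L) {
  if (nrow(sessions) == 0) return(sessions)
  G <- as.integer(handover_gap_max)
  for (j in seq_len(nrow(sessions))) {
    if (is.na(sessions$destination_peg[j])) next
    k <- match(as.character(sessions$destination_peg[j]), colnames(tl$contact))
    if (is.na(k)) next
    e <- sessions$end_frame[j] + 1L
    win <- max(1L, e - G - 2L):min(tl$frame_count, e)
    others <- tl$contact[win, k] & !is.na(tl$contact_ring[win, k]) &
      tl$contact_ring[win, k] != sessions$ring_id[j]
    sessions$dest_occupied_by_other[j] <- any(others)
  }
  sessions
}

#' Measure exercise duration
#'
#' Time from the first pickup to the last release, inclusive:
#' `(last end_frame - first start_frame + 1) / fps`, rounded to 2 decimals.
#'
#' @param sessions A session tibble from [segment_sessions()].
#' @param fps Frames per second.
#' @return Duration in seconds.
#' @export
measure_duration <- function(sessions, fps) {
  if (is.null(sessions) || nrow(sessions) == 0) {
    stop_pegtransfer("duration is undefined: no sessions were found",
                     "peg_undefined_duration")
  }
  round_half_up((max(sessions$end_frame) - min(sessions$start_frame) + 1) / fps, 2)
}
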