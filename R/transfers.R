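#' Group sessions into transfers
#'
#' Consecutive sessions of one ring, from its leaving one side of the board
#' until it rests on a peg of the opposite side, form one transfer. A
#' placement back on the origin side does not end the transfer (it is an
#' invalid release; the ring is still owed to the other side). The handover
#' is valid when the ring changes instrument either mid-air (both grabs
#' overlap in time on the ring) or across a gap of at most
#' `handover_gap_max` frames with no peg contact of the ring inside the gap.
#'
#' @param sessions Session tibble from [segment_sessions()].
#' @param geometry A `peg_geometry` (for peg sides).
#' @param config A `peg_config`.
#' @return A tibble with one row per transfer: ring, direction, completion
#'   and handover flags, and the indices of its sessions (`session_rows`,
#'   into the sorted `sessions` argument).
#' @export
assemble_transfers <- function(sessions, geometry, config = eval_config()) {
  G <- effective_handover_gap(config)
  ring_contact <- attr(sessions, "ring_contact") %||% list()
  out <- list()
  for (r in unique(sessions$ring_id)) {
    rows <- which(sessions$ring_id == r)
    rows <- rows[order(sessions$start_frame[rows])]
    contact_any <- ring_contact[[r]] %||% logical(0)
    group <- integer(0)
    origin_side <- NA_character_
    for (i in rows) {
      if (length(group) == 0) {
        origin_side <- peg_side(geometry, sessions$origin_peg[i])
      }
      group <- c(group, i)
      placed <- sessions$end_reason[i] == "placed"
      dest_side <- peg_side(geometry, sessions$destination_peg[i])
      done <- placed && !is.na(dest_side) && !is.na(origin_side) &&
        dest_side != origin_side
      if (done) {
        out[[length(out) + 1L]] <-
          summarise_transfer(sessions, group, origin_side, dest_side,
                             completed = TRUE, geometry, G, contact_any)
        group <- integer(0)
      }
    }
    if (length(group) > 0) {
      last <- group[length(group)]
      dest_side <- peg_side(geometry, sessions$destination_peg[last])
      out[[length(out) + 1L]] <-
        summarise_transfer(sessions, group, origin_side, dest_side,
                           completed = FALSE, geometry, G, contact_any)
    }
  }
  transfers <- if (length(out) == 0) empty_transfers() else dplyr::bind_rows(out)
  dplyr::arrange(transfers, .data$start_frame, .data$ring_id)
}

empty_transfers <- function() {
  tibble(ring_id = character(), direction = character(),
         origin_side = character(), dest_side = character(),
         start_frame = integer(), end_frame = integer(),
         n_sessions = integer(), completed = logical(), changed = logical(),
         handover_valid = logical(), any_invalid_change = logical(),
         session_rows = list())
}

summarise_transfer <- function(sessions, group, origin_side, dest_side,
                               completed, geometry, G, contact_any) {
  ss <- sessions[group, ]
  pickup <- ss$pickup_instrument[1]
  release <- ss$release_instrument[nrow(ss)]
  changed <- pickup != release || any(ss$holder_change)
  n_valid <- 0L
  n_invalid <- 0L
  # within-session changes
  for (j in seq_len(nrow(ss))) {
    if (ss$holder_change[j]) {
      ok <- ss$exchange_overlap[j] ||
        (ss$change_gap[j] <= G && !ss$change_contact[j])
      if (ok) n_valid <- n_valid + 1L else n_invalid <- n_invalid + 1L
    }
  }
  # cross-session changes
  if (nrow(ss) > 1) {
    for (j in 2:nrow(ss)) {
      if (ss$pickup_instrument[j] != ss$release_instrument[j - 1]) {
        gap <- ss$start_frame[j] - ss$end_frame[j - 1] - 1L
        gap_frames <- seq2(ss$end_frame[j - 1] + 2L, ss$start_frame[j])  # 1-based
        touched <- length(gap_frames) > 0 && length(contact_any) > 0 &&
          any(contact_any[gap_frames])
        if (gap <= G && !touched) n_valid <- n_valid + 1L
        else n_invalid <- n_invalid + 1L
      }
    }
  }
  direction <- if (!is.na(origin_side) && !is.na(dest_side) &&
                   origin_side != dest_side) {
    if (origin_side == "left") "left_to_right" else "right_to_left"
  } else {
    NA_character_
  }
  tibble(
    ring_id = ss$ring_id[1], direction = direction,
    origin_side = origin_side, dest_side = dest_side,
    start_frame = min(ss$start_frame), end_frame = max(ss$end_frame),
    n_sessions = nrow(ss), completed = completed, changed = changed,
    handover_valid = n_valid > 0L, any_invalid_change = n_invalid > 0L,
    session_rows = list(group)
  )
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Detect pitfalls
#'
#' Applies the rule set to assembled transfers and sessions:
#' \describe{
#'   \item{missed_handover}{a completed transfer carried by one instrument
#'     throughout (no exchange occurred); with `strict_paper_wording`, the
#'     literal converse — pickup and release instruments differ.}
#'   \item{invalid_handover}{an exchange occurred but not mid-air (the
#'     instrument change happened across a drop or rest).}
#'   \item{invalid_pickup}{the ring was picked up from a peg of the side it
#'     was supposed to have left; with `strict_drop_pickup`, also re-pickup
#'     of a dropped ring by the opposite instrument.}
#'   \item{invalid_release}{a drop, a placement on an occupied peg, or a
#'     placement back on the origin side.}
#' }
#' Each rule can be disabled through its `rule_*` config toggle.
#'
#' @param transfers Transfer tibble from [assemble_transfers()].
#' @param sessions Session tibble from [segment_sessions()].
#' @param config A `peg_config`.
#' @return A tibble with columns `kind`, `ring_id`, `frame`, `detail`.
#' @export
detect_pitfalls <- function(transfers, sessions, config = eval_config()) {
  out <- list()
  add <- function(kind, ring, frame, detail) {
    out[[length(out) + 1L]] <<- tibble(kind = kind, ring_id = ring,
                                       frame = as.integer(frame),
                                       detail = detail)
  }
  for (i in seq_len(nrow(transfers))) {
    tr <- transfers[i, ]
    rows <- tr$session_rows[[1]]
    ss <- sessions[rows, ]
    if (config$rule_missed_handover && tr$completed) {
      missed <- if (config$strict_paper_wording) {
        ss$pickup_instrument[1] != ss$release_instrument[nrow(ss)]
      } else {
        !tr$changed
      }
      if (missed) {
        add("missed_handover", tr$ring_id, tr$end_frame,
            "no instrument exchange during the transfer")
      }
    }
    if (config$rule_invalid_handover && tr$completed && tr$changed &&
        !tr$handover_valid) {
      add("invalid_handover", tr$ring_id, tr$end_frame,
          "instrument change did not happen mid-air")
    }
    if (config$rule_invalid_pickup) {
      if (nrow(ss) > 1 && !is.na(tr$origin_side)) {
        for (j in 2:nrow(ss)) {
          side_j <- peg_side_of(sessions, ss, j)
          if (!is.na(side_j) && side_j == tr$origin_side) {
            add("invalid_pickup", tr$ring_id, ss$start_frame[j],
                "picked up from a peg of the side already left")
          }
          if (config$strict_drop_pickup &&
              ss$end_reason[j - 1] == "dropped" &&
              ss$pickup_instrument[j] != ss$release_instrument[j - 1]) {
            add("invalid_pickup", tr$ring_id, ss$start_frame[j],
                "dropped ring picked up by the opposite instrument")
          }
        }
      }
    }
    if (config$rule_invalid_release) {
      for (j in seq_len(nrow(ss))) {
        if (ss$end_reason[j] == "dropped") {
          add("invalid_release", tr$ring_id, ss$end_frame[j], "ring dropped")
        } else if (ss$end_reason[j] == "placed") {
          if (isTRUE(ss$dest_occupied_by_other[j])) {
            add("invalid_release", tr$ring_id, ss$end_frame[j],
                "placed on an occupied peg")
          }
          if (!is.na(tr$origin_side) &&
              isTRUE(peg_side_attr(sessions, ss$destination_peg[j]) ==
                       tr$origin_side)) {
            add("invalid_release", tr$ring_id, ss$end_frame[j],
                "placed back on the origin side")
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(kind = character(), ring_id = character(),
                  frame = integer(), detail = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$kind)
}

# Side of a session's origin peg; sessions carry a geometry attribute set by
# the pipeline so detect_pitfalls() does not need geometry re-passed.
peg_side_of <- function(sessions, ss, j) {
  peg_side_attr(sessions, ss$origin_peg[j])
}

peg_side_attr <- function(sessions, peg) {
  geometry <- attr(sessions, "geometry")
  if (is.null(geometry) || is.na(peg)) return(NA_character_)
  peg_side(geometry, peg)
}
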