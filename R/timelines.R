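#' Derive per-instrument grab states
#'
#' Each `grab` detection is assigned to the dissector track with the largest
#' box intersection (ties broken by centroid distance) and to the rubber
#' track with the largest intersection; grab detections overlapping no
#' dissector or no rubber are dropped. At most one grab per instrument per
#' frame survives (highest confidence wins).
#'
#' Instrument identity (`L`/`R`) is resolved per frame: whenever both
#' dissectors are visible the left one (smaller x centre) is `L`, and
#' frames with a single visible dissector inherit the label of the nearer
#' of the two continuously tracked instrument positions. Anchoring the
#' label to geometry rather than to track identity makes the channels
#' immune to tracking-identity swaps during the mid-air exchange.
#'
#' @param tracks A `peg_tracks` tibble.
#' @param stream The originating `peg_stream` (source of grab detections).
#' @param geometry Optional `peg_geometry`; supplies the board midline
#'   (defaults to half the image width).
#' @param min_track_support Rubber/dissector tracks with fewer detections are
#'   ignored.
#' @return A list with `grab` (named list `L`/`R` of logical frame vectors),
#'   `grab_ring` (matching ring-id vectors, `NA` where not grabbing) and
#'   `n_dropped_grabs`.
#' @export
derive_grab_states <- function(tracks, stream, geometry = NULL,
                               min_track_support = 3L) {
  n <- attr(tracks, "frame_count") %||% stream_meta(stream)$frame_count
  empty <- list(
    grab = list(L = logical(n), R = logical(n)),
    grab_ring = list(L = rep(NA_character_, n), R = rep(NA_character_, n)),
    n_dropped_grabs = 0L
  )
  grabs <- as_tibble(stream) |> dplyr::filter(.data$cls == "grab")
  if (nrow(grabs) == 0) return(empty)
  grabs$.gid <- seq_len(nrow(grabs))

  supported <- function(cl) {
    as_tibble(tracks) |>
      dplyr::filter(.data$cls == cl) |>
      dplyr::add_count(.data$object_id) |>
      dplyr::filter(.data$n >= min_track_support) |>
      dplyr::select("frame", "object_id", tx1 = "x_min", ty1 = "y_min",
                    tx2 = "x_max", ty2 = "y_max")
  }
  diss <- fill_track_boxes(supported("dissector"))
  rubb <- fill_track_boxes(supported("rubber"))
  if (nrow(diss) == 0 || nrow(rubb) == 0) {
    empty$n_dropped_grabs <- nrow(grabs)
    return(empty)
  }
  midline_x <- if (!is.null(geometry)) geometry$midline_x else {
    (attr(tracks, "image_size") %||% stream_meta(stream)$image_size)[1] / 2
  }
  diss <- label_instruments(diss, midline_x)
  diss <- diss[!is.na(diss$instrument), , drop = FALSE]
  if (nrow(diss) == 0) {
    empty$n_dropped_grabs <- nrow(grabs)
    return(empty)
  }

  best_overlap <- function(cand) {
    cand$inter <- box_intersection(cand$x_min, cand$y_min, cand$x_max,
                                   cand$y_max, cand$tx1, cand$ty1,
                                   cand$tx2, cand$ty2)
    cand <- cand[cand$inter > 0, , drop = FALSE]
    if (nrow(cand) == 0) return(cand)
    cand$cdist <- sqrt(((cand$x_min + cand$x_max) / 2 - (cand$tx1 + cand$tx2) / 2)^2 +
                         ((cand$y_min + cand$y_max) / 2 - (cand$ty1 + cand$ty2) / 2)^2)
    # largest intersection, ties broken by smaller centroid distance
    cand$.key <- cand$inter - 1e-6 * cand$cdist
    cand |>
      dplyr::group_by(.data$.gid) |>
      dplyr::slice_max(.data$.key, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  gd <- best_overlap(dplyr::inner_join(grabs, diss, by = "frame",
                                       relationship = "many-to-many"))
  gr <- best_overlap(dplyr::inner_join(grabs, rubb, by = "frame",
                                       relationship = "many-to-many"))
  assigned <- dplyr::inner_join(
    dplyr::select(gd, ".gid", "frame", "confidence", "instrument"),
    dplyr::select(gr, ".gid", ring = "object_id"),
    by = ".gid"
  )
  empty$n_dropped_grabs <- nrow(grabs) - nrow(assigned)
  if (nrow(assigned) == 0) return(empty)
  # one grab per instrument per frame: keep the highest-confidence one
  assigned <- assigned |>
    dplyr::group_by(.data$frame, .data$instrument) |>
    dplyr::slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- empty
  for (inst in c("L", "R")) {
    a <- assigned[assigned$instrument == inst, ]
    idx <- a$frame + 1L
    out$grab[[inst]][idx] <- TRUE
    out$grab_ring[[inst]][idx] <- a$ring
  }
  out
}

# Carry each track's last observed box forward over short detection gaps
# (<= horizon frames), so that one missed dissector or rubber detection
# does not drop the grab of that frame.
fill_track_boxes <- function(d, horizon = 3L) {
  if (nrow(d) == 0) return(d)
  filled <- d |>
    dplyr::group_by(.data$object_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$frame)
      present <- g$frame
      cand <- setdiff(unique(as.vector(outer(present, seq_len(horizon), "+"))),
                      present)
      if (length(cand) == 0) return(g)
      src_idx <- findInterval(cand, present)
      ok <- cand - present[src_idx] <= horizon
      cand <- cand[ok]; src_idx <- src_idx[ok]
      if (length(cand) == 0) return(g)
      extra <- g[src_idx, ]
      extra$frame <- cand
      dplyr::bind_rows(g, extra)
    }) |>
    dplyr::ungroup()
  filled
}

# Instrument labels for dissector detections, one per (lane, frame).
#
# The two instruments enter from opposite ports and their tips never cross:
# whenever both dissectors are visible on a frame, the left one (smaller x
# centre) is L and the other R. Frames where only one dissector is visible
# inherit the label of the nearer of the two continuously updated slot
# positions. Re-deriving the label from geometry on every two-visible frame
# makes the channel immune to tracking-identity swaps; a wrong single-
# visible guess is isolated and removed by the sliding-average filter.
label_instruments <- function(diss, midline_x) {
  support <- table(diss$object_id)
  d <- dplyr::distinct(diss, .data$object_id, .data$frame, .keep_all = TRUE)
  d <- d[order(d$frame), ]
  cx <- (d$tx1 + d$tx2) / 2
  cy <- (d$ty1 + d$ty2) / 2
  lab <- rep(NA_character_, nrow(d))
  groups <- split(seq_len(nrow(d)), d$frame)
  slot <- c(L_x = NA_real_, L_y = NA_real_, R_x = NA_real_, R_y = NA_real_)
  for (g in groups) {
    if (length(g) > 2) {
      g <- g[order(-as.vector(support[d$object_id[g]]), cx[g])][1:2]
    }
    if (length(g) == 2) {
      g <- g[order(cx[g])]
      lab[g] <- c("L", "R")
      slot[] <- c(cx[g[1]], cy[g[1]], cx[g[2]], cy[g[2]])
    } else {
      x <- cx[g]; y <- cy[g]
      if (is.na(slot["L_x"]) && is.na(slot["R_x"])) {
        inst <- if (x <= midline_x) "L" else "R"
      } else if (is.na(slot["R_x"])) {
        inst <- "L"
      } else if (is.na(slot["L_x"])) {
        inst <- "R"
      } else {
        dl <- (x - slot["L_x"])^2 + (y - slot["L_y"])^2
        dr <- (x - slot["R_x"])^2 + (y - slot["R_y"])^2
        inst <- if (dl <= dr) "L" else "R"
      }
      lab[g] <- inst
      slot[paste0(inst, "_x")] <- x
      slot[paste0(inst, "_y")] <- y
    }
  }
  d$instrument <- lab
  dplyr::inner_join(diss,
                    d[c("object_id", "frame", "instrument")],
                    by = c("object_id", "frame"))
}

#' Derive ring-peg contact states
#'
#' A peg is in contact with a ring on a frame when the ring's box contains
#' the peg centre, or the intersection of ring box and peg box is at least
#' `tau` of the ring box area. The occupying ring is the candidate with the
#' largest relative overlap (ties broken by centroid distance to the peg).
#'
#' @param tracks A `peg_tracks` tibble.
#' @param geometry A `peg_geometry`.
#' @param tau Relative-overlap threshold in (0, 1].
#' @param min_track_support Rubber tracks with fewer detections are ignored.
#' @return A list with `contact` (frames x pegs logical matrix) and
#'   `contact_ring` (matching ring-id character matrix).
#' @export
derive_contact_states <- function(tracks, geometry, tau = 0.1,
                                  min_track_support = 3L) {
  n <- attr(tracks, "frame_count") %||% (max(tracks$frame) + 1L)
  np <- nrow(geometry$pegs)
  contact <- matrix(FALSE, nrow = n, ncol = np,
                    dimnames = list(NULL, geometry$pegs$peg))
  contact_ring <- matrix(NA_character_, nrow = n, ncol = np)
  rubb <- as_tibble(tracks) |>
    dplyr::filter(.data$cls == "rubber") |>
    dplyr::add_count(.data$object_id) |>
    dplyr::filter(.data$n >= min_track_support)
  if (nrow(rubb) == 0) {
    return(list(contact = contact, contact_ring = contact_ring))
  }
  area <- (rubb$x_max - rubb$x_min) * (rubb$y_max - rubb$y_min)
  rcx <- (rubb$x_min + rubb$x_max) / 2
  rcy <- (rubb$y_min + rubb$y_max) / 2
  for (k in seq_len(np)) {
    p <- geometry$pegs[k, ]
    inter <- box_intersection(rubb$x_min, rubb$y_min, rubb$x_max, rubb$y_max,
                              p$x_min, p$y_min, p$x_max, p$y_max)
    rel <- inter / area
    contains <- rubb$x_min <= p$x & p$x < rubb$x_max &
      rubb$y_min <= p$y & p$y < rubb$y_max
    hit <- which(contains | rel >= tau)
    if (length(hit) == 0) next
    cand <- tibble(frame = rubb$frame[hit], ring = rubb$object_id[hit],
                   rel = rel[hit],
                   cdist = sqrt((rcx[hit] - p$x)^2 + (rcy[hit] - p$y)^2))
    # largest relative overlap, ties broken by nearest centre
    cand$.key <- cand$rel - 1e-9 * cand$cdist
    best <- cand |>
      dplyr::group_by(.data$frame) |>
      dplyr::slice_max(.data$.key, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    contact[best$frame + 1L, k] <- TRUE
    contact_ring[best$frame + 1L, k] <- best$ring
  }
  list(contact = contact, contact_ring = contact_ring)
}

#' Assemble raw state timelines
#'
#' Combines per-instrument grab channels and per-peg contact channels into a
#' single `peg_timelines` object (at most 2 true grab channels and one
#' channel per peg true per frame).
#'
#' @param grab_states Result of [derive_grab_states()].
#' @param contact_states Result of [derive_contact_states()].
#' @param frame_count,fps Stream metadata.
#' @return A `peg_timelines` object.
#' @export
peg_timelines <- function(grab_states, contact_states, frame_count, fps) {
  structure(
    list(
      frame_count = as.integer(frame_count),
      fps = as.numeric(fps),
      grab = grab_states$grab,
      grab_ring = grab_states$grab_ring,
      contact = contact_states$contact,
      contact_ring = contact_states$contact_ring
    ),
    class = "peg_timelines"
  )
}

#' @export
print.peg_timelines <- function(x, ...) {
  cat(sprintf(
    "<peg_timelines> %d frames @ %g fps; grab frames L=%d R=%d; %d peg channels (%d contact frames)\n",
    x$frame_count, x$fps, sum(x$grab$L), sum(x$grab$R),
    ncol(x$contact), sum(x$contact)))
  invisible(x)
}

#' Tidy a timelines object into one row per (frame, channel)
#'
#' @param x A `peg_timelines`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `channel_group` (`grab`/`contact`),
#'   `channel`, `state` and `ring`.
#' @method tidy peg_timelines
#' @export
tidy.peg_timelines <- function(x, ...) {
  frames <- seq_len(x$frame_count) - 1L
  grab <- purrr::map_dfr(names(x$grab), function(inst) {
    tibble(frame = frames, channel_group = "grab", channel = inst,
           state = x$grab[[inst]], ring = x$grab_ring[[inst]])
  })
  contact <- purrr::map_dfr(seq_len(ncol(x$contact)), function(k) {
    tibble(frame = frames, channel_group = "contact",
           channel = paste0("peg_", colnames(x$contact)[k]),
           state = x$contact[, k], ring = x$contact_ring[, k])
  })
  dplyr::bind_rows(grab, contact)
}
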