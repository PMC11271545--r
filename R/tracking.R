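#' Link detections into identity tracks
#'
#' Greedy per-class nearest-centroid association between consecutive frames.
#' A detection farther than `max_jump_px` from every live track of its class
#' starts a new track; a track stays live for `patience` frames without a
#' detection. Pegs are static, so peg tracks are frozen to their median box
#' afterwards. The `grab` class encodes an event, not an object, and is not
#' tracked (see [derive_grab_states()]).
#'
#' @param stream A `peg_stream`.
#' @param max_jump_px Association gate in pixels.
#' @param patience Frames a track survives without a detection.
#' @return A tibble of the tracked detections with an `object_id` column
#'   (e.g. `"rubber_03"`), class `peg_tracks`, carrying the stream metadata
#'   as attributes.
#' @export
track_objects <- function(stream, max_jump_px = 40, patience = 10L) {
  meta <- stream_meta(stream)
  d <- as_tibble(stream)
  d <- d[d$cls != "grab", , drop = FALSE]
  out <- vector("list", 3)
  names(out) <- c("peg", "rubber", "dissector")
  for (cl in names(out)) {
    di <- d[d$cls == cl, , drop = FALSE]
    if (nrow(di) == 0) next
    di$object_id <- link_class(di, cl, max_jump_px, patience)
    out[[cl]] <- di
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- dplyr::mutate(d, object_id = character(0))
  }
  res <- dplyr::arrange(res, .data$frame, match(.data$cls, det_classes),
                        .data$x_min)
  res <- stitch_tracks(res, max_jump_px)
  res <- drop_duplicate_lanes(res)
  res <- freeze_peg_tracks(res)
  structure(res,
            video_id = meta$video_id, fps = meta$fps,
            frame_count = meta$frame_count, image_size = meta$image_size,
            class = c("peg_tracks", class(tibble())))
}

link_class <- function(di, cl, max_jump_px, patience) {
  n <- nrow(di)
  cx <- (di$x_min + di$x_max) / 2
  cy <- (di$y_min + di$y_max) / 2
  ids <- integer(n)
  frames <- di$frame
  groups <- split(seq_len(n), frames)
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  vel_x <- numeric(0); vel_y <- numeric(0)
  hits <- integer(0)
  n_tracks <- 0L
  for (g in groups) {
    f <- frames[g[1]]
    # tentative tracks (< 3 hits, typically spurious detections) only
    # survive one missed frame; confirmed tracks get the full patience
    live <- which(last_f >= f - 1L - ifelse(hits >= 3L, patience, 1L))
    if (length(live) > 0 && length(g) > 0) {
      # constant-velocity prediction (horizon capped at 3 frames) keeps two
      # objects moving in formation from swapping identities; the gate also
      # scales with the frames since the track was last seen (capped, so
      # stale tracks cannot capture distant detections)
      horizon <- pmin(pmax(1L, f - last_f[live]), 3L)
      pred_x <- last_x[live] + vel_x[live] * horizon
      pred_y <- last_y[live] + vel_y[live] * horizon
      dist <- sqrt(outer(cx[g], pred_x, "-")^2 +
                     outer(cy[g], pred_y, "-")^2)
      dist <- sweep(dist, 2, horizon, "/")
      repeat {
        m <- which.min(dist)
        if (length(m) == 0 || !is.finite(dist[m]) || dist[m] > max_jump_px) break
        ri <- (m - 1L) %% length(g) + 1L
        ci <- (m - 1L) %/% length(g) + 1L
        tr <- live[ci]
        ids[g[ri]] <- tr
        gap <- max(1L, f - last_f[tr])
        # exponentially smoothed velocity: jitter-robust prediction
        vel_x[tr] <- 0.6 * vel_x[tr] + 0.4 * (cx[g[ri]] - last_x[tr]) / gap
        vel_y[tr] <- 0.6 * vel_y[tr] + 0.4 * (cy[g[ri]] - last_y[tr]) / gap
        last_x[tr] <- cx[g[ri]]; last_y[tr] <- cy[g[ri]]; last_f[tr] <- f
        hits[tr] <- hits[tr] + 1L
        dist[ri, ] <- Inf
        dist[, ci] <- Inf
        if (all(!is.finite(dist))) break
      }
    }
    new_ones <- g[ids[g] == 0L]
    for (j in new_ones) {
      n_tracks <- n_tracks + 1L
      ids[j] <- n_tracks
      last_x[n_tracks] <- cx[j]; last_y[n_tracks] <- cy[j]; last_f[n_tracks] <- f
      vel_x[n_tracks] <- 0; vel_y[n_tracks] <- 0
      hits[n_tracks] <- 1L
    }
  }
  sprintf("%s_%02d", cl, ids)
}

# Re-join track fragments of one physical object. Under detector noise a
# track can be dragged onto a spurious box on a frame where the true
# detection was deleted and then lose its object to a freshly born track;
# the dragged lane may ride spurious boxes for a few more frames before
# dying. Fragments are re-linked when a new track starts close to where a
# lane was at that time (position looked up at the fragment's start frame,
# so a junk tail overlapping the new fragment does not block the join).
stitch_tracks <- function(tracks, max_jump_px, classes = c("dissector", "rubber"),
                          max_overlap = 12L, max_gap = 30L) {
  for (cl in classes) {
    idx <- which(tracks$cls == cl)
    if (length(idx) == 0) next
    sub <- tracks[idx, ]
    seg <- sub |>
      dplyr::group_by(.data$object_id) |>
      dplyr::summarise(n = dplyr::n(), f0 = min(.data$frame),
                       f1 = max(.data$frame), .groups = "drop") |>
      dplyr::filter(.data$n >= 3) |>
      dplyr::arrange(.data$f0)
    if (nrow(seg) <= 1) next
    # per-fragment frame/position series
    frames_of <- split(sub$frame, sub$object_id)
    cx_of <- split((sub$x_min + sub$x_max) / 2, sub$object_id)
    cy_of <- split((sub$y_min + sub$y_max) / 2, sub$object_id)
    lanes <- list()  # each: list(id, f = frames, x, y)
    mapping <- stats::setNames(seg$object_id, seg$object_id)
    for (j in seq_len(nrow(seg))) {
      id <- seg$object_id[j]
      ord <- order(frames_of[[id]])
      f_new <- frames_of[[id]][ord]
      x_new <- cx_of[[id]][ord]
      y_new <- cy_of[[id]][ord]
      best_k <- 0L; best_d <- Inf
      for (k in seq_along(lanes)) {
        lane <- lanes[[k]]
        i_at <- findInterval(seg$f0[j], lane$f)
        if (i_at < 1L) next
        gap <- seg$f0[j] - lane$f[i_at]
        if (gap > max_gap) next
        if (seg$f0[j] - max(lane$f) < -max_overlap) next
        d <- sqrt((x_new[1] - lane$x[i_at])^2 + (y_new[1] - lane$y[i_at])^2)
        gate <- 3 * max_jump_px + max_jump_px * max(0L, gap - 1L)
        if (d <= gate && d < best_d) { best_d <- d; best_k <- k }
      }
      if (best_k > 0L) {
        mapping[id] <- lanes[[best_k]]$id
        lane <- lanes[[best_k]]
        keep <- lane$f < f_new[1]
        lanes[[best_k]] <- list(id = lane$id,
                                f = c(lane$f[keep], f_new),
                                x = c(lane$x[keep], x_new),
                                y = c(lane$y[keep], y_new))
      } else {
        lanes[[length(lanes) + 1L]] <- list(id = id, f = f_new,
                                            x = x_new, y = y_new)
      }
    }
    ids <- tracks$object_id[idx]
    hit <- ids %in% names(mapping)
    ids[hit] <- unname(mapping[ids[hit]])
    tracks$object_id[idx] <- ids
  }
  tracks
}

# Fold shadow lanes into the lane they follow. Spurious detections can ride
# on top of a real object and capture some of its detections, producing a
# small parallel lane interleaved with the real one; such a lane is
# recognised by its positions tracking a better-supported lane's path and
# its detections are reassigned to that lane (a detector's non-maximum
# suppression would have removed most such boxes at the source).
drop_duplicate_lanes <- function(tracks, classes = c("rubber", "dissector"),
                                 radius_px = 30, near_frac = 0.6,
                                 horizon = 5L) {
  for (cl in classes) {
    idx <- which(tracks$cls == cl)
    if (length(idx) == 0) next
    sub <- tracks[idx, ]
    cx <- (sub$x_min + sub$x_max) / 2
    cy <- (sub$y_min + sub$y_max) / 2
    lanes <- sort(table(sub$object_id), decreasing = TRUE)
    lanes <- lanes[lanes >= 3]
    if (length(lanes) <= 1) next
    ids <- sub$object_id
    for (j in 2:length(lanes)) {
      small_id <- names(lanes)[j]
      si <- which(ids == small_id)
      for (k in seq_len(j - 1)) {
        big_id <- names(lanes)[k]
        bi <- which(ids == big_id)
        of <- order(sub$frame[bi])
        bf <- sub$frame[bi][of]; bx <- cx[bi][of]; by <- cy[bi][of]
        pos <- findInterval(sub$frame[si], bf)
        ok <- pos >= 1L
        if (!any(ok)) next
        near <- logical(length(si))
        gap <- sub$frame[si][ok] - bf[pos[ok]]
        d <- sqrt((cx[si][ok] - bx[pos[ok]])^2 + (cy[si][ok] - by[pos[ok]])^2)
        near[ok] <- gap <= horizon & d < radius_px
        # judge only over the big lane's lifespan: once the big lane is
        # gone, the shadow legitimately carries the object on
        within <- sub$frame[si] >= min(bf) & sub$frame[si] <= max(bf) + horizon
        if (sum(within) >= 10L && sum(near[within]) >= near_frac * sum(within)) {
          ids[si] <- big_id
          break
        }
      }
    }
    tracks$object_id[idx] <- ids
  }
  tracks
}

freeze_peg_tracks <- function(tracks) {
  pegs <- tracks$cls == "peg"
  if (!any(pegs)) return(tracks)
  med <- tracks[pegs, ] |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(mx1 = stats::median(.data$x_min),
                     my1 = stats::median(.data$y_min),
                     mx2 = stats::median(.data$x_max),
                     my2 = stats::median(.data$y_max), .groups = "drop")
  i <- match(tracks$object_id[pegs], med$object_id)
  tracks$x_min[pegs] <- med$mx1[i]
  tracks$y_min[pegs] <- med$my1[i]
  tracks$x_max[pegs] <- med$mx2[i]
  tracks$y_max[pegs] <- med$my2[i]
  tracks
}

#' Infer pegboard geometry from peg tracks
#'
#' Peg centres are median track centroids; the board midline is the midpoint
#' between the two side clusters (two-means on the x coordinate); pegs are
#' numbered 1..n, left column(s) first, top to bottom.
#'
#' @param tracks A `peg_tracks` tibble (or any tibble with peg detections and
#'   `object_id`).
#' @param image_size Optional `c(width, height)`; taken from `tracks`
#'   attributes when absent.
#' @param min_support_frac Peg tracks supported by fewer than
#'   `max(3, min_support_frac * frame_count)` detections are ignored
#'   (spurious-detection guard).
#' @return A `peg_geometry`: list with a `pegs` tibble (`peg`, `x`, `y`,
#'   box, `side`) and `midline_x`.
#' @export
infer_board_geometry <- function(tracks, image_size = NULL,
                                 min_support_frac = 0.05) {
  image_size <- image_size %||% attr(tracks, "image_size") %||% c(NA_real_, NA_real_)
  frame_count <- attr(tracks, "frame_count") %||% (max(tracks$frame) + 1L)
  pegs <- as_tibble(tracks) |>
    dplyr::filter(.data$cls == "peg") |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      x = stats::median((.data$x_min + .data$x_max) / 2),
      y = stats::median((.data$y_min + .data$y_max) / 2),
      x_min = stats::median(.data$x_min), y_min = stats::median(.data$y_min),
      x_max = stats::median(.data$x_max), y_max = stats::median(.data$y_max),
      .groups = "drop"
    )
  pegs <- merge_peg_clusters(pegs)
  pegs <- dplyr::filter(pegs, .data$n >= max(3, min_support_frac * frame_count))
  if (nrow(pegs) < 2) {
    stop_pegtransfer("board geometry needs at least 2 peg tracks",
                     "peg_geometry_error")
  }
  if (nrow(pegs) != 12) {
    warn(sprintf("expected 12 pegs, found %d; proceeding", nrow(pegs)))
  }
  km <- stats::kmeans(pegs$x, centers = matrix(range(pegs$x), ncol = 1))
  left_cluster <- which.min(km$centers)
  pegs$side <- ifelse(km$cluster == left_cluster, "left", "right")
  midline_x <- mean(km$centers)
  pegs <- dplyr::arrange(pegs, .data$side != "left", .data$y, .data$x)
  pegs$peg <- seq_len(nrow(pegs))
  structure(
    list(pegs = pegs[c("peg", "x", "y", "x_min", "y_min", "x_max", "y_max",
                       "side", "object_id")],
         midline_x = midline_x,
         image_size = image_size),
    class = "peg_geometry"
  )
}

# Pegs are static; track fragments of one peg are merged by proximity
# (25 px, well under the peg pitch) before the support filter, so a peg
# whose track was briefly dragged by a spurious detection still counts once.
merge_peg_clusters <- function(pegs) {
  pegs <- dplyr::arrange(pegs, dplyr::desc(.data$n))
  cluster <- integer(nrow(pegs))
  cx <- numeric(0); cy <- numeric(0)
  for (j in seq_len(nrow(pegs))) {
    if (length(cx) > 0) {
      d <- sqrt((pegs$x[j] - cx)^2 + (pegs$y[j] - cy)^2)
      k <- which.min(d)
      if (d[k] <= 25) {
        cluster[j] <- k
        next
      }
    }
    k <- length(cx) + 1L
    cx[k] <- pegs$x[j]; cy[k] <- pegs$y[j]
    cluster[j] <- k
  }
  pegs$cluster <- cluster
  pegs |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      object_id = .data$object_id[1], n = sum(.data$n),
      x = .data$x[1], y = .data$y[1],
      x_min = .data$x_min[1], y_min = .data$y_min[1],
      x_max = .data$x_max[1], y_max = .data$y_max[1],
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster")
}

#' @export
print.peg_geometry <- function(x, ...) {
  cat(sprintf("<peg_geometry> %d pegs (%d left / %d right), midline x = %.1f\n",
              nrow(x$pegs), sum(x$pegs$side == "left"),
              sum(x$pegs$side == "right"), x$midline_x))
  invisible(x)
}

peg_side <- function(geometry, peg) {
  out <- rep(NA_character_, length(peg))
  ok <- !is.na(peg)
  out[ok] <- geometry$pegs$side[match(peg[ok], geometry$pegs$peg)]
  out
}
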