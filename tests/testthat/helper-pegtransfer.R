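# Shared builders for tiny in-code fixtures.

det_row <- function(frame, cls, x, y, half = 10, confidence = 0.9) {
  tibble::tibble(frame = frame, cls = cls,
                 x_min = x - half, y_min = y - half,
                 x_max = x + half, y_max = y + half,
                 confidence = confidence)
}

tiny_stream <- function(detections, video_id = "t1", fps = 30,
                        frame_count = NULL, image_size = c(640, 480)) {
  frame_count <- frame_count %||% (max(c(detections$frame, 0L)) + 1L)
  detection_stream(detections, video_id = video_id, fps = fps,
                   frame_count = frame_count, image_size = image_size)
}

# Brute-force windowed-mean filter, the independent oracle for
# sliding_average_filter().
slide_oracle <- function(x, window, threshold) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - h):min(n, i + h)]
    out[i] <- mean(win) >= threshold
  }
  out
}

# Hand-built timelines: grab/contact channels from interval specs.
# grab_l / grab_r: list of list(from, to, ring); contact: list of
# list(peg, from, to, ring). Frames are 0-based inclusive.
make_timelines <- function(n, grab_l = list(), grab_r = list(),
                           contact = list(), n_pegs = 12, fps = 30) {
  g <- list(L = logical(n), R = logical(n))
  gr <- list(L = rep(NA_character_, n), R = rep(NA_character_, n))
  fill_grab <- function(inst, spec) {
    for (s in spec) {
      idx <- (s$from:s$to) + 1L
      g[[inst]][idx] <<- TRUE
      gr[[inst]][idx] <<- s$ring
    }
  }
  fill_grab("L", grab_l)
  fill_grab("R", grab_r)
  cm <- matrix(FALSE, n, n_pegs, dimnames = list(NULL, seq_len(n_pegs)))
  cr <- matrix(NA_character_, n, n_pegs)
  for (s in contact) {
    idx <- (s$from:s$to) + 1L
    cm[idx, s$peg] <- TRUE
    cr[idx, s$peg] <- s$ring
  }
  peg_timelines(list(grab = g, grab_ring = gr),
                list(contact = cm, contact_ring = cr),
                frame_count = n, fps = fps)
}

# Direct-formula oracles for the agreement statistics.
kappa_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  (po - pe) / (1 - pe)
}

board_sessions <- function(...) {
  rows <- list(...)
  base <- tibble::tibble(
    ring_id = character(), start_frame = integer(), end_frame = integer(),
    pickup_instrument = character(), release_instrument = character(),
    end_reason = character(), origin_peg = integer(),
    destination_peg = integer(), exchange_overlap = logical(),
    holder_change = logical(), change_gap = integer(),
    change_contact = logical(), dest_occupied_by_other = logical(),
    holders = list()
  )
  out <- dplyr::bind_rows(base, !!!rows)
  out <- out[order(out$start_frame, out$ring_id), ]
  attr(out, "ring_contact") <- list()
  attr(out, "geometry") <- board_template()
  out
}

session_row <- function(ring, start, end, pickup, release = pickup,
                        end_reason = "placed", origin = NA, dest = NA,
                        overlap = FALSE, change = NULL, change_gap = 0L,
                        change_contact = FALSE, occupied = FALSE) {
  tibble::tibble(
    ring_id = ring, start_frame = as.integer(start),
    end_frame = as.integer(end),
    pickup_instrument = pickup, release_instrument = release,
    end_reason = end_reason, origin_peg = as.integer(origin),
    destination_peg = as.integer(dest), exchange_overlap = overlap,
    holder_change = change %||% (pickup != release),
    change_gap = as.integer(change_gap), change_contact = change_contact,
    dest_occupied_by_other = occupied,
    holders = list(tibble::tibble(instrument = unique(c(pickup, release)),
                                  start = as.integer(start),
                                  end = as.integer(end)))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
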