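#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Known detection classes, in their canonical sort order.
det_classes <- c("peg", "rubber", "dissector", "grab")

# round() uses banker's rounding; reported figures use conventional
# round-half-up (e.g. 4.9673 -> 4.97 at 2 decimals).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Pairwise intersection area of axis-aligned boxes (vectorised).
box_intersection <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  w <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  h <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  w * h
}

stop_pegtransfer <- function(message, class, ...) {
  abort(message, class = c(class, "pegtransfer_error"), ...)
}

# Fill NA entries from the nearest non-NA neighbour (ties -> earlier frame).
fill_nearest <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L || length(ok) == length(x)) return(x)
  idx <- findInterval(seq_along(x), ok)
  prev <- ifelse(idx >= 1L, ok[pmax(idx, 1L)], NA_integer_)
  nxt <- ok[pmin(idx + 1L, length(ok))]
  prev[idx < 1L] <- NA_integer_
  use_next <- is.na(prev) | (!is.na(nxt) & (nxt - seq_along(x)) < (seq_along(x) - prev))
  pick <- ifelse(use_next, nxt, prev)
  x[is.na(x)] <- x[pick[is.na(x)]]
  x
}
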