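test_that("sliding average reproduces the windowed-mean oracle", {
  # frozen worked example: truncated edge window of size 2 at i=1 has
  # mean 0.5 >= theta, so the first frame switches on
  expect_equal(
    sliding_average_filter(c(FALSE, TRUE, TRUE, FALSE, FALSE), 3, 0.5),
    c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  expect_equal(sliding_average_filter(rep(FALSE, 40), 15, 0.5), rep(FALSE, 40))
  expect_equal(sliding_average_filter(rep(TRUE, 40), 15, 0.5), rep(TRUE, 40))

  withr::with_seed(7, {
    for (i in 1:25) {
      x <- runif(80) < 0.4
      w <- sample(c(1, 3, 7, 15), 1)
      th <- runif(1, 0.1, 1)
      expect_equal(sliding_average_filter(x, w, th), slide_oracle(x, w, th),
                   info = sprintf("case %d (w=%d, th=%.3f)", i, w, th))
    }
  })

  expect_error(sliding_average_filter(c(TRUE, FALSE), 4, 0.5),
               class = "peg_validation_error")
  expect_error(sliding_average_filter(c(TRUE, FALSE), 3, 0),
               class = "peg_validation_error")
})

test_that("filter preserves stable runs and is monotone in the threshold", {
  withr::with_seed(11, {
    for (i in 1:20) {
      # runs longer than the window, away from edges
      x <- rep(c(FALSE, TRUE, FALSE, TRUE, FALSE),
               times = sample(20:40, 5, replace = TRUE))
      w <- 15
      out <- sliding_average_filter(x, w, 0.5)
      h <- (w - 1) / 2
      interior <- which(seq_along(x) > h & seq_along(x) <= length(x) - h)
      trans <- which(diff(x) != 0)
      near_edge <- unique(unlist(lapply(trans, function(t) (t - h):(t + h + 1))))
      stable <- setdiff(interior, near_edge)
      expect_equal(out[stable], x[stable])

      # raising theta never turns a frame on
      th <- sort(runif(2, 0.2, 1))
      lo <- sliding_average_filter(x, w, th[1])
      hi <- sliding_average_filter(x, w, th[2])
      expect_true(all(lo | !hi))
    }
  })
})

test_that("noisy channels are recovered off-transition at high accuracy", {
  acc <- filter_accuracy_experiment(n_seeds = 5, flip_p = 0.15, seed = 3)
  expect_gte(mean(acc$accuracy), 0.99)
})

test_that("filter accounting matches direct arithmetic", {
  r <- filter_report(raw = c(TRUE, FALSE, TRUE), filtered = c(TRUE, TRUE, TRUE),
                     frames_total = 3, channels_max_per_frame = 1,
                     group = "grab")
  expect_equal(r$changed, 1)
  expect_equal(r$percent, 33.33)

  identical_r <- filter_report(raw = rep(TRUE, 10), filtered = rep(TRUE, 10),
                               frames_total = 10, channels_max_per_frame = 1)
  expect_equal(identical_r$changed, 0)
  expect_equal(identical_r$percent, 0)

  expect_error(
    filter_report(raw = c(TRUE, FALSE), filtered = TRUE, frames_total = 2,
                  channels_max_per_frame = 1),
    class = "peg_validation_error"
  )
  expect_error(
    filter_report(frames_total = 2, channels_max_per_frame = 1, changed = 5),
    class = "peg_validation_error"
  )
})

test_that("aggregated reports reproduce whole-study error-filtering rates", {
  contact <- filter_report(frames_total = 3038120, channels_max_per_frame = 12,
                           changed = 1333781, group = "contact")
  expect_equal(contact$percent, 3.66)

  # 301825 / (3038120 * 2) = 4.9673%; conventional rounding gives 4.97
  grab <- filter_report(frames_total = 3038120, channels_max_per_frame = 2,
                        changed = 301825, group = "grab")
  expect_equal(grab$percent, 4.97)

  # summing per-video rows before recomputing the percentage
  parts <- dplyr::bind_rows(
    filter_report(frames_total = 2000000, channels_max_per_frame = 12,
                  changed = 900000, group = "contact"),
    filter_report(frames_total = 1038120, channels_max_per_frame = 12,
                  changed = 433781, group = "contact")
  )
  agg <- aggregate_filter_reports(parts)
  expect_equal(agg$percent, 3.66)
})

test_that("ring attributes are resampled as windowed modes", {
  raw <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10))
  ids <- c(rep("a", 10), NA, rep("a", 4), "b", rep("a", 5))
  filt <- sliding_average_filter(raw, 5, 0.5)
  out <- pegtransfer:::window_mode_ids(ids, raw, filt, 5)
  expect_true(all(out[filt] == "a"))
  expect_true(all(is.na(out[!filt])))
})
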