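paper_table <- table2x2(125, 8, 4, 103)

test_that("contingency tables build from verdict maps", {
  ids <- sprintf("v%03d", 1:10)
  a <- stats::setNames(rep("pass", 10), ids)
  t <- contingency_2x2(a, a)
  expect_equal(c(t$a, t$b, t$c, t$d), c(10, 0, 0, 0))

  # verdict maps realising the published joint counts
  ids <- sprintf("v%03d", 1:240)
  joint <- c(rep("pp", 125), rep("pf", 8), rep("fp", 4), rep("ff", 103))
  a <- stats::setNames(ifelse(substr(joint, 1, 1) == "p", "pass", "fail"), ids)
  b <- stats::setNames(ifelse(substr(joint, 2, 2) == "p", "pass", "fail"), ids)
  t <- contingency_2x2(tibble::tibble(video_id = ids, verdict = a),
                       tibble::tibble(video_id = ids, verdict = b))
  expect_equal(c(t$a, t$b, t$c, t$d), c(125, 8, 4, 103))

  expect_error(
    contingency_2x2(stats::setNames("pass", "v1"), stats::setNames("pass", "v2")),
    class = "peg_pairing_error"
  )
})

test_that("percent agreement and kappa match published reference values", {
  expect_equal(percent_agreement(paper_table), 95.00)
  expect_equal(percent_agreement(table2x2(10, 0, 0, 10)), 100.00)
  expect_equal(percent_agreement(table2x2(0, 5, 5, 0)), 0.00)

  expect_equal(round(cohen_kappa(paper_table), 2), 0.90)
  expect_equal(cohen_kappa(table2x2(10, 0, 0, 10)), 1)
  expect_equal(cohen_kappa(table2x2(5, 5, 5, 5)), 0)
})

test_that("kappa has its defining properties", {
  withr::with_seed(5, {
    for (i in 1:30) {
      cells <- as.vector(stats::rmultinom(1, size = sample(20:200, 1),
                                          prob = runif(4, 0.05, 1)))
      if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
      t <- table2x2(cells[1], cells[2], cells[3], cells[4])
      k <- cohen_kappa(t)
      expect_true(is.nan(k) || (k >= -1 && k <= 1))
      # direct-formula oracle
      expect_equal(k, kappa_oracle(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
      # swapping the sources transposes the table but leaves kappa alone
      t2 <- table2x2(cells[1], cells[3], cells[2], cells[4])
      expect_equal(cohen_kappa(t2), k, tolerance = 1e-12)
      expect_equal(percent_agreement(t2), percent_agreement(t))
    }
  })
  # kappa = 1 iff no disagreements
  expect_equal(cohen_kappa(table2x2(7, 0, 0, 3)), 1)
  expect_lt(cohen_kappa(table2x2(7, 1, 0, 3)), 1)
})

test_that("path independence: verdict maps and their table agree", {
  withr::with_seed(9, {
    ids <- sprintf("v%02d", 1:60)
    a <- stats::setNames(sample(c("pass", "fail"), 60, TRUE), ids)
    b <- stats::setNames(sample(c("pass", "fail"), 60, TRUE), ids)
  })
  t <- contingency_2x2(a, b)
  expect_equal(percent_agreement(t),
               round(100 * mean(a == b[names(a)]), 2))
})

test_that("chi-square matches the published comparison and stats::chisq.test", {
  res <- pearson_chi_square_2x2(table2x2(29, 1, 28, 2))
  expect_equal(round(res$statistic, 2), 0.35)
  expect_equal(round(res$p_value, 2), 0.55)

  expect_equal(pearson_chi_square_2x2(table2x2(10, 10, 10, 10))$statistic, 0)

  withr::with_seed(13, {
    for (i in 1:20) {
      cells <- as.vector(stats::rmultinom(1, 40, runif(4, 0.1, 1)))
      t <- try(table2x2(cells[1], cells[2], cells[3], cells[4]), silent = TRUE)
      m <- matrix(cells, 2, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      ours <- pearson_chi_square_2x2(t)
      ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  })

  expect_error(pearson_chi_square_2x2(table2x2(5, 5, 0, 0)),
               class = "peg_undefined_statistic")
})

test_that("duration differences use mean |d| and sample sd", {
  same <- tibble::tibble(video_id = c("a", "b"), d1 = c(10, 20), d2 = c(10, 20))
  expect_equal(duration_difference_stats(same),
               tibble::tibble(mean_abs_diff_s = 0, sd_diff_s = 0))

  pairs <- tibble::tibble(video_id = c("a", "b"), d1 = c(10, 20), d2 = c(12, 19))
  out <- duration_difference_stats(pairs)
  expect_equal(out$mean_abs_diff_s, 1.50)
  expect_equal(out$sd_diff_s, round(stats::sd(c(-2, 1)), 2))

  expect_error(duration_difference_stats(tibble::tibble(video_id = character(),
                                                        d1 = double(),
                                                        d2 = double())),
               class = "peg_validation_error")
})

test_that("the agreement wrapper carries all statistics", {
  ids <- sprintf("v%03d", 1:240)
  joint <- c(rep("pp", 125), rep("pf", 8), rep("fp", 4), rep("ff", 103))
  a <- tibble::tibble(video_id = ids,
                      verdict = ifelse(substr(joint, 1, 1) == "p", "pass", "fail"))
  b <- tibble::tibble(video_id = ids,
                      verdict = ifelse(substr(joint, 2, 2) == "p", "pass", "fail"))
  ag <- peg_agreement(a, b)
  g <- glance(ag)
  expect_equal(g$n, 240)
  expect_equal(g$percent_agreement, 95.00)
  expect_equal(round(g$kappa, 2), 0.90)
  td <- tidy(ag)
  expect_equal(sum(td$count), 240)
})
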