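test_that("the scenario library is complete and internally consistent", {
  lib <- scenario_library()
  expect_gte(length(lib), 6)
  expect_true(all(c("perfect_run", "missed_handover",
                    "invalid_handover_via_drop", "invalid_release_drop",
                    "slow_run_over_limit", "single_direction_only")
                  %in% names(lib)))
  for (sc in lib) expect_s3_class(sc, "peg_scenario")

  # documented ground truth per scenario
  truths <- purrr::map(lib, ~ simulate_exercise(.x)$truth)
  expect_equal(truths$perfect_run$verdict, "pass")
  expect_equal(nrow(truths$perfect_run$pitfalls), 0)
  expect_equal(sum(truths$perfect_run$transfers$completed &
                     truths$perfect_run$transfers$handover_valid), 12)
  expect_equal(truths$missed_handover$pitfalls$kind, "missed_handover")
  expect_equal(truths$missed_handover$verdict, "fail")
  expect_setequal(truths$invalid_handover_via_drop$pitfalls$kind,
                  c("invalid_handover", "invalid_release"))
  expect_equal(truths$invalid_release_drop$pitfalls$kind, "invalid_release")
  expect_setequal(truths$invalid_pickup_return$pitfalls$kind,
                  c("invalid_pickup", "invalid_release"))
  expect_equal(truths$slow_run_over_limit$verdict, "fail")
  expect_equal(nrow(truths$slow_run_over_limit$pitfalls), 0)
  expect_gt(truths$slow_run_over_limit$duration_s, 300)
  expect_equal(truths$single_direction_only$verdict, "fail")
  expect_equal(nrow(truths$single_direction_only$pitfalls), 0)
})

test_that("an inconsistent script is rejected", {
  moves <- tibble::tibble(
    ring = c("r1", "r2"), start = c(30L, 130L), end = c(90L, 190L),
    inst1 = "L", inst2 = "R", switch_start = c(57L, 157L), overlap = 6L,
    outcome = "place", dest_peg = c(8L, 8L),
    drop_x = NA_real_, drop_y = NA_real_
  )
  expect_error(
    peg_scenario("conflict", stats::setNames(1:6, paste0("r", 1:6)), moves),
    class = "peg_scenario_error"
  )
})

test_that("simulation is deterministic and noise injection is seeded", {
  sc <- scenario_library()$single_direction_only
  s1 <- simulate_exercise(sc)
  s2 <- simulate_exercise(sc)
  expect_identical(as.data.frame(s1$stream), as.data.frame(s2$stream))

  spec <- noise_spec(fp_rate = 0.05, fn_rate = 0.05, jitter_sigma_px = 2)
  n1 <- inject_noise(s1$stream, spec, seed = 99)
  n2 <- inject_noise(s1$stream, spec, seed = 99)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  n3 <- inject_noise(s1$stream, spec, seed = 100)
  expect_false(identical(as.data.frame(n1), as.data.frame(n3)))
})

test_that("noise respects its specification", {
  sc <- scenario_library()$single_direction_only
  stream <- simulate_exercise(sc)$stream

  # no noise -> identity
  clean <- inject_noise(stream, noise_spec(), seed = 1)
  expect_identical(as.data.frame(clean), as.data.frame(stream))

  # total grab deletion
  no_grab <- inject_noise(stream, noise_spec(fn_rate = c(grab = 1)), seed = 1)
  expect_equal(sum(no_grab$cls == "grab"), 0)
  expect_equal(sum(no_grab$cls == "peg"), sum(stream$cls == "peg"))

  # deletion counts fall inside the binomial 99% interval
  n_grab <- sum(stream$cls == "grab")
  deleted <- vapply(1:10, function(s) {
    out <- inject_noise(stream, noise_spec(fn_rate = c(grab = 0.1)), seed = s)
    n_grab - sum(out$cls == "grab")
  }, numeric(1))
  bounds <- stats::qbinom(c(0.005, 0.995), n_grab, 0.1)
  expect_true(all(deleted >= bounds[1] & deleted <= bounds[2]))

  # burst mode deletes at the same marginal rate
  bursty <- vapply(1:20, function(s) {
    out <- inject_noise(stream,
                        noise_spec(fn_rate = c(grab = 0.2), burst = TRUE),
                        seed = s)
    (n_grab - sum(out$cls == "grab")) / n_grab
  }, numeric(1))
  expect_lt(abs(mean(bursty) - 0.2), 0.08)

  expect_error(noise_spec(fp_rate = 1.2), class = "peg_validation_error")
})

test_that("every ring is accounted for at stream end", {
  lib <- scenario_library()
  for (nm in names(lib)) {
    sc <- lib[[nm]]
    truth <- simulate_exercise(sc)$truth
    occ <- pegtransfer:::scenario_occupancy(sc)
    final <- occ[occ$to == sc$frame_count - 1L, ]
    # a ring either rests on exactly one peg at the end ...
    expect_lte(max(table(final$ring)), 1)
    loose <- setdiff(names(sc$rings), final$ring)
    for (r in loose) {
      # ... or its last session ended in a drop or ran to the stream end
      last <- truth$sessions[truth$sessions$ring_id == r, ]
      last <- last[which.max(last$end_frame), ]
      expect_true(last$end_reason %in% c("dropped", "stream_end"),
                  info = paste(nm, r))
    }
  }
})

test_that("noise-free evaluation reproduces the script (closure)", {
  cc <- closure_check(scenario_library()$missed_handover)
  expect_true(cc$ok, info = paste(cc$problems, collapse = "; "))
})
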