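#' Verdict-recovery experiment under detector noise
#'
#' Renders library scenarios, injects seeded detector noise and re-evaluates
#' each stream, recording whether the pipeline recovers the scripted
#' verdict. This mirrors, on synthetic ground truth, the agreement level an
#' assessment algorithm is validated against when compared with human
#' raters.
#'
#' @param n_runs Number of noisy evaluations.
#' @param seed Base seed; run `k` uses a seed derived from it.
#' @param fp_rate,fn_rate,jitter_sigma_px Noise level (see [noise_spec()]).
#' @param scenarios Named list of scenarios, cycled over runs.
#' @param config Evaluation configuration.
#' @return A tibble with one row per run (`run`, `scenario`,
#'   `truth_verdict`, `eval_verdict`, `agree`); the overall agreement is
#'   `mean(agree)`.
#' @export
verdict_agreement_experiment <- function(n_runs = 100, seed = 1,
                                         fp_rate = 0.10, fn_rate = 0.10,
                                         jitter_sigma_px = 2,
                                         scenarios = scenario_library(),
                                         config = eval_config()) {
  sims <- lapply(scenarios, simulate_exercise, config = config)
  spec <- noise_spec(fp_rate = fp_rate, fn_rate = fn_rate,
                     jitter_sigma_px = jitter_sigma_px)
  purrr::map_dfr(seq_len(n_runs), function(k) {
    i <- (k - 1L) %% length(sims) + 1L
    sim <- sims[[i]]
    run_seed <- as.integer((as.numeric(seed) * 10007 + k) %% 2147483629)
    noisy <- inject_noise(sim$stream, spec, seed = run_seed)
    verdict <- tryCatch(evaluate_stream(noisy, config)$verdict,
                        error = function(e) NA_character_)
    tibble(run = k, scenario = names(sims)[i],
           truth_verdict = sim$truth$verdict,
           eval_verdict = verdict,
           agree = !is.na(verdict) & verdict == sim$truth$verdict)
  })
}

#' Off-transition frame accuracy of the debouncer under flip noise
#'
#' Takes a scripted grab channel (left instrument of the perfect run),
#' flips each frame independently with probability `flip_p`, debounces, and
#' measures the fraction of frames recovered exactly, excluding the
#' `floor(window/2)` frames around each true transition where any centred
#' filter necessarily blurs the edge.
#'
#' @param n_seeds Number of noise replicates.
#' @param flip_p Symmetric flip probability per frame.
#' @param window,threshold Debouncer parameters.
#' @param seed Base seed.
#' @return A tibble with one accuracy row per replicate.
#' @export
filter_accuracy_experiment <- function(n_seeds = 20, flip_p = 0.15,
                                       window = 15L, threshold = 0.5,
                                       seed = 1) {
  sc <- scenario_library()$perfect_run
  truth <- scenario_truth(sc)
  gt <- logical(sc$frame_count)
  for (j in seq_len(nrow(truth$sessions))) {
    h <- truth$sessions$holders[[j]]
    h <- h[h$instrument == "L", , drop = FALSE]
    for (i in seq_len(nrow(h))) gt[(h$start[i] + 1L):(h$end[i] + 1L)] <- TRUE
  }
  half <- (as.integer(window) - 1L) %/% 2L
  trans <- which(diff(gt) != 0)
  excl <- unique(unlist(lapply(trans, function(t) {
    max(1L, t - half + 1L):min(length(gt), t + half)
  })))
  keep <- setdiff(seq_along(gt), excl)
  purrr::map_dfr(seq_len(n_seeds), function(k) {
    set.seed(as.integer((as.numeric(seed) * 7919 + k) %% 2147483629))
    noisy <- xor(gt, stats::runif(length(gt)) < flip_p)
    filt <- sliding_average_filter(noisy, window, threshold)
    tibble(replicate = k,
           accuracy = mean(filt[keep] == gt[keep]))
  })
}

#' Noise-free closure check of one scenario
#'
#' Renders the scenario, evaluates the clean stream and compares the result
#' with the scripted ground truth: verdict, pitfall-kind multiset, session
#' count and per-session structure (instruments, end reason, origin and
#' destination pegs, frame boundaries within `frame_tol`), and duration
#' within `(1 + window) / fps` seconds.
#'
#' @param scenario A `peg_scenario`.
#' @param config Evaluation configuration.
#' @param frame_tol Allowed per-boundary slack in frames.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
closure_check <- function(scenario, config = eval_config(), frame_tol = 2L) {
  sim <- simulate_exercise(scenario, config)
  result <- tryCatch(evaluate_stream(sim$stream, config),
                     error = function(e) e)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (inherits(result, "error")) {
    return(list(ok = FALSE,
                problems = paste("evaluation error:",
                                 conditionMessage(result))))
  }
  truth <- sim$truth
  if (result$verdict != truth$verdict) {
    note(sprintf("verdict %s != truth %s", result$verdict, truth$verdict))
  }
  pk <- sort(result$pitfalls$kind)
  tk <- sort(truth$pitfalls$kind)
  if (!identical(pk, tk)) {
    note(sprintf("pitfalls [%s] != truth [%s]",
                 paste(pk, collapse = ","), paste(tk, collapse = ",")))
  }
  if (nrow(result$sessions) != nrow(truth$sessions)) {
    note(sprintf("%d sessions != truth %d", nrow(result$sessions),
                 nrow(truth$sessions)))
  } else if (nrow(truth$sessions) > 0) {
    rs <- dplyr::arrange(result$sessions, .data$start_frame)
    ts <- dplyr::arrange(truth$sessions, .data$start_frame)
    for (j in seq_len(nrow(ts))) {
      same <- rs$pickup_instrument[j] == ts$pickup_instrument[j] &&
        rs$release_instrument[j] == ts$release_instrument[j] &&
        rs$end_reason[j] == ts$end_reason[j] &&
        identical(rs$origin_peg[j], ts$origin_peg[j]) &&
        identical(rs$destination_peg[j], ts$destination_peg[j]) &&
        abs(rs$start_frame[j] - ts$start_frame[j]) <= frame_tol &&
        abs(rs$end_frame[j] - ts$end_frame[j]) <= frame_tol
      if (!same) note(sprintf("session %d differs from script", j))
    }
  }
  dur_tol <- (1 + config$window_frames) / scenario$fps
  if (abs(result$duration_s - truth$duration_s) > dur_tol) {
    note(sprintf("duration %.2f s vs truth %.2f s beyond %.2f s",
                 result$duration_s, truth$duration_s, dur_tol))
  }
  list(ok = length(problems) == 0, problems = problems)
}
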