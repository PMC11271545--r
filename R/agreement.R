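#' Build a 2x2 pass/fail contingency table from two verdict sources
#'
#' Rows are source 1 (pass, fail), columns source 2 (pass, fail):
#' `a` = pass/pass, `b` = pass/fail, `c` = fail/pass, `d` = fail/fail.
#'
#' @param a,b Verdict sources: tibbles with columns `video_id` and `verdict`
#'   (`"pass"`/`"fail"`), or named character vectors keyed by video id. Key
#'   sets must match.
#' @return A `peg_table2x2`.
#' @examples
#' table2x2(125, 8, 4, 103)
#' @export
contingency_2x2 <- function(a, b) {
  va <- as_verdict_map(a, "source 1")
  vb <- as_verdict_map(b, "source 2")
  only_a <- setdiff(names(va), names(vb))
  only_b <- setdiff(names(vb), names(va))
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop_pegtransfer(
      paste0("verdict sources cover different videos; unmatched ids: ",
             paste(c(only_a, only_b), collapse = ", ")),
      "peg_pairing_error"
    )
  }
  vb <- vb[names(va)]
  table2x2(
    a = sum(va == "pass" & vb == "pass"),
    b = sum(va == "pass" & vb == "fail"),
    c = sum(va == "fail" & vb == "pass"),
    d = sum(va == "fail" & vb == "fail")
  )
}

as_verdict_map <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("video_id", "verdict") %in% names(x))) {
      stop_pegtransfer(paste0(what, " needs columns video_id and verdict"),
                       "peg_validation_error")
    }
    v <- stats::setNames(tolower(x$verdict), x$video_id)
  } else {
    v <- stats::setNames(tolower(as.character(x)), names(x))
  }
  if (anyDuplicated(names(v))) {
    stop_pegtransfer(paste0(what, " has duplicate video ids"),
                     "peg_duplicate_record_error")
  }
  bad <- which(!(v %in% c("pass", "fail")))
  if (length(bad) > 0) {
    stop_pegtransfer(
      sprintf("%s: unknown verdict '%s' for video '%s'", what, v[bad[1]],
              names(v)[bad[1]]),
      "peg_validation_error"
    )
  }
  v
}

#' @rdname contingency_2x2
#' @param c,d Counts (see above) when constructing a table directly.
#' @export
table2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_pegtransfer("table counts must be non-negative integers",
                     "peg_validation_error")
  }
  structure(as.list(c(counts, n = sum(counts))), class = "peg_table2x2")
}

#' @export
print.peg_table2x2 <- function(x, ...) {
  cat("<peg_table2x2>  (rows: source 1; cols: source 2)\n")
  cat(sprintf("        pass  fail\n  pass  %4d  %4d\n  fail  %4d  %4d\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

check_n <- function(t) {
  if (t$n <= 0) {
    stop_pegtransfer("statistic undefined for an empty table",
                     "peg_undefined_statistic")
  }
}

#' Percent agreement of a 2x2 table
#'
#' @param t A `peg_table2x2`.
#' @return `100 * (a + d) / n`, rounded to 2 decimals.
#' @examples
#' percent_agreement(table2x2(125, 8, 4, 103))
#' @export
percent_agreement <- function(t) {
  check_n(t)
  round_half_up(100 * (t$a + t$d) / t$n, 2)
}

#' Unweighted Cohen's kappa of a 2x2 table
#'
#' Chance-corrected agreement: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (a+d)/n} and chance agreement
#' \eqn{p_e = ((a+b)(a+c) + (c+d)(b+d))/n^2}. Returns 1 for complete,
#' degenerate agreement (`p_e = 1`, `p_o = 1`).
#'
#' @param t A `peg_table2x2`.
#' @return Kappa (unrounded).
#' @examples
#' cohen_kappa(table2x2(125, 8, 4, 103))
#' @export
cohen_kappa <- function(t) {
  check_n(t)
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' \eqn{\sum (O - E)^2 / E} over the four cells with expected counts from
#' the margins, 1 degree of freedom. No Yates correction is applied.
#'
#' @param t A `peg_table2x2`.
#' @return A list with `statistic`, `p_value` and `df`.
#' @examples
#' pearson_chi_square_2x2(table2x2(29, 1, 28, 2))
#' @export
pearson_chi_square_2x2 <- function(t) {
  check_n(t)
  obs <- c(t$a, t$b, t$c, t$d)
  r1 <- t$a + t$b; r2 <- t$c + t$d
  c1 <- t$a + t$c; c2 <- t$b + t$d
  if (any(c(r1, r2, c1, c2) == 0)) {
    stop_pegtransfer("chi-square undefined: a marginal total is zero",
                     "peg_undefined_statistic")
  }
  exp_counts <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / t$n
  statistic <- sum((obs - exp_counts)^2 / exp_counts)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Paired duration-difference statistics
#'
#' @param pairs A data frame whose first column identifies the video and
#'   whose next two numeric columns are the durations from the two sources
#'   (seconds).
#' @return One-row tibble with `mean_abs_diff_s` (mean of |d1 - d2|) and
#'   `sd_diff_s` (sample standard deviation, n - 1, of the signed
#'   differences), both rounded to 2 decimals; `sd_diff_s` is `NA` for a
#'   single pair.
#' @export
duration_difference_stats <- function(pairs) {
  num <- pairs[vapply(pairs, is.numeric, logical(1))]
  if (ncol(num) < 2 || nrow(pairs) < 1) {
    stop_pegtransfer("need at least one pair of durations",
                     "peg_validation_error")
  }
  d1 <- num[[1]]; d2 <- num[[2]]
  if (any(d1 < 0, na.rm = TRUE) || any(d2 < 0, na.rm = TRUE)) {
    stop_pegtransfer("durations must be non-negative", "peg_validation_error")
  }
  diffs <- d1 - d2
  tibble(
    mean_abs_diff_s = round_half_up(mean(abs(diffs)), 2),
    sd_diff_s = if (length(diffs) >= 2) {
      round_half_up(stats::sd(diffs), 2)
    } else {
      NA_real_
    }
  )
}

#' Compare two assessment sources
#'
#' Convenience wrapper building the 2x2 table and all agreement statistics,
#' optionally including paired duration differences.
#'
#' @inheritParams contingency_2x2
#' @param durations Optional duration pairs (see
#'   [duration_difference_stats()]).
#' @return A `peg_agreement` object with [tidy()] and [glance()] methods.
#' @export
peg_agreement <- function(a, b, durations = NULL) {
  t <- contingency_2x2(a, b)
  chi <- tryCatch(pearson_chi_square_2x2(t), error = function(e) NULL)
  dur <- if (!is.null(durations)) duration_difference_stats(durations) else NULL
  structure(
    list(table = t,
         percent_agreement = percent_agreement(t),
         kappa = cohen_kappa(t),
         chi_square = chi,
         durations = dur),
    class = "peg_agreement"
  )
}

#' @export
print.peg_agreement <- function(x, ...) {
  print(x$table)
  cat(sprintf("  agreement %.2f%%, kappa %.2f", x$percent_agreement, x$kappa))
  if (!is.null(x$chi_square)) {
    cat(sprintf(", chi-square %.2f (p = %.2f)", x$chi_square$statistic,
                x$chi_square$p_value))
  }
  cat("\n")
  if (!is.null(x$durations)) {
    cat(sprintf("  duration difference: mean |d| %.2f s, sd %.2f s\n",
                x$durations$mean_abs_diff_s, x$durations$sd_diff_s))
  }
  invisible(x)
}

#' @method glance peg_agreement
#' @export
glance.peg_agreement <- function(x, ...) {
  tibble(
    n = x$table$n,
    percent_agreement = x$percent_agreement,
    kappa = x$kappa,
    chi_square = if (!is.null(x$chi_square)) x$chi_square$statistic else NA_real_,
    chi_square_p = if (!is.null(x$chi_square)) x$chi_square$p_value else NA_real_,
    mean_abs_diff_s = if (!is.null(x$durations)) x$durations$mean_abs_diff_s else NA_real_,
    sd_diff_s = if (!is.null(x$durations)) x$durations$sd_diff_s else NA_real_
  )
}

#' @method tidy peg_agreement
#' @export
tidy.peg_agreement <- function(x, ...) {
  t <- x$table
  tibble(
    source1 = c("pass", "pass", "fail", "fail"),
    source2 = c("pass", "fail", "pass", "fail"),
    count = c(t$a, t$b, t$c, t$d)
  )
}
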