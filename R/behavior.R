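#' Fraction of correct test trials
#'
#' @param log an `episode_log`.
#' @return Proportion of trials answered correctly.
#' @export
performance <- function(log) {
  stopifnot(inherits(log, "episode_log"))
  mean(log$trials$correct)
}

#' Serial position curve
#'
#' Sorts trials by the recency position at which the test cue was last
#' presented before the test position (-1 = immediately preceding cue,
#' -2 = two before, ...) and measures the "yes" response rate at each
#' position. The most distant within-trial position (`-(trial_size - 1)`)
#' is the target position for Match-First: its yes-rate is the hit rate.
#' Trials whose test cue never appeared earlier form a separate "no-prior"
#' bin (position `NA`) and are excluded from fits. Empty bins are reported
#' with `NA` rate and a zero count, never silently as zero.
#'
#' @param log an `episode_log`.
#' @param stratify_target optional cue id: restrict to trials whose
#'   target (test) cue equals this value.
#' @return An `spc` object: data frame of `position`, `yes_rate`, `n`, with
#'   attributes `target_position`, `hit_rate` and `stratum`.
#' @export
serial_position_curve <- function(log, stratify_target = NULL) {
  stopifnot(inherits(log, "episode_log"))
  tr <- log$trials
  if (!is.null(stratify_target)) tr <- tr[tr$test_cue == stratify_target, ]
  k <- log$spec$trial_size
  target_pos <- -(k - 1L)
  positions <- seq(-1L, target_pos)
  yes <- tr$response == "yes"
  rate <- n <- numeric(length(positions))
  for (i in seq_along(positions)) {
    sel <- !is.na(tr$position) & tr$position == positions[i]
    n[i] <- sum(sel)
    rate[i] <- if (n[i] > 0) mean(yes[sel]) else NA_real_
  }
  no_prior <- is.na(tr$position)
  curve <- data.frame(position = positions, yes_rate = rate, n = n)
  structure(curve,
            target_position = target_pos,
            hit_rate = rate[positions == target_pos],
            no_prior_n = sum(no_prior),
            no_prior_rate = if (any(no_prior)) mean(yes[no_prior]) else NA_real_,
            stratum = stratify_target,
            class = c("spc", "data.frame"))
}

#' Linear fit of a serial position curve
#'
#' Fits a least-squares line to the yes-rates at the positions adjacent to
#' the target (by default the two positions immediately after it, e.g. -2
#' and -1 for trial size 4) and extrapolates it to the target position. The residual is the observed hit rate minus the extrapolated
#' value: a residual of 1 with near-zero slope indicates pure
#' target-selective behavior, while a negative slope with small residual is
#' the recency-like phenotype. Fits with extreme slope (|slope| > 0.5 per
#' position) are flagged, not dropped.
#'
#' @param curve an `spc` from [serial_position_curve()].
#' @param positions_used positions entering the fit (default the two
#'   adjacent to the target).
#' @return An `spc_fit`: list with `slope`, `intercept`, `residual`,
#'   `hit_rate`, `positions_used`, `flagged`.
#' @export
fit_spc <- function(curve, positions_used = NULL) {
  stopifnot(inherits(curve, "spc"))
  target_pos <- attr(curve, "target_position")
  if (is.null(positions_used))
    positions_used <- target_pos + c(1L, 2L)
  usable <- curve$position %in% positions_used & !is.na(curve$yes_rate)
  if (sum(usable) < 2L)
    stop("fewer than 2 usable positions for the linear fit")
  x <- curve$position[usable]
  y <- curve$yes_rate[usable]
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  hit <- attr(curve, "hit_rate")
  if (is.na(hit)) stop("hit rate undefined: empty target-position bin")
  residual <- hit - (intercept + slope * target_pos)
  structure(list(slope = slope, intercept = intercept, residual = residual,
                 hit_rate = hit, positions_used = sort(x),
                 flagged = abs(slope) > 0.5),
            class = "spc_fit")
}

#' @export
print.spc_fit <- function(x, ...) {
  cat(sprintf("<spc_fit> slope %.4f, residual %.4f, hit rate %.4f%s\n",
              x$slope, x$residual, x$hit_rate,
              if (x$flagged) " [extreme slope flagged]" else ""))
  invisible(x)
}

#' Lead-cue breakdown of match errors
#'
#' For each target cue A, takes the erroneous "yes" responses on no-match
#' trials of the two error categories — X-A-X-A (test cue repeated two
#' positions before the test position) and X-X-A-A (repeated immediately
#' before) — and computes the percentage of each category's errors
#' attributable to each lead-cue identity X. A pure recency-based strategy
#' predicts parity, `100 / (set_size - 1)` percent per lead cue; strongly
#' uneven shares refute it. Categories with zero errors are flagged
#' (`NA` percentages), never imputed.
#'
#' @param log an `episode_log` from a Match-First task.
#' @return An `error_profile`: data frame with `target_cue`, `lead_cue`,
#'   `category` (`"XAXA"`/`"XXAA"`), `errors` (count), `trials` (count of
#'   category trials with that lead), `error_rate` (errors/trials) and
#'   `percent` (share of the category's errors); attribute `parity` gives
#'   the recency-parity baseline.
#' @export
match_error_profile <- function(log) {
  stopifnot(inherits(log, "episode_log"))
  if (log$spec$task != "match_first")
    stop("match error profiles are defined for match_first")
  tr <- log$trials
  k <- log$spec$trial_size
  s <- log$spec$set_size
  stopifnot(k >= 3L)
  cue_prev1 <- tr[[paste0("cue", k - 1L)]]
  cue_prev2 <- tr[[paste0("cue", k - 2L)]]
  nomatch <- tr$label == "no_match"
  xaxa <- nomatch & cue_prev2 == tr$test_cue & cue_prev1 != tr$test_cue
  xxaa <- nomatch & cue_prev1 == tr$test_cue & cue_prev2 != tr$test_cue
  yes <- tr$response == "yes"

  rows <- list()
  for (A in seq_len(s)) {
    for (cat in c("XAXA", "XXAA")) {
      sel <- (if (cat == "XAXA") xaxa else xxaa) & tr$test_cue == A
      err_by_lead <- trials_by_lead <- integer(s)
      for (L in seq_len(s)) {
        in_cell <- sel & tr$lead_cue == L
        trials_by_lead[L] <- sum(in_cell)
        err_by_lead[L] <- sum(in_cell & yes)
      }
      total_err <- sum(err_by_lead)
      leads <- setdiff(seq_len(s), A)
      rows[[length(rows) + 1L]] <- data.frame(
        target_cue = A, lead_cue = leads, category = cat,
        errors = err_by_lead[leads], trials = trials_by_lead[leads],
        error_rate = ifelse(trials_by_lead[leads] > 0,
                            err_by_lead[leads] / trials_by_lead[leads],
                            NA_real_),
        percent = if (total_err > 0) 100 * err_by_lead[leads] / total_err
                  else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, parity = 100 / (s - 1L),
            class = c("error_profile", "data.frame"))
}

#' Replicate-level t tests
#'
#' Standard t statistics over replicate-level summaries (slopes, angles).
#' `one_sample_t` tests the replicate mean against `mu`;
#' `paired_one_sided_t` tests whether the second member of each pair
#' exceeds the first (one-sided paired test, as used for the increase of
#' the first sorting angle with training).
#'
#' @param values numeric vector of replicate values, or for the paired test
#'   a list of two equal-length vectors `list(before, after)`.
#' @param kind `"one_sample_t"` or `"paired_one_sided_t"`.
#' @param mu null value for the one-sample test.
#' @param alternative alternative hypothesis for the one-sample test.
#' @return List with `statistic`, `p_value`, `df`, `estimate`, `flagged`
#'   (TRUE when the statistic is undefined, e.g. zero variance).
#' @export
replicate_tests <- function(values, kind = c("one_sample_t",
                                             "paired_one_sided_t"),
                            mu = 0, alternative = "two.sided") {
  kind <- match.arg(kind)
  if (kind == "one_sample_t") {
    stopifnot(is.numeric(values), length(values) >= 2L)
    if (stats::sd(values) == 0)
      return(list(statistic = NA_real_, p_value = NA_real_,
                  df = length(values) - 1L, estimate = mean(values),
                  flagged = TRUE))
    tt <- stats::t.test(values, mu = mu, alternative = alternative)
  } else {
    stopifnot(is.list(values), length(values) == 2L,
              length(values[[1L]]) == length(values[[2L]]),
              length(values[[1L]]) >= 2L)
    d <- values[[2L]] - values[[1L]]
    if (stats::sd(d) == 0)
      return(list(statistic = NA_real_, p_value = NA_real_,
                  df = length(d) - 1L, estimate = mean(d), flagged = TRUE))
    tt <- stats::t.test(values[[2L]], values[[1L]], paired = TRUE,
                        alternative = "greater")
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), estimate = unname(tt$estimate),
       flagged = FALSE)
}
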