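make_spc <- function(positions, rates, ns = NULL) {
  if (is.null(ns)) ns <- rep(100L, length(positions))
  structure(data.frame(position = positions, yes_rate = rates, n = ns),
            target_position = min(positions),
            hit_rate = rates[which.min(positions)],
            no_prior_n = 0L, no_prior_rate = NA_real_, stratum = NULL,
            class = c("spc", "data.frame"))
}

test_that("hand-built six-trial log reproduces hand-counted rates", {
  spec <- task_spec("match_first", 5, 4)
  cues <- rbind(c(1L, 2L, 3L, 1L),   # match, position -3
                c(2L, 3L, 4L, 2L),   # match, position -3
                c(3L, 1L, 4L, 1L),   # no-match, position -2
                c(3L, 1L, 5L, 1L),   # no-match, position -2
                c(2L, 3L, 1L, 1L),   # no-match, position -1
                c(2L, 3L, 4L, 5L))   # no-match, no prior occurrence
  log <- manual_log(spec, cues, c("yes", "no", "yes", "no", "no", "yes"))
  curve <- serial_position_curve(log)
  expect_equal(curve$yes_rate[curve$position == -3], 1 / 2)
  expect_equal(curve$yes_rate[curve$position == -2], 1 / 2)
  expect_equal(curve$yes_rate[curve$position == -1], 0)
  expect_equal(curve$n, c(1L, 2L, 2L))
  expect_equal(attr(curve, "no_prior_n"), 1L)
  expect_equal(attr(curve, "no_prior_rate"), 1)
})

test_that("two-point linear fits match the hand-computable examples", {
  f1 <- fit_spc(make_spc(c(-1, -2, -3), c(0.2, 0.3, 0.9)))
  expect_equal(f1$slope, -0.1)
  expect_equal(f1$residual, 0.5)
  f2 <- fit_spc(make_spc(c(-1, -2, -3), c(0.1, 0.1, 0.9)))
  expect_equal(f2$slope, 0)
  expect_equal(f2$residual, 0.8)
  # pure target-selective curve: residual exactly 1
  f3 <- fit_spc(make_spc(c(-1, -2, -3), c(0, 0, 1)))
  expect_equal(f3$slope, 0)
  expect_equal(f3$residual, 1)
  expect_error(fit_spc(make_spc(c(-1, -2, -3), c(NA, 0.1, 0.9))),
               "fewer than 2")
})

test_that("empty position bins are flagged, never silently zero", {
  spec <- task_spec("match_first", 5, 4)
  cues <- rbind(c(1L, 2L, 3L, 1L), c(2L, 3L, 4L, 2L))
  log <- manual_log(spec, cues, c("yes", "yes"))
  curve <- serial_position_curve(log)
  expect_true(is.na(curve$yes_rate[curve$position == -1]))
  expect_identical(curve$n[curve$position == -1], 0)
})

test_that("scripted agents are recovered by curve and fit", {
  spec <- task_spec("match_first", 5, 4)
  # recency script: imposed yes-probabilities per position
  p <- c(`-1` = 0.2, `-2` = 0.35, `-3` = 0.9)
  rec <- scripted_log(spec, 5000, function(tr) {
    out <- rep(0.05, nrow(tr))
    for (pos in c(-1, -2, -3))
      out[!is.na(tr$position) & tr$position == pos] <- p[[as.character(pos)]]
    out
  }, seed = 41)
  curve <- serial_position_curve(rec)
  for (pos in c(-1, -2, -3)) {
    n <- curve$n[curve$position == pos]
    expect_lt(abs(curve$yes_rate[curve$position == pos] -
                    p[[as.character(pos)]]),
              2.576 * sqrt(0.25 / n))
  }
  fit <- fit_spc(curve)
  expect_lt(fit$slope, -0.05)  # imposed negative slope sign recovered
  # target-selective script: residual near 1, slope near 0
  sel <- scripted_log(spec, 5000,
                      function(tr) as.numeric(tr$lead_cue == tr$test_cue),
                      seed = 42)
  fsel <- fit_spc(serial_position_curve(sel))
  expect_lt(abs(fsel$slope), 0.02)
  expect_gt(fsel$residual, 0.95)
})

test_that("stratified curves restrict to the requested target cue", {
  spec <- task_spec("match_first", 5, 4)
  log <- scripted_log(spec, 4000, function(tr) rep(0.5, nrow(tr)), seed = 43)
  s1 <- serial_position_curve(log, stratify_target = 1)
  expect_equal(sum(s1$n) + attr(s1, "no_prior_n"),
               sum(log$trials$test_cue == 1))
})

test_that("performance is consistent with the curve decomposition", {
  spec <- task_spec("match_first", 5, 4)
  log <- scripted_log(spec, 4000, function(tr)
    0.2 + 0.6 * (tr$lead_cue == tr$test_cue), seed = 44)
  curve <- serial_position_curve(log)
  tr <- log$trials
  # reconstruct accuracy from yes-rates and bin composition: the target bin
  # holds the match trials, all other trials are no-match
  n_match <- curve$n[curve$position == attr(curve, "target_position")]
  hits <- attr(curve, "hit_rate") * n_match
  fa <- sum(curve$yes_rate[curve$position != attr(curve, "target_position")] *
              curve$n[curve$position != attr(curve, "target_position")]) +
    attr(curve, "no_prior_rate") * attr(curve, "no_prior_n")
  expect_equal(performance(log),
               (hits + (nrow(tr) - n_match) - fa) / nrow(tr),
               tolerance = 1e-12)
})

test_that("match error profiles agree with a brute-force count oracle", {
  spec <- task_spec("match_first", 5, 4)
  log <- scripted_log(spec, 6000, function(tr) rep(0.4, nrow(tr)), seed = 45)
  prof <- match_error_profile(log)
  tr <- log$trials
  for (row in sample(nrow(prof), 20)) {
    A <- prof$target_cue[row]; L <- prof$lead_cue[row]
    if (prof$category[row] == "XAXA") {
      sel <- tr$label == "no_match" & tr$test_cue == A & tr$cue2 == A &
        tr$cue3 != A
    } else {
      sel <- tr$label == "no_match" & tr$test_cue == A & tr$cue3 == A &
        tr$cue2 != A
    }
    expect_identical(prof$errors[row],
                     sum(sel & tr$lead_cue == L & tr$response == "yes"))
    expect_identical(prof$trials[row], sum(sel & tr$lead_cue == L))
  }
  # percentages sum to 100 within each category with errors
  sums <- tapply(prof$percent, interaction(prof$target_cue, prof$category),
                 sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("uniform error scripts give near-parity error shares", {
  spec <- task_spec("match_first", 5, 4)
  log <- scripted_log(spec, 20000, function(tr) rep(0.3, nrow(tr)), seed = 46)
  prof <- match_error_profile(log)
  expect_equal(attr(prof, "parity"), 25)
  expect_true(all(abs(prof$percent - 25) < 12))
  # concentrated errors: only 2-1-X-1 errors -> 100% for lead 2
  conc <- scripted_log(spec, 20000, function(tr)
    as.numeric(tr$lead_cue == 2 & tr$cue2 == 1 & tr$test_cue == 1 &
                 tr$cue3 != 1), seed = 47)
  pc <- match_error_profile(conc)
  xa1 <- pc[pc$category == "XAXA" & pc$target_cue == 1, ]
  expect_equal(xa1$percent[xa1$lead_cue == 2], 100)
  expect_true(all(xa1$percent[xa1$lead_cue != 2] == 0))
})

test_that("replicate t tests match the textbook formula and flag degeneracy", {
  sym <- c(-2, -1, 0, 1, 2)
  res <- replicate_tests(sym, "one_sample_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  x <- c(0.3, 0.5, 0.1, 0.4)
  res2 <- replicate_tests(x, "one_sample_t", mu = 0.2)
  t_hand <- (mean(x) - 0.2) / (sd(x) / sqrt(4))
  expect_equal(res2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res2$p_value, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  paired <- replicate_tests(list(c(1, 2, 3), c(2, 4, 5)),
                            "paired_one_sided_t")
  d <- c(1, 2, 2)
  expect_equal(paired$statistic, mean(d) / (sd(d) / sqrt(3)),
               tolerance = 1e-12)
  same <- replicate_tests(list(c(1, 2, 3), c(1, 2, 3)),
                          "paired_one_sided_t")
  expect_true(same$flagged)
})
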