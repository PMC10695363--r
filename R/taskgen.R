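#' Specify a working-memory match task
#'
#' Defines one variation of the three delayed match-to-sample tasks
#' (Same-Different, Match-First, Match-Any). A trial is an ordered sequence
#' of `trial_size` cues drawn from a deck of `set_size` cue types; after the
#' last cue the agent answers "yes" (match) or "no". The match rule depends
#' on the task: Same-Different compares the two cues of a 2-cue trial,
#' Match-First compares the first (lead) and last (test) cue, and Match-Any
#' asks whether the test cue occurred anywhere earlier in the trial.
#'
#' @param task one of `"same_different"`, `"match_first"`, `"match_any"`.
#' @param set_size number of distinct cue types (>= 2).
#' @param trial_size cues per trial; must be 2 for Same-Different, and is
#'   typically 4 or 8 for the other tasks.
#' @param encoding `"scalar"` presents cue k as the single value k
#'   (a similarity-based code); `"one_hot"` presents a length-`set_size`
#'   indicator vector. Blank (separator) timesteps are all-zero either way.
#' @param reward_scheme `"original"` (+5 correct / -5 incorrect) or
#'   `"recency"` (Match-First only), which additionally rewards erroneous
#'   "yes" responses by how recently the test cue was repeated: +3 when it
#'   last appeared two positions before the test position (X-A-X-A), +1 when
#'   it appeared in the immediately preceding position (X-X-A-A).
#' @param match_fraction probability that a sampled trial is a match trial.
#'   Balanced classes (0.5) by default; the label is chosen first and cues
#'   are then sampled consistently with it.
#' @return An object of class `task_spec`.
#' @examples
#' task_spec("match_first", set_size = 5, trial_size = 4)
#' @export
task_spec <- function(task = c("match_first", "same_different", "match_any"),
                      set_size = 5L, trial_size = 4L,
                      encoding = c("scalar", "one_hot"),
                      reward_scheme = c("original", "recency"),
                      match_fraction = 0.5) {
  task <- match.arg(task)
  encoding <- match.arg(encoding)
  reward_scheme <- match.arg(reward_scheme)
  set_size <- as.integer(set_size)
  trial_size <- as.integer(trial_size)
  if (set_size < 2L) stop("set_size must be >= 2")
  if (trial_size < 2L) stop("trial_size must be >= 2")
  if (task == "same_different" && trial_size != 2L)
    stop("same_different requires trial_size = 2")
  if (reward_scheme == "recency" && task != "match_first")
    stop("the recency reward scheme is defined for match_first only")
  if (match_fraction < 0 || match_fraction > 1)
    stop("match_fraction must be in [0, 1]")
  structure(
    list(task = task, set_size = set_size, trial_size = trial_size,
         encoding = encoding, reward_scheme = reward_scheme,
         match_fraction = match_fraction),
    class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "<task_spec> %s | set size %d | trial size %d | %s encoding | %s rewards | match fraction %.2f\n",
    x$task, x$set_size, x$trial_size, x$encoding, x$reward_scheme,
    x$match_fraction))
  invisible(x)
}

# cue-encoding length of one input frame
enc_len <- function(spec) if (spec$encoding == "one_hot") spec$set_size else 1L

# full network input dimension: cue encoding + 2 previous-action slots +
# 1 previous-reward slot
input_dim <- function(spec) enc_len(spec) + 3L

trial_label <- function(cues, task) {
  k <- length(cues)
  match <- switch(task,
    same_different = cues[1L] == cues[2L],
    match_first    = cues[1L] == cues[k],
    match_any      = cues[k] %in% cues[-k])
  if (match) "match" else "no_match"
}

#' Sample a batch of task trials
#'
#' Labels are assigned first (`match` with probability `match_fraction`) and
#' cue sequences are then drawn consistently with the label, so the realized
#' class balance is binomial around `match_fraction`. For Same-Different and
#' Match-First, intervening distractor cues are drawn uniformly from the
#' cues other than the lead cue, so the trial label is always determined by
#' the lead/test comparison. For Match-Any the leading cues are drawn
#' uniformly at random and the test cue is drawn from (match) or outside
#' (no-match) the set of cues already shown.
#'
#' @param spec a [task_spec()].
#' @param n number of trials.
#' @return A `trial_set`: list with `cues` (an `n` x `trial_size` integer
#'   matrix), `label` (character vector, `"match"`/`"no_match"`) and `spec`.
#' @export
sample_trials <- function(spec, n) {
  stopifnot(inherits(spec, "task_spec"), n >= 1)
  n <- as.integer(n)
  k <- spec$trial_size
  s <- spec$set_size
  is_match <- stats::runif(n) < spec$match_fraction
  cues <- matrix(0L, n, k)

  resample_not <- function(m, exclude) {
    # uniform draw from 1..s excluding one value per row
    out <- sample.int(s - 1L, m, replace = TRUE)
    out + (out >= exclude)
  }

  if (spec$task == "match_any") {
    for (j in seq_len(k - 1L))
      cues[, j] <- sample.int(s, n, replace = TRUE)
    for (i in seq_len(n)) {
      earlier <- unique(cues[i, seq_len(k - 1L)])
      if (is_match[i]) {
        cues[i, k] <- earlier[sample.int(length(earlier), 1L)]
      } else {
        pool <- setdiff(seq_len(s), earlier)
        while (length(pool) == 0L) {   # deck exhausted: redraw leading cues
          cues[i, seq_len(k - 1L)] <- sample.int(s, k - 1L, replace = TRUE)
          pool <- setdiff(seq_len(s), unique(cues[i, seq_len(k - 1L)]))
        }
        cues[i, k] <- pool[sample.int(length(pool), 1L)]
      }
    }
  } else {
    lead <- sample.int(s, n, replace = TRUE)
    cues[, 1L] <- lead
    if (k > 2L)
      for (j in 2:(k - 1L))
        cues[, j] <- resample_not(n, lead)
    cues[, k] <- ifelse(is_match, lead, resample_not(n, lead))
  }

  structure(
    list(cues = cues,
         label = ifelse(is_match, "match", "no_match"),
         spec = spec),
    class = "trial_set")
}

#' Sample a single trial
#'
#' @param spec a [task_spec()].
#' @param force_label optionally `"match"` or `"no_match"` to force the
#'   trial label (used to construct specific trial types).
#' @param lead_cue optionally fix the lead (first) cue.
#' @return A `wm_trial`: list with `cues`, `label`, `lead_cue`, `test_cue`
#'   and `target_positions` (earlier positions holding the test cue).
#' @export
sample_trial <- function(spec, force_label = NULL, lead_cue = NULL) {
  stopifnot(inherits(spec, "task_spec"))
  sp <- spec
  if (!is.null(force_label)) {
    force_label <- match.arg(force_label, c("match", "no_match"))
    sp$match_fraction <- if (force_label == "match") 1 else 0
  }
  repeat {
    ts <- sample_trials(sp, 1L)
    if (is.null(lead_cue) || ts$cues[1L, 1L] == lead_cue) break
  }
  cues <- ts$cues[1L, ]
  k <- spec$trial_size
  structure(
    list(cues = cues, label = ts$label[1L],
         lead_cue = cues[1L], test_cue = cues[k],
         target_positions = which(cues[-k] == cues[k])),
    class = "wm_trial")
}

#' Encode one cue as a network input frame
#'
#' @param cue_id an integer cue id in `[1, set_size]`, or 0 for a blank
#'   (separator) timestep.
#' @param spec a [task_spec()].
#' @return Numeric vector: length 1 under scalar encoding (`[cue_id]`, blank
#'   is `[0]`), length `set_size` under one-hot encoding (indicator of the
#'   cue, blank is the zero vector).
#' @export
encode_cue <- function(cue_id, spec) {
  stopifnot(inherits(spec, "task_spec"), length(cue_id) == 1L)
  if (is.na(cue_id) || cue_id < 0 || cue_id > spec$set_size)
    stop("cue_id must be 0 (blank) or in [1, set_size]")
  if (spec$encoding == "scalar") return(as.numeric(cue_id))
  v <- numeric(spec$set_size)
  if (cue_id > 0) v[cue_id] <- 1
  v
}

#' Build a continuous input stream from trials
#'
#' Trials are concatenated as `separator, cues_1, separator, cues_2, ...,
#' separator`: every trial is preceded by one blank timestep and the stream
#' ends with a trailing blank, matching the presentation protocol in which
#' trials are separated by a timestep with no cue. The decision timestep of
#' each trial is the index of its last cue.
#'
#' @param trials a `trial_set` from [sample_trials()].
#' @return A `trial_stream`: list with `inputs` (timesteps x encoding-length
#'   matrix of cue encodings), `cue_ids` (integer vector, 0 = blank),
#'   `trial_index` (0 for separators), `decision_steps` (indices of decision
#'   timesteps) and `trials`.
#' @export
build_stream <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  spec <- trials$spec
  n <- nrow(trials$cues)
  if (n == 0L) stop("empty trial list")
  k <- spec$trial_size
  len <- n * (k + 1L) + 1L
  cue_ids <- integer(len)
  trial_index <- integer(len)
  pos <- 1L  # leading separator at index 1
  decision <- integer(n)
  for (i in seq_len(n)) {
    idx <- pos + seq_len(k)
    cue_ids[idx] <- trials$cues[i, ]
    trial_index[idx] <- i
    decision[i] <- pos + k
    pos <- pos + k + 1L
  }
  enc <- vapply(cue_ids, encode_cue, numeric(enc_len(spec)), spec = spec)
  inputs <- if (is.matrix(enc)) t(enc) else matrix(enc, ncol = 1L)
  structure(
    list(inputs = inputs, cue_ids = cue_ids, trial_index = trial_index,
         decision_steps = decision, trials = trials, spec = spec),
    class = "trial_stream")
}

#' Recover trials from a built stream
#'
#' Inverse of [build_stream()]: parses the separator structure and re-labels
#' each recovered cue sequence under the task rule.
#'
#' @param stream a `trial_stream`.
#' @return A `trial_set` equal (cues and labels) to the one the stream was
#'   built from.
#' @export
parse_stream <- function(stream) {
  stopifnot(inherits(stream, "trial_stream"))
  spec <- stream$spec
  ids <- stream$cue_ids
  k <- spec$trial_size
  sep <- which(ids == 0L)
  n <- length(sep) - 1L
  cues <- matrix(0L, n, k)
  for (i in seq_len(n))
    cues[i, ] <- ids[(sep[i] + 1L):(sep[i + 1L] - 1L)]
  structure(
    list(cues = cues,
         label = apply(cues, 1L, trial_label, task = spec$task),
         spec = spec),
    class = "trial_set")
}

#' @export
as.data.frame.trial_stream <- function(x, ...) {
  data.frame(timestep = seq_along(x$cue_ids),
             trial = x$trial_index,
             cue_id = x$cue_ids,
             is_decision = seq_along(x$cue_ids) %in% x$decision_steps)
}

#' Reward delivered at a trial's decision timestep
#'
#' Under the original scheme a correct answer earns +5 and an incorrect one
#' -5. Under the recency scheme (Match-First only) an erroneous "yes" is
#' instead shaped by how recently the test cue was repeated before the test
#' position: +3 if it last occurred two steps before (X-A-X-A), +1 if one
#' step before (X-X-A-A); all other outcomes are rewarded as in the original
#' scheme. Rewards at non-decision timesteps are always 0.
#'
#' @param trial a `wm_trial` (or a list with `cues` and `label`).
#' @param response `"yes"` or `"no"`.
#' @param scheme `"original"` or `"recency"`.
#' @param spec the [task_spec()] of the task (needed to validate the scheme).
#' @return Scalar reward.
#' @export
reward <- function(trial, response = c("yes", "no"),
                   scheme = c("original", "recency"), spec = NULL) {
  response <- match.arg(response)
  scheme <- match.arg(scheme)
  if (scheme == "recency" && !is.null(spec) && spec$task != "match_first")
    stop("the recency reward scheme is defined for match_first only")
  correct <- (trial$label == "match") == (response == "yes")
  if (correct) return(5)
  if (scheme == "recency" && response == "yes" && trial$label == "no_match") {
    pos <- recency_position(trial$cues)
    if (!is.na(pos)) {
      if (pos == -2L) return(3)
      if (pos == -1L) return(1)
    }
  }
  -5
}

# Recency position of the test cue: -(distance to its most recent earlier
# occurrence), NA if it never occurred before the test position.
recency_position <- function(cues) {
  k <- length(cues)
  prior <- which(cues[-k] == cues[k])
  if (length(prior) == 0L) return(NA_integer_)
  max(prior) - k
}
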