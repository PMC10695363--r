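#' Training configuration for advantage actor-critic
#'
#' Defaults follow the study conditions: value and entropy loss
#' coefficients `beta_v = beta_H = 0.05`, Adam with learning rate `1e-3`
#' (moment decays 0.9/0.999, epsilon 1e-8), discount `gamma = 0` (actions
#' before the decision timestep have no bearing on the outcome), a gradient
#' update after every 3 trials with backpropagation truncated at the
#' 3-trial segment boundary, and checkpoints on the grid
#' \{0, 5, 10, 20, 30, 40, 50\} x 10^3 trial episodes.
#'
#' @param beta_v value-loss coefficient.
#' @param beta_H entropy-bonus coefficient.
#' @param learning_rate Adam learning rate.
#' @param gamma reward discount in `[0, 1]`.
#' @param update_every trials per gradient update (and truncation window).
#' @param decision_only if TRUE, accumulate the loss only at decision
#'   timesteps instead of over every timestep of the segment (with
#'   `gamma = 0` the non-decision terms carry no reward information, only
#'   a value-shrinkage signal).
#' @param checkpoints episode counts at which parameters are snapshotted.
#' @param n_test default number of test episodes per checkpoint.
#' @return A `train_config` list.
#' @export
train_config <- function(beta_v = 0.05, beta_H = 0.05, learning_rate = 1e-3,
                         gamma = 0, update_every = 3L,
                         checkpoints = c(0L, 5L, 10L, 20L, 30L, 40L, 50L) * 1000L,
                         n_test = 5000L, decision_only = FALSE) {
  stopifnot(beta_v >= 0, beta_H >= 0, gamma >= 0, gamma <= 1,
            update_every >= 1, length(checkpoints) >= 1)
  structure(list(beta_v = beta_v, beta_H = beta_H,
                 learning_rate = learning_rate, gamma = gamma,
                 update_every = as.integer(update_every),
                 checkpoints = sort(unique(as.integer(checkpoints))),
                 n_test = as.integer(n_test),
                 decision_only = isTRUE(decision_only)),
            class = "train_config")
}

# config list handed to the compiled core
core_cfg <- function(spec, config) {
  list(encoding = spec$encoding, set_size = spec$set_size,
       recency = spec$reward_scheme == "recency",
       reward_correct = 5, reward_incorrect = -5,
       reward_xaxa = 3, reward_xxaa = 1,
       gamma = config$gamma, lr = config$learning_rate,
       beta_v = config$beta_v, beta_h = config$beta_H,
       update_every = config$update_every,
       decision_only = config$decision_only)
}

#' Discounted return
#'
#' Computes `R_t = sum_{i=0}^{k-1} gamma^i r_{t+i} + gamma^k V_terminal`
#' for every `t` in a reward sequence, where `k` is the number of steps from
#' `t` to the end of the sequence. With `gamma = 0`, `R_t = r_t`.
#'
#' @param rewards numeric vector of per-timestep rewards.
#' @param gamma discount factor.
#' @param terminal_value bootstrap value beyond the last step.
#' @return Numeric vector of returns, same length as `rewards`.
#' @export
discounted_return <- function(rewards, gamma = 0, terminal_value = 0) {
  T <- length(rewards)
  out <- numeric(T)
  run <- terminal_value
  for (t in rev(seq_len(T))) {
    run <- rewards[t] + gamma * run
    out[t] <- run
  }
  out
}

#' Actor-critic loss over a trial segment (reference implementation)
#'
#' Computes the composite loss
#' `L = sum_t [ -log pi(a_t) delta_t + beta_v delta_t^2 - beta_H H(pi_t) ]`
#' with `delta_t = R_t - V_t` the advantage. The advantage is treated as a
#' constant in the policy term; `policy_advantage` can supply frozen
#' advantage values so that the loss becomes a differentiable surrogate
#' whose gradient equals the analytic actor-critic gradient (used for
#' finite-difference checks). Runs the forward pass in plain R.
#'
#' @param agent a `wm_agent`.
#' @param X timestep-by-input matrix for the segment.
#' @param actions character (`"yes"`/`"no"`) or integer (0 = yes, 1 = no)
#'   actions taken at each timestep.
#' @param rewards per-timestep rewards.
#' @param config a [train_config()] (supplies `beta_v`, `beta_H`, `gamma`).
#' @param state initial recurrent state (defaults to zeros).
#' @param policy_advantage optional frozen advantages for the policy term.
#' @return List with `total`, `policy`, `value`, `entropy` (summed H),
#'   `advantage`, `value_est`.
#' @export
a2c_loss <- function(agent, X, actions, rewards, config = train_config(),
                     state = NULL, policy_advantage = NULL) {
  if (is.character(actions)) actions <- ifelse(actions == "yes", 0L, 1L)
  T <- nrow(X)
  stopifnot(length(actions) == T, length(rewards) == T)
  if (is.null(state)) state <- agent_state(agent)
  V <- numeric(T)
  logp <- numeric(T)
  H <- numeric(T)
  for (t in seq_len(T)) {
    st <- lstm_step(agent, state, X[t, ])
    state <- st$state
    pv <- policy_value(agent, st$h)
    V[t] <- pv$V
    logp[t] <- log(pv$pi[[actions[t] + 1L]])
    H[t] <- -sum(pv$pi * log(pv$pi))
  }
  R <- discounted_return(rewards, config$gamma)
  adv <- R - V
  pol_adv <- if (is.null(policy_advantage)) adv else policy_advantage
  policy <- -sum(logp * pol_adv)
  value <- config$beta_v * sum(adv^2)
  entropy <- sum(H)
  list(total = policy + value - config$beta_H * entropy,
       policy = policy, value = value, entropy = entropy,
       advantage = adv, value_est = V)
}

#' Train an agent with advantage actor-critic
#'
#' Runs the full reinforcement-learning loop: trials are sampled from the
#' task generator, presented as a continuous stream (one blank separator
#' timestep before each trial), actions are sampled from the softmax policy
#' at every timestep, rewards (+5/-5, or the recency-shaped values under
#' that scheme) are delivered at decision timesteps and fed back as inputs,
#' and parameters are updated by Adam on the actor-critic loss after every
#' `update_every` trials. The recurrent state persists across trials;
#' backpropagation is truncated at segment boundaries.
#'
#' @param spec a [task_spec()].
#' @param n_units number of LSTM units.
#' @param config a [train_config()].
#' @param seed integer seed governing initialization, trial sampling and
#'   action sampling.
#' @return A `wm_checkpoints` object: list with `agents` (one `wm_agent`
#'   per checkpoint, named by episode count), `episodes`, `correct`
#'   (per-training-episode outcome), `spec`, `config`, `seed`.
#' @export
train_agent <- function(spec, n_units, config = train_config(), seed = 1L) {
  stopifnot(inherits(spec, "task_spec"), inherits(config, "train_config"))
  set.seed(seed)
  agent0 <- agent_init(n_units, spec)
  n_ep <- max(config$checkpoints)
  meta <- attr(agent0, "meta")
  if (n_ep == 0L) {
    agents <- list(`0` = agent0)
    correct <- integer(0)
  } else {
    ts <- sample_trials(spec, n_ep)
    res <- cpp_train(agent_params(agent0), ts$cues,
                     as.integer(ts$label == "match"),
                     core_cfg(spec, config), config$checkpoints)
    agents <- lapply(seq_along(res$checkpoints), function(i) {
      m <- meta
      m$episodes_trained <- config$checkpoints[i]
      agent_from_params(res$checkpoints[[i]], m)
    })
    names(agents) <- names(res$checkpoints)
    correct <- res$correct
  }
  structure(list(agents = agents, episodes = config$checkpoints,
                 correct = correct, spec = spec, n_units = n_units,
                 config = config, seed = seed),
            class = "wm_checkpoints")
}

#' @export
print.wm_checkpoints <- function(x, ...) {
  cat(sprintf("<wm_checkpoints> %d-unit agent on %s, checkpoints: %s\n",
              x$n_units, x$spec$task,
              paste(x$episodes, collapse = ", ")))
  invisible(x)
}

#' Extract one checkpoint agent
#'
#' @param ckpts a `wm_checkpoints` object.
#' @param episodes the checkpoint's episode count.
#' @return The `wm_agent` stored at that checkpoint.
#' @export
checkpoint_agent <- function(ckpts, episodes) {
  key <- as.character(episodes)
  if (!key %in% names(ckpts$agents))
    stop("no checkpoint at ", episodes, " episodes")
  ckpts$agents[[key]]
}

#' Evaluate an agent on test episodes
#'
#' Parameters are frozen; actions are sampled from the policy (so response
#' rates are graded probabilities), rewards are delivered and fed back as
#' inputs, and — when `record_states` — the hidden state after each cue
#' presentation is stored for the state-space analyses.
#'
#' @param agent a `wm_agent`.
#' @param spec a [task_spec()] compatible with the agent's input dimension.
#' @param n_test number of test episodes.
#' @param seed optional seed for trial generation and action sampling.
#' @param record_states store hidden states after each cue (episodes x
#'   trial-position x unit array).
#' @param record_steps store the full per-timestep record.
#' @return An `episode_log`: list with `trials` (one row per episode: cue
#'   columns, label, recency `position` of the test cue, response, correct,
#'   `prev_correct`, reward, `pi_yes`), optional `states` and `steps`,
#'   plus `spec` and `n_units`.
#' @export
evaluate_agent <- function(agent, spec, n_test = 5000L, seed = NULL,
                           record_states = FALSE, record_steps = FALSE) {
  stopifnot(inherits(agent, "wm_agent"), inherits(spec, "task_spec"))
  if (!is.null(seed)) set.seed(seed)
  ts <- sample_trials(spec, n_test)
  cfg <- core_cfg(spec, train_config())
  res <- cpp_evaluate(agent_params(agent), ts$cues,
                      as.integer(ts$label == "match"), cfg,
                      record_states, record_steps)
  trials <- trial_table(ts)
  trials$response <- ifelse(res$response_yes, "yes", "no")
  trials$correct <- res$correct
  trials$prev_correct <- c(NA, res$correct[-length(res$correct)])
  trials$reward <- res$reward
  trials$pi_yes <- res$pi_yes
  structure(list(trials = trials,
                 states = res$states,
                 steps = res$steps,
                 spec = spec,
                 n_units = attr(agent, "meta")$n_units),
            class = "episode_log")
}

# per-trial feature table shared by evaluate_agent() and scripted_log()
trial_table <- function(ts) {
  k <- ts$spec$trial_size
  cues <- ts$cues
  df <- as.data.frame(cues)
  names(df) <- paste0("cue", seq_len(k))
  df$lead_cue <- cues[, 1L]
  df$test_cue <- cues[, k]
  df$label <- ts$label
  df$position <- apply(cues, 1L, recency_position)
  df
}

#' @export
print.episode_log <- function(x, ...) {
  cat(sprintf("<episode_log> %d trials on %s (%s), %.1f%% correct%s\n",
              nrow(x$trials), x$spec$task, x$spec$encoding,
              100 * mean(x$trials$correct),
              if (!is.null(x$states)) ", states recorded" else ""))
  invisible(x)
}

#' Simulate a scripted (rule-based) agent
#'
#' Builds an `episode_log` for an agent whose yes-probability is an
#' explicit function of trial features rather than a trained network.
#' Useful for parameter-recovery checks of the behavioral analyses, e.g. a
#' target-selective script (`yes` iff lead = test) or a recency script
#' (yes-probability by recency position).
#'
#' @param spec a [task_spec()].
#' @param n_test number of trials.
#' @param prob_yes function taking the trial table (columns `cue1..cueK`,
#'   `lead_cue`, `test_cue`, `label`, `position`) and returning a vector of
#'   yes-probabilities.
#' @param seed optional seed.
#' @return An `episode_log` (without recorded states).
#' @export
scripted_log <- function(spec, n_test, prob_yes, seed = NULL) {
  stopifnot(inherits(spec, "task_spec"), is.function(prob_yes))
  if (!is.null(seed)) set.seed(seed)
  ts <- sample_trials(spec, n_test)
  trials <- trial_table(ts)
  p <- prob_yes(trials)
  stopifnot(length(p) == nrow(trials), all(p >= 0 & p <= 1))
  yes <- stats::runif(nrow(trials)) < p
  trials$response <- ifelse(yes, "yes", "no")
  trials$correct <- (trials$label == "match") == yes
  trials$prev_correct <- c(NA, trials$correct[-nrow(trials)])
  trials$reward <- ifelse(trials$correct, 5, -5)
  trials$pi_yes <- p
  structure(list(trials = trials, states = NULL, steps = NULL,
                 spec = spec, n_units = NA_integer_),
            class = "episode_log")
}
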