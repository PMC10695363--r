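# Independent scalar-arithmetic oracles used to cross-check the vectorized
# and compiled implementations. Kept deliberately naive (double loops,
# explicit sums) so they share no code path with the package internals.

oracle_lstm_step <- function(agent, state, x) {
  n <- length(state$h)
  sig <- function(z) 1 / (1 + exp(-z))
  h_new <- c_new <- numeric(n)
  for (u in seq_len(n)) {
    zf <- zi <- zo <- zg <- 0
    for (j in seq_along(x)) {
      zf <- zf + agent$Wxf[u, j] * x[j]
      zi <- zi + agent$Wxi[u, j] * x[j]
      zo <- zo + agent$Wxo[u, j] * x[j]
      zg <- zg + agent$Wxc[u, j] * x[j]
    }
    for (j in seq_len(n)) {
      zf <- zf + agent$Whf[u, j] * state$h[j]
      zi <- zi + agent$Whi[u, j] * state$h[j]
      zo <- zo + agent$Who[u, j] * state$h[j]
      zg <- zg + agent$Whc[u, j] * state$h[j]
    }
    f <- sig(zf + agent$bf[u, 1])
    i <- sig(zi + agent$bi[u, 1])
    o <- sig(zo + agent$bo[u, 1])
    g <- tanh(zg + agent$bc[u, 1])
    c_new[u] <- f * state$c[u] + i * g
    h_new[u] <- o * tanh(c_new[u])
  }
  list(h = h_new, c = c_new)
}

oracle_discounted_return <- function(rewards, gamma, terminal_value = 0) {
  T <- length(rewards)
  sapply(seq_len(T), function(t) {
    k <- T - t + 1L
    sum(gamma^(0:(k - 1L)) * rewards[t:T]) + gamma^k * terminal_value
  })
}

# random small agent on the current RNG stream
random_small_agent <- function(n_units = 3L, spec = task_spec("match_first", 5, 4)) {
  agent <- agent_init(n_units, spec)
  for (nm in c("bf", "bi", "bo", "bc", "bp", "bv"))
    agent[[nm]][] <- rnorm(length(agent[[nm]]), sd = 0.3)
  agent
}

# central finite differences of the frozen-advantage surrogate loss
fd_gradient <- function(agent, X, actions, rewards, config, eps = 1e-5) {
  base <- a2c_loss(agent, X, actions, rewards, config)
  adv <- base$advantage
  theta <- wmrnn:::agent_flatten(agent)
  vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    lp <- a2c_loss(wmrnn:::agent_unflatten(agent, tp), X, actions, rewards,
                   config, policy_advantage = adv)$total
    lm <- a2c_loss(wmrnn:::agent_unflatten(agent, tm), X, actions, rewards,
                   config, policy_advantage = adv)$total
    (lp - lm) / (2 * eps)
  }, numeric(1))
}

# manually assembled episode_log for hand-counted behavioral fixtures
manual_log <- function(spec, cues, responses, states = NULL) {
  ts <- structure(list(cues = cues,
                       label = apply(cues, 1L, wmrnn:::trial_label,
                                     task = spec$task),
                       spec = spec),
                  class = "trial_set")
  trials <- wmrnn:::trial_table(ts)
  trials$response <- responses
  trials$correct <- (trials$label == "match") == (responses == "yes")
  trials$prev_correct <- c(NA, trials$correct[-nrow(trials)])
  trials$reward <- ifelse(trials$correct, 5, -5)
  trials$pi_yes <- ifelse(responses == "yes", 1, 0)
  structure(list(trials = trials, states = states, steps = NULL,
                 spec = spec, n_units = NA_integer_),
            class = "episode_log")
}
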