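#' Initialize an LSTM agent
#'
#' Creates the parameter set of a gated recurrent (LSTM) agent with linear
#' policy and value readout heads. The recurrent dynamics follow the
#' standard five-equation LSTM update: sigmoid forget/input/output gates on
#' the weighted sum of the current input and previous output, a cell state
#' combining the gated previous cell with a tanh candidate, and output
#' `h = o * tanh(c)`. Two independent linear heads on `h` produce the two
#' action logits (softmax policy over yes/no) and the scalar value estimate.
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' (fan-in of the respective weight matrix); all biases start at zero, and
#' the initial hidden and cell states are zero. Draws come from the current
#' R random stream, so agents built under the same seed are identical.
#'
#' @param n_units number of neural units.
#' @param spec a [task_spec()], used to size the input layer:
#'   cue-encoding length + 2 previous-action slots + 1 previous-reward slot.
#' @return A `wm_agent`: named list of parameter matrices (`Wxf`, `Whf`,
#'   `Wxi`, `Whi`, `Wxo`, `Who`, `Wxc`, `Whc`, gate biases `bf`, `bi`,
#'   `bo`, `bc`, policy head `Wp` (2 x n) and `bp`, value head `Wv` (1 x n)
#'   and `bv`) plus a `meta` attribute (units, input dim, episodes trained).
#' @export
agent_init <- function(n_units, spec) {
  stopifnot(inherits(spec, "task_spec"), n_units >= 1)
  n <- as.integer(n_units)
  d <- input_dim(spec)
  u <- function(nr, nc) {
    lim <- 1 / sqrt(nc)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  z <- function(nr, nc = 1L) matrix(0, nr, nc)
  agent <- list(
    Wxf = u(n, d), Whf = u(n, n), Wxi = u(n, d), Whi = u(n, n),
    Wxo = u(n, d), Who = u(n, n), Wxc = u(n, d), Whc = u(n, n),
    bf = z(n), bi = z(n), bo = z(n), bc = z(n),
    Wp = u(2L, n), bp = z(2L), Wv = u(1L, n), bv = z(1L))
  attr(agent, "meta") <- list(n_units = n, input_dim = d,
                              encoding = spec$encoding,
                              set_size = spec$set_size,
                              episodes_trained = 0L)
  class(agent) <- "wm_agent"
  agent
}

#' @export
print.wm_agent <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<wm_agent> %d units, input dim %d, trained %d episodes\n",
              m$n_units, m$input_dim, m$episodes_trained))
  invisible(x)
}

#' Blank recurrent state
#'
#' @param agent a `wm_agent`.
#' @return List with zero vectors `h` and `c`.
#' @export
agent_state <- function(agent) {
  n <- attr(agent, "meta")$n_units
  list(h = numeric(n), c = numeric(n))
}

#' One LSTM update step
#'
#' Applies the five gating equations to advance the recurrent state by one
#' timestep:
#' `f = sigmoid(Wxf x + Whf h + bf)`, `i = sigmoid(Wxi x + Whi h + bi)`,
#' `o = sigmoid(Wxo x + Who h + bo)`,
#' `c' = f * c + i * tanh(Wxc x + Whc h + bc)`, `h' = o * tanh(c')`
#' (elementwise products throughout).
#'
#' @param agent a `wm_agent`.
#' @param state list with `h` and `c` (see [agent_state()]).
#' @param x input vector of length `input_dim`.
#' @return List with the new `state` and the output vector `h`.
#' @export
lstm_step <- function(agent, state, x) {
  d <- attr(agent, "meta")$input_dim
  if (length(x) != d) stop("input has length ", length(x), ", expected ", d)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- state$h
  f <- sig(drop(agent$Wxf %*% x + agent$Whf %*% h) + drop(agent$bf))
  i <- sig(drop(agent$Wxi %*% x + agent$Whi %*% h) + drop(agent$bi))
  o <- sig(drop(agent$Wxo %*% x + agent$Who %*% h) + drop(agent$bo))
  g <- tanh(drop(agent$Wxc %*% x + agent$Whc %*% h) + drop(agent$bc))
  c_new <- f * state$c + i * g
  h_new <- o * tanh(c_new)
  list(state = list(h = h_new, c = c_new), h = h_new)
}

#' Compose the network input vector
#'
#' The input at each timestep is the concatenation of the current cue
#' encoding, a one-hot encoding (yes, no) of the previous action, and the
#' previous reward. At the start of a stream (no previous action) the
#' trailing slots are zero.
#'
#' @param cue_vec cue-encoding vector from [encode_cue()].
#' @param prev_action `"yes"`, `"no"`, or `NULL` at stream start.
#' @param prev_reward previous scalar reward (0 at stream start).
#' @return Numeric input vector of length `length(cue_vec) + 3`.
#' @export
build_input <- function(cue_vec, prev_action = NULL, prev_reward = 0) {
  act <- c(0, 0)
  if (!is.null(prev_action)) {
    prev_action <- match.arg(prev_action, c("yes", "no"))
    act[if (prev_action == "yes") 1L else 2L] <- 1
  }
  c(cue_vec, act, prev_reward)
}

#' Policy and value readouts
#'
#' Two linear heads on the LSTM output: the two action logits are passed
#' through a softmax to give the policy over \{yes, no\}; the value estimate
#' is a scalar linear readout.
#'
#' @param agent a `wm_agent`.
#' @param h LSTM output vector.
#' @return List with `pi` (named probabilities `yes`, `no`), `V` and
#'   `logits`.
#' @export
policy_value <- function(agent, h) {
  logits <- drop(agent$Wp %*% h + agent$bp)
  z <- exp(logits - max(logits))
  pi <- z / sum(z)
  names(pi) <- names(logits) <- c("yes", "no")
  list(pi = pi, V = drop(agent$Wv %*% h + agent$bv), logits = logits)
}

#' Save / load an agent checkpoint
#'
#' Checkpoints are single-file containers holding all parameter arrays plus
#' the metadata record (units, input dimension, episodes trained); reloads
#' are bit-exact.
#'
#' @param agent a `wm_agent`.
#' @param path file path.
#' @return `read_agent` returns the restored `wm_agent`; `write_agent`
#'   returns `path` invisibly.
#' @export
write_agent <- function(agent, path) {
  stopifnot(inherits(agent, "wm_agent"))
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname write_agent
#' @export
read_agent <- function(path) {
  agent <- readRDS(path)
  stopifnot(inherits(agent, "wm_agent"))
  agent
}

# Flatten/unflatten the parameter list to a single numeric vector (fixed
# order); used by finite-difference checks and the zero-learning-rate test.
agent_flatten <- function(agent) {
  unlist(lapply(unclass(agent)[par_names()], as.numeric), use.names = FALSE)
}

agent_unflatten <- function(agent, theta) {
  off <- 0L
  for (nm in par_names()) {
    len <- length(agent[[nm]])
    agent[[nm]][] <- theta[off + seq_len(len)]
    off <- off + len
  }
  stopifnot(off == length(theta))
  agent
}

par_names <- function() {
  c("Wxf", "Whf", "Wxi", "Whi", "Wxo", "Who", "Wxc", "Whc",
    "bf", "bi", "bo", "bc", "Wp", "bp", "Wv", "bv")
}

# parameter list in the form the compiled core expects
agent_params <- function(agent) unclass(agent)[par_names()]

# rebuild a wm_agent from a compiled-core parameter list
agent_from_params <- function(params, meta) {
  agent <- params[par_names()]
  attr(agent, "meta") <- meta
  class(agent) <- "wm_agent"
  agent
}
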