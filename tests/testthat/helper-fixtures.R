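# Trained-agent fixtures shared across test files. Training is deterministic
# given the fixed fixture seed, and each arm is built lazily once per test
# run. Replicate counts and test depths are reduced relative to the full
# study (5 replicates, 5000 test episodes) to keep the suite fast.

fixture_env <- new.env(parent = emptyenv())
FIXTURE_SEED <- 42L

fixture_main <- function() {
  if (is.null(fixture_env$main)) {
    spec <- task_spec("match_first", 5, 4)
    reps <- train_replicates(spec, 25, 5, train_config(),
                             master_seed = FIXTURE_SEED, arm = 1L)
    logs <- lapply(reps, function(ck)
      evaluate_checkpoints(ck, n_test = 5000,
                           record_states_at = c(20000, 50000),
                           seed_base = ck$seed))
    fixture_env$main <- list(spec = spec, reps = reps, logs = logs)
  }
  fixture_env$main
}

fixture_recency <- function() {
  if (is.null(fixture_env$recency)) {
    spec <- task_spec("match_first", 5, 4, reward_scheme = "recency")
    cfg <- train_config(checkpoints = c(0, 5000, 10000, 12000))
    reps <- train_replicates(spec, 25, 5, cfg,
                             master_seed = FIXTURE_SEED, arm = 2L)
    logs <- lapply(reps, function(ck)
      evaluate_checkpoints(ck, n_test = 5000, seed_base = ck$seed))
    fixture_env$recency <- list(spec = spec, reps = reps, logs = logs)
  }
  fixture_env$recency
}

fixture_onehot <- function() {
  if (is.null(fixture_env$onehot)) {
    spec <- task_spec("match_first", 5, 4, encoding = "one_hot")
    cfg <- train_config(checkpoints = c(0, 10000, 20000))
    reps <- train_replicates(spec, 25, 5, cfg,
                             master_seed = FIXTURE_SEED, arm = 3L)
    fixture_env$onehot <- list(spec = spec, reps = reps)
  }
  fixture_env$onehot
}

fixture_grid <- function() {
  if (is.null(fixture_env$grid)) {
    spec <- task_spec("match_first", 5, 4)
    cfg <- train_config(checkpoints = c(0, 10000, 20000, 50000))
    fixture_env$grid <- run_grid(spec, sizes = c(10L, 25L, 50L),
                                 n_replicates = 3L, config = cfg,
                                 n_test = 5000, master_seed = FIXTURE_SEED)
  }
  fixture_env$grid
}

# per-replicate behavioral metric table for an evaluated arm
fixture_metric_table <- function(arm) {
  do.call(rbind, lapply(seq_along(arm$reps), function(r) {
    do.call(rbind, lapply(names(arm$logs[[r]]), function(ep) {
      m <- behavior_metrics(arm$logs[[r]][[ep]])
      data.frame(replicate = r, n_ep = as.integer(ep),
                 performance = m$performance, slope = m$slope,
                 residual = m$residual)
    }))
  }))
}
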