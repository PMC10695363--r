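#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a master seed with one or more indices (size,
#' replicate, checkpoint, arm) so every source of randomness in a grid run
#' is driven by the single master seed. Kept well below 2^31.
#'
#' @param master master seed (integer).
#' @param ... integer indices identifying the sub-stream.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  ix <- c(...)
  v <- as.numeric(master) %% 1e6
  for (i in seq_along(ix)) v <- (v * 131 + as.numeric(ix[i]) * 7919) %% 2147480000
  as.integer(v) + 1L
}

#' Behavioral metrics of one evaluation log
#'
#' @param log an `episode_log`.
#' @return List with `performance`, `slope`, `residual`, `hit_rate`.
#' @export
behavior_metrics <- function(log) {
  curve <- serial_position_curve(log)
  fit <- fit_spc(curve)
  list(performance = performance(log), slope = fit$slope,
       residual = fit$residual, hit_rate = fit$hit_rate)
}

#' State-space geometry summary of one evaluation log
#'
#' Embeds the hidden states recorded after the first three cues of correct
#' trials in top-`k` PC space and computes the three cue-sorting directions
#' and their angles; also reports the top-3 variance explained of the
#' final-state (after all cues) activity on correct trials.
#'
#' @param log an `episode_log` recorded with states.
#' @param fold fold angles to `[0, 90]` (one-hot runs).
#' @return List with `angles` (`theta_12`, `theta_23`, `theta_13`),
#'   `var3_cue3` and `var3_final` (top-3 variance fractions of the
#'   after-3-cues and final-state activity), and the `embedding`.
#' @export
geometry_summary <- function(log, fold = FALSE) {
  k <- log$spec$trial_size
  emb3 <- pca_embed(collect_states(log, after_cue = k - 1L,
                                   filter = "correct"), k = 3L)
  sd3 <- sorting_directions(emb3, fold = fold)
  embf <- pca_embed(collect_states(log, after_cue = k, filter = "correct"),
                    k = 3L)
  list(angles = sd3$angles,
       var3_cue3 = sum(emb3$variance_fractions[1:3]),
       var3_final = sum(embf$variance_fractions[1:3]),
       embedding = emb3)
}

#' Train a set of replicate agents
#'
#' @param spec a [task_spec()].
#' @param n_units LSTM units.
#' @param n_replicates number of independently seeded replicates.
#' @param config a [train_config()].
#' @param master_seed master seed; replicate seeds are derived from it.
#' @param arm integer tag distinguishing experiment arms sharing a master
#'   seed.
#' @return List of `wm_checkpoints`, one per replicate.
#' @export
train_replicates <- function(spec, n_units, n_replicates = 5L,
                             config = train_config(), master_seed = 1L,
                             arm = 1L) {
  lapply(seq_len(n_replicates), function(r)
    train_agent(spec, n_units, config,
                seed = derive_seed(master_seed, arm, r)))
}

#' Evaluate every checkpoint of a training run
#'
#' @param ckpts a `wm_checkpoints` object.
#' @param n_test test episodes per checkpoint.
#' @param record_states_at episode counts at which hidden states are also
#'   recorded (for geometry analyses).
#' @param seed_base evaluation seed base (mixed with the checkpoint index).
#' @return Named list of `episode_log`s keyed by episode count.
#' @export
evaluate_checkpoints <- function(ckpts, n_test = 5000L,
                                 record_states_at = integer(0),
                                 seed_base = 1L) {
  logs <- lapply(seq_along(ckpts$episodes), function(i) {
    ep <- ckpts$episodes[i]
    evaluate_agent(checkpoint_agent(ckpts, ep), ckpts$spec, n_test = n_test,
                   seed = derive_seed(seed_base, 91L, i),
                   record_states = ep %in% record_states_at)
  })
  names(logs) <- as.character(ckpts$episodes)
  logs
}

#' Run a network-size by training-experience grid
#'
#' Trains and evaluates every (size, replicate) cell of a grid on one task,
#' collecting performance and serial-position-curve metrics at every
#' checkpoint. Cells can be cached to disk so an interrupted grid resumes
#' to an identical table.
#'
#' @param spec a [task_spec()].
#' @param sizes vector of network sizes.
#' @param n_replicates replicates per size.
#' @param config a [train_config()] (its `checkpoints` define the
#'   experience axis).
#' @param n_test test episodes per cell.
#' @param master_seed master seed for the whole grid.
#' @param cache_dir optional directory for per-cell caching (resumability).
#' @return Long-form data frame: `n_units`, `seed`, `n_ep`, `performance`,
#'   `slope`, `residual`, `hit_rate`.
#' @export
run_grid <- function(spec, sizes = c(10L, 25L, 50L), n_replicates = 3L,
                     config = train_config(), n_test = 5000L,
                     master_seed = 1L, cache_dir = NULL) {
  rows <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(n_replicates)) {
      cell <- NULL
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, sprintf("grid_n%d_r%d.rds", sizes[si], r))
      if (!is.null(cache_file) && file.exists(cache_file))
        cell <- readRDS(cache_file)
      if (is.null(cell)) {
        seed <- derive_seed(master_seed, 10L + si, r)
        ck <- train_agent(spec, sizes[si], config, seed = seed)
        logs <- evaluate_checkpoints(ck, n_test = n_test, seed_base = seed)
        cell <- do.call(rbind, lapply(names(logs), function(ep) {
          m <- behavior_metrics(logs[[ep]])
          data.frame(n_units = sizes[si], seed = seed,
                     n_ep = as.integer(ep), performance = m$performance,
                     slope = m$slope, residual = m$residual,
                     hit_rate = m$hit_rate)
        }))
        if (!is.null(cache_file)) {
          dir.create(dirname(cache_file), showWarnings = FALSE,
                     recursive = TRUE)
          saveRDS(cell, cache_file)
        }
      }
      rows[[length(rows) + 1L]] <- cell
    }
  }
  do.call(rbind, rows)
}

#' Compare the original and recency reward schemes
#'
#' Trains matched-seed replicate sets under both reward schemes on the same
#' task and collects per-checkpoint performance and serial-position-curve
#' slope, the quantities in which the recency scheme shows earlier learning
#' and a larger slope deflection.
#'
#' @param spec a Match-First [task_spec()] (its `reward_scheme` is
#'   overridden per arm).
#' @param n_units LSTM units.
#' @param n_replicates replicates per arm.
#' @param config a [train_config()].
#' @param n_test test episodes per checkpoint.
#' @param master_seed master seed (matched across arms).
#' @return Long-form data frame: `scheme`, `seed`, `n_ep`, `performance`,
#'   `slope`, `residual`.
#' @export
compare_reward_schemes <- function(spec, n_units = 25L, n_replicates = 5L,
                                   config = train_config(), n_test = 5000L,
                                   master_seed = 1L) {
  if (spec$task != "match_first")
    stop("the reward-scheme comparison is defined for match_first")
  rows <- list()
  for (scheme in c("original", "recency")) {
    sp <- spec
    sp$reward_scheme <- scheme
    reps <- train_replicates(sp, n_units, n_replicates, config,
                             master_seed = master_seed, arm = 1L)
    for (r in seq_along(reps)) {
      logs <- evaluate_checkpoints(reps[[r]], n_test = n_test,
                                   seed_base = reps[[r]]$seed)
      for (ep in names(logs)) {
        m <- behavior_metrics(logs[[ep]])
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, seed = reps[[r]]$seed, replicate = r,
          n_ep = as.integer(ep), performance = m$performance,
          slope = m$slope, residual = m$residual)
      }
    }
  }
  do.call(rbind, rows)
}

#' Encoding-arm summaries: error profiles and distance-error correlations
#'
#' For a set of trained replicates (typically one-hot encoded), computes
#' per-replicate match-error profiles, the aggregate (across-replicate
#' mean) profile, and the per-replicate Pearson correlation between
#' intercluster centroid distances (lead-cue clusters after the first
#' three cues) and paired match-error rates.
#'
#' @param replicates list of `wm_checkpoints` (from [train_replicates()]).
#' @param at_episodes checkpoint at which to evaluate.
#' @param n_test test episodes per replicate.
#' @return List with `profiles` (per-replicate `error_profile`s),
#'   `aggregate` (mean percent per target/lead/category),
#'   `correlations` (per-replicate data frame: `replicate`, `r`,
#'   `p_value`).
#' @export
compare_encodings <- function(replicates, at_episodes = 20000L,
                              n_test = 5000L) {
  profiles <- list()
  cors <- list()
  for (r in seq_along(replicates)) {
    ck <- replicates[[r]]
    log <- evaluate_agent(checkpoint_agent(ck, at_episodes), ck$spec,
                          n_test = n_test,
                          seed = derive_seed(ck$seed, 77L, 1L),
                          record_states = TRUE)
    profiles[[r]] <- match_error_profile(log)
    emb <- pca_embed(collect_states(log, after_cue = ck$spec$trial_size - 1L,
                                    filter = "correct"), k = 3L)
    dd <- intercluster_distances(emb, by = "lead_cue")
    dec <- distance_error_correlation(dd, log)
    cors[[r]] <- data.frame(replicate = r, r = dec$r,
                            p_value = dec$p_value, n_pairs = dec$n_pairs)
  }
  agg <- profiles[[1L]][, c("target_cue", "lead_cue", "category")]
  agg$percent <- rowMeans(do.call(cbind, lapply(profiles, `[[`, "percent")),
                          na.rm = TRUE)
  list(profiles = profiles, aggregate = agg, correlations = do.call(rbind, cors))
}
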