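#' Collect hidden states into a trial-by-unit matrix
#'
#' Extracts the hidden state recorded after a given cue presentation from
#' an evaluation run, one row per qualifying trial, together with the
#' trial labels needed for cluster analyses. Filters follow the figure
#' conventions: all trials, correct trials only, or correct trials that
#' followed a correct trial.
#'
#' @param log an `episode_log` recorded with `record_states = TRUE`.
#' @param after_cue within-trial cue index (1 = after the lead cue,
#'   `trial_size` = the final pre-response state).
#' @param filter `"all"`, `"correct"` or `"correct_after_correct"`.
#' @return A `state_matrix`: list with `states` (rows = trials, columns =
#'   units) and `labels` (the matching rows of the trial table).
#' @export
collect_states <- function(log, after_cue,
                           filter = c("correct", "all",
                                      "correct_after_correct")) {
  stopifnot(inherits(log, "episode_log"))
  filter <- match.arg(filter)
  if (is.null(log$states))
    stop("log was not recorded with record_states = TRUE")
  k <- log$spec$trial_size
  stopifnot(after_cue >= 1L, after_cue <= k)
  keep <- switch(filter,
    all = rep(TRUE, nrow(log$trials)),
    correct = log$trials$correct,
    correct_after_correct =
      log$trials$correct & !is.na(log$trials$prev_correct) &
      log$trials$prev_correct)
  if (sum(keep) < 2L) stop("filter leaves fewer than 2 trials")
  structure(list(states = log$states[keep, after_cue, , drop = TRUE],
                 labels = log$trials[keep, , drop = FALSE],
                 after_cue = after_cue, filter = filter),
            class = "state_matrix")
}

#' PCA embedding of hidden states
#'
#' Mean-centered principal component analysis of a state matrix. Variance
#' fractions are relative to the total activity variance, so the reported
#' top-k sum is the "variance explained" of the embedding.
#'
#' @param sm a `state_matrix` from [collect_states()] (or a bare matrix).
#' @param k number of components to keep (default 3).
#' @return List with `scores` (rows x k), `rotation`, `variance_fractions`
#'   (all components), `labels` (carried through when present) and `k`
#'   (possibly reduced, with a warning, when the data have lower rank).
#' @export
pca_embed <- function(sm, k = 3L) {
  states <- if (inherits(sm, "state_matrix")) sm$states else sm
  labels <- if (inherits(sm, "state_matrix")) sm$labels else NULL
  stopifnot(nrow(states) >= k)
  pc <- stats::prcomp(states, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < k) {
    warning("data rank ", rank, " < k = ", k, "; returning ", rank,
            " components")
    k <- rank
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       variance_fractions = vf, labels = labels, k = k)
}

# centroids of embedding rows grouped by an integer label vector
label_centroids <- function(scores, labels) {
  lev <- sort(unique(labels))
  cen <- t(vapply(lev, function(l) colMeans(scores[labels == l, , drop = FALSE]),
                  numeric(ncol(scores))))
  rownames(cen) <- lev
  cen
}

#' Cue-sorting direction in state space
#'
#' Computes the centroid of the embedded states for each identity of the
#' cue shown at a given within-trial position, then fits a least-squares
#' line through the centroids (total least squares: the first principal
#' axis of the centroid set). The direction is oriented so that centroid
#' projections increase with cue value, which makes obtuse angles between
#' directions representable. Under one-hot encoding cue identities have no
#' order, so orientation is arbitrary there (see [angle_between()]'s
#' `fold`).
#'
#' @param embedding result of [pca_embed()] (needs `labels`).
#' @param position within-trial position of the cue used for grouping.
#' @param restrict optional logical vector (length = rows of the embedding)
#'   restricting the point cloud, e.g. to trials whose first cue is cue 1
#'   when computing the second and third sorting directions.
#' @return Unit vector (length k) of class `sorting_direction` with
#'   attribute `centroids`.
#' @export
sorting_direction <- function(embedding, position, restrict = NULL) {
  labels <- embedding$labels[[paste0("cue", position)]]
  scores <- embedding$scores
  if (!is.null(restrict)) {
    stopifnot(length(restrict) == nrow(scores))
    scores <- scores[restrict, , drop = FALSE]
    labels <- labels[restrict]
  }
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need >= 2 cue identities with states")
  cen <- label_centroids(scores, labels)
  if (max(apply(cen, 2L, stats::sd)) < 1e-12)
    stop("all centroids coincide; sorting direction undefined")
  dir <- stats::prcomp(cen, center = TRUE, scale. = FALSE)$rotation[, 1L]
  # orient by increasing cue value
  proj <- cen %*% dir
  if (stats::cov(proj, lev)[1L] < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  structure(dir, centroids = cen, class = "sorting_direction")
}

#' Sorting directions and angles for the first three cues
#'
#' Direction 1 is fit on all embedded trials grouped by the first cue;
#' directions 2 and 3 are fit within the point cloud whose first cue is
#' cue 1, grouped by the second and third cue respectively, following the
#' original analysis protocol.
#'
#' @param embedding result of [pca_embed()] on states collected after the
#'   first three cues.
#' @param fold fold angles to `[0, 90]` (used for one-hot runs where cue
#'   order, hence orientation, is arbitrary).
#' @return List with `directions` (list of 3 unit vectors) and `angles`
#'   (named: `theta_12`, `theta_23`, `theta_13`, degrees).
#' @export
sorting_directions <- function(embedding, fold = FALSE) {
  first_is_1 <- embedding$labels$cue1 == 1L
  d1 <- sorting_direction(embedding, 1L)
  d2 <- sorting_direction(embedding, 2L, restrict = first_is_1)
  d3 <- sorting_direction(embedding, 3L, restrict = first_is_1)
  ang <- c(theta_12 = angle_between(d1, d2, fold = fold),
           theta_23 = angle_between(d2, d3, fold = fold),
           theta_13 = angle_between(d1, d3, fold = fold))
  list(directions = list(d1, d2, d3), angles = ang)
}

#' Angle between two directions
#'
#' @param u,v nonzero vectors.
#' @param fold if TRUE, fold to `[0, 90]` degrees (direction orientation
#'   ignored); otherwise the angle is in `[0, 180]`.
#' @return Angle in degrees.
#' @export
angle_between <- function(u, v, fold = FALSE) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  ang <- acos(ct) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

#' Pairwise intercluster centroid distances
#'
#' Euclidean distances between the centroids of state clusters grouped by
#' a trial label (by default the lead cue) in the embedding space.
#' Distances are in PC-score units (arbitrary units); no normalization is
#' applied across networks.
#'
#' @param embedding result of [pca_embed()] (needs `labels`).
#' @param by trial-table column defining the clusters.
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   cluster identity.
#' @export
intercluster_distances <- function(embedding, by = "lead_cue") {
  labels <- embedding$labels[[by]]
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need >= 2 clusters")
  cen <- label_centroids(embedding$scores, labels)
  as.matrix(stats::dist(cen))
}

#' Correlation between intercluster distances and match-error rates
#'
#' Pairs each lead-cue cluster pair (i, j) with the corresponding paired
#' match-error rate: the erroneous yes-rate on j-i-X-i trials and on
#' i-j-X-j trials (averaged when both are sampled), i.e. the errors made by
#' confusing the two clusters. Returns the Pearson correlation over pairs;
#' smaller distances predicting higher error rates give a negative r.
#'
#' @param distances distance matrix from [intercluster_distances()].
#' @param log the `episode_log` the distances came from (error rates are
#'   counted on its trials).
#' @return List with `r`, `p_value`, `n_pairs`, the per-pair table
#'   (`pairs`), and `flagged` (TRUE when the correlation is undefined,
#'   e.g. constant distances or errors).
#' @export
distance_error_correlation <- function(distances, log) {
  stopifnot(inherits(log, "episode_log"))
  profile <- match_error_profile(log)
  xaxa <- profile[profile$category == "XAXA", ]
  ids <- as.integer(rownames(distances))
  pairs <- utils::combn(seq_along(ids), 2L)
  tab <- data.frame(i = ids[pairs[1L, ]], j = ids[pairs[2L, ]],
                    distance = distances[t(pairs)])
  rate_of <- function(lead, target) {
    row <- xaxa[xaxa$lead_cue == lead & xaxa$target_cue == target, ]
    if (nrow(row) == 0L) return(NA_real_)
    row$error_rate
  }
  tab$error_rate <- mapply(function(i, j) {
    r <- c(rate_of(j, i), rate_of(i, j))
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }, tab$i, tab$j)
  ok <- !is.na(tab$error_rate)
  if (sum(ok) < 3L) stop("fewer than 3 valid cluster pairs")
  if (stats::sd(tab$distance[ok]) == 0 || stats::sd(tab$error_rate[ok]) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_pairs = sum(ok),
                pairs = tab, flagged = TRUE))
  ct <- stats::cor.test(tab$distance[ok], tab$error_rate[ok],
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = sum(ok),
       pairs = tab, flagged = FALSE)
}
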