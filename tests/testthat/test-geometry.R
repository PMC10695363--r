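# small embedding-like object with controlled scores and labels
fake_embedding <- function(scores, labels) {
  list(scores = scores, rotation = NULL,
       variance_fractions = rep(1 / ncol(scores), ncol(scores)),
       labels = labels, k = ncol(scores))
}

test_that("state collection honors filters and indexing", {
  set.seed(51)
  spec <- task_spec("match_first", 5, 4)
  agent <- agent_init(6, spec)
  log <- evaluate_agent(agent, spec, 500, seed = 9, record_states = TRUE)
  sm <- collect_states(log, after_cue = 4, filter = "correct")
  expect_identical(nrow(sm$states), sum(log$trials$correct))
  # final pre-response state equals the stored slot for the 4th cue
  expect_equal(sm$states[1, ],
               log$states[which(log$trials$correct)[1], 4, ])
  cac <- collect_states(log, 4, "correct_after_correct")
  expect_true(all(rownames(cac$labels) %in% rownames(sm$labels)))
  expect_lte(nrow(cac$states), nrow(sm$states))
  expect_error(collect_states(evaluate_agent(agent, spec, 50, seed = 1),
                              4), "record_states")
})

test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(52)
  X <- matrix(rnorm(200 * 8), 200, 8) %*% matrix(rnorm(64, sd = 0.5), 8, 8)
  emb <- pca_embed(X, k = 3)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(emb$variance_fractions,
               ev$values / sum(ev$values), tolerance = 1e-9)
  # scores match projection onto eigenvectors up to sign
  Xc <- scale(X, center = TRUE, scale = FALSE)
  for (j in 1:3) {
    proj <- Xc %*% ev$vectors[, j]
    expect_equal(abs(cor(proj, emb$scores[, j]))[1], 1, tolerance = 1e-9)
  }
})

test_that("points on a plane need exactly two components", {
  set.seed(53)
  basis <- qr.Q(qr(matrix(rnorm(25 * 2), 25, 2)))
  X <- matrix(rnorm(100 * 2), 100, 2) %*% t(basis)
  emb <- suppressWarnings(pca_embed(X, k = 3))
  expect_equal(sum(emb$variance_fractions[1:2]), 1, tolerance = 1e-9)
  expect_warning(pca_embed(X, k = 3), "rank")
})

test_that("duplicating every row leaves the embedding unchanged up to sign", {
  set.seed(54)
  X <- matrix(rnorm(60 * 5), 60, 5)
  e1 <- pca_embed(X, 3)
  e2 <- pca_embed(rbind(X, X), 3)
  for (j in 1:3)
    expect_equal(abs(e2$scores[1:60, j]), abs(e1$scores[, j]),
                 tolerance = 1e-9)
})

test_that("sorting directions recover known axes and orientation", {
  # collinear centroids along the first axis
  lab <- data.frame(cue1 = rep(1:5, each = 10))
  scores <- cbind(lab$cue1, 0, 0) + 0
  emb <- fake_embedding(scores, lab)
  d <- sorting_direction(emb, 1)
  expect_equal(as.numeric(d), c(1, 0, 0), tolerance = 1e-12)
  # reversing cue order negates the direction
  lab_rev <- data.frame(cue1 = 6L - lab$cue1)
  d_rev <- sorting_direction(fake_embedding(scores, lab_rev), 1)
  expect_equal(as.numeric(d_rev), c(-1, 0, 0), tolerance = 1e-12)
  # noisy centroids around a known random axis stay within 2 degrees
  set.seed(55)
  for (rep in 1:10) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    pts <- do.call(rbind, lapply(1:5, function(cv)
      matrix(rep(cv * axis, 40), ncol = 3, byrow = TRUE) +
        matrix(rnorm(120, sd = 0.01), ncol = 3)))
    emb2 <- fake_embedding(pts, data.frame(cue1 = rep(1:5, each = 40)))
    d2 <- sorting_direction(emb2, 1)
    expect_lt(angle_between(d2, axis), 2)
  }
  # coincident centroids are an error
  same <- fake_embedding(matrix(1, 25, 3), data.frame(cue1 = rep(1:5, 5)))
  expect_error(sorting_direction(same, 1), "coincide")
})

test_that("angles follow the arccos closed forms and constructions", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(angle_between(e1, e2), 90)
  expect_equal(angle_between(e1, e1), 0)
  expect_equal(angle_between(e1, -e1), 180)
  expect_equal(angle_between(e1, -e1, fold = TRUE), 0)
  expect_error(angle_between(e1, c(0, 0, 0)), "zero vector")
  set.seed(56)
  for (rep in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    w <- rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    theta <- runif(1, 1, 179)
    v <- cos(theta * pi / 180) * u + sin(theta * pi / 180) * w
    expect_equal(angle_between(u, v), theta, tolerance = 1e-6)
  }
})

test_that("intercluster distances are Euclidean, symmetric, zero-diagonal", {
  lab <- data.frame(lead_cue = rep(1:2, each = 5))
  scores <- rbind(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
                  matrix(rep(c(3, 4, 0), 5), ncol = 3, byrow = TRUE))
  dd <- intercluster_distances(fake_embedding(scores, lab))
  expect_equal(dd["1", "2"], 5)
  set.seed(57)
  lab2 <- data.frame(lead_cue = sample(1:5, 200, replace = TRUE))
  sc2 <- matrix(rnorm(600), 200, 3)
  dd2 <- intercluster_distances(fake_embedding(sc2, lab2))
  expect_equal(dd2, t(dd2))
  expect_true(all(diag(dd2) == 0))
  # brute-force double-loop oracle
  cen <- t(sapply(1:5, function(l) colMeans(sc2[lab2$lead_cue == l, ])))
  for (i in 1:5) for (j in 1:5)
    expect_equal(dd2[i, j], sqrt(sum((cen[i, ] - cen[j, ])^2)),
                 tolerance = 1e-12)
})

test_that("distance-error correlation is exact on constructed data", {
  spec <- task_spec("match_first", 5, 4)
  # build trials so that the j-i-X-i error yes-rate is exactly controlled
  pairs <- t(combn(1:5, 2))
  rates <- (10:1) / 10  # multiples of 1/10 so counts realize them exactly
  cues <- NULL; responses <- NULL
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    other <- setdiff(1:5, c(i, j))[1]
    block <- matrix(rep(c(j, i, other, i), each = 10), ncol = 4)
    cues <- rbind(cues, block)
    responses <- c(responses, rep(c("yes", "no"),
                                  c(round(10 * rates[p]),
                                    10 - round(10 * rates[p]))))
  }
  log <- manual_log(spec, cues, responses)
  # distances exactly affine-inverse to the error rates -> r = -1
  dmat <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  for (p in seq_len(nrow(pairs))) {
    d <- 2 - rates[p]
    dmat[pairs[p, 1], pairs[p, 2]] <- d
    dmat[pairs[p, 2], pairs[p, 1]] <- d
  }
  res <- distance_error_correlation(dmat, log)
  expect_equal(res$r, -1, tolerance = 1e-9)
  expect_identical(res$n_pairs, 10L)
  # constant error rates -> flagged
  log2 <- manual_log(spec, cues, rep(c("yes", "no"), length.out = nrow(cues)))
  res2 <- distance_error_correlation(dmat, log2)
  expect_true(res2$flagged)
  # hand table against the direct Pearson formula
  x <- dmat[t(combn(1:5, 2))]
  y <- res$pairs$error_rate
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
})
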