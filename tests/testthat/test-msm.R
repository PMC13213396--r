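# Clustering, TPM estimation, implied timescales, CK test, GMRQ CV.

test_that("k-means recovers planted blobs and handles degenerate input", {
  withr::with_seed(1, {
    X <- rbind(matrix(rnorm(200, 0), ncol = 2),
               matrix(rnorm(200, 8), ncol = 2))
    truth <- rep(1:2, each = 100)
  })
  km <- kmeans_cluster(X, 2, seed = 3)
  expect_equal(adjusted_rand_index(km$dtrajs$trajectories[[1]], truth), 1.0)
  # centers in canonical order (ascending first coordinate)
  expect_true(km$centers[1, 1] < km$centers[2, 1])

  # k = n_frames: every frame its own cluster, inertia 0
  Xs <- matrix(seq_len(12), ncol = 2)
  km2 <- kmeans_cluster(Xs, 6, seed = 1)
  expect_equal(sort(unique(km2$dtrajs$trajectories[[1]])), 1:6)
  d <- sqrt(rowSums((Xs - km2$centers[km2$dtrajs$trajectories[[1]], ])^2))
  expect_lt(max(d), 1e-12)

  # identical frames with k = 3: converges, single occupied label
  Xc <- matrix(1, nrow = 10, ncol = 2)
  expect_warning(km3 <- kmeans_cluster(Xc, 3, seed = 1), "empty cluster")
  expect_equal(length(unique(km3$dtrajs$trajectories[[1]])), 1L)
})

test_that("k-means assignments are reproducible under a fixed seed", {
  withr::with_seed(2, X <- matrix(rnorm(600), ncol = 3))
  a <- kmeans_cluster(X, 5, seed = 42)
  b <- kmeans_cluster(X, 5, seed = 42)
  expect_identical(a$dtrajs$trajectories, b$dtrajs$trajectories)
  expect_equal(a$centers, b$centers)
})

test_that("TPM estimation matches hand counts and the known generator", {
  # hand count: [1,1,1,2,2,2] at lag 1 (trimming off: two singleton SCCs)
  d <- discrete_trajectory_set(list(c(1L, 1L, 1L, 2L, 2L, 2L)))
  tpm <- estimate_tpm(d, 1, connectivity = "none")
  expect_equal(tpm$counts, matrix(c(2, 1, 0, 2), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(tpm$matrix, matrix(c(2 / 3, 1 / 3, 0, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # default strong trimming keeps the largest SCC only
  tpm_s <- estimate_tpm(d, 1)
  expect_equal(nrow(tpm_s$matrix), 1L)

  # normalization invariant on arbitrary data
  spec <- memory_chain_spec()
  sim <- gen_fine_chain(spec, 5, 2000, seed = 21)
  t2 <- estimate_tpm(sim$observed, 3)
  expect_lt(max(abs(rowSums(t2$matrix) - 1)), 1e-10)

  # estimator consistency: identity projection, compare to known M
  M <- memory_chain_M()
  spec_id <- fine_chain_spec(M, 1:9)
  sim_id <- gen_fine_chain(spec_id, 20, 3000, seed = 22)
  est <- estimate_tpm(sim_id$observed, 1)
  expect_equal(length(est$active_set), 9L)
  rowc <- rowSums(est$counts[est$active_set, est$active_set])
  for (i in 1:9) for (j in 1:9) {
    s <- sqrt(M[i, j] * (1 - M[i, j]) / rowc[i])
    expect_lt(abs(est$matrix[i, j] - M[i, j]), 3 * s + 1e-9)
  }
})

test_that("reversible estimators satisfy detailed balance to 1e-8", {
  sim <- gen_fine_chain(memory_chain_spec(), 5, 3000, seed = 30)
  for (est in c("reversible-sym", "reversible-mle")) {
    tpm <- estimate_tpm(sim$observed, 2, estimator = est)
    p <- tpm$stationary
    db <- outer(p, rep(1, 3)) * tpm$matrix
    expect_lt(max(abs(db - t(db))), 1e-8)
  }
})

test_that("implied timescales follow closed forms and detect memory", {
  # 2-state chain, lambda2 = 0.9 -> t2 = -1/log(0.9) ~ 9.49 frames
  T0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  spec <- fine_chain_spec(T0, 1:2)
  sim <- gen_fine_chain(spec, 10, 5000, seed = 31)
  its <- implied_timescales(sim$observed, lags = c(1, 3, 5))
  t2 <- its$timescale[its$lag == 1]
  expect_equal(t2, -1 / log(0.9), tolerance = 0.08)
  # Markovian data: flat in lag (within sampling error)
  expect_equal(its$timescale[its$lag == 5], t2, tolerance = 0.15 * t2)

  # lumped chain: timescale grows with lag before plateauing; verify
  # against the exact projected propagators (no sampling noise)
  ser <- exact_projected_tpms(memory_chain_spec(), 12)
  t_at <- vapply(c(1, 4, 12), function(k) {
    lam <- sort(Mod(eigen(ser$matrices[[k]], only.values = TRUE)$values),
                decreasing = TRUE)[2]
    -k / log(lam)
  }, 1.0)
  expect_gt(t_at[2], t_at[1])
  expect_lt(abs(t_at[3] - t_at[2]) / t_at[2], 0.35)
})

test_that("CK test separates Markovian from lumped dynamics", {
  # factor 1 is definitionally exact
  sim_m <- gen_fine_chain(fine_chain_spec(memory_chain_M(), 1:9), 10, 3000,
                          seed = 41)
  ck1 <- ck_test(sim_m$observed, lag_base = 2, factors = 1)
  expect_equal(ck1$rmse$rmse, 0, tolerance = 1e-14)

  # Markov (identity projection) data: CK residuals at the noise floor;
  # lumped data at the same lag: clearly above it
  ck_markov <- ck_test(sim_m$observed, lag_base = 1, factors = c(2, 4))
  sim_l <- gen_fine_chain(memory_chain_spec(), 10, 3000, seed = 41)
  ck_lump <- ck_test(sim_l$observed, lag_base = 1, factors = c(2, 4))
  expect_gt(min(ck_lump$rmse$rmse), 5 * max(ck_markov$rmse$rmse))
  expect_gt(min(ck_lump$rmse$rmse), 0.01)

  # metastable-set lumping: self-transition curves in [0, 1]
  ck_sets <- ck_test(sim_m$observed, 1, c(2, 3),
                     sets = list(1:3, 4:6, 7:9))
  expect_true(all(ck_sets$self_transitions$predicted >= 0 &
                    ck_sets$self_transitions$predicted <= 1))
  expect_equal(nrow(ck_sets$self_transitions), 2 * 3)
})

test_that("GMRQ cross-validation scores match closed-form eigenvalues", {
  T0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  spec <- fine_chain_spec(T0, 1:2)
  sim <- gen_fine_chain(spec, 8, 3000, seed = 51)
  projections <- withr::with_seed(52, lapply(sim$observed$trajectories,
    function(x) matrix(x + rnorm(length(x), sd = 0.05), ncol = 1)))
  grid <- data.frame(n_clusters = 2, lag = 1)
  cv <- gmrq_cv(projections, grid, n_folds = 4, seed = 7)
  expect_equal(cv$table$mean_score, 1 + 0.9, tolerance = 0.03)
  expect_equal(cv$table$mean_score, cv$table$mean_train_score,
               tolerance = 0.03)

  # permuting grid rows permutes the table identically
  grid2 <- data.frame(n_clusters = c(2, 3), lag = c(1, 1))
  cva <- gmrq_cv(projections, grid2, n_folds = 4, seed = 7)
  cvb <- gmrq_cv(projections, grid2[2:1, ], n_folds = 4, seed = 7)
  expect_equal(cva$table$mean_score, rev(cvb$table$mean_score),
               tolerance = 1e-12)
})

test_that("overclustering shows the variational overfitting direction", {
  # short trajectories, k far above the needed 2: test score falls at or
  # below train score in the large majority of replicates (scaled to 25
  # replicates for runtime; direction per the variational principle)
  T0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  spec <- fine_chain_spec(T0, 1:2)
  hits <- 0
  for (r in 1:25) {
    sim <- gen_fine_chain(spec, 6, 120, seed = 600 + r)
    projections <- withr::with_seed(700 + r,
      lapply(sim$observed$trajectories,
             function(x) matrix(x + rnorm(length(x), sd = 0.05), ncol = 1)))
    cv <- suppressWarnings(gmrq_cv(projections,
                                   data.frame(n_clusters = 10, lag = 1),
                                   n_folds = 3, seed = r))
    if (is.finite(cv$table$mean_score) &&
        cv$table$mean_score <= cv$table$mean_train_score + 1e-9)
      hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * 25))
})
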