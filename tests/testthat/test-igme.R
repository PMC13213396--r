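# PCCA+ lumping and IGME fitting.

mat_pow_pub <- function(M, k) metaPPI:::mat_pow(M, k)

test_that("PCCA+ resolves decoupled and nearly decoupled blocks", {
  # exactly block-diagonal 4-state matrix, 2 blocks: memberships are 0/1
  Tb <- matrix(0, 4, 4)
  Tb[1:2, 1:2] <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  Tb[3:4, 3:4] <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  lump <- pcca_lump(Tb, 2)
  expect_true(all(abs(lump$memberships - round(lump$memberships)) < 1e-8))
  expect_equal(adjusted_rand_index(lump$assignment, c(1, 1, 2, 2)), 1.0)

  # nearly block 30-state chain with 100:1 separation
  pb <- planted_block_tpm(30, 3, intra = 0.1, sep = 100)
  lump3 <- pcca_lump(pb$matrix, 3)
  expect_equal(adjusted_rand_index(lump3$assignment, pb$labels), 1.0)

  # n_macro = n_micro: identity lumping (a permutation matrix)
  Ts <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  li <- pcca_lump(Ts, 2)
  expect_equal(sort(li$assignment), 1:2)
  expect_true(all(abs(li$memberships - round(li$memberships)) < 1e-8))
})

test_that("macro TPM series agrees with Markov propagation and the oracle", {
  # Markov macro data: T(k*tau) ~ T(tau)^k within sampling error
  T0 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  sim <- gen_fine_chain(fine_chain_spec(T0, 1:2), 20, 3000, seed = 61)
  ser <- macro_tpm_series(sim$observed, tau = 2, K = 4)
  T1 <- ser$matrices[[1]]
  for (k in 2:4) {
    nmin <- min(rowSums(ser$counts[[k]]))
    tol <- 3 * sqrt(0.25 / nmin) * 2
    expect_lt(max(abs(mat_pow_pub(T1, k) - ser$matrices[[k]])), tol)
  }

  # K = 1 equals estimate_tpm (untrimmed) on the same data
  ser1 <- macro_tpm_series(sim$observed, tau = 3, K = 1)
  et <- estimate_tpm(sim$observed, 3, connectivity = "none")
  expect_equal(ser1$matrices[[1]], et$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)

  # lumped fixture matches the exact projected propagators
  siml <- gen_fine_chain(memory_chain_spec(), 30, 3000, seed = 62)
  serl <- macro_tpm_series(siml$observed, tau = 1, K = 6)
  ex <- exact_projected_tpms(memory_chain_spec(), 6)
  for (k in c(1, 3, 6)) {
    nmin <- min(rowSums(serl$counts[[k]]))
    expect_lt(max(abs(serl$matrices[[k]] - ex$matrices[[k]])),
              3 * sqrt(0.25 / nmin) * 2)
  }
})

test_that("IGME least squares is exact in the memoryless limit", {
  T0 <- matrix(c(0.9, 0.05, 0.05, 0.1, 0.8, 0.1, 0.15, 0.05, 0.8),
               3, 3, byrow = TRUE)
  mats <- lapply(1:8, function(k) mat_pow_pub(T0, k))
  ser <- tpm_series(mats, tau = 1)
  m <- igme_lsf(ser, n0 = 1, L = 6)
  expect_lt(max(abs(m$A - diag(3))), 1e-6)
  expect_lt(max(abs(m$T_hat - T0)), 1e-6)
  expect_lt(m$rmse, 1e-10)
})

test_that("IGME recovers a planted operator pair and extrapolates", {
  withr::with_seed(71, {
    n <- 4
    Th <- matrix(rgamma(n * n, 1), n, n) + 5 * diag(n)
    Th <- Th / rowSums(Th)
    Arand <- matrix(rgamma(n * n, 1), n, n)
    A <- 0.85 * diag(n) + 0.15 * Arand / rowSums(Arand)
  })
  mats <- lapply(1:12, function(k) A %*% mat_pow_pub(Th, k))
  ser <- tpm_series(mats, tau = 1)
  m <- igme_lsf(ser, n0 = 2, L = 5)
  expect_lt(m$rmse, 1e-8)
  for (k in 1:12)  # in and beyond the window
    expect_lt(max(abs(m$A %*% mat_pow_pub(m$T_hat, k) - mats[[k]])), 1e-6)
  # window preconditions
  expect_error(igme_lsf(ser, n0 = 0, L = 3), "n0")
  expect_error(igme_lsf(ser, n0 = 1, L = 1), "L")
  expect_error(igme_lsf(ser, n0 = 10, L = 5), "window")
})

test_that("IGME stationary distribution matches the projected fine chain", {
  ser <- exact_projected_tpms(memory_chain_spec(), 16)
  m <- suppressWarnings(igme_lsf(ser, n0 = 5, L = 10))
  expect_lt(max(abs(m$stationary - memory_chain_pi()) / memory_chain_pi()),
            0.01)
})

test_that("hyperparameter scan ranks, retains and summarizes correctly", {
  # grid of 1: ensemble of 1, sd 0
  T0 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  ser <- tpm_series(lapply(1:10, function(k) mat_pow_pub(T0, k)), tau = 1)
  sc1 <- igme_scan(ser, data.frame(n0 = 1, L = 4), top_fraction = 0.5)
  expect_length(sc1$kept, 1)
  expect_equal(sc1$summary$population_sd, c(0, 0))

  # exact Markov series: every grid point near-zero rmse; mean populations
  # equal the eigenvector stationary distribution
  grid <- expand.grid(n0 = 1:4, L = c(3, 5))
  sc <- igme_scan(ser, grid, top_fraction = 0.25)
  expect_lt(max(sc$rmse), 1e-10)
  pi_exact <- metaPPI:::stationary_distribution(T0)
  expect_lt(max(abs(sc$summary$population_mean - pi_exact)), 1e-8)

  # summary invariant to grid enumeration order
  sc_perm <- igme_scan(ser, grid[sample(nrow(grid)), ], top_fraction = 0.25)
  expect_equal(sc$summary$population_mean, sc_perm$summary$population_mean,
               tolerance = 1e-12)
  expect_equal(sort(sc$summary$rmse_kept), sort(sc_perm$summary$rmse_kept))
})

test_that("model kinetics reproduce closed-form MFPT and stationary values", {
  Th <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  ser <- tpm_series(lapply(1:6, function(k) mat_pow_pub(Th, k)), tau = 1)
  m <- igme_lsf(ser, 1, 4)
  kin <- model_kinetics(m)
  expect_equal(m$stationary, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(kin$mfpt[1, 2], 10, tolerance = 1e-8)  # 1/p12 steps * tau
  expect_equal(kin$mfpt[2, 1], 5, tolerance = 1e-8)
  expect_equal(diag(kin$mfpt), c(0, 0))

  # symmetric propagator: uniform stationary distribution
  Ts <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  ms <- igme_lsf(tpm_series(lapply(1:6, function(k) mat_pow_pub(Ts, k)),
                            tau = 1), 1, 4)
  expect_equal(ms$stationary, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("IGME CK beats the MSM baseline on memory-bearing series", {
  ser <- exact_projected_tpms(memory_chain_spec(), 16)
  m <- suppressWarnings(igme_lsf(ser, n0 = 3, L = 10))
  ck <- igme_ck(m, ser)
  sub <- ck$rmse[ck$rmse$n >= 2, ]
  expect_true(all(sub$rmse_igme < sub$rmse_msm))
  # on Markov series the two coincide at machine precision
  T0 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  serm <- tpm_series(lapply(1:8, function(k) mat_pow_pub(T0, k)), tau = 1)
  ckm <- igme_ck(igme_lsf(serm, 1, 5), serm)
  expect_lt(max(abs(ckm$rmse$rmse_igme - ckm$rmse$rmse_msm)), 1e-9)
})
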