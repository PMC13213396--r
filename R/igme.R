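# Metastable lumping (PCCA+) and integrative generalized master equation
# (IGME) fitting.
#
# The IGME models the long-time propagator of a lumped (macro) process as
#   T(n*tau) ~ A %*% That^n
# where That is the asymptotic per-lag propagator and A absorbs the
# time-integrated memory of the discarded fast degrees of freedom. Fitting
# is least squares over a window of lag multiples n = n0..n0+L-1. The
# product form gives a closed-form two-stage solution:
#   (1) That minimizes sum_n || T(n) That - T(n+1) ||_F^2 over consecutive
#       window pairs (exact when the series truly follows A That^n), then
#   (2) A minimizes sum_n || A That^n - T(n) ||_F^2, linear in A.
# An optional quasi-Newton refinement polishes both matrices against the
# full objective. RMSE is the root mean square residual over all matrix
# entries and all window lags, in probability units.

#' Lag-indexed transition-probability-matrix series
#'
#' @param matrices list of n x n row-stochastic matrices `T(k*tau)`,
#'   `k = 1..K`
#' @param tau base lag in frames
#' @param n state count (defaults to the matrix dimension)
#' @param counts optional list of count matrices per lag
#' @return an object of class `TPMSeries`
#' @export
tpm_series <- function(matrices, tau, n = NULL, counts = NULL) {
  if (!length(matrices)) stop("`matrices` must be non-empty")
  if (is.null(n)) n <- nrow(matrices[[1]])
  for (k in seq_along(matrices)) {
    if (!all(dim(matrices[[k]]) == c(n, n)))
      stop("inconsistent matrix dimension at lag multiple ", k)
    assert_row_stochastic(matrices[[k]], tol = 1e-10,
                          name = sprintf("T(%d*tau)", k))
  }
  structure(list(matrices = matrices, tau = tau, K = length(matrices),
                 n = n, counts = counts),
            class = "TPMSeries")
}

#' PCCA+ metastable lumping
#'
#' Robust Perron Cluster Analysis on the dominant right eigenvectors of a
#' microstate transition matrix: an inner-simplex vertex search picks
#' `n_macro` microstates spanning the eigenvector simplex, and every
#' microstate's fuzzy membership is its barycentric coordinate in that
#' simplex (clipped to [0, 1] and row-renormalized). Hard labels are the
#' argmax memberships.
#'
#' @param tpm a `TPM` from [estimate_tpm()] (irreducible), or a plain
#'   row-stochastic matrix; a reversible estimator is recommended to keep
#'   the dominant spectrum real
#' @param n_macro number of metastable states (2..n_micro)
#' @param complex_tol largest tolerated imaginary part in the dominant
#'   eigenvectors
#' @return an object of class `Lumping`: `memberships` (n_micro x n_macro,
#'   rows sum to 1), `assignment` (hard labels), `n_micro`, `n_macro`
#' @export
pcca_lump <- function(tpm, n_macro, complex_tol = 1e-6) {
  if (is.matrix(tpm)) {
    assert_row_stochastic(tpm, tol = 1e-10, name = "tpm")
    tpm <- structure(list(matrix = tpm), class = "TPM")
  }
  stopifnot(inherits(tpm, "TPM"))
  n <- nrow(tpm$matrix)
  if (n_macro < 2 || n_macro > n) stop("`n_macro` must be in 2..n_micro")
  e <- sorted_eigen(tpm$matrix)
  X <- e$vectors[, seq_len(n_macro), drop = FALSE]
  if (max(abs(Im(X))) > complex_tol)
    stop("dominant eigenvectors are complex; use a reversible estimator ",
         "or a smaller `n_macro`")
  X <- Re(X)
  X[, 1] <- 1  # Perron eigenvector normalized to the constant
  # inner-simplex vertex search (Deuflhard-Weber)
  verts <- integer(n_macro)
  verts[1] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2, X[verts[1], ])
  for (j in 2:n_macro) {
    Yp <- Y
    if (j > 2) {
      # project out the span of previously chosen vertex directions
      B <- Y[verts[2:(j - 1)], , drop = FALSE]
      qrB <- qr(t(B))
      Qb <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
      Yp <- Y - (Y %*% Qb) %*% t(Qb)
    }
    verts[j] <- which.max(rowSums(Yp^2))
  }
  A <- solve(X[verts, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  assign <- max.col(chi, ties.method = "first")
  if (length(unique(assign)) < n_macro)
    stop("a macro state is empty under hard assignment; reduce `n_macro`")
  structure(list(memberships = chi, assignment = assign,
                 n_micro = n, n_macro = n_macro, vertices = verts),
            class = "Lumping")
}

#' Identity or near-identity lumping helper
#' @noRd
apply_lumping <- function(dtrajs, lumping) {
  map <- lumping$assignment
  discrete_trajectory_set(lapply(dtrajs$trajectories, function(x) map[x]),
                          n_states = lumping$n_macro,
                          frame_interval = dtrajs$frame_interval)
}

#' Estimate a macro-state TPM series over lag multiples
#'
#' Estimates `T(k*tau)` independently at each `k = 1..K` by sliding-window
#' counting on macro-state trajectories. Each lag uses all states (no
#' trimming) so the series shares one dimension; a lag whose counts contain
#' an empty row is an error.
#'
#' @param dtrajs_macro a [discrete_trajectory_set()] at macro resolution
#' @param tau base lag in frames
#' @param K number of lag multiples
#' @return a [tpm_series()]
#' @export
macro_tpm_series <- function(dtrajs_macro, tau, K) {
  stopifnot(inherits(dtrajs_macro, "DiscreteTrajectorySet"))
  minlen <- min(vapply(dtrajs_macro$trajectories, length, 1L))
  if (K * tau >= minlen)
    stop("`K * tau` must be shorter than the shortest trajectory")
  n <- dtrajs_macro$n_states
  mats <- vector("list", K)
  cnts <- vector("list", K)
  for (k in seq_len(K)) {
    lg <- k * tau
    counts <- matrix(0, n, n)
    for (x in dtrajs_macro$trajectories) {
      Tn <- length(x)
      s <- seq_len(Tn - lg)
      tab <- table(factor(x[s], levels = 1:n), factor(x[s + lg], levels = 1:n))
      counts <- counts + as.matrix(tab)
    }
    if (any(rowSums(counts) == 0))
      stop("empty counts at lag multiple k = ", k)
    mats[[k]] <- counts / rowSums(counts)
    cnts[[k]] <- counts
  }
  tpm_series(mats, tau = tau, n = n, counts = cnts)
}

#' Fit an IGME model by least squares over a lag window
#'
#' @param series a [tpm_series()]
#' @param n0 first lag multiple of the fit window (>= 1); plays the role of
#'   the trial memory-relaxation time in units of tau
#' @param L window length in lag multiples (>= 2); window is
#'   `n0 .. n0+L-1` and must fit within the series
#' @param refine if `TRUE`, polish the closed-form solution with BFGS on
#'   the full least-squares objective
#' @param stochastic_tol tolerance for the soft row-sum check on the
#'   predicted propagators
#' @return an object of class `IGMEModel`: `A`, `T_hat`, `fit_window`,
#'   `rmse`, `stationary`, `timescales`, `provenance`
#' @export
igme_lsf <- function(series, n0, L, refine = FALSE, stochastic_tol = 1e-6) {
  stopifnot(inherits(series, "TPMSeries"))
  if (n0 < 1) stop("`n0` must be >= 1")
  if (L < 2) stop("`L` must be >= 2")
  if (n0 + L - 1 > series$K) stop("fit window exceeds the series length")
  ns <- n0:(n0 + L - 1)
  Tm <- series$matrices[ns]
  n <- series$n
  # stage 1: That from consecutive-pair propagation
  G <- matrix(0, n, n); H <- matrix(0, n, n)
  for (i in seq_len(L - 1)) {
    G <- G + crossprod(Tm[[i]])
    H <- H + crossprod(Tm[[i]], Tm[[i + 1]])
  }
  That <- tryCatch(solve(G, H), error = function(e) pinv(G) %*% H)
  # stage 2: A from the window, linear least squares
  fitA <- function(That) {
    Pn <- mat_pow(That, ns[1])
    Ms <- matrix(0, n, n); B <- matrix(0, n, n)
    for (i in seq_along(ns)) {
      Ms <- Ms + tcrossprod(Pn)
      B <- B + Tm[[i]] %*% t(Pn)
      Pn <- Pn %*% That
    }
    tryCatch(t(solve(t(Ms), t(B))), error = function(e) B %*% pinv(Ms))
  }
  A <- fitA(That)
  obj <- function(par) {
    Ai <- matrix(par[1:(n * n)], n, n)
    Ti <- matrix(par[-(1:(n * n))], n, n)
    Pn <- mat_pow(Ti, ns[1])
    s <- 0
    for (i in seq_along(ns)) {
      s <- s + sum((Ai %*% Pn - Tm[[i]])^2)
      Pn <- Pn %*% Ti
    }
    s
  }
  path <- "closed-form"
  if (refine) {
    opt <- stats::optim(c(as.vector(A), as.vector(That)), obj,
                        method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-14))
    if (opt$value < obj(c(as.vector(A), as.vector(That)))) {
      A <- matrix(opt$par[1:(n * n)], n, n)
      That <- matrix(opt$par[-(1:(n * n))], n, n)
      path <- "closed-form+bfgs"
    }
  }
  rmse <- sqrt(obj(c(as.vector(A), as.vector(That))) / (L * n * n))
  # soft stochasticity check on predictions across the window
  Pn <- mat_pow(That, ns[1])
  worst <- 0
  for (i in seq_along(ns)) {
    worst <- max(worst, max(abs(rowSums(A %*% Pn) - 1)))
    Pn <- Pn %*% That
  }
  if (worst > stochastic_tol)
    warning(sprintf("predicted propagators deviate from row-stochasticity by %.3g",
                    worst))
  ev <- sorted_eigen(That, warn_complex_tol = Inf)
  lam <- ev$values
  pi_hat <- {
    eL <- eigen(t(That))
    i <- which.min(abs(eL$values - 1))
    v <- abs(Re(eL$vectors[, i]))
    v / sum(v)
  }
  lam_sub <- Mod(lam[-1])
  ts <- ifelse(lam_sub > 0 & lam_sub < 1,
               -series$tau / log(lam_sub), NA_real_)
  structure(list(A = A, T_hat = That,
                 fit_window = c(n0 = n0, L = L),
                 rmse = rmse, stationary = pi_hat, timescales = ts,
                 tau = series$tau, row_sum_dev = worst,
                 provenance = list(path = path, n0 = n0, L = L,
                                   K = series$K, tau = series$tau)),
            class = "IGMEModel")
}

#' @export
print.IGMEModel <- function(x, ...) {
  cat(sprintf("IGMEModel: %d states, window n0=%d L=%d, rmse=%.3g\n",
              nrow(x$A), x$fit_window["n0"], x$fit_window["L"], x$rmse))
  cat("stationary:", paste(sprintf("%.4f", x$stationary), collapse = " "), "\n")
  invisible(x)
}

#' Scan IGME hyperparameters and retain the best-fitting fraction
#'
#' Fits an IGME model at every `(n0, L)` grid point, ranks models by
#' ascending RMSE (ties: smaller `n0`, then smaller `L`), and retains
#' `ceiling(top_fraction * n_models)`. Ensemble summaries (mean and sd of
#' stationary populations, timescales, and mean first passage times) are
#' computed over the retained set only.
#'
#' @param series a [tpm_series()]
#' @param grid data frame with columns `n0` and `L`; every row must satisfy
#'   the [igme_lsf()] preconditions
#' @param top_fraction fraction of models to keep (default 0.05)
#' @param ... passed to [igme_lsf()]
#' @return an object of class `IGMEEnsemble`: `models` (all fits), `kept`
#'   (indices into `models`, best first), `summary` (list of mean/sd
#'   matrices and vectors)
#' @export
igme_scan <- function(series, grid, top_fraction = 0.05, ...) {
  if (nrow(grid) == 0) stop("`grid` must be non-empty")
  fits <- vector("list", nrow(grid))
  errs <- character(0)
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(igme_lsf(series, grid$n0[i], grid$L[i], ...),
                          error = function(e) conditionMessage(e))
  }
  ok <- vapply(fits, inherits, TRUE, what = "IGMEModel")
  if (!any(ok))
    stop("all IGME fits failed: ",
         paste(unique(unlist(fits[!ok])), collapse = "; "))
  models <- fits[ok]
  g <- grid[ok, , drop = FALSE]
  rmses <- vapply(models, function(m) m$rmse, 1.0)
  ord <- order(rmses, g$n0, g$L)
  n_keep <- ceiling(top_fraction * length(models))
  kept <- ord[seq_len(n_keep)]
  pis <- t(vapply(models[kept], function(m) m$stationary,
                  numeric(series$n)))
  tss <- t(vapply(models[kept], function(m) m$timescales,
                  numeric(series$n - 1)))
  mfpts <- lapply(models[kept], function(m) model_kinetics(m)$mfpt)
  mfpt_arr <- simplify2array(mfpts)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  summ <- list(
    population_mean = colMeans(pis),
    population_sd = apply(pis, 2, sd0),
    timescale_mean = colMeans(tss),
    timescale_sd = apply(tss, 2, sd0),
    mfpt_mean = apply(mfpt_arr, c(1, 2), mean),
    mfpt_sd = apply(mfpt_arr, c(1, 2), sd0),
    rmse_kept = rmses[kept]
  )
  structure(list(models = models, grid = g, rmse = rmses, kept = kept,
                 top_fraction = top_fraction, summary = summ),
            class = "IGMEEnsemble")
}

#' Thermodynamics and kinetics of an IGME model
#'
#' Relaxation timescales come from the eigenvalues of `T_hat`
#' (`t_i = -tau / log |lambda_i|`); mean first passage times solve the
#' standard linear system on the embedded chain with time step `tau`
#' (diagonal = 0). Eigenvalues above 1 are clipped for the timescale report
#' only, with a warning.
#'
#' @param model an `IGMEModel`
#' @return list with `stationary`, `timescales`, `mfpt` (n x n matrix,
#'   `mfpt[i, j]` = mean time from i to j)
#' @export
model_kinetics <- function(model) {
  stopifnot(inherits(model, "IGMEModel"))
  Tm <- model$T_hat
  n <- nrow(Tm)
  tau <- model$tau
  ev <- eigen(Tm, only.values = TRUE)$values
  if (max(Mod(ev)) > 1 + 1e-6)
    warning("spectral radius of T_hat exceeds 1; clipping for timescales")
  lam <- sort(pmin(Mod(ev), 1), decreasing = TRUE)[-1]
  ts <- ifelse(lam > 0 & lam < 1, -tau / log(lam), NA_real_)
  mfpt <- matrix(0, n, n)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    Ak <- diag(length(keep)) - Tm[keep, keep, drop = FALSE]
    m <- solve(Ak, rep(tau, length(keep)))
    mfpt[keep, j] <- m
  }
  list(stationary = model$stationary, timescales = ts, mfpt = mfpt)
}

#' Chapman-Kolmogorov check of an IGME model against estimated propagators
#'
#' Compares the IGME prediction `A %*% T_hat^n` and the MSM baseline
#' `T(tau)^n` against the independently estimated `T(n*tau)` for every lag
#' multiple in the series, reporting per-state self-transition curves and
#' per-multiple RMSEs for both models.
#'
#' @param model an `IGMEModel`
#' @param series a [tpm_series()], typically extending beyond the fit window
#' @return an object of class `IGMECKResult`: data frames `rmse`
#'   (`n`, `rmse_igme`, `rmse_msm`, `in_window`) and `self_transitions`
#' @export
igme_ck <- function(model, series) {
  stopifnot(inherits(model, "IGMEModel"), inherits(series, "TPMSeries"))
  n0 <- model$fit_window["n0"]; L <- model$fit_window["L"]
  T1 <- series$matrices[[1]]
  rows <- list(); selfs <- list()
  Pn <- mat_pow(model$T_hat, 1)
  Qn <- T1
  for (k in seq_len(series$K)) {
    pred_igme <- model$A %*% Pn
    pred_msm <- Qn
    est <- series$matrices[[k]]
    rows[[k]] <- data.frame(
      n = k,
      rmse_igme = sqrt(mean((pred_igme - est)^2)),
      rmse_msm = sqrt(mean((pred_msm - est)^2)),
      in_window = k >= n0 && k <= n0 + L - 1)
    selfs[[k]] <- data.frame(n = k, state = seq_len(series$n),
                             igme = diag(pred_igme), msm = diag(pred_msm),
                             estimated = diag(est))
    Pn <- Pn %*% model$T_hat
    Qn <- Qn %*% T1
  }
  structure(list(rmse = do.call(rbind, rows),
                 self_transitions = do.call(rbind, selfs)),
            class = "IGMECKResult")
}
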