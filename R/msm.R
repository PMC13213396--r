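# Microstate MSM construction and validation: k-means clustering, transition
# matrix estimation with ergodic trimming, implied timescales,
# Chapman-Kolmogorov testing and GMRQ cross-validation.

#' Seeded k-means clustering with canonical center ordering
#'
#' Lloyd iterations from k-means++ initialization. Centers are returned in
#' canonical order (sorted by first coordinate, then subsequent coordinates
#' on ties) and assignments relabeled accordingly, so results are
#' reproducible across runs with the same seed. Empty clusters are re-seeded
#' from the farthest point, with a warning.
#'
#' @param projection frames x d numeric matrix, or a list of matrices (one
#'   per trajectory)
#' @param n_clusters number of microstates (<= total frames)
#' @param seed integer seed for the k-means++ initialization
#' @param max_iter Lloyd iteration cap
#' @return list with `dtrajs` (a [discrete_trajectory_set()]) and `centers`
#'   (n_clusters x d matrix)
#' @export
kmeans_cluster <- function(projection, n_clusters, seed, max_iter = 200L) {
  traj_list <- if (is.list(projection)) projection else list(projection)
  traj_list <- lapply(traj_list, function(x) {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  })
  X <- do.call(rbind, traj_list)
  nf <- nrow(X)
  if (n_clusters > nf) stop("`n_clusters` must be <= the number of frames")
  centers <- with_seed(seed, kmeanspp_init(X, n_clusters))
  d2mat <- function(C) {
    outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * tcrossprod(X, C)
  }
  assign <- max.col(-d2mat(centers), ties.method = "first")
  warned_empty <- FALSE
  for (it in seq_len(max_iter)) {
    newc <- centers
    for (k in seq_len(n_clusters)) {
      members <- which(assign == k)
      if (length(members) == 0L) {
        if (!warned_empty) {
          warning("empty cluster re-seeded from the farthest point")
          warned_empty <- TRUE
        }
        d2 <- d2mat(centers)
        far <- which.max(apply(d2, 1, min))
        newc[k, ] <- X[far, ]
      } else {
        newc[k, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    newa <- max.col(-d2mat(newc), ties.method = "first")
    conv <- all(newa == assign) && max(abs(newc - centers)) < 1e-12
    centers <- newc
    assign <- newa
    if (conv) break
  }
  ord <- do.call(order, as.data.frame(centers))
  relabel <- integer(n_clusters)
  relabel[ord] <- seq_len(n_clusters)
  centers <- centers[ord, , drop = FALSE]
  assign <- relabel[assign]
  lens <- vapply(traj_list, nrow, 1L)
  splits <- split(assign, rep(seq_along(traj_list), lens))
  dtrajs <- discrete_trajectory_set(unname(splits), n_states = n_clusters)
  list(dtrajs = dtrajs, centers = centers)
}

#' @noRd
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2 / sum(d2))
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Estimate a transition probability matrix at a fixed lag
#'
#' Counts transitions by a sliding (default) or strided window, trims to the
#' largest strongly connected component (ergodic trimming) and
#' row-normalizes. The default estimator is non-reversible; detailed-balance
#' estimators are available via `estimator`.
#'
#' @param dtrajs a [discrete_trajectory_set()]
#' @param lag lag in frames (< the shortest trajectory)
#' @param mode counting mode: `"sliding"` uses every start frame,
#'   `"strided"` uses start frames `1, 1+lag, ...`
#' @param estimator `"nonreversible"` (row-normalized counts),
#'   `"reversible-sym"` (symmetrized counts, exact detailed balance) or
#'   `"reversible-mle"` (maximum-likelihood reversible, fixed-point
#'   iteration)
#' @param connectivity `"strong"` (default) trims to the largest strongly
#'   connected component; `"none"` keeps every state with outgoing counts
#' @return an object of class `TPM`: `matrix` (row-stochastic on the active
#'   set), `counts`, `lag`, `active_set` (original state indices retained),
#'   `stationary`
#' @export
estimate_tpm <- function(dtrajs, lag, mode = c("sliding", "strided"),
                         estimator = c("nonreversible", "reversible-sym",
                                       "reversible-mle"),
                         connectivity = c("strong", "none")) {
  stopifnot(inherits(dtrajs, "DiscreteTrajectorySet"))
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  connectivity <- match.arg(connectivity)
  minlen <- min(vapply(dtrajs$trajectories, length, 1L))
  if (lag >= minlen) stop("`lag` must be shorter than the shortest trajectory")
  n <- dtrajs$n_states
  counts <- matrix(0, n, n)
  for (x in dtrajs$trajectories) {
    Tn <- length(x)
    starts <- if (mode == "sliding") seq_len(Tn - lag)
              else seq(1L, Tn - lag, by = lag)
    tab <- table(factor(x[starts], levels = 1:n),
                 factor(x[starts + lag], levels = 1:n))
    counts <- counts + as.matrix(tab)
  }
  if (sum(counts) == 0) stop("empty count matrix")
  active <- if (connectivity == "strong") sort(largest_scc(counts))
            else which(rowSums(counts) > 0)
  C <- counts[active, active, drop = FALSE]
  Tm <- switch(estimator,
    "nonreversible" = C / rowSums(C),
    "reversible-sym" = {
      S <- (C + t(C)) / 2
      S / rowSums(S)
    },
    "reversible-mle" = reversible_mle(C)
  )
  structure(list(matrix = Tm, counts = counts, lag = lag,
                 active_set = active,
                 stationary = stationary_distribution(Tm),
                 estimator = estimator,
                 frame_interval = dtrajs$frame_interval),
            class = "TPM")
}

#' @noRd
reversible_mle <- function(C, max_iter = 1000L, tol = 1e-12) {
  ci <- rowSums(C)
  S <- C + t(C)
  x <- S / sum(S)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, `+`)
    xnew <- S / denom
    xnew <- xnew / sum(xnew)
    if (max(abs(xnew - x)) < tol) { x <- xnew; break }
    x <- xnew
  }
  x / rowSums(x)
}

#' Implied relaxation timescales across lag times
#'
#' For each lag, estimates a TPM and reports
#' `t_i = -lag * frame_interval / log(|lambda_i|)` for the non-stationary
#' eigenvalues sorted by modulus. Flat timescales in lag indicate Markovian
#' behavior at that resolution; growth before a plateau is the signature of
#' memory from state lumping.
#'
#' @param dtrajs a [discrete_trajectory_set()]
#' @param lags integer vector of lags
#' @param n_timescales how many timescales to report (default all available)
#' @param ... passed to [estimate_tpm()]
#' @return data frame with columns `lag`, `index`, `timescale`
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = NULL, ...) {
  out <- lapply(lags, function(lg) {
    tpm <- estimate_tpm(dtrajs, lg, ...)
    if (nrow(tpm$matrix) < 2)
      stop("fewer than 2 states after ergodic trimming at lag ", lg)
    ev <- sorted_eigen(tpm$matrix)$values
    lam <- Mod(ev[-1])
    m <- if (is.null(n_timescales)) length(lam) else min(n_timescales, length(lam))
    lam <- lam[seq_len(m)]
    ts <- ifelse(lam > 0 & lam < 1,
                 -lg * dtrajs$frame_interval / log(lam), NA_real_)
    data.frame(lag = lg, index = seq_len(m) + 1L, timescale = ts)
  })
  do.call(rbind, out)
}

#' Chapman-Kolmogorov test
#'
#' Compares the propagated model `T(lag_base)^k` against independently
#' estimated `T(k * lag_base)` for each factor `k`, optionally after lumping
#' states into metastable sets (stationary-weighted row aggregation).
#' Reports per-set self-transition probabilities and an aggregate RMSE per
#' factor over all compared entries.
#'
#' @param dtrajs a [discrete_trajectory_set()]
#' @param lag_base base lag in frames
#' @param factors integer multiples k to test
#' @param sets optional list of integer vectors partitioning the states into
#'   metastable groups
#' @param ... passed to [estimate_tpm()]
#' @return an object of class `CKResult`: data frame `self_transitions`
#'   (`factor`, `set`, `predicted`, `estimated`) and data frame `rmse`
#'   (`factor`, `rmse`, `ok`)
#' @export
ck_test <- function(dtrajs, lag_base, factors, sets = NULL, ...) {
  base <- estimate_tpm(dtrajs, lag_base, ...)
  act <- base$active_set
  lump <- function(Tm, pi0) {
    if (is.null(sets)) return(Tm)
    ns <- length(sets)
    out <- matrix(0, ns, ns)
    local <- lapply(sets, function(s) which(act %in% s))
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      ia <- local[[a]]; ib <- local[[b]]
      if (length(ia) == 0) { out[a, b] <- NA; next }
      w <- pi0[ia] / sum(pi0[ia])
      out[a, b] <- sum(w * rowSums(Tm[ia, ib, drop = FALSE]))
    }
    out
  }
  selfs <- list(); rmses <- list()
  for (k in factors) {
    pred_full <- mat_pow(base$matrix, k)
    est <- tryCatch(estimate_tpm(dtrajs, lag_base * k, ...),
                    error = function(e) NULL)
    if (is.null(est) || !identical(est$active_set, act)) {
      common_ok <- !is.null(est) && all(act %in% est$active_set) &&
        all(est$active_set %in% act)
      if (!common_ok) {
        rmses[[length(rmses) + 1L]] <-
          data.frame(factor = k, rmse = NA_real_, ok = FALSE)
        next
      }
    }
    est_full <- est$matrix
    pred <- lump(pred_full, base$stationary)
    estm <- lump(est_full, est$stationary)
    resid <- pred - estm
    rmses[[length(rmses) + 1L]] <-
      data.frame(factor = k, rmse = sqrt(mean(resid^2, na.rm = TRUE)), ok = TRUE)
    ns <- nrow(pred)
    selfs[[length(selfs) + 1L]] <-
      data.frame(factor = k, set = seq_len(ns),
                 predicted = diag(pred), estimated = diag(estm))
  }
  structure(list(lag_base = lag_base, factors = factors,
                 self_transitions = do.call(rbind, selfs),
                 rmse = do.call(rbind, rmses)),
            class = "CKResult")
}

#' GMRQ cross-validation over MSM hyperparameters
#'
#' Scores each hyperparameter setting (rows of `grid`, columns `n_clusters`,
#' `lag`, and optionally `m` eigenvalues to sum) by the generalized matrix
#' Rayleigh quotient on held-out trajectories: clustering and the MSM are
#' fitted on training trajectories, and the trace quotient of the train
#' eigenvectors under the test correlation matrices is the fold score. Folds
#' are whole trajectories, respecting temporal correlation.
#'
#' @param projections list of frames x d matrices, one per trajectory
#' @param grid data frame of settings: `n_clusters`, `lag`, optional `m`
#' @param n_folds number of folds (>= 2)
#' @param seed integer seed (fold shuffling and k-means)
#' @return list with `table` (grid plus `mean_score`, `sd_score`) and
#'   `best` (row index of the highest mean test score)
#' @export
gmrq_cv <- function(projections, grid, n_folds, seed) {
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  if (!is.list(projections) || length(projections) < n_folds)
    stop("need at least `n_folds` trajectories")
  nt <- length(projections)
  fold_of <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = nt)))
  scores <- matrix(NA_real_, nrow(grid), n_folds)
  train_scores <- matrix(NA_real_, nrow(grid), n_folds)
  for (gi in seq_len(nrow(grid))) {
    k <- grid$n_clusters[gi]
    lg <- grid$lag[gi]
    m <- if ("m" %in% names(grid)) grid$m[gi] else k
    for (f in seq_len(n_folds)) {
      train <- projections[fold_of != f]
      test <- projections[fold_of == f]
      setting_seed <- seed + 1000L * f +
        (as.integer(k) * 131L + as.integer(lg) * 17L + as.integer(m)) %% 997L
      sc <- tryCatch(
        gmrq_score_fold(train, test, k, lg, m, setting_seed),
        error = function(e) c(NA_real_, NA_real_))
      scores[gi, f] <- sc[1]
      train_scores[gi, f] <- sc[2]
    }
    if (all(is.na(scores[gi, ])))
      warning(sprintf("all folds failed for grid row %d", gi))
  }
  if (all(is.na(scores))) stop("all folds were skipped for every setting")
  tab <- cbind(grid,
               mean_score = rowMeans(scores, na.rm = TRUE),
               sd_score = apply(scores, 1, stats::sd, na.rm = TRUE),
               mean_train_score = rowMeans(train_scores, na.rm = TRUE))
  list(table = tab, best = which.max(tab$mean_score), fold_scores = scores,
       train_fold_scores = train_scores)
}

#' @noRd
gmrq_score_fold <- function(train, test, n_clusters, lag, m, seed) {
  km <- kmeans_cluster(train, n_clusters, seed = seed)
  tpm <- estimate_tpm(km$dtrajs, lag)
  act <- tpm$active_set
  e <- sorted_eigen(tpm$matrix)
  m <- min(m, ncol(e$vectors))
  Psi <- Re(e$vectors[, seq_len(m), drop = FALSE])
  # discretize test trajectories against the train centers
  centers <- km$centers
  C00 <- matrix(0, length(act), length(act))
  C0t <- matrix(0, length(act), length(act))
  relabel <- integer(n_clusters); relabel[act] <- seq_along(act)
  for (X in test) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) - 2 * tcrossprod(X, centers)
    a <- max.col(-d2, ties.method = "first")
    Tn <- length(a)
    if (Tn <= lag) next
    s <- a[1:(Tn - lag)]; t2 <- a[(1 + lag):Tn]
    keep <- s %in% act & t2 %in% act
    s <- relabel[s[keep]]; t2 <- relabel[t2[keep]]
    nact <- length(act)
    C00 <- C00 + diag(tabulate(s, nbins = nact), nact)
    C0t <- C0t + as.matrix(table(factor(s, levels = seq_len(nact)),
                                 factor(t2, levels = seq_len(nact))))
  }
  ntot <- sum(C00)
  if (ntot == 0) stop("no usable test pairs")
  C0t <- (C0t + t(C0t)) / 2
  S <- t(Psi) %*% (C00 / ntot) %*% Psi
  Q <- t(Psi) %*% (C0t / ntot) %*% Psi
  test_score <- sum(diag(pinv(S) %*% Q))
  # train score: GMRQ of the train model on its own data = sum of the
  # leading eigenvalue moduli of the train propagator
  train_score <- sum(Mod(e$values[seq_len(m)]))
  c(test_score, train_score)
}
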