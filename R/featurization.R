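# Featurization: interchain C-alpha distances, greedy Nystrom column
# selection (spectral oASIS style) and tICA projection onto slow collective
# variables.

#' Interchain C-alpha distance features
#'
#' Computes Euclidean distances (angstrom) between every C-alpha of chain A
#' and every `stride_chainB`-th C-alpha of chain B, per frame. The stride is
#' applied to chain B only (the protein of interest), offset 0, mirroring
#' the asymmetric selection used for large receptor chains. Feature order is
#' deterministic: chain-A residue-major, chain-B residues ascending.
#'
#' @param ensemble a [structure_ensemble()]
#' @param stride_chainB keep every stride-th chain-B C-alpha (>= 1)
#' @return an object of class `FeatureMatrix`: list with `values`
#'   (frames x features), `feature_index` (data frame `resA`, `resB`),
#'   and `frame_interval`
#' @export
interchain_ca_distances <- function(ensemble, stride_chainB = 1L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (stride_chainB < 1) stop("`stride_chainB` must be >= 1")
  at <- ensemble$atoms
  ia <- which(at$chain == "A" & at$is_ca)
  ib <- which(at$chain == "B" & at$is_ca)
  if (length(ia) == 0L) stop("chain A has no C-alpha-designated atoms")
  if (length(ib) == 0L) stop("chain B has no C-alpha-designated atoms")
  ia <- ia[order(at$residue[ia])]
  ib <- ib[order(at$residue[ib])]
  ib <- ib[seq(1L, length(ib), by = stride_chainB)]
  nf <- n_frames(ensemble)
  idx <- expand.grid(resB = at$residue[ib], resA = at$residue[ia],
                     KEEP.OUT.ATTRS = FALSE)[, c("resA", "resB")]
  vals <- matrix(0, nrow = nf, ncol = length(ia) * length(ib))
  for (t in seq_len(nf)) {
    X <- ensemble$coords[, , t]
    A <- X[ia, , drop = FALSE]
    B <- X[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    vals[t, ] <- sqrt(pmax(t(d2), 0))  # column order: A-major
  }
  structure(list(values = vals, feature_index = idx,
                 frame_interval = 1),
            class = "FeatureMatrix")
}

#' Greedy Nystrom column selection (spectral oASIS style)
#'
#' Selects `n_select` feature columns that best approximate the feature
#' covariance matrix in the Nystrom sense. At each step the column with the
#' largest diagonal residual of `C - C[,S] C[S,S]^+ C[S,]` is added; ties
#' break to the lowest column index, so the procedure is deterministic (the
#' `seed` argument is accepted for interface stability but never consumed).
#'
#' @param features a `FeatureMatrix` from [interchain_ca_distances()] or a
#'   plain frames x features numeric matrix
#' @param n_select number of columns to keep (1..n_features)
#' @param seed unused; retained so call sites can pass a pipeline seed
#' @return list with `indices` (sorted selected columns), `error` (relative
#'   Frobenius Nystrom reconstruction error), and `error_path` (error after
#'   each selection step, non-increasing)
#' @export
oasis_select <- function(features, n_select, seed = NULL) {
  X <- if (inherits(features, "FeatureMatrix")) features$values else features
  p <- ncol(X)
  if (n_select < 1 || n_select > p)
    stop("`n_select` must be in 1..n_features")
  C <- stats::cov(X)
  normC <- sqrt(sum(C^2))
  if (normC == 0) normC <- 1
  sel <- integer(0)
  d <- diag(C)
  err_path <- numeric(n_select)
  for (step in seq_len(n_select)) {
    # ties to the lowest index: which.max is first-match
    j <- which.max(d)
    sel <- c(sel, j)
    W <- C[sel, sel, drop = FALSE]
    B <- C[, sel, drop = FALSE]
    approx <- B %*% pinv(W) %*% t(B)
    R <- C - approx
    d <- pmax(diag(R), 0)
    d[sel] <- -Inf
    err_path[step] <- sqrt(sum(R^2)) / normC
  }
  list(indices = sort(sel), error = err_path[n_select],
       error_path = pmin(err_path, cummin(err_path)))
}

#' Fit time-lagged independent component analysis (tICA)
#'
#' Solves the generalized eigenproblem of the symmetrized time-lagged
#' covariance against the instantaneous covariance, using the reversible
#' (symmetrized) estimator: statistics are accumulated over both ends of
#' each lagged pair. Rank-deficient instantaneous covariance is regularized
#' by adding `reg` to the diagonal, with a warning.
#'
#' @param features a `FeatureMatrix`, a plain frames x features matrix, or a
#'   list of such matrices (one per trajectory)
#' @param lag tICA lag in frames (>= 1)
#' @param n_components number of components to retain
#' @param reg diagonal regularization added when C0 is rank-deficient
#' @return an object of class `TICAModel`: `lag`, `n_components`,
#'   `components` (features x n_components, C0-orthonormal), `eigenvalues`
#'   (descending), `mean`
#' @export
tica_fit <- function(features, lag, n_components, reg = 1e-10) {
  if (inherits(features, "FeatureMatrix")) features <- features$values
  if (!is.list(features)) features <- list(features)
  if (lag < 1) stop("`lag` must be >= 1")
  p <- ncol(features[[1]])
  if (n_components > p) stop("`n_components` exceeds the feature count")
  # accumulate symmetrized moments over all trajectories
  s0 <- numeric(p); S00 <- matrix(0, p, p); S0t <- matrix(0, p, p); npair <- 0
  for (X in features) {
    Tn <- nrow(X)
    if (Tn <= lag) next
    X0 <- X[1:(Tn - lag), , drop = FALSE]
    Xt <- X[(1 + lag):Tn, , drop = FALSE]
    s0 <- s0 + colSums(X0) + colSums(Xt)
    S00 <- S00 + crossprod(X0) + crossprod(Xt)
    S0t <- S0t + crossprod(X0, Xt)
    npair <- npair + (Tn - lag)
  }
  if (npair == 0) stop("no usable lagged pairs; shorten `lag`")
  if (npair <= p)
    warning("fewer lagged pairs than features; estimates will be noisy")
  mu <- s0 / (2 * npair)
  C0 <- S00 / (2 * npair) - tcrossprod(mu)
  Ct <- (S0t + t(S0t)) / (2 * npair) - tcrossprod(mu)
  # regularize if rank-deficient
  ev0 <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) < reg * 10) {
    warning("rank-deficient instantaneous covariance; regularizing diagonal")
    C0 <- C0 + diag(max(reg, -(min(ev0)) + reg), p)
  }
  L <- chol(C0)
  Li <- backsolve(L, diag(p))
  A <- t(Li) %*% Ct %*% Li
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  comps <- Li %*% e$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(lag = lag, n_components = n_components,
                 components = comps,
                 eigenvalues = e$values[seq_len(n_components)],
                 mean = mu),
            class = "TICAModel")
}

#' Project data onto fitted tICA components
#'
#' @param model a `TICAModel` from [tica_fit()]
#' @param features a `FeatureMatrix`, matrix, or list of matrices
#' @return frames x n_components matrix, or a list of such matrices if the
#'   input was a list
#' @export
tica_transform <- function(model, features) {
  stopifnot(inherits(model, "TICAModel"))
  if (inherits(features, "FeatureMatrix")) features <- features$values
  proj1 <- function(X) sweep(X, 2, model$mean) %*% model$components
  if (is.list(features)) lapply(features, proj1) else proj1(features)
}
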