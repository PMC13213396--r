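# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG seed, restoring caller state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Check a matrix is row-stochastic
#' @noRd
assert_row_stochastic <- function(M, tol = 1e-12, name = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  if (any(M < -tol))
    stop(sprintf("`%s` has negative entries", name), call. = FALSE)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > max(tol, 1e-12)))
    stop(sprintf("rows of `%s` must sum to 1 (max deviation %.3g)", name,
                 max(abs(rs - 1))), call. = FALSE)
  invisible(TRUE)
}

#' Stationary distribution (left Perron eigenvector) of a stochastic matrix
#' @noRd
stationary_distribution <- function(M) {
  e <- eigen(t(M))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Integer matrix power by repeated squaring
#' @noRd
mat_pow <- function(M, k) {
  stopifnot(k >= 0, k == round(k))
  n <- nrow(M)
  out <- diag(n)
  P <- M
  k <- as.integer(k)
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2L
  }
  out
}

#' Moore-Penrose pseudo-inverse via SVD
#' @noRd
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Eigen-decomposition sorted by modulus (descending), stable by real part
#' @noRd
sorted_eigen <- function(M, warn_complex_tol = 1e-8) {
  e <- eigen(M)
  ord <- order(-Mod(e$values), -Re(e$values))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (any(abs(Im(vals)) > warn_complex_tol))
    warning("complex eigenvalues present; reporting moduli", call. = FALSE)
  list(values = vals, vectors = vecs)
}

#' Largest strongly connected component of a transition graph
#'
#' Kosaraju's algorithm on the graph with an edge i -> j iff counts[i, j] > 0.
#' @noRd
largest_scc <- function(counts) {
  n <- nrow(counts)
  adj <- lapply(seq_len(n), function(i) which(counts[i, ] > 0))
  radj <- lapply(seq_len(n), function(j) which(counts[, j] > 0))
  # iterative DFS, finish order
  visited <- logical(n)
  order_out <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- list(list(v = s, i = 0L))
    visited[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nb <- adj[[top$v]]
      if (top$i < length(nb)) {
        stack[[length(stack)]]$i <- top$i + 1L
        w <- nb[top$i + 1L]
        if (!visited[w]) {
          visited[w] <- TRUE
          stack[[length(stack) + 1L]] <- list(v = w, i = 0L)
        }
      } else {
        order_out <- c(order_out, top$v)
        stack[[length(stack)]] <- NULL
      }
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in rev(order_out)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      for (w in radj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        stack <- c(stack, w)
      }
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

#' Kabsch optimal rotation superposing `mob` onto `ref` (n x 3 each)
#'
#' Returns the transform applied to the FULL coordinate set `full`
#' (defaults to `mob`): rotate about the matched centroids.
#' @noRd
kabsch_superpose <- function(mob, ref, full = mob) {
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  H <- crossprod(sweep(mob, 2, cm), sweep(ref, 2, cr))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(sweep(full, 2, cm) %*% t(R), 2, cr, `+`)
}

#' FNV-1a hash of a character string (for provenance manifests)
#' @noRd
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
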