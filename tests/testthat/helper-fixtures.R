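# Shared fixtures, all built in code.

#' 9-state hidden chain lumped 3->1 per block, with strong gateway-induced
#' memory but fast global mixing (lambda2 of the projected chain ~ 0.37).
#' Each block has one "gateway" state carrying almost all of the outflow to
#' the next block, so the lumped process is strongly non-Markovian at short
#' lags while the stationary distribution equilibrates quickly.
memory_chain_M <- function() {
  M <- matrix(0.01, 9, 9)
  wi <- list(
    matrix(c(0.25, 0.28, 0.28, 0.28, 0.25, 0.28, 0.22, 0.22, 0.25), 3, 3, byrow = TRUE),
    matrix(c(0.28, 0.25, 0.25, 0.24, 0.30, 0.25, 0.26, 0.20, 0.28), 3, 3, byrow = TRUE),
    matrix(c(0.30, 0.24, 0.24, 0.24, 0.28, 0.26, 0.20, 0.26, 0.28), 3, 3, byrow = TRUE))
  for (b in 0:2) M[b * 3 + 1:3, b * 3 + 1:3] <- wi[[b + 1]]
  M[3, 4] <- 0.85; M[3, 1] <- 0.03; M[3, 2] <- 0.03; M[3, 3] <- 0.03
  M[6, 7] <- 0.80; M[6, 4] <- 0.04; M[6, 5] <- 0.04; M[6, 6] <- 0.04
  M[9, 1] <- 0.85; M[9, 7] <- 0.03; M[9, 8] <- 0.03; M[9, 9] <- 0.03
  M[4, 3] <- 0.30; M[7, 6] <- 0.28; M[1, 9] <- 0.24
  M / rowSums(M)
}

memory_chain_spec <- function() {
  fine_chain_spec(memory_chain_M(), projection = rep(1:3, each = 3))
}

#' Exact projected stationary distribution of the memory chain
memory_chain_pi <- function() {
  piF <- metaPPI:::stationary_distribution(memory_chain_M())
  as.numeric(tapply(piF, rep(1:3, each = 3), sum))
}

#' Nearly block-diagonal n-state chain with `blocks` blocks and a
#' rate separation `sep` between intra- and inter-block moves.
planted_block_tpm <- function(n = 30, blocks = 3, intra = 0.1, sep = 100) {
  stopifnot(n %% blocks == 0)
  per <- n / blocks
  block_of <- rep(seq_len(blocks), each = per)
  M <- matrix(intra / sep, n, n)
  for (b in seq_len(blocks)) {
    idx <- which(block_of == b)
    M[idx, idx] <- intra
  }
  diag(M) <- 0
  diag(M) <- 1 - rowSums(M)
  list(matrix = M, labels = block_of)
}

#' Adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / choose2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

rot_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Planted two-chain world for the end-to-end test: 4 well-defined docked
#' geometries, one deliberately heterogeneous family (two fast-exchanging
#' anchor poses with large rigid pose noise: a loose, disordered encounter
#' state), and one low-burial grazing decoy.
planted_world_spec <- function() {
  spec0 <- toy_interface_spec(n_res_a = 20, n_res_b = 16, n_sites = 3)
  tmpl <- spec0$chain_templates
  bidx <- tmpl$chain == "B" & !tmpl$is_ligand
  cB <- unname(colMeans(as.matrix(tmpl[bidx, c("x", "y", "z")])))
  si <- which(tmpl$chain == "B" & tmpl$is_ligand)
  tmpl[si[1], c("x", "y", "z")] <- cB + c(7, 0, 5)
  tmpl[si[2], c("x", "y", "z")] <- cB + c(-7, 0, 5)
  tmpl[si[3], c("x", "y", "z")] <- cB + c(0, 7, -5)
  geoms <- list(
    list(R = diag(3), t = c(10, 0, 3)),      # G1 docked
    list(R = diag(3), t = c(0, 10, 3)),      # G2 docked
    list(R = diag(3), t = c(-10, 0, 3)),     # G3 docked
    list(R = rot_z(pi / 2), t = c(0, -10, 3)),  # G4 docked
    list(R = rot_z(pi / 4), t = c(9, 9, 12)),   # G5a heterogeneous
    list(R = rot_z(5 * pi / 4), t = c(-9, -9, -6)),  # G5b heterogeneous
    list(R = diag(3), t = c(16, 3, 3))       # G6 low-burial decoy
  )
  H <- matrix(0.012, 7, 7); diag(H) <- 0
  H[5, 6] <- 0.30; H[6, 5] <- 0.30
  diag(H) <- 1 - rowSums(H)
  interface_ensemble_spec(tmpl, geoms, H, jitter_sigma = 0.3,
                          pose_trans_sigma = c(0, 0, 0, 0, 7, 7, 0),
                          pose_rot_sigma = c(0, 0, 0, 0, 2.2, 2.2, 0))
}

#' Planted family of each raw geometry label (G5a/G5b merge into family 5)
planted_family <- function(labels) c(1, 2, 3, 4, 5, 5, 6)[labels]

#' Noise-free frame of one planted geometry
planted_frame <- function(spec, g) {
  tmpl <- spec$chain_templates
  X <- as.matrix(tmpl[, c("x", "y", "z")])
  isB <- tmpl$chain == "B"
  tr <- spec$pose_transforms[[g]]
  X[isB, ] <- sweep(X[isB, , drop = FALSE] %*% t(tr$R), 2, tr$t, `+`)
  X
}

#' A tiny two-chain ensemble from explicit coordinates (one frame per
#' element of `coord_list`); one C-alpha bead per residue.
bead_ensemble <- function(coord_list, chain, residue = NULL,
                          radius = 1.9, resclass = NULL) {
  if (!is.list(coord_list)) coord_list <- list(coord_list)
  n <- nrow(coord_list[[1]])
  if (is.null(residue)) {
    residue <- integer(n)
    for (ch in unique(chain)) residue[chain == ch] <- seq_len(sum(chain == ch))
  }
  if (is.null(resclass))
    resclass <- rep(c("charged", "polar", "hydrophobic"), length.out = n)
  atoms <- data.frame(chain = chain, residue = residue, atom = "CA",
                      resclass = resclass, element = "C",
                      radius = rep(radius, length.out = n),
                      is_ca = TRUE, is_ligand = FALSE, site = NA_character_,
                      stringsAsFactors = FALSE)
  coords <- array(0, c(n, 3, length(coord_list)))
  for (k in seq_along(coord_list)) coords[, , k] <- coord_list[[k]]
  structure_ensemble(coords, atoms)
}
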