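# Synthetic-data generators with known ground truth.
#
# Three generators cover the inputs of the analysis pipeline:
#   * a hidden fine-grained Markov chain projected onto fewer observed states,
#     the cleanest controllable source of non-Markovian memory;
#   * a toy two-chain complex hopping between planted interface geometries;
#   * binding-energy tables with known per-compound means.
# All generators are bit-reproducible under a fixed seed and leave the
# caller's RNG state untouched.

#' Specification of a hidden fine-grained Markov chain
#'
#' The observed process is the framewise projection of a Markov chain on
#' `n_fine` hidden states. When the projection lumps kinetically distinct
#' fine states, the observed dynamics carry memory and are non-Markovian --
#' the regime that motivates memory-corrected propagator fitting.
#'
#' @param M row-stochastic fine transition matrix (per step of `tau_frame`)
#' @param projection integer vector of length `nrow(M)` mapping each fine
#'   state to an observed state in `1..n_obs`; must be surjective
#' @param tau_frame frame interval in abstract time units
#' @return an object of class `FineChainSpec`
#' @export
fine_chain_spec <- function(M, projection, tau_frame = 1) {
  assert_row_stochastic(M, tol = 1e-12, name = "M")
  projection <- as.integer(projection)
  if (length(projection) != nrow(M))
    stop("`projection` must have one entry per fine state")
  n_obs <- max(projection)
  if (!setequal(unique(projection), seq_len(n_obs)))
    stop("`projection` must cover all observed indices 1..n_obs")
  structure(list(M = M, projection = projection,
                 n_fine = nrow(M), n_obs = n_obs, tau_frame = tau_frame),
            class = "FineChainSpec")
}

#' Simulate observed and hidden trajectories from a fine chain
#'
#' Hidden trajectories start from the exact stationary distribution of `M`
#' (no burn-in ambiguity) and evolve by `M`; observed trajectories apply the
#' projection framewise.
#'
#' @param spec a [fine_chain_spec()]
#' @param n_traj number of independent trajectories
#' @param n_frames frames per trajectory (>= 2)
#' @param seed integer seed; identical seed gives identical output
#' @return list with elements `observed` and `hidden`, both
#'   [discrete_trajectory_set()] objects
#' @export
gen_fine_chain <- function(spec, n_traj, n_frames, seed) {
  stopifnot(inherits(spec, "FineChainSpec"))
  if (n_frames < 2) stop("`n_frames` must be >= 2")
  if (n_traj < 1) stop("`n_traj` must be >= 1")
  M <- spec$M
  n <- spec$n_fine
  pi0 <- stationary_distribution(M)
  cumM <- t(apply(M, 1, cumsum))
  hidden <- with_seed(seed, {
    S <- matrix(0L, nrow = n_traj, ncol = n_frames)
    s <- 1L + rowSums(outer(runif(n_traj), cumsum(pi0), `>=`))
    S[, 1] <- s
    for (t in 2:n_frames) {
      u <- runif(n_traj)
      s <- 1L + as.integer(rowSums(cumM[s, , drop = FALSE] < u))
      s[s > n] <- n  # guard against cumsum rounding at the top edge
      S[, t] <- s
    }
    S
  })
  hid <- lapply(seq_len(n_traj), function(i) hidden[i, ])
  obs <- lapply(hid, function(x) spec$projection[x])
  list(
    observed = discrete_trajectory_set(obs, n_states = spec$n_obs,
                                       frame_interval = spec$tau_frame),
    hidden = discrete_trajectory_set(hid, n_states = n,
                                     frame_interval = spec$tau_frame)
  )
}

#' Exact lag-indexed propagators of the projected chain
#'
#' Analytic oracle for memory-corrected propagator fitting. The observed
#' transition probability at lag k steps is the stationary-weighted
#' projection of the k-step fine propagator:
#' \deqn{T_{obs}(k)[a,b] = \sum_{i \in a, j \in b} \pi_i (M^k)_{ij} /
#'       \sum_{i \in a} \pi_i}
#' When the projection is a bijection this equals `M^k`; when it lumps
#' kinetically distinct states, `T_obs(k)` differs measurably from
#' `T_obs(1)^k`.
#'
#' @param spec a [fine_chain_spec()]
#' @param max_lag_steps largest lag multiple K (>= 1)
#' @return an object of class `TPMSeries` with `tau = 1` (in frame steps)
#'   and matrices `T_obs(k)`, `k = 1..K`
#' @export
exact_projected_tpms <- function(spec, max_lag_steps) {
  stopifnot(inherits(spec, "FineChainSpec"))
  if (max_lag_steps < 1) stop("`max_lag_steps` must be >= 1")
  piF <- stationary_distribution(spec$M)
  P <- matrix(0, spec$n_fine, spec$n_obs)
  P[cbind(seq_len(spec$n_fine), spec$projection)] <- 1
  wA <- as.numeric(crossprod(P, piF))  # stationary weight per observed state
  mats <- vector("list", max_lag_steps)
  Mk <- diag(spec$n_fine)
  for (k in seq_len(max_lag_steps)) {
    Mk <- Mk %*% spec$M
    Tk <- crossprod(P, piF * Mk) %*% P / wA
    mats[[k]] <- Tk
  }
  tpm_series(mats, tau = 1L, n = spec$n_obs)
}

#' Specification of a toy two-chain interface ensemble
#'
#' Chain A stays fixed; chain B (with its bound ligand) is placed by one of
#' `n_geometries` rigid transforms per frame, chosen by a Markov hop chain,
#' and every atom receives isotropic Gaussian jitter. Memoryless hopping by
#' construction: observed memory can only come from downstream state lumping.
#'
#' @param chain_templates per-atom template: a data frame as accepted by
#'   [structure_ensemble()] plus columns `x`, `y`, `z` (angstrom, bound pose)
#' @param pose_transforms list of `list(R = 3x3 rotation, t = length-3
#'   translation)`, one per geometry; rotations must be proper (det = +1)
#' @param hop_matrix row-stochastic geometry-to-geometry matrix (per frame)
#' @param jitter_sigma isotropic per-atom Gaussian noise, angstrom (>= 0)
#' @param pose_trans_sigma per-geometry rigid translational noise of chain B
#'   (angstrom, recycled; default 0). Models loose, disordered encounter
#'   states whose interface is not a single well-defined pose.
#' @param pose_rot_sigma per-geometry rigid rotational noise (radians about
#'   a uniformly random axis through the chain-B centroid, recycled;
#'   default 0)
#' @return an object of class `InterfaceEnsembleSpec`
#' @export
interface_ensemble_spec <- function(chain_templates, pose_transforms,
                                    hop_matrix, jitter_sigma = 0.5,
                                    pose_trans_sigma = 0,
                                    pose_rot_sigma = 0) {
  if (nrow(chain_templates) == 0L) stop("degenerate (zero-atom) template")
  need <- c("chain", "residue", "atom", "resclass", "element", "radius",
            "is_ca", "is_ligand", "site", "x", "y", "z")
  miss <- setdiff(need, names(chain_templates))
  if (length(miss)) stop("template missing columns: ", paste(miss, collapse = ", "))
  if (jitter_sigma < 0) stop("`jitter_sigma` must be >= 0")
  assert_row_stochastic(hop_matrix, tol = 1e-10, name = "hop_matrix")
  if (length(pose_transforms) != nrow(hop_matrix))
    stop("one pose transform required per geometry")
  for (g in seq_along(pose_transforms)) {
    tr <- pose_transforms[[g]]
    if (!all(c("R", "t") %in% names(tr)))
      stop("each pose transform needs elements `R` and `t`")
    R <- tr$R
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      stop(sprintf("pose transform %d is not a proper rigid rotation", g))
  }
  # ligand-site contract: one anchor on chain A's ligand, >= 1 candidate
  # site on chain B's ligand
  anchors <- which(chain_templates$chain == "A" & chain_templates$is_ligand &
                     !is.na(chain_templates$site))
  sites <- which(chain_templates$chain == "B" & chain_templates$is_ligand &
                   !is.na(chain_templates$site))
  if (any(chain_templates$is_ligand)) {
    if (length(anchors) != 1L)
      stop("chain A ligand must carry exactly one labeled anchor atom")
    if (length(sites) < 1L)
      stop("chain B ligand must carry at least one labeled candidate site")
  }
  ng <- length(pose_transforms)
  pose_trans_sigma <- rep_len(pose_trans_sigma, ng)
  pose_rot_sigma <- rep_len(pose_rot_sigma, ng)
  if (any(pose_trans_sigma < 0) || any(pose_rot_sigma < 0))
    stop("pose noise sigmas must be >= 0")
  structure(list(chain_templates = chain_templates,
                 pose_transforms = pose_transforms,
                 hop_matrix = hop_matrix,
                 n_geometries = ng,
                 jitter_sigma = jitter_sigma,
                 pose_trans_sigma = pose_trans_sigma,
                 pose_rot_sigma = pose_rot_sigma),
            class = "InterfaceEnsembleSpec")
}

#' Generate a jittered two-chain ensemble with planted geometries
#'
#' @param spec an [interface_ensemble_spec()]
#' @param n_frames number of frames to generate
#' @param seed integer seed
#' @return list with `ensemble` (a [structure_ensemble()] whose
#'   `frame_state` holds the planted geometry labels) and `labels`
#'   (the same labels as a plain integer vector)
#' @export
gen_interface_ensemble <- function(spec, n_frames, seed) {
  stopifnot(inherits(spec, "InterfaceEnsembleSpec"))
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  tmpl <- spec$chain_templates
  X0 <- as.matrix(tmpl[, c("x", "y", "z")])
  isB <- tmpl$chain == "B"
  ng <- spec$n_geometries
  out <- with_seed(seed, {
    # geometry hop chain from its stationary distribution
    pi0 <- stationary_distribution(spec$hop_matrix)
    cumH <- t(apply(spec$hop_matrix, 1, cumsum))
    g <- integer(n_frames)
    g[1] <- 1L + sum(runif(1) >= cumsum(pi0))
    if (n_frames > 1) for (t in 2:n_frames) {
      g[t] <- 1L + sum(cumH[g[t - 1], ] < runif(1))
    }
    g[g > ng] <- ng
    coords <- array(0, c(nrow(tmpl), 3, n_frames))
    for (t in seq_len(n_frames)) {
      gi <- g[t]
      tr <- spec$pose_transforms[[gi]]
      X <- X0
      B <- sweep(X0[isB, , drop = FALSE] %*% t(tr$R), 2, tr$t, `+`)
      rs <- spec$pose_rot_sigma[gi]
      ts <- spec$pose_trans_sigma[gi]
      if (rs > 0) {
        # rigid tumble about the chain-B centroid: random axis, N(0, rs) angle
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        th <- rnorm(1, sd = rs)
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        Rn <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
        ctr <- colMeans(B)
        B <- sweep(sweep(B, 2, ctr) %*% t(Rn), 2, ctr, `+`)
      }
      if (ts > 0) B <- sweep(B, 2, rnorm(3, sd = ts), `+`)
      X[isB, ] <- B
      if (spec$jitter_sigma > 0)
        X <- X + matrix(rnorm(length(X), sd = spec$jitter_sigma), ncol = 3)
      coords[, , t] <- X
    }
    list(coords = coords, g = g)
  })
  atoms <- tmpl[, setdiff(names(tmpl), c("x", "y", "z"))]
  ens <- structure_ensemble(out$coords, atoms, frame_state = out$g)
  list(ensemble = ens, labels = out$g)
}

#' Specification of a synthetic binding-energy table
#'
#' Emulates end-point binding free-energy output (kcal/mol): per
#' compound-state cell, `n_traj` independent trajectory-level estimates drawn
#' from a Gaussian with a known mean and standard deviation.
#'
#' @param compounds character vector of compound ids
#' @param states character vector of state ids
#' @param mean matrix (compound x state) of true means, kcal/mol
#' @param sd matrix of true standard deviations (>= 0), or a scalar
#' @param n_traj trajectories per cell (default 5)
#' @return an object of class `EnergyTableSpec`
#' @export
energy_table_spec <- function(compounds, states, mean, sd = 1, n_traj = 5L) {
  compounds <- as.character(compounds)
  states <- as.character(states)
  if (length(compounds)) {
    mean <- matrix(mean, nrow = length(compounds), ncol = length(states),
                   dimnames = list(compounds, states))
    sd <- matrix(sd, nrow = length(compounds), ncol = length(states),
                 dimnames = list(compounds, states))
    if (any(sd < 0)) stop("standard deviations must be >= 0")
  }
  if (n_traj < 1) stop("`n_traj` must be >= 1")
  structure(list(compounds = compounds, states = states, mean = mean,
                 sd = sd, n_traj = as.integer(n_traj)),
            class = "EnergyTableSpec")
}

#' Draw a binding-energy table from its specification
#'
#' @param spec an [energy_table_spec()]
#' @param seed integer seed
#' @return data frame with columns `compound`, `state`, `trajectory`,
#'   `dG_kcal_mol`
#' @export
gen_energy_table <- function(spec, seed) {
  stopifnot(inherits(spec, "EnergyTableSpec"))
  if (length(spec$compounds) == 0L || length(spec$states) == 0L) {
    return(data.frame(compound = character(0), state = character(0),
                      trajectory = integer(0), dG_kcal_mol = numeric(0)))
  }
  grid <- expand.grid(compound = spec$compounds, state = spec$states,
                      trajectory = seq_len(spec$n_traj),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$compound, grid$state, grid$trajectory), ]
  rownames(grid) <- NULL
  grid$dG_kcal_mol <- with_seed(seed, {
    mu <- spec$mean[cbind(grid$compound, grid$state)]
    sg <- spec$sd[cbind(grid$compound, grid$state)]
    rnorm(nrow(grid), mean = mu, sd = sg)
  })
  grid
}

#' Build a small two-chain bead complex with planted interface geometries
#'
#' Convenience constructor for demos and tests: chain A is a fixed bead
#' protein carrying a buried ligand with a single anchor atom; chain B is a
#' second bead protein whose ligand carries several labeled candidate
#' linkage sites. Geometries are rotations/translations of chain B around
#' chain A chosen to produce docked poses of varying burial, plus optional
#' far-apart decoys.
#'
#' @param n_res_a,n_res_b residues (one backbone bead each) per chain
#' @param n_sites labeled candidate sites on the chain-B ligand
#' @param geometries list of `list(R, t)` pose transforms; defaults to four
#'   docked poses around chain A
#' @param hop_matrix geometry hop matrix; defaults to sticky uniform hopping
#' @param jitter_sigma per-atom Gaussian jitter (angstrom)
#' @return an [interface_ensemble_spec()]
#' @export
toy_interface_spec <- function(n_res_a = 20, n_res_b = 16, n_sites = 3,
                               geometries = NULL, hop_matrix = NULL,
                               jitter_sigma = 0.3) {
  mk_chain <- function(chain, n_res, origin) {
    # beads on a compact helix-like curve, 3.8 A pitch
    i <- seq_len(n_res)
    xyz <- cbind(4 * cos(i * 1.75), 4 * sin(i * 1.75), 1.6 * i)
    xyz <- sweep(xyz, 2, origin, `+`)
    classes <- rep(c("charged", "polar", "hydrophobic"), length.out = n_res)
    data.frame(chain = chain, residue = i, atom = "CA", resclass = classes,
               element = "C", radius = 1.9, is_ca = TRUE, is_ligand = FALSE,
               site = NA_character_, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  a <- mk_chain("A", n_res_a, c(0, 0, 0))
  b <- mk_chain("B", n_res_b, c(0, 0, 0))
  # chain A ligand: buried near the middle of chain A, single anchor atom
  midA <- unname(colMeans(as.matrix(a[, c("x", "y", "z")])))
  liga <- data.frame(chain = "A", residue = 900L,
                     atom = c("C1", "C2"), resclass = "hydrophobic",
                     element = "C", radius = 1.7, is_ca = FALSE,
                     is_ligand = TRUE,
                     site = c("SiteC", NA_character_),
                     x = midA[1] + c(0, 1.5), y = midA[2] + c(0, 0),
                     z = midA[3] + c(0, 0), stringsAsFactors = FALSE)
  # chain B ligand: shallow-bound, candidate sites fanned outward
  midB <- unname(colMeans(as.matrix(b[, c("x", "y", "z")])))
  ang <- seq(0, pi, length.out = max(n_sites, 2))[seq_len(n_sites)]
  ligb <- data.frame(chain = "B", residue = 900L,
                     atom = paste0("S", seq_len(n_sites)),
                     resclass = "polar", element = "C", radius = 1.7,
                     is_ca = FALSE, is_ligand = TRUE,
                     site = paste0("Site", seq_len(n_sites)),
                     x = midB[1] + 6 * cos(ang), y = midB[2] + 6 * sin(ang),
                     z = midB[3], stringsAsFactors = FALSE)
  tmpl <- rbind(a, liga, b, ligb)
  if (is.null(geometries)) {
    rot_z <- function(th) matrix(c(cos(th), sin(th), 0,
                                   -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    geometries <- list(
      list(R = diag(3), t = c(9, 0, 0)),
      list(R = rot_z(pi / 2), t = c(0, 9, 0)),
      list(R = rot_z(pi), t = c(-9, 0, 0)),
      list(R = rot_z(3 * pi / 2), t = c(0, -9, 5))
    )
  }
  ng <- length(geometries)
  if (is.null(hop_matrix)) {
    hop_matrix <- matrix(0.05 / max(ng - 1, 1), ng, ng)
    diag(hop_matrix) <- 1 - rowSums(hop_matrix) + diag(hop_matrix)
  }
  interface_ensemble_spec(tmpl, geometries, hop_matrix, jitter_sigma)
}
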