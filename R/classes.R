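# Core S3 containers.

#' Discrete trajectory set
#'
#' Container for integer state sequences, the substrate of MSM and IGME
#' estimation. State labels are 1-based (`1..n_states`).
#'
#' @param trajectories list of integer vectors, each of length >= 2
#' @param n_states total number of states; defaults to the largest label seen
#' @param frame_interval time between consecutive frames (abstract units)
#' @return an object of class `DiscreteTrajectorySet`
#' @export
discrete_trajectory_set <- function(trajectories, n_states = NULL,
                                    frame_interval = 1) {
  if (!is.list(trajectories) || length(trajectories) == 0L)
    stop("`trajectories` must be a non-empty list of integer vectors")
  trajectories <- lapply(trajectories, function(x) as.integer(x))
  lens <- vapply(trajectories, length, 1L)
  if (any(lens < 2L)) stop("each trajectory must have length >= 2")
  labs <- unlist(trajectories, use.names = FALSE)
  if (any(labs < 1L)) stop("state labels must be >= 1 (1-based)")
  if (is.null(n_states)) n_states <- max(labs)
  if (max(labs) > n_states) stop("state label exceeds `n_states`")
  structure(list(trajectories = trajectories,
                 n_states = as.integer(n_states),
                 frame_interval = frame_interval),
            class = "DiscreteTrajectorySet")
}

#' @export
print.DiscreteTrajectorySet <- function(x, ...) {
  cat(sprintf("DiscreteTrajectorySet: %d trajectories, %d states, %d frames total\n",
              length(x$trajectories), x$n_states,
              sum(vapply(x$trajectories, length, 1L))))
  invisible(x)
}

#' Structural ensemble of a two-chain complex
#'
#' Frames share a constant atom roster described by `atoms`, a data frame with
#' columns `chain` ("A" or "B"), `residue` (integer), `atom` (name),
#' `resclass` ("charged", "polar" or "hydrophobic"), `element`, `radius`
#' (angstrom, > 0), `is_ca`, `is_ligand` (logical) and `site` (label or NA).
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (angstrom)
#' @param atoms per-atom metadata data frame (see Details)
#' @param frame_state optional per-frame state label (integer vector)
#' @return an object of class `StructureEnsemble`
#' @export
structure_ensemble <- function(coords, atoms, frame_state = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  need <- c("chain", "residue", "atom", "resclass", "element", "radius",
            "is_ca", "is_ligand", "site")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("`atoms` missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != dim(coords)[1])
    stop("atom roster size does not match coordinate array")
  if (nrow(atoms) == 0L) stop("zero-atom roster")
  if (any(atoms$radius <= 0)) stop("all atom radii must be > 0")
  if (!all(atoms$chain %in% c("A", "B"))) stop("chains must be 'A' or 'B'")
  if (!is.null(frame_state) && length(frame_state) != dim(coords)[3])
    stop("`frame_state` length must equal the number of frames")
  structure(list(coords = coords, atoms = atoms, frame_state = frame_state),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("StructureEnsemble: %d atoms (%d chain A, %d chain B), %d frames\n",
              nrow(x$atoms), sum(x$atoms$chain == "A"), sum(x$atoms$chain == "B"),
              dim(x$coords)[3]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `StructureEnsemble`
#' @return integer frame count
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Coordinates of one frame
#' @param ensemble a `StructureEnsemble`
#' @param i frame index
#' @return `n_atoms x 3` numeric matrix
#' @export
frame_coords <- function(ensemble, i) ensemble$coords[, , i, drop = TRUE]
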