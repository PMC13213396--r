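# Post-docking candidate prioritization: receptor-ensemble preparation,
# pose selection by unsuperposed ligand RMSD, bootstrap aggregation of
# per-trajectory binding energies, and threshold/tier classification.

#' Prepare a receptor ensemble from the core region of a state
#'
#' The core region keeps microstates with stationary population strictly
#' greater than `pop_min` (default 1 percent); `n_snapshots` frames are
#' drawn uniformly without replacement from the pooled core-region frames
#' (with replacement only when the pool is smaller, with a warning).
#' Receptor preparation for docking removes ligands; the flag is recorded.
#'
#' @param microstate_populations stationary population per microstate
#' @param frames_by_microstate list: microstate -> frame indices
#' @param n_snapshots snapshots to draw, default 200
#' @param pop_min core-region population threshold, default 0.01
#' @param seed integer seed
#' @return list with `frames` (selected frame ids), `core_microstates`,
#'   `ligand_removed` (TRUE), `with_replacement`
#' @export
prepare_receptor_ensemble <- function(microstate_populations,
                                      frames_by_microstate,
                                      n_snapshots = 200L, pop_min = 0.01,
                                      seed = 1L) {
  core <- which(microstate_populations > pop_min)
  if (length(core) == 0) stop("empty core region at pop_min = ", pop_min)
  pool <- sort(unique(unlist(frames_by_microstate[core])))
  if (length(pool) == 0) stop("core region contains no frames")
  replace <- length(pool) < n_snapshots
  if (replace)
    warning("core-region pool smaller than `n_snapshots`; sampling with replacement")
  frames <- with_seed(seed, sample(pool, n_snapshots, replace = replace))
  list(frames = frames, core_microstates = core,
       ligand_removed = TRUE, with_replacement = replace)
}

#' Keep the lowest-RMSD docked poses per compound-state pair
#'
#' Poses are ranked within each (compound, state) group by ascending ligand
#' RMSD -- computed without ligand superposition, so it reflects absolute
#' placement in the receptor frame -- with ties broken by pose id.
#'
#' @param poses data frame with columns `compound`, `state`, `pose`,
#'   `ligand_rmsd` (angstrom, >= 0; unique (compound, state, pose) rows)
#' @param n_keep poses to keep per group, default 5
#' @return data frame of kept rows, ordered by group then RMSD
#' @export
select_poses <- function(poses, n_keep = 5L) {
  need <- c("compound", "state", "pose", "ligand_rmsd")
  miss <- setdiff(need, names(poses))
  if (length(miss)) stop("`poses` missing columns: ", paste(miss, collapse = ", "))
  if (n_keep < 1) stop("`n_keep` must be >= 1")
  if (any(poses$ligand_rmsd < 0)) stop("ligand RMSD must be >= 0")
  key <- paste(poses$compound, poses$state, poses$pose, sep = "\r")
  if (anyDuplicated(key)) stop("(compound, state, pose) rows must be unique")
  grp <- split(seq_len(nrow(poses)),
               paste(poses$compound, poses$state, sep = "\r"))
  kept <- lapply(grp, function(ix) {
    if (length(ix) == 0) return(integer(0))
    if (length(ix) < n_keep)
      warning("group smaller than `n_keep`; keeping all poses")
    ord <- ix[order(poses$ligand_rmsd[ix], poses$pose[ix])]
    ord[seq_len(min(n_keep, length(ord)))]
  })
  out <- poses[unlist(kept, use.names = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap aggregation of per-trajectory binding energies
#'
#' For each (compound, state) cell, the trajectory list is resampled with
#' replacement `n_boot` times; each iteration's statistic is the mean of
#' the resampled energies, and the reported value and error are the mean
#' and standard deviation across iterations.
#'
#' @param energies data frame with columns `compound`, `state`,
#'   `trajectory`, `dG_kcal_mol`
#' @param n_boot bootstrap iterations, default 10
#' @param seed integer seed
#' @return data frame with columns `compound`, `state`, `n_traj`,
#'   `dG_mean`, `dG_sd`
#' @export
bootstrap_energy <- function(energies, n_boot = 10L, seed = 1L) {
  need <- c("compound", "state", "trajectory", "dG_kcal_mol")
  miss <- setdiff(need, names(energies))
  if (length(miss)) stop("`energies` missing columns: ", paste(miss, collapse = ", "))
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  if (any(!is.finite(energies$dG_kcal_mol))) stop("energies must be finite")
  grp <- split(energies$dG_kcal_mol,
               list(compound = energies$compound, state = energies$state),
               drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(grp), "\r", fixed = TRUE))
  out <- with_seed(seed, {
    res <- vector("list", length(grp))
    for (i in seq_along(grp)) {
      e <- grp[[i]]
      if (length(e) == 1) warning("single trajectory; bootstrap sd is 0")
      bm <- vapply(seq_len(n_boot), function(b)
        mean(sample(e, length(e), replace = TRUE)), 1.0)
      res[[i]] <- c(mean(bm), if (n_boot > 1) stats::sd(bm) else 0)
    }
    res
  })
  data.frame(compound = keys[, 1], state = keys[, 2],
             n_traj = vapply(grp, length, 1L),
             dG_mean = vapply(out, `[`, 1.0, 1),
             dG_sd = vapply(out, `[`, 1.0, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify and rank compounds by bootstrapped binding free energy
#'
#' Per compound the best state is the argmin of the mean binding free
#' energy across states. Compounds are ranked ascending by that best mean
#' (ties broken by compound id). Two tiering rules are recorded separately
#' so either can be audited: membership in the top `tier_fraction` of the
#' ranking, and mean energy at or below the absolute `threshold`; the
#' reported class is `"top"` iff both hold.
#'
#' @param summaries data frame with columns `compound`, `state`, `dG_mean`,
#'   and optionally `dG_sd` (e.g. from [bootstrap_energy()])
#' @param threshold absolute cut in kcal/mol, default -77
#' @param tier_fraction top fraction of the ranking, default 0.5
#' @return an object of class `RankingReport`: data frame with columns
#'   `compound`, `best_state`, `dG_mean`, `dG_sd`, `rank`, `in_top_tier`,
#'   `below_threshold`, `class`
#' @export
classify_compounds <- function(summaries, threshold = -77,
                               tier_fraction = 0.5) {
  need <- c("compound", "state", "dG_mean")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("`summaries` missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.finite(summaries$dG_mean)
  excluded <- unique(summaries$compound[bad])
  summaries <- summaries[!summaries$compound %in% excluded, , drop = FALSE]
  if (length(excluded))
    warning("excluded compounds with non-finite energies: ",
            paste(excluded, collapse = ", "))
  if (nrow(summaries) == 0) stop("no scorable compounds")
  grp <- split(seq_len(nrow(summaries)), summaries$compound)
  rows <- lapply(names(grp), function(cmp) {
    ix <- grp[[cmp]]
    best <- ix[which.min(summaries$dG_mean[ix])]
    data.frame(compound = cmp,
               best_state = as.character(summaries$state[best]),
               dG_mean = summaries$dG_mean[best],
               dG_sd = if ("dG_sd" %in% names(summaries))
                 summaries$dG_sd[best] else NA_real_,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$dG_mean, rep$compound), , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  n_top <- ceiling(tier_fraction * nrow(rep))
  rep$in_top_tier <- rep$rank <= n_top
  rep$below_threshold <- rep$dG_mean <= threshold
  rep$class <- ifelse(rep$in_top_tier & rep$below_threshold, "top", "bottom")
  rownames(rep) <- NULL
  class(rep) <- c("RankingReport", class(rep))
  rep
}
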