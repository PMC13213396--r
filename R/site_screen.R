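# Linkage-site viability screening: ligand-atom solvent exposure,
# site-anchor distance distributions, and the state x site viability matrix.

#' Site definition by atom selector
#'
#' @param id site label (e.g. "Site1", "SiteC")
#' @param chain chain id ("A" or "B")
#' @param residue residue index
#' @param atom atom name
#' @param role `"E3_site"` (candidate linkage site) or `"POI_anchor"`
#' @return an object of class `SiteDefinition`
#' @export
site_definition <- function(id, chain, residue, atom,
                            role = c("E3_site", "POI_anchor")) {
  role <- match.arg(role)
  structure(list(id = id, chain = chain, residue = as.integer(residue),
                 atom = atom, role = role),
            class = "SiteDefinition")
}

#' Resolve a site selector to a single atom index
#' @noRd
resolve_site <- function(ensemble, site) {
  at <- ensemble$atoms
  hits <- which(at$chain == site$chain & at$residue == site$residue &
                  at$atom == site$atom)
  if (length(hits) != 1L)
    stop(sprintf("selector for %s resolves to %d atoms (chain %s, residue %d, atom %s)",
                 site$id, length(hits), site$chain, site$residue, site$atom))
  hits
}

#' Sites labeled in an ensemble's atom metadata
#'
#' Collects `SiteDefinition`s from the `site` column of the atom roster:
#' labeled ligand atoms on chain B become candidate linkage sites and the
#' labeled chain-A ligand atom the anchor.
#'
#' @param ensemble a [structure_ensemble()]
#' @return list with `sites` (list of `SiteDefinition`) and `anchor`
#' @export
labeled_sites <- function(ensemble) {
  at <- ensemble$atoms
  lab <- which(!is.na(at$site))
  sites <- list(); anchor <- NULL
  for (i in lab) {
    sd <- site_definition(at$site[i], at$chain[i], at$residue[i], at$atom[i],
                          role = if (at$chain[i] == "A") "POI_anchor"
                                 else "E3_site")
    if (sd$role == "POI_anchor") anchor <- sd else sites[[length(sites) + 1]] <- sd
  }
  list(sites = sites, anchor = anchor)
}

#' Per-atom ligand SASA profile, ranked by exposure
#'
#' Mean solvent-accessible surface area of each ligand heavy atom, computed
#' in the full complex context and averaged over the supplied frames,
#' returned in descending order of exposure.
#'
#' @param ensemble a [structure_ensemble()]
#' @param frames frame indices (default all)
#' @param chain restrict to the ligand of this chain (default both)
#' @param probe,n_points SASA settings
#' @return data frame with columns `chain`, `residue`, `atom`, `site`,
#'   `sasa_mean`, `sasa_sd`, sorted by descending `sasa_mean`
#' @export
ligand_atom_sasa_profile <- function(ensemble, frames = NULL, chain = NULL,
                                     probe = 1.4, n_points = 960L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  at <- ensemble$atoms
  lig <- which(at$is_ligand & (if (is.null(chain)) TRUE else at$chain == chain))
  if (length(lig) == 0) stop("no ligand atoms present")
  vals <- matrix(0, length(frames), length(lig))
  for (f in seq_along(frames)) {
    s <- sasa(frame_coords(ensemble, frames[f]), at$radius, probe, n_points)
    vals[f, ] <- s[lig]
  }
  out <- data.frame(chain = at$chain[lig], residue = at$residue[lig],
                    atom = at$atom[lig], site = at$site[lig],
                    sasa_mean = colMeans(vals),
                    sasa_sd = apply(vals, 2, function(x)
                      if (length(x) > 1) stats::sd(x) else 0),
                    stringsAsFactors = FALSE)
  out[order(-out$sasa_mean), ]
}

#' Site-anchor distance distribution over state frames
#'
#' @param ensemble a [structure_ensemble()]
#' @param site,anchor `SiteDefinition`s resolving to one atom each
#' @param frames frame indices (default all)
#' @return list with `mean`, `sd`, `distances` (per frame), `degenerate`
#'   (TRUE iff site and anchor resolve to the same atom)
#' @export
site_anchor_distance <- function(ensemble, site, anchor, frames = NULL) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  i <- resolve_site(ensemble, site)
  j <- resolve_site(ensemble, anchor)
  degenerate <- i == j
  if (degenerate) warning("site and anchor resolve to the same atom")
  d <- vapply(frames, function(f) {
    X <- frame_coords(ensemble, f)
    sqrt(sum((X[i, ] - X[j, ])^2))
  }, 1.0)
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
       distances = d, degenerate = degenerate)
}

#' Verdict for one state x site cell
#'
#' Pure threshold logic, separated so its monotonicity (decreasing distance
#' or increasing exposure can never turn a viable cell non-viable) can be
#' checked in isolation.
#' @noRd
site_verdict <- function(sasa_mean, dist_mean, dist_max = 15, sasa_min = 10,
                         caveat_band = 0.1) {
  too_far <- dist_mean > dist_max
  occluded <- sasa_mean < sasa_min
  reason <- character(0)
  if (too_far)
    reason <- c(reason, sprintf("mean distance %.1f > %.1f", dist_mean, dist_max))
  if (occluded)
    reason <- c(reason, sprintf("mean SASA %.1f < %.1f", sasa_mean, sasa_min))
  verdict <- if (too_far) "too_far" else if (occluded) "occluded" else {
    near_dist <- dist_mean > dist_max * (1 - caveat_band)
    near_sasa <- sasa_mean < sasa_min * (1 + caveat_band)
    if (near_dist || near_sasa) "viable_with_caveat" else "viable"
  }
  if (verdict == "viable_with_caveat")
    reason <- sprintf("within %.0f%% of a threshold", 100 * caveat_band)
  list(verdict = verdict,
       reason = if (length(reason)) paste(reason, collapse = "; ") else "")
}

#' State x site viability matrix
#'
#' For every shortlisted state and candidate site, computes the mean ligand
#' site exposure (SASA in complex context) and the site-anchor distance,
#' and issues a verdict: `too_far` when the mean distance exceeds
#' `dist_max`, `occluded` when the mean SASA falls below `sasa_min`,
#' `viable_with_caveat` when passing but within `caveat_band` of either
#' threshold, else `viable`. Orientation and linker-path judgments are left
#' to human review (the `notes` column).
#'
#' @param ensemble a [structure_ensemble()]
#' @param state_frames named list: state id -> frame indices (typically the
#'   core-region frames of each shortlisted state)
#' @param sites list of candidate `SiteDefinition`s
#' @param anchor anchor `SiteDefinition`
#' @param dist_max distance ceiling, default 15 angstrom
#' @param sasa_min exposure floor, default 10 angstrom^2
#' @param caveat_band relative width of the caveat band, default 0.1
#' @param probe,n_points SASA settings
#' @return an object of class `SiteViabilityMatrix`: data frame with one
#'   row per state x site (`state`, `site`, `sasa_mean`, `sasa_sd`,
#'   `dist_mean`, `dist_sd`, `verdict`, `reason`, `notes`)
#' @export
viability_matrix <- function(ensemble, state_frames, sites, anchor,
                             dist_max = 15, sasa_min = 10,
                             caveat_band = 0.1,
                             probe = 1.4, n_points = 960L) {
  rows <- list()
  at <- ensemble$atoms
  for (sname in names(state_frames)) {
    fr <- state_frames[[sname]]
    # per-frame SASA of all atoms once per state, reused across sites
    svals <- matrix(0, length(fr), nrow(at))
    for (f in seq_along(fr))
      svals[f, ] <- sasa(frame_coords(ensemble, fr[f]), at$radius,
                         probe, n_points)
    for (site in sites) {
      i <- resolve_site(ensemble, site)
      sm <- mean(svals[, i]); ss <- if (length(fr) > 1) stats::sd(svals[, i]) else 0
      dd <- site_anchor_distance(ensemble, site, anchor, fr)
      v <- site_verdict(sm, dd$mean, dist_max, sasa_min, caveat_band)
      verdict <- v$verdict
      reason <- v$reason
      rows[[length(rows) + 1]] <- data.frame(
        state = sname, site = site$id,
        sasa_mean = sm, sasa_sd = ss,
        dist_mean = dd$mean, dist_sd = dd$sd,
        verdict = verdict,
        reason = if (length(reason)) paste(reason, collapse = "; ") else "",
        notes = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("SiteViabilityMatrix", class(out))
  out
}
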