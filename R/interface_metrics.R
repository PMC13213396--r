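# Structural characterization of metastable states: representative frames,
# interface RMSD, Shrake-Rupley SASA, buried surface area, residue contact
# frequencies and design-readiness shortlisting.

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#' @noRd
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the Shrake-Rupley method with deterministic
#' golden-spiral sphere points (no RNG): an atom's accessible area is the
#' fraction of test points on its solvent-expanded sphere (radius
#' `r + probe`) not buried inside any neighbor's expanded sphere, times
#' `4 * pi * (r + probe)^2`.
#'
#' @param coords n_atoms x 3 coordinate matrix (angstrom)
#' @param radii per-atom radii (angstrom)
#' @param probe probe radius, default 1.4 angstrom (water)
#' @param n_points sphere test points per atom (>= 32), default 960
#' @return numeric vector of per-atom SASA (angstrom^2)
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("`radii` must have one entry per atom")
  if (n_points < 32) stop("`n_points` must be >= 32")
  sphere <- golden_spiral_points(n_points)
  er <- radii + probe
  out <- numeric(n)
  # neighbor candidates: atoms within er_i + er_j
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    pts <- sweep(sphere * er[i], 2, coords[i, ], `+`)
    nb <- which(d2[i, ] < (er[i] + er)^2)
    nb <- nb[nb != i]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      exposed <- exposed & dj2 > er[j]^2
      if (!any(exposed)) break
    }
    out[i] <- sum(exposed) / n_points * 4 * pi * er[i]^2
  }
  out
}

#' Buried surface area of a two-chain frame
#'
#' `BSA = SASA(chain A alone) + SASA(chain B alone) - SASA(complex)`.
#' Symmetric under chain relabeling. Values below -0.1 trigger a warning
#' and are clipped at 0.
#'
#' @param ensemble a [structure_ensemble()]
#' @param frame frame index
#' @param probe,n_points passed to [sasa()]
#' @return buried surface area in angstrom^2
#' @export
bsa <- function(ensemble, frame = 1L, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  at <- ensemble$atoms
  if (length(unique(at$chain)) < 2) stop("BSA requires two chains")
  X <- frame_coords(ensemble, frame)
  ia <- at$chain == "A"; ib <- at$chain == "B"
  sa <- sum(sasa(X[ia, , drop = FALSE], at$radius[ia], probe, n_points))
  sb <- sum(sasa(X[ib, , drop = FALSE], at$radius[ib], probe, n_points))
  sab <- sum(sasa(X, at$radius, probe, n_points))
  val <- sa + sb - sab
  if (val < -0.1) warning(sprintf("negative BSA (%.3f) clipped to 0", val))
  max(val, 0)
}

#' Representative frame of a metastable state
#'
#' Picks the frame nearest (Euclidean, in projection space) to the center
#' of the state's most populated member microstate. Population ties break
#' to the lower microstate index; distance ties to the lower frame index.
#'
#' @param projection frames x d matrix for the state's frames
#' @param microstate_labels per-frame microstate label (parallel to rows)
#' @param populations stationary population per microstate, indexed by label
#' @return index (into the rows of `projection`) of the representative frame
#' @export
representative_structure <- function(projection, microstate_labels,
                                     populations) {
  projection <- as.matrix(projection)
  if (nrow(projection) == 0) stop("state has no frames")
  present <- sort(unique(microstate_labels))
  pops <- populations[present]
  top <- present[which.max(pops)]
  members <- which(microstate_labels == top)
  ctr <- colMeans(projection[members, , drop = FALSE])
  d2 <- rowSums(sweep(projection[members, , drop = FALSE], 2, ctr)^2)
  members[which.min(d2)]
}

#' Interface RMSD of frames against reference structures
#'
#' Interface residues are defined on each reference as residues with any
#' heavy atom within `interface_cutoff` of the other chain. Every frame is
#' superposed onto the reference using chain-A interface atoms (so the RMSD
#' measures relative pose change of chain B), and the RMSD is computed over
#' the interface C-alpha atoms of both chains. Per frame the `aggregate`
#' over references (default min) is taken, then mean and sd over frames.
#'
#' @param ensemble a [structure_ensemble()]
#' @param reference_frames frame indices used as references
#' @param frames frame indices to score (default all)
#' @param interface_cutoff heavy-atom interface cutoff, default 10 angstrom
#' @param aggregate `"min"` (default) or `"mean"` over references
#' @return list with `mean`, `sd`, `per_frame`
#' @export
interface_rmsd <- function(ensemble, reference_frames, frames = NULL,
                           interface_cutoff = 10,
                           aggregate = c("min", "mean")) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  aggregate <- match.arg(aggregate)
  if (length(reference_frames) < 1) stop("need at least one reference frame")
  if (interface_cutoff <= 0) stop("`interface_cutoff` must be > 0")
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  at <- ensemble$atoms
  ia <- which(at$chain == "A"); ib <- which(at$chain == "B")
  per_ref <- matrix(NA_real_, length(frames), length(reference_frames))
  for (r in seq_along(reference_frames)) {
    R <- frame_coords(ensemble, reference_frames[r])
    dAB <- outer(rowSums(R[ia, , drop = FALSE]^2),
                 rowSums(R[ib, , drop = FALSE]^2), `+`) -
      2 * tcrossprod(R[ia, , drop = FALSE], R[ib, , drop = FALSE])
    near <- sqrt(pmax(dAB, 0)) < interface_cutoff
    resA <- unique(at$residue[ia][apply(near, 1, any)])
    resB <- unique(at$residue[ib][apply(near, 2, any)])
    if (length(resA) == 0 || length(resB) == 0) next  # unusable reference
    fitA <- which(at$chain == "A" & at$residue %in% resA)
    ca_iface <- which(at$is_ca &
                        ((at$chain == "A" & at$residue %in% resA) |
                           (at$chain == "B" & at$residue %in% resB)))
    # the RMSD must measure the relative pose: require interface C-alpha
    # atoms on both chains, else the reference is unusable
    if (!any(at$chain[ca_iface] == "A") || !any(at$chain[ca_iface] == "B"))
      next
    for (f in seq_along(frames)) {
      X <- frame_coords(ensemble, frames[f])
      Xs <- kabsch_superpose(X[fitA, , drop = FALSE],
                             R[fitA, , drop = FALSE], full = X)
      per_ref[f, r] <- sqrt(mean(rowSums((Xs[ca_iface, , drop = FALSE] -
                                            R[ca_iface, , drop = FALSE])^2)))
    }
  }
  if (all(is.na(per_ref)))
    stop("empty interface at cutoff ", interface_cutoff,
         " for every reference; consider a larger cutoff")
  per_frame <- apply(per_ref, 1, function(x) {
    x <- x[!is.na(x)]
    if (aggregate == "min") min(x) else mean(x)
  })
  list(mean = mean(per_frame),
       sd = if (length(per_frame) > 1) stats::sd(per_frame) else 0,
       per_frame = per_frame)
}

#' Interchain residue contact frequencies
#'
#' A residue pair (a in chain A, b in chain B) is in contact in a frame iff
#' any interchain heavy-atom distance is below `cutoff`. Frequencies are
#' fractions of the supplied frames. The residue-class breakdown aggregates
#' contact events by the class of the participating residue on each chain.
#'
#' @param ensemble a [structure_ensemble()]
#' @param frames frame indices (default all)
#' @param cutoff heavy-atom contact cutoff, default 4.5 angstrom
#' @return list with `frequency` (resA x resB matrix in [0, 1]),
#'   `class_fractions` (list with elements `A` and `B`, each a named vector
#'   over residue classes summing to 1 when any contacts exist)
#' @export
contact_frequency <- function(ensemble, frames = NULL, cutoff = 4.5) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (cutoff <= 0) stop("`cutoff` must be > 0")
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  at <- ensemble$atoms
  ia <- which(at$chain == "A"); ib <- which(at$chain == "B")
  resA <- sort(unique(at$residue[ia])); resB <- sort(unique(at$residue[ib]))
  ra <- match(at$residue[ia], resA); rb <- match(at$residue[ib], resB)
  freq <- matrix(0, length(resA), length(resB),
                 dimnames = list(resA, resB))
  classA <- at$resclass[ia][match(resA, at$residue[ia])]
  classB <- at$resclass[ib][match(resB, at$residue[ib])]
  clsA_events <- c(charged = 0, polar = 0, hydrophobic = 0)
  clsB_events <- clsA_events
  cut2 <- cutoff^2
  for (f in frames) {
    X <- frame_coords(ensemble, f)
    A <- X[ia, , drop = FALSE]; B <- X[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    hit <- d2 < cut2
    # reduce atoms -> residues: pair contacts if any atom pair is close
    pair <- rowsum(hit + 0, ra) > 0
    pair <- t(rowsum(t(pair) + 0, rb) > 0)
    freq <- freq + pair
    ca <- rowSums(pair) > 0
    cb <- colSums(pair) > 0
    ta <- table(factor(classA[ca], levels = names(clsA_events)))
    tb <- table(factor(classB[cb], levels = names(clsB_events)))
    clsA_events <- clsA_events + as.numeric(ta)
    clsB_events <- clsB_events + as.numeric(tb)
  }
  freq <- freq / length(frames)
  norm <- function(x) if (sum(x) > 0) x / sum(x) else x
  list(frequency = freq,
       class_fractions = list(A = norm(clsA_events), B = norm(clsB_events)))
}

#' Build a per-state interface report
#'
#' Convenience aggregation: representative frame, interface RMSD against
#' supplied references, BSA over (a sample of) state frames, and contact
#' frequencies.
#'
#' @param ensemble a [structure_ensemble()]
#' @param state_id state identifier
#' @param frames frame indices of the state
#' @param reference_frames iRMSD reference frame indices
#' @param population stationary population of the state
#' @param interface_cutoff,contact_cutoff cutoffs (angstrom)
#' @param probe,n_points SASA settings
#' @param max_bsa_frames cap on frames scored for BSA (evenly subsampled)
#' @param representative_frame frame index to record as representative
#'   (e.g. from [representative_structure()]); defaults to the first frame
#' @return an object of class `StateInterfaceReport`
#' @export
state_interface_report <- function(ensemble, state_id, frames,
                                   reference_frames, population,
                                   interface_cutoff = 10,
                                   contact_cutoff = 4.5,
                                   probe = 1.4, n_points = 960L,
                                   max_bsa_frames = 20L,
                                   representative_frame = frames[1]) {
  ir <- tryCatch(
    interface_rmsd(ensemble, reference_frames, frames, interface_cutoff),
    error = function(e) {
      warning("interface RMSD unavailable for state ", state_id, ": ",
              conditionMessage(e))
      list(mean = NA_real_, sd = NA_real_, per_frame = NULL)
    })
  bf <- frames
  if (length(bf) > max_bsa_frames)
    bf <- bf[unique(round(seq(1, length(bf), length.out = max_bsa_frames)))]
  bs <- vapply(bf, function(f) bsa(ensemble, f, probe, n_points), 1.0)
  cf <- contact_frequency(ensemble, frames, contact_cutoff)
  structure(list(state = state_id,
                 population = population,
                 representative_frame = representative_frame,
                 irmsd_mean = ir$mean, irmsd_sd = ir$sd,
                 bsa_mean = mean(bs), bsa_sd = stats::sd(bs),
                 contact_frequency = cf$frequency,
                 residue_class_fractions = cf$class_fractions),
            class = "StateInterfaceReport")
}

#' Shortlist design-ready metastable states
#'
#' A state passes iff its population is at least `pop_min`, its mean
#' interface RMSD is at most `irmsd_max`, and its mean BSA is at least
#' `bsa_min` (default: 60 percent of the median mean-BSA across states, so
#' "significantly smaller burial" is judged relative to the ensemble).
#' Failing criteria are recorded per state.
#'
#' @param reports list of `StateInterfaceReport`
#' @param populations per-state populations (defaults to report fields)
#' @param pop_min population threshold, default 0.05
#' @param irmsd_max interface-RMSD ceiling, default 10 angstrom
#' @param bsa_min burial floor; `NULL` (default) uses 0.6 * median BSA
#' @return data frame with columns `state`, `population`, `irmsd_mean`,
#'   `bsa_mean`, `pass`, `reasons`
#' @export
shortlist_states <- function(reports, populations = NULL,
                             pop_min = 0.05, irmsd_max = 10,
                             bsa_min = NULL) {
  if (is.null(populations))
    populations <- vapply(reports, function(r) r$population, 1.0)
  bsas <- vapply(reports, function(r) r$bsa_mean, 1.0)
  irs <- vapply(reports, function(r) r$irmsd_mean, 1.0)
  if (is.null(bsa_min)) bsa_min <- 0.6 * stats::median(bsas, na.rm = TRUE)
  out <- data.frame(
    state = vapply(reports, function(r) as.character(r$state), ""),
    population = populations, irmsd_mean = irs, bsa_mean = bsas,
    stringsAsFactors = FALSE)
  reasons <- character(nrow(out))
  pass <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (any(is.na(c(populations[i], irs[i], bsas[i])))) {
      reasons[i] <- "insufficient data"; pass[i] <- FALSE; next
    }
    fail <- character(0)
    if (populations[i] < pop_min) fail <- c(fail, "population")
    if (irs[i] > irmsd_max) fail <- c(fail, "heterogeneity")
    if (bsas[i] < bsa_min) fail <- c(fail, "burial")
    pass[i] <- length(fail) == 0
    reasons[i] <- if (pass[i]) "" else paste(fail, collapse = ",")
  }
  out$pass <- pass
  out$reasons <- reasons
  out
}
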