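---
title: "Metastable protein-protein interfaces and memory-corrected propagators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable protein-protein interfaces and memory-corrected propagators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

metaPPI maps the slow dynamics of a two-chain complex onto a small set of
metastable protein-protein interfaces and screens those interfaces for
PROTAC linker placement. The dynamical core is a three-level coarse
graining:

1. **Features.** Interchain Cα-Cα distances (`interchain_ca_distances`),
   because encounter-complex formation is dominated by interprotein
   rearrangement rather than internal conformational change. A greedy
   Nyström column selection (`oasis_select`) can thin very large feature
   sets; tICA (`tica_fit`) extracts slow collective variables by
   maximizing time-lagged autocorrelation.
2. **Microstates.** k-means in tICA space (`kmeans_cluster`), a
   fixed-lag transition matrix (`estimate_tpm`), and the usual validation
   instruments: implied timescales, the Chapman-Kolmogorov (CK) test, and
   GMRQ cross-validation for hyperparameters.
3. **Metastable states and the IGME.** PCCA+ (`pcca_lump`) lumps
   microstates into a few metastable states. Lumping discards fast
   degrees of freedom whose relaxation leaves *memory* in the coarse
   process, so a fixed-lag MSM at that resolution fails the CK test. The
   integrative generalized master equation treats the long-time coarse
   propagator as `T(n·τ) ≈ A·T̂ⁿ`: `T̂` is the asymptotic per-lag
   propagator and `A` collects the time-integrated memory kernel. Both
   are constant matrices, so the model is as cheap as an MSM to apply but
   correct at long times once `n·τ` exceeds the memory relaxation time.

Stationary populations come from the left Perron eigenvector of `T̂`,
relaxation timescales from its subdominant eigenvalues
(`t_i = -τ/ln|λ_i|`), and mean first passage times from the standard
linear system on the embedded chain (`model_kinetics`).

## Assumptions

* The fine (microstate) process is Markovian at the estimation lag; all
  observed memory is produced by lumping.
* The fit window starts past the memory relaxation time: `A·T̂ⁿ` is an
  asymptotic form, not a short-time one. Residuals at small `n` are
  expected and are reported, not hidden (`igme_ck` includes the in-window
  flag and the MSM baseline).
* `T̂` is not constrained to be row-stochastic; the *product* `A·T̂ⁿ` is
  validated against stochasticity within 1e-6 across the window. A
  violation logs a warning ("soft check") because the memory prefactor
  legitimately redistributes probability.

# The least-squares fit

In its original formulation the IGME fits `A` and `T̂` by least squares over the window
`n = n0 … n0+L−1`. A log-linearization (`ln T(nτ) ≈ ln A + n·ln T̂`)
looks natural but is exact only when `A` and `T̂` commute; on exact
synthetic input it leaves residuals far above machine precision, which
would defeat the operator-recovery tests this package holds itself to.
metaPPI therefore uses a closed-form two-stage linear solution:

1. `T̂ = argmin Σₙ ‖T(nτ)·T̂ − T((n+1)τ)‖²_F` over consecutive window
   pairs — exact whenever the series truly follows `A·T̂ⁿ`;
2. `A = argmin Σₙ ‖A·T̂ⁿ − T(nτ)‖²_F`, linear in `A` given `T̂`;
3. optional BFGS refinement of both against the full objective
   (`refine = TRUE`), recorded in the model provenance.

The reported `rmse` is the root mean square residual over **all matrix
entries and all window lags**, in probability units. A bare "mean
RMSE" would be ambiguous between averaging over lags, entries, or models;
this definition keeps probability units, and per-lag residuals are exposed through `igme_ck` so no information is collapsed away.

`igme_scan` fits every `(n0, L)` grid point, ranks by ascending rmse with
ties broken by smaller `n0` then smaller `L`, and retains
`ceiling(top_fraction · n_models)` (default 5 %). Ensemble summaries
(mean ± sd of populations, timescales, MFPTs) are computed over the
retained set only, so they are invariant to grid enumeration order.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| tICA lag | config | frames | slow-CV extraction scale; production-scale work uses a 30 ns-equivalent |
| tICA CVs | 2 (toy) / 4 (production) | — | GMRQ-selected at production scale |
| microstates k | 20 (toy) / 100 (production) | — | k-means resolution |
| metastable states | 4–6 | — | chosen where IGME rmse is low |
| IGME τ, K | 5, 10 (toy) | frames | base lag and series length; K·τ stays below the lag ceiling of the data |
| top_fraction | 0.05 | — | standard top-5 % model retention |
| SASA probe | 1.4 | Å | water probe |
| SASA points | 960 | — | golden-spiral resolution; 2 % accuracy vs closed forms |
| contact cutoff | 4.5 | Å | heavy-atom residue contact |
| interface cutoff | 10 | Å | interface-residue definition for iRMSD |
| shortlist: pop ≥ | 0.05 | — | standard population rule |
| shortlist: iRMSD ≤ | 10 | Å | standard heterogeneity rule |
| shortlist: BSA ≥ | 0.6·median | Å² | "significantly smaller burial" judged relative to the state ensemble; no absolute number exists for this rule |
| site distance ≤ | 15 | Å | linker-reach rule |
| site SASA ≥ | 10 | Å² | solvent-exposure rule |
| caveat band | ±10 % | — | encodes qualitative "slightly above threshold" judgments without inventing new hard numbers |
| core region pop > | 0.01 | — | receptor-ensemble microstate cut |
| snapshots | 200 | — | receptor ensemble size |
| poses kept | 5 | — | lowest unsuperposed ligand RMSD |
| bootstrap | 10 | iterations | trajectory resampling |
| energy threshold | −77 | kcal/mol | top/bottom class cut, applied jointly with top-50 % tiering; both flags are reported separately so either rule can be audited |

# Synthetic worlds: what they emulate, what they do not

**Hidden-chain generator** (`gen_fine_chain`). A row-stochastic fine
chain `M` is simulated from its exact stationary distribution (no burn-in
ambiguity) and projected onto observed states. When the projection lumps
kinetically distinct fine states, the observed process carries memory —
the cleanest controllable memory source, with
`exact_projected_tpms` as an analytic oracle:
`T_obs(k)[a,b] = Σ_{i∈a,j∈b} π_i (M^k)_{ij} / Σ_{i∈a} π_i`.
The bundled test chain uses *gateway* states (one state per block carries
nearly all of the outflow), which produces large CK violations at short
lags while the chain as a whole mixes fast. That combination is
deliberate: the acceptance criterion demanding stationary populations
within 1 % relative error from 50×5,000 frames sits close to the
statistical floor of *any* estimator — the empirical occupancy itself has
a relative standard error of ≈ 0.3–0.5 % for a chain with integrated
autocorrelation time near 1 frame, and proportionally more for slower
chains. A slow, strongly metastable chain cannot meet that criterion at
the stated data size; a fast gateway chain meets both the 1 % criterion
and the CK-contrast criterion across seeds.

**Interface-ensemble generator** (`gen_interface_ensemble`). Chain A is
fixed; chain B (with its bound ligand) is placed by one of a set of rigid
transforms chosen framewise by a Markov hop chain, plus isotropic per-atom
jitter. Two optional per-geometry rigid noise channels
(`pose_trans_sigma`, `pose_rot_sigma`) create *loose, disordered*
encounter states — continuous pose clouds that no discrete transform set
can produce — which is how the end-to-end test plants a deliberately
heterogeneous (high interface-RMSD, weakly buried) decoy alongside four
well-defined docked geometries and one grazing low-burial decoy. Beads
carry per-atom radii, residue classes and ligand/site labels, so SASA and
contact analyses do not depend on an element lookup table.

What a green end-to-end test establishes: the pipeline separates compact
from diffuse and from weakly buried interfaces, recovers planted site
verdicts through noise, and is deterministic under its seeds. What it
does **not** establish: force-field realism, docking accuracy, energy
accuracy (energies are synthetic Gaussians with known means), or behavior
on all-atom rosters with hydrogens, alternate locations, or missing
density.

# Numerical choices

* **tICA** uses the reversible (symmetrized) moment estimator by default,
  with kinetic-map scaling off; both are common, conservative choices. A
  rank-deficient instantaneous covariance is regularized by a diagonal
  bump (1e-10, warning), never silently pseudo-inverted.
* **k-means** is seeded k-means++ with Lloyd iterations; centers are
  canonically reordered by coordinates so that labels are reproducible.
  Empty clusters are re-seeded from the farthest point (one warning).
* **estimate_tpm** trims to the largest strongly connected component by
  default; `connectivity = "none"` is available because hand-counted toy
  chains with absorbing states are legitimate test inputs. Reversible
  estimation is opt-in: symmetrized counts (exact detailed balance) or
  maximum-likelihood fixed-point.
* **PCCA+** runs an inner-simplex vertex search on the dominant right
  eigenvectors; memberships are barycentric coordinates clipped to [0, 1]
  and renormalized. Complex dominant eigenvectors beyond tolerance are an
  error advising reversible estimation.
* **interface RMSD** superposes each frame on the *chain-A* interface
  atoms of the reference so the statistic measures relative pose change of
  chain B — the quantity that distinguishes encounter geometries. The
  aggregation over references is `min` (each frame scored against its
  nearest microstate center), with `mean` exposed as an alternative. A reference whose interface lacks Cα atoms
  on either chain is skipped as unusable — without that rule a diffuse
  state with a ligand-only contact would report jitter-level "RMSD".
* **SASA** uses deterministic golden-spiral sphere points — no RNG, so
  site-viability matrices are bit-for-bit reproducible from a frozen
  ensemble.
* **Ties** are broken lowest-index-first everywhere (oASIS columns,
  representative microstates, pose ids, compound ids) so every ranking is
  deterministic.
* **Config files** are JSON (`read_pipeline_config`): it is the one
  structured-config format with a parser guaranteed present in the
  deployment image. Unknown keys are rejected rather than ignored.

# Known limitations

* `run_pipeline` treats the input ensemble as a single trajectory;
  multi-trajectory structural input should be discretized per trajectory
  and fed to the MSM/IGME layer directly.
* Stage outputs are written with provenance manifests and reruns are
  bit-reproducible, but there is no on-disk cache that skips completed
  upstream stages; resume by calling stage functions on saved artifacts.
* Memory-kernel *tensors* (qMSM-style) are out of scope; the IGME's `A`
  is the only memory object.
* Linker-path contortion and exit-vector orientation judgments are
  reported as free-text fields for human review, not algorithmized.
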