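Package: metaPPI
Title: Metastable Protein-Protein Interface Mapping and PROTAC Linkage Screening
Version: 0.1.0
Authors@R:
    person("metaPPI", "Developers", email = "metappi@example.org", role = c("aut", "cre"))
Description: Tools for mapping metastable protein-protein encounter complexes
    from trajectory data and turning them into PROTAC design decisions.
    Implements interchain Calpha distance featurization, greedy Nystrom
    (oASIS-style) feature selection, time-lagged independent component
    analysis (tICA), k-means microstate clustering, Markov state model
    estimation with implied-timescale and Chapman-Kolmogorov validation,
    GMRQ cross-validation, PCCA+ metastable lumping, and integrative
    generalized master equation (IGME) fitting of long-time propagators
    T(n*tau) ~ A %*% That^n with hyperparameter scanning. Structural
    characterization of metastable states includes Shrake-Rupley
    solvent-accessible surface area, buried surface area, interface RMSD,
    residue contact frequencies, linkage-site viability screening, and
    post-docking candidate ranking with bootstrap energy aggregation.
    Ships a synthetic-data module that generates discrete trajectories with
    planted non-Markovian memory, toy two-chain interface ensembles, and
    binding-energy tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
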