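Package: netdyn
Title: Dynamical Residue-Interaction Networks and Allosteric Path Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dynamical residue-interaction networks from molecular
    dynamics trajectories of protein complexes and computes optimal and
    suboptimal allosteric communication paths between user-specified source
    and sink residues. Residues become network nodes anchored at their alpha
    carbons; edges join residue pairs in persistent contact (within a distance
    cutoff for at least a threshold fraction of frames) and are weighted by
    the negative log of the pairwise displacement cross-correlation. Includes
    windowed (segmented) network analysis, RMSD/RMSF/distance trajectory
    metrics with Kabsch superposition, a seeded Gaussian elastic generator of
    synthetic trajectories with plantable correlation paths and contact
    occupancies, Shrake-Rupley solvent-accessible surface area with buried
    interface area and an interface hydrophobicity resampling statistic, and
    construction of two-fold crystallographic dimer models by superposition
    onto a template.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
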