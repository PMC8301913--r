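---
title: "Dynamical residue networks and allosteric paths: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical residue networks and allosteric paths: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdyn)
```

## The model

`netdyn` analyses molecular-dynamics trajectories of protein complexes as
*dynamical residue-interaction networks*. Each residue is a node anchored at
its alpha carbon. Two residues are joined by an edge when they are in
*persistent contact*: their inter-residue distance stays within a cutoff
(default 4.5 Å) in at least a threshold fraction of trajectory frames
(default 75%, inclusive). Each edge is weighted by the motional coupling of
its endpoints,

$$ w_{ij} = -\log |C_{ij}|, \qquad
   C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
                 {\sqrt{\langle \Delta r_i^2\rangle\,
                        \langle \Delta r_j^2\rangle}}, $$

where $\Delta r_i$ is the displacement of residue $i$'s Cα from its mean
position after superposing every frame onto the iterated mean structure.
Perfectly correlated contacts cost nothing to traverse; uncorrelated ones
are effectively impassable. The *optimal path* between a user-chosen source
and sink residue is the path minimising $\sum w_{ij}$; *suboptimal paths*
are all simple paths within a tolerance of that minimum. Residues that
recur across the path ensemble are candidates for mediating allosteric
communication between the endpoints — in the Ras–Raf systems that motivate
this package, between the galectin-pocket aspartates (D113) of the two
Raf-RBD protomers across the two-fold (α4–α5) Ras dimer interface.

Around this core the package provides trajectory metrics (RMSD, RMSF,
distance series), windowed (segmented) network analysis, Shrake–Rupley
solvent-accessible surface areas with buried-interface reporting,
construction of two-fold crystallographic dimer models by superposition
onto a template, and a synthetic trajectory generator used to validate the
entire pipeline by parameter recovery.

## Parameters that matter

* **`contact_cutoff`** (Å, default 4.5) and **`occupancy_threshold`**
  (fraction, default 0.75): the persistent-contact definition. The
  threshold is *inclusive* — a contact present in exactly 75% of frames
  forms an edge.
* **`contact_mode`**: which distance the cutoff applies to. The default is
  the minimum heavy-atom distance between the two residues, the convention
  of the dynamical-network methodology; a literal Cα–Cα reading of the
  4.5 Å cutoff would leave almost no contacts in a real protein. A
  `"calpha"` mode applies the cutoff to Cα–Cα distances and is what the
  Cα-resolution synthetic systems use. The mode is recorded in network
  output headers.
* **`exclude_neighbors`** (default 1): edges between sequence neighbours
  $|i-j| \le 1$ within a chain are suppressed, preventing trivial
  backbone-only paths. Cross-chain pairs are never excluded.
* **Path `tolerance`** (edge-weight units, default 20): the suboptimal
  allowance above the optimum. No faithful literature default exists; 20
  follows the tradition of Carma-style implementations and should be tuned
  to the system. `max_paths` (default 500) bounds the enumeration.
* **SASA `probe`** (1.4 Å water) and **`n_points`** (960 sphere points):
  Shrake–Rupley quadrature. Radii are the Bondi van der Waals set, recorded
  in every report; buried-area numbers shift by several percent across
  published radii sets. HETATM records are excluded from burial by default.

## Edge-weight and path-definition choices

The weight functional $-\log|C|$ is the standard mapping from correlation
to path cost: it is additive along a path (a path's weight is the negative
log of the product of its |correlations|), maps $|C| = 1$ to zero cost and
$|C| \to 0$ to infinity. Edges whose measured correlation is exactly zero
would carry infinite weight and are dropped with a warning. A
`weights = "uniform"` mode is provided, under which the optimal path is the
fewest-edge path; the weighted definition subsumes it and is the primary
one.

Dijkstra's algorithm computes optimal paths with deterministic
tie-breaking: among equal-weight optima (compared at tolerance $10^{-9}$)
the lexicographically smallest node sequence wins. Suboptimal paths are
enumerated with a Yen-style k-shortest-simple-paths search that stops at
the weight bound or `max_paths`; the resulting ensemble is sorted by
(weight, lexicographic order), so results are exactly reproducible. Both
routines are validated against exhaustive simple-path enumeration on
seeded random graphs of up to 8 nodes.

## The synthetic generator: what it emulates, and what it does not

No public trajectories accompany the studies this methodology serves, so
the package ships a generator whose statistical structure matches what the
network analysis consumes:

* **Gaussian elastic sampling.** Frames are independent draws
  $r = r_\mathrm{ref} + \delta$, $\delta \sim N(0, S \otimes I_3)$, where
  $S$ is a residue-level covariance with per-residue amplitudes `sigma`
  (per-axis standard deviation, Å; profiles such as a stiff core with a
  floppy CRD-like domain are per-residue vectors). Frames carry no temporal
  autocorrelation: occupancies and equal-time cross-correlations — all the
  downstream stages use — do not require it. This is the generator's main
  departure from real MD, and it means the package's validation says
  nothing about convergence with respect to simulation *time*.
* **Planted correlation paths.** `plant_correlated_path` imposes
  correlation $\rho$ between consecutive residues of an ordered path, with
  $\rho^{|a-b|}$ between path residues $a, b$ — a Kac–Murdock–Szegő
  structure that is positive semidefinite by construction, so the planted
  value survives exactly rather than being eroded by a PSD re-projection.
  (Setting only the consecutive pairs to $\rho$ and clipping negative
  eigenvalues — the obvious alternative — provably shrinks the planted
  correlations; e.g. a three-residue chain at $\rho = 0.9$ repairs to
  about 0.73.) `psd_repair` (eigenvalue clipping plus diagonal
  renormalisation) remains available for hand-edited covariances.
* **Planted contacts.** `plant_contact` registers residue pairs with a
  target occupancy. The sampler first relaxes the reference geometry once
  so every planted pair sits at 4.0 Å — just inside the cutoff — under an
  excluded-volume term that keeps all other non-neighbour pairs at ≥ 5.5 Å
  (without it, the relaxation can crumple a toy fold into accidental
  persistent contacts). Each frame then pins the pair at 4.0 Å with the
  target probability and pushes it to 6.0 Å otherwise, moving both
  partners symmetrically along their separation axis; shared residues are
  handled by Gauss–Seidel constraint sweeps. Pinning only the radial
  coordinate preserves transverse motion, but a permanently pinned pair is
  necessarily somewhat correlated — a real feature of persistent contacts,
  and the reason validation fixtures separate correlation-planted from
  merely contact-planted pairs.
* **Determinism.** The same `(model, seed)` gives bit-identical
  trajectories; the generator restores the caller's RNG state.

The central validation is end-to-end parameter recovery: a 32-residue
two-chain fold with a planted $\rho = 0.9$, occupancy-1.0 path between the
chains and an uncorrelated three-edge decoy detour at occupancy 0.8; at
5000 frames the optimal path returns exactly the planted residue sequence
across independent seeds, with the planted path roughly an order of
magnitude cheaper than the decoy route.

## The superposition–correlation interaction

Cross-correlations are computed after a rigid-body fit, and the fit is not
neutral: removing the best-fit rotation/translation absorbs part of the
common motion of any strongly correlated block, biasing its measured
correlation downward. The effect scales with the correlated fraction of
the system — on a 10-residue toy with a 3-residue planted block at
$\rho = 0.9$ the fitted DCCM reads ≈ 0.65–0.70, while the raw
(un-superposed) correlations are exactly 0.9; at 100 residues the fitted
value is ≈ 0.89. This is a property of the DCCM methodology, not an
artefact of this implementation. Consequently the generator is validated
against raw displacement correlations, the DCCM's quantitative contract is
asserted on systems of ~100 residues, and `cross_correlation(fit = FALSE)`
is available for trajectories already expressed in a common frame.
Network-level conclusions are robust to the bias because it compresses all
strong correlations similarly, preserving their ranking.

## Numerical choices

* **RMSF reference**: iterated mean structure, two superposition passes,
  initialised from the raw coordinate mean so the result is invariant
  under frame reordering; `reference = "first"` is available.
* **Superposition**: Kabsch SVD with the determinant correction (no
  reflections); fewer than 3 points or collinear point sets are rejected.
  Mass weighting is off by default (Cα-level analysis).
* **Occupancy boundary**: the threshold comparison is `f >= threshold`
  with a $10^{-12}$ guard so that an exact 75% count is kept regardless of
  floating-point representation.
* **SASA quadrature**: deterministic Fibonacci-lattice sphere points;
  doubling `n_points` moves totals by well under 0.5%. The isolated-sphere
  case is exact by construction.
* **Windowing**: `window_scheme` partitions frames contiguously, sizes
  differing by at most one frame; a 3500-frame run at 0.1 ns/frame in 7
  windows gives exactly 500 frames (50 ns) per segment, and a single
  window reproduces the full-trajectory network bit-identically. Windows
  shorter than 2 frames are rejected.
* **Dimer clash policy**: inter-protomer heavy-atom distances below 1.5 Å
  are an error, below 2.5 Å a warning — thresholds meant to catch gross
  assembly errors only.
* **Trajectory time**: `dt` defaults to 0.1 ns/frame when a format carries
  no time information and should be set explicitly, since all windowing is
  time-based.

## Design decisions on open points

* The contact distance is heavy-atom minimum by default (see above); the
  literal Cα reading is available as a mode rather than silently changed.
* The optimal path is defined by summed edge weights; the fewest-edge
  variant is the `"uniform"` weight mode.
* The suboptimal tolerance default (20) is flagged as convention, not as a
  faithful reproduction of any particular study.
* Correlations are computed per trajectory (per replicate), not pooled;
  callers can concatenate frames if pooling is wanted.
* Symmetry operators are supplied explicitly (or parsed from REMARK 290)
  and applied one at a time; full space-group expansion is out of scope —
  a single two-fold is all the dimer construction requires, and explicit
  operators keep every applied transform auditable.
* The interface hydrophobicity statistic is a *resampling analog* of
  crystallographic interface-specificity scores: mean Kyte–Doolittle
  hydropathy of the interface residues against seeded random contiguous
  surface patches of the same size, reported as a mid-p value. It is not a
  solvation free-energy calculation.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
systems: toy folds of 10–100 residues, trajectories of 2000–10,000 frames
for statistical checks (5000 frames for path recovery, 10,000 for
closed-form fluctuation checks), 100 random graphs of up to 8 nodes for
path-search oracles, and a synthetic two-sphere lattice complex
(~400 atoms) for surface-area and dimer machinery. These sizes give
sampling errors comfortably inside the asserted tolerances while keeping
the suite quick to run.

## Known limitations

* No deposited structures ship with the package, so the surface-area and
  dimer modules are validated by internal consistency (symmetry,
  additivity, analytic sphere overlaps, planted-transform recovery) on
  synthetic assemblies, not against published interface areas.
* The generator's independent-frame sampling cannot exercise
  time-dependent analyses, and its Cα-resolution folds cannot exercise
  heavy-atom contact mode beyond small fixtures.
* XTC trajectories are not read (no reader in the R ecosystem this package
  builds on); DCD and multi-model PDB are supported.
* mmCIF is not parsed; PDB fixed-column format only.
* Passing the planted-path recovery test shows the pipeline recovers the
  statistical structure it defines; real trajectories add force-field,
  sampling and convergence questions that are out of scope here.
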