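---
title: "Trajectory metrics and correlation networks for riboswitch dynamics"
author: "ribonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory metrics and correlation networks for riboswitch dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Riboswitches are structured mRNA elements that bind a small metabolite and
change gene expression. The thiamine-pyrophosphate (TPP) aptamer is the
classic case: a switch helix (P1) and two sensor arms (P2/P3 and P4/P5)
whose long-range P3–L5 tertiary contact closes around the ligand. Whether
and how ligand binding re-wires the internal communication of the aptamer
is a question about *correlated motion*: which residues move together,
which residues sit on the shortest communication routes between the binding
site and the tertiary contact, and how those routes change between the
ligand-free (apo) and ligand-bound (holo) states.

ribonet implements the complete post-simulation side of that analysis for
nucleic-acid conformational ensembles: superposition-based deviation and
fluctuation metrics, geometric hydrogen-bond occupancy, principal component
analysis of backbone coordinates, dynamic cross-correlation matrices,
contact-filtered correlation networks with centrality profiles, and
k-shortest-path communication ensembles. It does **not** run molecular
dynamics; trajectories come from elsewhere (any engine that can export
multi-model PDB, or the package's own synthetic generator).

## Models and conventions

### Superposition and deviation metrics

All fitting is unweighted least squares (Kabsch, proper rotation enforced
via the SVD determinant correction). Two reference conventions coexist and
are deliberately kept distinct:

* **RMSD series** use the *initial structure* (first production frame) as
  reference, and each substructure is fitted on *its own* heavy atoms
  before its RMSD is measured — so a floppy loop's deviation is not
  inflated by a moving stem.
* **RMSF and PCA** use the *average structure*: frames are fitted to the
  raw frame-mean once and the mean is recomputed (a single pass;
  `iterate = TRUE` refits to convergence, which matters only for very large
  rigid excursions).

No mass weighting is applied anywhere. Reported standard deviations are
sample SDs (n − 1); covariance matrices in PCA and DCCM use the population
(1/n) denominator, and variance *fractions* are denominator-free.

### Hydrogen bonds

A donor/acceptor pair scores a hit in a frame when the two polar heavy
atoms are closer than 3.5 Å **and** the D–H...A arrangement deviates from
linearity by at most 30° (i.e. the D–H–A angle is at least 150°). Two
readings of such cutoffs circulate; the opposite one (angle from linearity
larger than the cutoff) inverts results, so the convention is stated here
prominently and tested. The distance criterion applies to the donor–acceptor
distance, not H...A. Donor hydrogens are found by a name/distance heuristic
(hydrogen in the same residue within 1.25 Å), because PDB fixtures rarely
carry explicit bond records. Occupancy is the percentage of frames passing
the criterion.

### Contact mask

Residue pairs are "persistently in contact" when their minimum heavy-atom
distance is strictly below 4.5 Å in at least 75% of frames (the comparison
is `>=`, so exactly 75% passes). A C5′-only distance alternative is
available via the `selection` argument. The mask is computed on whatever
trajectory is supplied; for replicated simulations, concatenate the
replicas first (`concat_trajectories()`).

### PCA

The 3N × 3N covariance of C5′ coordinates (one backbone atom per
nucleotide) is eigendecomposed after superposition to the average
structure. Eigenvector signs are fixed by making each vector's
largest-magnitude component positive, so projections are reproducible
across platforms. Conformations are partitioned by complete-linkage
hierarchical clustering (`hclust`) on the PC1–PC2 scores; tie-breaking
follows `hclust`'s deterministic merge rule.

### Correlation network

The DCCM entry for residues i and j is the normalised covariance of their
C5′ displacement vectors after superposing every frame onto the initial
structure. Replicas are combined by element-wise mean (`consensus_dccm`); a
stricter cutoff mode keeps an entry only when `|C|` clears a threshold in
*all* replicas. The network places an edge on contact-masked pairs with
`|C| > 0` and uses two weightings of the same edges:

* shortest-path machinery uses distances `w_ij = −log|C_ij|` (natural log;
  perfectly coupled pairs are at distance 0, weak coupling is far), and
* eigenvector centrality uses the coupling strengths `|C_ij|` directly,
  because a "bigger = stronger" matrix is what the eigenvalue problem
  `A c = α⁻¹ c` requires.

Betweenness is Brandes' algorithm over weighted geodesics, summed over
unordered pairs and reported unnormalised (flags exist for both choices).
Profile similarity between states is the square inner product,
`SIP = (wᵃᵀwᵇ)² / ((wᵃᵀwᵃ)(wᵇᵀwᵇ))` — the squared cosine between profiles,
scale-invariant, 1 for proportional and 0 for orthogonal profiles. The
`|C| > 0.6` filter seen in published network figures is a *display* filter
(`edge_list(net, threshold = 0.6)`) and never affects construction.

### Path ensembles

Yen's algorithm collects the k = 1000 shortest loopless paths between a
designated source and sink (for the TPP aptamer, the G27/A59-equivalent
residues of the P3–L5 contact). Path length is the sum of edge weights.
Equal-length paths are ordered by the lexicographically smallest node-index
sequence, which makes ensembles deterministic — necessary for regression
testing and absent from most library implementations, one reason the
algorithm is implemented here rather than delegated. Node degeneracy is the
fraction of *found* paths through each node (endpoints are 1 by
construction); when fewer than k simple paths exist the ensemble saturates
silently. Path-node centrality summaries count each node once by default
(`mode = "multiset"` weights by path multiplicity; the published figure
style is ambiguous on this point, so both are provided).

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` + `make_trajectory()` produce a statistical emulator of
a solvated RNA trajectory, not a physical simulation: no force field, no
integrator, no solvent, no time correlation (frames are i.i.d.). What it
plants, the analysis modules must recover:

* **Geometry.** Residues are instantiated from a 7-heavy-atom + 1-hydrogen
  nucleotide template along a hairpin fold: two antiparallel strands 10 Å
  apart with a 4 Å rise and base atoms facing inward. This yields the two
  features of real RNA contact maps that matter downstream: a near-diagonal
  band (i, i±1) and long-range cross-strand rungs (i, n+1−i) that mimic
  P3–L5-like tertiary contacts. Defaults are aptamer-scale
  (`n_residues = 76`).
* **Correlation blocks.** Each block shares one latent Gaussian 3-vector
  per frame; loadings are chosen so the pairwise displacement correlation
  equals the target ρ. Blocks must be disjoint; negative ρ is representable
  only for pairs (one-factor model) and must satisfy ρ ≥ −1/(m−1) to be
  positive semi-definite.
* **Hydrogen bonds.** Scheduled pairs are placed at 2.9 Å/collinear
  (criterion-passing) or 5.0 Å (failing) according to seeded Bernoulli
  draws, so occupancy recovers the schedule to binomial error.
* **Fluctuation scales.** Per-residue σ (Å per axis), with all atoms of a
  residue moving rigidly plus 0.05 Å independent jitter; isotropic
  displacement means RMSF recovers √3·σ.
* **Planted modes.** As an alternative displacement model, a set of
  orthonormal residue-level directions with prescribed variances — the
  ground truth for PCA eigenvalue recovery. Mode directions are
  orthogonalised against rigid-body translations/rotations so the
  superposition step cannot distort the spectrum; jitter defaults to 0 in
  this model so the planted spectrum is exact.

All randomness flows from the single recorded seed; `write_fixture_bundle()`
emits PDB/CSV/JSON fixtures plus a manifest sufficient to regenerate them
bit-identically (and refuses to regenerate without a seed).

### Two artifacts of rigid-body fitting worth knowing about

Both are properties of the *method*, faithfully reproduced, not bugs:

1. **Correlation attenuation.** Removing the best-fit rigid motion absorbs
   roughly a 1/n share of any coherent displacement into the fitted
   translation/rotation. A planted block correlation of 0.80 is therefore
   recovered as ≈ 0.76–0.78 at n = 76 with a 5-residue mid-structure block
   (and lower for small systems or blocks near the ends, where the rotation
   fit has leverage). The recovery tests use aptamer-scale systems where
   the residual attenuation sits comfortably inside the stated 0.05 band.
2. **Spurious anchor correlation.** A residue fluctuating much *less* than
   the fit residual (~σ/√n) inherits the common fit noise and appears
   strongly correlated with every other such residue. The generator
   therefore keeps its near-rigid anchor residues at 0.15 Å — enough to
   condition the superposition, but above the fit-residual floor. Users
   analysing real trajectories should expect the same effect for genuinely
   rigid cores.

What passing the synthetic tests does **not** show: recovery under
time-correlated motion, anharmonic or multi-basin dynamics, solvent-mediated
contacts, or force-field-specific artifacts. The generator validates the
*estimators*, not the physics.

## Numerical choices

* Kabsch fits require ≥ 3 non-collinear points (second singular value
  above 1e−8 of the first), and always return a proper rotation.
* Dijkstra/Brandes treat path lengths equal within 1e−10 (relative) as
  ties; geodesic counting and Yen's tie-break both use this tolerance,
  because summing the same float edge weights in different orders must not
  split a tie.
* Eigenvector centrality is computed with a dense symmetric
  eigendecomposition on the largest connected component (zeros elsewhere),
  sign-fixed to the non-negative Perron vector and normalised to unit
  maximum. Note that power iteration *without* a diagonal shift fails to
  converge on bipartite graphs (±λ spectral symmetry) — the test oracle
  shifts by +I.
* DCCM rejects nodes whose post-superposition displacement variance is
  ~0 (undefined denominator) rather than silently writing C = 0. Raw-frozen
  anchors are fine: they acquire variance from the removed rigid motion.
* PCA refuses all-identical frames (zero variance), clamps eigenvalues in
  (−1e−9, 0) to 0, and errors on anything more negative.
* Percent occupancies are reported at full precision in CSV; round for
  display as needed.

## Design choices that were genuinely open

* **Betweenness pair convention.** The sum runs over unordered pairs
  (`ordered = TRUE` doubles every value); published equations are ambiguous
  on the factor of two, and SIP is insensitive to it.
* **Consensus semantics.** "Consensus matrix" is taken as the element-wise
  mean; the cutoff-masked variant is provided as an explicit mode.
* **Contact atoms.** Minimum heavy-atom distance defines contact, with a
  C5′-only override, since residue-level contact can reasonably be defined
  on either.
* **Ligand-row fitting.** RMSD of a bound ligand is measured after fitting
  on the RNA heavy atoms by default (`fit_region` overrides), since the
  interesting quantity is ligand motion relative to its pocket.
* **Whole-molecule selections** exclude nothing by default; ions or
  terminal groups are included exactly when the annotation's `whole` region
  includes their residues.
* **Pipeline interface.** The driver is the R function `run_pipeline()` on
  a declarative config (R list or YAML) rather than a shell executable;
  this package's users work in R, and every stage is equally usable as a
  plain function call.

## Problem sizes used in the shipped checks

The verification suite runs at desk scale, chosen so each stochastic bound
is comfortably met by sampling theory: 10 000 frames for DCCM block and PCA
spectrum recovery, 5 000 for RMSF scale recovery, 2 000 for occupancy
(binomial SE ≈ 1 point), 200 random ≤ 8-node graphs against exhaustive
enumeration for the exact graph algorithms, and a 20-residue two-system
demo for the end-to-end pipeline. The crystal-structure worked example
(bacterial vs eukaryotic TPP aptamer, heavy-atom RMSD ≈ 0.63 Å, ligand
≈ 0.69 Å) needs the two public coordinate files, which are not
redistributed with the package; place `2GDI.pdb` and `3D2G.pdb` under
`inst/extdata/` to activate it.

## Known limitations

* Only PDB (single- and multi-model) is parsed natively; binary trajectory
  formats enter through `trajectory_from_xyz()` after external decoding.
* Frames are treated as exchangeable: no autocorrelation analysis, no
  convergence diagnostics, no block averaging of errors.
* The synthetic hairpin is geometrically idealized; its contact map is a
  band plus rungs, not a full tertiary fold.
* Yen's algorithm is exact but O(k · n · Dijkstra); on networks much larger
  than a few hundred nodes with k = 1000 it becomes the dominant cost.
* No secondary-structure assignment, base-pair edge classification, or
  graphics; outputs are tables and matrices intended for downstream
  plotting.
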