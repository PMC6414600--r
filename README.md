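# ribonet

Trajectory metrics and correlation-network analysis for RNA dynamics.

## What it is for

Riboswitches — and structured RNAs generally — transmit the effect of
ligand binding through networks of correlated residue motion. Given a
conformational ensemble (an MD trajectory exported as multi-model PDB, or
any coordinate source), ribonet answers the standard questions of an
aptamer dynamics study:

* how much does each substructure (P1, P3–L3, ...) deviate and fluctuate
  (RMSD/RMSF after Kabsch superposition);
* which hydrogen bonds persist, and at what occupancy (geometric 3.5 Å /
  30°-from-linearity criterion);
* what are the dominant collective motions (PCA of the 3N×3N covariance of
  C5′ coordinates, complete-linkage clustering of the PC1–PC2 subspace);
* which residues move together (dynamic cross-correlation matrix, DCCM,
  with replica consensus) and how is the residue interaction network wired
  (edges on persistent contacts — within 4.5 Å for ≥ 75% of frames —
  weighted `w_ij = −log|C_ij|`);
* which residues carry the communication: betweenness centrality
  `c_B(n) = Σ_{i≠j≠n} σ(i,j|n)/σ(i,j)` over weighted geodesics,
  eigenvector centrality from `A c = α⁻¹ c` on the coupling strengths, and
  the square inner product `SIP = (wᵃᵀwᵇ)²/((wᵃᵀwᵃ)(wᵇᵀwᵇ))` to compare
  centrality profiles between apo and holo states;
* which routes connect two sites: Yen's k = 1000 shortest loopless paths,
  per-node degeneracy (fraction of paths through each node), and
  nodes-per-path statistics.

A seeded synthetic-trajectory generator plants known correlation blocks,
hydrogen-bond occupancies, fluctuation scales and PCA modes, so every
estimator in the package is verified against ground truth at desk scale.

## Worked example

Two synthetic states of a 40-residue hairpin; the "holo" state strengthens
the correlation of a 5-residue block (0.45 → 0.85) and its planted
hydrogen bond (68% → 74% occupancy):

```r
library(ribonet)

spec_apo <- synthetic_spec(
  n_residues = 40, n_frames = 800,
  correlation_blocks = list(list(residues = 15:19, rho = 0.45)),
  hbonds = list(list(donor = 10, acceptor = 31, occupancy = 0.68)),
  seed = 2024)
spec_holo <- synthetic_spec(
  n_residues = 40, n_frames = 800,
  correlation_blocks = list(list(residues = 15:19, rho = 0.85)),
  hbonds = list(list(donor = 10, acceptor = 31, occupancy = 0.74)),
  seed = 2025)

analyse <- function(spec) {
  ref <- make_reference(spec)
  trj <- make_trajectory(ref, spec)
  sel <- select_atoms(ref, "C5'")
  net <- build_network(compute_dccm(trj, sel), contact_mask(trj))
  list(trj = trj, net = net, b = betweenness_profile(net))
}
apo <- analyse(spec_apo); holo <- analyse(spec_holo)

rmsd_table(apo$trj, default_annotation(spec_apo),
           regions = c("whole", "P1", "P3-L3"))
#>   region mean_rmsd    sd_rmsd n_frames
#> 1  whole  1.220259 0.08261796      800
#> 2     P1  0.580724 0.14344063      800
#> 3  P3-L3  1.299344 0.11233177      800

hbond_occupancy(apo$trj, default_pairs(spec_apo))
#>            pair frames_observed occupancy
#> 1 A10:N1-C31:O2             556      69.5

apo$net
#> <residue network> 40 nodes, 58 edges (contact filter 4.5 A / 75%)

sip(apo$b, holo$b)
#> [1] 0.9263...
```

The RMSD table is read as "mean (sd)" per region: the closing stem P1
(0.58 Å) is visibly stiffer than the arm carrying the correlated block
(1.30 Å). The planted 68% hydrogen bond is recovered at 69.5% (binomial
noise at 800 frames). The SIP of 0.93 says ligand-style strengthening of
one block leaves the overall betweenness profile largely intact — values
well below 1 flag genuinely re-routed communication.

Communication paths between the bonded residues in the holo state:

```r
ens <- yen_k_shortest(holo$net, "10", "31", k = 1000)
ens
#> <path ensemble> 10 -> 31: 20/1000 paths, lengths 4.091 .. 64.419

head(sort(node_degeneracy(ens), decreasing = TRUE), 8)
#>   10   31   11   30    9   12   29   32
#> 1.00 1.00 0.50 0.50 0.45 0.45 0.45 0.45

nodes_per_path(ens)$mean
#> [1] 12
```

Only 20 simple paths exist in this small network, so the requested
ensemble of 1000 saturates at 20 (`k_found`); endpoints have degeneracy 1
by construction, and the 0.45–0.50 band identifies the residues that carry
nearly half of all routes.

The same analysis runs end-to-end from one declarative config with
`run_pipeline(config, outdir)` (per-system CSV/JSON artifacts plus a
provenance manifest; reruns are bit-identical), and two output bundles are
compared with `compare_states()`.

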