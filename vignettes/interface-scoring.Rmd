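---
title: "Interface-emphasized scoring and selection of protein complex models"
author: "interqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-emphasized scoring and selection of protein complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the geometric and
statistical model behind each score, the parameters that matter, what the
synthetic fixtures do and do not emulate, and the design choices made where
the design was genuinely open.

## The contact-area model

Every score in `interqa` is built on one geometric object: the partition of
space among probe-expanded atomic spheres by the additively-weighted
(power) Voronoi diagram. Atom $i$ with van der Waals radius $r_i$ and probe
radius $p$ (default 1.4 Å, the water-probe convention) owns the region where
its power distance $\|x - c_i\|^2 - (r_i + p)^2$ is smallest. The *contact
area* $A_{ij}$ is the area of the radical-plane face separating the cells of
$i$ and $j$, clipped to both expanded spheres and to the other neighbors'
half-spaces; the *solvent area* of $i$ is the part of its expanded sphere
surface inside its own cell. For two equal spheres of radius $r$ at center
distance $d$ the face is a disc of area $\pi(r^2 - d^2/4)$ — the package's
two-ball oracle.

`compute_contact_map()` estimates these areas by deterministic ray casting:
a Fibonacci lattice of `n_samples` directions (seed-rotated as a whole, so
one integer seed fixes every area in a run) is traced from each atom
center; each ray either crosses the nearest power plane or exits through
the sphere (solvent). The directed area toward neighbor $j$ is the *exact*
unclipped disc area times the sampled fraction of disc-bound rays that
survive clipping, with matched surface-element weights in numerator and
denominator; the reported $A_{ij}$ is the mean of the two directed
estimates. This ratio form is exact for isolated pairs at any sample count.

Numerical behavior, measured against an independent plane-sampling oracle:
large well-exposed faces are accurate to ~1–3% at the default
`n_samples = 1024`; the noisiest faces (worst ~20%) are the half-clipped
discs between deeply overlapping *bonded* atoms (center distance ~1.2 Å at
expanded radii ~3 Å). Totals and residue-level aggregates are accurate to
well under 1%. Contacts between atoms of adjacent residues are kept — no
bonded-neighbor exclusion — because every downstream quantity
(CAD-scores, potentials, features) is a difference or a ratio in which the
bonded background largely cancels, and a single consistent rule is easier
to reason about than an exclusion list.

Neighbor search uses the exact support cutoff $r_i + r_j + 2p$, so the
estimator never misses a face. `aggregate_residues()` rolls atom areas up
to residue pairs (intra-residue contacts excluded, inter-chain pairs
flagged), conserving total area to 1e-6.

## CAD-scores

With target residue-pair areas $T_{ij}$ and model areas $M_{ij}$, over the
set $G$ of pairs with $T_{ij} > 0$:

$$\mathrm{CAD} = 1 - \min\!\left(1,
  \frac{\sum_G |T_{ij} - M_{ij}|}{\sum_G T_{ij}}\right).$$

The score is target-referenced: model-only contacts are ignored, which
pins identity at exactly 1 and an empty model at exactly 0. The local score
restricts the sums to pairs containing one residue; the interface variant
restricts $G$ to inter-chain pairs; the binding-site variant first
aggregates each residue's inter-chain area ignoring the partner's identity,
$t_i = \sum_j T_{ij}^{\mathrm{inter}}$, and applies the same bounded
difference to the $t_i$. The binding-site definition is this package's
convention, chosen so that a subunit spun in place — same patch, different
cross-pairs — keeps a high binding-site score while the interface score
collapses; the analogous contrast holds between IPS (Jaccard of interface
residues) and ICS (F1 of contact pairs). Residue correspondence is by chain
identifier plus author residue number throughout; no sequence alignment is
attempted, and `match_chains()` resolves interchangeable homomer labels by
enumerating permutations within equal-length chain classes (capped at 8!)
and maximizing the interface CAD (global CAD when the target has no
interface, so monomer comparisons still work).

## Contact potential and pseudo-energies

`derive_potential()` tallies observed contact area $O(a,b)$ between coarse
atom classes (backbone N/C/O, CA, CB, sidechain C/N/O, S, plus a solvent
pseudo-type) over reference structures and compares with the area expected
under independent pairing of type endpoints:
$e(a,b) = -\ln[(O+c)/(E+c)]$ with pseudocount $c$ (default 1 Ų). Two
consequences worth stating plainly:

* The area-weighted mean energy of the references equals minus the KL
  divergence of the observed pairing distribution from independence — it is
  *always* ≤ 0, and its magnitude measures how structured the reference
  world is (≈0.22 /Ų for the fixture ensembles). "Self-consistency" can
  therefore only mean *favorable and bounded*, not zero.
* In the idealized fixture world there are only five heavy-atom classes and
  no hydrophobic core: CB is predominantly solvent-exposed in any helix
  fixture, so the derived potential genuinely rewards CB solvation and
  penalizes burying CB at an interface. That is a faithful statistic of the
  fixture ensemble, not an artifact — but it means a fixture-derived
  log-odds potential cannot drive burial-seeking pose search. For that, the
  package provides `uniform_contact_potential()`: every atom–atom contact
  −1 per Ų, solvent neutral, i.e. classic shape complementarity. Pose
  enumeration uses it; quality scoring (light score, dark features) uses
  the derived potential, where only relative differences matter.

`pseudo_energy()` is linear in areas, split half/half between the partner
atoms so per-atom terms sum exactly to the total; `interface_energy()` sums
cross-chain (or cross-group) contacts only. The "light" global score
squashes the mean energy density through $1/(1+e^{k\bar e})$ with $k = 1$ —
a calibration of this package, not a reproduction of any published scale.

## The learned local-quality score

`dark_train()` fits a one-hidden-layer network (default 20 tanh units,
sigmoid output, z-scored inputs, full-batch gradient descent with momentum,
fixed 2000 iterations, seeded initialization — fully deterministic) to
predict per-residue CAD-scores from a fixed, versioned 16-feature vector:
total/solvent/same-chain/cross-chain areas, per-class area sums, residue
pseudo-energy, area-weighted neighbor energy density, burial fraction. The
global score is the exact arithmetic mean of the per-residue predictions —
asserted to identity in the tests.

`train_dark_on_decoys()` builds the training set from rigid-body decoys of
a fixture complex. The perturbation grid crosses interface degradation
(shift/rotation) with coordinate noise *independently*; an earlier coupled
ladder let the fit confound overall noise with interface loss and produced
a predictor that inverted on new data. On a held-out complex the trained
predictor's global score ranks a graded decoy ladder with Spearman ~0.8–0.95
against true interface CAD.

## Tournament selection with an interface tolerance

`compare_pair()` prefers the higher global score *unless* the two globals
differ by at most the tolerance (default 0.02 score units, exposed in
`ranking_config()`), in which case the interface pseudo-energy alone
decides; exact ties fall back to global, then lexicographic id, making the
full round-robin (`tournament_rank()`, Copeland win counts) deterministic
and order-independent. The two limits are exact and tested: tolerance 0
reproduces the global-score sort, tolerance beyond the score spread
reproduces the interface-energy sort. `select_diverse()` is greedy leader
clustering in rank order on pairwise interface CAD similarity (threshold
0.65): cheapest scheme that returns one representative per distinct
interface.

## Two-ring docking

For stacked ring oligomers, `enumerate_poses()` aligns both rings on their
gyration-tensor minor axes (flat rings make this well-posed; a near-
degenerate tensor, relative eigenvalue gap < 0.1, is an error), then scans
axial offsets in 1 Å decrements from the first-contact separation and
rotations in 2° steps over $[0, 360/n)$ for cyclic symmetry order $n$ — the
rest of the circle is redundant. The scan stops before the first offset at
which *every* rotation violates the clash rule, so the pose count is
exactly `n_offsets × n_rotations`. The clash fraction counts cross-ring
pairs closer than 0.6× the radius sum *among pairs within contact range*
(≤ 0.1% allowed): normalizing by in-range pairs keeps the gate independent
of ring size, whereas an all-pairs denominator grows quadratically and, on
sparse idealized rings, let physically impossible tunnel-through
arrangements pass. Scoring is the cross-ring interface pseudo-energy with
the shape-complementarity potential; the recovery experiment splits a
two-ring complex built half a grid step off-grid and checks that default-
step re-docking finds a pose within interface CAD ≥ 0.7 — evaluated over
the docked ring's cyclic chain relabelings, since a $C_n$ ring's chains are
interchangeable. Ring tilt and lateral offset are deliberately not scanned.

## What the fixtures emulate — and what they don't

`make_dimer()`/`make_ring()` build idealized poly-alanine helices (rise
1.5 Å, 100°/residue, backbone + CB) into dimers and flat $C_n$ rings;
`make_decoys()` perturbs one chain rigidly and adds coordinate noise, with
ground-truth interface CAD recomputed from contact maps. This gives
realistic contact-map *topology* (packed interfaces, buried and exposed
residues, symmetric assemblies) with complete ground truth and
bit-reproducible seeds. It does *not* emulate sequence diversity, sidechain
chemistry, a hydrophobic core, loops, or flexibility — so passing tests
demonstrate the machinery's correctness and the selection logic's behavior
under controlled conditions, not predictive performance on real proteins.
Generator geometry is deterministic; `make_ring()` accepts a seed argument
for interface uniformity but uses no randomness, because seeded jitter
would break the exact $C_n$ symmetry the fixtures guarantee.

## Problem sizes and numerical defaults

The shipped experiments use desk-scale sizes chosen to exercise every code
path with comfortable statistics: dimers of 18–24 residues per chain,
rings of 5 × 10 subunit residues (~250 atoms per ring), decoy ladders of
6–15 models, 50-trial selection experiments, and 96–256 estimator samples
where ranking (not absolute area) is what matters, 1024–4096 where
accuracy is asserted. Tolerances follow the measured estimator precision
profile above. Degenerate inputs have defined behavior throughout:
monomers score zero interface energy with a warning, targets without
contacts raise an undefined-score error rather than returning a number,
rings that never touch return an empty pose list with a warning.

## Known limitations

* The contact estimator is sampled, not exact; worst-case per-face error
  (~20% on deeply overlapping bonded pairs) is documented above and in the
  tests.
* The derived potential reflects its references; on chemically uniform
  fixtures it cannot reward burial (see above). Real-protein use would
  require deriving it from a real, diverse reference set.
* The dark predictor is a deliberately small network trained on fixture
  decoys; its feature set and architecture are this package's conventions.
* Chain matching enumerates at most 8 interchangeable chains.
* The two-ring enumerator scans exactly two degrees of freedom (axial
  offset, axial rotation); no relaxation step follows scoring.
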