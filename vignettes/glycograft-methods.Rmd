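---
title: "Methods: conformer extraction and steric grafting in glycograft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer extraction and steric grafting in glycograft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycograft)
```

# The problem

A glycan in solution is an ensemble, not a structure: its glycosidic
torsions interconvert on nanosecond timescales, so the object a
glycoprotein builder needs is a *weighted set of conformers* together with
a way of deciding which of them, if any, fits the protein surface at a
given glycosylation site. `glycograft` implements both halves: reducing a
molecular-dynamics ensemble of the free glycan to such a library, and
grafting library entries onto protein sidechains by steric-loss
minimization. This vignette describes the models, the tunable parameters,
the numerical choices, and what the synthetic test data do and do not
establish.

# Conformer-library extraction

## Featurization

Each trajectory frame (hydrogens removed) is represented by the flattened
lower triangle of its pairwise Euclidean distance matrix, in column-major
order: `{g21, g31, ..., gn1, g32, ...}`. Distances are internal
coordinates, so the representation is *exactly* invariant under rigid-body
motion of a frame — the pipeline deliberately has no superposition step,
and a property test holds this invariance to 1e-9 Å. The cost is a
p = N(N−1)/2-dimensional feature vector, which motivates the next step.

## Embedding and clustering

PCA (centered, unscaled) reduces the distance features to three
components. Three is a compromise we keep fixed: enough to separate
torsional basins of oligosaccharides (where one to three glycosidic
torsions dominate the variance), while keeping density estimation and
silhouette computation well-conditioned; in higher dimensions points grow
uniformly distant and both degrade. The explained-variance ratio and its
cumulative sum are reported so users can see when three components are
not enough.

Clustering uses full-covariance Gaussian mixtures (via mclust's "VVV"
parameterization — torsional basins in the embedding are elongated and
oblique, so spherical or diagonal models would split them). The number of
clusters is selected by the mean silhouette over k = 2…10, computed with
the Euclidean metric on the embedding; ties within 1e-6 go to the smaller
k (parsimony). Fits that fail or collapse to a single component are
skipped with a warning rather than aborting the scan over k. Above 50,000
frames the silhouette uses a seeded subsample of that size; the mixture
itself is always fitted on all frames.

## Representatives

The representative of a cluster is *not* its centroid — an average of
distance vectors corresponds to no sampled geometry. Instead a kernel
density estimate with a Gaussian kernel and a single scalar bandwidth is
fitted to the cluster's embedding rows; the bandwidth is chosen by
five-fold cross-validation (negative mean held-out log-density, the
natural loss for a density model) over 20 log-spaced candidates spanning
[0.1, 10] × the Scott plug-in value, a grid that brackets the plug-in
estimate symmetrically. The density is maximized by L-BFGS-B under box
bounds given by the per-dimension min/max of the cluster's points, with
eight restarts from the highest-density training points (the surface is
multimodal at small bandwidths; restarts make the argmax reliable). The
library entry is the *sampled frame* nearest the peak, with weight equal
to the cluster's frame fraction; entries are ordered G0, G1, … by
descending weight with lower cluster id breaking ties.

Two numerical edge cases are handled explicitly: clusters with fewer than
10 points fall back to the medoid (cross-validation is meaningless at
that size) with a warning, and empty clusters are dropped with weight
renormalization.

One genuinely open design point: the density could be estimated either in
the embedding or in the full distance-feature space. We estimate it in
the embedding, because that is the space in which the clusters are
defined and in which their boundaries are meaningful; the choice is
recorded here rather than claimed as the only reading.

## What the planted ensembles show

The generator builds a two-ring branched disaccharide and perturbs three
rotatable torsions (two glycosidic, one exocyclic) around k planted
centers with Gaussian spread 8°, centers ≥ 120° apart (> 6 spreads — the
"well-separated" regime); frames are pure functions of (spec, seed).
Recovery tests then demand k back from the silhouette, weights within
±0.05 of the planted proportions, and representatives inside the planted
basins. This validates the machinery — featurization, embedding,
model selection, density peaks — under torsional heterogeneity with known
truth. It does *not* emulate ring-pucker transitions, solvent memory,
anomeric equilibria, or correlated multi-linkage motion of real
trajectories, so passing tests certify the pipeline, not force-field
realism.

# Steric grafting

## The loss

For a conformer placed at a site, the loss sums `200·exp(D²)` over all
protein–glycan atom pairs strictly closer than 1.7 Å (the van der Waals
radius of carbon); the glycan's anomeric carbon is exempt, since it is
covalently bonded to the sidechain. Zero loss means clash-free, and
"success" means exactly zero — there is no partial credit. Two properties
of this loss matter numerically: it is discontinuous at the threshold
(pairs at exactly 1.7 Å contribute nothing), and *within* the threshold
it increases with distance, so its gradient points into the clash. The
optimizers below are therefore population/sampling methods, not descent
methods.

## Attachment geometry

The linkage table (`inst/extdata/linkage_table.csv`, editable) defines
per chemistry the five atoms a–e (a, b on the glycan: ring oxygen and
anomeric carbon; c, d, e on the sidechain), the b–c bond length and
angle, and the φ = a-b-c-d / ψ = b-c-d-e torsion ranges. The shipped
ranges are conventional glycosidic statistics — the exo-anomeric region
for the N-linkage φ, free ψ — and are meant to be replaced by users with
linkage-specific data; the dihedral convention is IUPAC right-handed,
range (−180°, 180°]. Attachment places the anomeric carbon by
internal-coordinate construction (bond length, angle, ψ at its range
midpoint), aligns the glycan's anomeric substituent direction with the
new bond (displacing the anomeric hydroxyl O1, as in the physiological
condensation; the anomeric configuration of the conformer is preserved
by rigidity), and sets φ to its range midpoint. Setting (φ, ψ) is two
rigid rotations about the b–c and c–d axes; protein atoms never move —
clash resolution is glycan-side only, because silently re-rotamerizing
the protein would destroy exactly the structural information
high-resolution models carry.

## Genetic search

The GA evolves 128 (φ, ψ) pairs over at most eight generations: the best
half become parents, children are produced by gene-wise uniform crossover
(each gene from a random parent — the simplest operator consistent with a
two-gene genome) and per-gene mutation with probability 0.2 (resampling
uniformly within the gene's range, keeping exploration range-bounded).
Children replace the bottom half wholesale, so the best individual always
survives and the best-fitness trajectory is non-increasing by
construction. The search exits as soon as a zero-loss individual appears;
this is purely a speed optimization and cannot change which sites
succeed. Conformers are tried in descending-weight order and the first
zero-loss conformer wins, reflecting the assumption that an accessible
site leaves the solution equilibrium intact.

## The wiggle fallback

If every conformer retains clashes, the lowest-loss pose enters a
stochastic refinement over *all* rotatable torsions: the linkage φ/ψ plus
every quartet found on the molecular graph (non-ring atoms of degree two
anchor the rotation axes; the rotating side is always the one away from
the anomeric anchor, so the new bond never moves). Each iteration draws
an independent uniform move within ±10° per torsion — 10° being the low
end of glycosidic-torsion fluctuation at room temperature; whether the
stated range is a half-width or a total width is ambiguous, so half-width
is the default and both are selectable. Up to 40 iterations are taken;
the moves accumulate as a random walk and the best pose encountered is
returned. A greedy walk restarted from the best pose each iteration was
deliberately rejected: within the threshold the loss *rewards deeper
overlap*, so greedy descent drives a shallow clash inward and then cannot
release it — the random walk with best-tracking resolves an
8°-resolvable clash in ≥ 95 of 100 seeded runs where the greedy variant
managed ~87. Whether moves should perturb one torsion per iteration or
all of them is a second ambiguity; all-torsion moves are the default,
per-call selectable in principle via the quartet list.

## Occupancy scanning and the amide swap

GlcNAc scanning runs the full cascade with a single-GlcNAc probe at every
N-X-S/T sequon, against the *bare* protein per site: a one-monosaccharide
probe at one sequon should not change accessibility at another, so no
cross-talk is introduced. The literal N-X-S/T rule is the default —
whether published occupancy benchmarks excluded X = P is not stated in
the sources we follow — with `excludeProlineX` exposing the biological
convention prominently. Terminal partial motifs are not sequons, residue
numbering (offsets, insertion codes) is reported exactly as authored, and
numbering gaps (missing residues) never create spurious motifs. The
OD1/ND2 swap exchanges the two amide-atom coordinate triplets — an exact
involution — because X-ray assignment of those atoms is largely
arbitrary and a wrong assignment aims the graft into the protein;
the blocked-amide fixture reproduces that false-negative-to-yes rescue.

## Multi-site grafting

Sites are processed in residue order and previously grafted glycans join
the protein atom set for later sites (toggleable), preventing
glycan–glycan overlap; per-site failures are reported while other sites
proceed. One master seed fans out deterministic per-site sub-seeds, so
reports are byte-reproducible.

# Ensemble fitting and SASA

For exclusion-volume estimation, 200 frames per repeat (drawn without
replacement; with replacement plus a warning when the trajectory is
shorter) are attached with (φ, ψ) drawn uniformly from the linkage
ranges, clash-tested at 1.7 Å, over 5 repeats. Accepted poses aggregate
into a multi-model complex whose SASA is computed by a native
Shrake–Rupley implementation: a deterministic golden-spiral dot lattice
(15 dots per sphere by default; the closed-form single-sphere and
two-sphere tests show ≤ 5% error at 15 dots and ≤ 0.5% at 960), van der
Waals radii from an overridable table, results in nm². The probe
parameter is 0.14 nm interpreted as the probe *radius* — the water probe
convention — although the parameter name in some tools reads "diameter";
a literal-diameter mode is available and the interpretation is logged.
Glycan occlusion is reported as ΔSASA = SASA(protein alone) − mean
SASA(protein within complex).

# Synthetic fixtures and their guarantees

The pocket fixture surrounds a sequon's attachment direction with a
spherical shell of carbon pseudo-atoms (dot spacing 0.8 Å), centered 3 Å
out along the amide direction with radius 3 + clearance. Because both
linkage torsion axes pass through the attachment region, every glycan
atom's distance to the shell center is nearly pose-invariant, and because
the forbidden annulus (±1.7 Å around the shell) is wider than any bond
step, a connected glycan cannot thread through it: feasibility is
monotone in clearance with a single no→yes transition, which the scanning
ladder tests assert. Carbon pseudo-atoms keep the 1.7 Å analysis exact.
The extended-chain peptide generator provides idealized backbones with
just enough sidechain atoms for detection and attachment (Asn CG/OD1/ND2,
Ser OG, Thr OG1/CG2, Trp CG/CD1); it makes no claim of physical realism —
no force field is involved anywhere in the fixtures.

# Problem sizes and determinism

The shipped tests run the pipeline at 1,000 frames for recovery tests
(hundreds elsewhere), 100-seed batteries for the stochastic-optimizer
contracts, and a 1° torsion grid for the feasible-region oracle — sizes
chosen so the whole suite completes in a few minutes while keeping every
statistical margin wide. All randomness flows through explicit seeds
(GMM seed 42 by default, one master seed fanning out per-site sub-seeds),
and every generator is a pure function of its parameters and seed.

# Known limitations

- The steric loss is geometry only: no electrostatics, hydrogen bonding
  or torsional strain; "fits" means "packs", not "binds".
- Conformer libraries inherit whatever the input sampling missed;
  the pipeline cannot invent basins it never saw.
- O-glycosylation *occupancy* is not predicted — spatial accessibility is
  not the limiting factor for O-sites, so scanning is N-linked only.
- Protein structures are taken as rigid; mis-modelled sidechains must be
  fixed upstream (or via the amide swap) rather than auto-rotamerized.
- PDB is the only structure dialect (no mmCIF), hydrogens are neither
  placed nor required, and glycans are named by PDB component codes.
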