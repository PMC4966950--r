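---
title: "Methods: trajectory analysis for proteins in crowded environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis for proteins in crowded environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcrowd)
```

## Scope and model of the data

mdcrowd analyses molecular dynamics trajectories of proteins in three
kinds of environments — dilute water, synthetic polymer crowders, and
protein crowders at cell-like concentrations (roughly 80–400 g/L). The
analysis treats a trajectory as per-frame coordinates (nm) with
timestamps (ps) and per-frame **orthorhombic** box edges bound to a
static topology (atom names, elements, masses, residue and molecule
identity). Triclinic boxes are rejected explicitly: orthorhombic
minimum-image arithmetic is exact and covers the standard solvated-box
setups this analysis targets. All readers convert to nm/ps/amu/K on
ingest, so no downstream function takes unit flags.

The package does not run dynamics, evaluate force fields, or predict
disorder; intrinsic-disorder percentages enter the trend analysis as
externally supplied numbers from a sequence predictor.

## The estimators

### Contacts and quinary interactions

A residue pair is in contact in a frame when its Cα–Cα distance is at or
below 0.8 nm. Distances use the minimum-image convention whenever a box
is present — including intra-molecular pairs, so maps are invariant to
periodic re-wrapping of whole molecules (with a 0.8 nm cutoff far below
half a box edge this is exact). Intra-molecular statistics exclude the
sequence-neighbor band |i−j| ≤ 2, which would otherwise be saturated by
trivially satisfied pairs; the exclusion width is a parameter and is
echoed in outputs.

An intra-protein pair counts as **explored** when it is in contact in
strictly more than `min_frames = 5` frames, in absolute frames at the
analysis stride; a pair seen in exactly five frames is not explored.
This strictness matters at the boundary and is pinned by a dedicated
test. The inter-protein share of contacts is computed per frame as
inter/(inter+intra) events and averaged over frames with at least one
contact (empty frames are skipped and counted). Quinary-contact
composition weights each contacting residue by its total contact
occupancy — a contact-time weighting — and reports the chain's sequence
composition as the background. The three residue classes default to
charged = {Asp, Glu, Lys, Arg, His}, polar = {Ser, Thr, Asn, Gln, Cys,
Tyr, Trp}, hydrophobic = the rest; the mapping is overridable and is an
analysis convention, not a claim of physics (histidine sits in the
charged class because of its titratable side chain; the SASA polar
class, by contrast, is defined purely by element).

### GROMOS clustering and conformational changes

Frames are clustered by the greedy neighbor-count rule: the frame with
the most neighbors within the RMSD cutoff becomes a center, it and its
neighbors are removed, and the process repeats. Each pair of frames is
optimally superposed before the distance is taken. Two deliberate
choices make the partition deterministic: ties in neighbor count go to
the lowest frame index, and the pairwise RMSD is computed by a
quaternion characteristic-polynomial method in C++ (the n²/2 pair loop
is the only performance-critical code in the package; a 10⁴-frame
trajectory needs ~5×10⁷ pairwise RMSDs). An independently written R
reference of the same greedy rule is kept in the test suite and the
acceptance script; the two must agree exactly on random frame sets.

The two-step protocol reduces each environment's trajectory at 0.15 nm,
pools the surviving centers with their population weights, and
re-clusters at 0.35 nm; each joint cluster then reports per-environment
occupancy (each environment's weights sum to 1). **Conformational
overlap** between two environments is the sum over joint clusters of the
minimum of their occupancies — 1 for identical occupancy vectors, 0 for
disjoint cluster usage. This min-occupancy form is one defensible
reading of "overlap"; because it is not the only one, the shared-cluster
count is emitted alongside it.

Conformational-change timing clusters the trajectory (default cutoff
0.15 nm; 0.1 nm is the appropriate choice for rigid, well-folded
proteins whose fluctuations never reach 0.15 nm) and counts any change
of label between consecutive frames as a transition; the mean
inter-change time is total duration over transition count, flagged as
undefined when nothing changes.

### Structural descriptors

Superposition is the weighted Kabsch solution via SVD with the
reflection guard (det = +1 enforced), so the reported RMSD is the global
minimum over proper rigid motions. RMSF superposes all frames onto their
**iterated mean structure** (not frame 1) before measuring per-atom
fluctuations — the standard choice, which removes rigid-body tumbling
exactly in the noise-free limit. SASA is Shrake–Rupley with a
deterministic Fibonacci sphere of 960 points (≈1% quadrature error
against analytic spheres and two-sphere caps) over Bondi radii with a
0.14 nm probe; unknown elements get 0.17 nm with a warning. Per residue,
ALL = BB + SIDE and SIDE = POL + APOL hold exactly, with POL = side-chain
O and N atoms only. Whether backbone O/N should count as polar is a
genuine convention choice; the side-chain-only definition is the default
because the decomposition is defined per element over side chains, and
the per-class tables let a user reconstruct the alternative.

Secondary structure is a two-state helix/coil rule, not a STRIDE
reimplementation: with a full backbone, a residue qualifies when φ ∈
[−100°, −30°] and ψ ∈ [−80°, −5°]; with Cα-only models, when the i→i+3
Cα distance falls in [0.49, 0.56] nm; qualifying residues are labelled H
only inside runs of ≥ 4. The crowding analysis consumes helicity
*trends* along the sequence, for which this rule is sufficient and fully
specified; absolute agreement with STRIDE on real proteins is not
claimed, and the limitation is intentional.

### Helix orientation

A helix axis is the first principal axis of its Cα positions, sign-fixed
from N- to C-terminus, with the residue range frozen from the reference
assignment even if the helix partially unfolds. The principal axis of a
*finite* ideal helix is tilted off the geometric axis by an O(1/n²)
angle (≈2.2° at 18 residues) — an intrinsic property of the definition,
not an implementation error — so the pair generator plants its angles in
the frame of the *measured* axis, making planted orientations
recoverable to machine precision at any length. The molecular frame for
(elevation, azimuth) is z = first helix axis, x = the second helix's
component perpendicular to z, y = z × x; the convention id
`"z-h1/x-h2perp"` travels with every output so alternative frames remain
pluggable. At the poles the azimuth is undefined and reported as 0 with
a degeneracy flag.

### Diffusion

MSD uses every stored frame as a time origin (maximal averaging; origin
decorrelation is not enforced, and the per-lag origin counts are emitted
so the user can judge the effective sample size). Input series must be
unwrapped; a jump above half a box edge aborts with a pointer to
`unwrap_series()`. The Einstein fit is a least-squares line over lags in
[10%, 90%] of the window — the window itself (10 ns for water-like
species, 25 ns for proteins in production data; scaled down for
fixtures) is the analyst's choice. A log-log slope outside 1 ± 0.15
raises a poor-linearity diagnostic (ballistic motion gives slope 2), and
a negative fitted slope reports D = 0 with a warning rather than a
negative coefficient. The finite-size correction k_B T ξ/(6πηL) with
ξ = 2.837297 requires a viscosity the trajectory cannot supply, so the
solvent viscosity is an explicit input (default 0.89e-3 Pa·s, water at
300 K) and corrected and uncorrected values are always reported
together.

### Quasi-harmonic entropy

The mass-weighted covariance C = ⟨M^{1/2} Δx Δxᵀ M^{1/2}⟩ is built over
a trailing window of frames (default the second half, mirroring the
common practice of using the equilibrated tail of a production run)
after iterative superposition onto the mean. Superposition leaves six
near-zero rigid-body eigenvalues; the six smallest are dropped, plus
anything below 1e-8 amu·nm², before the harmonic-oscillator entropy sum
is evaluated. "Backbone" defaults to N, Cα, C, O. Entropy differences
between environments carry a block-bootstrap standard error (blocks of
5% of the frames by default) computed by re-estimating the covariance on
resampled frames, which respects the short-time correlation of the
fluctuations. Constants (k_B, ħ, amu, unit bridges) live in one audited
table, `md_constants`; in internal units 1 amu·nm²/ps² = 1 kJ/mol, so
k_B is numerically R/1000.

## The synthetic generators: what they emulate, and what they do not

Each generator plants exactly the statistical feature its estimator
measures, stores the ground truth in a manifest attached to the
trajectory, and is bit-reproducible given (spec, seed) without touching
the global RNG stream:

- `gen_brownian()` — independent Gaussian random walks wrapped into a
  box (displacement variance 2·D·dt per axis): the ground truth for the
  MSD/Einstein machinery.
- `gen_gaussian_ensemble()` — frames whose mass-weighted covariance has
  a planted eigenvalue spectrum in a random orthogonal eigenbasis: the
  end-to-end oracle for the entropy path.
- `build_helix()` / `build_helix_pair()` — ideal α-helical Cα traces
  (radius 0.23 nm, rise 0.15 nm, twist 100°/residue, giving the
  canonical 0.38 nm Cα–Cα and ≈0.505 nm i→i+3 distances) with planted
  relative orientations.
- `gen_random_coil()` — a freely jointed chain (exact 0.38 nm bonds,
  no excluded volume), sampled independently per frame, or by pivot
  Monte Carlo under flat-bottom restraints when contacts are planted
  (onset 0.5 nm, 200 kT/nm², holding planted pairs within the 0.8 nm
  cutoff in ≥95% of frames). The ideal-chain choice keeps closed forms
  available (⟨R_g²⟩ = b²(n²−1)/6n) at the price of polymer realism.
- `gen_two_state()` — a hidden two-state Markov chain (switch
  probability 1/dwell) emitting one of two conformers plus isotropic
  noise below cutoff/4: ground truth for clustering and change timing.
- `build_crowded_box()` — bead chains placed with random positions and
  orientations in a cubic box whose edge is set by mass/volume
  arithmetic to hit a target g/L exactly (110 amu per residue by
  default, an average-residue mass), with a 0.3 nm minimum-image
  overlap threshold.

What passing the recovery tests shows is that the estimators are
*correct*: they return the planted diffusion coefficient within 5%, the
planted entropy within 2%, planted angles within 1° (5° under 0.02 nm
noise), planted contacts at ≥95% occupancy, and exact agreement with the
brute-force clustering reference. What it does not show is realism:
the generators have isotropic Gaussian fluctuations (the quasi-harmonic
assumption made exact), no excluded volume, no solvent, no force field
and no genuine free-energy surface. Conclusions about real crowding data
therefore rest on the estimators' correctness plus the user's judgment
of the simulation, not on these fixtures.

The bundled demo (`make_synthetic_demo()`) builds one 192 g/L crowded
box (eight chains — one ordered helix, six intermediate chains, one
coil, echoing a 6:1:1 hub-protein stoichiometry) and a ten-fold more
dilute reference, and emulates dynamics as per-chain center-of-mass
random walks plus conformer switching whose amplitude and rate grow
with the chain's nominal disorder and shrink under crowding. It is a
smoke fixture for the pipeline, and its trend table is a construction,
not a result about crowding.

## Numerical and design choices

- Pairwise RMSD: Newton iteration on the quartic characteristic
  polynomial of the 4×4 quaternion matrix, started from its upper bound;
  tolerance 1e-12 relative, ≈1e-9 nm agreement with the SVD route.
- GROMOS tie-break: lowest frame index; block structure of the pairwise
  computation cannot change results because the full adjacency is formed
  before the greedy loop.
- SASA coincident-sphere tie-break: a test point exactly on a neighbor's
  surface is buried only when the neighbor has the lower atom index, so
  two coincident identical spheres contribute the union area once.
- Degenerate inputs: zero box lengths, collinear superposition
  references, parallel frame vectors, empty clustering input, zero
  target concentration and infeasible restraint sets all raise immediate
  errors naming the problem; ambiguous unwrapping (a displacement at or
  above half a box edge) warns with the frame index.
- Permutation test for the disorder trend: Spearman ρ per effect
  column, one-sided in the direction of the observed correlation,
  exhaustive over all orderings for ≤6 proteins (so a perfect trend over
  three proteins gives p = 1/6) and 10⁴ seeded shuffles otherwise.
- Analysis frames may be wrapped or whole-molecule: contact analysis is
  wrapping-invariant by construction, and `com_series()` makes molecules
  whole by minimum image before taking centers of mass, so either input
  convention is safe; only MSD requires explicitly unwrapped series.

## Problem sizes in the shipped tests

The suite validates at desk scale, chosen to keep the full run in
minutes while leaving comfortable statistical margins: Brownian recovery
uses 100 particles × 10⁴ steps (three seeds), the entropy oracle 12
modes × 10⁵ frames, the clustering oracle 20 frames × 20 seeds plus one
10⁴-frame two-state trajectory, helix recovery 100 noise seeds, and the
demo pipeline 2 environments × 120 frames × 190 beads. Microsecond-scale
all-atom systems are far larger; the estimators scale as the pairwise
loops indicate (clustering is O(n² · atoms), SASA O(frames · atoms ·
neighbors · points)), and the clustering core is the piece engineered
for that load.

## Known limitations

Orthorhombic boxes only; Cα-based contacts (no heavy-atom or salt-bridge
typing); a two-state secondary-structure rule rather than a full
assignment method; no rotational diffusion or Green–Kubo route; no
anharmonic or mutual-information corrections to the entropy; the
energy-decomposition analysis that requires force-field terms is out of
scope by design. The min-occupancy overlap and the side-chain-only polar
SASA convention are documented choices among defensible alternatives,
and both emit enough raw material to recompute the alternatives.
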