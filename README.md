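# mdcrowd

Analysis of molecular dynamics trajectories of proteins in **crowded
environments** — the cell-like regime of 80–400 g/L macromolecule
concentration where excluded volume and weak, transient (quinary)
protein–protein contacts compete to reshape protein structure, dynamics
and thermodynamics. The package targets the comparative setting in which
the same proteins (ordered, molten-globule and intrinsically disordered)
are simulated in water, in a synthetic crowder, and in protein crowders,
and the analyst asks how each environment shifts compactness, secondary
structure, contact networks, conformational entropy and diffusion.

Every estimator ships with a seeded synthetic-trajectory generator that
plants the quantity being estimated, so the whole toolchain is validated
by parameter recovery rather than by eye.

## What it computes

- **Contacts** — Cα contact maps at a 0.8 nm cutoff with minimum-image
  periodic boundaries; "explored" contacts (pairs seen in strictly more
  than 5 frames); the per-frame fraction of contacts that are
  inter-protein; quinary-contact composition over
  hydrophobic/polar/charged residue classes; native-contact overlap and
  signed contact-difference maps between environments.
- **Clustering** — the GROMOS greedy neighbor-count algorithm on pairwise
  optimal-superposition RMSD (C++ core, quaternion characteristic-
  polynomial RMSD), the two-step protocol (per-trajectory reduction at
  0.15 nm, pooled re-clustering at 0.35 nm), per-environment cluster
  occupancy and conformational overlap, and conformational-change timing
  (any cluster change between consecutive frames is a transition).
- **Descriptors** — Kabsch superposition and RMSD series, radius of
  gyration, RMSF about the iterated mean structure, Shrake–Rupley SASA
  with the ALL/BB/SIDE/POL/APOL decomposition (side-chain O and N are
  polar), a simple helix/coil secondary-structure rule, and 2-D sampling
  maps (e.g. RMSD vs R_g).
- **Helix geometry** — helix axis vectors as Cα principal axes and the
  relative (elevation, azimuth) of helix pairs in a molecular frame,
  with orientation frequency maps.
- **Dynamics** — center-of-mass MSD over all time origins, the Einstein
  relation `MSD(τ) = 6 D τ`, and the Yeh–Hummer finite-size correction
  `D₀ = D_PBC + k_B T ξ / (6 π η L)`, ξ = 2.837297.
- **Entropy** — quasi-harmonic conformational entropy from the
  mass-weighted covariance of superposed fluctuations:
  `S = k_B Σᵢ [ xᵢ/(e^{xᵢ}−1) − ln(1−e^{−xᵢ}) ]` with
  `xᵢ = ħωᵢ/k_BT`, `ωᵢ = sqrt(k_BT/λᵢ)`, plus block-bootstrap
  uncertainties on entropy differences between environments.
- **Pipeline** — `run_pipeline()` orchestrates all stages over a set of
  environments and aggregates, per protein, the crowding effects
  (% inter-protein contacts, ΔS vs water, Δ explored contacts, RMSF,
  time between conformational changes) into a trend table tested for
  rank correlation with intrinsic disorder (exact permutation p-values).

Internal units are nm, ps, amu and kelvin throughout; residue numbers are
0-based internally and 1-based in every report.

## Worked example

Recover a planted diffusion coefficient from a Brownian box and apply the
periodic-box correction:

```r
library(mdcrowd)

tr <- gen_brownian(n_particles = 100, D = 1e-3, dt = 1, n_steps = 10000,
                   seed = 42)
coms <- lapply(seq_len(n_atoms(tr)), function(i) tr$xyz[, (3*i-2):(3*i)])
unwrapped <- lapply(coms, unwrap_series, boxes = tr$boxes)
curve <- msd(unwrapped, times = tr$times, window = 100)
est <- einstein_diffusion(curve)
#> D = 0.001004 nm^2/ps (1004 um^2/s), R^2 = 1.0000
finite_size_correction(est$D_um2_s, temperature = 300,
                       viscosity = 0.89e-3, box_edge = 10)
#> $D_corrected 1074.3   $correction 70.1   (um^2/s)
```

The estimate lands within 0.4% of the planted 1e-3 nm²/ps; the correction
term is the analytic `k_B T ξ/(6πηL)` for a 10 nm cubic box of water.

Contact analysis on a freely jointed Cα coil with one planted contact:

```r
planted <- gen_random_coil(50, 200, planted_pairs = rbind(c(5, 40)), seed = 1)
cm <- contact_map(planted, 1, cutoff = 0.8)
cm$occupancy[5, 40]
#> 1.000                      # the restrained pair stays in contact
explored_contacts(contact_map(gen_random_coil(50, 30, seed = 1), 1))
#> $count 533  $possible 1128  $fraction 0.473
```

A 50-residue ideal chain explores 47% of its possible long-range pairs
(|i−j| > 2) in more than five of 30 frames — the "explored contact"
statistic that drops under crowding as the conformational search slows.

The quasi-harmonic entropy of a single mode at `ħω = k_B T`:

```r
quasiharmonic_entropy(md_constants$hbar^2 / (md_constants$kB * 300), 300)
#> Quasi-harmonic entropy: 1.0407 kB (8.652 J/(mol K)) over 1 modes at 300 K
```

The full pipeline on the bundled synthetic crowded box (eight chains at
192 g/L plus a dilute reference):

```r
demo <- make_synthetic_demo(seed = 1)
res <- run_pipeline(demo, "demo_out", seed = 1)
res$trend_table   # one row per protein: disorder %, inter-protein %,
                  # dS vs water, d explored %, RMSF, change time
```

File-based studies use the same pipeline through a YAML configuration
(`load_analysis_config()`) or the wrapper script
`inst/scripts/run_pipeline.R`.

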