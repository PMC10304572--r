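# dyeaggr

Geometric analysis of counterion-dependent aggregation of cationic xanthene
dyes (rhodamine B ethyl ester and relatives) in molecular trajectories.

Cationic dyes paired with bulky hydrophobic anions (tetraarylborate types)
self-assemble in water into aggregates in which the counterion acts as a
spacer: dyes sit close enough for energy transfer, but the cofacial H-dimers
that quench fluorescence stay rare. With small anions (iodide) the dyes stay
dispersed. Whether a dye pair is benign or quenching is a question of
geometry, and `dyeaggr` answers it per frame, for every pair:

* **Dimer classification.** Each dye's xanthene plane defines a local frame
  (centroid, best-fit plane normal, long axis = transition-dipole proxy). A
  pair is *interacting* when the center distance r<sub>CC</sub> < 6 Å;
  interacting pairs are **crossed-J** when the long-axis angle θ ≥ 12°, and
  otherwise split into **H** (α > 54.7°, the magic angle arccos(1/√3)) and
  **J** (α ≤ 54.7°), where α is the angle between the center line and the
  mean long axis.
* **π-stacking detection** from lateral offsets (r<sub>x</sub> < 4 Å,
  r<sub>y</sub> < 2 Å in the base molecule's frame) plus all four of the
  partner's probe atoms within 4.5 Å of the base plane.
* **Aggregation metrics.** Per-frame dimer counts by class, the sum of all
  dye–dye center distances (drops when large aggregates form), contact-graph
  clusters ("full aggregate" = all dyes in one component), 0.1 ns block
  averages, and tail-averaged radial distribution functions.
* **Nonbonded energetics.** AMBER-convention Coulomb + Lennard-Jones
  rigid-dimer energies, approach scans ΔE(r<sub>CC</sub>) = E(r<sub>CC</sub>)
  − E(40 Å), selective ε-scaling of the xanthene atoms only, and recovery of
  the ε scale factor from a reference (e.g. DFT) curve.
* **Torsion refitting.** Linear least-squares fitting of AMBER cosine-series
  dihedral terms (Σ (V<sub>n</sub>/2)(1 + cos(nφ − γ<sub>n</sub>)),
  γ ∈ {0°, 180°}) to reference scans, judged to 0.2 kcal/mol inside the
  minima regions.
* **Synthetic generator.** A seeded rigid-body Monte Carlo stand-in for the
  reference MD conditions (10 dyes + 10 counterions, 85 Å periodic box) with
  a counterion toggle: `bulky_hydrophobic` drives full aggregation,
  `small_ionic` leaves dyes dispersed.

Everything takes and returns tidy tables: trajectories are tibbles (one row
per atom per frame), classification and stats verbs return tibbles, fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Classify a planted dimer, scan the dimer approach energy before and after
doubling the xanthene ε, and refit a three-well torsional profile:

```r
library(dyeaggr)
topo <- template_topology()

# a parallel dimer 4 A apart with its center line 75 degrees off the long axis
classify_frame(make_planted_dimer(theta = 5, alpha = 75, rcc = 4), topo)
#>   mol_a mol_b   rcc theta alpha interacting geometry_class stacked
#> 1     1     2     4  5.00    75 TRUE        H              TRUE

# dimer approach curve of the toy dye (charges scaled to 0.25):
# a Coulomb barrier, then a van der Waals well that deepens when the
# xanthene epsilons are doubled
mol <- dye_nonbonded_table(charge_scale = 0.25)
d <- seq(3.2, 40, 0.1)
dplyr::bind_rows(
  glance(scan_pes(mol, mol, c(0, 0, 1), d, scale_factor = 1)),
  glance(scan_pes(mol, mol, c(0, 0, 1), d, scale_factor = 2)))
#>   well_depth barrier_height r_min_location reference_distance scale_factor
#> 1      -8.69           1.30            3.5                 40            1
#> 2     -17.6            1.14            3.5                 40            2

# refit the packaged three-well dihedral scan with a cosine series up to n = 4
ref <- read_torsion_csv(system.file("extdata",
        "torsion_scan_3well_synthetic.csv", package = "dyeaggr"))
fit_torsion(ref, torsion_profile(ref$angle, rep(0, 36)), max_n = 4)
#> <torsion_fit> 4 cosine term(s), offset -0.1127 kcal/mol
#>   n = 1: V = 0.4000 kcal/mol, gamma = 0 deg
#>   n = 2: V = 0.0000 kcal/mol, gamma = 180 deg
#>   n = 3: V = 2.0000 kcal/mol, gamma = 180 deg
#>   n = 4: V = 0.0000 kcal/mol, gamma = 0 deg
#>   max deviation: 0.0473 (minima regions), 0.0473 (global) kcal/mol
#>   converged (<= 0.2 kcal/mol in minima): TRUE
```

The classification recovers the planted geometry exactly; the well depth
roughly doubles (−8.69 → −17.6 kcal/mol) when the xanthene ε is doubled
while the Coulomb barrier barely moves, which is the mechanism the ε-refit
procedure exploits; and the torsion fit recovers the underlying n = 1 and
n = 3 terms with the residual 0.047 kcal/mol coming from a deliberate
out-of-basis perturbation in the fixture.

A full pipeline run — simulate, analyze, plot — is three calls:

```r
sim <- run_simulation(synthetic_config(seed = 1), out_dir = "run1")
res <- run_analysis("run1/trajectory.pdb", "run1/topology.yaml", out_dir = "run1")
plot_aggregation(res$stats, window = 0.1)
```

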