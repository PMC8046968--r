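# fibrilstats

Quantitative in-situ analysis of amyloid fibril inclusions from segmented
cryo-electron tomograms.

Intracellular inclusions of aggregation-prone proteins such as
α-Synuclein are meshworks of amyloid fibrils crisscrossing cellular
organelles inside a thin (~100–200 nm) lamella milled out of a vitrified
cell. Two questions drive their quantitative analysis: *what are the
fibrils like* (length, abundance, stiffness), and *do they interact with
the surrounding membranes, or merely crowd them*? `fibrilstats`
implements both halves for the standard annotation products — an integer
organelle label volume (MRC2014) plus traced fibril centerlines (CSV or
legacy VTK polylines) — and ships a synthetic scene generator so every
stage is testable without tomographic data.

## What it computes

- **Morphometrics** — fibril lengths; cytosolic fibril density, the
  fraction of cytosolic volume (X·Y extent × lamella thickness, minus
  organelle lumina) occupied by fibrils modelled as cylinders of radius
  *r* = 5 nm; gold-label periodicity in β-strand units (bead spacing /
  4.8 Å).
- **Mechanics** — persistence length from the worm-like-chain tangent
  correlation ⟨cos(θ₀ − θ_l)⟩ = e^(−l/Lp), fitted as a linear model on
  log mean cosine; Young's modulus E = Lp·k_B·T / I with I = πr⁴/4
  (solid rod, T = 295 K).
- **Spatial statistics** — exact Euclidean distance transform of the
  membrane voxels; per-point fibril→membrane distances; inter-membrane
  nearest distances between different organelles; normalized distance
  profiles with median and 5–95% bands.
- **Null model** — a Monte-Carlo ensemble (default 200 simulations) that
  rigidly re-places each fibril with a uniform 3D rotation and an
  in-bounds uniform translation, rejecting placements inside organelle
  lumina; close contacts (< 20 nm) are compared between experiment and
  null by a two-tailed Kolmogorov–Smirnov test on per-fibril minimum
  distances.
- **Condition-level reporting** — pooled length histograms, one-way
  ANOVA of per-tomogram densities across conditions, JSON/CSV outputs
  stamped with a configuration hash and seed.

## Worked example

Simulate an inclusion-like scene (four spherical organelles, 40
worm-like-chain fibrils with planted Lp = 1000 nm in a 400 × 400 × 150 nm
lamella) and run the full analysis:

```r
library(fibrilstats)

sp  <- scene_spec(extent_nm = c(400, 400, 150), voxel_size = 5,
                  organelles = replicate(4, list(shape = "sphere", radius = 30),
                                         simplify = FALSE),
                  n_fibrils = 40, L_p = 1000, rng_seed = 1)
gen <- generate_scene(sp)

cytosolic_fibril_density(gen$scene, gen$fibrils)
#> density_result: 40 fibrils, density 3.179e-02 (fibril 7.485e+05 / cytosol 2.355e+07 nm^3)

fit <- fit_persistence_length(
  tangent_correlation(gen$fibrils, step = 5, max_sep = 300))
fit
#> persistence_fit: L_p = 1082 nm (95% CI 1053-1113), E = 8.98e+06 Pa
#>   fit over 60 bins (0 excluded), slope -0.000924, intercept 0.00788

field <- membrane_distance_field(gen$scene)
dd    <- fibril_membrane_distances(gen$fibrils, field)
ne    <- null_ensemble(gen$scene, gen$fibrils, n_simulations = 200,
                       seed = 1, field = field)
exp_min <- tapply(dd$distance_nm,
                  factor(dd$fibril_id, levels = unique(dd$fibril_id)), min)
ks_compare(as.numeric(exp_min), as.numeric(ne$per_fibril_min))
#> ks_result: D = 0.202, p = 0.423 (cutoff 20 nm; n = 19 vs 2747)
```

Reading the numbers: the density (3.2% of cytosolic volume) and the
recovered persistence length (1082 nm against the planted 1000 nm, E ≈
9 MPa) describe the fibril population; the KS p = 0.42 says the observed
frequency of close fibril–membrane contacts is indistinguishable from
the rigid-motion null — as it must be here, since the generator placed
fibrils with no membrane interaction. Planting an attraction
(`attraction_strength = 0.9, attraction_range_nm = 20`) drives the
experimental sub-20 nm contact mass above the null's 95th percentile.

`run_pipeline()` composes all stages over conditions of tomograms and
writes CSV/JSON reports; the same pipeline is scriptable from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fibrilstats.R", package="fibrilstats"))')" \
    all --scene labels.mrc --fibrils fibrils.csv --seed 1 --out-dir out/
```

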