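---
title: "Methods: fibril morphometrics and membrane-contact statistics in segmented tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibril morphometrics and membrane-contact statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilstats)
```

# Scope and data model

`fibrilstats` quantifies the architecture of intracellular amyloid
inclusions from the two products of cryo-electron tomogram annotation: an
integer *label volume* in which voxel value 0 is cytosol and each value
`k >= 1` marks the lumen of one organelle, and a set of *fibril
centerlines*, ordered 3D polylines traced through the fibril density. The
package does not touch raw tomographic density; segmentation and filament
tracing are upstream and their parameters are only recorded as provenance
in the run configuration.

All internal lengths are nanometres. MRC headers carry Angstrom cell
dimensions, divided by 10 on read. Voxel indices are 0-based and world
positions sit at voxel centers, `world_nm = index * voxel_size`, so
distance-field values, membrane point sets and fibril coordinates share
one frame. Anisotropic voxels are rejected rather than averaged because
the Euclidean distance transform assumes an isotropic metric.

Membranes are represented as the 26-connected boundary voxels of each
lumen label. Deriving membranes from lumina keeps synthetic fixtures
self-consistent; an explicit membrane point set, when supplied, takes
precedence.

# Morphometrics

**Length.** The arc length of a polyline is the sum of consecutive
segment norms.

**Cytosolic fibril density.** The imaged cell volume is the X-Y grid
extent times the lamella thickness (the thin slab produced by
focused-ion-beam milling, typically 100-200 nm). Cytosolic volume
subtracts the labelled lumina (voxel counts times `voxel_size^3`); only
lumina are subtracted, not the membrane voxels themselves, which are a
single-voxel shell and below the discretization error of the label
volume. Fibril volume approximates each fibril by a solid cylinder of
radius 5 nm (the fibril radius observed at ~10 nm diameter), summed
linearly without overlap de-duplication: at observed densities of order
10^-3 the expected crossing volume is negligible, and the per-fibril
cylinder sum is the convention the density is defined by.

**Gold-label periodicity.** Gold beads coupled to a seed fibril sit every
`k`-th beta-strand; with the ~4.8 Angstrom axial strand repeat of the
amyloid fold, `k = mean bead spacing / 4.8`. The function is plain
arithmetic; the synthetic fixture generator plants `k`, jitter and the
repeat so the inversion is testable.

# Persistence length and Young's modulus

For a worm-like chain, the expectation of the cosine of the angle between
tangents separated by arc length $l$ decays as

$$\langle \cos(\theta_0 - \theta_l) \rangle = e^{-l/L_p},$$

with $L_p$ the persistence length. The estimator:

1. resample every fibril at a uniform arc-length step (default 5 nm;
   sub-voxel steps add no information and the step is far below reported
   $L_p$);
2. estimate unit tangents by central differences (one-sided at the two
   ends);
3. pool, across all fibrils of a condition, the cosines for every ordered
   point pair with separation up to `max_sep`, binned at the step width;
4. fit `log(mean_cos)` against $l$ by unweighted linear least squares
   with a **free intercept**; $L_p = -1/\mathrm{slope}$.

The intercept is left free because tangent smoothing by the central
difference and tracing noise multiply the correlation by a constant; a
free intercept absorbs that factor and leaves the slope unbiased, whereas
forcing the line through zero would not. Bins with non-positive mean
cosine (whose logarithm is undefined) are excluded and reported. The 95%
confidence interval is propagated from the slope's standard error; the
slope interval itself is also reported, since it is ambiguous which scale
a "CI from a linear fit" lives on. Correlations are pooled per condition
before fitting: per-fibril fits are unstable at typical ~250 nm lengths.
The fit window should scale with the decay length (the acceptance tests
use `max_sep = min(500, 2 L_p)` nm); far beyond $L_p$ the mean cosine is
noise around zero and its logarithm degrades an unweighted fit.

Equation 1 is applied to 3D tangent angles with decay `exp(-l/L_p)` as
written, with no 1/2 projection factor: the centerlines are traced in 3D.

The Young's modulus follows from

$$E = \frac{L_p k_B T}{I}, \qquad I = \frac{\pi r^4}{4},$$

treating the fibril as a solid rod of radius $r$ = 5 nm at $T$ = 295 K
with $k_B$ = 1.380649e-23 J/K. For $L_p$ = 1 um this evaluates to
8.30e6 Pa, which the test suite asserts against an independent closed-form
computation.

# Distance fields and spatial statistics

**Fibril-membrane distance.** The exact Euclidean distance transform
(Felzenszwalb-Huttenlocher lower-envelope construction, compiled code) of
the union of membrane voxels gives the nearest-membrane distance at every
voxel center. Each fibril, resampled at the voxel size, contributes one
distance per point by trilinear interpolation of the field. Distances are
measured from the centerline to membrane voxel centers; neither the 5 nm
fibril radius nor half the membrane thickness is subtracted, because the
statistic is defined on points of the fibril, and any constant offset
cancels in the experiment-vs-null comparison.

**Inter-membrane distance.** For each organelle, the distance transform
of the union of all *other* organelles' membrane voxels is evaluated at
the organelle's own membrane voxels. At voxel centers this is exact, and
it is verified against a brute-force pairwise scan on small scenes.

**Profiles and bands.** Distance samples are binned at 2 nm over
0-200 nm (resolving the 20 nm contact zone into 10 bins) and normalized
to sum to one; values beyond the range are clamped into the last bin and
counted. Across tomograms or simulations the per-bin median and the 5th
and 95th percentiles form the summary band.

# The rigid-motion null model

The null hypothesis is that fibrils and membranes are mutually
indifferent: any apparent contact enrichment is what crowding alone would
produce. Each simulation gives every fibril, independently, a uniform
random rotation about its centroid (uniform over SO(3) via a uniform
quaternion; an `in_plane` switch restricts rotation to the Z axis if the
slab geometry is considered constraining) and a uniform translation among
those that keep all points inside the volume. Placements putting any
point inside a lumen are rejected and redrawn (fibrils are cytosolic);
fibril-fibril crossings are permitted, since self-avoidance of the
reference procedure is unspecified and its effect on nearest-membrane
distances is second-order. Shape and length are preserved exactly, which
the tests assert via invariance of lengths and tangent correlations.

Each of the default 200 simulations re-samples the fibril-membrane
distances against the fixed membrane field and bins them. All randomness
derives from one master seed through deterministic per-simulation
substreams, so ensembles are reproducible and independent of evaluation
order.

**Close-contact test.** The contact statistic is the mass of the distance
distribution below the 20 nm cutoff, compared by a two-sample, two-tailed
Kolmogorov-Smirnov test on samples truncated to [0, 20] nm. The KS input
is the *per-fibril minimum* distance, not the pooled point-wise sample:
points a few nanometres apart along one fibril are strongly correlated,
and a KS test that treats thousands of such points as independent
rejects far above its nominal level. Fibrils are independent under the
null, so per-fibril minima form an honest sample; with that choice the
self-calibration criterion (data generated by the null, rejection rate ~
5% at alpha = 0.05) holds, which the acceptance suite verifies over 200
replicate scenes. Histograms and bands still use every point, as the
distance profiles are defined point-wise. No multiple-testing correction
is applied across the KS/ANOVA family; output metadata states this.

**Condition-level statistics.** Per-tomogram densities are compared
across conditions by one-way ANOVA, with pairwise Welch t-tests reported
alongside and labelled as such, since the post-hoc convention behind
printed pairwise p-values is not standardized.

# The synthetic world

The generator produces the *analysis products* the pipeline consumes, not
images: no tomographic image formation, missing wedge, noise, membrane
bilayer separation, or tracing-error model. A green test therefore
establishes the correctness of the measurement and inference machinery on
scenes whose ground truth is known, not robustness to segmentation or
tracing artifacts.

Defaults state the emulated world: a 400 x 400 x 150 nm lamella at 5 nm
voxels; spherical, ellipsoidal or tube-shaped organelles placed without
overlap, uniformly or clustered to a planted surface gap; worm-like-chain
fibrils with target $L_p$ 1 um (within the 0.1-10 um range of interest)
and log-normal lengths with mean 250 nm (`sdlog` 0.4) truncated below at
the 100 nm tracing minimum. The log-normal shape matches the
right-skewed length histograms such tracing produces; the exact form is a
pragmatic choice, not a claim about any dataset. Lengths are additionally
truncated above at 0.8 x the box diagonal so a stiff fibril can be placed
under some rotation, mirroring the clipping of traced filaments at the
field of view.

**WLC sampler.** Each step deflects the tangent by a polar angle with
uniform azimuth. The polar angle follows a von Mises-Fisher distribution
whose concentration solves the Langevin equation
$\coth\kappa - 1/\kappa = e^{-\mathrm{step}/L_p}$, making the per-step
mean cosine exactly `exp(-step/L_p)`. Azimuthally symmetric deflections
compound multiplicatively in their mean cosine, so the ensemble decay is
exact at every lag. The more common Gaussian small-angle sampler has the
same limit but a stiffness bias of order `(step/L_p)^2`, about +10% at
`L_p` = 100 nm with a 5 nm step - large enough to matter against a 15%
recovery criterion, which is why the exact sampler is used.

**Planted membrane attraction.** With attraction strength $s$ and range
$a$, candidate fibril placements whose minimum membrane distance exceeds
$a$ are accepted only with probability $1-s$; placements inside the range
are always accepted. This enriches close contacts monotonically in $s$
(paired-seed tests verify the direction), giving the power benchmark for
the null-model comparison a known effect to detect.

# Numerical choices and degenerate inputs

- Resampling preserves both endpoints; the trailing segment may be
  shorter than the step, and the tangent-correlation code drops the final
  point when it is. Resampling an already-uniform polyline is a no-op
  (idempotence), detected with a relative tolerance of 1e-5 that absorbs
  chord-versus-arc error.
- A resampling step at or beyond the fibril length degrades to the
  two-point endpoint fibril, with a warning.
- The distance transform treats out-of-volume space as unknown, not
  background: boundary voxels at the volume face count as membrane
  boundary (their outside neighbourhood is unobserved).
- KS comparisons use the asymptotic two-sample p-value; truncation counts
  on both sides are reported. An empty truncated sample is an error, not
  a silent p = 1.
- ANOVA on groups that are all identical constants is an error
  (zero-variance F is undefined) rather than NaN.
- Seeds derive from a Lehmer-style mix modulo 2^31 - 1 so every derived
  seed remains a valid 32-bit `set.seed()` input.

# Known limitations

- Membrane points are voxel centers; sub-voxel membrane geometry is not
  modelled. All distance statements carry half-voxel-scale
  discretization, which the oracle-equivalence tests bound at half a
  voxel diagonal.
- The per-fibril-minimum KS input is this package's resolution of an
  ambiguity in the reference procedure; absolute p-values from other
  choices of test input are not comparable.
- The null permits fibril-fibril overlap and confines placements to the
  full slab; whether the reference null forbade either is unknown, so
  both choices are stated in output metadata rather than assumed.
- Persistence-length CIs from the pooled fit understate uncertainty when
  few fibrils dominate the pooling; bootstrap over fibrils would be the
  next step and is out of scope.
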