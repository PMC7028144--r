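---
title: "Dissecting root growth into cell production and cell elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting root growth into cell production and cell elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkin)
library(dplyr)
```

## The model

A growing root apex is treated as a one-dimensional continuum along the
distance `x` (µm) from the quiescent centre (QC). Tissue at position `x`
moves shootward at velocity `v(x)` (µm/h); its spatial derivative is the
relative elemental growth rate (REGR, or strain rate) `r(x) = dv/dx` (1/h).
Cells proliferate in the meristem (`0 ≤ x ≤ Lm`) and expand post-mitotically
in the rapid-elongation zone (`Lm < x ≤ Lg`); beyond `Lg` growth has ceased,
tissue moves at the constant final velocity `V` (the root elongation rate)
and cells are at their mature length.

Three conservation relations connect what can be measured to what one wants
to know, all assuming the growth zone is at steady state over the
observation interval:

* **Cell flux** `F(x) = v(x) / ℓ(x)`, the number of cells per file passing
  `x` per hour, is constant beyond the meristem and equals the **cell
  production rate** `P = V / ℓ_mature`.
* **Cell-cycle duration** under steady exponential proliferation of `N`
  meristematic cells is `Tc = ln(2) · N / P`.
* The **elongation-zone transit time**, the average time a cell spends
  expanding, is `tₑ = ∫ dx / v(x)` across the elongation zone.

`rootkin` implements the full chain from raw observations to these
quantities, plus the static (micrograph-based) segmentation of cortical
cell-length profiles, ploidy-class quantification from flow-cytometry
DNA-content intensities, and the group statistics used to contrast
genotypes. A steady-state simulator generates all three observation kinds
with known ground truth, so every estimator in the package is validated by
parameter recovery.

## The simulator

`growth_zone_spec()` fixes a meristem of length `Lm` with constant strain
rate `r_m` and constant cell length `l0` (divisions hold cell length at
`l0`; the rising flux implies the division activity), and an elongation-zone
strain-rate bump integrating to `A_e` (µm/h), by default a raised cosine
(smooth and unimodal, the shape REGR profiles show in practice) with a
rectangular option retained for closed-form checks. Everything else follows:
`V = r_m·Lm + A_e`, `P = r_m·Lm / l0`, `ℓ_mature = V/P`.

```{r spec}
spec <- growth_zone_spec(
  meristem_length = 500, initial_cell_length = 10,
  meristem_strain_rate = 0.04, elongation_zone_length = 400,
  elongation_strain_integral = 280
)
glance(spec)
```

Observation models:

* `simulate_particles()`: surface particles start uniformly over the domain,
  are advected for `dt` hours along `v(x)` (4th-order Runge-Kutta, 100
  steps), and both endpoint positions carry additive Gaussian error
  (instrument-scale, so additive).
* `simulate_cell_file()`: cells tile the axis from the QC outward. Each
  cell's noiseless length is consistent with the length field at its own
  midpoint (the fixed point of `l = ℓ(x + l/2)`), which makes the discrete
  file conserve flux exactly: `v/l` at cell midpoints equals `P` beyond the
  meristem. Biological length variation scales with size, so noise is
  multiplicative lognormal with a given CV (log deviates truncated at ±3
  sd). Files extend until six cells lie wholly beyond the growth zone.
* `simulate_ploidy()`: nuclei draw a class from {2C,…,32C} and an intensity
  `anchor · (C/2) · e^η`, `η` lognormal with a given CV — the geometric
  ladder a DNA-content histogram shows.

Defaults used throughout the validation suite are the study conditions the
estimators are meant for: 10 roots per cohort, 40 particles per root
observed over 1 h with 5 µm position noise, 5% cell-length CV, and ploidy
samples of 10 000 nuclei with 5% intensity CV, six pooled samples per
genotype. What the simulator deliberately does *not* model: individual
division events (cell lengths in a real meristem cycle between birth and
division length), time-varying growth, curvature or lateral roots, and
cytometry debris/doublets. Passing recovery tests therefore demonstrates
correctness of the estimators under the steady-state model, not robustness
to every artefact of real material.

## Velocity-profile estimation

Each particle yields a raw point: the secant velocity
`(x_end − x_start)/dt`. Because `dt = ∫ dx/v` along the path, that value is
the *harmonic spatial mean* of `v` over the traversed interval — over one
hour a fast particle crosses hundreds of µm, so assigning the value to the
displacement midpoint is biased wherever the velocity curves. The estimator
therefore:

1. fits the raw points at their midpoints by local quadratic kernel
   regression (Gaussian kernel scaled so ±`bandwidth` covers ~95% of the
   kernel mass; default bandwidth 50 µm, grid step 1 µm);
2. applies a **secant correction** (2 passes by default): each working value
   is rescaled by the ratio of its observed secant velocity to the secant
   velocity the current fit predicts over the same interval, and the fit is
   repeated. A fit that reproduces every observed secant — in particular the
   true field on noiseless data — is a fixed point;
3. projects the grid onto the nearest non-decreasing sequence
   (pool-adjacent-violators via `stats::isoreg`) and clamps at zero, since
   steady-state tissue can only speed up shootward.

Two numerical safeguards: the bandwidth has a nearest-neighbour floor
(locally widened to the 3rd-nearest distinct midpoint) so the quadratic
stays determined across coverage gaps, and kernel weights are normalised per
grid point to avoid underflow far from data (the local intercept is
invariant to that rescaling).

## Zone boundaries: the 95%-of-plateau rule

Both boundaries use the same plateau rule: scanning shootward, the boundary
is the **first grid point whose value reaches 95% of the mean of the
remaining, more distal values** — applied to the flux `v̂/ℓ̂` for the
meristem boundary `L̂m`, and to `v̂` itself for the growth-zone boundary
`L̂g`. The candidate point is excluded from the "remaining" mean
(configurable), the scan is restricted to the occupied grid below 99% of the
maximum velocity plus one plateau point, boundaries are reported at grid
resolution, and a series that never qualifies raises a boundary-not-found
error rather than silently returning the last point. The flux uses a
cell-length field linearly interpolated from the paired file's cell
midpoints; grid points without coverage are excluded.

One property of this rule matters for interpretation: on a smooth profile it
returns the point where the curve *reaches 95% of its plateau*, which is
systematically tipward of the true boundary (for the reference zone, ~475 µm
against a true 500 µm). Recovered boundaries and the transit time inherit a
bias of this order; the validation suite checks recovery at the 10-15%
level, which this rule meets under the study conditions. Roots whose
particles all sit in the plateau yield a final velocity but a
boundary-not-found note for `L̂m`, reported per root without aborting the
batch.

Downstream scalars: `P̂ = V̂/ℓ̂_mature`; `N̂` is the number of cells of the
paired file whose midpoints lie within `L̂m` — the kinematic count, matching
how the meristem cell number is defined in this framework (the static
doubling-rule count is the fallback when no boundary is available);
`T̂c = ln 2 · N̂/P̂`; `t̂ₑ` integrates `1/v̂` between the boundaries exactly,
segment by segment of the piecewise-linear profile.

## Static segmentation of cell-length profiles

Two literal rules, applied to raw lengths (no pre-smoothing, matching manual
practice; a 3-cell running-median pre-filter for detection is available but
off by default):

* **Elongation onset**: the first cell at least twice as long as its
  predecessor *and* followed by a longer cell (the second clause skips
  recently divided cells). The last cell can never qualify.
* **Maturation onset**: the first later cell whose successor is within a
  ratio tolerance `tol` of its own length, with at least five cells
  remaining; "approximately the same length" is made precise as `tol`,
  default 0.05, since no number is standard.

The mature cell length is the mean of the first five mature-zone cells; the
meristem length is the summed length of the cells before the onset plus the
declared QC offset (cell files start at the cortex/endodermis initial, not
the QC; the offset defaults to 0 and is a declared input). Left and right
files of a seedling are averaged; a file the rules cannot segment is
reported with its failure reason and the seedling flagged partial.

A caveat the validation makes explicit: under the steady-state simulator the
length field is *continuous* at the meristem exit (`ℓ(Lm) = l0` because
`P = r_m·Lm/l0`), so successive noiseless simulated lengths never double at
the true boundary; at the reference parameters the per-cell ratio peaks
around `e^{r/P} ≈ 2` near the REGR maximum, far shootward of `Lm`. The
doubling rule is an operational definition built for real profiles, whose
sharp transitions come from division dynamics the simulator deliberately
omits. Exactness of the detectors is therefore unit-tested on hand-built
sharp-transition profiles, while the simulator-based acceptance check of
exact zone recovery records this tension by failing — a documented model
property, not an implementation defect. The kinematic pipeline is immune to
it because its meristem cell count is kinematic (previous section).

## Ploidy quantification

Interactive gating is replaced by a deterministic, reproducible procedure:
the 2C anchor is the lowest mode of a kernel density estimate of
log2-intensity whose density exceeds 10% of the global maximum (supply the
anchor explicitly for samples without a clear 2C population); each nucleus
gets class index `round(log2(I/anchor))` clipped to 2C-32C. Classification
is scale-invariant, and with class spacing 1.0 on the log2 scale against a
noise sd of `log2(e)·√(ln(1+cv²))` ≈ 0.072 at cv = 0.05, misclassification
is negligible below cv ≈ 0.10. Genotypes are contrasted per class by Welch
t-tests on per-sample proportions; raw p-values by default (as these
figure-level contrasts are usually reported), Benjamini-Hochberg optional.
Debris/doublet exclusion is out of scope; min/max intensity gates are
exposed for real data.

## Group statistics and pipeline

`welch_t()` (unequal-variance, Satterthwaite df; the variant is logged in
the run manifest since plain "t-test" is ambiguous) and `anova_tukey()`
(one-way ANOVA with Tukey HSD via the studentized range) wrap the standard
`stats` machinery behind tidy interfaces; degenerate constant-data cases
return the conventional limits (p = 1 for identical constant groups).
`run_pipeline()` executes simulate → static-profile → kinematics → ploidy →
compare from a flat YAML config (unknown keys rejected by name), writes all
tables as UTF-8 CSV with units embedded in column names, and emits a
manifest (config echo, seed, versions, rule-interpretation flags) from which
a run can be reproduced byte-identically.

```{r pipeline, eval = FALSE}
res <- run_pipeline(system.file("extdata", "demo-config.yaml",
                                package = "rootkin"),
                    out = tempfile("rootkin-demo"))
res$kinematics
```

## Numerical choices and degenerate inputs

* Randomness: one integer seed per simulation call; cohort members use
  deterministic per-root substreams, so root *i* is unchanged when the
  cohort grows. RNG state is always restored.
* Transit-time and secant integrals are evaluated in closed form per linear
  segment (`Δx · ln(v₁/v₀)/(v₁−v₀)`), exact for the piecewise-linear
  profile, rather than by adaptive quadrature, which is fragile on kinked
  integrands.
* Trajectory integration error of the RK4 scheme is far below measurement
  noise (checked against the exponential closed form in constant-strain
  regions at 10⁻⁴ relative).
* Boundary ties: the plateau scan returns the first qualifying point;
  indices are 1-based in all user-facing outputs.
* Degenerate inputs raise classed errors (`rootkin_error_*`) naming the
  violated requirement: empty particle tables, fewer than 3 distinct
  midpoints, non-positive cell lengths or intensities, unnormalised class
  proportions, observation intervals that overrun the simulated domain.
  Batch wrappers convert per-root failures to notes instead of aborting.

## Validation problem sizes

The recovery suite uses cohorts of 10 roots × 40 particles (50 seeds), the
contrast checks 40 replicate cohort pairs, ploidy checks 10 000 nuclei per
sample with 20 replicate 6-vs-6 contrasts, and the rule oracles 1000 random
sequences per detector — sizes chosen to hold Monte-Carlo error on each
checked rate or median well below the tolerance it is compared against.

## Known limitations

* Steady-state only: the analysis assumes the growth zone is stationary over
  the observation hour; non-steady kinematics need different methods.
* The 95% plateau rule is a biased boundary estimator by construction (it
  reports the 95% crossing); comparisons between genotypes are unaffected
  because the bias is shared, but absolute zone lengths are conservative.
* The doubling rule requires profiles with a sharp length transition, as
  real micrographs show; on smooth profiles it fires late or not at all.
* Ploidy classification assumes log2-spaced classes around a single 2C
  anchor; aneuploidy or strong staining drift would need per-sample gates.
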