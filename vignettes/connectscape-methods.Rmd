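---
title: "Methods: circuit-theory migratory connectivity and road-impact forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit-theory migratory connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`connectscape` treats a migratory landscape as an electrical network. Every
valid raster cell is a node; each node is joined to its 8 nearest
neighbours by a resistor. With cell resistances $r_i$ the edge resistance
is the series sum of two half-cells, $R_{ij} = (r_i + r_j)/2$, scaled by
the centre-to-centre distance $\sqrt2$ on diagonals, so conductances are
$g_{ij} = 2/(r_i+r_j)$ and $g_{ij} = 2/(\sqrt2\,(r_i+r_j))$. Injecting a
unit current at a migration's start cell (source) and extracting it at the
end cell (ground) gives the linear system $L v = b$ on the graph Laplacian
$L$; branch currents are $i_{ij} = g_{ij}(v_i - v_j)$ and the node current
density — half the sum of absolute incident branch currents at interior
nodes, the injection value at terminals — is proportional to the expected
number of visits of a random walker travelling source to ground. Because
only current *ratios* matter, maps are computed at unit injection and used
relatively throughout.

Cell resistance is not assumed to be inverse suitability. Relative habitat
suitability $hs \in (0,1]$ is linked to resistance under five competing
scenarios:

| id | relationship | transform |
|----|--------------|-----------|
| r0 | neutral | $r = 1$ |
| r1 | positive linear | $r = hs$ |
| r2 | negative exponential | $r = (1/hs)^2$ |
| r3 | negative linear | $r = 1/hs$ |
| r4 | negative logarithmic | $r = \ln(1/hs)$ |

Each non-neutral surface is stretched linearly to $[1, 1000]$. The data
choose among the scenarios: for each individual migration, the five
current maps are scored by the summed current density at the observed
fixes, and the scenario with the highest sum ranks top. Tabulating top
ranks across individuals measures the consistency of support; summing each
individual's top map (standardized to sum 1) gives the population
connectivity surface.

## Suitability

$hs$ comes from a used-available resource-selection fit: observed
migration fixes (used, coded 1) against 20 uniformly drawn available
points per used point over the study-area rectangle, fit as a binomial
logistic regression, optionally with random intercepts for year nested in
animal (Laplace approximation via `lme4`). Covariates: standardized
terrain ruggedness (vector dispersion of unit surface normals from Horn
3×3 slope/aspect, 9-cell window; flat cells contribute $(0,0,1)$), a
rasterized major-river indicator, land-cover indicators against the open
reference class, and the road proximity covariate $e^{-\alpha/d}$ with $d$
the point-to-segment distance to the nearest road in km. Because theory
gives no $\alpha$, it is scanned over 36 candidates (every km 1–20, every
5 km 25–50, every 10 km 60–100, every 50 km 150–350) plus a
linear-distance model, ranked by AICc; the winning metric enters a
factorial candidate set ($2^4$ covariate-group subsets, including the
intercept-only model — 16 formulas) that is again ranked by AICc with
Akaike weights. Suitability over the grid is
$hs = e^{\eta} / \max e^{\eta}$ with $\eta$ the fixed-effect linear
predictor *without* intercept or random effects; max-normalization is the
minimal monotone map onto the $(0,1]$ domain the scenario transforms
require, and any common multiplicative factor cancels in it.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| availability ratio | 20 | pts/used pt | standard design for stable RSF coefficients |
| analysis grain | 1 | km | matches the grain at which road effects on ungulates are typically assessed; coarser than the functional grain costs little accuracy |
| stretch bounds | 1–1000 | — | fixed relative-resistance range; only relative magnitudes are informative |
| clamp epsilon | 1e-3 | — | keeps $1/hs$ and $\ln(1/hs)$ finite near $hs=0$; the subsequent stretch makes results insensitive to its exact value (tested) |
| solver tolerance | 1e-8 | relative | maximum Kirchhoff residual accepted at non-terminal nodes |
| snap radius | 5 | cells | maximum distance a migration endpoint may be moved to the nearest valid cell |
| buffer radius | 20 | km | day-trip community hunting range |
| k folds | 10 | — | standard for RSF and map validation |
| bootstrap draws | 500 | — | response-curve intervals |
| NSD plateau fractions | 0.05 / 0.95 | of plateau | migration departure/arrival thresholds |

# The synthetic study system

`generateLandscape` produces a Gaussian-smoothed random elevation field
with spatially varying amplitude (so ruggedness itself varies), a
land-cover field carved into open (most frequent, the reference), dense
vegetation and burned classes plus a 3-km coastal strip, meandering river
and road polylines, and labelled community points. `simulateTracks`
produces range residency, a biased 8-neighbour lattice walk toward the
destination range with per-step weight
$\exp(\kappa \cos\theta)\,(1/r)^s$ ($\theta$ = heading error toward the
goal, $s$ = `selectionStrength`, $\kappa$ = `goalBias`), then residency
again, at 8-h fix spacing — reproducing the low–rise–plateau NSD signature
and the preferential use of low-resistance cells that the pipeline
assumes. Defaults $s = 2$, $\kappa = 1$ give strong but not deterministic
corridor-following, the regime the method is designed for.

What the generator does **not** emulate: temporal covariate dynamics
(snow, ice, phenology), autocorrelated step lengths and turning angles of
real collar data, fix dropout, collar error, herd-level social behaviour,
and real geography. Passing tests therefore demonstrate internal
correctness and recoverability of the model's own structure, not field
validity on any particular herd.

A deliberate departure from visual practice: migration endpoints are
usually read off NSD plots by eye. Here the plateau level $P$ is the
median of the top quartile of the series, migration starts at the last fix
before NSD exceeds $0.05P$ and ends at the first fix $\ge 0.95P$, and a
track whose trailing-window maximum does not exceed 4× the leading-window
median + 1 km² is declared non-migratory. No automated rule can claim
equivalence to expert judgement; this one is deterministic, reproducible
and threshold-exposed.

# Numerical choices

* **Solver.** The grounded Laplacian (ground row/column removed) is
  symmetric positive definite and solved by sparse Cholesky (`Matrix`),
  with up to three steps of iterative refinement if the Kirchhoff residual
  exceeds tolerance; solutions are deterministic for fixed input. Tests
  cross-check against an independent dense `solve()` oracle on random
  grids ($\le 12 \times 12$, with nodata holes) at 1e-8.
* **Stretch.** The linear stretch pins the raw extremes exactly to the
  bounds (floating-point rounding can otherwise overshoot by one ulp) and
  clamps interior values into $[lo, hi]$; rank order is preserved.
* **Terminals.** Terminal cells keep their own resistance via the
  half-cell edge rule (they are not shorted); their current density is
  reported as the injection value.
* **Ties.** Exact ties in scenario ranking are broken by the fixed order
  r0 < r3 < r1 < r4 < r2 (simpler hypotheses first) and flagged.
* **Effect-size boundaries.** The Cohen thresholds are strict
  inequalities in prose; boundary values (0.2, 0.5, 0.8) are assigned to
  the larger class.
* **Validation binning.** RSF validation bins predicted scores into 10
  equal-interval bins over the availability sample. Population
  current-density maps are extremely right-skewed (terminals carry the
  injection), so map validation uses quantile (equal-area) bins by
  default — with equal-interval bins nearly every cell lands in the
  lowest bin and the rank correlation degenerates; `binMethod =
  "interval"` remains available.
* **Distance then aggregate.** Road distance and decay are computed at
  the native grain from exact point-to-segment distances and then
  aggregated (mean) to the analysis grain.
* **Stretch population.** Each surface (per scenario, per road variant)
  is stretched over its own valid cells — the only self-contained choice.
* **Availability redraws.** Available points are drawn fresh per
  season/table build, seeded.
* **Bootstrap.** Response curves use a parametric bootstrap over the
  coefficient sampling distribution (multivariate normal at the estimate
  and covariance) rather than refitting per resample; this trades some
  fidelity for desk-scale runtime and is recorded in the serialized fit
  metadata. Effect-size intervals use a paired nonparametric bootstrap
  over buffer cells (2,000 resamples, seeded); whether real-data intervals
  should reflect cell- or individual-level variation is unresolved, so the
  standardizer (baseline vs pooled sd) is config-exposed.
* **Degenerate inputs.** Constant rasters standardize to zero and stretch
  to the lower bound; zero-variance baselines make $d$ undefined and are
  reported as such; all-nodata rasters, empty road sets, disconnected
  terminals and unreachable destinations raise informative errors.

# Problem sizes used by the test-suite experiments

Chosen as scaled-down analogues of a full telemetry study that keep the
whole suite desk-sized: scenario recovery uses 30 simulated migrations on
a 100×100-km landscape; coefficient recovery uses $n = 50{,}000$ rows once
and 200 replicates of $n = 2{,}500$ for interval coverage; the
$\alpha$-recovery experiment uses 5,000 used points (1:20 availability)
with a road-response strength of 6 on the linear-predictor scale —
comparable to strong empirical road avoidance — over 10 replicates; the
road-impact experiment uses a two-corridor landscape (80×60 km) with 20
seeded replicates of 4 migrations each; the demo pipeline runs 12–15
migrations on 40–60-km extents.

# Known limitations

* Pairwise terminals only — no all-to-all mode, no polygon terminals.
* One seasonal $hs$ for all individuals; no per-individual selection.
* The unweighted logistic likelihood is used for the used-available
  design (infinitely-weighted schemes are out of scope).
* No reprojection: coordinates are an abstract projected km plane.
* Current-map validation statistics depend on the binning convention (see
  above); both conventions are exposed.
* The NSD rule, not expert inspection, delimits migrations; borderline
  nomadic tracks may be classified differently than a human would.
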