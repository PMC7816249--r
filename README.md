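# connectscape

Circuit-theory connectivity mapping for migratory wildlife, with road-impact
forecasting.

## The problem

Long-distance ungulate migrations — the motivating system is barren-ground
caribou (*Rangifer tarandus*) in roadless arctic tundra — are increasingly
threatened by proposed road networks. Managers need to know *where*
migration corridors run, *how* habitat selection maps onto resistance to
movement, and *what* a proposed road system would do to the flow of animals
near the communities that hunt them. `connectscape` implements that whole
workflow as a tested, reproducible R pipeline:

1. **Migration delimitation.** Net-squared displacement
   NSD(t) = (x_t − x_0)² + (y_t − y_0)² is computed per GPS track; a
   deterministic plateau rule (5%/95% of the plateau level) delimits each
   seasonal migration and its start/end fixes.
2. **Resource selection.** A used-available design (20 uniform available
   points per used fix) fit by binomial GLM/GLMM (logit link, random
   intercepts for year within animal optional) over four covariates:
   standardized terrain ruggedness (vector dispersion of surface normals),
   a major-river indicator, land-cover classes against an open reference,
   and an exponential road distance decay e^(−α/d). The decay range α is
   scanned over 36 candidates (1–20 by 1, 25–50 by 5, 60–100 by 10,
   150–350 by 50 km, plus a linear-distance model) and the full factorial
   of the four covariate groups (16 models) is ranked by
   AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1).
3. **Resistance scenarios.** Relative suitability hs ∈ (0, 1] (exponentiated
   fixed-effect predictor, max-normalized) is transformed under five
   hypotheses — r0: r = 1, r1: r = hs, r2: r = (1/hs)², r3: r = 1/hs,
   r4: r = ln(1/hs) — and each non-neutral surface is stretched linearly to
   [1, 1000].
4. **Circuit solves.** Each raster cell is a node joined to its 8
   neighbours by resistors (R = (r_i + r_j)/2, ×√2 on diagonals). For each
   individual, 1 A is injected at the migration start and extracted at the
   end; solving the graph Laplacian yields voltages, branch currents, and a
   per-cell current density proportional to random-walker visitation.
5. **Scenario ranking and population maps.** Scenarios are ranked per
   individual by summed current at the observed fixes; each individual's
   top-ranked map is standardized to sum 1 and summed into a
   population-level connectivity surface, validated by individual-fold
   cross-validation.
6. **Road impacts.** Surfaces are rebuilt with proposed roads injected
   (same coefficients and α), circuits re-solved, and for each community a
   raw-score standardized effect size
   d = (mean_with − mean_without) / sd_without over the cells of a 20-km
   buffer is reported with a paired bootstrap CI and Cohen class
   (|d| < 0.2 negligible, < 0.5 small, < 0.8 medium, else large).

A seeded synthetic module (`generateLandscape`, `simulateTracks`) generates
landscapes and biased lattice random-walk migrations with the statistical
structure the pipeline assumes, so every stage is testable without field
data.

## Worked example

```r
library(connectscape)

cfg <- pipelineConfig(seed = 7, outDir = file.path(tempdir(), "demo"))
res <- runPipeline(cfg)

res$support
#>   scenario count proportion
#> 1       r0     0 0.00000000
#> 2       r1     0 0.00000000
#> 3       r2     0 0.00000000
#> 4       r3    11 0.91666667
#> 5       r4     1 0.08333333
```

The demo simulates 12 migrations on a resistance surface generated under
the negative-linear scenario (r3); ranking by summed current at the
simulated fixes recovers r3 as the top-ranked scenario for 11 of 12
individuals — the headline end-to-end property of the method.

```r
res$populationValidation$mean_rho
#> [1] 0.88
res$populationValidation$mean_at_fixes   # vs study-area mean 0.0038
#> [1] 0.01024
res$effects[, c("community", "d", "class", "sign")]
#>   community           d      class     sign
#> 1    midway -0.25289296      small decrease
#> 2  eastside  0.23001049      small increase
#> 3 southport  0.09113786 negligible increase
```

The population connectivity map ranks withheld individuals' fixes well
(mean Spearman ρ = 0.88 over folds), current at fixes is ~2.7× the
study-area mean, and the proposed road crossing the simulated migration
area reduces current flow at the community sitting on the corridor
(`midway`, d < 0) while communities on newly favoured paths gain.

Every run writes its artifacts (ASCII-grid rasters, CSV tables, GeoJSON
features, a JSON model fit) plus a manifest of md5 checksums under
`cfg$outDir`; rerunning an identical config reproduces them bit for bit.

## Scope

The package operates on an abstract projected plane in km (a CRS tag is
carried opaquely); reprojection, GeoTIFF I/O and the acquisition of any
real-world data products are out of scope. Rasters are exchanged as ESRI
ASCII grids and vector features as GeoJSON.
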