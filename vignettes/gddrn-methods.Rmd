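---
title: "Growth degree-day reaction-norm models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth degree-day reaction-norm models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gddrn)
```

## The problem

Multi-environment wheat trials confound three things a breeder wants to
separate: the additive genetic merit of a line, the way that merit bends
across environments (genotype-by-environment interaction, G×E), and the
spatial and experimental noise of field trials. `gddrn` implements a
reaction-norm approach in which G×E is modeled through the covariance
induced by the product of marker relationships and environmental
similarity, with the environment characterized at fixed thermal-time
stages rather than at observed phenological stages.

## Environmental characterization at 100-GDD stages

Thermal time is the cumulative sum of daily average temperature truncated
at 0 °C from sowing to a fixed season end (August 15 by default; no crop
phenology simulation is attempted — completeness of stage coverage is the
user's responsibility and incomplete trailing stages are flagged). The
season is partitioned greedily into stages of 100 growing degree-days: a
stage closes on the day its running total reaches the stage size, so every
complete stage accumulates at least 100 GDD and less than 100 plus the
largest daily increment. The alternative convention — assigning the
boundary-crossing day to the next stage — can produce "complete" stages
with less than 100 accumulated GDD, which we considered a worse failure
mode than slight stage-to-stage drift of boundaries.

Within each stage window, 17 climatic covariates summarize radiation,
temperature, frost, photothermal ratio and water balance (see
`?compute_stage_ecs` for the full list). Numerical conventions worth
stating explicitly:

* the photothermal ratio is accumulated radiation over accumulated
  truncated temperature, so its denominator is the stage's GDD and is
  always at least the stage size for complete stages;
* a dry day is `precip <= evap` — ties count as dry;
* the accumulated negative water balance keeps its (non-positive) sign;
* the low-radiation threshold of 1,045 J/cm² is converted to 10.45 MJ/m²
  to match the radiation unit;
* frost sums and counts use `tmin`, falling back to `tavg` when a minimum
  temperature is not recorded;
* a covariate with any missing day inside a stage is `NA` for that stage —
  never silently zero — and column-level quality control decides its fate.

Quality control drops covariate columns with more than 10% missing values
or more than 30% repeated values (strict inequalities). "Repeated" is
measured as the fraction of rows whose value occurs more than once in the
column: this reading satisfies the usual worked cases (a column with 31%
identical values is dropped, one with exactly 30% is kept, a constant
column is 100% repeated) and remains meaningful for the small numbers of
environments typical of a single breeding program, where the fraction
held by the single most frequent value degenerates.

Soil profiles contribute one covariate per variable and depth layer
(7 variables × 4 standard layers by default), constant across the years
of a location. Covariates are centered and scaled at the environment
level by default — each environment weighted once, so the derived kernel
Ω = WW′/q is constant within environment — with observation-level scaling
available as an option; the observation-expanded definition of W leaves
the level ambiguous, and the environment-level choice is the one that
keeps Ω an environment similarity.

## Kernels

* **G** — VanRaden method-1 genomic relationships from −1/0/1 SNP codes:
  `G = ZZ′ / (2Σ pᵢ(1−pᵢ))` with `Z = M − P`, `P[,i] = 2(pᵢ − 0.5)`.
  `pᵢ` is the observed frequency of the +1-coded allele (folded only for
  QC), so Z columns are centered and G has zero row sums. Missing calls
  are imputed to the per-SNP mean before centering; most GRM pipelines
  leave this step unstated, and mean imputation is the conventional
  default.
* **S** — nine-neighbour spatial relationships: each plot's spatial value
  is the sum of nine square effects (its own 3×3 square and the eight
  surrounding ones); virtual plots complete the neighbourhoods on trial
  borders and grid gaps. `S = XX′/(tr(XX′)/n)` has unit diagonal and
  entries `k/9` for `k` shared squares. Spatial ids are scoped per
  year-location: fields in different environments share no squares.
* **Ω** — environmental similarity `WW′/q` over observations.
* **GW** — the reaction-norm kernel, the Hadamard product
  `(Z_g G Z_g′) ∘ Ω`, positive semidefinite by the Schur product theorem.

## The model ladder M1–M5

M1 is the baseline: fixed trial effects (trials nested in year-location;
reference levels dropped lexicographically) plus random line (iid),
line-by-environment (iid) and spatial (kernel S) effects. M2 adds the
genomic effect (kernel G); M3 adds the genomic-by-EC reaction-norm effect
(kernel GW). M4 and M5 are the bivariate versions of M2 and M3 with an
unstructured 2×2 between-trait covariance per random term (Kronecker
structure) and a correlated bivariate residual.

### Gibbs sampler

Every random effect is rotated once into a basis in which both its prior
and its information matrix are diagonal: incidence effects are already
diagonal; an observation-level kernel effect uses the truncated
eigendecomposition of its kernel (eigenvalues below 1e−10 of the maximum
dropped); a line-level kernel effect uses the kernel eigendecomposition
followed by a second small eigendecomposition of the rotated design
cross-product. Full conditionals then factor into independent univariate
(single-trait) or 2×2 (bivariate) normal draws, evaluated in vectorized
form — the sampler is pure R with BLAS doing the heavy lifting, and the
expensive decompositions can be precomputed once and reused across refits
of the same design with different masking (`precompute_blocks()`), which
is what makes the cross-validation protocol affordable.

Variance components use scaled-inverse-χ² full conditionals; bivariate
trait covariances use inverse-Wishart (`ν₀ = traits + df₀`). Prior scales
follow the usual proportion-of-variance partition — each random term's
scale references an equal share of `R² · var(y)` divided by the mean
diagonal of its observation-level kernel, the residual references
`(1 − R²) · var(y)` — but the scales carry only `df₀` prior degrees of
freedom. This detail matters: weighting the scale so the prior *mode*
matches the partition (a tempting parameterization) makes the
`exp(−S₀/2σ²)` term of the prior a strong repulsion from small variances
whenever `df₀` is tiny, visibly inflating small components such as the
line and line-by-environment variances. With the scale weighted by
`df₀ = 0.0001` the priors are genuinely uninformative and the partition
only seeds the chain's starting values. Fixed effects carry flat priors and are drawn as
a matrix-normal block. Missing trait records — including deliberately
masked validation sets and the trait-assisted pattern in which only the
target trait is masked — are handled by residual data augmentation, which
is exactly what lets the model predict unphenotyped lines and exploit the
secondary trait.

The default chain (5,000 iterations, 1,000 burn-in, thinning 5) is a
desk-scale compromise; production analyses of commercial data use chains
an order of magnitude longer (e.g. 50,000/10,000/10), and the
convergence tooling (`mcmc_diagnostics()`: Geyer initial-positive-sequence
effective sample sizes and Monte Carlo errors) is there to check whether
a chain was long enough. Variance pairs with overlapping footprints —
line vs. genomic, line-by-environment vs. reaction-norm — mix slowly and
need the long end of that range.

### Heritability

Plot-level heritabilities use the mean diagonal of G (one plus the mean
genomic inbreeding): `h² = d(G)σ²_g/σ²_P`, `H² = (σ²_l + d(G)σ²_g)/σ²_P`
with `σ²_P = σ²_l + d(G)σ²_g + σ²_f + σ²_s + σ²_e`, computed per retained
draw. Heritabilities reported in the applied literature are not always
reproducible from the accompanying variance-component tables via these
formulas; the package follows the formulas, and its worked test case
freezes a hand-verified plug-in value.

## Validation protocol

`run_cv()` implements leave-one-year-location-out (CV1) and
leave-one-breeding-cycle-out (CV2) cross-validation. Fixed effects for
the line-mean correction are estimated once on the full data (the
protocol's own choice, accepting the mild leakage it implies); corrected
line means are plot observations minus fixed effects, averaged within
line and year-location. Predictive ability is the Pearson correlation
between corrected means and predictions pooled over all masked cells —
a single value per scheme — with per-fold values available in the cells
table. Bootstrap standard errors resample (line, environment) cells with
replacement. Model contrasts use a two-tailed paired t-test on per-cell
squared prediction errors (the paired unit is not dictated by the
protocol; squared error is the documented, swappable default). The
maximum-PA bound is `n·h²_f/(1 + (n−1)h²_f)` with the realized average
replicate count; `h²_f` is computed from plot-level posterior variance
components as genomic signal over the variance of a corrected line mean,
substituting genomic-plus-interaction variance for reaction-norm
predictions. The inflation slope `b_w,p = cov(û_w, û_p)/var(û_p)`
regresses whole-information on partial-information predictions, per
effect (`g`, and `gw` as the difference of `g+gw` and `g` predictions).

## The synthetic study system

The generator emulates a northern-European winter-wheat program: breeding
cycles of highly homozygous lines (fully homozygous calls with
probability 0.95, so the mean GRM diagonal sits well above 1, as in real
inbred panels), cycle-structured allele-frequency drift on the logit
scale, three locations with daily weather from autumn sowing to
August 15, soil profiles per location, and trials of blocks holding 21
distinct lines plus 2 checks, all duplicated, on an X-Y grid 23 plots
wide. Weather combines location offsets with regional year anomalies
shared across locations — sites of one small country experience the same
warm and dull seasons — plus daily noise; the shared component is what
makes environmental covariates transferable across locations, the
property leave-one-environment-out prediction relies on. Baseline
temperatures are set so every environment comfortably exceeds 2,700 GDD
and yields the full 27 complete stages.

Phenotypes are drawn from the full bivariate reaction-norm model (M5) at
the variance-component and between-trait-correlation magnitudes reported
for grain yield and protein content in commercial trials, with a genomic
trait correlation of −0.5 and trait means of 8.85 kg/plot and 9.84%.
Trial fixed effects are deliberately large (SD 0.6) so the fixed-effect
correction is genuinely exercised. What the generator does **not**
emulate: linkage disequilibrium maps, pedigree recombination, selection
between cycles, non-Gaussian trait distributions, and weather-station
measurement error — so passing tests demonstrate correctness of the
machinery and qualitative reproduction of the methodology's orderings,
not field performance on real data.

## Problem sizes used by the test and acceptance studies

The shipped studies are sized for a single CPU:

* **Parameter recovery** — M5 refits of its own generative model at
  60 lines, 12 environments, 8,000-iteration chains, three seeds, with
  pooled credible-interval coverage across (component, seed) pairs. With
  components as confounded as line vs. genomic main effects and
  line-by-environment vs. reaction-norm interactions, fixed-truth
  coverage of 95% intervals is only approximate at desk scale; the study
  checks it stays at or above 90% pooled.
* **Ordering studies** — the reaction-norm gain in CV1 is measured on
  data with a strong genomic-by-EC component (its share raised well above
  the additive share, mirroring the strong-G×E regime the methodology
  targets) and climatically contrasting seasons (`year_anomaly_sd = 1.6`),
  48 lines across 12 environments, pooled leave-three-environments-out
  folds, 20 seeds; trait-assisted and cycle-versus-environment orderings
  use single-fold refits at 4 environments where their margins are wide.
* **The acceptance script** re-runs the headline computations at 60 lines
  and 12 environments with 4,000-iteration bivariate chains — the
  smallest scale at which cross-environment covariate transfer, the
  mechanism leave-one-environment-out prediction relies on, is clearly
  expressed.
* The full 300-line, 6-environment default of `sim_config()` fits in
  minutes per M5 chain and is the recommended starting point for
  interactive use.

## Known limitations

* Two traits only in the multivariate case; more would require
  generalizing the inverse-Wishart blocks.
* Dense observation-level kernels: eigendecompositions are O(n³), so
  beyond ~20,000 plots the kernels should be factored rather than
  materialized (the `max_n` guard exists for this reason).
* No REML fitting; a likelihood-based cross-check is only available
  externally for sub-models with identity kernels.
* The sampler's slow-mixing variance pairs need long chains; always read
  `mcmc_diagnostics()` before trusting a credible interval.
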