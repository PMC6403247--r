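---
title: "Models and methods in paleoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoniche)
```

`paleoniche` quantifies where a fossil clade could have lived (habitat
suitability from climate) and where it could have been preserved (virtual
taphofacies from sediment flux and runoff), and tests whether the observed
record clusters where preservation was good rather than where habitat was.
This vignette explains each model, its assumptions, the tunable parameters,
and the numerical choices; it also states what the synthetic-world tests do
and do not demonstrate about real data.

## The maximum-entropy niche model

The niche model is a presence-background density estimator: given presence
cells and a background of training-region cells, it finds the distribution
over the background that maximises entropy subject to matching the presence
means of a set of climate-derived features — equivalently, an L1-penalised
Gibbs (log-linear) model. `fit_maxent()` maximises

$$L(\lambda) = \frac{1}{m}\sum_{i \in \text{presence}} \eta(x_i)
 - \log \sum_{x \in \text{background}} e^{\eta(x)}
 - \sum_j \beta_j |\lambda_j|, \qquad \eta(x) = \sum_j \lambda_j f_j(x),$$

with per-feature penalty $\beta_j = \texttt{reg\_multiplier}/\sqrt{m}$ on
standardised features ($m$ = presence count). The objective is concave; the
solver is a monotone proximal-gradient ascent (ISTA with backtracking and
step growth), stopped at a KKT residual of 1e-7 or 5000 iterations. The
objective trace is retained so the tests can assert monotone convergence on
every fitted model.

Feature classes are fixed to linear + quadratic + product. Variables are
first standardised to background mean 0 / SD 1, features are then built on
the standardised variables and standardised once more. The ordering
matters under strong L1 regularisation: quadratic features of raw variables
put the response optimum at the raw-unit origin whenever the linear term is
shrunk to zero, whereas variable-first standardisation centres the default
optimum on the background climate — the biologically neutral prior. A
side-effect is an exact form of the affine-invariance property: logistic
suitability is unchanged by linear rescaling of any input variable.

Prediction supports *extrapolation* (features evaluated as-is outside the
training range) and *clamping* (variables truncated to the training range
first); the two agree exactly in-range. The raw output is the Gibbs density
renormalised over the prediction region; the logistic output is
$s = c\,q/(1 + c\,q)$ with $q = e^{\eta - \log Z}$ and $c = e^{H}$, $H$ the
entropy of the fitted distribution over the training background (the
classical definition of the logistic scale). Cells with any variable
strictly outside its training range are flagged non-analogue
(`mess_flags()`) but keep their values — they are to be interpreted with
caution, not discarded.

Evaluation (`evaluate_maxent()`) uses k seeded random 75/25 presence
splits (default k = 50), reporting test AUC against the full background —
AUC is computed exactly from ranks, with ties counted half. Variable
importance comes in two forms: jackknife gains (with-only / without models
on the full presence set; gain is the mean presence log-likelihood relative
to the uniform distribution) and percent contribution, implemented as
permutation importance (drop in training gain when a variable's values are
permuted across presence and background, averaged over the k replicate fits
and rescaled to 100). The original path-dependent contribution heuristic of
the historical software is solver-specific and not reproducible, so
permutation importance replaces it deliberately.

Thresholding uses the True Skill Statistic on a 0.01 grid, with ties going
to the smallest threshold; binary habitat maps at the conventional 0.2 /
0.45 / 0.7 levels are quantified as sums of spherical cell areas
($R = 6371$ km authalic radius). Forward/backward projections between
adjacent time bins are compared by the fraction of region cells on which
the binary maps disagree; pairs exceeding 15% deviation fail the consensus
rule.

## Climate predictors and screening

Twelve candidate predictors are derived from the monthly cycle: annual
means, the coldest/warmest/driest/wettest quarters of temperature and
precipitation, and the two annual (population) standard deviations.
Quarters are 3-consecutive-month moving windows with December–January
wrap-around, ties resolved to the earliest starting month — the bioclim
convention. Precipitation stays in model units (mm/s).

Collinearity screening computes pairwise Pearson correlations over the
training-region cells only (that is where the model sees the variables) and
greedily eliminates: while any pair has |r| at or above 0.7, drop the
member of the worst pair with the larger mean absolute correlation to the
remaining variables; ties drop the later name in canonical order. The
returned set provably satisfies all-pairs |r| < 0.7.

## Occurrences: deduplication, thinning, binning

Occurrences are deduplicated to one per (clade, time bin, grid cell),
keeping the first in input order. Spatial thinning uses the Clark–Evans
average nearest-neighbour statistic on great-circle distances:
$R = \bar D_{obs} / \bar D_{exp}$ with $\bar D_{exp} = 1/(2\sqrt{\rho})$,
$\rho$ = points per km² of the study area (conventionally the training
mask, not the point hull), and
$z = (\bar D_{obs} - \bar D_{exp}) / (0.26136/\sqrt{n\rho})$. While the
one-sided test indicates clustering ($z < -z_{0.95}$), one member of the
current closest pair is removed — the member whose removal yields the larger
new mean nearest-neighbour distance, residual ties broken by a seeded draw —
until randomness or n = 3.

The uncorrected statistic carries a known positive edge bias of roughly
$0.2\,P/\sqrt{A}$ standard errors (window perimeter $P$, area $A$; about
+0.8 z on a square window), independent of n. Two consequences are
documented rather than corrected (the expectation formula is part of the
method definition): two-sided CSR acceptance sits near 85–88% rather than
the nominal 95%, and — the property that matters for thinning — the bias is
*away* from the clustering side, so random point sets are essentially never
thinned (false-alarm rate well under 5%).

Time bins default to five ~3.5 Myr Campanian–Maastrichtian substages
(boundaries 83.6, 79.77, 75.93, 72.1, 69.05, 66.0 Ma) plus the Danian for
post-boundary projection.

## Virtual taphofacies

The palaeo-DEM is depression-filled by priority-flood with an epsilon
gradient (1e-6 m) so flats drain toward their spill path; D8 directions
take the steepest descent on the filled surface (diagonal distance
$\sqrt 2$ cells), ties resolved in the fixed order E, NE, N, NW, W, SW, S,
SE. A cell whose best descent enters the sea, or that has no positive
on-grid descent, is an outlet; the construction is acyclic, and flow
accumulation is computed in decreasing filled-elevation order.

Basins are the drainage trees of outlets. Each gets surface area A (km²,
spherical cell areas), relief R (max basin elevation minus outlet
elevation, km, on the raw DEM), area-weighted mean annual temperature T
(°C), and discharge Q = runoff integrated over the basin
(mm/s × km² × 3.1536e7 s/yr × 1e-6 km/mm, in km³/yr). The BQART sediment
load is

$$Q_s = \omega B\, Q^{0.31} A^{0.5} R\, T \;(T \ge 2\,°C), \qquad
  Q_s = 2 \omega B\, Q^{0.31} A^{0.5} R \;(T < 2\,°C),$$

in MT/yr with $\omega = 0.02$ and B = 1 (no glacial, lithological or
anthropogenic terms are resolvable in deep time; all constants are
arguments of `bqart_params()`). Mapping basin loads to a deposition-rate
field requires two conventions the flux model itself does not supply: a
bulk density (default 2.0 g/cm³) and a depositional area (default: basin
cells at or below the basin's 25th elevation percentile, i.e. the lowland
quarter where accommodation is concentrated). The load is spread uniformly
there: rate [cm/ky] = $Q_s \cdot 10^{12} / (\rho \cdot A_{dep} \cdot
10^{10}) \cdot 10^{3}$; the tests verify the field integrates back to the
basin loads.

Sediment-flux and runoff fields are classified into two "virtual
taphofacies" (high/low) by the two-class Jenks natural break: an exhaustive
scan over sorted split positions minimising within-class sum of squares,
the break reported as the midpoint of the boundary observations (ties to
the smaller break; equivalent to 1-D 2-means, which the tests assert).
Published class bounds (280.32 cm/ky for flux, 1.97e-7 mm/s for runoff) can
be supplied as overrides wherever a break is accepted. Jenks is applied to
linear (not log) values.

## Hotspots and association tests

Kernel density uses the quartic kernel
$K(d) = \tfrac{3}{\pi h^2}(1 - (d/h)^2)^2$ on great-circle distances; each
point integrates to 1, so the surface integrates to the point count up to
edge loss (asserted within 2%). The density surface acts as the analysis
mask (cells with positive density). Getis–Ord Gi* standardises each masked
cell's neighbourhood sum of per-cell occurrence counts (binary weights
within a radius, self included) against the mask-wide mean and population
SD; hot cells have Z > 1 and p < 0.05, cold cells Z < −1 and p < 0.05, and
a constant field is defined to give Z = 0 everywhere.

Occurrences falling in hot or cold cells are cross-tabulated against the
high/low taphofacies class of their cell (occurrences in "neither" or
unclassified cells are excluded) and tested with Pearson's χ² (df = 1),
with and without Yates' continuity correction, and Fisher's exact test
(two-sided by the point-probability rule with the standard 1 + 1e-7
tolerance factor, matching the convention of `fisher.test`). The χ² formula
form $n(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ is asserted against the
generic $\sum (O-E)^2/E$ computation, and both tests are cross-checked
against the base-R implementations on random tables. Tables used for the
stage-level statistics are built from deduplicated (not thinned)
occurrence sets. The printed stage-level contingency counts are packaged as
a plain-text fixture (`published_contingency_tables()`), and
`published_association_results()` reproduces all the published statistics
from them with no external data.

Bandwidth and radius defaults are expressed in grid units (kernel bandwidth
2 cell diagonals; Gi* radius 1.5 cell sizes) since the source analysis'
projected-units radius does not transfer. The packaged association demo and
the null calibration pass a 3-cell radius explicitly: at demo sample sizes
a ~9-cell neighbourhood cannot reach p < 0.05 on the cold side (counts are
bounded below by zero), which would make every table degenerate.

## The synthetic palaeo-world

The generator builds a continent on a 72 × 40 cell grid at 1.25°
(continental scale, seconds to run): a plain that tapers into an ocean ring
at the margins, a Gaussian mountain ridge near the western margin, and a
meridional seaway trough that splits the land into western and eastern
subcontinents — the Laramidia/Appalachia configuration. Monthly temperature
is latitude-, elevation- and season-driven with Gaussian noise; monthly
precipitation decays with coastal distance plus an orographic term; surface
runoff is a fixed coefficient (0.4) of annual precipitation. Outcrop masks
are bands along the seaway's western shore: 15° wide for the
Campanian-style preset, 7° for the Maastrichtian-style one, emulating the
contraction of the preserved sampling window. Stage climates are held
identical between the presets so the preservation-window effect is isolated
from climate change.

Virtual species have Gaussian niches on predictors that survive the
collinearity screen (one temperature, one precipitation variable), with
optima at the regional medians. "Niche breadth" is parameterised as the
full ±2σ tolerance envelope as a fraction of the regional climate range
(default one quarter, so σ = range/16). Occurrence sampling weights cells
by true suitability × preservation weight of the taphofacies class (default
10:1 favouring high flux) × outcrop membership, with seeded coordinate
jitter; per-bin target counts default to the published per-clade magnitudes
(2–58).

What the synthetic tests demonstrate: that every operation implements its
stated formula (oracle tests), that the estimator recovers a known niche
essentially exactly in rank terms (Spearman ≥ 0.99 against truth over land),
and that the sampling-bias mechanism is reproducible — narrowing the
outcrop window shrinks outcrop-masked habitat area while the continental
projection does not shrink. What they do not demonstrate: realistic spatial
autocorrelation of real climate fields, taphonomic processes beyond the
two-class facies model, or taxonomic error in real occurrence data.

An honest limit worth stating: with presences sampled proportional to
suitability from a ~314-cell training window, the mean subsample test AUC
of even the *true* suitability is about 0.87–0.92 at the default breadth;
the fitted model tracks that ceiling (0.84–0.90 across seeds). High
published AUCs on real data reflect occurrence sets far more concentrated,
relative to their background, than suitability-proportional sampling
produces.

The null calibration runs the full association stage on 50 seeded
replicates with equalised preservation weights (occurrences independent of
facies) on a generalist species; replicates are expected non-significant at
least 90% of the time, with degenerate tables (a zero margin — no evidence
either way) counted as non-significant.

## Numerical and design choices

- Grid registration is cell-centre, row 1 = south, longitudes normalised to
  [−180, 180); extents are half-open.
- Bilinear resampling propagates missingness strictly (any missing corner
  poisons the target cell) to avoid silent coastal extrapolation; it is
  exact for planes and idempotent on the identical grid.
- Raster I/O uses the ESRI ASCII grid text format (with the DX/DY extension
  for non-square cells) plus a JSON sidecar carrying the units label;
  round-trips preserve values to 1e-6 relative and the missing mask
  exactly.
- All stochastic operations take explicit integer seeds and are bitwise
  reproducible; pipeline stages derive per-stage seeds from one master
  seed.
- Degenerate inputs are handled explicitly: coincident points give R = 0
  with the closed-form z; all-equal values are rejected by Jenks ("no
  natural break"); zero-variance predictors are dropped with a warning;
  zero-margin contingency tables are rejected by χ² and reported as NA by
  the pipeline.

## Problem sizes used by the tests

The packaged demonstrations use the 72 × 40 demo grid, 50 presence cells,
k = 50 evaluation replicates (k = 5–10 inside pipeline-level tests), and 50
null-calibration replicates; the full suite and the acceptance script each
run in about a minute on one CPU.
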