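---
title: "Demand-constrained land-change simulation and PFT subdivision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demand-constrained land-change simulation and PFT subdivision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pftsim)
```

`pftsim` implements a complete scenario-based land-cover projection
pipeline on regular rasters: top-down demand calibration, bottom-up
cellular-automata (CA) allocation with learned suitability surfaces,
bioclimatic subdivision of the simulated broad classes into a 20-class
plant functional type (PFT) scheme, and a map-comparison validation suite.
This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic test data do and
do not establish.

## The land scheme

Seven broad classes: forest (1), grassland (2), barren (3), cropland (4),
urban (5), water (6), permanent snow/ice (7). Water and snow/ice are
*frozen*: they take no part in demand, suitability learning, or allocation,
and their cells are bit-identical across every simulation step. Urban is
active but irreversible — it can absorb other classes and never converts
away. The shrubland occasionally distinguished in coarse land products is
merged into forest here; its identity survives through the preliminary
forest labels (the `shrub` label), so no information relevant to the PFT
product is lost.

## Demand calibration

The coarse series supplies, per region $r$, class $j$ and step $t$, an area
$L_{r,j}^t$ (km²). Rates are handled as gross ratios $g = L^t / L^{t-1}$
with net rate $n = g - 1$; a zero area at $t-1$ yields $g = 1$ (hold
constant) rather than a division by zero. One calibration step maps the
fine-scale area $A^{t-1}$ to

$$A^t = \begin{cases}
A^{t-1}\,(n \cdot L^{t-1}/A^{t-1} + 1) & L^{t-1}/A^{t-1} < 1,\ j \neq \text{urban}\\
A^{t-1}\, g & L^{t-1}/A^{t-1} \ge 1,\ j \neq \text{urban}\\
A^{t-1}\, \max(g, 1) & j = \text{urban.}
\end{cases}$$

The first branch damps the net rate by the coarse-to-fine area ratio, so a
large initial gap between the coarse series and the fine baseline cannot
produce drastic spurious change; the urban branch encodes the assumption
that urban land does not shrink at km scale. The branch structure uses the
net rate additively and the gross rate multiplicatively: that is the only
reading under which no-change ($g = 1$) is a fixed point of every branch.
After calibration, the non-urban active classes are rescaled
proportionally so each region's active total (including urban, untouched)
equals its actual active land area. Frozen classes are excluded from both
calibration and rescaling.

Two consequences are tested as invariants: totals are conserved to 1e-9
relative at every (region, step), and when the baseline census equals the
coarse initial areas *and* the coarse series conserves per-region totals
(as a harmonised coarse land product does — land area is fixed), the
calibrated trajectory reproduces the coarse trajectory to the same
tolerance. `make_transfer_series()` generates exactly such
total-conserving series; `make_coarse_series()` with independent per-class
geometric trends deliberately does not, which exercises the rescaling.

Demands are converted to integer cell counts by largest-remainder rounding
per (region, step), so counts always sum to the region's active cell
count and the CA's feasibility precondition holds by construction.

## Suitability surfaces

Per-class probability-of-occurrence is learned by a single-hidden-layer
neural network (`nnet`: 12 logistic hidden units, softmax output, weight
decay 1e-4, at most 200 optimiser iterations). Twelve units is the
smallest standard width that saturates held-out accuracy for the default
eight-driver stack; training is deterministic given the seed that
initialises the weights. Drivers are min–max normalised per layer over the
classified cells, and the training ranges are stored in the model so
prediction normalises identically — heterogeneous driver units
(population counts, distances, temperatures) make a shared scale
necessary.

Training cells come from a per-class 10 % draw without replacement
(at least one cell per class present); a `stratified = FALSE` switch draws
uniformly over the region instead, since the sampling statement admits
both readings. Evaluation uses the rank-statistic AUC (probability that a
random positive cell outscores a random negative one, ties counting one
half) on an independently seeded 10 % sample; the implementation is tested
exactly against all-pairs enumeration. Models are fitted per region
(`fit_region_models()`); single-region fits are used in small tests.

## The CA allocation engine

A cell of class $k$ converts to class $j$ with probability proportional to

$$TP_{i,j} = Pg_{i,j} \cdot \max(\text{neighbor}_{i,j}, \varepsilon) \cdot \text{inertia}_j \cdot \text{cons}_{k \to j}$$

- `neighbor` is the share of class-$j$ cells in the (default 3×3) window
  excluding the centre; edge cells use the truncated window's available
  neighbours as denominator.
- $\varepsilon$ (`neighborhood_floor`, default 1e-4) exists because the
  pure product makes a class with zero neighbourhood permanently
  unreachable; the floor permits nucleation while keeping the
  neighbourhood term dominant. Setting it to 0 restores the literal
  product.
- `cons` is a 0/1 matrix; the default freezes water and snow/ice in and
  out, and forbids urban converting away.
- `inertia` starts at 1 per class and is updated between macro-iterations
  from the last two demand gaps $d = \text{demand} - \text{allocated}$:
  unchanged while $|d_1| \le |d_2|$, scaled by $d_2/d_1$ when
  over-allocation worsens ($d_1 < d_2 < 0$), by $d_1/d_2$ when
  under-allocation worsens ($0 < d_2 < d_1$). The functional form follows
  the established adaptive-inertia CA lineage; it is recorded here as the
  package's normative rule.

Each macro-iteration sweeps all of a region's active cells in a fresh
seeded random permutation (inner loop compiled via Rcpp, drawing from R's
own random stream so runs are bit-reproducible under `set.seed`). A
destination whose demand is already met is excluded from the roulette of
other cells, and a cell whose own class is strictly over demand must
leave: this over-fill guard accelerates convergence without changing the
fixed points — demand equal to the current census yields zero conversions
immediately. Iteration stops when every class is within tolerance
(default `max(1, 0.1 %)` of the class demand, in cells) or after
`max_iterations` (default 300) sweeps. Demands exceeding the region's
active cell count raise an error before any iteration. Suitability
surfaces are held static over the simulation horizon, consistent with
static driver layers.

## PFT subdivision

Forest cells first receive one of five preliminary forest types
(broadleaf/needleleaf × evergreen/deciduous trees, shrub). A future forest
cell that carries a baseline label keeps it; any other takes the label of
the nearest labelled baseline cell by Euclidean distance between cell
centres, with exact integer squared distances and ties broken by row-major
scan order of the sources. The search is global within the raster (not
constrained per region).

Climate rules then split the five labels into 11 forest PFTs on four
indicators: coldest/warmest monthly means `T_c`/`T_w`, growing-degree days
`GDD` (annual sum of monthly mean excess over 5 °C, weighted by month
length under a 365-day year), annual precipitation `P_ann`, and winter
half-year precipitation `P_win` (November–April where the cell-centre
latitude is ≥ 0 — latitude exactly 0 counts as northern — May–October
otherwise). Thresholds: 15.5 °C separates tropical from temperate
broadleaf trees; −15 °C / GDD 1200 / GDD 600 bound the temperate and
boreal deciduous classes; −19 °C / GDD 600 bound the needleleaf and shrub
temperate–boreal split; 520 mm and `P_win > 2/3 P_ann` separate evergreen
from deciduous temperate shrubs. The printed temperate/boreal rules for
broadleaf deciduous trees leave 600 < GDD ≤ 1200 at mild `T_c`
unassigned; within each preliminary type the last rule row acts as the
fallback (boreal), which keeps the classifier total with minimal deviation
from the printed rules — so the temperate/boreal boundary over GDD sits at
1200 for broadleaf deciduous trees and 600 for needleleaf evergreens.
Needleleaf deciduous has no climate split.

Grassland splits by first match in table order: arctic C3 (`GDD < 400`);
C3 (`GDD ≥ 400` and `T_w ≤ 22 °C`, or at least six months simultaneously
dry ≤ 25 mm and hot > 22 °C — the `n_dry_hot` indicator, our parenthesis
of a compound dryness clause); C4 (`GDD ≥ 400`, `T_c ≥ 22 °C`, driest
month > 25 mm); otherwise mixed C3/C4, stored as a single code carrying
the 50/50 semantic. Precedence is needed because the C3 and C4 clauses are
not mutually exclusive. The C4 temperature clause conditions on the
*coldest* month as printed; a `c4_on_warmest` switch implements the
plausible `T_w` reading but is non-normative. First-match order means the
C4 class requires a hot coldest month with a wet driest month — hot-arid
cells fall to C3 via the dryness clause.

Barren, cropland, urban, water and snow/ice map 1–1 to codes 16–20.
Collapsing codes 1–11 to forest and 12–15 to grassland inverts the
refinement exactly on every input — a tested invariant.

## The synthetic world

`make_world(seed, ...)` emulates the *statistical roles* of the real
inputs, not their geography:

- **Baseline map** — argmax over seven smoothed Gaussian random fields
  with biases tuned so every class holds roughly a realistic share
  (forest 24 %, grassland 20 %, cropland 18 %, barren 14 %, water 12 %,
  urban 6 %, snow/ice 6 %); thresholding smoothed noise yields the
  spatially autocorrelated patches that make neighbourhood effects
  non-trivial.
- **Drivers** — eight continuous layers mirroring the usual driver roles
  (two socioeconomic-like, two accessibility-like, four physical-like).
  Five carry the latent field of one active class each plus smooth noise
  (the planted monotone signal a classifier can recover); three are
  nuisance fields. The wiring is recorded in `truth`.
- **Coarse series** — initial areas are the per-region census times a
  `gap_factor` (a gap ≠ 1 exercises the calibration's damping branch),
  evolving either by exact per-class geometric trends or by
  total-conserving transfers.
- **Climate** — a deterministic north–south annual-mean gradient (−18 to
  30 °C) with latitude-dependent seasonal amplitude (18 to 6 °C), warm
  month July in the northern hemisphere and January in the southern, and
  four longitudinal precipitation regimes (uniform wet 100 mm/month;
  winter-wet; summer-dry; arid 5 mm/month). The defaults are chosen so
  the derived indicators cross every rule threshold; `make_climate`
  warns if a profile leaves a branch unreachable.
- **History pair** — `make_history` changes an exact share of classified
  cells (default destination weights skewed toward cropland and urban so
  the pair carries net directional change rather than self-cancelling
  churn; urban is never a source; frozen cells never change), placing
  changes preferentially where the planted signal favours the
  destination. This makes suitability learning and figure-of-merit
  evaluation on the pair meaningful.

What passing tests on these worlds establish: the algorithms converge,
conserve, constrain and reproduce as specified, and the learner recovers a
signal that is genuinely present. What they do not establish: accuracy on
real land-cover data, whose class frequencies, driver collinearity and
change processes the generator does not emulate. Published headline
accuracies of CA land simulations on real data are therefore not
reproduced here, only the metric definitions that produce them.

## Validation metrics

Overall accuracy is trace/total of the confusion matrix over jointly
classified cells; Cohen's kappa uses expected agreement from the
marginals (errors when chance agreement is 1). The figure of merit
decomposes cells into misses A (observed change, simulated persistence),
hits B (correct simulated change), wrong-class C and false alarms D, with
`FoM = B / (A + B + C + D)` and the convention FoM = 0 when no cell
changes in either map. A `mask_frozen` flag excludes frozen cells from the
agreement metrics, since published comparisons sometimes blank them.
Block change sums per-class cell deltas over k×k blocks (partial edge
blocks as-is) times the cell area. All metrics are tested exactly against
brute-force per-cell oracles on random fixtures.

## Raster encoding

No GeoTIFF tag machinery is assumed: class rasters are single-band uint8
TIFF payloads (nodata 255), continuous layers are 32-bit payloads scaled
to [0, 0.9] with 1.0 as nodata sentinel and the linear scale/offset
recorded alongside; the georeference (rows, columns, cell size in km,
top-left origin, with row 1 northernmost and latitudes evaluated at cell
centres) travels in a plain-text `.hdr` sidecar whose doubles are printed
with 17 significant digits, so round-trips are bit-exact. The encoding is
a documented convention of this package, not a reproduction of any
published file layout.

## Problem sizes and determinism

The shipped tests run worlds up to 200×200 cells with 2–4 regions and
5-step horizons, 10 % sampling, and 5-seed replicates for the stochastic
properties — sizes chosen so the full suite completes in well under a
minute while every class still holds thousands of cells. All stochastic
stages take explicit seeds; two runs with equal seeds and inputs produce
byte-identical outputs, which the end-to-end test asserts on the written
file set.

## Known limitations

- Nearest-neighbour label transfer is brute-force (chunked exact
  distances); adequate at test scales, superlinear in label count.
- The adaptive-inertia rule and the over-fill guard are normative choices
  of this package where the lineage literature leaves the functional form
  unstated.
- Demand tolerance is expressed in cells, not km².
- No reprojection or resampling: all layers must be co-registered.
- Fractional per-cell PFT cover is out of scope; each cell carries one
  code.
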