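---
title: "How bubblegrid encodes and lays out metabolomics association results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How bubblegrid encodes and lays out metabolomics association results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblegrid)
```

## The display problem

High-throughput NMR metabolomics panels such as Nightingale Health's
report a few hundred correlated measures per blood sample, and a single
association analysis (one exposure against every metabolite) produces one
signed effect estimate and one P-value per measure. Forest plots do not
scale to this: the 12 lipid measures repeated across 14 lipoprotein
subclasses alone are 168 coefficients whose interesting structure is
*positional* — how an association changes across subclass sizes (rows)
and within a subclass (columns).

bubblegrid draws each result as one circle in a categorical grid,
dual-encoding the two numbers per cell:

* **fill colour** — the signed effect estimate, on a diverging colour
  scale symmetric about zero, so the sign is readable at a glance and
  equal magnitudes in either direction get equally saturated colours;
* **circle size** — the significance as `-log10(P)`, optionally capped,
  so very small P-values do not blow up the scale.

Both encodings are shared across every panel of a figure, which is what
makes panels comparable.

## The colour scale

The colour scale is defined by a single half-range `vmax`: estimates are
clamped to `[-vmax, vmax]` and mapped linearly onto a palette whose
middle entry is the zero colour. By default `vmax` is the largest
absolute estimate among the plotted values, so the scale is as tight as
the data allow while staying symmetric; `vmax` can be fixed explicitly
to make two figures share one scale. The invariant the tests enforce is
`position(v) + position(-v) = 1` on the unit ramp. The default palette
is a colourblind-safe blue–white–red ramp; palettes are configuration,
not contract, and any odd-length colour vector works. Clamping rather
than erroring on out-of-range values is deliberate: one outlier should
saturate, not kill a figure.

Missing estimates in cells that still have a significance value are
drawn in a neutral grey (`na_col`); cells with no usable size value are
masked entirely.

## The size scale and capping

Significance is first mapped through `neglog10()`. A P-value of exactly
zero (possible when upstream software underflows) returns a finite
ceiling, 300 by default — beyond any plausible display cap but safely
finite.

`cap_score(s, cap)` is plain saturation, `min(s, cap)`, and is
idempotent. Capping is applied at *scale* time, not at alignment time:
aligned data store the uncapped score so the same aligned object can be
rendered under different caps (a 35-cap and a 25-cap figure from one
alignment, as one does when biochemistry and disease outcomes warrant
different ceilings).

Radii interpolate between `rmin` (score 0) and `rmax` (score at the
cap). Two transforms are available because the perceptually honest
choice is not obvious and conventions differ:

* `"area"` (default): circle **area** grows linearly with the capped
  score, `r(s) = sqrt(rmin² + (rmax² − rmin²)·min(s, cap)/cap)`. Area is
  what the eye integrates, so equal score increments read as equal
  ink increments.
* `"radius"`: the radius itself is linear in the capped score, which
  exaggerates differences at the top of the scale.

`rmin > 0` keeps a null result visible as a small dot — an empty cell
means *missing*, never *non-significant*. When no cap is requested the
observed maximum score bounds the size domain for that figure.

## Catalogs: grids as data, not code

Which variable sits in which cell is pure data. A catalog is a CSV
(`variable_id, display_name, group, grid, row_label, col_label,
footnote, …`) plus an optional layout JSON (panel anchors on an abstract
canvas, a legend anchor, a footnote line). Grids are assembled from the
unique row and column labels of each grid name in order of appearance,
so the CSV row order *is* the presentation order; cells no row claims
stay empty, which is legal and load-bearing (see nh249 below).

Three catalogs ship with the package, authored from Nightingale
Health's public biomarker documentation:

* **nh251** — the current 251-variable profile;
* **nh225** — the legacy 225-variable panel;
* **nh249** — the legacy 249-variable release, represented as the nh251
  layout with the two later additions blanked, so 249-variable results
  render into the familiar 251-variable figure with two visibly empty
  cells rather than a silently different layout.

Each defines 10 grids. The dominant one is the lipoprotein-subclass
block: 14 subclass rows (chylomicrons/extremely large VLDL down to
small HDL) × 12 repeated measures (particle concentration, total
lipids, phospholipids, total/esterified/free cholesterol, triglycerides,
and the five compositional percentages) = 168 cells, roughly 75% of the
225-variable panel. The remaining nine grids group the other measures
by function: particle sizes, apolipoproteins, cholesterol fractions,
other lipids, fatty acids (with their ratio-to-total column), glycolysis
metabolites, amino acids, ketone bodies, and fluid balance &
inflammation. The published figure convention places the
lipoprotein-related blocks to the right of the main block with fatty
acids below them, and the small metabolite blocks along the bottom; the
packaged layout JSONs follow that convention. Where the public
documentation leaves the partition of non-subclass variables into
display blocks open, the grouping here is an editorial choice recorded
in the CSVs — change the data, not the code, to regroup.

The exact biochemical naming in the CSVs is descriptive, and the tests
deliberately assert structure and counts rather than names. The shipped
`ukb_field` keyspace is a **synthetic** illustration of the two-column
mapping-file format (external id → variable id); real external-id
dictionaries are supplied by the user as mapping files, never fetched.

## Alignment semantics

`align_results()` is conservative in what it assumes and loud about
what it finds:

* unmatched input rows and unfilled template cells are *warnings plus a
  machine-readable report*, never errors — partial legacy panels are a
  normal, expected input;
* two result rows resolving to the same variable are an error naming
  the variable, because silently picking one would be wrong either way;
* conservation is an invariant: matched + unmatched = input rows, and
  matched + unfilled = catalog size, always;
* when both `p` and a supplied `-log10(P)` are present, the supplied
  score wins (it may encode sub-double-precision P-values) and a
  discrepancy above 0.01 is warned about.

## Rendering and determinism

Panels are lists of drawing primitives (circles, rectangles, text,
polylines) in an abstract unit coordinate system — one unit is one cell
pitch. Composition translates panels onto a shared canvas and refuses
overlapping regions by name. SVG output is serialised natively with
fixed three-decimal coordinates, no timestamps and no generated ids, so
identical inputs give byte-identical files; that makes golden-file
regression testing and `diff`-able figure review possible. PDF and PNG
go through the grid graphics device; PNG honours `dpi` against a 96-dpi
reference size.

Label margins are sized from character counts (a fixed per-glyph width
estimate) rather than font metrics, because font metrics depend on the
rendering host and would break byte-stability. Overlong labels are
ellipsized at a configurable length rather than shrinking the cell
pitch, and the pitch must be at least `2·rmax` so bubbles can never
collide. Missing cells are blank by default; `na_dot = TRUE` marks them
with a small grey dot when the missing/non-significant distinction
needs to be explicit in print.

The one-step `metab_figure()` is defined as — and tested to be
byte-identical with — the four-step pipeline
(`align_results()` → `make_scales()` → `render_bubble_grid()` /
`render_legends()` → `compose_figure()`).

## The synthetic results generator

`generate_results()` exists so every other module is testable and
demonstrable without any cohort data. It emulates the *shape* of a CETP
genetic-score association profile scaled to higher HDL cholesterol:
positive base effects for HDL subclass measures, negative for VLDL and
triglyceride-related ones, a smooth linear gradient across the 14
subclass rows, Gaussian per-variable noise, and a constant standard
error. P-values are the two-sided normal tail of `estimate/se`, so
estimate, SE, P and `-log10(P)` are mutually consistent by
construction, with `|z|` clamped at 38 to keep P strictly positive in
double precision.

Defaults (base effects around ±0.1–0.3 SD, `se = 0.03`, `noise_sd =
0.04`, `gradient = 0.02` per row) were chosen once to look like a
strong genetic-score analysis in a cohort of a few thousand
participants — strong enough that a 35-cap is actually exercised — and
the magnitudes are documented as illustrative. What the generator does
*not* emulate: correlation between metabolites, heteroscedastic SEs,
and any real cohort's estimates. Tests passing on generated data
therefore demonstrate the plumbing (coverage, alignment, encodings,
determinism), not numerical agreement with any published analysis.

The generator uses the Mersenne-Twister RNG with inversion normal
sampling and restores the caller's RNG state, so fixtures are
reproducible across platforms and `generate_results()` is
side-effect-free.

## Numerical and design choices worth knowing

* **Problem sizes in the test suite**: property checks run on grids up
  to 8×8 over a handful of seeds, capping properties on 10⁴ sampled
  scores, and full-figure determinism on the 225-variable template —
  sizes at which every invariant is already exercised end to end.
* **Legend ticks** always include both domain endpoints; interior ticks
  come from `pretty()` and are thinned near the endpoints so endpoint
  labels (including the "capped" annotation) never collide.
* **Exit codes** in the CLI: 0 success, 1 validation/usage, 2 I/O.
  Warnings (partial matches) never change the exit code, matching the
  alignment module's lenient policy; `--report` writes the alignment
  report as JSON next to the figure.
* **Known limitations**: no interactive output; no font embedding; text
  extents are estimates, so extreme style settings can crowd labels
  even though panel regions never overlap; the packaged layouts target
  the composed multi-panel figure and are not optimised for single-panel
  extraction (render the panel directly for that).
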