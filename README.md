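# bubblegrid

Bubble heatmaps for high-dimensional association results, with packaged
figure templates for the Nightingale Health (NH) NMR metabolomics
panels.

## The problem

An association analysis against an NH metabolomics profile yields one
signed effect estimate and one P-value for each of 225–251 correlated
measures — including 12 lipid measures repeated across 14 lipoprotein
subclasses, whose scientific content is positional (trends across
subclass sizes, contrasts within a subclass). Forest plots cannot show
all of this in one figure. bubblegrid draws each result as a circle in
a categorical grid and dual-encodes the two numbers per cell:

* **colour** = the effect estimate β, on a diverging scale symmetric
  about 0 (colour position `(clamp(β, ±v_max)/v_max + 1)/2` on a
  blue–white–red ramp);
* **size** = significance, `s = −log10(P)` capped at `c`, with circle
  area linear in the capped score:
  `r(s) = sqrt(r_min² + (r_max² − r_min²) · min(s, c)/c)`.

Packaged catalogs lay out the 251-variable (current), 249- and
225-variable (legacy) NH panels as one composed multi-panel figure — a
14 × 12 lipoprotein-subclass block plus nine functional blocks and a
legend — and the same machinery renders arbitrary user-defined grids
(e.g. variants × outcomes). Intended users are epidemiologists and
biobank analysts who need one publication-quality, comparable figure
per analysis.

## Worked example

Synthetic demo results emulate a CETP genetic-score analysis (scaled to
higher HDL cholesterol): VLDL-related measures associate negatively,
HDL-related positively, with a smooth gradient across subclass sizes.

```r
library(bubblegrid)

res <- generate_results("nh225", seed = 1)
head(res, 3)
#>   variable_id   estimate   se            p neglog10p
#> 1  XXL_VLDL_P -0.4050582 0.03 1.523152e-41  40.81726
#> 2  XXL_VLDL_L -0.3726543 0.03 1.990102e-35  34.70112
#> 3 XXL_VLDL_PL -0.4134251 0.03 3.323906e-43  42.47835

load_template("nh225")
#> <bubble_catalog 'nh225': 225 variables, 10 grids>
#>   Lipoprotein subclasses             14 x 12 (168 filled)
#>   Lipoprotein particle sizes          3 x  1 (3 filled)
#>   Apolipoproteins                     3 x  1 (3 filled)
#>   Cholesterol                         7 x  1 (7 filled)
#>   Other lipids                        9 x  1 (9 filled)
#>   Fatty acids                         8 x  2 (15 filled)
#>   Glycolysis                          5 x  1 (5 filled)
#>   Amino acids                         9 x  1 (9 filled)
#>   Ketone bodies                       3 x  1 (3 filled)
#>   Fluid balance & inflammation        3 x  1 (3 filled)

fig <- metab_figure(res, "nh225", cap = 35)
fig
#> <bubble_figure: 11 panels, 229 circles, canvas 33.0 x 33.0 units>
write_figure(fig, "cetp_demo.svg")
```

The 229 circles are the 225 data bubbles (one per template variable)
plus 4 reference bubbles in the size legend; `cap = 35` saturates the
size scale at P = 10⁻³⁵, and the first row above shows why (observed
scores reach the 40s). Estimates above are in SD units of each
metabolite per unit of genetic score. The same call with real results
needs only `read_results("yourfile.csv", id_col = ..., est_col = ...,
p_col = ...)` first; identifiers in an external scheme are translated
via a two-column mapping file (`resolve_ids()`/`--mapping`).

For fine control the figure decomposes into four steps —
`align_results()`, `make_scales()`, `render_bubble_grid()` +
`render_legends()`, `compose_figure()` — which produce byte-identical
output, and panels accept labelled row/column brackets
(`add_bracket()`).

### Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bubblegrid", package = "bubblegrid"))')
$CLI fixtures --template nh225 --seed 1 --out demo.csv
$CLI metabfigure --in demo.csv --template nh225 --cap 35 \
    --out fig.svg --report report.json
$CLI validate --catalog nh251
```

Exit codes: 0 success (warnings such as partial matches do not change
it), 1 validation/usage error, 2 I/O error.

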