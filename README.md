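# lactshape

Lactation-curve modelling and gestation-length cohort comparison for
first-parity dairy cattle.

Primiparous cows that calve after an unusually short gestation — whether
spontaneously or after an abortion — enter lactation with less developed
mammary tissue, and their lactation curves differ in shape, not just in
level. `lactshape` is for herd-data analysts who want to quantify that
effect from routine management records: daily milk weights plus
reproduction events (birth, last insemination, calving).

## The model

Each first lactation is summarized by the four-parameter **MilkBot** curve

```
y(t) = a · (1 − e^((c − t)/b) / 2) · e^(−d·t)
```

where `t` is days in milk (DIM), `a` is the **scale** (theoretical maximum
daily yield, kg/d), `b` the **ramp** (rate of rise in early lactation, d),
`c` the **offset** (lag between parturition and the start of lactation, d)
and `d` the **decay** (senescence rate of production capacity, 1/d; lower
decay = higher persistency). Three traits follow in closed form:

* time to peak `t_peak = c − b·ln(2bd / (1 + bd))` (a usable
  within-lactation peak exists when `b·d < 1`);
* peak yield, the curve evaluated at `t_peak`;
* 305-day milk yield
  `M305 = a(1 − e^(−305d))/d − a·b·e^(c/b)(1 − e^(−305(1/b + d)))/(2(1 + bd))`,
  the exact integral of the curve from calving to day 305.

Curves are fitted per lactation by bounded multi-start Levenberg–Marquardt
least squares. Gestation length (GL: last insemination to calving, kept
within 150–297 d) splits the cohort into five categories C-I…C-V — either
at the empirical 1/5/25/75% quantiles or at the fixed reference cut-points
243/267/275/283 d. Each derived trait is then compared across GL
categories with a multi-level mixed model (random herd intercept; fixed
calving month and year; age at first calving as a covariate), reported as
LS-means ± SE with pairwise contrasts (significance p < 0.05, tendency
0.05 ≤ p < 0.10) and compact letter displays.

## Worked example

The package bundles a synthetic-herd generator whose defaults emulate a
multi-herd primiparous Holstein cohort (GL ≈ N(279, 5.5²) days with a rare
short-GL tail, category-dependent curve parameters, 2 kg observation
noise). The whole analysis runs from one configuration:

```r
library(lactshape)
cfg <- list(simulate   = list(n_herds = 12, animals_per_herd = 40),
            categories = list(scheme = "fixed"))
rep <- run_pipeline(cfg, out_dir = "results/demo", seed = 42)
cat(rep$table, sep = "\n")
```

```
Trait                    C-I                    C-II                   C-III                  C-IV                   C-V
--------------------------------------------------------------------------------------------------------------------------------------------
305-day milk yield (kg)  7,359 ± 272^a^         8,303 ± 245^bc^        8,306 ± 115^b^         8,522 ± 103^c^         8,296 ± 120^b^
Scale                    30.6 ± 1.12^a^         34.6 ± 1.01^bc^        35.5 ± 0.49^b^         36.4 ± 0.44^c^         35.5 ± 0.51^b^
Ramp                     27.3 ± 1.30^a^         28.4 ± 1.16^a^         29.7 ± 0.36^a^         29.5 ± 0.24^a^         29.3 ± 0.40^a^
Decay                    0.00119 ± 0.000072^a^  0.00124 ± 0.000064^a^  0.00137 ± 0.000020^b^  0.00137 ± 0.000014^b^  0.00138 ± 0.000022^b^
Time to peak (d)         78.3 ± 2.35^a^         78.5 ± 2.10^a^         78.3 ± 0.65^a^         77.8 ± 0.45^a^         77.2 ± 0.73^a^
Peak yield (kg)          27.0 ± 0.97^a^         30.4 ± 0.88^bc^        30.7 ± 0.42^b^         31.5 ± 0.37^c^         30.7 ± 0.44^b^
Lactations               9                      11                     116                    251                    93
```

Cells are LS-means ± SE; categories sharing a superscript letter do not
differ at p < 0.05. Here the 9 shortest-gestation lactations (C-I) yield
roughly 950 kg less 305-day milk than the bulk categories, driven by a
lower scale and peak — the pattern the generator builds in. `out_dir`
receives `lactations.csv`, `fitted_params.csv`, `categories.csv`,
`comparison.csv`, `contrasts.csv` and a `report.json` with per-stage
counts, filter tallies, the category scheme and variance components.

The same pipeline runs on real delimited tables (`input:` block with
`milkings.csv` and `repro.csv` paths instead of `simulate:`), and from the
shell via the thin wrapper:

```sh
Rscript inst/cli/lactshape.R run --config run.yaml --out results/ --seed 42
```

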