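# xylemclim

Direct and indirect environmental control of conifer xylem anatomy.

Trees at climatic treelines record their environment twice over: seasonal
climate acts *directly* on wood formation (cell-wall deposition is
temperature-limited, lumen expansion is water-limited), while the
environment's cumulative effect on *tree height* acts indirectly — taller
trees build wider conduits at a given stem height to keep hydraulic
resistance constant along the path ("conduit widening"). Disentangling
the two requires following individual trees through time and modeling
anatomy as a function of both height and climate at once.

`xylemclim` is an R package for exactly that analysis, aimed at
dendroecologists and quantitative wood anatomists. It takes per-tracheid
measurements (as produced by image-analysis tools), ring-width series
(Tucson `.rwl` or long CSV), monthly climate and tree metadata, and runs:

1. **Height reconstruction** — missing-ring imputation (pooled 10-year
   windows), backward DBH recursion
   (`DBH_{t-1} = DBH_t − 2·rw_t`), and linear height interpolation
   `h_it = h_i0 + a_i·DBH_it` anchored at the coring height and the
   measured sampling height.
2. **Trait chronologies** — earlywood/latewood classification by Mork's
   index (`MI = 4·CWT_rad / LD_rad`, latewood at `MI ≥ 1`) and annual
   means of lumen area (LA), conduit reinforcement
   (`TB² = (2·CWT_s/B_s)²`, thinner wall side), anatomical density
   (`DEN = CWA/(CWA+LA)`) and cell-wall thickness (CWT).
3. **Seasonal climate** — previous fall / previous winter / spring /
   summer temperature means and precipitation sums per ring year.
4. **Mixed models** — for each trait × portion, REML estimation of

   ```
   y_it = x_it' β + b_0i + b_1i h_it + b_2i h_it² + ε_it
   ```

   with 29 fixed effects (site, h, h², 8 seasonal predictors, site ×
   climate interactions), diagonal per-tree random effects,
   continuous-lag AR1 errors (`cor = φ^|Δyear|`) and per-tree variance
   weights — the REML engine is implemented in the package (tridiagonal
   AR1 precision + Woodbury identity, RcppArmadillo) and is validated
   against a dense-covariance oracle and against `nlme::lme`.
5. **Inference and counterfactuals** — Tukey-adjusted pairwise site
   contrasts with compact letter displays, and predictions with height
   (or summer temperature) held at its mean to isolate each pathway.

A synthetic-data generator (`generate_dataset()`) emulates the full study
— three contrasting treeline sites, negative-exponential ring-width age
trends, within-ring anatomical gradients, configurable height/climate/
site effect structure with AR1 noise — with known ground truth, so every
stage is testable end to end. Site height–diameter allometries use the
modified Weibull curve `h = h_max·exp(a·DBH^b)`, and regional-curve
ring-width/age relationships compose with it into age–diameter–height
ontogenies.

## Worked example

```r
library(xylemclim)

# one synthetic study at the default design: 3 sites x 6 trees x ~80 rings
ds <- generate_dataset(seed = 42)

heights  <- reconstruct_heights(ds$tree_set$rings_observed, ds$tree_set$trees)
chron    <- build_chronology(ds$cells)
seasonal <- aggregate_seasons(ds$climate, years = unique(heights$year))

spec <- xylem_model_spec("la", "ew")      # earlywood lumen area
md   <- build_model_data(chron, heights, seasonal, ds$tree_set$trees, "la", "ew")
std  <- standardize(md, spec)
fit  <- fit_reml(std$data, spec, record = std$record)

tab <- coef_table(fit)
tab[tab$term %in% c("siteC-D", "siteC-M", "temp_summer", "h", "h2"), ]
site_contrasts(fit)$means
```

Output (abridged):

```
        term estimate     se   df     t        p stars
     siteC-D   0.4762 0.3683   15  1.29 2.16e-01
     siteC-M   0.3030 0.3329   15  0.91 3.77e-01
 temp_summer   0.0965 0.0841 1408  1.15 2.51e-01
           h   0.8926 0.1169 1408  7.64 4.04e-14   ***
          h2  -0.1464 0.1282 1408 -1.14 2.54e-01
AR1 phi = 0.37, residual SD = 0.55, random-effect SDs = 0.359/0.001/0.125

 site  emmean    se letters
  W-D -0.0799 0.234       a
  C-D  0.3963 0.284       a
  C-M  0.2231 0.236       a
```

Read: a one-SD increase in reconstructed tree height raises earlywood
lumen area by 0.89 SD (p < 0.001) — the indirect, height-mediated route —
while summer temperature shows no direct effect on this trait at the
reference site, matching the structure this dataset was generated with.
Site marginal means (at average height and climate) share one
significance letter: no site-level offset survives the Tukey adjustment
here. The years-long memory of the residuals (φ = 0.37) and the
between-tree spread of intercepts (0.36 SD) are estimated alongside.

`counterfactual_predict(fit, "height")` then re-predicts every
observation with height held at its mean; the difference from the full
prediction is exactly the height terms' contribution (fixed slopes plus
each tree's random slopes).

The whole chain, including an 8-model coefficient matrix, contrasts,
predictions and a markdown report, runs from one config:

```r
run_pipeline(list(synthetic = list(seed = 1), out_dir = "run1"))
```

or from the shell via the thin CLI in `inst/cli/xylem.R`
(`generate`, `run`, `recover` subcommands).

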