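# pon1qsar

QSAR models for the substrate-dependent hydrolysis rates of the human serum
paraoxonase-1 (PON1) Q192 and R192 isozymes.

PON1 is a Ca²⁺-dependent lactonase whose position-192 polymorphism (Gln "Q"
vs Arg "R") changes how fast it hydrolyzes lactones, thiolactones, aryl
esters and organophosphates — chemically similar substrates can differ more
than 30-fold. `pon1qsar` is for computational chemists and QSAR modellers
who want to reproduce, probe, or extend four-variable multiple-linear
regression models of the form

    log10(A) = b0 + b1·d1 + b2·d2 + b3·d3 + b4·d4

where `A` is the relative hydrolysis rate (phenyl acetate = 100) and the
`d_j` are 3D molecular descriptors, with the descriptor subset selected by a
genetic algorithm scored on leave-one-out cross-validation (GA-MLR).

The package provides:

- **the curated 30-substrate rate table** (`pon1_dataset()`), with SMILES
  curated from the compound names, per-isozyme rates and the original
  test-set markings;
- **descriptor operators implemented from their literature definitions**:
  mass-weighted 3D-MoRSE signals `Mor01m`–`Mor32m`
  (Σ wᵢwⱼ sin(s·rᵢⱼ)/(s·rᵢⱼ)), the van-der-Waals-volume-weighted WHIM
  accessibility index `E1v`, the mass-weighted GETAWAY autocorrelation
  `H8m` built on the molecular influence matrix H = M(MᵀM)⁻¹Mᵀ, and the
  order-0 structural information content `SIC0`;
- **deterministic conformer embedding** (ETKDG distance geometry + MMFF94,
  via the RDKit toolkit's Python interface) behind
  `compute_descriptor_matrix()`;
- **model search and validation**: correlation pre-filter at |r| > 0.95,
  the ordered 80:20 response split, `ga_select()`, and a validation battery
  (R², R²adj, RMSE, MAE, CCC, s, F; Q²LOO by closed-form PRESS; Q²LMO;
  external R²/RMSE/MAE/CCC; `y_scramble()`);
- **applicability-domain analysis**: leverages, the critical hat
  h\* = 3(p+1)/n, standardized residuals, Williams classification and
  `autoplot()`;
- **the two published four-variable equations as fixtures**
  (`pon1_model("Q")`, `pon1_model("R")`) and a synthetic-data generator
  (`pon1_like()`) with planted signals so every stage is testable without
  chemistry in the loop.

## Worked example

A full run on the packaged Q-isozyme data — descriptors, filter, split,
GA-MLR, validation, applicability domain:

```r
library(pon1qsar)

run <- run_pipeline(run_config(isozyme = "Q", seed = 1))
print(run)
#> <qsar_run>
#>   dataset: 30 compounds, isozyme Q
#>   descriptors: computed 35 columns for 30 compounds
#>   correlation filter (|r| > 0.95): 35 -> 35 columns
#>   ordered split (period 5): 24 train / 6 test
#>   GA-MLR: 5952 subsets scored, best fitness 0.6645 (Mor09m+Mor17m+Mor30m+Mor31m)
#>   validation: R2tr = 0.764, Q2LOO = 0.664, R2ext = 0.752
#>   applicability domain: h* = 0.625, 0 structural / 0 response outliers

tidy(run$model)
#> # A tibble: 5 × 2
#>   term        estimate
#>   <chr>          <dbl>
#> 1 (Intercept)    0.176
#> 2 Mor09m        -1.99
#> 3 Mor17m         2.84
#> 4 Mor30m         2.06
#> 5 Mor31m         4.13
```

Reading the output: the 24-compound training fit explains 76% of the
variance in log10 rate, leave-one-out cross-validation retains Q² = 0.66,
and the 6 held-out compounds are predicted with R²ext = 0.75 — the same
regime as the published Q model. The selected subset again contains
`Mor17m` with a positive coefficient, the one descriptor the two published
models share. `h* = 0.625` is the leverage cutoff 3(p+1)/n at p = 4,
n = 24; no compound falls outside the applicability domain.
`autoplot(run$ad)` draws the Williams plot.

The published equations themselves are available as fixtures and evaluate
exactly as printed:

```r
predict(pon1_model("Q"), data.frame(Mor10m = 0, Mor17m = 0, E1v = 0, H8m = 0))
#> [1] -0.487
predict(pon1_model("R"), data.frame(SIC0 = 0, Mor17m = 0, Mor22m = 0, Mor25m = 0))
#> [1] 4.879
```

Note that applying the published *coefficients* to descriptors computed by
this package is a provenance demonstration only: the original models were
fitted on descriptors from a proprietary toolchain and different conformers,
so their coefficients do not transfer numerically (see the methods
vignette, `vignettes/pon1-qsar-methods.Rmd`).

## A command-line entry point

A thin CLI over the package functions lives at `inst/cli/qsar.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "qsar.R", package = "pon1qsar"))')" \
  train --isozyme Q --seed 1 --out runs/q-model
```

Subcommands: `descriptors`, `train`, `validate`, `ad`, `simulate`,
`fixtures`; options can come from a YAML config file (`--config`) with CLI
flags taking precedence.
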