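# eimm — eco-intersectional multilevel (MAIHDA) models for area-level exposure inequalities

`eimm` implements eco-intersectional multilevel (EIM) analysis: the
ecological form of MAIHDA (Multilevel Analysis of Individual Heterogeneity
and Discriminatory Accuracy), in which small geographic areas (level 1) are
nested within intersectional *strata* (level 2) — cross-classifications of
categorised area characteristics such as deprivation, ethnic composition,
education, urbanicity and age structure. It is aimed at researchers in
social epidemiology and environmental justice who want to quantify how
unequally a continuous area-level exposure (e.g. annual mean NOx, µg m⁻³)
is distributed across community types, and how much of that inequality is
additive versus intersectional.

## The model

Each area *i* in stratum *j* is modelled with a two-level Gaussian
random-intercept model estimated by exact maximum likelihood:

    y_ij = x_j' β + u_j + e_ij,   u_j ~ N(0, σ²_u),   e_ij ~ N(0, σ²_e)

* **Null models** put only an intercept in x: σ²_u then measures total
  between-stratum inequality, summarised by the **variance partition
  coefficient** VPC = σ²_u / (σ²_u + σ²_e).
* **Main-effects models** add the stratum-defining categories as dummies:
  the drop in σ²_u is the **proportional change in variance**
  PCV = (σ²_u,null − σ²_u,adj) / σ²_u,null, the additive share of the
  inequality; the residual VPC is attributed to interaction effects.
* The empirical-Bayes stratum residuals û_j = R_j · (raw stratum mean
  residual), with reliability R_j = σ²_u / (σ²_u + σ²_e/n_j), are the
  stratum-specific **interaction effects**: departures from additively
  expected means, shrunken toward zero for small strata. A stratum is
  flagged when û_j ± 1.96·√(σ²_u(1−R_j)) excludes zero.

The likelihood is evaluated per stratum in closed form from sufficient
statistics with β profiled out by GLS, so a fit on 33,755 areas takes
milliseconds.

## Worked example

```r
library(eimm)

sim <- simulate_areas(preset_study_like(seed = 1))  # 33,755 synthetic areas
res <- run_model_sequence(sim$table)
print(res)
```

```
EIM model sequence
 model n_areas n_strata sigma2_u sigma2_e    loglik      aic vpc_pct pcv_pct
    1a   33755       54    44.52    58.59 -116743.1 233492.2   43.18      NA
    1b   33755       54    21.25    58.59 -116723.7 233467.3   26.62   52.26
    2a   33755      105    55.94    49.99 -114161.1 228328.2   52.81      NA
    2b   33755      105    27.56    50.00 -114127.0 228276.0   35.54   50.73
     3   33755      105    27.27    50.00 -114126.5 228278.9   35.29   51.25
```

Reading this: models 1a/1b use the four-variable strata (no urban digit,
54 codes), 2a/2b the five-variable strata (108 codes, 105 occupied here),
and model 3 adds the % minority ethnic × urban interaction to 2b. The 2a
VPC of 52.8% says half the outcome variance lies between community types;
the 2b PCV of 50.7% says the additive category effects explain about half
of that, leaving a residual VPC of 35.5% attributed to interaction
effects (this synthetic world is generated with σ²_u = 35 of genuinely
non-additive stratum variance on top of σ²_e = 50, so these are the
numbers the generator should produce). Stratum-level detail:

```r
s <- res$models[["2b"]]$summary
s$top$description[1]
#> "least deprived, high % minority ethnic, low education, urban, not ageing"
nrow(s$significant)   # strata whose 95% EB interval excludes zero
#> 81
```

## Building strata from your own data

```r
tab <- read_area_table("areas.csv")          # area_id, outcome, covariates
st  <- categorize(tab, default_scheme(TRUE)) # five-digit codes, e.g. "21301"
fit <- fit_eim(tab, st, model_spec(names(st$scheme$rules)))
eb  <- eb_residuals(fit)
vpc(fit$sigma2_u, fit$sigma2_e)
```

Code `21301` reads digit-by-digit: mid deprivation (2), low % minority
ethnic (1), high education (3), rural (0), ageing (1).

There is also a command-line driver:

```sh
Rscript inst/cli/eimm run-all --preset study-like --seed 1 --out results/
Rscript inst/cli/eimm fit --input areas.csv --out results/
```

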