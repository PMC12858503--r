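---
title: "Eco-intersectional multilevel models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-intersectional multilevel models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`eimm` analyses a continuous area-level outcome (in the motivating
application, annual mean NOx concentration in µg m⁻³) across
*intersectional strata*: cross-classifications of categorised area
characteristics. Areas i nested in strata j follow a two-level Gaussian
random-intercept model

$$y_{ij} = x_j'\beta + u_j + e_{ij}, \qquad u_j \sim N(0,\sigma_u^2),
\qquad e_{ij} \sim N(0,\sigma_e^2),$$

with both residuals independent and homoscedastic. Because every fixed
covariate is stratum-defining, the fixed design has exactly one distinct
row $x_j$ per stratum — an important structural fact used throughout
(estimation, prediction, and the calibration discussion below).

Assumptions worth stating plainly: Gaussian, homoscedastic errors at
both levels; exchangeable strata (no spatial structure between areas or
strata); and the ecological reading — all inference is about
*neighbourhood-level* inequality, not about individuals living in those
neighbourhoods.

## Stratum construction

`default_scheme()` encodes the study's coding rules, in digit order:

| digit | variable | rule | categories |
|---|---|---|---|
| 1 | IMD deprivation score | fixed 20/60/20 split | 1 least → 3 most deprived |
| 2 | % minority ethnic | tertiles | 1 low → 3 high |
| 3 | % degree-educated | tertiles | 1 low → 3 high |
| 4 | rural/urban flag | pass-through | 0 rural, 1 urban |
| 5 | % aged 65+ | threshold at 25% | 0 not ageing, 1 ageing |

Cut points are nearest-rank empirical quantiles (the value at rank
⌈p·n⌉). Values tied exactly at a cut fall into the **lower** category;
published descriptions of such codings are generally silent on ties, so
this is our convention, chosen so that category sizes are exactly
reproducible from the data alone. With heavy ties two cuts can
coincide, in which case the middle category is structurally empty — the
partition property (category sizes within 1 of the target proportions)
is guaranteed only under distinct values. Higher IMD score is read as
more deprived, so "most deprived 20%" is the top quintile of the score.
The 25% ageing boundary is inclusive (≥ 25); boundary rows are
measure-zero under continuous data. Codes are stored as strings to
preserve digit positions, including the binary 0.

## Maximum-likelihood estimation

The marginal likelihood factorises over strata under the
compound-symmetry covariance. With $n_j$, $\bar y_j$ and the
within-stratum sum of squares $SSW_j$ as sufficient statistics, and
$\lambda_j = \sigma_e^2 + n_j\sigma_u^2$,

$$-2\,\ell(\sigma_u^2, \sigma_e^2) = N\log 2\pi + (N-J)\log\sigma_e^2 +
\sum_j \log \lambda_j + \frac{\sum_j SSW_j}{\sigma_e^2} +
\sum_j \frac{n_j \bar r_j^2}{\lambda_j},$$

where $\bar r_j = \bar y_j - x_j'\beta(\theta)$ and $\beta(\theta)$ is
the GLS solution with stratum weights $n_j/\lambda_j$ — i.e. β is
profiled out exactly at every variance evaluation. The two variances
are maximised by Nelder-Mead on the log scale (relative log-likelihood
tolerance 1e-12, restarted once to guard against simplex collapse),
with the $\sigma_u^2 = 0$ boundary evaluated explicitly: at the
boundary β is the n-weighted OLS independent of $\sigma_e^2$ and
$\hat\sigma_e^2$ has a closed form, so the boundary candidate costs one
evaluation. Whichever of interior/boundary attains the higher
likelihood is returned, with `boundary_u` flagged (the VPC is then 0).
A degenerate all-constant outcome short-circuits to β₀ = c with both
boundaries flagged.

Estimation is ML, *not* REML, deliberately: the PCV compares
$\hat\sigma_u^2$ across models with different fixed parts, and REML's
fixed-part adjustment would break that comparability. The cost is the
textbook downward bias of order p/J in $\hat\sigma_u^2$ when p
stratum-level coefficients are estimated from J strata — visible and
quantified in the tests (see "calibration" below).

Inference on β is Wald with a normal reference (±1.96 for every 95%
interval; stars at 0.05/0.01/0.001). No Satterthwaite or
Kenward-Roger degrees-of-freedom correction is attempted — none is
standard in this literature. AIC counts both variance parameters:
AIC = −2ℓ + 2(p + 2).

The engine is verified two independent ways: against a dense-matrix
oracle (explicit N×N covariance, grid search plus refinement of the
same likelihood) on random small instances, and against `lme4::lmer`
with `REML = FALSE` on a simulated study-scale dataset (agreement to
~1e-7 in log-likelihood).

## Empirical-Bayes stratum effects

The published analyses interpret stratum residuals from main-effects
models as intersectional "interaction effects" but never write the
predictor; we freeze the standard two-level normal posterior mean:

$$\hat u_j = R_j \bar r_j, \qquad R_j =
\frac{\sigma_u^2}{\sigma_u^2 + \sigma_e^2/n_j}, \qquad
SE(\hat u_j) = \sqrt{\sigma_u^2 (1 - R_j)},$$

with plug-in ML variances. $SE$ is the *comparative* (posterior) SD; a
stratum is flagged as having a significant interaction effect when
$\hat u_j \pm 1.96\,SE$ excludes zero, with no multiplicity
correction — matching apparent practice in caterpillar-plot based
reporting, and stated prominently here because 90+ simultaneous
intervals at 5% will flag several strata by chance under any
nearly-null configuration.

Stratum predictions are $x_j'\hat\beta + \hat u_j$ with intervals from
the EB posterior SD only; fixed-part uncertainty is **not** propagated
(the source analyses give no formula for their prediction intervals;
this choice is documented rather than guessed). Ranks sort descending
by prediction, ties broken by code lexicographically, so output tables
are byte-stable under row permutations of the input.

### Calibration properties of the flag rule (what a green test means)

Two facts established by simulation in the acceptance suite, stated
here so nobody over-reads the flags:

* **Under additive truth the rule is conservative, not 5%.** With
  $\sigma_u^2 = 0$ in truth, $\hat\sigma_u^2$ collapses to the boundary
  and shrinkage sends every $\hat u_j$ and its interval to zero: the
  observed flag rate is ~0%, because $\hat u_j / SE$ has null variance
  $R_j < 1$. A nominal-5% expectation would hold only for an
  unshrunken test with known fixed part; the corresponding acceptance
  criterion is therefore left red, with the conservative direction
  asserted instead as the attainable property.
* **The comparative SE understates total uncertainty for large
  strata.** $\bar r_j$ contains the fixed-part estimation error
  $x_j'(\hat\beta - \beta)$, which the comparative SD ignores. In this
  ecological design each covariate pattern is exactly one stratum, so
  that error does not average out; for large $n_j$ it dominates the EB
  SD and interval coverage of the true $u_j$ degrades. This is
  structural to stratum-level MAIHDA machinery, not an implementation
  artefact; the frozen formulas are kept because they are what the
  field's software reports.

Relatedly, a single-stratum deviation δ is partially absorbed by the
fixed part: with GLS leverage $h_j = w_j x_j'(X'WX)^{-1}x_j$, the
recoverable effect is $R_j(1-h_j)\delta$, not $R_j\delta$. The
injection-recovery acceptance test uses this leverage-corrected target
(h ≈ 0.15 for a 300-area stratum in a 4,800-area world).

## The synthetic-data generator

`simulate_areas()` emulates the *statistical* structure of the
motivating national dataset, nothing geographic. Covariates come from
a Gaussian copula: lognormal deprivation score (meanlog 2.874, sdlog
0.635 — mean ≈ 21.7 above median ≈ 17.7, matching the right skew of
published IMD descriptives), Beta-distributed percentage variables
moment-matched to published means/SDs, urbanicity cut at prevalence
0.8294, and latent correlations chosen once for plausibility (minority
share up with urbanicity and education; 65+ down with urbanicity). The
point of the copula is not demographic realism but *uneven occupancy*:
at study scale it occupies ~100 of 108 strata with sizes from 1 to
thousands, leaving some codes empty, as real cross-classifications do.

The outcome is built additively from per-category effects (defaults
anchored to the magnitude of published main-effects estimates:
minority tertile effects up to ~10.7 µg m⁻³, urban ~3.8, ageing
~−1.8, intercept 10.75), plus an optional per-code injected
interaction effect, plus $u_j \sim N(0, \sigma_u^2 = 35)$ drawn for
every *possible* code in fixed order (so a code's draw is independent
of occupancy), plus area noise with $\sigma_e^2 = 50$. Under the
default seed-driven preset the outcome mean ≈ 21 and SD ≈ 10–11, and a
main-effects fit returns a residual VPC inside [0.35, 0.50].

What the generator does **not** emulate — and therefore what no green
test establishes anything about: spatial autocorrelation, skewed or
bounded outcomes (simulated concentrations can go slightly negative in
the cleanest rural strata; real ones cannot), measurement error in
covariates, and any causal structure. The truth record (including the
realised $u_j$) is returned on a separate channel from the table so
fitting code cannot see it.

Replication designs offset the seed deterministically
(`seed = base + r`); every randomness source in the package flows from
the config seed, and the caller's RNG state is restored on exit.

## Simulation-experiment design choices

* *Variance recovery* is assessed by fitting the null model to a world
  with additive effects switched off, i.e. the generating model equals
  the fitted model. Fitting the 10-parameter main-effects model
  instead would shift $E[\hat\sigma_u^2]$ to roughly
  $\sigma_u^2 (J-p)/J$ (≈ 31.7 at truth 35 with J ≈ 94) — an ML
  property, informative but not a recovery failure, so it is kept out
  of the recovery check and noted here.
* *CI coverage* for fixed effects is assessed in the full study-like
  world with the main-effects model (pooled coverage ≈ 0.93, slightly
  below nominal for the same ML-bias reason).
* *Injection recovery* uses a background interaction variance of
  $\sigma_u^2 = 10$ — the residual, post-main-effects between-stratum
  scale seen in such studies (~7–9 µg² m⁻⁶) — rather than the null
  model's 35, because the experiment isolates one multiplicative
  deviation against realistic residual heterogeneity. The target
  stratum (code 23310) was chosen for its expected occupancy of ~300
  areas at n = 4,800 under the default covariate model.

## Numerical choices and degenerate inputs

Log-scale optimisation keeps variances positive without constraints;
convergence is declared on relative log-likelihood change (1e-12),
with the reported parameters accurate to ~√tol (the likelihood is
quadratically flat at its maximum — log-likelihood agreement is the
sharp test, and is what the oracle-equivalence criterion checks at
1e-6). Singular designs are rejected with the collinear columns named
from the QR pivot. Strata with $n_j = 1$ contribute no within
information but are fully supported; $n_j = 0$ codes never enter the
likelihood and are listed separately as empty. Percentages are
formatted half-up at two decimals; full precision is kept in all data
CSVs, display rounding only in human-readable summaries.

## Known limitations

No spatial error structure (published sensitivity analyses suggest
spatially correlated errors can drive the VPC to zero — a substantive
caveat for any EIM application); Gaussian outcomes only; exactly two
levels; EB intervals as frozen above (no fixed-part variance, no
multiplicity control); and the PCV is only defined between models
sharing a stratum structure — the package enforces that pairing (1b
vs 1a, 2b vs 2a, 3 vs 2a) rather than leaving it to the caller.
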