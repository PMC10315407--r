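---
title: "Within-class fatty-acid lipidomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-class fatty-acid lipidomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidfa)
```

# The analytic unit: within-class fatty acids

Shotgun lipidomics platforms report absolute concentrations (µmol/L) of
molecular lipid species written in shorthand, `CLASS(C:D/...)`, where each
acyl chain is identified by its carbon count `C` and number of double bonds
`D`. Sixteen lipid classes are supported, carrying one chain per molecule
(CE, MAG, CER, DCER, LCER, HCER, SM, LPE, LPC), two (DAG, PC, PE, PEO, PEP,
PI) or three (TG). Chain identity deliberately ignores double-bond position
and geometry, because infusion MS/MS assays generally cannot resolve them;
two chains are equal iff both counts match.

The package's central quantity is the *within-class fatty-acid
concentration*: for a class $c$ and fatty acid $f$,

$$\mathrm{FA}_{c,f} = \sum_{s \in c} m_{s,f} \, x_s,$$

where $x_s$ is the species concentration and $m_{s,f}$ the *multiplicity* —
how many chains of $f$ the molecule $s$ carries. A DAG with two palmitic
chains contributes twice to DAG[16:0]; a mixed 16:0/14:0 DAG contributes
once each to DAG[16:0] and DAG[14:0]. For one-chain classes the within-class
fatty acid equals the species concentration. Class totals are plain
unweighted sums, giving the conservation law
$\sum_f \mathrm{FA}_{c,f} = k_c \cdot \mathrm{Total}_c$ with $k_c$ the class
arity — the identity the aggregation tests enforce to $10^{-9}$ relative.
Pairs with no observed species are left absent rather than zero-filled.

# Left-censored imputation

Missingness in this type of data is dominated by concentrations below the
detection limit, i.e. *left-censoring*. Species missing in at least 75% of
samples are excluded outright (the threshold is a configuration value; the
rule is `>=`). For the rest, `impute_qrilc()` works per species on the
natural-log scale:

1. the mean $\mu$ and SD $\sigma$ of the uncensored log-normal are estimated
   by least-squares regression of the observed order statistics on standard
   normal quantiles, evaluated at Blom plotting positions shifted by the
   censored count — the observed values occupy the upper ranks of the full
   sample;
2. each missing cell is drawn from $N(\mu, \texttt{tune\_sigma}\cdot\sigma)$
   truncated above at the species' minimum observed log-concentration;
3. values are exponentiated back.

Observed cells are never altered, and no imputed value can exceed the
observed minimum — the censoring semantics. On a censored log-normal with
$n = 1000$ and 20% censoring the regression recovers $(\mu, \sigma)$ within
5%. Species with fewer than three observed values cannot support the
regression and are set to half the global minimum observed concentration,
flagged in the report. Randomness is governed by a master seed; each
species draws from a substream derived from the seed and the observed
column, so identical observed columns impute identically regardless of
position.

Imputation is run separately per visit stratum (week 0 and week 16), so an
intervention cannot leak into baseline imputations; the exclusion pass is a
single joint pass across visits. Both choices are conservative defaults for
a randomized trial where the assay and detection limits are common across
visits.

# Dietary-arm effects

For every within-class fatty acid, the post-intervention concentration is
log-transformed and z-normalized (sample SD, $n-1$) and regressed on two
intervention-arm dummies (SFA-rich arm as reference) adjusted for age, sex,
BMI, the baseline concentration of the same within-class fatty acid, and
the baseline and post-intervention totals of its lipid class. Concentration
covariates enter on the log scale, consistent with the outcome transform.
Arm coefficients are therefore SD shifts versus the reference diet, with
two-sided t-tests. Constant concentration covariates are dropped as inert
rather than declared collinear; any other rank deficiency is an error
naming the offending columns. Familywise control is Bonferroni with an
explicit family size $m$ (default: the number of models fitted), since
published analyses sometimes fix the denominator externally; the
significance threshold is $0.05/m$. Residual-normality diagnostics
(Shapiro–Wilk) can be logged per model; they never gate results.

# Elastic-net stability selection

Changes from baseline (week 16 − week 0; never log-transformed, as deltas
can be negative) in the within-class fatty acids — z-normalized — are
linked to changes in each cardiometabolic risk marker with elastic-net
regression,

$$\min_{\beta_0,\beta}\; \tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
 + \lambda\left(\alpha\lVert\beta\rVert_1 +
 \tfrac{1-\alpha}{2}\lVert\beta\rVert^2\right),$$

solved by cyclic coordinate descent with soft-thresholding (compiled;
unpenalized intercept; convergence when no coefficient moves by $10^{-7}$;
active-set iteration between full sweeps). At $\lambda = 0$ the solution is
OLS; with one standardized predictor and $\alpha = 1$ it is the
soft-threshold closed form — both serve as oracles in the tests, alongside
a KKT subgradient check and a glmnet cross-check at $\alpha = 1$.

Hyperparameters are tuned by averaging test-set MSE over ten seeded random
80/20 train/test splits on a grid of $\alpha \in \{0.1, \dots, 1.0\}$ and
50 log-spaced $\lambda$ values spanning four decades below the per-alpha
$\lambda_{\max}$. A "ten-fold CV with 80/20 splits" is internally
inconsistent (ten-fold implies 90/10); the explicit 80/20 fractions are
honored, as repeated random splits. Selection follows the one-standard-error
parsimony rule by default — the sparsest pair whose mean MSE lies within one
SE of the minimum — which is the standard operationalization of optimizing
model complexity while minimizing prediction error; plain minimum-MSE
selection (ties broken toward larger $\lambda$, then larger $\alpha$) is
available via `rule = "min"`.

Stability selection then refits the tuned model on ten fresh seeded 80/20
splits (fresh, because the tuning and selection stages are described as
separate procedures). A predictor counts as selected in an iteration iff
its coefficient is nonzero; predictors selected in at least 9 of 10
iterations are retained, and their final coefficient is the mean over the
iterations in which they were nonzero (zero entries from non-selecting
iterations are not averaged in — mixing selection and estimation would
shrink retained coefficients for reasons unrelated to the data). Held-out
predictions from every iteration are collated and the overall Pearson
correlation with the measured values is the performance proxy. An empty
retained set is a valid result and is flagged; the collated correlation is
then based on intercept-only predictions and should be treated as
undefined.

Retained predictors are finally re-tested in a fully adjusted OLS model per
marker — all retained deltas simultaneously, plus age, sex, BMI, the
baseline marker value and the intervention arm — reporting marker-unit
effects per SD of fatty-acid change with t-based 95% CIs.

# Prentice-weighted case-cohort Cox models

Associations with incident disease use a nested case-cohort design: a
random subcohort serves as the comparison set, and all incident cases enter
regardless of subcohort membership. Under the Prentice scheme the risk set
at failure age $t$ contains all subcohort members under observation
($\mathrm{entry} < t \le \mathrm{exit}$) plus any case failing exactly at
$t$; non-subcohort cases contribute to no other risk sets. The
pseudo-partial-likelihood is maximized by Newton–Raphson with Breslow tie
handling, on the age timescale with left truncation at entry age.
Convergence requires a score below $10^{-8}$ or a relative log-likelihood
change below $10^{-10}$; a coefficient diverging past $|\beta| > 15$ is
reported as separation. Variance is the robust sandwich grouped by
individual, since the model-based inverse information is anti-conservative
under case-cohort weighting; hazard ratios are per SD of the
log-transformed, z-normalized exposure, each model adjusted for the log
class total of the exposure's lipid class. With the whole cohort flagged as
subcohort the fit coincides with standard Cox regression to $10^{-6}$ —
verified against an independent implementation — and on true case-cohort
data it matches the epsilon-entry construction of the same likelihood.
Benjamini–Hochberg FDR (via `p.adjust`) and Bonferroni with $m = 41$-style
explicit family sizes are reported side by side, since published analyses
have used either for the same panel. Scaled Schoenfeld residuals correlated
with event age provide proportional-hazards diagnostics; they are reported,
never used as gates.

# The synthetic-data generators

Because the motivating cohort data are not publicly deposited, the package
ships generators that emulate the statistical structure each stage assumes;
all analyses and calibration claims in this package are computed on these
synthetic data.

`gen_trial()` draws a three-arm, 113-participant trial (38/39/36 per arm,
reflecting a completed dietary-fat intervention of that shape) over a fixed
~66-species miniature panel spanning all 16 classes and 12 fatty acids.
Baseline log-concentrations are Gaussian with within-class exchangeable
correlation $\rho = 0.4$; week-16 values track baseline with latent
correlation 0.3, chosen so that the arm-coefficient standard errors land
near the mid-0.1 range typical of adjusted z-scale analyses at this sample
size. Intervention effects are specified per (within-class FA, arm) in SD
units; the generator scales every species containing the target fatty acid
by a common factor — which moves the aggregate by exactly the configured
log shift — and rescales the remaining species of the class so the class
total is preserved, keeping the total-adjustment covariates unconfounded
with the arm. The log shift is inflated by
$1/\sqrt{1 - z^2 p(1-p)}$ so the configured value is recovered on the z
scale of the analyzed outcome, whose SD includes the shift-induced
between-arm variance. Detection-limit censoring replaces values below a
per-species quantile of the pooled concentrations with missing; one
species carries an 0.8 quantile so the 75% exclusion rule is exercised.
Risk markers are baseline plus a linear combination of z-scored
within-class FA changes plus Gaussian noise, with default coefficients
matching the effect sizes the confirmatory models are designed to detect
(e.g. LDL change of 0.20 per SD of CE[18:0] change and 0.15 per SD of
TG[12:0] change).

`gen_casecohort()` simulates a cohort (default 5000) with entry ages
uniform on 35–65, a constant baseline hazard on the age timescale
calibrated by moments to a target case count (default ~180), exponential
residual event times under a proportional-hazards linear predictor
(z-scored exposure with configurable true log hazard ratio; sex, one
continuous and one binary confounder; a correlated log class total), and
administrative censoring after 6–10 years of follow-up. Exit age is the
minimum of event and censoring age. The emitted table is the random
subcohort (default 300) plus all cases, satisfying the case-cohort record
invariants by construction, with the generating parameters attached for
recovery tests. The defaults are a deliberate scale-down of a
1262-subcohort design with several hundred cases per endpoint, sized so
that hundreds of replicate fits run in seconds.

What these generators do *not* emulate: mass-spectrometry noise physics,
batch and drift structure, correlated missingness between related species,
non-log-normal tails, informative censoring of follow-up, or the full
17-covariate confounder set of a real cohort analysis (a reduced set is
used; additional covariates add nothing testable). Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the stated generating model, not that any particular biological finding
replicates on real data.

# Numerical and design details

* Sample SDs use the $n-1$ denominator everywhere; z-scores are exact to
  $10^{-10}$ mean-0/SD-1 by construction.
* The elastic-net path is solved warm-started from large to small
  $\lambda$; tuning uses a looser solver tolerance ($10^{-5}$) than final
  fits ($10^{-7}$), since the selected pair is refit exactly downstream.
* All randomness derives from explicit integer seeds; stages accept no
  ambient entropy, and rerunning any function with the same inputs and
  seed is byte-identical. `run_pipeline()` writes a manifest with MD5
  checksums of all inputs and outputs to make this checkable.
* Ties at identical event ages are handled by the Breslow approximation —
  the simplest form consistent with the weighted pseudo-likelihood; with
  continuous simulated ages ties are measure-zero anyway.
* Problem sizes in the test suite (e.g. 200 case-cohort replicates, 500
  global-null trial replicates, 20 pure-noise stability-selection runs)
  were chosen as the smallest giving stable Monte-Carlo assertions at the
  stated bounds.

# Known limitations

* The within-class aggregation assumes every species name parses under the
  supported 16-class taxonomy; unknown vendor dialects must be added to
  the alias table.
* The QRILC-style imputation assumes per-species log-normality and a
  sharp detection limit at the observed minimum; heavy-tailed species or
  probabilistic censoring will bias $(\mu, \sigma)$.
* Stability selection treats "nonzero coefficient" as selection; at small
  $\alpha$ the elastic net rarely produces exact zeros, so retention is
  most meaningful for $\alpha$ near 1 — one reason the parsimony rule
  matters.
* The case-cohort fitter supports Prentice weighting only; Barlow,
  Self–Prentice and Lin–Ying weightings are out of scope, as are competing
  risks and time-varying coefficients (beyond the Schoenfeld diagnostic).
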