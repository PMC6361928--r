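---
title: "Models and methods behind gweis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gweis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
per-SNP models and tests, the questionnaire scales, the polygenic
scoring rules, the evaluation layer, and — because the package ships its
own synthetic-data generator — exactly what that generator does and does
not emulate. Design choices that were genuinely open are flagged as
such, with the reasoning.

## The per-SNP models

For a quantitative symptom score $Y$, an exposure count $E$ (e.g. a
stressful-life-events tally), dosage $G \in \{0,1,2\}$ of the effect
allele and a covariate matrix $C$ (age, sex, principal components), the
additive scan (`run_gwas()`) fits per SNP

$$Y = \beta_0 + \beta_G G + \gamma' C + \varepsilon$$

by ordinary least squares with classical standard errors and t-based
p-values. The interaction scan (`run_gweis()`) fits the full model

$$Y = \beta_0 + \beta_G G + \beta_E E + \beta_{G\times E}\,(G \cdot E)
      + \gamma' C + \varepsilon$$

and reports two tests:

* **1-df GxE**: the Wald z for $\beta_{G\times E}$, $z^2$ referred to
  $\chi^2_1$;
* **2-df joint**: $b' S^{-1} b$ for $b = (\beta_G, \beta_{G\times E})$
  with $S$ their robust covariance block, referred to $\chi^2_2$ — the
  test of the SNP's combined main-plus-interaction contribution against
  both coefficients being zero.

Both use the Huber–White sandwich covariance

$$V = (X'X)^{-1}\, X' \mathrm{diag}(e^2)\, X\, (X'X)^{-1}$$

with raw residuals (HC0, the default) or the small-sample factor
$n/(n-k)$ (HC1, by flag). The motivation is heteroscedasticity:
symptom-score residual variance typically grows with the exposure, and
under such noise the classical variance of the interaction coefficient
is badly underestimated — in the package's own calibration scan
(2000 samples, 5000 null SNPs, residual SD growing linearly in the
exposure) the classical 1-df test rejects at roughly 2–3 times the
nominal 5% while the robust test stays near nominal. HC0 retains a
small finite-sample anti-conservativeness under strong
heteroscedasticity with a skewed exposure (its true rejection rate in
that scan sits slightly above 0.05, a known property of HC0 at
high-leverage design points); HC2/HC3-style leverage corrections would
shrink this but are deliberately out of scope because the classical
Huber–White forms are the ones this field's GWEIS tooling uses.

Assumptions worth stating: the mean model is linear in $G$, $E$ and
$G\cdot E$ on the analysed scale; samples are unrelated (no mixed-model
relatedness correction); the exposure enters on its raw count scale
(the 1-df p-value is invariant to affine rescaling of $E$, a property
the test suite checks); missing dosages are handled by per-SNP listwise
deletion with `n_used` recorded; monomorphic SNPs and singular fits are
flagged, never silently dropped. P-values are accompanied by
`log10_p_*` columns computed on the log scale, so evidence beyond
double underflow survives.

The joint statistic is implemented as a Wald test. A full-vs-null
comparison of the same two coefficients could also be run as a
robust-score or LRT variant; the Wald form was chosen because it needs
only the fitted full model and the robust covariance already computed,
and under the model's assumptions the three are asymptotically
equivalent.

### Inflation diagnostics and thresholds

`genomic_inflation()` reports $\lambda_{GC}$ (median implied 1-df
chi-square over 0.4549364) and the quantitative-trait standardisation
$\lambda_{1000} = 1 + (\lambda_{GC} - 1) \cdot 1000/n$; the latter
formula is a convention choice, documented here because printed
$\lambda_{1000}$ values rarely state it. `bonferroni_threshold()` is
$\alpha / (\text{SNPs} \times \text{tests per SNP})$ — e.g. three
exposure measures over 560,351 SNPs give $2.97\times10^{-8}$, two test
types over 1,009,208 SNPs give $2.48\times10^{-8}$ (prints as
$2.47\times10^{-8}$ when truncated rather than rounded to three
significant figures).

## Questionnaire scales

`score_sle()` counts "yes" responses: the total (TSLE), the subscale of
events potentially dependent on the respondent's own behaviour (DSLE,
items 6–11 of the default 12-item classification), and the independent
subscale (ISLE, items 1–5 with the pregnancy item removed). Item 12
belongs to neither subscale by default; the classification is a plain
tibble argument so other instruments can be mapped. Missing item
responses count as "no" — the instrument yields counts of reported
events, and an unanswered item reports none — with a per-sample
missingness column so callers can apply their own exclusion rule.

`transform_ghq()` returns $\log(1 + \text{raw sum})$ of the 28
Likert-scored items (0–3 each). The +1 offset is a design choice: a raw
sum of zero is common and must stay finite, and the base of the
logarithm is irrelevant to any rank- or regression-based downstream
use. The binary 0-0-1-1 scoring variant is available but not default.
`bin_phq()` recodes a skewed short-form sum onto four points
(0→0, 1–2→1, 3–5→2, ≥6→3). `map_proxy_cases()` implements mapping by
proxy: unaffected first-degree relatives of cases join the case group,
never demoting an actual case.

## Polygenic scores

`clump()` is the greedy LD procedure: repeatedly index the
smallest-p unclaimed SNP (ties broken by chromosome then position, which
makes the result independent of input row order) and claim all
unclaimed SNPs within the window whose dosage $r^2$ with the index
reaches the threshold. Defaults $r^2 = 0.1$, 250 kb, $p_1 = 1$ follow
common PRS practice. `build_weights()` defines the three schemes:
additive ($\beta_G$ from the additive scan, ranked by its p), gxe
($\beta_{G\times E}$, ranked by the robust 1-df p) and joint
($\beta_G + \beta_{G\times E}$, ranked by the 2-df p). The joint weight
is an interpretation that deserves emphasis: "the combined additive and
interaction effect" is here the per-allele effect at one exposure unit,
the natural single number combining the two coefficients; other
combinations (e.g. at the mean exposure) would be defensible and can be
built from the scan columns directly.

`prs_score()` follows PLINK `--score ... sum` semantics: dosages are
re-oriented onto each weight's effect allele (flipping $2-d$ when the
effect allele is the panel's other allele), strand-ambiguous (A/T, C/G)
and allele-mismatched SNPs are dropped with a warning, and missing
dosages impute at twice the target-panel effect-allele frequency. The
simulator never emits ambiguous pairs, so fixtures exercise the drop
path only when constructed to. Raw and standardised scores are both
returned; `prs_threshold_grid()` scores a fixed threshold grid
(5e-8 … 1) and reports incremental $R^2$ per cutoff.

## Evaluation layer

`fit_comparison()` compares nested OLS (or logistic) models that share
the covariates. Variance explained is reported as *model $R^2$ minus
covariate-only $R^2$* — the share attributable to the score terms —
because that is the quantity PRS studies print. The LRT uses exact
Gaussian (or binomial) log-likelihoods, $2(\ell_1 - \ell_0)$ on the
parameter difference; for binary traits the pseudo-$R^2$ is
Nagelkerke's, the convention of the PRS tooling this mirrors, with the
liability scale left to the caller. Identical term sets are allowed and
return the degenerate comparison (statistic 0 on 0 df, p = 1).

`permutation_empirical_p()` permutes the *phenotype* against the intact
(score, covariates) design and counts permuted single-term p-values at
least as extreme, returning $(1+k)/(N+1)$ so zero is impossible. The
alternative — permuting score residuals — tests the same null but does
not match the convention of the empirical p-values this package is
meant to reproduce; the phenotype-permutation choice is therefore fixed
and documented rather than configurable. `fdr_adjust()` is
Benjamini–Hochberg; `improvement_report()` assembles comparisons into
the traits-by-schemes table (percentage improvement
$= \Delta R^2 / R^2_{\text{null}} \times 100$) and BH-adjusts LRT
p-values within each weighting scheme, the family structure of a
multi-trait PRS screen.

## The synthetic-data generator

The generator exists so that every downstream stage is testable at desk
scale. What it emulates:

* **Genotypes**: biallelic SNPs in Hardy–Weinberg proportions, one
  frequency per SNP uniform over `maf_range`. LD comes from two latent
  AR(1) Gaussian haplotype vectors per block (adjacent correlation
  `ld_rho`, default block of 10 SNPs) thresholded at the frequency
  quantile and summed — realised $r^2$ decays along the block and never
  crosses a block or chromosome boundary. Alleles avoid strand-ambiguous
  pairs by construction.
* **Exposure**: a latent liability
  $\sqrt{h^2}\,\text{score} + \sqrt{1-h^2}\,\text{noise}$ over a random
  SNP subset, quantile-mapped onto Poisson counts with mean
  `exposure_mean` (default 2, a typical recent-SLE tally). `exposure_h2`
  is the gene–environment-correlation dial: 0 makes the exposure
  genotype-independent; 0.13 reproduces the heritable-exposure regime
  reported for behaviour-dependent life events. The count
  discretisation attenuates the realised variance explained slightly
  (about 0.12 realised at a configured 0.13), which the recovery test
  bands accommodate.
* **Phenotype**: standardised-dosage additive and interaction
  components, each rescaled so its realised sample variance equals the
  configured fraction exactly (`var_additive`, `var_gxe`), plus
  `beta_E`·E, small fixed-effect covariates, and Gaussian noise with
  $\sigma(E) = \sigma_0 (1 + \text{hetero\_factor}\cdot E)$,
  $\sigma_0 = \sqrt{1 - \text{var\_additive} - \text{var\_gxe}}$. The
  variance fractions are therefore fractions of the unit-variance
  genetic-plus-residual core; the exposure main effect, covariates and
  heteroscedastic inflation add variance on top. Effects are drawn
  standard normal before rescaling, so causal SNPs have a realistic
  spread of magnitudes. The true causal sets and scaled effects are
  returned for recovery tests.

What it does **not** emulate, hence what green tests do not show about
real data: realistic demography and fine-scale LD (a single AR
parameter, no recombination maps), genotyping error and missingness
patterns, imputation dosage uncertainty, relatedness and population
structure, selection on reporting, item-level exposure measurement
error, and binary liability-threshold disease outcomes. Results on this
generator validate the *statistical machinery*, not cohort-specific
biology.

Reproducibility: one integer seed drives everything. The stage
functions draw from fixed offsets of it (genotypes at `seed`, exposure
at `seed + 1`, covariates/phenotype at `seed + 2`), so each stage is
independently reproducible and `simulate_study()` is bit-identical for
identical configs; the pipeline writes byte-identical outputs for the
same config and seed.

## Parameters that matter

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `maf_range` | frequency, (0, 0.5] | (0.05, 0.5) | common variants, post-QC panels |
| `var_additive`, `var_gxe` | fraction of core variance | 0.10, 0.02 | modest polygenic signal; interaction an order smaller |
| `beta_E` | phenotype SD per event | 0.2 | strong, well-detected exposure main effect |
| `exposure_mean` | events | 2 | typical recent-SLE count |
| `exposure_h2` | fraction [0,1) | 0 | gene–environment correlation off unless studied |
| `hetero_factor` | SD multiplier per event | 0 | homoscedastic unless the robust test is being exercised |
| `ld_rho` | latent correlation [0,1) | 0 | independent SNPs unless clumping is being exercised |
| clumping | $r^2$, kb, $p_1$ | 0.1, 250, 1 | common PRS defaults |
| `robust` | HC0/HC1 | HC0 | the classical Huber–White form |

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to what
the checks need, not more: calibration of the robust test uses one
cohort of 2000 samples × 5000 SNPs; effect recovery uses 20 cohorts of
5000 × 300; the PRS model comparison uses 8 replicates of 4000 samples
(half discovery, half target) × 1000 SNPs; the pipeline demo is
2000 × 5000 with 1000 permutations. These run in seconds to a couple of
minutes each and give the assertions comfortable statistical margins.

Numerical details: per-SNP fits go through the Cholesky of $X'X$ with
singular fits flagged; the joint statistic uses the closed-form 2×2
inverse and is flagged when the robust block is numerically singular;
p-values are also emitted as $\log_{10}$; clumping ties break by
(chromosome, position); empirical p uses the $(k+1)/(N+1)$ estimator;
BH adjustment delegates to `stats::p.adjust`. Degenerate inputs —
constant exposure (collinear with the interaction), constant phenotype
in permutation, empty p-vectors, identical nested term sets — raise
errors or return the documented degenerate result rather than NaNs.

## Known limitations

* **Same-discovery score redundancy.** When the additive-weighted and
  GxE-weighted scores are both derived from the same discovery scan of
  the same trait, the additive score already absorbs each
  pure-interaction SNP's main-channel signal (a marginal regression
  estimates $E[E]\cdot\beta_{G\times E}$ for such a SNP), so entering
  the GxE score as an additional main-effect predictor adds only
  second-order information and its incremental LRT is weak at desk
  scale. The package's replicated comparison therefore targets the
  contrast that is structurally identifiable — the combined
  additive + GxE model against the single joint-weighted score, which
  the joint weight's mixing of the two coefficients cannot match — and
  that comparison is the one the acceptance checks assert.
* HC0's slight finite-sample anti-conservativeness under strong
  heteroscedasticity, noted above.
* Quantitative traits only in the scans (the evaluation layer handles
  binary outcomes); no mixed models, meta-analysis, imputation or
  post-scan gene-based machinery.
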