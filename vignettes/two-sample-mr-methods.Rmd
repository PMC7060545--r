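---
title: "Two-sample Mendelian randomization: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

For instrument $j$, the two-sample design observes the SNP–exposure
association $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ from one GWAS
and the SNP–outcome association
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ from
another, where $\theta$ is the causal effect of the exposure on the
(log-odds of the) outcome and $\alpha_j$ is a horizontal-pleiotropy term
that is zero for a valid instrument. Each instrument gives a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order version adding the
exposure-beta uncertainty is available via `se_order = "second"`; the
first-order form is the default because it matches the weighting convention
of the standard summary-data implementations).

The estimators differ in how they defend against $\alpha_j \ne 0$:

- **IVW** pools the ratios with inverse-variance weights
  $w_j = \mathrm{se}_j^{-2}$; it is consistent only if all instruments are
  valid (or pleiotropy is balanced and independent of the weights). The
  multiplicative random-effects model inflates the fixed-effect SE by
  $\max\{1, \sqrt{Q/(k-1)}\}$, where $Q$ is Cochran's statistic — never
  deflating, so the random-effects SE is always at least the fixed one.
- **Weighted median** takes the 50th percentile of the weight-ordered ratio
  distribution (linear interpolation of the standardized cumulative weights
  $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$ at $s = 1/2$; when some
  $s_j$ hits $1/2$ exactly that ratio is returned without interpolation).
  It is consistent while instruments carrying at least half the weight are
  valid. The point estimate is deterministic; only its SE uses a
  parametric bootstrap (default 10,000 draws, mandatory explicit seed).
- **MR-Egger** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with an
  unconstrained intercept after orienting every pair to
  $\hat\beta_{Xj} \ge 0$. Under InSIDE (pleiotropy independent of
  instrument strength) the slope is a pleiotropy-adjusted causal estimate
  and the intercept estimates the average directional pleiotropic effect;
  a two-sided intercept test is the pleiotropy diagnostic. Both coefficient
  SEs carry the same $\max\{1,\cdot\}$ multiplicative-random-effects
  inflation with $k-2$ degrees of freedom.
- **MR-PRESSO** computes, for each instrument, the leave-one-out IVW
  prediction of its outcome beta and the standardized residual; the
  observed residual sum of squares is compared with its distribution over
  datasets simulated under the fitted no-pleiotropy model (betas redrawn
  from their reported sampling distributions, residuals recomputed by the
  identical leave-one-out procedure). Global and per-SNP p-values use the
  add-one empirical construction $(\#\{\cdot\} + 1)/(n_{sim} + 1)$, so they
  are always in $(0, 1]$; per-SNP p-values are Bonferroni-corrected by $k$
  and instruments below `alpha` are removed before a random-effects IVW
  re-estimation. The default
  $n_{sim} = \max(10{,}000, \lceil k/\alpha\rceil)$ keeps the empirical
  resolution finer than the Bonferroni threshold $\alpha/k$.
- **Multivariable IVW** regresses $\hat\beta_{Yj}$ on the matrix of $m$
  exposures' betas without intercept, weights $\sigma_{Yj}^{-2}$, SE
  inflation $\max\{1, \sqrt{RSS_w/(k-m)}\}$; with $m = 1$ it reduces
  exactly to univariable random-effects IVW.

Confidence intervals and p-values use normal quantiles throughout (no
$t$ corrections): this matches the convention of the summary-data MR
package family and, with the SE inflation above, reproduces the CI widths
such analyses print. All arithmetic stays on the log-odds scale;
exponentiation to odds ratios happens only at reporting.

## Harmonization and proxies

GWAS tables do not share allele codings. The harmonizer aligns the outcome
record to the exposure's effect allele: swapped labels negate the outcome
beta (and complement the reported frequency), complement codings (A↔T,
C↔G relabelling) are recognized as strand flips, and irreconcilable allele
sets are rejected with reason `"allele mismatch"`. Palindromic variants
(A/T, C/G) cannot be resolved from labels alone; the default policy drops
them — the safest choice when allele frequencies are unavailable, and sign
errors are the dominant failure mode of MR pipelines. `infer_by_eaf`
aligns by frequency concordance provided both frequencies lie outside the
ambiguity band `[threshold, 1 − threshold]` (default threshold 0.42);
`keep` aligns by label only.

Instruments missing from the outcome GWAS can be replaced by the
highest-r² proxy strictly above `r2_min` (default 0.9) from an explicit LD
table that carries its own allele correspondence — the table is an input
artifact rather than an online panel query, because LD estimates depend on
the reference panel and an explicit table keeps the pipeline deterministic
and reproducible. A proxy row keeps the proxy's rsid and records the
original instrument in `proxy_of`; exclusion lists match on either.
Duplicated rsids within a table keep the smallest p-value. Positions are
1-based and carried but never used in computation.

## The synthetic-data generator

`simulate_dataset()` emulates the smoking-initiation → rheumatoid-arthritis
configuration by default: $k = 367$ independent instruments jointly
explaining $R^2 = 2.3\%$ of exposure variance in a GWAS of $n = 1{,}232{,}091$,
a binary outcome GWAS of 14,361 cases and 43,923 controls (standard errors
via the effective sample size $n_\mathrm{eff} = 4/(1/n_1 + 1/n_0)$, the
standard case-control approximation), minor-allele frequencies uniform on
$(0.05, 0.5)$, and a true causal log-odds effect $\ln(1.32)$, the effect
size this configuration was designed around.

Two generator choices deserve explanation:

- **Effect-size distribution.** An instrument panel consists of
  *discovered*, genome-wide-significant SNPs, so drawing true effects from
  an unconstrained normal — which leaves roughly half the panel below the
  significance threshold — would misrepresent the design. True effect
  magnitudes are instead drawn, in discovery z-score units, from a shifted
  exponential floored at the significance threshold plus a 3-SD sampling
  margin; the exponential mean is fixed by the variance budget
  $E[z^2] = nR^2/k$, and the whole vector is rescaled to hit $R^2$
  exactly. When the budget cannot support the floor, the floor shrinks
  toward the equal-effects limit. A consequence of the study's own numbers
  ($nR^2/k \approx 77$ against a threshold of $\approx 30$) is that
  instrument strengths are tightly clustered, which leaves MR-Egger weakly
  identified at these dimensions — visible in the wide Egger CIs the
  pipeline reports there, and the reason the Egger property tests use a
  smaller, wider-spread configuration. About 0.1–0.2 instruments per 378
  still fall below the threshold by sampling noise, so end-to-end
  accounting checks allow a ±2 band.
- **Pleiotropy regimes.** `balanced` draws $\alpha_j \sim N(0,\sigma_\alpha)$,
  `directional` shifts the mean to $\mu_\alpha$, and `inside_violating`
  couples $\alpha_j$ to instrument strength ($\mu_\alpha + q\gamma_j +$
  noise), the violation that breaks MR-Egger. The pleiotropic count is
  fixed at $\mathrm{round}(\pi k)$ (a random subset) rather than binomial,
  so scenario accounting is deterministic. The default is `none`:
  pleiotropy is an explicit scenario choice, not background noise.

Outcome-side missingness removes a configured fraction of instruments from
the outcome table; a fraction of those receive a high-LD proxy row whose
outcome effect is attenuated by $\sqrt{r^2}$ — the standard LD-attenuation
expectation — so the proxy path is exercised with realistic signal loss.
Winner's curse on the *observed* exposure betas is not modelled by default
(instruments are externally discovered, as in the two-sample design).

What the generator does **not** emulate: linkage disequilibrium between
instruments (the source GWASs provide conditionally independent SNPs),
sample overlap between the two GWASs, population stratification, and the
heterogeneous real-data dispersion that made the study's random-effects
CIs noticeably wider than the homogeneity expectation. Passing tests on
synthetic data therefore validate the estimators and the plumbing, not the
robustness of any real-data conclusion to those complications.

## Numerical and degenerate-input choices

- Strict inequality in the significance filter (`pval < threshold`).
- `beta_exposure = 0` is a domain error ("null instrument") in ratio
  computation; all-equal exposure betas after orientation are a
  "degenerate regressor" error in MR-Egger; rank-deficient multivariable
  designs error naming the collinear columns.
- Simulated p-values are floored at $10^{-300}$ so extremely strong
  instruments never produce a literal zero.
- MR-PRESSO accumulates exceedance counts over simulation blocks of 2,500
  rather than materializing the full $k \times n_{sim}$ residual matrix;
  the p-values are numerically identical and memory stays bounded.
- The report's JSON stores full-precision numbers; only the TSV is
  formatted (two-decimal ORs, scientific p-values). Reruns with identical
  config and seeds are byte-identical; the provenance block carries a
  config hash and all seeds.

## Known limitations

- The MR-PRESSO global test is measurably conservative for very small
  instrument sets (empirical type-I error ≈ 0.03 at nominal 0.05 for
  $k = 10$): the leave-one-out slope estimated from nine instruments
  inflates the simulated RSS dispersion. Calibration is accurate by
  $k \approx 25$, and all practical instrument panels here are far larger.
  The test suite asserts calibration at moderate $k$ and
  conservative-never-anticonservative behaviour at small $k$.
- The MR-PRESSO distortion test is intentionally not implemented; the
  corrected estimate is a plain random-effects IVW on the non-outliers.
- No additive ($\tau^2$-estimating) random-effects model, no mode-based
  estimators, and no LD clumping: instrument sets are taken as already
  independent.
- The weighted-median bootstrap resamples both betas from their reported
  sampling distributions; ratios at resampled exposure betas near zero are
  legitimate heavy-tail contributions, which is why the default bootstrap
  is large (10,000).

## Problem sizes used in the checks

The packaged tests and the acceptance script run at the study's own
dimensions where the quantity under test depends on them (367–378
instruments; 200-replicate coverage checks; 1,000-replicate PRESSO
calibration at $k = 25$ with 1,000 simulations per test; 500-replicate
Egger bias checks at $k = 40$), and at small dimensions (toy sets of 3–20
instruments) where closed-form oracles are the comparison.
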