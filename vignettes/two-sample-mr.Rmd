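---
title: "Methods: two-sample Mendelian randomization with tsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with tsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

## The estimation problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here a serum lipid
trait, measured in SD units) on an outcome (here a binary disease such as
chronic kidney disease, on the log-odds scale). A variant is a valid
instrument if it is (i) associated with the exposure, (ii) independent of
confounders of the exposure-outcome relation, and (iii) affects the outcome
only through the exposure. In the two-sample design the SNP-exposure
associations $\hat\gamma_i \pm \sigma_{\gamma i}$ and SNP-outcome
associations $\hat\alpha_i \pm \sigma_{\alpha i}$ come from two
non-overlapping GWAS, consumed purely as summary statistics.

Under validity of instrument $i$, $\alpha_i = \beta \gamma_i$, so each SNP
supplies a Wald ratio $\hat\beta_i = \hat\alpha_i/\hat\gamma_i$ with
first-order standard error $\sigma_{\alpha i}/|\hat\gamma_i|$. Estimators
differ in how they pool these ratios and which violations they tolerate.

## Instrument selection and harmonization

Selection follows the convention of consortium-scale lipid MR analyses, in
a fixed order:

1. **Genome-wide filter.** Keep SNPs with exposure $P$ strictly below
   $5\times10^{-8}$ (the threshold is exclusive).
2. **Confounder exclusion.** Remove SNPs on a user-supplied blacklist
   (e.g. GWAS-Catalog hits for known confounders). Whether published
   pipelines apply this before or after clumping is rarely stated; placing
   it before clumping means a removed index SNP cannot suppress an
   otherwise independent neighbour, which we consider the conservative
   choice.
3. **LD clumping.** Greedy: repeatedly promote the lowest-$P$ unclaimed SNP
   to index status and discard every remaining SNP with $r^2 > 0.001$
   against any index. LD is consumed as a precomputed pairwise table
   (PLINK-style sparse output); absent pairs count as $r^2 = 0$, and
   equal-$P$ ties break lexicographically by rsID so output is
   deterministic.

Instruments missing from the outcome GWAS may be replaced by the
highest-$r^2$ proxy with $r^2 > 0.8$ that is present, taken from a
precomputed proxy table whose rows are assumed allele-aligned with the
requested SNP (as SNAP-style exports are); unresolvable SNPs are dropped
and reported, never fatal.

Harmonization aligns both studies to a shared effect allele: identical
coding is kept, swapped coding flips the sign of $\hat\alpha_i$ and
reflects the outcome allele frequency, strand-complement coding is
complemented first. Palindromic SNPs (A/T, C/G) with exposure-side minor
allele frequency above 0.3 are removed as strand-ambiguous; palindromes at
or below 0.3 are retained under the forward-strand assumption, with no
frequency-based strand inference. The exposure study supplies the MAF
because it is the instrument-defining sample. Every excluded SNP carries a
reason, and `nInstruments(x) + nrow(exclusions(x))` always equals the
number of SNPs entering a stage.

Instrument strength is summarised by per-SNP $F_j = (\hat\gamma_j /
\sigma_{\gamma j})^2$ and, when allele frequencies are available, by
$R^2 = \sum_j 2 f_j (1-f_j) \hat\gamma_j^2$ (standardized-trait
approximation) with aggregate $F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$. Both
definitions are stated explicitly because published aggregate "F
statistics" in this literature are often irreproducible from the printed
inputs; we report quantities with a formula rather than imitate.

## Estimators

**IVW.** Weighted regression of $\hat\alpha$ on $\hat\gamma$ through the
origin with weights $\sigma_{\alpha i}^{-2}$,
$\hat\beta = \sum_i \gamma_i \alpha_i \sigma_{\alpha i}^{-2} / \sum_i
\gamma_i^2 \sigma_{\alpha i}^{-2}$. The default standard error is the
multiplicative random-effects one, the fixed-effect SE inflated by
$\max(1, \sqrt{Q/(J-1)})$ — the behaviour of the established two-sample MR
toolchain — and the fixed-effect estimate is always reported alongside.
With one instrument IVW degenerates to that SNP's Wald ratio.

**MR-Egger.** The same regression with a free intercept, after orienting
all instruments so $\gamma_i \ge 0$ (the model is orientation-dependent and
this is the established convention). The slope is a pleiotropy-corrected
causal estimate under InSIDE (instrument strength independent of direct
effects); the intercept $\beta_0$ estimates mean directional pleiotropy,
with $p > 0.05$ conventionally read as no evidence of horizontal
pleiotropy. Residual scale is floored at 1, as for IVW.

**Cochran's Q.** $Q = \sum_i w_i (\hat\beta_i - \hat\beta)^2$ over Wald
ratios (IVW form, $J-1$ df) and the analogous weighted residual sum about
the Egger line ($J-2$ df), referred to the upper chi-square tail
(`chi2UpperTail()`, a thin wrapper over `pchisq(lower.tail = FALSE)`, i.e.
the regularized upper incomplete gamma).

**Maximum likelihood.** Gaussian measurement-error model
$\hat\gamma_i \sim N(g_i, \sigma^2_{\gamma i})$,
$\hat\alpha_i \sim N(\beta g_i, \sigma^2_{\alpha i})$ with the latent
$g_i$ profiled out analytically, leaving a one-dimensional minimisation of
$\sum_i (\hat\alpha_i - \beta\hat\gamma_i)^2 / (\sigma^2_{\alpha i} +
\beta^2 \sigma^2_{\gamma i})$; the SE comes from the numerical curvature of
the profile likelihood. It converges to fixed-effect IVW as
$\sigma_\gamma \to 0$.

**Weighted median.** The ratio value at cumulative standardized
inverse-variance weight 0.5, interpolating with each SNP's cumulative
weight reduced by half its own weight; consistent when valid instruments
carry more than half the weight. The penalized variant multiplies each
weight by $\min(1, 20 p_i)$, $p_i$ the $\chi^2_1$ upper tail of the SNP's
contribution to Q about the unpenalized median (penalization constant 20,
the canonical published default). SEs by parametric bootstrap: ratios are
resampled from their normal errors, `nBoot = 1000` by default, always
seeded.

**Mode estimators.** The argmax of a normal-kernel density of the ratios
with bandwidth $\varphi \times 0.9\min(\mathrm{sd},\mathrm{mad})
J^{-1/5}$ (modified Silverman; $\varphi = 1$ by default and exposed as
`bandwidthFactor`). The weighted variant weights kernels by inverse
variance. The argmax is located on a 512-point grid and refined by golden
search in the bracketing cell, which agrees with a dense-grid evaluation to
well under the bandwidth. Bootstrap SEs as for the median.

**RAPS.** Root of the adjusted profile score
$\sum_i (\hat\alpha_i - \beta\hat\gamma_i)\hat\gamma_i /
(\sigma^2_{\alpha i} + \beta^2\sigma^2_{\gamma i} + \tau^2) = 0$, which
accounts for measurement error in $\hat\gamma$; with
`overdispersion = TRUE`, $\tau^2$ is estimated jointly from the second
moment of the standardized residuals (floored at 0), alternating the two
one-dimensional solves to convergence. The SE is the sandwich estimate
$\sqrt{\sum_i \psi_i^2}/|\sum_i \partial\psi_i/\partial\beta|$. The root is
bracketed around the ratio range, doubling the bracket up to six times
before declaring failure.

All slope estimates use two-sided normal p-values and
$\hat\beta \pm 1.96\,\mathrm{se}$ intervals, for consistency across the
battery (some toolchains use a t reference for Egger; the difference is
immaterial at the instrument counts involved and the normal convention
keeps every method on the same footing). Odds ratios and their intervals
are the exponentiated log-odds quantities; published lipid-CKD tables
sometimes print OR intervals symmetric on the OR scale, which is a
reporting idiosyncrasy this package does not imitate.

**Leave-one-out** re-runs IVW omitting each SNP in turn, alongside the
all-SNP estimate, to flag results driven by a single variant.

## The synthetic-data generator

Because consortium GWAS cannot be bundled, every downstream stage is
exercised against a generator with known truth. Its defaults describe the
study conditions the package targets: a standardized lipid exposure from a
GWAS of $n_x = 187{,}365$ against a binary kidney-disease outcome from
$n_y = 117{,}165$, minor allele frequencies Uniform(0.1, 0.4), lead-SNP
exposure effects with magnitude $|N(0.1, 0.05)|$ SD per allele, and
standard errors from the per-allele variance approximation
$1/\sqrt{2f(1-f)n}$ — which puts per-SNP F statistics in the hundreds to
thousands, comfortably beyond the $F > 10$ rule, as in the consortium
setting it emulates. Outcome effects are
$\alpha_j = \beta\gamma_j + \delta_j$ with
$\delta_j \sim N(\mu_\delta, \sigma_\delta)$ drawn independently of
$\gamma_j$ (InSIDE holds) unless `insideViolation = TRUE`, in which case
$\delta_j$ gains the linear term $0.5\gamma_j$. The two samples are
generated independently (no overlap), and binary-outcome effects are
produced directly on the log-odds scale since the pipeline only ever
consumes summary statistics.

Four presets fix the scenarios used by the tests and the acceptance
script: `null` ($\beta = 0$, $J = 50$, no pleiotropy) for type-I error and
coverage calibration; `causal` ($\beta = -0.28$, the protective
total-cholesterol direction, OR $\approx e^{-0.28} = 0.76$; $J = 30$) for
recovery; `directional_pleiotropy` ($\mu_\delta = 0.01$,
$\sigma_\delta = 0.005$) for Egger-intercept recovery; and
`heterogeneous` ($\sigma_\delta = 0.01$), under which each SNP adds about
$\sigma_\delta^2/\sigma_\alpha^2 \approx 6$ to the expected Q, far above
its degrees of freedom.

One design point deserves a note: the directional-pleiotropy preset
orients all exposure effects positive (`gammaSigns = "positive"`). With
randomly signed $\gamma_j$ and the Egger orientation convention, flipping a
$(\gamma_j, \alpha_j)$ pair also negates $\delta_j$, so a directional
pleiotropy mean cancels out of both the Egger intercept and the IVW bias —
directional pleiotropy is only a meaningful scenario when instruments are
reported on the exposure-raising allele, which is also how real instrument
sets are published. Strong instruments matter here for a second reason:
regression-dilution from noise in $\hat\gamma$ biases the Egger intercept
by roughly $-\beta\bar\gamma(1-\lambda)$ with
$\lambda = \mathrm{var}(\gamma)/(\mathrm{var}(\gamma) +
\sigma_\gamma^2)$; at the default instrument strength this is an order of
magnitude below the Monte-Carlo resolution of the recovery checks.

What the generator does **not** emulate: genome-scale LD (linkage enters
only through small synthetic pair tables), winner's-curse selection bias
from discovering instruments and estimating their effects in the same
sample, sample overlap between the two GWAS, population stratification,
and non-normal effect-size distributions. Passing calibration and recovery
under the generator therefore demonstrates correctness of the estimators
under the stated model, not robustness to everything real consortium data
can do.

## Numerical choices and degenerate inputs

* P-values of exactly 0 on input are clamped to $10^{-300}$ (downstream
  log transforms); simulated p-values are floored there too.
* All result tables are written with 15 significant digits so a
  write-read round trip is lossless to at least 12.
* `mrIvw` with one instrument returns the Wald ratio; estimators needing
  3+ instruments (Egger, median, modes, RAPS, leave-one-out) report
  themselves unavailable rather than degrade silently, and the battery
  (`mrAll`) skips them with a message.
* Zero-$\gamma$ SNPs are excluded from ratio-based computations with a
  warning; an all-zero $\gamma$ vector is fatal.
* Bootstrap and simulation seeds are mandatory function arguments or
  config fields; every stochastic path restores the caller's RNG state, so
  identical configs reproduce outputs byte-identically.
* Mode estimators with zero ratio spread return the common ratio.

## Problem sizes

The packaged checks use $J$ between 3 and 50 instruments and Monte-Carlo
batteries of 500 replicates (100 for the pipeline-level pleiotropy false
alarm check), sizes at which the Monte-Carlo standard errors are small
enough to resolve the biases of interest while a full run of the test
suite and the reproduction script completes in well under a minute each on
a laptop core.

## Limitations

The package deliberately excludes MR-PRESSO outlier correction, Steiger
directionality filtering, multivariable MR, genotype-level LD computation
and online proxy/confounder lookups; LD, proxies and confounder lists are
consumed as precomputed tables. Odds-ratio reporting assumes the outcome
GWAS provides log-odds effects. rsID is the only join key — no positional
matching or liftover.
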