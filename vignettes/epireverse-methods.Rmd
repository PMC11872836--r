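---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which knobs matter, what the synthetic generator
does and does not emulate, and where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. The data model

Everything operates on three validated objects: a CpG × sample matrix of
beta values in [0, 1]; a sample sheet assigning each animal an age in
years, a group (`young`, `old_control`, `old_treated`) and a species with a
maximum lifespan; and a per-CpG annotation (0-based half-open coordinates,
nearest gene, signed TSS distance with negative meaning upstream, region
class, CpG-island flag, chromatin state). Missing betas are handled by
dropping the CpG row — the conservative choice for clock application, since
an imputed probe feeds a weighted sum directly — with per-CpG mean
imputation available behind a flag. Files are plain TSV/CSV with exactly
one header line; no quoting dialects.

## 2. The synthetic aging methylome

The generator is the package's *stated world*, invented here (the source
study does not describe a generative model) and documented as such. For CpG
$j$ and sample $i$:

$$\operatorname{logit}(\beta_{ij}) = m_j + a_j A'_i + r_j T_i +
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma)$$

* $m_j \sim N(0, 1)$: baseline logit methylation, a property of the CpG
  (cohorts simulated from the same design share it — that is what lets a
  clock trained on one cohort transfer to another).
* $A'_i$: age standardized to [0, 1] over the young-to-old span, so the
  effect size `delta_age` has the same meaning whatever the species' age
  units.
* $a_j = \pm\,$`delta_age` for age-affected CpGs, the sign set by chromatin
  context: gain in bivalent-promoter, TSS and PRC2-target states or island
  CpGs; loss in heterochromatin/quiescent states or intergenic CpGs. CpGs
  whose context matches neither rule are ineligible, and exactly
  `age_effect_fraction × n_cpgs` causal CpGs are drawn from the eligible
  pool.
* $r_j = -\,$`reversal_strength`$\,\cdot a_j$ for a fraction
  `reversal_fraction` of causal CpGs, 0 otherwise: in treated samples
  ($T_i = 1$) the age effect (which equals $a_j$ at $A' = 1$) is removed in
  that proportion.
* Betas are clipped to [0.001, 0.999]; array betas are never exactly 0/1,
  and the clip keeps logits finite.

Working on the logit scale keeps betas bounded and makes effects
approximately additive in the mid-range. Effects are linear in age — two
age groups make anything richer unidentifiable anyway.

**Defaults are the emulated study design**: 6 young (3.5 months), 6 old
control and 8 old treated rats (25.3 months), species maximum lifespan
3.8 y, 5000 CpGs, `reversal_fraction` 0.6, `reversal_strength` 1,
`noise_sd` 0.15 logit units. Where the emulated study states no value the
choice was made once: `age_effect_fraction` 0.2 (an array enriched for
conserved, age-informative probes shows effects at a substantial minority
of CpGs), `delta_age` 1 logit unit (a mid-range beta moving ~0.23 over the
full lifespan, the magnitude seen at strongly age-coupled probes), and
`noise_sd` 0.15 (per-sample biological plus technical scatter a fraction of
the full age effect). The state proportions and the state-conditional
island/region probabilities encode the textbook associations (islands and
promoters concentrate in bivalent/TSS chromatin, intergenic positions in
heterochromatin) and are checked only directionally.

What the generator does **not** emulate: the bimodal marginal distribution
of real array betas, probe chemistry and batch effects, cell-composition
heterogeneity, spatial correlation along the genome, and a real genome's
gene annotation. A green test therefore establishes that the statistics
recover the structure *this* model plants — directions, orderings,
calibration — not that they would reproduce any particular study's numbers.

## 3. Clocks

`fit_clock()` minimizes the standard elastic-net objective
$\frac{1}{2n}\sum_i (y_i - b_0 - w^\top x_i)^2 + \lambda(\alpha\|w\|_1 +
\frac{1-\alpha}{2}\|w\|_2^2)$ via glmnet with **unstandardized**
predictors — betas already share the [0, 1] scale, and standardization
would silently reweight the penalty. λ defaults to seeded 5-fold
cross-validation (`lambda.min`); fold assignment is the only stochastic
ingredient and is fully determined by the seed. Constant CpGs are dropped
with a message. Transforms: `identity` (years) and `relative_age`
(age / maximum lifespan, multiplied back to years on application). The
published clocks' coefficient sets live in external code releases, not in
any paper text, so the package consumes arbitrary coefficient CSVs and
trains its own on synthetic cohorts; log-linear age calibrations used by
some published clocks are out of scope.

A subtlety worth recording: elastic-net *predictions* are invariant to
duplicating a predictor column only for the pure lasso (the L1 penalty is
indifferent to how weight splits across identical columns). The ridge
component strictly prefers splitting, so at mixing values below 1 the
duplicated fit differs at order λ. The test suite asserts the lasso
invariance at 1e−6 and the mixed-penalty λ→0 limit at 1e−4.

Group comparison uses the Welch (unequal-variance) t-test — the emulated
study says only "Student's t-test", and Welch is the safer default for
n = 6 vs 8 — with a one-sided p for the pre-registered direction
(treated < control), reported alongside the two-sided value.

## 4. EWAS

Each scan is a per-CpG Pearson correlation against the contrast variable
(numeric age when at least three distinct ages exist, otherwise the group
indicator — with two age groups the two are affinely identical), mapped
through $t = r\sqrt{n-2}/\sqrt{1-r^2}$ to a two-sided p and a signed
$z = \operatorname{sign}(r)\,\Phi^{-1}(1-p/2)$, capped at $|z| \le 40$ so
p-underflow never yields infinite quantiles. The authors' exact per-CpG
test is not recoverable from the main text; the correlation-t construction
is the one consistent with a standard-normal null Z. Zero-variance CpGs get
$z = 0$, $p = 1$, and a logged count. Nominal (unadjusted) p-values at the
deliberately lenient 0.01 threshold are the headline output, mirroring the
low-power 6/6/8 design; Benjamini–Hochberg is a flag, never the headline.

Classification at threshold $z^\* = \Phi^{-1}(1-\alpha/2)$: `rejuvenated`
(both significant, opposite signs), `aggravated` (both, same sign),
`age_only`, `treat_only`, `null`.

### The shared-control artifact

The age scan (young vs old control) and the treatment scan (old control vs
old treated) both use the control animals. Control-sample noise therefore
pushes the two Z statistics of the same CpG in opposite directions, and the
across-CpG correlation of $(z_{age}, z_{treat})$ is negative *even when the
treatment does nothing* — with equal group sizes the noise-only correlation
approaches −0.5, diluted by the deterministic spread of true age effects.
The naive t-transform p on thousands of CpGs then calls essentially every
null dataset "significantly reversed".

`reversal_correlation()` keeps the standard Pearson statistic — it is the
number the field reports — but significance calls in the pipeline report
and the acceptance tests come from `reversal_permutation_test()`: old
animals are exchangeable under a treatment null, so treated/control labels
are permuted among them and **both** Z vectors are recomputed per
permutation (recomputing only the treatment scan would break exactly the
coupling the null must reproduce). The one-sided p is the rank of the
observed correlation among 199 permuted ones (minimum attainable p 0.005).
Under the generator's null this test is calibrated; under planted reversal
the observed correlation falls below every permutation.

## 5. Chromatin-state analysis

Per state, per sample, the trimmed mean of all member CpGs (drop
⌊trim·n⌋ from each tail, average the rest). The trim fraction is unstated
in the emulated work; the default 0.05 per tail removes outlying probes
without discarding most of the state, and is exposed as `--trim`. The
per-state aging and treatment Zs are Welch t-tests **on the per-sample
state means** (old control vs young; old treated vs old control), mapped to
Z as in the EWAS. Samples, not CpGs, are the analysis unit: treating the
thousands of member CpGs as replicates would pseudo-replicate wildly.
States need ≥ 10 CpGs to be eligible; constant-mean states are flagged with
z = 0 rather than erroring. Degenerate Welch inputs follow a fixed policy
(equal constant groups → t = 0; separated constant groups → ±capped Z).
State-level reversal is the Pearson correlation of $(z_{age}, z_{treat})$
over eligible states (≥ 3 required), with each state classified
`gain_reversed`, `loss_mitigated`, `concordant` or `neutral` by its sign
pattern at |z| ≥ 1.96.

## 6. Enrichment

All backgrounds are the CpGs that entered the scan, not the whole
annotation — that is the conditioning implicit in hit-versus-background
questions. TSS-position enrichment bins the signed TSS distance at
(−∞,−50], (−50,−5], (−5,−1], (−1,0], (0,1], (1,5], (5,50], (50,∞) kb (the
emulated figure does not print its edges) and tests each bin's 2×2 with a
Fisher exact test: sample odds ratio $ad/bc$ (∞ when $bc = 0$ with
$ad > 0$) and two-sided p by summing hypergeometric probabilities no
larger than the observed table's. Chromatin-state enrichment is an exact
hypergeometric tail — upper for fold ≥ 1, lower (depletion) otherwise.
Island status is a Welch t on the Z vectors. Stars follow the conventional
0.05/0.01/0.001/0.0001 ladder. Exact tests on discrete counts are
conservative, so the realized false-positive rate under a uniform null sits
at or slightly below the nominal level — the calibration test asserts a
band, not equality.

## 7. Pipeline and determinism

`run_pipeline()` chains simulate (or load) → clock → EWAS → states →
enrichment, with every threshold in the config (headline α 0.01, secondary
α 0.05) and one seed controlling all randomness: generator draws,
cross-validation folds, permutations. In simulated runs the clock trains on
an independent cohort (12/12 young/old animals by default, cohort seed
offset by 7919) sharing the analysis cohort's CpG truth; file-driven runs
train on the supplied young and control samples. Identical config and seed
give byte-identical `report.json` (version-stamped); a stage failure aborts
naming the stage, retaining earlier outputs.

## 8. Stereology

The optical-dissector estimator is pure arithmetic,
$N = RQ_\Sigma/(ssf \cdot asf \cdot tsf)$, vectorized, unrounded (callers
round for reporting), with the sampling fractions validated into (0, 1].

## 9. Known limitations

* Two-point age designs cannot distinguish linear from nonlinear aging;
  the clock transfer claim holds within the generator's world.
* The permutation reversal test assumes old animals are exchangeable under
  the null — true in the generator, approximate in real cohorts with
  batch structure.
* The EWAS offers no covariate adjustment, mixed models or inflation
  correction (explicit non-goals).
* Enrichment treats CpGs as independent; real arrays have correlated
  neighboring probes, which widens the true null of count-based tests.
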