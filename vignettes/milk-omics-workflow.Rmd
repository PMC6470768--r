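---
title: "Linking preterm breast-milk omics to infant growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking preterm breast-milk omics to infant growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactomics)
```

# The problem

Preterm infants fed their mother's milk grow at very different rates, and
macronutrient content alone does not explain the difference. `lactomics`
implements a multi-block chemometric workflow that asks whether the
*composition* of preterm breast milk — its metabolome (ESI+ and ESI− LC-HRMS
fingerprints), lipidome, glycome (human milk oligosaccharides, HMOs), free
amino acids (FAA) and total fatty acids (FA) — carries a signature of early
infant weight growth. The study design it targets is a cohort of
mother–infant dyads whose infants are ranked by the change in weight Z-score
between birth and hospital discharge (ΔZ, in SD units) and split into
"faster" and "slower" growth groups by terciles; milk is sampled weekly at
lactation weeks 2–4, with twins sharing their mother's milk samples.

Because no such cohort data are public, the package ships a synthetic-data
module that reproduces the design's statistical structure, so that every
stage of the analysis is testable end to end.

# The analysis chain

## Feature filtration and scaling

Features whose relative standard deviation across repeated pooled-QC
injections exceeds 30% (`qc_rsd_filter()`) are removed: they are technically
unstable, not biologically variable. Metabolome and lipidome peak areas span
orders of magnitude, so these blocks are *log-Pareto* scaled
(`log_pareto_scale()`): \(x \mapsto \log_{10}(x + c)\), then per feature
centered and divided by \(\sqrt{s}\), with \(s\) the feature's standard
deviation. We read "log Pareto" as the composition of a log transform with
Pareto scaling, since the scaling taxonomy it comes from defines the two as
composable steps. The pseudocount \(c\) defaults to half the smallest
nonzero value of the block — a standard below-detection guard; the source
method description is silent on it. Glycome relative abundances, FAA and FA
concentrations are on comparable scales and are autoscaled (unit variance).
A deliberate consequence of Pareto scaling is that the scaled feature
variance equals the pre-scaling standard deviation, which the tests assert
as an algebraic identity.

Weeks 2–4 are pooled for the block-level models (matching how the result
tables pool them); a per-mother-mean mode exists for sensitivity checks.

## Glycome specifics

HMOs are named by monosaccharide composition codes — hexose, fucose,
N-acetylhexosamine, N-acetylneuraminic acid counts plus an optional isomer
letter (e.g. `4230b`) — parsed by `parse_hmo_code()` into fucosylation and
sialylation classes. Relative abundances are each sample's peak areas as a
percentage of its total HMO signal (rows sum to 100).

Maternal secretor status (FUT2 activity) dominates glycome structure:
secretor milk has abundant 2′-fucosyllactose (2′-FL), non-secretor milk
almost none. `classify_secretor()` therefore splits mothers on their mean
relative 2′-FL by the largest gap in the *sorted log10 values* — abundances
are log-normal, so cluster separation is multiplicative — accepting the
split only when the gap exceeds 3× the median of the remaining gaps, plus
an absolute floor: below 1% relative 2′-FL a mother is non-secretor
regardless. Before fusion, the glycome is mean-centered within each
secretor stratum (`secretor_stratified_center()`), removing the secretor
dichotomy so it cannot masquerade as a growth signal.

## Discrimination: ANOVA-PLS with Fisher LDA

`anova_decompose()` splits the scaled matrix feature-wise into grand mean,
group effect and residual (one-way; a nuisance factor such as week can be
swept out, which is how the decomposition generalizes to multi-factor
designs). PLS (NIPALS, X-deflation only) is fitted on *effect + residual*
against the centered group-indicator response; in a one-way design this is
algebraically PLS-DA on the centered matrix, a reduction the tests assert.
A Fisher linear discriminant on the first \(A\) latent scores provides the
canonical axis and classification threshold (equal priors — the published
plots show symmetric separation despite unbalanced groups; configurable).
\(A\) is chosen by minimizing the leave-one-out error over \(A \in 1..A_{max}\)
(default scan to 3 for routine runs; the published account says only that
"appropriate" components were selected).

Feature importance uses the VIP index,
\(\mathrm{VIP}_j = \sqrt{p \sum_a s_a (w_{ja}/\|w_a\|)^2 / \sum_a s_a}\)
with \(s_a\) the response sum of squares captured by component \(a\);
\((1/p)\sum_j \mathrm{VIP}_j^2 = 1\) by construction, and features with
VIP ≥ 1.5 form the candidate biomarker set.

**Cross-validation is grouped by milk sample.** Twins duplicate their
mother's milk row under two infant labels. Plain leave-one-out would keep
the duplicate of the held-out measurement in the training set — for a
growth-discordant twin with the *opposite* label — and the fold is then
decided by leakage, not by the model. `loo_cv()` therefore excludes every
sample sharing the held-out sample's milk. A discordant twin pair still
contributes exactly one error per fold pair (same milk, both labels), which
places a deterministic floor of one error per discordant set on any
cross-validated error under this design. Errors are reported at sample
level and at infant level (majority vote over weeks).

## Univariate screening and biomarker regression

Group differences use the two-sided Mann–Whitney U test: the exact
enumeration null when the combined sample size is ≤ 12 without ties,
otherwise the normal approximation with midranks, tie-corrected variance
and continuity correction (peak tables contain repeated zeros, so tie
handling matters). Benjamini–Hochberg q-values are computed per block, and
tables report median (P25–P75) per group with linear (type-7) quartile
interpolation — the convention is unstated in the source, so it is fixed
and documented here — plus significance tiers (`**` q<0.01, `*` q<0.05,
`#` q<0.1).

Candidate biomarkers are then regressed one at a time: ordinary least
squares of ΔZ on the feature plus nine clinical confounders (maternal BMI,
birth weight, gestational age, protein/lipid/energy intakes, parenteral
feeding and ventilation durations, hospital-stay length), BH-FDR over the
screen, reliable at q < 0.1. The regression is at infant level while milk
is at mother-week level; the collapse rule (not stated in the source) is
weekly values averaged per mother and carried to her infants, with a
week-3-only alternative. All nine confounders enter each model by default
(≈15 residual df at 26 infants — limited, but the published screen did the
same count of models); a reduced set is configurable. A confounder whose
missingness would drop more than 20% of infants is median-imputed instead
of deleted listwise.

## Multi-omics fusion

Fusion uses the week-3 slice (previously the most discriminant lactation
week) of: VIP-selected metabolome (ESI+ and ESI− concatenated) and
lipidome features, the full secretor-centered glycome, and the full FAA and
FA blocks. Blocks are weighted \(1/\sqrt{p_b}\) so no block dominates by
width (the source is silent; configurable, including weight 1).

`upca()` provides the unsupervised view: mean-centered PCA of the (possibly
mode-1-unfolded) super-matrix. `fit_mbpls()` is the supervised model:
block-wise NIPALS in which the per-block weight sub-vectors are normalized
*jointly*, block scores are combined into a super score
\(t_a = \sum_b \omega_{ba} t_{ba}\) with \(\sum_b \omega_{ba}^2 = 1\), and
all blocks are deflated on the super score. In this variant the super
scores coincide with ordinary PLS on the weighted concatenated super-matrix
— the equivalence is the oracle the tests check — while \(\omega_{ba}^2\)
provides per-component block importances summing to 1.

Two numerical choices deserve note. First, with a two-class (rank-one)
response, the second common component is variance- rather than
class-driven; the fusion leave-one-out therefore classifies super scores
through a Fisher LDA (down-weighting uninformative axes) rather than a raw
nearest-centroid rule, though both are available and behave similarly on
the synthetic study. Second, features are ranked for selection by the norm
of their loadings on the chosen components *expressed on the unweighted
common scale* — raw super-block loadings scale with the block weight
\(1/\sqrt{p_b}\), which would spuriously favor narrow blocks. Selection
returns the ranked list with block provenance and a direction of
association (component 1 is oriented so that "faster"-growth samples score
positive); the published analysis reports a top set without stating its
cutoff rule, so both top-k and top-quantile cutoffs are exposed and no
particular selected count is claimed.

# The synthetic cohort generator

`synthetic_config()` defaults define the emulated study: 26 dyads (hence 22
mothers), four twin sets of which two are growth-discordant, weeks 2–4, a
~20% non-secretor rate, 8 pooled-QC injections with 10% technical CV, and
below-detection zeros at 2%. ΔZ is drawn from a two-mode Gaussian mixture
at the published group medians (−0.479 and −1.538 SD, spreads 0.19/0.42);
birth weight is negatively correlated with ΔZ (default −0.5, the direction
the cohort reports). Abundances are log-normal with feature-specific log10
location U(4,7) and scale U(0.1,0.5), matching the orders-of-magnitude
spread of MS peak areas; a smooth multiplicative week drift and a
within-mother week-to-week correlation (default 0.5 — the study does not
state one, so it is a parameter, not an assertion) give the repeated
samples realistic structure.

Planted group-discriminant features are shifted on the log scale by a
standardized effect (Cohen's d, default 1.0) between growth groups; their
identities and signs are persisted as ground truth for recovery tests. The
planted density (~10% of features per block) follows the published
bookkeeping of discriminant features (on the order of 125 VIP species among
1256, 68/143/79 selected features per block). Discordant-twin mothers'
milk carries *no* group effect — the same milk fed infants in both groups,
and the published score plots show those samples between the clusters. The
glycome contains composition-coded features including 2′-FL and an LNFP-I
analogue pinned as major HMOs (~10% relative abundance in secretor milk, as
observed); in non-secretor milk the FUT2-dependent features are reduced
~200-fold. A small fraction of features (5%) get a large technical CV
(U(0.4, 0.8)) so the QC-RSD filter has realistic work; planted and
FUT2-dependent features are always stable. Zeros are written as true zeros;
below-detection handling is downstream's job.

What the generator does *not* emulate: raw spectra, m/z or retention-time
drift, isotope patterns, batch effects, correlated feature modules
(features are independent given the mother latent), and annotation
ambiguity. Passing recovery tests therefore show the chain recovers planted
structure under the design's sample sizes and noise — not that it would
survive every artifact of real LC-HRMS data.

# Problem sizes and runtime choices

Routine runs and tests use the default block sizes (120/110/140 metabolome
ESI+/ESI−/lipidome features, 40 HMOs, 20 FAA, 12 FA) with 78 milk-week
samples; calibration checks use 2000 simulated features (Mann–Whitney
type-I at n = 11 vs 15) and 20-seed recovery averages; the fusion error is
averaged over 10 simulated studies. The full pipeline on the default study
completes in well under a minute on one CPU.

# Known limitations

* The published headline numbers (R2Y values, the 7.14% LDA error, the
  125/119/68/87 feature counts) were computed on the unreleased cohort and
  are not reproducible here; the package reports the corresponding
  quantities for its own (synthetic) inputs instead.
* On the default synthetic study the week-3 fusion leave-one-out error
  averages ~0.17–0.19: the two discordant twin sets alone contribute a
  deterministic 2/26 ≈ 7.7%, and at planted effect d = 1.0 with
  within-mother correlation 0.5 the remaining finite-sample error at 26
  samples is of similar size. Stronger planted effects would lower it, but
  the generator's conditions are fixed by design, not by result.
* Plain MLR ignores the repeated-measures structure (as did the published
  analysis); a mixed-effects extension is out of scope.
* The Mann–Whitney screen pools weekly samples as independent, which
  overstates the effective n; the per-mother-mean mode is the conservative
  alternative.
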