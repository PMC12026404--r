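---
title: "Methods: multi-omic inflammation severity scoring in IBD"
author: "ibdatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic inflammation severity scoring in IBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdatlas)
```

# Scope

`ibdatlas` implements a cross-modality pipeline for quantifying intestinal
inflammation severity in inflammatory bowel disease (IBD) cohorts. Five
analysis stages share one conceptual axis — how inflamed a given tissue at a
given visit is — read out through different assays:

1. **Histopathology normalization** puts the modified Naini Cortina score
   (Crohn's disease, CD) and the modified Riley score (ulcerative colitis,
   UC) on a common 0–1 scale.
2. **Serum proteomics** derives inflammatory protein severity signatures
   (IPSS) from Olink-style NPX panels and scores them per sample.
3. **Single-sample gene-set variation scoring** computes biopsy molecular
   inflammation scores (bMIS) from bulk RNA expression.
4. **Cytokine activity inference** regresses differential expression
   profiles on a cytokine response-signature matrix.
5. **Attention-based multiple-instance learning (attMIL)** predicts the
   normalized histology score from per-slide tile-feature bags.

A synthetic cohort generator ties the stages together: every simulated
modality is driven by one latent severity per (visit, tissue context), so
recovery of planted effects is a meaningful end-to-end test without any
patient data.

# Histopathology score normalization

Raw scores are divided by the maximum attainable score of their scoring
context. The maxima depend on the scoring system, the tissue group
(colonic: colon, rectum, caecum; ileal: ileum, ileocecal valve, small
intestine, anastomosis, pouch) and the sampling method:

```{r}
defaultNormTable()
```

Raw scores outside `[0, max]` are rejected rather than clipped: an overflow
signals an upstream scoring error and silently truncating it would bias every
downstream correlation. Matching between modalities happens at tissue-group
granularity because the maxima themselves are only defined at that
granularity. A sample is labeled *inflamed* when a histopathology record of
the same patient and tissue group within `window_days` of the sample date has
a raw score above zero; the default window is 0 days (same-visit specimens
share a calendar date in this cohort model), and the window is exposed as a
parameter because multi-day gaps between endoscopy and serum draw occur in
practice.

# Serum proteomics and the IPSS

NPX values are log2-scale arbitrary units. Proteins enter the analysis only
when detected in at least 90% of samples (inclusive boundary). Differential
abundance uses the Welch unequal-variance t-test per protein on complete
observations — no imputation, which keeps the estimator unbiased when
below-detection missingness is unrelated to group given the protein — with
Benjamini–Hochberg correction across the testable proteins only. A signature
is the set of proteins with BH-adjusted p strictly below the FDR threshold
and positive effect (inflamed minus non-inflamed). The default threshold is
0.05; 0.1 is a supported alternative because both conventions are common in
published serum-proteomics work, and the choice is recorded in the signature
metadata.

Scoring a signature on a sample reuses the single-sample enrichment machinery
below, with one proteomics-specific choice: below-LOD values are floored at
the protein's observed minimum before the rank transform. A below-detection
measurement *is* a low abundance; ranking it at the bottom preserves that
information, whereas dropping every protein with any censored value empties
realistic panels. The flooring applies only to single-sample scoring, never
to the Welch tests.

# Single-sample enrichment (kernel CDF + rank walk)

Stage one re-expresses each feature as its estimated cumulative distribution
across samples, either with a gaussian kernel
$z_{ij} = \frac{1}{n}\sum_k \Phi\left((x_{ij}-x_{ik})/h_i\right)$, bandwidth
$h_i = s_i/4$, or with the empirical CDF. Stage two orders the features of
one sample by $z$ (descending, ties broken by stable feature order) and runs
a weighted Kolmogorov–Smirnov-like walk: up-steps at set members
proportional to $|p/2 - \mathrm{rank}|^\tau$ (normalized to sum to 1),
down-steps $1/(p-m)$ elsewhere. The default score is the maximum positive
excursion plus the minimum negative excursion ("difference" mode); the
single largest-magnitude excursion is available as "max_deviation". Because
both the up-mass and down-mass integrate to 1, scores are bounded by
$[-1, 1]$ for every $\tau$.

Numerical edge cases are handled explicitly: a zero-variance feature is an
error under the gaussian kernel (no silent epsilon); a lone set member
falling exactly at rank $p/2$ (possible for even $p$) has zero rank weight,
and the walk falls back to equal up-steps so it still integrates to 1; sets
losing members absent from the matrix are trimmed with a reported count and
skipped below 2 surviving members. The ecdf-kernel pipeline is invariant
under any strictly increasing per-feature transform — the property the tests
assert — while per-sample global shifts do alter cross-sample ranks and are
therefore *not* an invariance of rank-based scoring.

The bMIS is the set score of an externally supplied inflammation gene set on
log2(TPM+1), minus the score of a down-regulated set when one is provided.

# Cytokine activity inference

The input is a centered per-gene differential profile
$y = \log_2(\mathrm{TPM}+1)_{case} - \log_2(\mathrm{TPM}+1)_{ref}$ on the
genes shared with the response matrix $S$ (genes × cytokines). Activities
are ridge coefficients $\beta = (S^\top S + \alpha I)^{-1} S^\top y$ with
$\alpha = 10^4$ by default — the heavy penalty stabilizes the heavily
collinear cytokine signatures and is exposed as a parameter. Significance
comes from gene-label permutations of $y$: the SE of each coefficient is its
standard deviation over `nPerm` permutations (default 1000), $z = \beta /
\mathrm{SE}$, and the two-sided p-value uses the add-one correction
$(1 + \#\{|\beta_{perm}| \ge |\beta|\})/(1+n_{perm})$ so p is never zero.
With `nPerm = 0` the package falls back to the classical linear-model t
formulation with $\widehat{\mathrm{cov}}(\beta) = \hat\sigma^2 M S^\top S M$,
$M = (S^\top S + \alpha I)^{-1}$, and residual degrees of freedom
$n - \mathrm{tr}(H)$; the fallback is this package's reading of a t-test on
ridge coefficients, since no canonical formula exists for penalized fits.
Group-level runs assign star tiers on the BH-adjusted p at 0.1 / 0.05 / 0.01.
The single-cell-style operator is the normalized weighted mean: raw score
$\sum_g w_g x_g / \sum_g |w_g|$ per cell, normalized against gene-label
permutations.

# Attention-MIL histology regression

Each slide is a bag of tile feature vectors; only the bag carries a label
(the normalized histology score). The model embeds tiles (linear + tanh),
scores them with gated additive attention
$u_i = w^\top(\tanh(V^\top h_i) \odot \sigma(U^\top h_i))$, pools by softmax
attention and regresses the bag vector linearly. Training minimizes squared
error with AdamW — adaptive moments with decoupled weight decay, matching
the stated hyperparameters (learning rate $10^{-4}$, weight decay 0.01,
batch size 1) — for a default of 25 epochs with no early stopping; the
gradients are analytic and the whole trainer is deterministic given the seed
and bag order. Cross-validation is 5-fold with score-based stratification:
targets are cut into 4 quantile bins and each bin is dealt cyclically across
folds after a seeded within-bin shuffle, so per-bin fold counts differ by at
most one. External predictions average the five fold models arithmetically
and are clipped to $[0,1]$ only at reporting. Attention maps are min-max
rescaled per slide for display with a default display threshold of 0.4;
constant-attention bags are flagged uninformative rather than rescaled into
noise.

# The synthetic cohort

The generator defines the study conditions under which the pipeline is
validated. Disease labels are allocated by deterministic largest-remainder
apportionment (exact composition, reproducible; ties in remainders resolve
in category order). Each patient contributes one visit with one colonic and
one ileal tissue context; severity is Beta(2,2) per context for IBD patients
and exactly 0 for nonIBD controls, so site-discordant inflammation occurs
naturally. Visit-level readouts (serum, clinical indices) use the maximum
severity across the visit's contexts, on the view that systemic markers
track the worst inflamed site. Each modality draws from its own RNG
sub-stream derived from the master seed, so regenerating one modality never
perturbs another.

Per modality: histology raw scores are Binomial(max, severity) in the
disease-appropriate system (nonIBD slides are scored with both systems);
NPX baselines are Normal(mean ~ N(5, 1.5), sd 0.5) with planted proteins
shifted by 1 NPX unit per unit severity and censoring 2 SD below the
baseline mean; expression is negative binomial (dispersion 10) around a
log-scale model with 100 planted genes at 2 log2 units per unit severity
plus a cytokine-driven term $S a \cdot \mathrm{severity}$ with one planted
TNF-like activity; bags displace a Binomial(n, severity) subset of tiles by
2 background SDs along a fixed unit direction (the first feature axis);
clinical indices (UCEIS 0–8, partial Mayo 0–9, SES-CD 0–56, HBI 0–16,
Bristol 1–7) are rounded, clipped monotone maps of severity with Gaussian
noise. Effect sizes were chosen once as moderate, realistic signals — about
one residual SD per unit severity — and are not tuned per analysis.

What the generator does **not** emulate: batch and plate effects,
covariate structure (age, sex, center) in the outcomes, heavy-tailed or
correlated noise, tissue composition shifts, real foundation-model feature
geometry, and informative missingness beyond the LOD mechanism. Passing the
recovery suites therefore demonstrates the correctness of the computations
and reasonable statistical behaviour under clean conditions, not performance
on real cohorts.

# Problem sizes in the test and acceptance runs

The property suites run at desk scale, chosen to keep the statistical checks
well-powered: Welch calibration uses 2,000-protein null panels with 20 vs 20
samples over 200 replicates; IPSS recovery uses 120-patient cohorts over 10
seeds; the enrichment oracle enumerates all walks up to 8 features × 5
samples over 200 draws; cytokine recovery uses 200 genes × 8 cytokines with
1,000 permutations over 10 seeds; MIL recovery uses 300 bags at feature
dimension 64 (3 seeds), a 200-bag null run, and 100-bag attention-recovery
runs; cross-modality coherence uses a 100-patient (200-context) cohort. The
real feature dimensions (768–2560) remain supported.

# Known limitations

A structural caveat on attention explainability under the synthetic
conditions: because the simulated lesion displaces tiles linearly along one
axis and the bag target is (up to binomial noise) the lesion fraction, the
bag *mean* is a sufficient statistic for the target. Uniform attention is
then an exact optimum of the squared-error objective, and the trained models
reach out-of-fold correlations above 0.8 while their attention stays
essentially uniform — attention-based lesion localization does not emerge
(attention–lesion AUC stays near 0.5 at any training length). The tests
record this honestly rather than adjusting the generator: on real
histopathology, where the evidence for a score is carried by focal,
nonlinearly-informative regions, attention has a reason to concentrate; on a
linearly-pooled synthetic signal it does not. Treat the attention-map
machinery as exercised-but-not-validated by the synthetic cohort.

* The IPSS scoring function on NPX mirrors the bMIS machinery (single-sample
  enrichment); a simple mean-z alternative is easy to build from
  `kcdfTransform` but is not the packaged default.
* The ridge t-test fallback is approximate for penalized fits; permutation
  inference is the primary path.
* The attMIL trainer is CPU-only and single-threaded; it is sized for
  hundreds of bags, not tens of thousands.
* `assembleAtlas` validates referential integrity and score ranges but is a
  lightweight store, not a database engine.
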