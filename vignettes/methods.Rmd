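---
title: "Models and methods behind itcatlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind itcatlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`itcatlearn` analyzes simultaneous spike-count recordings from two
inferotemporal subregions (TE and TEO) while a subject learns to
categorize morphed cat--dog images, and ships a synthetic-data generator
so that every stage of the analysis can be exercised and calibrated
without recorded data. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic experiments do
and do not establish about real recordings.

## The task and the data model

Stimuli form a morph matrix: each *morph identity* is one morphing
sequence built from a unique cat--dog prototype pair, sampled at eleven
*morph levels* (percent dog: 0, 25, 35, 40, 45, 50, 55, 60, 65, 75, 100),
densest around the category boundary. Levels below 50 are "cat", above 50
"dog", and the 50% image belongs to neither category; it is excluded from
every category analysis and from behavioral correct rates, and is the
substrate for the choice analyses.

A session is one day's data: a neuron roster (`TE`/`TEO` labels), a trial
table (image, choice, outcome), and a trials-by-neurons spike-count
matrix for a fixed response window. Counts, not rates, are stored; rate =
count / window, and since the window is constant within an animal every
analysis here is invariant to that scaling. Neurons are keyed per day and
never tracked across days — each day is an independent sample, which is
why cross-day inference (below) treats the day as the exchangeable unit.
Sessions round-trip through plain TSV tables plus a small JSON sidecar,
deliberately inspectable formats since no standard bioinformatics
container covers trial-aligned electrophysiology.

## The synthetic generator

Each simulated neuron's mean rate to an image is

```
baseline + identity_offset[id] + level_slope * (level - 50)/50
         + cat_dir * g(day) * axis[id]
```

with `cat_dir` = +1 (dog), -1 (cat), 0 (boundary), and the category-term
magnitude following a linear schedule `g(day) = initial + slope*(day-1)`
per region. The category direction of a neuron is split between a
*shared axis* common to all morph identities (per-neuron sign, dog-biased
with probability `dog_preference_prob`) and *identity-specific* axes
(independent signs per identity):

```
axis[id] = sqrt(rho) * shared_sign + sqrt(1 - rho) * identity_sign[id]
```

The square-root weights split the category-signal *variance* exactly
rho : (1 - rho), so moving rho reallocates signal between the two axes
without changing its total power. That matters: rho is the generator's
generalization dial — a decoder trained on some identities transfers to
held-out identities only through the shared component — and it must not
double as a signal-strength dial. rho may be scheduled per day and per
region; the learning profile grows TE's rho across days while holding
TEO's fixed.

Rates are rectified at zero *before* noise sampling (so the configured
mean stays interpretable), and counts are Poisson around rate x window by
default (a Gaussian alternative is available). Choices follow a
two-parameter logistic psychometric model, P(second-interval release) =
logistic(slope x (level - 50)/50 + bias), with per-day slope/bias
schedules; the second interval is the dog response. Optionally the
category term is attenuated on error trials (`error_signal_attenuation`),
giving the correct-versus-error analyses a constructed effect to recover.

Two presets exist. `learning_profile_config()` is the two-region learning
profile: TE gain grows (0.3 Hz + 0.45 Hz/day), TEO gain is flat at 2 Hz
(so TEO starts stronger and TE crosses over mid-learning), TE's rho grows
0.35 to 0.85, and the psychometric slope steepens from 1 to 5.
`null_profile_config()` freezes all day schedules. For test-level null
*calibration* the suite additionally zeroes the category gain *and* the
level ramp: a monotone level ramp is itself category-correlated (low
levels are always cat), so a generator with a level ramp is not a null
for category tests, nor — because the ramp is common to all identities —
for the rho = 0 generalization contract.

What the generator does not emulate: temporal dynamics within the window,
adaptation, noise correlations beyond the shared axis, eye movements, and
reward bookkeeping. Passing tests therefore show that the analysis code
recovers what it claims under Poisson-like count noise with the stated
tuning structure — not that real IT populations have that structure.

## Single-unit statistics

Per neuron and day, a fixed-effects nested ANOVA on trial rates tests
modulation by category, morph identity, and morph level nested within
category (sequential sums of squares via `aov`; boundary trials
excluded; every identity-by-level cell needs at least two trials). Which
two-way interaction enters is selectable (`category:identity` by
default, identity-by-level-within-category available) since small daily
designs cannot always support both. Effect size is omega-squared,

```
w^2 = (SSQ_effect - df_effect * MS_error) / (SSQ_total + MS_error)
```

an unbiased estimator ranging from -1 to 1; the pipeline reports it from
a one-way category ANOVA (the raw arithmetic is exported separately), and
significance from the nested model.

Category preference per morph identity uses ROC analysis with dog as the
positive class; AUC equals the Mann--Whitney statistic with ties counted
one half (the threshold-sweep definition leaves ties unspecified; the
tie-half convention makes `auc(a,b) + auc(b,a) = 1`). Significance comes
from 1000 label permutations summarized by a Gaussian fit — the sample
mean and SD of the permuted AUCs, which is the maximum-likelihood
Gaussian fit and avoids any binning choice — with the 1.96-sigma band as
the criterion. Cat-preferring strength is reported as 1 - AUC so both
preferences share one scale. A neuron whose significant AUCs all share
one preference is category-selective; both preferences make it
mixed-selectivity. Choice probability applies the same ROC machinery to
boundary-trial choices, folded to max(AUC, 1 - AUC); crucially its
permutation null folds each permuted AUC the same way, otherwise the
folded statistic would be tested against an unfolded null and the test
would be invalid.

## Population decoding

The read-out is deliberately minimal: one linear unit with sigmoid
output trained on cross-entropy, specified as a *contract* rather than an
optimizer — any deterministic batch gradient method qualifies provided
training halts on whichever fires first: (1) validation error rising for
6 successive epochs (returning the weights at minimum validation error),
(2) gradient infinity-norm below 1e-7, (3) 10000 epochs. The
implementation is a C++ full-batch gradient descent with a bold-driver
step size, zero-initialized (the loss is convex, so determinism needs no
seed). The decision threshold on the sigmoid output is 0.5.

Responses are z-scored per neuron before decoding. By default the
z-scoring is fit on the full per-repeat trial draw
(train + validation + test); a leakage-free variant fit on the training
split alone is available by flag (`zscore_scope = "train"`) and is the
recommendation for new studies — the default exists for comparability
with the unconditional phrasing of the original procedure.

Four strategies share this core. *Traditional*: per repeat, a fresh
neuron subsample and per-image trial draw split train/validation/test
within each image, so test trials are new trials of seen images.
*Generalization*: folds partition morph identities (a seeded uniform
permutation; no assignment rule is prescribed), training uses only
other-identity images and testing only held-out-identity images, so high
accuracy requires identity-general category structure. *Choice*: boundary
trials grouped by the animal's choice, split 80/10/10 per group (val/test
round down, remainder to train, one trial forced into each part).
*Correct-versus-error*: the decoder trains on correct trials of
low-ambiguity images (levels 0/25/75/100) on days with performance at
least 75%, and is evaluated separately on correct and error trials of
ambiguous images (35--65). An image lacking the minimum correct count in
any qualifying day is excluded from all days together with its category
partner (0 with 100, 25 with 75, same identity) to keep training
balanced; ambiguous test images are excluded day-locally, and every
exclusion is emitted in a ledger. Training draws `min_correct` correct
trials per image plus, where available, one extra correct trial per image
as the validation set (the original procedure does not say where its
validation trials came from); if no image has a spare, the training set
doubles as validation.

Every strategy computes its shuffled control *inside the same repeat*
with identical neuron and trial draws, permuting only training labels —
plus validation labels in the generalization variant, matching the
different stated scopes of the two shuffles; the generalization
validation shuffle is switchable. Sampling is always without
replacement, and an over-request errors rather than resampling.

One known pathology is documented deliberately: when the population
signal is effectively one-dimensional (rho = 1, no other tuning), the
traditional shuffled control is biased above chance by roughly +0.1. The
mechanism is selection, not leakage — early stopping returns the
weights at minimum validation error and validation keeps *true* labels,
so repeats whose label shuffle happens to align with the signal axis
survive with high accuracy while anti-aligned repeats revert to near
0.5. With realistic multi-axis tuning (identity offsets, level ramps,
mixed rho) the bias is negligible, and the chance-level tests run there.

## Discriminability and the combination taxonomy

Per decoding repeat, d' = |mean_cat - mean_dog| /
sqrt(0.5 (var_cat + var_dog)) over the decoder's test-trial outputs. The
"decoder output score" is taken as the pre-threshold sigmoid output;
logit-scale scores are available by flag and the d' properties hold on
both (d' is invariant to positive affine maps, not to the sigmoid, so
the two scales genuinely differ — near-saturated scores compress
variances and inflate sigmoid-scale d', which is why summary reports
quote mid-learning days). Combined ensembles pool equal neuron counts
from both regions. The four-way taxonomy compares per-repeat d' vectors
with two-sided permutation tests at level alpha (default 0.05): combined
indistinguishable from the stronger region is *redundant*; significantly
below it, *noise_adding*; significantly above it but below the per-repeat
sum, *complementary*; not significantly below the sum, *independent*.
Repeat-level comparison is the default; comparing repeat means is the
exposed alternative.

## Representational dissimilarity

Patterns are trial-averaged responses per image, then z-scored per neuron
across the image set — this scope makes 1 - r depend only on pattern
shape; a raw-trial z-score variant exists by flag, and trial-averaging
before correlation (rather than averaging correlations over trial draws)
is the default. Dissimilarity is 1 - Pearson r between two images'
patterns, in [0, 2]. Pairs are always drawn from *different* morph
identities (same-identity pairs would confound visual similarity within a
sequence), boundary images excluded, giving exactly 25I(I-1)
between-category and 25I(I-1)/2 per within-category class for I
identities — 2250/1125/1125 at I = 10 and 9500/4750/4750 at I = 20. SEM
is computed over pairs, matching those counts.

## Cross-day inference

Linear fits code day as 1, 2, 3, ... and region as 0 = TEO, 1 = TE; a
positive day coefficient is the learning test and the region-by-day
interaction the divergence test. The pipeline fits these on *day-level
aggregates* (one mean per day and region): observations within a day
share that day's roster, so repeat- or pair-level fits overstate the
evidence (pseudo-replication). The repeat- and pair-level tables are
returned so finer fits remain a one-liner where appropriate.

Bootstrap correlation tests resample repeat-level values within day
(5000 samples by default; day labels are never resampled), average per
day, correlate the day means with the day number — or with behavioral
performance — and summarize r(real) - r(shuffled control); the CI
excluding zero is the significance criterion, with sidedness a per-call
parameter since different summaries print one- and two-tailed intervals.
For series without repeated measures (one value per day) the
observation indices are resampled jointly for both series. Permutation
p-values use the add-one convention (b+1)/(n+1) so finite permutation
counts never yield p = 0; exhaustive enumeration is available for small
groups. Multiple testing across days uses Benjamini--Hochberg FDR.

Behavior--neural association fits behavior ~ accuracy + monkey (monkey as
a fixed 0/1 covariate, raw fraction correct as the scale) for TE, TEO,
and TE+TEO predictor sets, compares AIC/BIC, and exposes Pearson partial
correlations (residualize both variables on the covariates, then the t
transform with n - k - 2 degrees of freedom). Psychometric fits are
binomial maximum likelihood with the slope capped (default 50) for
separable data.

`learning_signature()` condenses a full analysis to the qualitative
two-region pattern: TE-only positive day slopes (significant-neuron
fraction, decoding accuracy, cat-vs-dog dissimilarity), significant
region-by-day interactions, and TE-only behavior correlation. The four
TEO "flatness" checks form one comparison family and are BH-adjusted
before being called flat — without that, four independent null tests at
alpha = 0.05 would wrongly flag about one experiment in ten.

## Problem sizes and calibration choices in the test suite

The suite validates everything on generated data at sizes chosen to keep
the full run to a few minutes while leaving the statistics interpretable:
the signature-recovery experiments use 9 days, 40 neurons per region per
day, subsamples of 10, 12 decoding repeats per day and region, and 1000
bootstrap samples (daily rosters much smaller than 40 make day-to-day
roster sampling itself a noticeable source of cross-day variance in a
way the within-day bootstrap cannot see); null-calibration rates use 500
simulated units or experiments against the binomial 95% CI of the
nominal 5%; the generalization contract uses 60-neuron populations and
50 repeats; and the d'-taxonomy simulations use 8-channel Gaussian
populations with per-channel class separation 0.25 — strong enough for
reliable verdicts, weak enough that sigmoid scores stay unsaturated.

## Limitations

Beyond the generator simplifications above: the nested ANOVA uses
balanced-design sequential decomposition and is exact on (near-)balanced
daily designs, not a general unbalanced-data ANOVA; the decoder is
linear by design, so none of the analyses speak to nonlinear population
codes; d' on sigmoid scores saturates for very strong signals; and the
day-level inference deliberately trades power for calibration, so with
very few days the TE trend tests need large effects — which is a fact
about the design, not the implementation.
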