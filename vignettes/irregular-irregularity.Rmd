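---
title: "Quantifying irregular irregularity: methods and design notes"
author: "regularogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying irregular irregularity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(regularogram)
```

## The problem and the model

Atrial fibrillation (AF) produces a heart rhythm that clinicians call
*irregularly irregular*: not only do the inter-beat (RR) intervals vary, the
beat-to-beat *changes* themselves look random. Rhythms such as bigeminy,
trigeminy or second-degree AV block are merely *regularly* irregular — they
are superpositions of a few regular rhythms, so their beat-to-beat changes
follow a few discrete patterns.

`regularogram` operationalizes this distinction with the **MESC** family
(modified entropy scale). The MESC of order 0 is the RR series itself; the
MESC of order $n$ is the first difference of the order-$(n-1)$ series,

$$m^{(n)}_i \;=\; m^{(n-1)}_{i+1} - m^{(n-1)}_i
      \;=\; \sum_{k=0}^{n} (-1)^k \binom{n}{k}\, \mathrm{RR}_{i+n-k},$$

computed here by iterated differencing and verified in the tests against the
binomial closed form. Order 1 — the difference between consecutive RR
intervals — is the default and the workhorse.

Within a sliding *estimation window* of $W$ consecutive intervals the package
computes three indices:

* **Variability** — the distribution width of the windowed order-$n$ MESC,
  implemented as the sample standard deviation (seconds). An IQR-based
  robust alternative sits behind `variability_estimator = "iqr"`. Width is
  high for *any* irregular rhythm, regular or not.
* **Normality** — the windowed MESC values are standardized by their own
  sample mean and SD and compared with the standard normal distribution;
  the index is $1 - D$, with $D$ the Kolmogorov–Smirnov distance. It is
  bounded in $[0,1]$, dimensionless, and invariant under affine rescaling
  of the MESC. Randomly-changing rhythms (AF) score high; alternans-like
  patterns score low (a symmetric two-point distribution has
  $D = 0.5 - \Phi(-1) \approx 0.341$, i.e. normality $\approx 0.66$, an
  upper ceiling that no amount of data can lift).
* **Mean RR** — the mean of the order-0 MESC in the window, addressing the
  tachycardic tendency of rapid AF episodes.

A window is *irregularly irregular* when variability **and** normality are
both high. Plotting one point per window in the (variability, normality)
plane yields the **regularogram** (RGG); AF windows concentrate in the
high/high corner — the *irregular irregularity zone* — while sinus rhythm
sits at low variability and bigeminy/trigeminy at high variability but low
normality. A third axis (mean RR) gives the 3-D variant.

## Tunable parameters

| Key | Default | Units | Why |
|---|---|---|---|
| `mesc_order` | 1 | — | first differences carry the irregularity signal; higher orders add nothing and shorten the series |
| `window_length` | 150 | beats | ≈2.5 min of rhythm; enough KS resolution while remaining episode-local. Down to ~70 beats remains usable; the hard floor is `mesc_order + 8` |
| `stride` | 30 | beats | 5× overlap balances temporal resolution against cost |
| `ks_mode` | `"fast"` | — | single-pass binned estimator; `"exact"` available everywhere |
| `ks_grid_size` | 32 | bins | error bound $1/32 \approx 0.031$, small relative to class separation |
| `max_splits` | 30 | splits | complexity cap of the decision tree, the only tree control |

## The fast KS estimator

The normality index needs one KS statistic per window. The exact statistic
(`ks_statistic_exact`) evaluates the empirical-CDF sup gap at the sorted
sample, $D = \max_i \max(|i/n - F(x_{(i)})|, |(i-1)/n - F(x_{(i)})|)$. The
fast path (`ks_statistic_fast`) bins the sample into `grid_size`
equal-probability bins of the reference distribution and compares cumulative
bin fractions with the reference CDF at the bin edges. Because the empirical
and reference CDFs are both monotone and the reference rises by exactly
$1/g$ per bin, the binned sup can miss the true sup by at most $1/g$, and it
never exceeds it:

$$D_{\mathrm{exact}} - 1/g \;\le\; D_{\mathrm{fast}} \;\le\; D_{\mathrm{exact}}.$$

The bound is asserted property-style over a thousand seeded samples
(normal, uniform, bimodal; $n$ = 70–300) in the test suite. The estimator
is a stand-in with a proven bound, built from first principles, not a
reconstruction of any particular published construction. The underestimation
bias (≤ $1/g$) slightly *inflates* normality for all rhythms equally; with
the default grid it does not move any class across the zone boundary.

```{r ks-demo}
set.seed(1)
x <- rnorm(150)
c(exact = ks_statistic_exact(x), fast = ks_statistic_fast(x, grid_size = 32))
```

## Preprocessing and labeling rules

Beat times enter in seconds (CSV) or as sample indices (WFDB MIT-format
annotations, converted at read time; sample indices never leave the reader).
Duplicate beat times are collapsed. RR intervals are consecutive beat-time
differences; no ectopy filtering or "cleaning" is applied — the indices are
meant to see the raw rhythm.

Windows are defined over 0-based beat indices (half-open), but labeled over
their time spans against the rhythm segments: a window wholly inside AF
segments is `"AF"`, wholly inside non-AF segments `"non-AF"`, and any window
spanning a rhythm boundary (or lying outside all segments) is
`"ambiguous"` and discarded by every downstream consumer. Containment uses
a $10^{-9}$ s seam tolerance so that windows ending exactly at a segment
boundary are kept.

Degenerate windows (zero MESC variance, i.e. a perfectly regular rhythm)
receive variability 0 and normality 0 — the extreme opposite of irregular
irregularity — rather than an error or an undefined standardization.

## The decision-tree detector

The detector is deliberately the simplest non-linear, explainable model: an
axis-aligned binary tree over (variability, normality, mean RR), grown
best-first on Gini impurity until purity or a cap on the number of internal
split nodes (default 30). "Default settings otherwise" means: minimum leaf
size 1, no pruning. Determinism is guaranteed by explicit tie-breaks — on
equal impurity gain the lowest feature index wins, then the lowest
threshold (midpoints between distinct sorted values), then the
lowest-numbered leaf; majority ties in a leaf go to the first class level.
The cap is interpreted as "maximum number of splits", the common
tree-complexity control.

`evaluate_detection()` reports TP/FP/TN/FN and sensitivity, specificity,
PPV, NPV, accuracy and F1 from their defining ratios; any ratio with a zero
denominator is reported as `NA` (for an all-negative test set only
specificity and accuracy remain defined).

Three protocols wrap the tree:

* `cross_validate()` — hyperparameter selection over a (MESC order ×
  window length) grid. Fold assignment is **record-level** (never
  window-level) so overlapping windows of one record can never leak between
  training and validation. Five folds by default. The best cell is compared
  with every other by a one-tailed unpaired pooled-variance t-test over fold
  accuracies; two identical cells yield $t = 0$, $p = 0.5$, and a
  zero-variance comparison degenerates to $p = 0.5$ (equal means) or the
  smallest representable $p$ (strictly better mean).
* `patient_to_self()` — within each record, a chronological train/holdout
  split (default 70/30; chronological, not random, so the holdout is a
  genuine future). Records whose training part lacks both classes are
  skipped and reported.
* `cross_database()` — one tree trained on a full collection, evaluated on
  id-disjoint collections; metrics on the training collection are included
  but flagged optimistic.

## What the synthetic generator emulates — and what it does not

The generator (`gen_segment`, `gen_record`, `gen_cohort`) targets the
distributional structure the indices assume, no more:

* **AF**: a clipped, mean-reverting Gaussian random walk on RR —
  $\mathrm{RR}_{i+1} = \mathrm{RR}_i + \varepsilon_i - \rho\,(\mathrm{RR}_i -
  \mu)$ with $\varepsilon_i \sim N(0, \sigma_m)$ — so the order-1 MESC is
  approximately $N(0, \sigma_m)$. A pure random walk drifts out of the
  physiologic range; the reversion coefficient is set to $\rho = 0.25$/beat
  so that the stationary RR spread is $\sigma_m/\sqrt{1-(1-\rho)^2} \approx
  1.5\,\sigma_m$ and clipping at the 0.25–2.5 s bounds stays below ~3 % of
  beats even at the widest cohort settings (a weaker pull would park a
  double-digit share of beats on the lower clip bound and visibly distort
  the MESC distribution). The reversion adds a small negative lag-1
  correlation and scales the order-1 MESC sd by $\sqrt{2/(2-\rho)} \approx
  1.07$ — both checked by test.
* **NSR**: mean RR plus a respiratory sinusoid (period 4–7 beats) plus
  Gaussian jitter.
* **Bigeminy / trigeminy**: period-2 / period-3 interval patterns plus
  jitter — wide but decidedly non-normal MESC.
* **AV block**: sinus rhythm in which each beat is dropped with a fixed
  probability, merging its two intervals.
* **PAC**: sinus rhythm with premature couplings
  (`coupling_fraction × mean RR`) followed by a full compensatory pause.

`gen_cohort()` draws per-patient parameters once per record: AF mean RR ~
U(0.5, 0.75) s with MESC sd ~ U(0.06, 0.09) s, sinus mean RR ~
U(0.70, 1.0) s. The mean-rate ranges deliberately **overlap**: AF is
tachycardic only on average, and a gap between the class means would hand
the tree an artifactual single-threshold shortcut on mean RR that no real
cohort offers — an early design with disjoint ranges did exactly that, and
the resulting tree generalized through a spurious one-window leaf. AF
burden is drawn from the requested range and split over 2–5 episodes
interleaved with sinus blocks; an ectopy block (bigeminy, trigeminy, or
none, cycling deterministically over the patient index so every cohort
contains every kind regardless of the seed) replaces a quarter of one sinus
block. Default record length is 8000 beats (~2 h of rhythm), the problem
size also used by the bundled experiments and the acceptance script —
twenty records per cohort, indices at order 1 / window 150 / stride 30.

What the generator does **not** emulate: annotation noise and beat-detector
error, atrial flutter with variable conduction (which genuinely mimics AF
in RR data), gradual autonomic drift, heart-rate-dependent ectopy coupling,
or inter-patient diversity beyond the parameter ranges above. Passing the
bundled experiments therefore shows that the indices and the detector
behave as designed *under the model's own assumptions*; it does not certify
clinical performance on Holter recordings, which must be established on
annotated databases read through the `wfdb` dialect.

## Worked example

```{r example}
rec <- gen_record(list(
  list(profile = rhythm_profile("NSR"), n_beats = 2000),
  list(profile = rhythm_profile("AF"),  n_beats = 1000),
  list(profile = rhythm_profile("NSR"), n_beats = 2000)), seed = 42)
tab <- compute_indices(rec$rr, rec$segments)
aggregate(cbind(variability, normality, mean_rr) ~ label, tab, median)
plot(build_rgg(tab))

fit <- mesc_tree(label ~ variability + normality + mean_rr, tab)
fit
estimate_burden(tab, synthetic_af_zone())
mean(tab$label == "AF")   # annotated AF window fraction
```

## Numerical choices, degenerate inputs, limitations

* Iterated `diff()` and the binomial form agree to ~$10^{-15}$; tests
  assert $10^{-12}$.
* Index tables round-trip through CSV exactly (numerics written with 17
  significant digits).
* Burden is a **window fraction** (denominator: non-ambiguous windows), not
  a time fraction, matching how windows are labeled; `time_weighted = TRUE`
  gives the duration-weighted variant. Rectangle boundaries are inclusive.
* Rhythm series shorter than the MESC order return an empty series with a
  warning; windows shorter than `mesc_order + 8` are rejected at
  configuration time (the KS distance needs a handful of points to mean
  anything).
* Open-ended rhythm annotations are closed at the last beat time and
  flagged (`closed_at_last_beat`).
* The tree's greedy Gini growth cannot solve XOR-like geometries that a
  lookahead could; with the irregularity indices this does not arise, but
  it is a known property, shared with every CART implementation.
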