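---
title: "Methods: drought-diurnal crosstalk calling in dielcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-diurnal crosstalk calling in dielcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielcross)
```

## The problem

Leaf transcriptomes of field-grown rice oscillate with the day/night
cycle, and a large share of the genes that respond to water deficit are
also diurnally rhythmic. Quantifying that overlap takes two independent
classifications that must then be joined on a common gene universe:

1. a **drought-response call** (up / down / unresponsive) from a
   multi-series stress compendium of paired stress/MOCK arrays, and
2. a **diurnal call** (rhythmic or not, plus a peak phase window) from a
   dense time course sampled every 2 h over 2 days across developmental
   stages.

`dielcross` implements both classifications, the crosstalk summary that
joins them, hypergeometric term enrichment of the resulting gene sets, a
pathway-centered interaction network scored by expression correlation,
and the comparative-Ct utility used to validate candidates by qRT-PCR.

## Drought-response calling

Raw linear intensities are log2-transformed (`log2_normalize()`;
nonpositive values are an error, never floored, because a silently
imputed intensity corrupts every downstream fold change). For every
stressed sample the matched MOCK control — same series, same replicate
index — gives a per-replicate fold change
\(\mathrm{log2FC} = \log_2(\text{stress}) - \log_2(\text{mock})\).
The pairing rule is a package decision: per-replicate fold changes
require *some* stress-to-control matching, and replicate index within a
series is the only identifier that generalizes across series designs.

Profiles are clustered with the package's own K-means engine
(`kmeans_profiles()`): Lloyd iterations under squared-Euclidean
distance, run either from every distinct k-subset of points (small
instances, deterministic and independent of row order) or from seeded
k-means++ restarts (large instances, best of 25 by final WCSS). Empty
clusters are repaired by reseeding at the point farthest from its
centroid, which also claims that point so the repair always terminates.
The WCSS history is recorded and is non-increasing by construction.

Cluster labels, not gene labels, decide responsiveness: a cluster whose
mean drought log2FC is at least `up_threshold` is *up*, at most
`-down_threshold` is *down*, otherwise *none*, and members inherit the
cluster label. Defaults are one log2 unit (two-fold) in either
direction. The cluster count for stress profiles defaults to `k = 10`;
because labels derive from cluster means rather than cluster identity,
the final up/down/none partition is robust to moderate changes in `k`
within reason: merging or splitting clusters on the same side of a
threshold leaves every gene's label unchanged.

## Diurnal calling

Time-course profiles are median-centered per gene before clustering so
groups form by shape rather than expression level, and clustered with
the same engine at the default of seven groups.

Rhythmicity needs an explicit criterion for software even where a human
would judge a heatmap by eye. We use a fixed-period 24-h cosinor,
\(y = m + a\cos(2\pi t/24) + b\sin(2\pi t/24)\), fit by least squares;
the score is the fraction of variance explained, clamped to [0, 1], with
a constant series scoring 0 by convention. By default the score is
evaluated on each *cluster centroid* (averaging washes out gene-level
noise and per-gene stage offsets) and every member inherits the call at
the threshold \(R^2 \ge 0.3\); a per-gene mode is available. Under the
white-noise null the expected score is \(2/(n-1)\) — about 0.01 at 216
samples — so 0.3 is far into the signal regime while still admitting
cosine signals attenuated by stage-to-stage level shifts.

The peak phase is assigned by window averaging: the mean of the (pooled,
both days, all included stages) values falling in each of the four clock
windows — midday 08–16, lateday 18–20, midnight 22–02 (wrapping),
predawn 04–06, inclusive even-hour membership — and the window with the
largest mean wins. Exact ties are broken by the fixed order predawn,
midday, lateday, midnight. The windows partition the twelve even
sampling hours, which is asserted whenever windows meet data. Because
every stage contributes the same samples to every window, adding a
constant to one stage's samples cannot change the assignment; the
assignment is likewise invariant under any positive affine transform of
the whole series.

One consequence of window-mean assignment worth knowing: a cosine
peaking *near a window boundary* can be assigned to the neighboring
window even without noise, because a narrow flanking window (predawn,
lateday) concentrates more of the peak than a wide one (midday) does.
With peak hours spread uniformly inside their windows this affects
roughly 6–7% of rhythmic genes at the default phase mix, which is why
recovery accuracy on synthetic data plateaus near 0.93 rather than 1.0.
It is a property of the four-window design itself, not of this
implementation.

`crosstalk_summary()` joins the two calls, reporting per-direction
diurnal percentages to one decimal and the phase distribution of the
rhythmic subset to two decimals (matching the precision conventions of
the quantities it mirrors). An empty direction yields `NA`, not 0.

## Enrichment

Term enrichment is the classical hypergeometric upper tail
\(P(X \ge k)\) for \(X \sim \mathrm{Hyp}(N, K, n)\), evaluated in log
space, with fold enrichment \(k/(nK/N)\) and the two-threshold pass flag
(fold \(\ge 2\), \(P \le 0.05\)). The background defaults to all
annotated genes — the array, not the genome. P values are reported raw
by default because the filter this mirrors used raw hypergeometric
values; Benjamini–Hochberg is available behind `adjust = TRUE`. Terms
smaller than 2 genes or larger than half the background are excluded
before testing to avoid degenerate folds. Annotations are used as given:
no GO-DAG ancestor propagation (that belongs upstream of the annotation
file, and whether the original tooling propagated is unknowable).

## Network construction

The network is pathway-centered: nodes are the pathway genes plus every
interaction partner, and pathway genes without interactions are kept as
isolated nodes. Interaction records are validated (confidence in (0, 1]),
stripped of self loops and duplicate unordered pairs, and the removal
arithmetic is retained in the network log so edge counts always
reconcile with the input. Edges are scored by the Pearson correlation of
their endpoints' log2 expression profiles (log2 matches the rest of the
pipeline; the transform is applied automatically to linear input), and
flagged when the correlation exceeds 0.5. An undefined correlation —
constant profile, missing endpoint — stays `NA` and is never flagged;
dropping such edges silently would hide data problems. All edges are
retained regardless of correlation, mirroring a display convention of
coloring rather than filtering. Regulator relations (bound,
direct target, regulated up/down) overlay as directed edges, with
missing endpoints added as nodes and counted. Exports are SIF plus
node/edge attribute tables, or a single GraphML that round-trips
byte-identically through `import_network_graphml()`.

## qPCR utility

`ddct_fold()` is the pure comparative-Ct method: per-replicate
\(\Delta Ct = Ct_\text{target} - Ct_\text{reference}\), then
\(\Delta\Delta Ct\) as the difference of group means and fold
\(2^{-\Delta\Delta Ct}\). No amplification-efficiency correction is
applied. Error bars come from per-replicate folds
\(2^{-(\Delta Ct_i - \overline{\Delta Ct}_\text{control})}\); the
standard error is computed on the linear scale by default (log2 scale
optional) because the propagation convention behind published error bars
is rarely stated — both are exposed and documented rather than guessed.
Significance is Welch's unequal-variance t test on the \(\Delta Ct\)
values, two-tailed, with inclusive star thresholds at 0.05, 0.01, 0.001
and 0.0001. The utility compares exactly the two groups it is given.

## The synthetic-data generators

The generators exist so every classifier above can be tested against
planted ground truth. They emulate the *statistical structure* the
pipeline assumes, not array physics:

* **Stress series**: nine series (six drought) of paired stress/MOCK
  replicates, two pairs per series by default (per-series replicate
  counts are freely configurable since only the compendium total is
  known). Linear intensities are \(2^{b_g + e_g \cdot s + \varepsilon}\)
  with per-gene baselines \(b_g \sim N(8, 1.5^2)\) log2 units, planted
  effects \(e_g = \pm 2\) (drought series only) for the up/down
  fractions (defaults 0.2/0.2), and noise \(\varepsilon\) of 0.25 log2
  units.
* **Diurnal course**: samples at every even hour, 2 days, nine stages.
  Rhythmic genes (default fraction 0.5, the crosstalk-level rate) get a
  cosine of log2 amplitude 1 with the peak hour drawn uniformly inside a
  window sampled from the phase mix (default 0.35/0.30/0.17/0.18 for
  predawn/midday/lateday/midnight, the reported proportions for
  drought-up genes). Per-gene stage offsets of SD 0.5 log2 units mimic
  vegetative-versus-reproductive level differences.
* **Annotations**: term sizes log-uniform in a recorded range; planted
  terms annotate target-set genes (truth-up ∩ rhythmic) at a rate ratio
  of `planted_term_fold`, with the out-of-set rate deflated to preserve
  expected term size. Note the downstream observed/expected fold is
  diluted to \(f N / (N + (f-1) n_t)\) when the target set is a large
  background share; a planted 10-fold term still clears the 2-fold
  filter comfortably at the default fractions. Infeasible requests
  (membership probability above 1) error out.
* **Interactions**: partner profiles correlated with their pathway
  anchor at a target PCC (default 0.9) for a planted edge subset,
  independent otherwise, over a 24-sample anatomical-style matrix.

All generators emit *linear* intensities so the normalization stage is
always exercised, share one truth table drawn from the configuration
seed (the stress and diurnal datasets agree on which genes are
responsive and rhythmic), and are byte-reproducible from `(config,
seed)`.

What passing recovery tests does **not** show: real arrays have
probe-level effects, correlated noise, RMA/MAS5 summarization artifacts
and batch structure, none of which are modeled (deliberately — see the
non-goals of each module). Recovery rates on this synthetic structure
are an upper bound on real-data performance, and the package's value on
real data rests on the correctness of each step, which is what the
oracle tests (exhaustive partitions, exact enumeration, textbook
formulas) establish.

## Numerical choices

* K-means: relative WCSS tolerance 1e-8, max 100 iterations, restarts as
  above; ties in nearest-centroid assignment go to the lowest cluster
  index.
* Cosinor: fit via `lm.fit` on the \([1, \cos, \sin]\) design; requires
  at least 6 timepoints spanning at least 24 h.
* Hypergeometric tail computed via the log-space distribution function
  and exponentiated once.
* GraphML doubles are serialized with `%.17g` so parse-and-reformat is
  the identity, which is what makes the round trip byte-identical.
* Percentages: one decimal for diurnal shares, two decimals for phase
  proportions.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 1000 genes for the
stress-recovery check, 2000 genes (216 diurnal samples) for the
rhythmicity/phase check, 100 random instances of 4–8 points for the
exhaustive K-means oracle, and every valid hypergeometric tuple up to a
background of 30. These sizes give binomial standard errors well below
the margins being asserted while keeping a full run near one minute.

## Known limitations

* No period estimation: the cosinor period is fixed at 24 h, so a gene
  with a strong 12-h harmonic scores poorly unless its 24-h component is
  substantial.
* Cluster-level rhythmicity inherits cluster granularity: a rhythmic
  gene absorbed into a flat cluster (or vice versa) is miscalled; the
  per-gene mode trades noise robustness for independence from `k`.
* Window-boundary peaks are intrinsically ambiguous (see above).
* The responsiveness thresholds are declared defaults, not values
  recovered from any published cluster figure; sensitivity to them
  should be reported alongside results.
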