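---
title: "Behavior-anchored reconstruction of developmental transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-anchored reconstruction of developmental transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behaveseq)
```

## The problem

Developmental gene expression changes on timescales of minutes, but
conventional time courses pool many animals per timepoint. Because
individuals develop at different paces even when synchronized at hatch, each
pool smears together animals that are effectively at different developmental
ages, capping temporal resolution at the width of the pooling window.

`behaveseq` implements the alternative: monitor each *C. elegans* individual's
locomotion continuously, read its developmental age off its own behavior
(hatching and the three lethargus quiescence bouts whose midpoints mark
larval-stage boundaries), collect single-animal RNA-seq at staggered times,
and sort the profiles along the inferred age axis. With enough individuals,
the sorted single-animal profiles form a minute-resolution trajectory for
every gene.

## Behavioral staging

The staging model treats a centroid track as alternating high-activity
(larval stage) and low-activity (lethargus) epochs:

1. **Speed** — Euclidean displacement over a trailing 10-s window divided by
   the window (`compute_speed`). A trailing window was chosen because the
   centered/trailing choice is not observable at the 225-frame smoothing
   scale; the subsequent smoothing is centered, so bout midpoints are
   unbiased either way.
2. **Smoothing** — centered 225-frame (75 s at 3 fps) moving average with
   shrinking edge windows (`smooth_speed`).
3. **Threshold** — no absolute speed threshold generalizes across arenas and
   optics, so the default is scale-free: a fraction (default 0.1) of the
   track's active speed level, estimated as the 75th percentile of the
   smoothed speed (valid whenever the track is mostly active, which holds
   for any full larval recording).
4. **Hatch** — first sustained (default 2 min) suprathreshold run
   (`detect_hatch`).
5. **Bouts** — maximal subthreshold runs, merged across gaps < 5 min,
   discarded under 10 min (`detect_quiescence_bouts`). Defaults reflect
   lethargus bouts lasting tens of minutes with possible brief twitches
   inside.
6. **Transitions** — midpoints of the three longest post-hatch bouts, in
   temporal order (`call_transitions`). Duration ranking with
   earlier-start tie-breaking rejects spurious short bouts
   deterministically.

Two age coordinates follow for a collection at time $t$:
$\mathrm{age}_\mathrm{hatch} = t - t_\mathrm{hatch}$ and
$\mathrm{age}_\mathrm{L4} = t - t_3$, with the exact identity
$\mathrm{age}_\mathrm{L4} + t_3 - t_\mathrm{hatch} = \mathrm{age}_\mathrm{hatch}$.

The roaming/dwelling classifier (`roaming_fraction`) uses a two-threshold
speed-by-turning-rate rule. The published classifiers live in prior work and
are not reproduced exactly; ours is documented as approximate and is used
only for descriptive per-3-min-bin summaries, never for staging.

## Expression processing

Counts are normalized per sample to reads per million (RPM). Genes that are
all-zero or contain missing values are dropped first and RPM totals are
computed on the surviving matrix (the order of operations is a documented
choice; totals are barely affected because dropped genes carry no or almost
no counts). The *active* set is genes with $\ge 7$ counts in $\ge 30\%$ of
samples ("at least" read inclusively; the sample threshold is a ceiling, so
30% of 193 means 58 samples). Both boundaries are configurable.

## Trajectory reconstruction diagnostics

*Gap curves.* For every unordered sample pair we compute the Pearson
correlation of their profiles (log2(RPM+1) by default; a raw-scale flag
exists, see below) and the absolute age gap, then bin pairs every 5 min from
0 to 600. The first bin ($\le 5$ min) is the "close pair" group. If
behavioral ages order the samples correctly, close pairs correlate more than
far pairs (two-sample Kolmogorov–Smirnov test), and the stage-relative
coordinate should beat the hatch-relative one whenever developmental pace
varies between individuals — at zero pace variability the two coordinates
differ by a constant and are exactly equivalent.

*Smoothing.* Gene trajectories are boxcar means over a 1.45-h window on a
0.17-h grid anchored at age 0. Empty windows yield `NA`, never
interpolation; smoothing is exactly linear in the data.

*Embedding.* Exact $O(n^2)$ t-SNE (perplexity 40, learning rate 110, seeded
initialization, early exaggeration 4 for 100 iterations, momentum 0.5 then
0.8). Layout is seed-dependent by contract, so quality is summarized by a
statistic instead of coordinates: the mean age gap of each sample's five
nearest embedded neighbors, compared with the cohort-wide mean pairwise age
gap.

*Artificial pooling.* Hatch-aligned profiles are averaged in $\pm 30$-min
windows around integer hours, emulating a conventional hourly pooled time
course; comparison against a reference course applies a configurable hour
offset (for e.g. growth-temperature differences), computes per-gene Pearson
r over shared bins, and contrasts the r distribution with a
shuffled-reference control by unpaired t-test.

## Clustering

The temporal-pattern pipeline ("profiles" preset) bins mean RPM per gene in
1-h windows of stage-relative age, applies $\log_2(x+1)$, z-scores each
gene, and subtracts the first bin. Distance is $D = 2(1-r)$ (Pearson),
agglomerated with Ward's criterion treating $D$ as already-squared
(`hclust` method `ward.D`). The marker-selection pipeline ("markers"
preset) clusters per-sample $\log_2(x+1)$ profiles under Ward with a
correlation metric ($1-r$, `ward.D2`), matching the convention of toolboxes
that pair Ward linkage with a correlation distance. The cluster count is a
required user parameter in both presets (defaults 20 and 30); no selection
criterion is imposed. Zero-variance profiles get $r = 0$ (distance 2)
rather than being dropped, preserving gene accounting. Each cluster's
representative gene is the member maximizing Pearson correlation with the
cluster mean, ties broken to the lexicographically smaller id.

A caveat the tests make explicit: because $\log_2(x+1)$ precedes the
z-score, per-gene rescaling of raw expression is absorbed only approximately
(exactly in the large-count limit where $\log_2(cx+1) \approx \log_2 x +
\log_2 c$). The invariance test therefore uses a tolerance rather than
exact equality.

## Per-window differential expression

For two genotype cohorts on the stage-relative coordinate, each half-open
1-h window is tested per gene with a two-sided Mann–Whitney U test,
Benjamini–Hochberg corrected **across genes within the window** (cross-bin
correction would contradict the per-window design). Exact p-values are used
when the data are tie-free (both groups $\le 50$), otherwise the
tie-corrected normal approximation with continuity correction — the
`wilcox.test` convention, against which the implementation is verified.
Fold changes are $\log_2$ ratios of window means with a symmetric 1-RPM
pseudocount, so swapping cohorts negates them exactly. Persistence counts
genes significant ($q < \alpha$, default $\alpha = 0.01$ on adjusted
values; a raw-p flag exists because the thresholded quantity is ambiguous
in the source convention) in at least $k$ windows; the $\ge$-half-of-windows
gene list is emitted for downstream use.

A note on calibration: the Mann–Whitney statistic is discrete. At 15 vs 15
samples the largest achievable two-sided level not exceeding 0.05 is
0.0453, so a well-calibrated implementation should reject slightly *below*
nominal; the calibration test's acceptance band (0.05 ± 0.01) brackets
this value.

## Age prediction

A multilayer perceptron with hidden layers of 4 and 2 ReLU units and one
linear output predicts stage-relative age (minutes) from expression.
Training minimizes mean absolute error with an L2 penalty on weights
($\lambda = 7.3\times10^{-5}$, biases unpenalized) by full-batch Adam
(default 800 iterations, step 0.01, loss-change tolerance $10^{-6}$),
deterministic given the seed. A network this small has genuine bad local
minima under MAE loss (single-init training error varied several-fold
across initializations in development), so each fit runs a few seeded
restarts (default 3) and keeps the lowest training loss — the standard
remedy, and still fully deterministic. Inputs are $\log_2(\mathrm{RPM}+1)$
standardized per gene with training-set statistics only, and the target is
standardized the same way, preventing test leakage; these preprocessing
choices, the activation and the optimizer are recorded config fields
because the source toolbox defaults are not observable.

The evaluation protocol: ~90/10 train/test trials; per-trial shuffled
controls (predictions permuted against truth — for accurate predictions of
ages uniform on $[0, L]$ the expected shuffled MAE tends to $L/3$);
feature-count sweeps in which the train/test split stream is shared across
sizes while gene draws are independent per size ("same selection sequence
across feature numbers"); representative-marker evaluation (the k cluster
representatives vs equally sized random sets, paired by split, compared by
Mann–Whitney over trials); and a random search over small subsets of the
representatives ranked by mean test MAE.

## The synthetic world

The generators plant known structure so every stage has ground truth.

*Tracks* (`gen_locomotion_track`): egg period (default 60 min), four active
stages (defaults 720/480/480/600 min — stage transitions land ~30.5 h
post-recording-start, inside the observed 28–39 h window), three 30-min
quiescence bouts, collection uniform within L4. Active speed is
gamma-distributed around 0.15 units/s with persistent headings
(roaming-grade); quiescent speed is half-normal with a small mean (default
0.004) rather than exactly zero, so threshold selection is genuinely
exercised. Walls reflect specularly (implemented as a coordinate fold,
which preserves per-frame step lengths exactly). Per-individual lognormal
jitter (default SD 0.05) multiplies stage durations.

*Expression cohorts* (`gen_expression_cohort`): collection ages uniform
(or stratified/clustered) over a 600-min stage; 8 parametric archetypes
(ramps up/down, two-rate decay, ~4-h oscillation, ON/OFF switches,
symmetric and asymmetric bursts) with modest per-gene parameter spread —
wide enough that genes are not copies, narrow enough that the 8 planted
classes are genuinely distinct (the recovery criterion is only meaningful
if the classes exist); negative-binomial counts (dispersion 0.1 by
default; 0 gives the deterministic noise-free limit); per-sample library
factors uniform over ±20%. Hatch-relative age adds a per-individual
lognormal pre-stage duration (mean 1830 min, SD parameter 0.1), making
hatch alignment strictly noisier than stage alignment. `param_seed`
decouples gene-level truth from individual-level draws so paired cohorts
(wild-type vs mutant, or null comparisons) share their genes. Genotype
effects multiply expected expression of chosen genes within a stated age
window.

*Stationary cohort* (`gen_stationary_cohort`): gap-curve monotonicity
cannot be exact on a generic cohort — the binned mean correlation wiggles
at the $1/\sqrt{G}$ scale wherever the true curve is flat. This world
makes the property exact by construction: genes come in quadruples
$1 \pm a\cos(\omega t)$, $1 \pm a\sin(\omega t)$ over a half-normal
frequency grid, so across genes the pairwise Pearson correlation equals
$\frac{1}{K}\sum_k \cos(\omega_k \Delta)$ — a closed-form, strictly
decreasing function of the age gap $\Delta$ alone (verified in tests to
machine precision). Raw-scale correlation is used here because the log
transform would break the closed form; that is precisely why the raw-RPM
flag exists.

What a green suite does **not** establish: the simulators emulate sampling
design, timing jitter, count noise and planted temporal shapes — not
mapping artifacts, batch structure, amplification noise, or biological
co-regulation between genes. Recovery statistics on this world bound what
the algorithms can do under their own assumptions, not what any real
cohort will yield; none of the source study's real-data numbers (its
correlations, MAEs or gene counts) are targets of the synthetic tests.

## Numerical and degenerate-input policy

* Zero-variance samples are excluded from pair correlations (warning);
  zero-variance gene profiles z-score to all-zero rows (warning) and take
  correlation 0 (distance 2) in clustering.
* All-tied Mann–Whitney inputs give $p = 1$.
* Empty smoothing windows and empty pooling/fold-change bins yield missing
  flags, never interpolation.
* Hourly pooling requires only that at least one integer-hour center is
  covered; a single populated bin is legal.
* Ties: bout ranking prefers longer duration then earlier start;
  representative-gene ties prefer the lexicographically smaller id; Ward
  merge ties follow `hclust`'s deterministic pair ordering.
* All randomness flows through explicit seeds; internal seeding
  saves/restores the caller's RNG state, and derived seeds stay within
  32-bit integer range.

## Known limitations

* The roaming classifier is an approximation; per-bin roaming fractions are
  descriptive only.
* Staging assumes the recording starts before hatching and covers all three
  transitions; partial timelines require an explicit flag.
* The t-SNE implementation is exact (no Barnes–Hut); practical up to a few
  thousand samples.
* The MLP optimizer is plain full-batch Adam; very large feature sets are
  slower in R than a native toolbox, so sweep trial counts should be scaled
  with available time.
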