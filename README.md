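# behaveseq

Behavior-anchored reconstruction of minute-resolution developmental
transcriptomes in single *C. elegans* individuals.

## The problem

Pooled developmental time courses average animals that are at genuinely
different developmental ages, because individuals hatch-synchronized at
t = 0 drift apart in pace. Pooling therefore caps the temporal resolution
of gene-expression trajectories at the pooling window (typically an hour).
If instead each animal's developmental age can be read off its own
behavior, single-animal RNA-seq profiles can be sorted along that age axis
and rapid (minute-scale) expression dynamics become visible.

`behaveseq` implements that workflow end to end:

1. **Behavioral staging** — from a centroid locomotion track (3 frames/s),
   compute 10-s windowed speed, smooth over 225 frames, detect hatching as
   the onset of sustained activity and the three lethargus quiescence bouts
   as sub-threshold epochs; stage transitions are the bout midpoints. Each
   collection time then has two age coordinates:
   `age_since_hatch` and `age_since_L4` (time since the L3/L4 transition).
2. **Expression processing** — RPM normalization
   (counts / sample total × 10⁶), dead-gene removal, and the active-gene
   filter (≥ 7 reads in ≥ 30% of samples).
3. **Reconstruction diagnostics** — Pearson correlation of every sample
   pair against its age gap (5-min bins over 5–600 min), close-pair
   (≤ 5 min) vs far-pair KS tests, stage- vs hatch-alignment comparison,
   t-SNE embedding (perplexity 40, learning rate 110), sliding-window
   trajectories (1.45-h window, 0.17-h step), and artificial hourly
   pooling (± 30 min) with shuffled-reference controls.
4. **Temporal clustering** — hour-binned profiles, log2(x+1), z-score,
   first-bin normalization; distance `D = 2(1 − r)`; Ward agglomeration
   (presquared convention) cut at user-chosen k; cluster means and
   representative genes (member best correlated with the cluster mean).
5. **Per-window differential expression** — per 1-h window Mann–Whitney U
   tests between genotypes, BH-corrected across genes within each window;
   log2 fold changes with pseudocount; persistence counts (genes
   significant in ≥ k windows).
6. **Age prediction** — a 4-2-1 ReLU multilayer perceptron regressing
   `age_since_L4` on log2(RPM+1) profiles (MAE loss, L2 λ = 7.3×10⁻⁵,
   seeded multi-restart Adam), with train/test trials, shuffled-prediction
   controls, feature-count sweeps, representative-marker evaluation and
   5-of-30 subset search.

A synthetic-data generator with planted ground truth (staged tracks;
expression archetypes: ramps, two-rate decays, oscillations, ON/OFF
switches, localized bursts; negative-binomial counts; per-individual pace
jitter) backs the entire test suite. See
`vignettes/behaveseq-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(behaveseq)

# --- stage one simulated individual -------------------------------------
cfg <- behavior_sim_config()                    # 3 fps, L1-L4 + 3 bouts
sim <- gen_locomotion_track(cfg, individual_seed = 42)
stage_track(sim$track)
#> <developmental_timeline> ind042 hatch=59.5 t=[846.4, 1343.3, 1863.2]
#>   collect=2165.6 (L4 age 302.4 min)
# planted truth: transitions at 846.4, 1343.3, 1863.1 min

# --- reconstruct a 193-individual expression cohort ---------------------
co  <- gen_expression_cohort(expression_sim_config(seed = 1))
rpm <- rpm_normalize(drop_dead_genes(co$counts))
al  <- compare_alignments(rpm, co$samples$age_since_L4, co$samples$age_since_hatch)
#> close-pair mean r: stage-aligned 0.879 vs hatch-aligned 0.270 (KS p ~ 0)

# --- cluster temporal patterns ------------------------------------------
fit <- cluster_preset(rpm, co$samples$age_since_L4, preset = "profiles", k = 8)
truth <- co$truth$genes$archetype[match(names(fit$result$labels),
                                        co$truth$genes$gene_id)]
adjusted_rand_index(fit$result$labels, truth)
#> [1] 1        # the 8 planted archetypes are recovered exactly

# --- predict age from expression ----------------------------------------
X <- t(log2(rpm$values + 1))
model <- fit_age_model(X[1:174, ], co$samples$age_since_L4[1:174], seed = 1)
evaluate_trial(model, X[175:193, ], co$samples$age_since_L4[175:193])$mae
#> all-gene test MAE ~ 10 min (shuffled-prediction control ~ 200 min,
#> the L/3 chance level for ages uniform on [0, 600])
```

The staging call reports the three lethargus midpoints within ~0.1 min of
the planted schedule. The alignment comparison shows why the stage-relative
coordinate matters: under per-individual pace jitter, neighbors in
`age_since_L4` stay transcriptionally similar (r ≈ 0.88) while neighbors in
`age_since_hatch` do not (r ≈ 0.27). The age model inverts the mapping:
~10-minute prediction error from expression alone, against a ~200-minute
chance level.

## Command line

```sh
behaveseq simulate --out sim/ --seed 7          # tracks + counts + metadata
behaveseq stage --tracks sim/ --out timelines.tsv --threshold-frac 0.1
behaveseq run-all --config pipeline.json --out run/   # full pipeline
```

Configs are JSON (YAML accepted when the `yaml` package is present); see
`default_pipeline_config()` for the schema. Every numeric output carries a
header with the package version, a config hash and the seed. Exit codes:
0 ok, 2 validation error, 3 compute error.

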