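# cogtraj

Longitudinal dual-modal detection of early cognitive decline from
spontaneous-speech interviews.

## The problem

Mild cognitive impairment (MCI) leaves fingerprints in free narration:
more and longer pauses, shorter utterances, shifted part-of-speech usage,
stories that drift off topic, and subtle acoustic changes. Most speech
classifiers score a single recording. `cogtraj` is for *longitudinal*
cohorts — subjects retelling life stories across repeated visits — and
classifies the cognitive label of the **last** visit from the whole
trajectory of visits, for researchers working on speech and language
biomarkers of dementia.

## The model

Each story yields two inputs: a pooled acoustic feature vector
`x^a` (frame features from a speech encoder, averaged per 15 s clip and
then across clips) and a timed transcript, from which come an enriched
text (topic sentence + pause markers + topic/content context ids) and a
9-vector `x^l` = (mean length of utterance; short/medium/long pause
counts; noun/verb/adjective/pronoun/other counts). Encoders map these to
128-dim embeddings: a 3-layer 1-D CNN (16/32/64 filters, temporal
reduction ×8) for audio, a transformer backbone with context embeddings
plus a standardized numeric branch for text; the two are summed and fused
by one multi-head self-attention layer into the story embedding `e`.

The **aging trajectory module** consumes visit triplets
`(e_1, e_2, e_3)`: visit k attends to visit k−1 (query from the present,
key/value from the past — strictly causal, with a residual), and a
direction encoder `f_D` maps each difference into a 32-dim direction
embedding `d_k = f_D(e_{k+1} − e_k)`. A batch-norm + linear head scores
the 448-dim concatenation `[ē_1‖ē_2‖ē_3‖d_1‖d_2]`. Training minimizes

```
L = L_class + α·L_E + δ·L_G + γ·L_S ,   (α, δ, γ) = (0.01, 0.001, 0.001)
```

with `L_class` binary cross-entropy, `L_E` a supervised contrastive loss
over story embeddings labeled by cognitive status, `L_G` a supervised
contrastive loss over directions labeled by transition class
(HC→HC / HC→MCI / MCI→MCI), and `L_S` a cosine loss pulling each
subject's directions toward their per-subject mean. All forward passes
*and* backpropagation are hand-written vectorized R (no deep-learning
framework required), trained with Adam, and gradient-checked against
finite differences in the test suite. A synthetic longitudinal cohort
generator with empirically grounded label-transition structure makes the
whole pipeline trainable and testable at desk scale.

## Worked example

Simulate a cohort whose class signal lives **only** in the per-visit
drift direction (nothing separates the classes in any single visit), fit
the longitudinal model, and score held-out subjects:

```r
library(cogtraj)

cohort <- simulate_cohort(n_subjects = 20, drift = 2, static_sep = 0,
                          linguistic_effect = 0, noise_sd = 0.1, base_sd = 5,
                          seed = 42)
cohort
#> <cogtraj_cohort: 20 subjects, 3 visits, 125 stories (seed 42)>

features <- story_features(cohort)
cfg <- trajectory_config(acoustic_dim = 32, text_dim = 32,
                         lr = 3e-3, max_epochs = 40)
fit <- fit_trajectory_model(features, cfg, seed = 42)
fit
#> <cogtraj_fit: mode=lg, 40 epochs (best 33), 193747 parameters>

val <- features[features$subject_id %in% fit$val_subjects, ]
preds <- predict_subjects(fit, val)
preds
#> # A tibble: 4 × 4
#>   subject_id probability label predicted
#>   <chr>            <dbl> <int>     <int>
#> 1 S003            0.0960     0         0
#> 2 S009            0.986      1         1
#> 3 S015            0.847      1         1
#> 4 S017            0.260      0         0
compute_metrics(preds$label, preds$probability)
#> # A tibble: 1 × 6
#>   accuracy    f1 precision sensitivity specificity auroc
#> 1        1     1         1           1           1     1
```

Each row of `preds` is one subject: `probability` is the soft-voted mean
over that subject's triplet probabilities (one triplet per last-visit
story) and `predicted` is impaired iff it exceeds 0.5. With only four
held-out subjects the perfect metrics carry little evidence on their own;
the acceptance experiments below use 60 subjects with 3-fold
cross-fitting, where the same setup reaches mean AUROC >= 0.95 while a
signal-free cohort stays at chance. `cv_trajectory()` runs the full
subject-wise k-fold protocol; `story_embeddings() |>
project_trajectories() |> autoplot()` draws the per-subject embedding
trajectories on the first two principal components; `tidy()`, `glance()`
and `autoplot()` work on fitted objects. A thin CLI
(`inst/exec/cogtraj`) wraps `simulate` / `extract` / `fit` / `evaluate`.

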