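---
title: "Modeling longitudinal cognitive decline from spontaneous speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal cognitive decline from spontaneous speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtraj)
library(dplyr)
```

## The problem

Mild cognitive impairment (MCI) changes how people speak long before it
shows up in structured testing: more and longer pauses, shorter utterances,
simpler syntax, and stories that wander from their announced topic.
Autobiographical-memory interviews — a subject freely narrating life
stories, revisited every six months or so — produce exactly the kind of
spontaneous speech where these signals live. `cogtraj` implements a
longitudinal dual-modal classifier for such interviews: each *story* at
each *visit* yields an acoustic feature vector and a timed transcript; a
fusion encoder turns the pair into a story embedding; and an *aging
trajectory module* models how a subject's embeddings move between visits,
classifying the cognitive label of the final visit from the whole
trajectory rather than from a single snapshot.

## Data model

One row per story: `subject_id`, `visit_index` (1-based, up to 3 visits),
`story_index`, `topic`, visit-level `label` (0 = healthy control, 1 =
impaired; serialized as strings in manifests), a WAV reference, and a timed
transcript (the `"segments"` JSON dialect of timestamped ASR tools).
Longitudinal mode requires every subject to have at least one story at
every visit; `validate_longitudinal()` reports violations instead of
imputing, because the triplet construction below has no principled way to
fill a missing visit.

## Feature extraction

**Acoustic.** Audio is channel-averaged, polyphase-resampled to 16 kHz and
normalized to zero mean and unit (population) variance, then cut into
15-second clips with 5-second overlap. A pluggable frame-level extractor
maps each clip to a `seq_len x F` matrix (a pretrained speech encoder with
F = 1024 in production; deterministic toy extractors at desk scale). Frames
are averaged within each clip and clip vectors are averaged with equal
weight — deliberately *not* the global frame mean, so long clips do not
dominate. A trailing partial clip is kept when it is at least 1 s long; no
padding is applied, because padding would bias the clip means that the
pooling consumes.

**Linguistic.** Each ASR segment is one utterance (the transcripts carry no
other sentence boundary). Inter-utterance gaps are classified as short
(< 0.5 s), medium (0.5–2 s, boundaries inclusive — the outer bands are
defined by strict inequalities) or long (> 2 s); overlapping segments are
clipped to a zero gap. The 9-vector per story is: mean length of utterance,
the three pause counts, and five coarse part-of-speech counts (noun, verb,
adjective, pronoun, other) from a pluggable tagger — a deterministic
rule-table tagger ships for tests, and fine-grained tagsets map onto the
five classes via `map_pos_tags()`. The *enriched transcript* for the text
encoder prepends a topic sentence ("I'm going to share a story of {topic}."
— the template is configurable per language) and inserts bracketed pause
markers (`[PAUSE_S]`/`[PAUSE_M]`/`[PAUSE_L]`) at the gaps; bracketed tokens
survive subword tokenization when registered as special tokens. Every token
carries a context id: 0 over the topic sentence, 1 over the story content.

## Encoders and fusion

The acoustic encoder is a small CNN: three 1-D convolutions (kernel 3,
stride 1; 16/32/64 filters), each followed by batch normalization, ReLU and
max-pooling (kernel and stride 2), reducing the temporal resolution by a
factor of 8, then a fully connected projection to 128 dimensions. The
linguistic encoder adds a 2-row context-embedding table to the token
embeddings of a bidirectional transformer backbone, pools the first token,
standardizes the 9 numeric features with statistics fit on the training
fold only (count scales differ by orders of magnitude), embeds them through
one affine layer, and projects the concatenation — pooled text first, then
the numeric embedding — to 128 dimensions. Fusion sums the two modality
embeddings and applies one multi-head self-attention layer; on a one-token
sequence the softmax weight is identically 1, so the layer contributes its
value and output projections, and fusion is symmetric in its arguments.

This build consumes the text backbone *frozen*, as a pooled-feature
extractor (a tiny seeded transformer with the same interface stands in at
desk scale). The package's trainable linguistic parameters are the numeric
encoder and projector. Freezing keeps the hand-written training loop
focused on the parts this package contributes; fine-tuning a pretrained
checkpoint would be done outside it.

## The aging trajectory module

Triplets `(e1, e2, e3)` of story embeddings, one per visit, are processed
causally: visit k queries visit k-1 through one shared cross-attention
layer (key and value from the *previous* visit only — the model may look
back, never forward), with a residual connection so the enhanced embedding
stays anchored to the current visit. Visit 1 has no predecessor and passes
through unchanged. The direction encoder maps each consecutive difference
`e_k - e_(k-1)` through two affine layers (128 → 64 → 32, ReLU between)
into a 32-dimensional *direction embedding*. The classifier applies batch
normalization and one fully connected layer to the 448-dimensional
concatenation (3 × 128 + 2 × 32) and emits a single sigmoid logit for the
last visit's label. Setting `ablate_direction = TRUE` removes the
cross-attention enhancement and the directions, leaving a classifier over
the raw concatenated embeddings — the "treat every visit as independent"
ablation. A separate batch-norm + affine head serves the cross-sectional
(single-story) mode.

## Losses

Four components, combined as
`L = L_class + 0.01 L_E + 0.001 L_G + 0.001 L_S`:

- **Classification** `L_class`: binary cross-entropy on the triplet logit.
- **Encoder loss** `L_E`: supervised contrastive loss over story
  embeddings labeled by their visit's cognitive status. In its original
  formulation the sum starts at visit 2; `include_visit1` restores
  visit-1 embeddings if wanted (default off).
- **Group alignment** `L_G`: supervised contrastive loss over direction
  embeddings labeled by transition class — 0 (HC→HC), 1 (HC→impaired),
  2 (impaired→impaired). Reverse (impaired→HC) transitions occur in real
  cohorts but have no transition class; they are excluded rather than
  granted a fourth class the model never trains on.
- **Subject alignment** `L_S`: a subject's story-pair directions for a
  visit pair should agree; each contributes `1 - cos(mean direction, d)`.
  Cosine is scale-free, so directions are not normalized first;
  denominators are guarded at 1e-8. The original formulation is a raw double
  sum; the default here divides by the number of terms so the loss
  magnitude is batch-size independent, with `reduction = "sum"` recovering
  the raw sum (the oracle tests use it).

The supervised contrastive temperature defaults to 0.07, the conventional
setting for this loss. All loss gradients are analytic and are verified
against finite differences and naive-loop oracles in the test suite.

## Training

Because no deep-learning framework is assumed, forward passes *and*
backpropagation are hand-written in vectorized base R and optimized with
Adam. Each epoch rebuilds triplets by pairing every last-visit story with
uniformly sampled stories from visits 1 and 2 (seeded by subject and epoch,
so epochs see fresh transitions while runs reproduce exactly), then
down-samples the majority class — training data only; validation is never
balanced or used for standardization statistics. Early stopping monitors
validation loss with patience 10. The published operating point (128/128/32
embedding widths, batch size 8, at most 150 epochs, loss weights as above)
is the default configuration; two knobs differ at desk scale and are
deliberate choices of this package:

- **Learning rate.** 1e-5 suits fine-tuning large pretrained backbones;
  training the compact encoders from scratch uses 1e-3 (default) to 3e-3.
- **Dropout.** The published 0.3 dropout rates live inside the fine-tuned
  text backbone. Since this build freezes the backbone, the same rate is
  instead applied to story embeddings during training, with one mask shared
  across a triplet's three visits. The shared mask matters: independent
  masks would break the cancellation of subject-level offsets inside the
  direction encoder's differences and drown the trajectory signal.

Subject-wise k-fold cross-validation (`cv_trajectory()`) splits by subject
— never by story — to prevent leakage, stratifying folds by last-visit
label; the leakage guard is also asserted inside the training loop.
Evaluation soft-votes story/triplet probabilities into one probability per
subject (ties at 0.5 go to HC) and reports accuracy, F1, precision,
sensitivity, specificity and rank-based AUROC, averaged at fold level.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the model assumes,
not the surface form of real interviews. Label paths follow a two-state
chain whose defaults reproduce the observed longitudinal transition counts
(50 HC→HC, 10 HC→MCI, 8 MCI→HC, 40 MCI→MCI of 108 transitions, normalized
within origin state; 26/54 impaired at baseline; 54 subjects with 1–3
stories per visit). Story features in each modality are
`b_i + (k-1)·drift·g_c + static_sep·u·[impaired] + noise`, with `b_i` a
subject base vector and `g_HC`, `g_impaired`, `u` fixed orthonormal
directions. `drift` puts signal *only* in the trajectory (it cancels
nothing a static classifier can use once `static_sep = 0`, while
consecutive-visit differences cancel `b_i` exactly); `static_sep` puts
signal in every snapshot. Impaired visits also scale pause-count means by
1.5 and cut mean utterance length by 20% (`linguistic_effect` interpolates
this shift down to none), and transcripts are rendered from a template
lexicon so the extractor reproduces the intended counts exactly. Default
effect sizes (`drift = 0.3`, `static_sep = 0.5`, `linguistic_effect = 1`,
`noise_sd = 0.5`, `base_sd = 1`) describe a moderately separable cohort.

What passing on synthetic data does and does not show: the generator's
stories are Gaussian vectors and template text — no speaker variation in
recording conditions, no ASR errors, no topic semantics. Recovery results
demonstrate that the pipeline's machinery (features → encoders → trajectory
module → losses → CV) extracts the structure it claims to extract; they say
nothing about effect sizes in real cohorts.

## The recovery and null experiments

The acceptance experiments use a frozen desk-scale protocol: 60 subjects,
32-dimensional acoustic/text features, `drift = 3`, `static_sep = 0`,
`linguistic_effect = 0`, `noise_sd = 0.1`, `base_sd = 5` (trajectory-only
signal: within-visit class separation stays at sampling-noise level while
consecutive-visit differences separate cleanly, and the 9 linguistic
features carry no group shift); training at `lr = 3e-3`, at most 80 epochs,
patience 10; evaluation by 3-fold subject-wise cross-fit with AUROC on the
pooled out-of-fold soft-voted subject probabilities, over 5 seeds. The full
longitudinal model is expected to reach mean AUROC at least 0.95 and to
beat or match the direction-ablated configuration in at least 4 of 5
seeds; the null cohort (`drift = static_sep = 0`) must stay at chance
(mean within 0.5 ± 0.08). These sizes keep the whole suite within minutes
on one CPU while leaving the comparisons well powered.

## Numerical choices and degenerate inputs

- Batch normalization uses batch statistics in training and running
  averages in evaluation; evaluation is fully deterministic.
- Pause-band boundaries (0.5 s, 2 s) fall in the medium band; negative ASR
  gaps clip to zero; a single-segment transcript has zero pauses.
- `supcon_loss()` skips anchors without positives and returns 0 with a
  warning when none remain; `group_alignment_loss()` likewise with fewer
  than two usable directions.
- AUROC is the Mann-Whitney rank statistic with mid-ranks for ties; a
  single-class truth yields `NA` with a warning while the threshold
  metrics are still reported.
- Triplet pairing, down-sampling, splits, initialization and dropout all
  derive their streams from one user seed; two runs with the same seed are
  bit-identical.

## Known limitations

- Exactly three visits; subjects with fewer are reported as violations,
  not imputed, and irregular inter-visit intervals carry no time encoding
  (visits are ordinal).
- The bundled tagger and tokenizer are toys; languages without spaced
  orthography need a real segmenter/tagger behind the `PosTagger`
  interface.
- The frozen-backbone design means context embeddings are exercised in the
  forward path but not trained end-to-end here.
- Probabilities are not calibrated; soft voting averages them as-is.
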