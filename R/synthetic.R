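# Synthetic longitudinal cohort generator. Emulates the statistical
# structure the longitudinal model assumes — subjects with up to 3 visits,
# 1-3 stories per visit, visit-level labels with empirically grounded
# transition proportions, group-dependent drift in feature space and
# group-dependent linguistic behaviour (more/longer pauses, shorter
# utterances) — so every stage of the pipeline is trainable and testable
# with no data download.

#' Simulate a longitudinal dual-modal cohort
#'
#' Label paths follow a two-state chain whose transition proportions default
#' to the observed longitudinal cohort counts (HC-to-HC 50, HC-to-impaired
#' 10, impaired-to-HC 8, impaired-to-impaired 40 of 108 transitions,
#' normalized within origin state) with 26/54 impaired at baseline. Story
#' feature vectors in each modality follow
#' `b_i + (k-1) * drift * g_c + static_sep * u * [impaired] + noise`,
#' where `b_i` is the subject's latent base, `g_HC`/`g_impaired`/`u` are
#' fixed orthonormal vectors and `c` is the visit's label: `drift` controls
#' how informative the trajectory is, `static_sep` how informative a single
#' visit is. Setting `static_sep = 0` with `drift` large produces data
#' where only the trajectory carries the label; `drift = static_sep = 0` is
#' the null cohort. Impaired visits also shift the rendered transcripts:
#' pause counts scale by 1.5 and mean utterance length drops 20%.
#' Transcripts are rendered from a template lexicon so the linguistic
#' extractor reproduces the intended counts exactly; `linguistic_effect`
#' scales those group shifts (0 removes every linguistic difference, so a
#' cohort with `drift = static_sep = linguistic_effect = 0` carries no
#' label information at all).
#'
#' @param n_subjects Number of subjects (default 54, the longitudinal
#'   cohort size).
#' @param visits Visits per subject (default 3).
#' @param stories_range Inclusive range of stories per visit (default 1-3).
#' @param transition_counts Named counts for `hc_hc`, `hc_mci`, `mci_hc`,
#'   `mci_mci`, normalized within origin state.
#' @param p_baseline_impaired Probability of the impaired label at visit 1.
#' @param drift Per-visit drift magnitude along the group direction.
#' @param static_sep Visit-independent class offset magnitude.
#' @param linguistic_effect Scale of the group shift in the rendered
#'   transcripts (1 = the full 1.5x pauses / -20% utterance length; 0 =
#'   no linguistic group difference).
#' @param noise_sd Per-story feature noise standard deviation.
#' @param base_sd Standard deviation of the subject base vector.
#' @param acoustic_dim,text_dim Feature dimensions (desk-scale defaults 32).
#' @param audio Also synthesize toy waveforms per story (slower; exercises
#'   the audio preprocessing stack).
#' @param seed Seed; everything downstream is deterministic in it.
#' @return Object of class `cogtraj_cohort`: `stories` (story tibble with
#'   `transcript`, `acoustic`, `text_vec` list-columns and the 9 linguistic
#'   feature columns), `truth` (per subject-visit labels and transition
#'   codes), and the generator `config`.
#' @export
simulate_cohort <- function(n_subjects = 54, visits = 3L,
                            stories_range = c(1L, 3L),
                            transition_counts = c(hc_hc = 50, hc_mci = 10,
                                                  mci_hc = 8, mci_mci = 40),
                            p_baseline_impaired = 26 / 54,
                            drift = 0.3, static_sep = 0.5,
                            linguistic_effect = 1,
                            noise_sd = 0.5, base_sd = 1,
                            acoustic_dim = 32L, text_dim = 32L,
                            audio = FALSE, seed = 1) {
  stopifnot(n_subjects >= 1, visits >= 2,
            all(c("hc_hc", "hc_mci", "mci_hc", "mci_mci") %in% names(transition_counts)))
  if (any(transition_counts < 0) || drift < 0 || static_sep < 0 ||
      linguistic_effect < 0 || noise_sd < 0 || base_sd < 0) {
    abort("Counts, drift, separation and standard deviations must be >= 0")
  }
  p_decline <- transition_counts[["hc_mci"]] /
    (transition_counts[["hc_hc"]] + transition_counts[["hc_mci"]])
  p_revert <- transition_counts[["mci_hc"]] /
    (transition_counts[["mci_hc"]] + transition_counts[["mci_mci"]])
  if (!is.finite(p_decline) || !is.finite(p_revert)) {
    abort("Transition counts must give valid within-state probabilities")
  }

  basis_a <- orthonormal_triple(acoustic_dim, derive_seed(seed, "basis_a"))
  basis_t <- orthonormal_triple(text_dim, derive_seed(seed, "basis_t"))
  lexicon <- default_toy_lexicon()
  topics <- names(lexicon)[lexicon == "noun"]

  stories <- list()
  truth <- list()
  with_seed(derive_seed(seed, "cohort"), {
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("S%03d", i)
      labels <- integer(visits)
      labels[1] <- rbinom(1, 1, p_baseline_impaired)
      for (k in 2:visits) {
        labels[k] <- if (labels[k - 1] == 0L) rbinom(1, 1, p_decline)
        else 1L - rbinom(1, 1, p_revert)
      }
      base_a <- rnorm(acoustic_dim, sd = base_sd)
      base_t <- rnorm(text_dim, sd = base_sd)
      truth[[sid]] <- tibble::tibble(
        subject_id = sid, visit_index = seq_len(visits), label = labels,
        transition_from_prev = c(NA_integer_,
                                 transition_code(labels[-visits], labels[-1]))
      )
      story_choices <- stories_range[1]:stories_range[2]
      for (k in seq_len(visits)) {
        n_stories <- story_choices[sample.int(length(story_choices), 1)]
        for (m in seq_len(n_stories)) {
          lab <- labels[k]
          mean_a <- base_a + (k - 1) * drift * basis_a[, 1 + lab] +
            static_sep * lab * basis_a[, 3]
          mean_t <- base_t + (k - 1) * drift * basis_t[, 1 + lab] +
            static_sep * lab * basis_t[, 3]
          tr <- render_story_transcript(lab, lexicon, linguistic_effect)
          stories[[length(stories) + 1L]] <- tibble::tibble(
            subject_id = sid, visit_index = k, story_index = m,
            topic = sample(topics, 1), label = lab,
            transcript = list(tr),
            acoustic = list(mean_a + rnorm(acoustic_dim, sd = noise_sd)),
            text_vec = list(mean_t + rnorm(text_dim, sd = noise_sd))
          )
        }
      }
    }
  })
  stories <- dplyr::bind_rows(stories)
  feats <- purrr::map(stories$transcript, linguistic_features)
  stories <- dplyr::bind_cols(stories, dplyr::bind_rows(feats))
  if (audio) {
    stories$audio <- purrr::map(seq_len(nrow(stories)), function(j) {
      dur <- max(stories$transcript[[j]]$end) + 0.3
      generate_toy_audio(dur, "sine_mix", seed = derive_seed(seed, "audio", j))
    })
  }
  structure(
    list(stories = stories,
         truth = dplyr::bind_rows(truth),
         config = list(n_subjects = n_subjects, visits = visits,
                       stories_range = stories_range,
                       transition_counts = transition_counts,
                       p_baseline_impaired = p_baseline_impaired,
                       drift = drift, static_sep = static_sep,
                       linguistic_effect = linguistic_effect,
                       noise_sd = noise_sd, base_sd = base_sd,
                       acoustic_dim = acoustic_dim, text_dim = text_dim,
                       seed = seed)),
    class = "cogtraj_cohort"
  )
}

#' @export
print.cogtraj_cohort <- function(x, ...) {
  cat(sprintf("<cogtraj_cohort: %d subjects, %d visits, %d stories (seed %d)>\n",
              x$config$n_subjects, x$config$visits, nrow(x$stories),
              x$config$seed))
  invisible(x)
}

# Fixed orthonormal directions (g_HC, g_impaired, u) via QR of a seeded
# Gaussian matrix.
orthonormal_triple <- function(dim, seed) {
  stopifnot(dim >= 3)
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(dim * 3), dim, 3)))
  })
  Q
}

# Render one story transcript with group-dependent pause/utterance
# structure. Impaired visits at full effect: pause-count means x1.5,
# utterance length -20%; `effect` interpolates toward no group difference.
render_story_transcript <- function(label, lexicon = default_toy_lexicon(),
                                    effect = 1) {
  f <- if (label == 1L) 1 + 0.5 * effect else 1
  mlu_mean <- if (label == 1L) 8 * (1 - 0.2 * effect) else 8
  n_short <- rpois(1, 3 * f)
  n_medium <- rpois(1, 2 * f)
  n_long <- rpois(1, 0.7 * f)
  n_seg <- n_short + n_medium + n_long + 1L
  gap_cat <- sample(rep(c("short", "medium", "long"),
                        c(n_short, n_medium, n_long)))
  gaps <- vapply(gap_cat, function(g) {
    switch(g, short = runif(1, 0.05, 0.45), medium = runif(1, 0.5, 2),
           long = runif(1, 2.05, 4))
  }, numeric(1), USE.NAMES = FALSE)
  words_per_seg <- pmax(1L, rpois(n_seg, mlu_mean))
  vocab <- names(lexicon)
  texts <- vapply(words_per_seg, function(nw) {
    paste(sample(vocab, nw, replace = TRUE), collapse = " ")
  }, character(1))
  start <- numeric(n_seg)
  end <- numeric(n_seg)
  t0 <- 0.5
  for (s in seq_len(n_seg)) {
    start[s] <- t0
    end[s] <- t0 + 0.35 * words_per_seg[s]
    t0 <- end[s] + if (s < n_seg) gaps[s] else 0
  }
  tibble::tibble(start = round(start, 3), end = round(end, 3), text = texts)
}

#' Model-ready feature table of a synthetic cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Story feature tibble for [fit_trajectory_model()].
#' @export
story_features <- function(cohort) {
  stopifnot(inherits(cohort, "cogtraj_cohort"))
  cohort$stories[, c("subject_id", "visit_index", "story_index", "label",
                     "acoustic", "text_vec", linguistic_feature_names)]
}

#' Write a cohort to the standard on-disk layout
#'
#' Writes `manifest.csv`, one transcript JSON per story under
#' `transcripts/`, and (when the cohort carries audio) one WAV per story
#' under `wav/`. The layout round-trips through
#' [read_story_manifest()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cogtraj_cohort"))
  dir.create(file.path(dir, "transcripts"), recursive = TRUE, showWarnings = FALSE)
  has_audio <- "audio" %in% names(cohort$stories)
  if (has_audio) dir.create(file.path(dir, "wav"), showWarnings = FALSE)
  st <- cohort$stories
  stem <- sprintf("%s_v%d_s%d", st$subject_id, st$visit_index, st$story_index)
  st$transcript_path <- file.path("transcripts", paste0(stem, ".json"))
  st$audio_path <- if (has_audio) file.path("wav", paste0(stem, ".wav")) else ""
  for (j in seq_len(nrow(st))) {
    write_timed_transcript(st$transcript[[j]], file.path(dir, st$transcript_path[j]))
    if (has_audio) write_wav(st$audio[[j]], file.path(dir, st$audio_path[j]))
  }
  manifest <- file.path(dir, "manifest.csv")
  write_story_manifest(st, manifest, rel_to = dir)
  invisible(manifest)
}

#' Deterministic toy audio
#'
#' A 16 kHz mono waveform for exercising the preprocessing, segmentation
#' and pooling stack: either a mix of three seeded sinusoids (near-zero
#' mean) or white noise.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param kind `"sine_mix"` or `"noise"`.
#' @param seed Seed.
#' @param rate_hz Sampling rate (default 16000).
#' @return A [waveform()].
#' @export
generate_toy_audio <- function(duration_s, kind = c("sine_mix", "noise"),
                               seed = 1, rate_hz = 16000) {
  kind <- match.arg(kind)
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a positive number")
  }
  n <- round(duration_s * rate_hz)
  t <- seq_len(n) / rate_hz
  x <- with_seed(derive_seed(seed, "toy_audio", kind), {
    if (kind == "sine_mix") {
      freqs <- runif(3, 80, 1000)
      amps <- runif(3, 0.2, 0.5)
      phases <- runif(3, 0, 2 * pi)
      x <- rowSums(vapply(1:3, function(i) amps[i] * sin(2 * pi * freqs[i] * t + phases[i]),
                          numeric(n)))
      x / max(1, max(abs(x)) / 0.9)   # keep within PCM range
    } else {
      rnorm(n, sd = 0.3)
    }
  })
  waveform(x, rate_hz)
}

#' Deterministic toy transcript
#'
#' Builds a transcript with exactly the requested inter-segment gaps and
#' per-segment word counts, so pause counts and mean utterance length are
#' known by construction.
#'
#' @param n_segments Number of segments.
#' @param gap_s Vector of `n_segments - 1` gaps in seconds.
#' @param words_per_segment Scalar or length-`n_segments` word counts.
#' @param seed Seed for word sampling.
#' @param lexicon Vocabulary to draw words from.
#' @return Timed-transcript tibble.
#' @export
generate_toy_transcript <- function(n_segments, gap_s,
                                    words_per_segment = 5,
                                    seed = 1,
                                    lexicon = names(default_toy_lexicon())) {
  if (length(gap_s) != n_segments - 1L) {
    abort(sprintf("Need %d gaps for %d segments, got %d",
                  n_segments - 1L, n_segments, length(gap_s)))
  }
  if (length(words_per_segment) == 1L) {
    words_per_segment <- rep(words_per_segment, n_segments)
  }
  if (length(words_per_segment) != n_segments) {
    abort("`words_per_segment` must be scalar or one per segment")
  }
  with_seed(derive_seed(seed, "toy_transcript"), {
    texts <- vapply(words_per_segment, function(nw) {
      paste(sample(lexicon, nw, replace = TRUE), collapse = " ")
    }, character(1))
  })
  start <- numeric(n_segments)
  end <- numeric(n_segments)
  t0 <- 0
  for (s in seq_len(n_segments)) {
    start[s] <- t0
    end[s] <- t0 + 0.35 * words_per_segment[s]
    t0 <- end[s] + if (s < n_segments) gap_s[s] else 0
  }
  tibble::tibble(start = start, end = end, text = texts)
}
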