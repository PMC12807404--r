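#' Preprocess audio for feature extraction
#'
#' Standardizes raw audio to the form the frame-feature extractor expects:
#' channel-averaged mono, polyphase-resampled to `rate_hz` (16 kHz by
#' default), then zero-mean unit-variance normalized using the population
#' standard deviation.
#'
#' @param w A [waveform()] (any rate, mono or multi-channel).
#' @param rate_hz Target sampling rate.
#' @return Mono [waveform()] at `rate_hz` with sample mean 0 and population
#'   standard deviation 1.
#' @export
preprocess_audio <- function(w, rate_hz = 16000) {
  stopifnot(inherits(w, "waveform"))
  x <- if (is.matrix(w$samples)) rowMeans(w$samples) else as.numeric(w$samples)
  if (length(x) < 2L) abort("Audio must have at least 2 samples")
  if (w$rate_hz != rate_hz) {
    x <- as.numeric(signal::resample(x, p = rate_hz, q = w$rate_hz))
  }
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) abort("Cannot normalize a constant (zero-variance) signal")
  waveform((x - mu) / sd_pop, rate_hz)
}

#' Segment a waveform into overlapping clips
#'
#' Clips of `clip_len_s` seconds are taken on the start grid
#' `0, hop, 2*hop, ...` with `hop = clip_len_s - overlap_s`. After the last
#' full clip, any uncovered remainder becomes a final shorter clip starting
#' at the next grid position, kept when it is at least `min_tail_s` long.
#' Audio shorter than one clip yields a single clip of the whole signal
#' (the sole clip is always kept). No padding is applied: speech encoders
#' accept variable-length input and padding would bias clip means.
#'
#' @param w A [waveform()].
#' @param clip_len_s Clip length in seconds (default 15).
#' @param overlap_s Overlap between consecutive clips in seconds (default 5).
#' @param min_tail_s Minimum length for a trailing partial clip (default 1).
#' @return Object of class `clip_set`: list with `clips` (list of
#'   waveforms), `starts_s`, `seg_num`, `clip_len_s`, `overlap_s`.
#' @export
#' @examples
#' w <- generate_toy_audio(35, seed = 1)
#' segment_clips(w)$seg_num  # 3 clips starting at 0, 10, 20 s
segment_clips <- function(w, clip_len_s = 15, overlap_s = 5, min_tail_s = 1) {
  stopifnot(inherits(w, "waveform"))
  if (!is_scalar_number(clip_len_s) || !is_scalar_number(overlap_s) ||
      overlap_s < 0 || clip_len_s <= overlap_s) {
    abort("Need clip_len_s > overlap_s >= 0")
  }
  x <- w$samples
  if (is.matrix(x)) abort("segment_clips expects mono audio (run preprocess_audio first)")
  n <- length(x)
  dur <- n / w$rate_hz
  if (dur <= 0) abort("Waveform has zero duration")
  hop <- clip_len_s - overlap_s
  L <- round(clip_len_s * w$rate_hz)
  hopn <- round(hop * w$rate_hz)

  starts <- integer()
  s <- 0L
  while (s + L <= n) {
    starts <- c(starts, s)
    s <- s + hopn
  }
  if (length(starts) == 0L) {
    starts <- 0L
    ends <- n
  } else {
    ends <- pmin(starts + L, n)
    covered <- ends[length(ends)]
    if (covered < n) {
      tail_len <- (n - s) / w$rate_hz
      if (tail_len >= min_tail_s) {
        starts <- c(starts, s)
        ends <- c(ends, n)
      }
    }
  }
  clips <- purrr::map2(starts, ends, function(a, b) waveform(x[(a + 1L):b], w$rate_hz))
  structure(
    list(clips = clips, starts_s = starts / w$rate_hz, seg_num = length(clips),
         clip_len_s = clip_len_s, overlap_s = overlap_s),
    class = "clip_set"
  )
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("<clip_set: %d clip(s) of <= %g s, overlap %g s; starts %s>\n",
              x$seg_num, x$clip_len_s, x$overlap_s,
              paste(format(x$starts_s), collapse = ", ")))
  invisible(x)
}

#' Two-stage average pooling of frame features
#'
#' First stage: each clip's frame-feature matrix (`seq_len x F`) is averaged
#' over frames, giving one vector per clip. Second stage: the clip vectors
#' are averaged with equal weight per clip (not per frame), giving the
#' story-level acoustic feature. The result is permutation-invariant over
#' clips and, for clips of unequal length, deliberately differs from the
#' global frame mean.
#'
#' @param clip_features List of numeric matrices, all with the same number
#'   of columns F.
#' @return Numeric vector of length F.
#' @export
pool_clip_features <- function(clip_features) {
  if (length(clip_features) == 0L) abort("No clip features to pool")
  dims <- vapply(clip_features, ncol, integer(1))
  if (length(unique(dims)) != 1L) abort("Clip feature matrices have differing dimensions")
  clip_means <- vapply(clip_features, colMeans, numeric(dims[1]))
  if (is.null(dim(clip_means))) clip_means <- matrix(clip_means, nrow = 1)
  rowMeans(clip_means)
}

# -- toy frame-feature extractors ---------------------------------------------

# Split a mono sample vector into frames (rows). Short clips yield one frame.
frame_signal <- function(x, frame_len = 400L, hop = 160L) {
  n <- length(x)
  if (n < frame_len) return(matrix(x, nrow = 1, ncol = n))
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  t(vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len)))
}

#' Deterministic toy frame-feature extractors
#'
#' A frame-feature extractor is any function mapping a clip [waveform()] to
#' a `seq_len x F` matrix with F fixed across clips; production pipelines
#' bind a pretrained speech encoder checkpoint here (F = 1024 for the large
#' multilingual checkpoints). These toy extractors keep the pipeline
#' testable at desk scale: `toy_frame_extractor()` computes 8 summary
#' statistics per 25 ms frame (10 ms hop) and projects them through a fixed
#' seeded random matrix to F dimensions; `constant_frame_extractor()` emits
#' a constant frame, which makes two-stage pooling a fixed point.
#'
#' @param dim Output feature dimension F.
#' @param seed Seed fixing the projection matrix.
#' @param frame_len,hop Frame length and hop in samples.
#' @return A function `waveform -> matrix(seq_len, dim)`.
#' @export
toy_frame_extractor <- function(dim = 32, seed = 1, frame_len = 400L, hop = 160L) {
  proj <- with_seed(derive_seed(seed, "toy_frame_extractor"),
                    matrix(rnorm(8 * dim, sd = 1 / sqrt(8)), nrow = 8, ncol = dim))
  function(clip) {
    stopifnot(inherits(clip, "waveform"))
    fr <- frame_signal(clip$samples, frame_len, hop)
    stats <- cbind(
      rowMeans(fr),
      apply(fr, 1, stats::sd),
      sqrt(rowMeans(fr^2)),
      apply(fr, 1, max),
      apply(fr, 1, min),
      colMeans(abs(diff(t(fr)))),
      rowMeans(fr^3),
      apply(fr, 1, function(r) mean(diff(sign(r)) != 0))
    )
    stats[!is.finite(stats)] <- 0
    stats %*% proj
  }
}

#' @rdname toy_frame_extractor
#' @param value Constant value of every frame feature.
#' @export
constant_frame_extractor <- function(value = 1, dim = 32) {
  function(clip) matrix(value, nrow = 1, ncol = dim)
}

#' Story-level acoustic feature of one waveform
#'
#' Full acoustic path for one story: preprocess (mono, 16 kHz,
#' zero-mean unit-variance), segment into overlapping clips, extract frame
#' features per clip, then two-stage average pooling. Deterministic for a
#' deterministic extractor.
#'
#' @param w A [waveform()].
#' @param extractor Frame-feature extractor (see [toy_frame_extractor()]).
#' @param clip_len_s,overlap_s Clip segmentation parameters.
#' @param preprocess Apply [preprocess_audio()] first (default `TRUE`).
#' @return Numeric vector of length F (the extractor's dimension).
#' @export
story_acoustic_features <- function(w, extractor = toy_frame_extractor(),
                                    clip_len_s = 15, overlap_s = 5,
                                    preprocess = TRUE) {
  if (preprocess) w <- preprocess_audio(w)
  cs <- segment_clips(w, clip_len_s, overlap_s)
  pool_clip_features(purrr::map(cs$clips, extractor))
}

#' Extract acoustic features for every story in a table
#'
#' Reads each story's audio (from an `audio` list-column of waveforms if
#' present, otherwise from `audio_path`) and computes
#' [story_acoustic_features()].
#'
#' @param stories Story tibble.
#' @inheritParams story_acoustic_features
#' @return The id columns of `stories` plus an `acoustic` list-column of
#'   length-F numeric vectors.
#' @export
extract_acoustic_features <- function(stories, extractor = toy_frame_extractor(),
                                      clip_len_s = 15, overlap_s = 5) {
  assert_cols(stories, c("subject_id", "visit_index", "story_index"), "Story table")
  get_wave <- if ("audio" %in% names(stories)) {
    function(i) stories$audio[[i]]
  } else {
    assert_cols(stories, "audio_path", "Story table")
    function(i) read_wav(stories$audio_path[i])
  }
  acoustic <- purrr::map(seq_len(nrow(stories)), function(i) {
    story_acoustic_features(get_wave(i), extractor, clip_len_s, overlap_s)
  })
  out <- stories[, intersect(c("subject_id", "visit_index", "story_index", "label"),
                             names(stories))]
  out$acoustic <- acoustic
  tibble::as_tibble(out)
}
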