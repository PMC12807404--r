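test_that("cohort generation is deterministic and longitudinal-complete", {
  a <- simulate_cohort(n_subjects = 6, acoustic_dim = 8, text_dim = 8, seed = 21)
  b <- simulate_cohort(n_subjects = 6, acoustic_dim = 8, text_dim = 8, seed = 21)
  expect_identical(a$stories$acoustic, b$stories$acoustic)
  expect_identical(a$stories$text_vec, b$stories$text_vec)
  expect_identical(a$truth, b$truth)

  for (seed in c(1, 7, 99)) {
    co <- simulate_cohort(n_subjects = 5, acoustic_dim = 8, text_dim = 8,
                          seed = seed)
    expect_equal(nrow(validate_longitudinal(co$stories)), 0L)
    expect_true(all(dplyr::count(co$stories, .data$subject_id,
                                 .data$visit_index)$n %in% 1:3))
  }

  # on-disk layout is byte-stable under the seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
})

test_that("label paths follow the transition proportions", {
  co <- simulate_cohort(n_subjects = 500, acoustic_dim = 8, text_dim = 8,
                        stories_range = c(1L, 1L), seed = 31)
  tr <- co$truth |>
    dplyr::arrange(.data$subject_id, .data$visit_index) |>
    dplyr::mutate(prev = dplyr::lag(.data$label), .by = "subject_id") |>
    dplyr::filter(!is.na(.data$prev))
  # conditional decline probability 10/60, reversion 8/48 (within 3 se)
  n_hc <- sum(tr$prev == 0)
  p_decline <- mean(tr$label[tr$prev == 0] == 1)
  expect_lt(abs(p_decline - 10 / 60),
            3 * sqrt((10 / 60) * (50 / 60) / n_hc))
  n_mci <- sum(tr$prev == 1)
  p_revert <- mean(tr$label[tr$prev == 1] == 0)
  expect_lt(abs(p_revert - 8 / 48),
            3 * sqrt((8 / 48) * (40 / 48) / n_mci))
  # reverse transitions exist and are excluded from the group loss coding
  expect_gt(sum(is.na(transition_code(tr$prev, tr$label))), 0)
})

test_that("group effects shift the linguistic features as designed", {
  co <- simulate_cohort(n_subjects = 200, acoustic_dim = 8, text_dim = 8,
                        seed = 41)
  st <- co$stories
  hc <- st[st$label == 0, ]
  mci <- st[st$label == 1, ]
  pauses <- function(d) mean(d$n_short + d$n_medium + d$n_long)
  expect_gt(pauses(mci) / pauses(hc), 1.2)   # target ratio 1.5
  expect_lt(mean(mci$mlu) / mean(hc$mlu), 0.9)  # target ratio 0.8
})

test_that("drift places class structure in the trajectory, not the static snapshot", {
  co <- simulate_cohort(n_subjects = 60, drift = 2, static_sep = 0,
                        noise_sd = 0.1, base_sd = 5,
                        acoustic_dim = 16, text_dim = 8, seed = 51)
  st <- co$stories
  Xa <- do.call(rbind, st$acoustic)
  # per-subject consecutive-visit differences separate by transition class
  by_sv <- st |>
    dplyr::summarise(x = list(colMeans(do.call(rbind, .data$acoustic))),
                     label = .data$label[1],
                     .by = c("subject_id", "visit_index"))
  wide <- by_sv |> dplyr::arrange(.data$subject_id, .data$visit_index)
  diffs <- wide |>
    dplyr::mutate(prev = dplyr::lag(.data$x), prev_lab = dplyr::lag(.data$label),
                  .by = "subject_id") |>
    dplyr::filter(!is.na(.data$prev_lab))
  D <- do.call(rbind, purrr::map2(diffs$x, diffs$prev, `-`))
  codes <- transition_code(diffs$prev_lab, diffs$label)
  keep <- !is.na(codes) & codes %in% c(0L, 2L)
  # direction vectors of stable-HC vs stable-impaired pairs are separable
  centroid0 <- colMeans(D[keep & codes == 0L, , drop = FALSE])
  centroid2 <- colMeans(D[keep & codes == 2L, , drop = FALSE])
  expect_gt(sqrt(sum((centroid0 - centroid2)^2)), 1)

  # while single-visit features separate no more than sampling noise allows
  # (static_sep = 0): the class-mean distance stays within 2x its null
  # expectation under base variation alone
  v1 <- st[st$visit_index == 1, ]
  X1 <- do.call(rbind, v1$acoustic)
  n1 <- sum(v1$label == 1); n0 <- sum(v1$label == 0)
  sep <- sqrt(sum((colMeans(X1[v1$label == 1, , drop = FALSE]) -
                     colMeans(X1[v1$label == 0, , drop = FALSE]))^2))
  null_scale <- 5 * sqrt(16 * (1 / n1 + 1 / n0))  # base_sd, dim from above
  expect_lt(sep, 2 * null_scale)
})

test_that("toy transcripts and audio honour their requested structure", {
  tr <- generate_toy_transcript(3, c(0.3, 2.5), c(3, 5, 4), seed = 2)
  expect_equal(pause_counts(tr), c(n_short = 1L, n_medium = 0L, n_long = 1L))
  expect_equal(mean_utterance_length(tr), 4)
  expect_identical(tr, generate_toy_transcript(3, c(0.3, 2.5), c(3, 5, 4), seed = 2))
  expect_error(generate_toy_transcript(3, c(0.3)), "2 gaps")

  w <- generate_toy_audio(35, "sine_mix", seed = 3)
  expect_equal(segment_clips(preprocess_audio(w))$seg_num, 3L)
  expect_identical(w$samples, generate_toy_audio(35, "sine_mix", seed = 3)$samples)
  expect_lt(abs(mean(w$samples)), 1e-3)
  expect_error(generate_toy_audio(0), "positive")
})

test_that("audio-bearing cohorts exercise the preprocessing stack end to end", {
  co <- simulate_cohort(n_subjects = 2, acoustic_dim = 8, text_dim = 8,
                        stories_range = c(1L, 1L), audio = TRUE, seed = 61)
  expect_true("audio" %in% names(co$stories))
  af <- extract_acoustic_features(co$stories,
                                  extractor = toy_frame_extractor(dim = 8),
                                  clip_len_s = 5, overlap_s = 1)
  expect_equal(nrow(af), nrow(co$stories))
  expect_true(all(vapply(af$acoustic, length, integer(1)) == 8L))

  # and the on-disk round trip preserves the audio
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ds <- read_story_manifest(file.path(dir, "manifest.csv"))
  w <- read_wav(ds$audio_path[1])
  expect_equal(length(w$samples), length(co$stories$audio[[1]]$samples))
})
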