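test_that("preprocessing yields zero-mean unit-variance 16 kHz mono", {
  w <- preprocess_audio(waveform(c(1, 3), 16000))
  expect_equal(w$samples, c(-1, 1))  # population sd, not sample sd

  x <- withr::with_seed(1, rnorm(32000))
  p <- preprocess_audio(waveform(x, 16000))
  expect_lt(abs(mean(p$samples)), 1e-9)
  expect_lt(abs(sqrt(mean(p$samples^2)) - 1), 1e-6)

  stereo <- waveform(cbind(c(0, 2, 4), c(2, 4, 6)), 16000)
  m <- preprocess_audio(stereo)
  expect_equal(length(m$samples), 3L)

  rs <- preprocess_audio(waveform(sin(seq(0, 20 * pi, length.out = 8000)), 8000))
  expect_equal(rs$rate_hz, 16000)
  expect_equal(length(rs$samples), 16000L)

  expect_error(preprocess_audio(waveform(rep(1, 100), 16000)), "constant")
})

test_that("clip segmentation follows the overlapping start grid", {
  mk <- function(dur) waveform(seq_len(round(dur * 16000)) / 16000, 16000)

  cs35 <- segment_clips(mk(35))
  expect_equal(cs35$seg_num, 3L)
  expect_equal(cs35$starts_s, c(0, 10, 20))

  expect_equal(segment_clips(mk(15))$seg_num, 1L)

  sole <- segment_clips(mk(12))
  expect_equal(sole$seg_num, 1L)
  expect_equal(length(sole$clips[[1]]$samples), 12 * 16000)

  cs18 <- segment_clips(mk(18))
  expect_equal(cs18$starts_s, c(0, 10))
  expect_equal(length(cs18$clips[[2]]$samples), 8 * 16000)

  expect_error(segment_clips(mk(20), clip_len_s = 5, overlap_s = 5),
               "clip_len_s > overlap_s")

  # coverage: every sample index appears in at least one clip
  for (dur in c(16, 22.5, 30, 41)) {
    cs <- segment_clips(mk(dur))
    covered <- unique(unlist(purrr::map2(
      cs$starts_s * 16000, cs$clips,
      function(s, cl) s + seq_along(cl$samples))))
    expect_equal(length(covered), round(dur * 16000))
  }
})

test_that("two-stage pooling averages frames then clips with equal clip weight", {
  clip1 <- rbind(c(1, 3), c(3, 5))
  clip2 <- rbind(c(0, 0))
  expect_equal(pool_clip_features(list(clip1, clip2)), c(1, 2))

  v <- c(4.2, -1, 7)
  expect_equal(pool_clip_features(list(matrix(v, 1))), v)

  # permutation invariance over clips
  clips <- withr::with_seed(9, lapply(1:4, function(i) matrix(rnorm(3 * 5), 3)))
  expect_equal(pool_clip_features(clips), pool_clip_features(rev(clips)))

  # unequal clip lengths: clip-weighted mean, not the global frame mean
  a <- matrix(0, nrow = 9, ncol = 1)
  b <- matrix(1, nrow = 1, ncol = 1)
  expect_equal(pool_clip_features(list(a, b)), 0.5)
  global_frame_mean <- mean(c(a, b))
  expect_false(isTRUE(all.equal(0.5, global_frame_mean)))

  expect_error(pool_clip_features(list()), "No clip")
  expect_error(pool_clip_features(list(matrix(0, 1, 2), matrix(0, 1, 3))),
               "differing dimensions")
})

test_that("the story acoustic pipeline is deterministic and respects the extractor", {
  w <- generate_toy_audio(35, "sine_mix", seed = 4)

  const <- story_acoustic_features(w, constant_frame_extractor(2.5, dim = 6))
  expect_equal(const, rep(2.5, 6))  # pooling fixed point

  fx <- toy_frame_extractor(dim = 12, seed = 2)
  v1 <- story_acoustic_features(w, fx)
  v2 <- story_acoustic_features(generate_toy_audio(35, "sine_mix", seed = 4), fx)
  expect_identical(v1, v2)
  expect_equal(length(v1), 12L)
  expect_true(all(is.finite(v1)))
})

test_that("WAV files round-trip through the PCM reader/writer", {
  dir <- withr::local_tempdir()
  w <- generate_toy_audio(0.25, "sine_mix", seed = 8)
  p <- file.path(dir, "t.wav")
  write_wav(w, p)
  r <- read_wav(p)
  expect_equal(r$rate_hz, 16000)
  expect_equal(length(r$samples), length(w$samples))
  # 16-bit PCM: scale mismatch |x|/32768 plus rounding 0.5/32768
  expect_lt(max(abs(r$samples - w$samples)), 5e-5)

  st <- waveform(cbind(sin(1:800 / 40), cos(1:800 / 40)) * 0.5, 8000)
  write_wav(st, p)
  r2 <- read_wav(p)
  expect_true(is.matrix(r2$samples))
  expect_equal(dim(r2$samples), c(800L, 2L))
  expect_lt(max(abs(r2$samples - st$samples)), 5e-5)
})
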