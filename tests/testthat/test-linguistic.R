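test_that("pause classification follows the clinical bands with medium boundaries", {
  expect_equal(as.character(classify_pause(0.3)), "short")
  expect_equal(as.character(classify_pause(2.5)), "long")
  # boundary values fall in the medium band (strict < 0.5 and > 2)
  expect_equal(as.character(classify_pause(c(0.5, 2.0, 1.0))),
               c("medium", "medium", "medium"))
  expect_error(classify_pause(-0.1), ">= 0")
  # partition: every non-negative gap maps to exactly one category
  gaps <- c(0, 0.49, 0.5, 1.99, 2, 2.01, 10)
  expect_false(anyNA(classify_pause(gaps)))
})

test_that("pause counts come from inter-segment gaps, clipped at zero", {
  tr <- toy_transcript(c(0, 1.3, 4.5), c(1, 2, 5), c("a b", "c", "d"))
  expect_equal(pause_counts(tr), c(n_short = 1L, n_medium = 0L, n_long = 1L))

  expect_equal(pause_counts(toy_transcript(0, 2, "solo words")),
               c(n_short = 0L, n_medium = 0L, n_long = 0L))

  # overlapping ASR segments: negative gap clipped to 0, counted short
  over <- toy_transcript(c(0, 0.8), c(1, 2), c("x", "y"))
  expect_equal(pause_counts(over)[["n_short"]], 1L)

  # counts always sum to n_segments - 1
  for (seed in 1:5) {
    gaps <- withr::with_seed(seed, runif(6, 0, 4))
    tr <- generate_toy_transcript(7, gaps, 4, seed = seed)
    expect_equal(sum(pause_counts(tr)), 6L)
  }
})

test_that("mean utterance length averages words per segment", {
  tr <- toy_transcript(c(0, 2, 4), c(1, 3, 5),
                       c("one two three", "a b c d e", "w x y z"))
  expect_equal(mean_utterance_length(tr), 4)
  expect_equal(mean_utterance_length(toy_transcript(0, 1, "a b c d e f g")), 7)
  expect_equal(mean_utterance_length(
    toy_transcript(0:3, 0:3 + 0.5, rep("word", 4))), 1)
})

test_that("POS counts conserve the tagger token total", {
  tagger <- toy_pos_tagger()
  tr <- toy_transcript(0, 1, "I visited my old school")
  pc <- pos_counts(tr, tagger)
  expect_equal(pc, c(n_noun = 1L, n_verb = 1L, n_adjective = 1L,
                     n_pronoun = 2L, n_other = 0L))

  expect_equal(sum(pos_counts(toy_transcript(0, 1, " "), tagger)), 0L)

  # conservation on arbitrary generated text
  for (seed in 1:5) {
    tr <- generate_toy_transcript(4, c(0.2, 1, 3), 6, seed = seed)
    n_tokens <- sum(vapply(tr$text, function(t) length(tokenize_words(t)),
                           integer(1)))
    expect_equal(sum(pos_counts(tr, tagger)), n_tokens)
  }
})

test_that("fine tags map onto the five coarse classes, pronouns first", {
  expect_equal(map_pos_tags(c("Na", "VC", "Nh", "A", "D", "Nb")),
               c("noun", "verb", "pronoun", "adjective", "other", "noun"))
})

test_that("enriched transcripts prefix the topic and mark context spans", {
  tr <- toy_transcript(0, 1, "it was hard")
  en <- enrich_transcript(tr, "college")
  expect_equal(en$text, "I'm going to share a story of college. it was hard")
  expect_equal(en$context_ids, c(rep(0L, 8), rep(1L, 3)))

  # a 2.5 s gap inserts the long-pause marker
  tr2 <- toy_transcript(c(0, 3.5), c(1, 4), c("first part", "second part"))
  en2 <- enrich_transcript(tr2, "trip")
  expect_match(en2$text, "first part \\[PAUSE_L\\] second part")

  # context ids are non-decreasing and one per token for any input
  for (seed in 1:4) {
    trn <- generate_toy_transcript(5, withr::with_seed(seed, runif(4, 0, 3)),
                                   5, seed = seed)
    enn <- enrich_transcript(trn, "wedding")
    expect_equal(length(enn$context_ids), length(enn$tokens))
    expect_true(all(diff(enn$context_ids) >= 0))
    expect_true(startsWith(enn$text, "I'm going to share a story of wedding."))
  }

  expect_error(enrich_transcript(tr, ""), "non-empty")
  # template wording is configurable (e.g. for Chinese interviews)
  zh <- enrich_transcript(tr, "училище", template = "разказ за {topic}:")
  expect_true(startsWith(zh$text, "разказ за училище:"))
})

test_that("the 9-vector composes its parts in fixed order", {
  tr <- toy_transcript(c(0, 1.3, 4.5), c(1, 2, 5),
                       c("I visited school", "happy old garden", "we walked"))
  lf <- linguistic_features(tr)
  expect_equal(names(lf),
               c("mlu", "n_short", "n_medium", "n_long",
                 "n_noun", "n_verb", "n_adjective", "n_pronoun", "n_other"))
  expect_equal(ncol(lf), 9L)
  expect_equal(lf$mlu, mean_utterance_length(tr))
  expect_equal(unlist(lf[2:4]), pause_counts(tr))
  expect_equal(unlist(lf[5:9]), pos_counts(tr))

  single <- toy_transcript(0, 1, "I visited school")
  lfs <- linguistic_features(single)
  expect_equal(lfs$mlu, 3)
  expect_equal(unlist(lfs[2:4]), c(n_short = 0L, n_medium = 0L, n_long = 0L))
  expect_equal(unlist(lfs[5:9]),
               c(n_noun = 1L, n_verb = 1L, n_adjective = 0L,
                 n_pronoun = 1L, n_other = 0L))
})

test_that("batch extraction yields one feature row per story", {
  co <- tiny_cohort(n_subjects = 3, seed = 5)
  lf <- extract_linguistic_features(co$stories)
  expect_equal(nrow(lf), nrow(co$stories))
  expect_true(all(c("mlu", "n_other") %in% names(lf)))
  # generator renders transcripts so the extractor reproduces stored counts
  expect_equal(lf$mlu, co$stories$mlu)
  expect_equal(lf$n_long, co$stories$n_long)
})
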