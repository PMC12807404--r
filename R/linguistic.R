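pause_levels <- c("short", "medium", "long")
pause_markers <- c(short = "[PAUSE_S]", medium = "[PAUSE_M]", long = "[PAUSE_L]")
linguistic_feature_names <- c("mlu", "n_short", "n_medium", "n_long",
                              "n_noun", "n_verb", "n_adjective", "n_pronoun", "n_other")

#' Classify an inter-utterance pause
#'
#' Pauses between utterances are grouped into three clinically motivated
#' bands: short (< 0.5 s), medium (0.5 s to 2 s inclusive) and long (> 2 s).
#' The boundary values 0.5 and 2.0 fall in the medium band (the short/long
#' bands are defined by strict inequalities).
#'
#' @param gap_s Numeric vector of gaps in seconds (must be >= 0).
#' @return Factor with levels `short`, `medium`, `long`.
#' @export
#' @examples
#' classify_pause(c(0.3, 0.5, 2, 2.5))
classify_pause <- function(gap_s) {
  if (any(!is.finite(gap_s)) || any(gap_s < 0)) abort("Pause gaps must be finite and >= 0")
  factor(ifelse(gap_s < 0.5, "short", ifelse(gap_s > 2, "long", "medium")),
         levels = pause_levels)
}

transcript_gaps <- function(tr) {
  n <- nrow(tr)
  if (n < 2L) return(numeric())
  # Overlapping ASR segments produce negative gaps; durations cannot be
  # negative, so gaps are clipped at zero (and then count as short).
  pmax(tr$start[-1] - tr$end[-n], 0)
}

#' Count pauses in a timed transcript
#'
#' Gaps are the intervals between consecutive utterances
#' (`start[i] - end[i-1]`, clipped at 0); each is classified with
#' [classify_pause()]. A transcript with n utterances yields n - 1 gaps.
#'
#' @param tr Timed transcript tibble (`start`, `end`, `text`).
#' @return Named integer vector `c(n_short, n_medium, n_long)`.
#' @export
pause_counts <- function(tr) {
  if (nrow(tr) < 1L) abort("Cannot count pauses in an empty transcript")
  gaps <- transcript_gaps(tr)
  tab <- table(classify_pause(gaps))
  c(n_short = as.integer(tab[["short"]]),
    n_medium = as.integer(tab[["medium"]]),
    n_long = as.integer(tab[["long"]]))
}

#' Mean length of utterance
#'
#' Average number of words per utterance, with each ASR segment treated as
#' one utterance.
#'
#' @param tr Timed transcript tibble.
#' @param tokenizer Word tokenizer (default [tokenize_words()]).
#' @return Mean words per utterance (scalar).
#' @export
mean_utterance_length <- function(tr, tokenizer = tokenize_words) {
  if (nrow(tr) < 1L) abort("Cannot compute utterance length of an empty transcript")
  mean(vapply(tr$text, function(t) length(tokenizer(t)), integer(1)))
}

#' Coarse part-of-speech counts
#'
#' Runs the tagger over the concatenated utterances and tabulates the five
#' coarse classes. The five counts always sum to the tagger's token total.
#'
#' @param tr Timed transcript tibble.
#' @param tagger Tagger function (see [toy_pos_tagger()]).
#' @return Named integer vector
#'   `c(n_noun, n_verb, n_adjective, n_pronoun, n_other)`.
#' @export
pos_counts <- function(tr, tagger = toy_pos_tagger()) {
  text <- paste(tr$text, collapse = " ")
  tagged <- tagger(text)
  if (nrow(tagged) > 0 && !all(tagged$pos %in% pos_classes)) {
    abort(paste0("Tagger produced classes outside {",
                 paste(pos_classes, collapse = ", "), "}"))
  }
  tab <- table(factor(tagged$pos, levels = pos_classes))
  stats::setNames(as.integer(tab), paste0("n_", pos_classes))
}

#' Build the enriched transcript for the text encoder
#'
#' Prepends a topic sentence (so the encoder can judge topic/content
#' coherence) and inserts a pause-marker token at every inter-utterance gap
#' (`[PAUSE_S]`, `[PAUSE_M]`, `[PAUSE_L]` by pause class). `context_ids`
#' label every token 0 over the topic sentence and 1 over the story content,
#' mirroring segment-embedding style context marking.
#'
#' @param tr Timed transcript tibble (>= 1 segment).
#' @param topic Non-empty topic string.
#' @param template Topic-sentence template containing `{topic}`; the default
#'   is English and the wording is configurable per language.
#' @param tokenizer Word tokenizer used to produce `tokens`/`context_ids`.
#' @return Object of class `enriched_transcript`: list with `text`,
#'   `tokens`, `context_ids` (0 = topic part, 1 = context part,
#'   non-decreasing).
#' @export
#' @examples
#' tr <- tibble::tibble(start = c(0, 4), end = c(1, 5), text = c("it was hard", "but fun"))
#' enrich_transcript(tr, "college")
enrich_transcript <- function(tr, topic,
                              template = "I'm going to share a story of {topic}.",
                              tokenizer = tokenize_words) {
  if (nrow(tr) < 1L) abort("Cannot enrich an empty transcript")
  if (!is.character(topic) || length(topic) != 1L || trimws(topic) == "") {
    abort("`topic` must be a non-empty string")
  }
  topic_sentence <- gsub("{topic}", topic, template, fixed = TRUE)
  gaps <- transcript_gaps(tr)
  markers <- if (length(gaps)) as.character(pause_markers[as.integer(classify_pause(gaps))]) else character()
  parts <- character(2L * nrow(tr) - 1L)
  parts[seq(1, length(parts), by = 2)] <- tr$text
  if (length(markers)) parts[seq(2, length(parts), by = 2)] <- markers
  body <- paste(parts, collapse = " ")
  text <- paste(topic_sentence, body)
  topic_tokens <- tokenizer(topic_sentence)
  body_tokens <- tokenizer(body)
  structure(
    list(
      text = text,
      tokens = c(topic_tokens, body_tokens),
      context_ids = c(rep(0L, length(topic_tokens)), rep(1L, length(body_tokens)))
    ),
    class = "enriched_transcript"
  )
}

#' @export
print.enriched_transcript <- function(x, ...) {
  cat(sprintf("<enriched_transcript: %d tokens (%d topic, %d context)>\n",
              length(x$tokens), sum(x$context_ids == 0L), sum(x$context_ids == 1L)))
  cat(substr(x$text, 1, 120), if (nchar(x$text) > 120) "..." else "", "\n")
  invisible(x)
}

#' The 9-dimensional linguistic feature vector of one story
#'
#' Composes [mean_utterance_length()], [pause_counts()] and [pos_counts()]
#' into the fixed-order 9-vector: mean length of utterance; short, medium
#' and long pause counts; noun, verb, adjective, pronoun and other counts.
#'
#' @param tr Timed transcript tibble (>= 1 segment).
#' @param tagger Tagger function.
#' @param tokenizer Word tokenizer.
#' @return One-row tibble with the 9 named feature columns.
#' @export
linguistic_features <- function(tr, tagger = toy_pos_tagger(),
                                tokenizer = tokenize_words) {
  if (nrow(tr) < 1L) abort("Cannot extract linguistic features from an empty transcript")
  out <- c(list(mlu = mean_utterance_length(tr, tokenizer)),
           as.list(pause_counts(tr)),
           as.list(pos_counts(tr, tagger)))
  tibble::as_tibble(out[linguistic_feature_names])
}

#' Extract linguistic features for every story in a table
#'
#' @param stories Story tibble with a `transcript` list-column (from
#'   [read_story_manifest()] or [simulate_cohort()]).
#' @param tagger,tokenizer Passed to [linguistic_features()].
#' @return `stories`' id columns joined with the 9 feature columns, one row
#'   per story.
#' @export
extract_linguistic_features <- function(stories, tagger = toy_pos_tagger(),
                                        tokenizer = tokenize_words) {
  assert_cols(stories, c("subject_id", "visit_index", "story_index", "transcript"),
              "Story table")
  feats <- purrr::map(stories$transcript, linguistic_features,
                      tagger = tagger, tokenizer = tokenizer)
  dplyr::bind_cols(
    stories[, intersect(c("subject_id", "visit_index", "story_index", "topic", "label"),
                        names(stories))],
    dplyr::bind_rows(feats)
  )
}
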