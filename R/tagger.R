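pos_classes <- c("noun", "verb", "adjective", "pronoun", "other")

# Small bilingual surface-form lexicon for the deterministic toy tagger.
# Coverage is intentionally tiny: it exists so the counting pipeline is
# testable without a trained part-of-speech model.
default_toy_lexicon <- function() {
  c(
    # pronouns
    "i" = "pronoun", "you" = "pronoun", "he" = "pronoun", "she" = "pronoun",
    "we" = "pronoun", "they" = "pronoun", "it" = "pronoun", "me" = "pronoun",
    "my" = "pronoun", "him" = "pronoun", "her" = "pronoun", "us" = "pronoun",
    # verbs
    "am" = "verb", "is" = "verb", "was" = "verb", "were" = "verb", "go" = "verb",
    "went" = "verb", "share" = "verb", "remember" = "verb", "walked" = "verb",
    "visited" = "verb", "told" = "verb", "lived" = "verb", "worked" = "verb",
    "studied" = "verb", "married" = "verb", "travelled" = "verb", "met" = "verb",
    # adjectives
    "happy" = "adjective", "old" = "adjective", "young" = "adjective",
    "beautiful" = "adjective", "hard" = "adjective", "long" = "adjective",
    "small" = "adjective", "warm" = "adjective", "quiet" = "adjective",
    # nouns
    "story" = "noun", "school" = "noun", "college" = "noun", "family" = "noun",
    "house" = "noun", "garden" = "noun", "wedding" = "noun", "trip" = "noun",
    "mother" = "noun", "father" = "noun", "friend" = "noun", "village" = "noun",
    "teacher" = "noun", "summer" = "noun", "sea" = "noun", "train" = "noun",
    "job" = "noun", "city" = "noun", "child" = "noun", "year" = "noun"
  )
}

#' Deterministic toy part-of-speech tagger
#'
#' Rule-table tagger for tests and synthetic cohorts: tokens are looked up in
#' a surface-form lexicon and mapped to the five coarse classes (noun, verb,
#' adjective, pronoun, other); unknown tokens get `default`. Real taggers
#' (e.g. a CKIP-style Chinese tagger) plug in behind the same interface: a
#' function `text -> tibble(token, pos)` whose `pos` values lie in the five
#' classes.
#'
#' @param lexicon Named character vector mapping lower-cased tokens to
#'   coarse classes.
#' @param default Class for out-of-lexicon tokens.
#' @param tokenizer Word tokenizer (default [tokenize_words()]).
#' @return A tagger function `function(text)` returning a tibble with
#'   columns `token` and `pos`.
#' @export
#' @examples
#' tagger <- toy_pos_tagger()
#' tagger("I visited my old school")
toy_pos_tagger <- function(lexicon = default_toy_lexicon(), default = "other",
                           tokenizer = tokenize_words) {
  stopifnot(default %in% pos_classes, all(lexicon %in% pos_classes))
  function(text) {
    tokens <- tokenizer(text)
    key <- tolower(gsub("[[:punct:]]+$", "", tokens))
    pos <- unname(lexicon[key])
    pos[is.na(pos)] <- default
    tibble::tibble(token = tokens, pos = pos)
  }
}

#' Map fine-grained tagger output to the five coarse classes
#'
#' Default mapping follows CKIP-style conventions: `Nh` (personal pronouns)
#' first, then prefixes `N*` to noun, `V*` to verb, `A*` to adjective,
#' everything else to other. The table is configurable because published
#' tagsets differ while the model consumes only the five coarse classes.
#'
#' @param tags Character vector of fine-grained tags.
#' @param rules Named character vector of regex -> coarse class, applied in
#'   order; first match wins.
#' @return Character vector over the five coarse classes.
#' @export
#' @examples
#' map_pos_tags(c("Na", "VC", "Nh", "A", "D"))
map_pos_tags <- function(tags,
                         rules = c("^Nh" = "pronoun", "^N" = "noun",
                                   "^V" = "verb", "^A" = "adjective")) {
  out <- rep("other", length(tags))
  done <- logical(length(tags))
  for (i in seq_along(rules)) {
    hit <- !done & grepl(names(rules)[i], tags)
    out[hit] <- rules[i]
    done <- done | hit
  }
  out
}

#' Whitespace word tokenizer
#'
#' Default tokenizer for utterance length and tagging: splits on runs of
#' whitespace. Languages without spaced orthography need a segmenting
#' tokenizer supplied by the caller.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (length 0 for blank input).
#' @export
tokenize_words <- function(text) {
  if (length(text) != 1L) abort("`text` must be a single string")
  t <- trimws(text)
  if (identical(t, "") || is.na(t)) return(character())
  strsplit(t, "\\s+")[[1]]
}
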