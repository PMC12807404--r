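# Tiny deterministic transformer text backbone.
#
# The linguistic branch consumes a pluggable bidirectional transformer
# encoder. Production deployments bind a pretrained checkpoint here; this
# bundled backbone has the same interface (tokens + context ids -> pooled
# first-token vector) at desk scale: hashed token embeddings, learned-style
# positional and 2-row context embeddings, and post-layernorm transformer
# blocks, all drawn once from a fixed seed. It is used frozen: the trainable
# linguistic parameters live in the numeric encoder and projector.

layernorm_rows <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  va <- rowMeans((X - mu)^2)
  sweep(sweep((X - mu) / sqrt(va + eps), 2, gamma, `*`), 2, beta, `+`)
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Tiny deterministic text backbone
#'
#' Builds a small randomly initialized transformer encoder with hashed token
#' embeddings, positional embeddings and a 2-row context-embedding table
#' (row 1: topic span, id 0; row 2: content span, id 1) that is element-wise
#' added to the token embeddings. All weights are fixed by `seed`, so
#' encoding is deterministic.
#'
#' @param dim Model width (pooled output dimension).
#' @param n_heads Attention heads (must divide `dim`).
#' @param n_layers Transformer blocks.
#' @param vocab_size Hash-bucket vocabulary size.
#' @param max_tokens Truncation length (default 512).
#' @param seed Seed fixing all weights.
#' @return Object of class `text_backbone`.
#' @export
tiny_text_backbone <- function(dim = 32, n_heads = 4, n_layers = 1,
                               vocab_size = 503, max_tokens = 512, seed = 42) {
  stopifnot(dim %% n_heads == 0)
  with_seed(derive_seed(seed, "text_backbone"), {
    layers <- lapply(seq_len(n_layers), function(i) {
      list(Wq = init_weight(dim, dim), Wk = init_weight(dim, dim),
           Wv = init_weight(dim, dim), Wo = init_weight(dim, dim),
           bo = numeric(dim),
           ln1 = list(gamma = rep(1, dim), beta = numeric(dim)),
           W1 = init_weight(4 * dim, dim), b1 = numeric(4 * dim),
           W2 = init_weight(dim, 4 * dim), b2 = numeric(dim),
           ln2 = list(gamma = rep(1, dim), beta = numeric(dim)))
    })
    structure(
      list(dim = dim, n_heads = n_heads, vocab_size = vocab_size,
           max_tokens = max_tokens,
           emb = init_weight(vocab_size, dim),
           cls = rnorm(dim, sd = 0.1),
           pos = init_weight(max_tokens, dim) * 0.1,
           ctx = init_weight(2, dim) * 0.1,
           layers = layers),
      class = "text_backbone"
    )
  })
}

token_ids <- function(backbone, tokens) {
  vapply(tokens, function(t) {
    as.integer(hash_string(tolower(t)) %% as.integer(backbone$vocab_size)) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

mha_forward <- function(lay, X, n_heads) {
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- X %*% t(lay$Wq); K <- X %*% t(lay$Wk); V <- X %*% t(lay$Wv)
  O <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    P <- softmax_rows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh))
    O[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  O %*% t(lay$Wo) + matrix(lay$bo, nrow(X), d, byrow = TRUE)
}

#' Encode tokens with a text backbone
#'
#' Prepends a classification pseudo-token (context id 0), adds positional
#' and context embeddings to the token embeddings, runs the transformer
#' blocks and returns the first-token pooled vector. Token/context sequences
#' longer than `max_tokens - 1` are truncated together.
#'
#' @param backbone A [tiny_text_backbone()] (or compatible object).
#' @param tokens Character vector of tokens.
#' @param context_ids Integer vector over \{0, 1\}, same length as `tokens`.
#' @param use_context Add the context-embedding rows (default `TRUE`).
#' @return Numeric vector of length `backbone$dim`.
#' @export
encode_text <- function(backbone, tokens, context_ids, use_context = TRUE) {
  stopifnot(inherits(backbone, "text_backbone"))
  if (length(tokens) != length(context_ids)) {
    abort("`context_ids` must have one id per token")
  }
  if (length(context_ids) && !all(context_ids %in% c(0L, 1L))) {
    abort("`context_ids` must be 0 (topic) or 1 (context)")
  }
  keep <- min(length(tokens), backbone$max_tokens - 1L)
  tokens <- tokens[seq_len(keep)]
  context_ids <- context_ids[seq_len(keep)]

  X <- rbind(backbone$cls,
             backbone$emb[token_ids(backbone, tokens), , drop = FALSE])
  Tn <- nrow(X)
  X <- X + backbone$pos[seq_len(Tn), , drop = FALSE]
  if (use_context) {
    X <- X + backbone$ctx[c(1L, context_ids + 1L), , drop = FALSE]
  }
  for (lay in backbone$layers) {
    X <- layernorm_rows(X + mha_forward(lay, X, backbone$n_heads),
                        lay$ln1$gamma, lay$ln1$beta)
    FF <- pmax(X %*% t(lay$W1) + matrix(lay$b1, Tn, length(lay$b1), byrow = TRUE), 0) %*%
      t(lay$W2) + matrix(lay$b2, Tn, length(lay$b2), byrow = TRUE)
    X <- layernorm_rows(X + FF, lay$ln2$gamma, lay$ln2$beta)
  }
  X[1, ]
}

#' Pooled text vectors for every story
#'
#' Builds the enriched transcript (topic sentence + pause markers + context
#' ids) for each story and encodes it with the backbone, returning the
#' frozen pooled text feature consumed by the linguistic encoder.
#'
#' @param stories Story tibble with `transcript` list-column and `topic`.
#' @param backbone A text backbone.
#' @param template,tokenizer Passed to [enrich_transcript()].
#' @return `stories`' id columns plus a `text_vec` list-column.
#' @export
extract_text_features <- function(stories, backbone = tiny_text_backbone(),
                                  template = "I'm going to share a story of {topic}.",
                                  tokenizer = tokenize_words) {
  assert_cols(stories, c("subject_id", "visit_index", "story_index",
                         "topic", "transcript"), "Story table")
  text_vec <- purrr::map(seq_len(nrow(stories)), function(i) {
    en <- enrich_transcript(stories$transcript[[i]], stories$topic[i],
                            template = template, tokenizer = tokenizer)
    encode_text(backbone, en$tokens, en$context_ids)
  })
  out <- stories[, intersect(c("subject_id", "visit_index", "story_index", "label"),
                             names(stories))]
  out$text_vec <- text_vec
  tibble::as_tibble(out)
}
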