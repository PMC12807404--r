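# Encoder stage: CNN acoustic encoder, linguistic encoder (frozen pooled
# text vector + standardized numeric branch + projector), attention fusion.

#' Initialize the CNN acoustic encoder
#'
#' Three 1-D convolution blocks (kernel 3, stride 1; 16, 32 and 64 filters),
#' each followed by batch normalization, ReLU and max-pooling with kernel
#' and stride 2 — reducing the temporal resolution by a factor of 8 — then a
#' flatten and a fully connected projection to the latent width.
#'
#' @param input_dim Length F of the story-level acoustic feature vector
#'   (1024 for the production frame extractor).
#' @param latent_dim Output embedding width (default 128).
#' @param filters Filter counts of the three convolution layers.
#' @return Parameter list of class `acoustic_encoder` with attribute
#'   metadata (`input_dim`, `flat_len`, `latent_dim`).
#' @export
acoustic_encoder_init <- function(input_dim, latent_dim = 128,
                                  filters = c(16, 32, 64)) {
  if (input_dim < 8) abort("Acoustic input dimension must be at least 8")
  l_out <- input_dim %/% 2L %/% 2L %/% 2L
  flat_len <- filters[3] * l_out
  structure(
    list(conv1 = conv1d_init(1L, filters[1]), bn1 = bn_init(filters[1]),
         conv2 = conv1d_init(filters[1], filters[2]), bn2 = bn_init(filters[2]),
         conv3 = conv1d_init(filters[2], filters[3]), bn3 = bn_init(filters[3]),
         proj = affine_init(flat_len, latent_dim)),
    class = "acoustic_encoder",
    input_dim = input_dim, flat_len = flat_len, latent_dim = latent_dim,
    filters = filters
  )
}

acoustic_forward <- function(enc, X, training = FALSE) {
  n <- nrow(X)
  A <- array(X, c(n, 1L, ncol(X)))
  caches <- list()
  for (i in 1:3) {
    cv <- enc[[paste0("conv", i)]]
    f1 <- conv1d_forward(cv, A)
    b1 <- bn_conv_forward(enc[[paste0("bn", i)]], f1$out, training)
    enc[[paste0("bn", i)]] <- b1$params
    r1 <- relu_forward(b1$out)
    p1 <- maxpool2_forward(r1$out)
    caches[[i]] <- list(conv = f1, bn = b1$cache, relu = r1, pool = p1)
    A <- p1$out
  }
  dm <- dim(A)
  flat <- matrix(aperm(A, c(1, 3, 2)), nrow = n)   # n x (L_out * C) column-major
  pf <- affine_forward(enc$proj, flat)
  list(out = pf$out, enc = enc,
       cache = list(blocks = caches, proj = pf, flat_dim = dm))
}

acoustic_backward <- function(enc, cache, dOut) {
  pb <- affine_backward(enc$proj, cache$proj, dOut)
  grads <- list(proj = pb$grads)
  dm <- cache$flat_dim
  dA <- aperm(array(pb$dX, c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  for (i in 3:1) {
    cc <- cache$blocks[[i]]
    dA <- maxpool2_backward(cc$pool, dA)
    dA <- relu_backward(cc$relu, dA)
    bb <- bn_conv_backward(enc[[paste0("bn", i)]], cc$bn, dA)
    grads[[paste0("bn", i)]] <- bb$grads
    cb <- conv1d_backward(enc[[paste0("conv", i)]], cc$conv, bb$dX)
    grads[[paste0("conv", i)]] <- cb$grads
    dA <- cb$dX
  }
  list(grads = grads[c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3", "proj")],
       dX = matrix(dA, nrow = dm[1]))
}

#' Encode acoustic feature vectors
#'
#' Runs the CNN acoustic encoder in evaluation mode (batch-normalization
#' running statistics, deterministic).
#'
#' @param x Length-F numeric vector or n-by-F matrix of story acoustic
#'   features.
#' @param encoder An [acoustic_encoder_init()] parameter list.
#' @return Length-`latent_dim` vector (or n-by-`latent_dim` matrix).
#' @export
acoustic_encode <- function(x, encoder) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != attr(encoder, "input_dim")) {
    abort(sprintf("Acoustic input has %d dims; encoder expects %d",
                  ncol(X), attr(encoder, "input_dim")))
  }
  out <- acoustic_forward(encoder, X, training = FALSE)$out
  if (single) drop(out) else out
}

#' Initialize the linguistic encoder head
#'
#' The trainable linguistic parameters: a single affine numeric encoder for
#' the standardized 9-vector and an affine projector from the concatenated
#' (pooled text vector, numeric embedding) — in that order — to the latent
#' width. Standardization statistics are fit on training data only via
#' [set_numeric_stats()].
#'
#' @param text_dim Width of the pooled text vector from the backbone.
#' @param numeric_dim Width of the numeric embedding (default 32).
#' @param latent_dim Output width (default 128).
#' @return Parameter list of class `linguistic_encoder`.
#' @export
linguistic_encoder_init <- function(text_dim, numeric_dim = 32, latent_dim = 128) {
  structure(
    list(num = affine_init(9L, numeric_dim),
         proj = affine_init(text_dim + numeric_dim, latent_dim),
         center = numeric(9L), scale = rep(1, 9L)),
    class = "linguistic_encoder",
    text_dim = text_dim, numeric_dim = numeric_dim, latent_dim = latent_dim
  )
}

#' Fit standardization statistics for the 9 numeric linguistic features
#'
#' Mixing raw count scales (utterance length vs part-of-speech counts) into
#' one affine layer lets large counts dominate, so the 9-vector is z-scored
#' with statistics computed on the training fold only.
#'
#' @param encoder A [linguistic_encoder_init()] list.
#' @param X9 Training matrix (n x 9) of linguistic features.
#' @return The encoder with `center`/`scale` set.
#' @export
set_numeric_stats <- function(encoder, X9) {
  stopifnot(ncol(X9) == 9L)
  encoder$center <- colMeans(X9)
  s <- apply(X9, 2, stats::sd)
  encoder$scale <- ifelse(s > 0, s, 1)
  encoder
}

standardize9 <- function(encoder, X9) {
  sweep(sweep(as.matrix(X9), 2, encoder$center), 2, encoder$scale, `/`)
}

linguistic_forward <- function(enc, Xt, X9) {
  Z <- standardize9(enc, X9)
  nf <- affine_forward(enc$num, Z)
  inp <- cbind(as.matrix(Xt), nf$out)
  pf <- affine_forward(enc$proj, inp)
  list(out = pf$out, cache = list(num = nf, proj = pf, text_dim = ncol(Xt)))
}

linguistic_backward <- function(enc, cache, dOut) {
  pb <- affine_backward(enc$proj, cache$proj, dOut)
  d_num <- pb$dX[, (cache$text_dim + 1L):ncol(pb$dX), drop = FALSE]
  nb <- affine_backward(enc$num, cache$num, d_num)
  list(grads = list(num = nb$grads, proj = pb$grads,
                    center = 0 * enc$center, scale = 0 * enc$scale))
}

#' Encode one story's linguistic input
#'
#' Pools the enriched transcript with the (frozen) text backbone, embeds the
#' standardized 9-vector through the numeric encoder, concatenates and
#' projects to the latent width.
#'
#' @param enriched An [enrich_transcript()] object (or a precomputed pooled
#'   text vector of length `text_dim`).
#' @param features9 The story's 9 linguistic features (numeric vector or
#'   1-row tibble in [linguistic_features()] order).
#' @param encoder A [linguistic_encoder_init()] list.
#' @param backbone Text backbone used when `enriched` is a transcript.
#' @return Numeric vector of length `latent_dim`.
#' @export
linguistic_encode <- function(enriched, features9, encoder,
                              backbone = tiny_text_backbone(dim = attr(encoder, "text_dim"))) {
  pooled <- if (inherits(enriched, "enriched_transcript")) {
    encode_text(backbone, enriched$tokens, enriched$context_ids)
  } else {
    as.numeric(enriched)
  }
  if (length(pooled) != attr(encoder, "text_dim")) {
    abort(sprintf("Pooled text vector has %d dims; encoder expects %d",
                  length(pooled), attr(encoder, "text_dim")))
  }
  x9 <- as.numeric(unlist(features9))
  if (length(x9) != 9L) abort("`features9` must contain exactly 9 values")
  drop(linguistic_forward(encoder, matrix(pooled, 1), matrix(x9, 1))$out)
}

#' Fuse acoustic and linguistic embeddings
#'
#' The two modality embeddings are summed element-wise (they share the
#' latent width) and passed through one multi-head self-attention layer. On
#' the one-token fused sequence the attention weight is identically 1, so
#' the layer applies its value and output projections; fusion is symmetric
#' in its two arguments.
#'
#' @param a,t Acoustic and linguistic embeddings (equal-length vectors or
#'   n-by-d matrices).
#' @param fusion Parameter list from [fusion_init()].
#' @return Fused story embedding, same shape as the inputs.
#' @export
fuse_embeddings <- function(a, t, fusion) {
  single <- is.null(dim(a))
  A <- if (single) matrix(a, nrow = 1) else as.matrix(a)
  Tt <- if (single) matrix(t, nrow = 1) else as.matrix(t)
  if (!all(dim(A) == dim(Tt))) abort("Acoustic and linguistic embeddings must have equal dimensions")
  out <- attn1_forward(fusion, A + Tt)$out
  if (single) drop(out) else out
}

#' @rdname fuse_embeddings
#' @param dim Embedding width.
#' @export
fusion_init <- function(dim = 128) {
  structure(attn1_init(dim), class = "fusion_layer", embed_dim = dim)
}
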