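# Aging trajectory module: cross-attention contrast of consecutive-visit
# embeddings, the direction encoder, and the triplet classifier head.

#' Initialize the aging trajectory module
#'
#' Holds one shared cross-attention layer (the current visit queries the
#' previous visit, which supplies key and value), the direction encoder
#' (two affine layers with a ReLU between, `embed_dim -> fd_hidden ->
#' direction_dim`), and the classifier head (batch normalization + fully
#' connected layer) over the concatenated enhanced embeddings and
#' directions.
#'
#' @param embed_dim Story-embedding width (default 128).
#' @param direction_dim Direction-embedding width (default 32).
#' @param fd_hidden Hidden width of the direction encoder (default 64).
#' @param visits Number of visits per triplet (default 3).
#' @param ablate_direction If `TRUE`, the classifier sees only the raw
#'   concatenated visit embeddings — no cross-attention enhancement and no
#'   directions — reproducing the "without direction" ablation.
#' @return Parameter list of class `trajectory_module`.
#' @export
trajectory_module_init <- function(embed_dim = 128, direction_dim = 32,
                                   fd_hidden = 64, visits = 3L,
                                   ablate_direction = FALSE) {
  clf_dim <- if (ablate_direction) visits * embed_dim else
    visits * embed_dim + (visits - 1L) * direction_dim
  structure(
    list(cross = attn1_init(embed_dim),
         fd1 = affine_init(embed_dim, fd_hidden),
         fd2 = affine_init(fd_hidden, direction_dim),
         clf_bn = bn_init(clf_dim),
         clf = affine_init(clf_dim, 1L)),
    class = "trajectory_module",
    embed_dim = embed_dim, direction_dim = direction_dim,
    visits = visits, clf_dim = clf_dim, ablate_direction = ablate_direction
  )
}

#' Contrast consecutive visit embeddings by cross-attention
#'
#' The current visit's embedding is the query; the previous visit's is key
#' and value (each a one-token sequence, so the attention weight is 1). A
#' residual connection keeps the enhanced embedding anchored to the current
#' visit: `e_curr + Wo (Wv e_prev) + bo`. Later visits never enter, so the
#' operation is causal by construction.
#'
#' @param e_curr,e_prev Embeddings of visit k and k-1 (vectors or n-by-d
#'   matrices).
#' @param tm A [trajectory_module_init()] list.
#' @return Enhanced embedding, same shape as `e_curr`.
#' @export
contrast_visits <- function(e_curr, e_prev, tm) {
  single <- is.null(dim(e_curr))
  Ec <- if (single) matrix(e_curr, nrow = 1) else as.matrix(e_curr)
  Ep <- if (single) matrix(e_prev, nrow = 1) else as.matrix(e_prev)
  if (!all(dim(Ec) == dim(Ep))) abort("Visit embeddings must have equal dimensions")
  out <- Ec + attn1_forward(tm$cross, Ep)$out
  if (single) drop(out) else out
}

fd_forward <- function(tm, Delta) {
  f1 <- affine_forward(tm$fd1, Delta)
  r1 <- relu_forward(f1$out)
  f2 <- affine_forward(tm$fd2, r1$out)
  list(out = f2$out, cache = list(f1 = f1, r1 = r1, f2 = f2))
}

fd_backward <- function(tm, cache, dOut) {
  b2 <- affine_backward(tm$fd2, cache$f2, dOut)
  dr <- relu_backward(cache$r1, b2$dX)
  b1 <- affine_backward(tm$fd1, cache$f1, dr)
  list(grads = list(fd1 = b1$grads, fd2 = b2$grads), dX = b1$dX)
}

#' Encode the aging direction between two visits
#'
#' `d = f_D(e_curr - e_prev)`: the embedding difference passed through the
#' two-layer direction encoder. The pre-encoder difference flips sign when
#' the arguments are swapped.
#'
#' @inheritParams contrast_visits
#' @return Direction embedding of width `direction_dim`.
#' @export
encode_direction <- function(e_curr, e_prev, tm) {
  single <- is.null(dim(e_curr))
  Ec <- if (single) matrix(e_curr, nrow = 1) else as.matrix(e_curr)
  Ep <- if (single) matrix(e_prev, nrow = 1) else as.matrix(e_prev)
  if (!all(dim(Ec) == dim(Ep))) abort("Visit embeddings must have equal dimensions")
  out <- fd_forward(tm, Ec - Ep)$out
  if (single) drop(out) else out
}

# Batch forward through the trajectory module. E_list: list of V matrices
# (n x embed_dim) in visit order. Returns logits, enhanced embeddings,
# directions and caches; updates BN running stats in training mode.
triplet_forward <- function(tm, E_list, training = FALSE) {
  V <- length(E_list)
  n <- nrow(E_list[[1]])
  ablate <- attr(tm, "ablate_direction")
  caches <- list(cross = vector("list", V), fd = vector("list", V - 1L))
  Ebar <- vector("list", V)
  D <- vector("list", V - 1L)
  Ebar[[1]] <- E_list[[1]]
  if (!ablate) {
    for (k in 2:V) {
      at <- attn1_forward(tm$cross, E_list[[k - 1]])
      Ebar[[k]] <- E_list[[k]] + at$out
      caches$cross[[k]] <- at
      fdv <- fd_forward(tm, E_list[[k]] - E_list[[k - 1]])
      D[[k - 1L]] <- fdv$out
      caches$fd[[k - 1L]] <- fdv$cache
    }
    Z <- do.call(cbind, c(Ebar, D))
  } else {
    for (k in 2:V) Ebar[[k]] <- E_list[[k]]
    D <- list()
    Z <- do.call(cbind, Ebar)
  }
  bnf <- bn_flat_forward(tm$clf_bn, Z, training)
  tm$clf_bn <- bnf$params
  cf <- affine_forward(tm$clf, bnf$out)
  logits <- drop(cf$out)
  list(logits = logits, prob = stats::plogis(logits),
       Ebar = Ebar, D = D, tm = tm,
       cache = list(cross = caches$cross, fd = caches$fd,
                    bn = bnf$cache, clf = cf, V = V, n = n))
}

# Backward: dlogits (length n), dD_extra list of (n x dir) matrices from the
# alignment losses (or NULL). Returns grads for tm and dE list.
triplet_backward <- function(tm, cache, dlogits, dD_extra = NULL) {
  V <- cache$V
  n <- cache$n
  ablate <- attr(tm, "ablate_direction")
  ed <- attr(tm, "embed_dim")
  dd <- attr(tm, "direction_dim")

  cb <- affine_backward(tm$clf, cache$clf, matrix(dlogits, ncol = 1))
  bb <- bn_flat_backward(tm$clf_bn, cache$bn, cb$dX)
  dZ <- bb$dX
  grads <- list(cross = tree_zeros(tm$cross),
                fd1 = tree_zeros(tm$fd1), fd2 = tree_zeros(tm$fd2),
                clf_bn = bb$grads, clf = cb$grads)

  dEbar <- lapply(seq_len(V), function(k) dZ[, ((k - 1L) * ed + 1L):(k * ed), drop = FALSE])
  dE <- lapply(seq_len(V), function(k) matrix(0, n, ed))
  if (!ablate) {
    dD <- lapply(seq_len(V - 1L), function(j) {
      g <- dZ[, (V * ed + (j - 1L) * dd + 1L):(V * ed + j * dd), drop = FALSE]
      if (!is.null(dD_extra) && !is.null(dD_extra[[j]])) g <- g + dD_extra[[j]]
      g
    })
    for (k in V:2) {
      # classifier path into ebar_k = e_k + attn(e_{k-1})
      ab <- attn1_backward(tm$cross, cache$cross[[k]], dEbar[[k]])
      grads$cross <- tree_add(grads$cross, ab$grads)
      dE[[k]] <- dE[[k]] + dEbar[[k]]
      dE[[k - 1L]] <- dE[[k - 1L]] + ab$dX
      # direction path d_{k-1} = f_D(e_k - e_{k-1})
      fb <- fd_backward(tm, cache$fd[[k - 1L]], dD[[k - 1L]])
      grads$fd1 <- tree_add(grads$fd1, fb$grads$fd1)
      grads$fd2 <- tree_add(grads$fd2, fb$grads$fd2)
      dE[[k]] <- dE[[k]] + fb$dX
      dE[[k - 1L]] <- dE[[k - 1L]] - fb$dX
    }
    dE[[1L]] <- dE[[1L]] + dEbar[[1L]]
  } else {
    for (k in seq_len(V)) dE[[k]] <- dEbar[[k]]
  }
  list(grads = grads, dE = dE)
}

#' Run a visit triplet through the trajectory module
#'
#' Computes the enhanced embeddings (visit 1 passes through unchanged; later
#' visits are contrasted against their predecessor), the two direction
#' embeddings, and the classifier logit/probability for the last visit's
#' label.
#'
#' @param e1,e2,e3 Story embeddings of visits 1..3 (vectors or n-by-d
#'   matrices).
#' @param tm A [trajectory_module_init()] list.
#' @return List with `enhanced` (list of 3), `directions` (list of 2, or
#'   empty under ablation), `logit`, `probability`.
#' @export
forward_triplet <- function(e1, e2, e3, tm) {
  single <- is.null(dim(e1))
  as_m <- function(e) if (is.null(dim(e))) matrix(e, nrow = 1) else as.matrix(e)
  fw <- triplet_forward(tm, list(as_m(e1), as_m(e2), as_m(e3)), training = FALSE)
  shape <- function(x) if (single) drop(x) else x
  list(enhanced = lapply(fw$Ebar, shape),
       directions = lapply(fw$D, shape),
       logit = fw$logits, probability = fw$prob)
}

#' Cross-sectional classifier head
#'
#' Single-visit mode: batch normalization + fully connected layer on one
#' story embedding, with no trajectory module. A separate head from the
#' triplet classifier (the two are not interchangeable).
#'
#' @param embed_dim Embedding width.
#' @return Parameter list of class `cs_head`.
#' @export
cs_head_init <- function(embed_dim = 128) {
  structure(list(bn = bn_init(embed_dim), clf = affine_init(embed_dim, 1L)),
            class = "cs_head", embed_dim = embed_dim)
}

cs_forward <- function(head, E, training = FALSE) {
  bnf <- bn_flat_forward(head$bn, E, training)
  head$bn <- bnf$params
  cf <- affine_forward(head$clf, bnf$out)
  logits <- drop(cf$out)
  list(logits = logits, prob = stats::plogis(logits), head = head,
       cache = list(bn = bnf$cache, clf = cf))
}

cs_backward <- function(head, cache, dlogits) {
  cb <- affine_backward(head$clf, cache$clf, matrix(dlogits, ncol = 1))
  bb <- bn_flat_backward(head$bn, cache$bn, cb$dX)
  list(grads = list(bn = bb$grads, clf = cb$grads), dE = bb$dX)
}

#' @rdname cs_head_init
#' @param e Story embedding (vector or matrix).
#' @param head A `cs_head`.
#' @return For `forward_cross_sectional`: list with `logit` and
#'   `probability`.
#' @export
forward_cross_sectional <- function(e, head) {
  E <- if (is.null(dim(e))) matrix(e, nrow = 1) else as.matrix(e)
  fw <- cs_forward(head, E, training = FALSE)
  list(logit = fw$logits, probability = fw$prob)
}
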