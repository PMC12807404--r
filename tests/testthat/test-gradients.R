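# End-to-end gradient verification: the hand-derived backward pass of the
# complete model (CNN encoder, linguistic head, fusion, cross-attention,
# direction encoder, batch-norm classifier) under the combined loss is
# compared against central finite differences at a tiny width.

test_that("full-model analytic gradients match finite differences", {
  co <- simulate_cohort(n_subjects = 5, acoustic_dim = 16, text_dim = 5, seed = 11)
  feats <- story_features(co)
  cfg <- trajectory_config(
    acoustic_dim = 16, text_dim = 5, numeric_dim = 3, embed_dim = 8,
    direction_dim = 4, fd_hidden = 5, filters = c(2, 3, 4), dropout = 0,
    weights = loss_weights(alpha = 0.1, delta = 0.2, gamma = 0.3, tau = 0.5)
  )
  mats <- cogtraj:::story_feature_matrices(feats)
  model <- cogtraj:::trajectory_model_init(cfg, seed = 2)
  model$params$ling <- set_numeric_stats(model$params$ling, mats$X9)
  trip <- make_triplets(feats, seed = 5, epoch = 1)
  rows <- seq_len(nrow(trip))

  bp <- cogtraj:::lg_batch_pass(model, mats, trip, rows, training = TRUE)
  expect_true(is.finite(bp$total))

  total_at <- function(m) {
    cogtraj:::lg_batch_pass(m, mats, trip, rows, training = TRUE,
                            want_grads = FALSE)$total
  }
  check_leaf <- function(get, set, analytic, n_probe = 4, h = 1e-5) {
    leaf <- get(model$params)
    for (j in withr::with_seed(j_seed <<- j_seed + 1,
                               sample(length(leaf), min(n_probe, length(leaf))))) {
      m2 <- model
      l <- leaf; l[j] <- l[j] + h
      m2$params <- set(m2$params, l)
      f1 <- total_at(m2)
      l[j] <- leaf[j] - h
      m2$params <- set(m2$params, l)
      f0 <- total_at(m2)
      expect_equal(analytic[j], (f1 - f0) / (2 * h), tolerance = 1e-4)
    }
  }
  j_seed <- 1000

  check_leaf(function(p) p$ac$conv1$W,
             function(p, v) { p$ac$conv1$W[] <- v; p }, bp$grads$ac$conv1$W)
  check_leaf(function(p) p$ac$bn2$gamma,
             function(p, v) { p$ac$bn2$gamma[] <- v; p }, bp$grads$ac$bn2$gamma)
  check_leaf(function(p) p$ac$proj$W,
             function(p, v) { p$ac$proj$W[] <- v; p }, bp$grads$ac$proj$W)
  check_leaf(function(p) p$ling$num$W,
             function(p, v) { p$ling$num$W[] <- v; p }, bp$grads$ling$num$W)
  check_leaf(function(p) p$ling$proj$W,
             function(p, v) { p$ling$proj$W[] <- v; p }, bp$grads$ling$proj$W)
  check_leaf(function(p) p$fus$Wv,
             function(p, v) { p$fus$Wv[] <- v; p }, bp$grads$fus$Wv)
  check_leaf(function(p) p$tm$cross$Wo,
             function(p, v) { p$tm$cross$Wo[] <- v; p }, bp$grads$tm$cross$Wo)
  check_leaf(function(p) p$tm$fd1$W,
             function(p, v) { p$tm$fd1$W[] <- v; p }, bp$grads$tm$fd1$W)
  check_leaf(function(p) p$tm$fd2$W,
             function(p, v) { p$tm$fd2$W[] <- v; p }, bp$grads$tm$fd2$W)
  check_leaf(function(p) p$tm$clf$W,
             function(p, v) { p$tm$clf$W[] <- v; p }, bp$grads$tm$clf$W)
  check_leaf(function(p) p$tm$clf_bn$gamma,
             function(p, v) { p$tm$clf_bn$gamma[] <- v; p }, bp$grads$tm$clf_bn$gamma)
})

test_that("cross-sectional head gradients match finite differences", {
  co <- simulate_cohort(n_subjects = 4, acoustic_dim = 16, text_dim = 5, seed = 13)
  feats <- story_features(co)
  cfg <- trajectory_config(
    acoustic_dim = 16, text_dim = 5, numeric_dim = 3, embed_dim = 8,
    filters = c(2, 3, 4), mode = "cs", dropout = 0,
    weights = loss_weights(alpha = 0.1)
  )
  mats <- cogtraj:::story_feature_matrices(feats)
  model <- cogtraj:::trajectory_model_init(cfg, seed = 3)
  model$params$ling <- set_numeric_stats(model$params$ling, mats$X9)
  rows <- seq_len(min(8L, nrow(feats)))
  bp <- cogtraj:::cs_batch_pass(model, mats, feats, rows, training = TRUE)
  h <- 1e-5
  leaf <- model$params$cs$clf$W
  for (j in seq_len(min(4, length(leaf)))) {
    m2 <- model
    m2$params$cs$clf$W[j] <- leaf[j] + h
    f1 <- cogtraj:::cs_batch_pass(m2, mats, feats, rows, training = TRUE,
                                  want_grads = FALSE)$total
    m2$params$cs$clf$W[j] <- leaf[j] - h
    f0 <- cogtraj:::cs_batch_pass(m2, mats, feats, rows, training = TRUE,
                                  want_grads = FALSE)$total
    expect_equal(bp$grads$cs$clf$W[j], (f1 - f0) / (2 * h), tolerance = 1e-4)
  }
})
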