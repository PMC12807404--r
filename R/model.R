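# Full trainable model: CNN acoustic encoder + linguistic head + attention
# fusion feeding the trajectory module (longitudinal mode) or the
# cross-sectional head. Hand-written analytic backpropagation throughout;
# optimized with Adam.

#' Model and training configuration
#'
#' Collects the architecture and optimization knobs. Embedding widths and
#' loss weights default to the published operating point (128-dim audio and
#' text embeddings, 32-dim directions, batch size 8, at most 150 epochs with
#' early-stopping patience 10, alpha/delta/gamma = 0.01/0.001/0.001). The
#' learning rate defaults to 1e-3, appropriate for training the compact
#' encoders from scratch; fine-tuning large pretrained backbones calls for
#' the much smaller published rate (1e-5), available through this knob.
#'
#' @param acoustic_dim Length F of story acoustic features.
#' @param text_dim Width of the pooled text vector.
#' @param numeric_dim Width of the numeric linguistic embedding.
#' @param embed_dim Story-embedding width.
#' @param direction_dim Direction-embedding width.
#' @param fd_hidden Hidden width of the direction encoder.
#' @param filters CNN filter counts.
#' @param visits Visits per subject (longitudinal mode).
#' @param mode `"lg"` (triplet, longitudinal) or `"cs"` (single story).
#' @param ablate_direction Drop the trajectory module from the classifier
#'   input (the "without direction" ablation).
#' @param include_visit1 Include visit-1 embeddings in the encoder loss.
#' @param weights [loss_weights()].
#' @param dropout Dropout rate applied to story embeddings during training
#'   (default 0.3, the published rate; 0 disables).
#' @param lr,batch_size,max_epochs,patience Optimization parameters.
#' @return A config list.
#' @export
trajectory_config <- function(acoustic_dim = 1024, text_dim = 32,
                              numeric_dim = 32, embed_dim = 128,
                              direction_dim = 32, fd_hidden = 64,
                              filters = c(16, 32, 64), visits = 3L,
                              mode = c("lg", "cs"),
                              ablate_direction = FALSE,
                              include_visit1 = FALSE,
                              weights = loss_weights(),
                              dropout = 0.3,
                              lr = 1e-3, batch_size = 8L,
                              max_epochs = 150L, patience = 10L) {
  list(acoustic_dim = acoustic_dim, text_dim = text_dim,
       numeric_dim = numeric_dim, embed_dim = embed_dim,
       direction_dim = direction_dim, fd_hidden = fd_hidden,
       filters = filters, visits = as.integer(visits),
       mode = match.arg(mode),
       ablate_direction = isTRUE(ablate_direction),
       include_visit1 = isTRUE(include_visit1),
       weights = weights, dropout = dropout,
       lr = lr, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience))
}

trajectory_model_init <- function(config, seed = 1) {
  with_seed(derive_seed(seed, "model_init"), {
    params <- list(
      ac = acoustic_encoder_init(config$acoustic_dim, config$embed_dim,
                                 config$filters),
      ling = linguistic_encoder_init(config$text_dim, config$numeric_dim,
                                     config$embed_dim),
      fus = fusion_init(config$embed_dim)
    )
    if (config$mode == "lg") {
      params$tm <- trajectory_module_init(config$embed_dim, config$direction_dim,
                                          config$fd_hidden, config$visits,
                                          config$ablate_direction)
    } else {
      params$cs <- cs_head_init(config$embed_dim)
    }
    structure(list(params = params, config = config), class = "cogtraj_model")
  })
}

# Forward all story instances: Xa (n x F), Xt (n x text_dim), X9 (n x 9).
model_stories_forward <- function(model, Xa, Xt, X9, training = FALSE) {
  p <- model$params
  af <- acoustic_forward(p$ac, Xa, training)
  model$params$ac <- af$enc
  lf <- linguistic_forward(p$ling, Xt, X9)
  S <- af$out + lf$out
  ff <- attn1_forward(p$fus, S)
  list(E = ff$out, model = model,
       cache = list(ac = af$cache, ling = lf$cache, fus = ff))
}

model_stories_backward <- function(model, cache, dE) {
  p <- model$params
  fb <- attn1_backward(p$fus, cache$fus, dE)
  dS <- fb$dX
  ab <- acoustic_backward(p$ac, cache$ac, dS)
  lb <- linguistic_backward(p$ling, cache$ling, dS)
  list(ac = ab$grads, ling = lb$grads, fus = fb$grads)
}

# -- feature table plumbing ---------------------------------------------------

story_feature_matrices <- function(features) {
  assert_cols(features, c("subject_id", "visit_index", "story_index", "label",
                          "acoustic", "text_vec", linguistic_feature_names),
              "Feature table")
  list(
    Xa = do.call(rbind, features$acoustic),
    Xt = do.call(rbind, features$text_vec),
    X9 = as.matrix(features[, linguistic_feature_names])
  )
}

visit_labels <- function(features) {
  features |>
    dplyr::distinct(.data$subject_id, .data$visit_index, .data$label)
}

# -- training -----------------------------------------------------------------

lg_batch_pass <- function(model, mats, trip, rows, training, want_grads = TRUE) {
  cfg <- model$config
  w <- cfg$weights
  B <- length(rows)
  idx <- c(trip$i1[rows], trip$i2[rows], trip$i3[rows])
  sf <- model_stories_forward(model, mats$Xa[idx, , drop = FALSE],
                              mats$Xt[idx, , drop = FALSE],
                              mats$X9[idx, , drop = FALSE], training)
  model <- sf$model
  E <- sf$E
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    # one mask per triplet, shared across its three visits: coordinate
    # dropout that leaves within-subject differences (and hence the
    # direction encoder's input) consistent
    m1 <- (matrix(runif(B * ncol(E)), B) > cfg$dropout) / (1 - cfg$dropout)
    drop_mask <- rbind(m1, m1, m1)
    E <- E * drop_mask
  }
  E_list <- list(E[seq_len(B), , drop = FALSE],
                 E[B + seq_len(B), , drop = FALSE],
                 E[2L * B + seq_len(B), , drop = FALSE])
  tf <- triplet_forward(model$params$tm, E_list, training)
  model$params$tm <- tf$tm

  y <- trip$target[rows]
  bce <- bce_with_logits(tf$logits, y, return_grad = TRUE)

  inst_labels <- c(trip$l1[rows], trip$l2[rows], trip$l3[rows])
  inst_visits <- rep(1:3, each = B)
  le <- encoder_loss(E, inst_labels, inst_visits, tau = w$tau,
                     include_visit1 = cfg$include_visit1, return_grad = TRUE)

  if (!cfg$ablate_direction) {
    D <- rbind(tf$D[[1]], tf$D[[2]])
    codes <- c(transition_code(trip$l1[rows], trip$l2[rows]),
               transition_code(trip$l2[rows], trip$l3[rows]))
    subj <- rep(trip$subject_id[rows], 2L)
    pairn <- rep(1:2, each = B)
    lg <- group_alignment_loss(D, codes, tau = w$tau, return_grad = TRUE)
    ls <- subject_alignment_loss(D, subj, pairn, reduction = "mean",
                                 return_grad = TRUE)
  } else {
    lg <- list(loss = 0); ls <- list(loss = 0)
  }

  losses <- c(l_class = bce$loss, l_e = le$loss, l_g = lg$loss, l_s = ls$loss)
  total <- total_loss(bce$loss, le$loss, lg$loss, ls$loss, w)
  out <- list(model = model, losses = losses, total = total,
              prob = tf$prob, E = E)
  if (!want_grads) return(out)

  dD_extra <- NULL
  if (!cfg$ablate_direction) {
    dD_all <- w$delta * lg$grad + w$gamma * ls$grad
    dD_extra <- list(dD_all[seq_len(B), , drop = FALSE],
                     dD_all[B + seq_len(B), , drop = FALSE])
  }
  tb <- triplet_backward(model$params$tm, tf$cache, bce$grad, dD_extra)
  dE <- rbind(tb$dE[[1]], tb$dE[[2]], tb$dE[[3]]) + w$alpha * le$grad
  if (!is.null(drop_mask)) dE <- dE * drop_mask
  enc_grads <- model_stories_backward(model, sf$cache, dE)
  out$grads <- c(enc_grads, list(tm = tb$grads))
  out
}

cs_batch_pass <- function(model, mats, stories, rows, training, want_grads = TRUE) {
  cfg <- model$config
  w <- cfg$weights
  sf <- model_stories_forward(model, mats$Xa[rows, , drop = FALSE],
                              mats$Xt[rows, , drop = FALSE],
                              mats$X9[rows, , drop = FALSE], training)
  model <- sf$model
  E <- sf$E
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    drop_mask <- (matrix(runif(length(E)), nrow(E)) > cfg$dropout) / (1 - cfg$dropout)
    E <- E * drop_mask
  }
  cs <- cs_forward(model$params$cs, E, training)
  model$params$cs <- cs$head
  y <- stories$label[rows]
  bce <- bce_with_logits(cs$logits, y, return_grad = TRUE)
  le <- encoder_loss(E, y, visit = stories$visit_index[rows], tau = w$tau,
                     include_visit1 = TRUE, return_grad = TRUE)
  losses <- c(l_class = bce$loss, l_e = le$loss, l_g = 0, l_s = 0)
  out <- list(model = model,
              losses = losses,
              total = total_loss(bce$loss, le$loss, 0, 0, w),
              prob = cs$prob, E = E)
  if (!want_grads) return(out)
  cb <- cs_backward(model$params$cs, cs$cache, bce$grad)
  dE <- cb$dE + w$alpha * le$grad
  if (!is.null(drop_mask)) dE <- dE * drop_mask
  enc_grads <- model_stories_backward(model, sf$cache, dE)
  out$grads <- c(enc_grads, list(cs = cb$grads))
  out
}

#' Fit the longitudinal (or cross-sectional) trajectory model
#'
#' Trains on precomputed per-story features (acoustic vector, pooled text
#' vector, 9 linguistic features). Longitudinal mode builds one visit
#' triplet per last-visit story each epoch by randomly pairing stories
#' across visits within each subject, down-samples the majority class in
#' the training portion, and optimizes the combined loss (classification +
#' encoder + group alignment + subject alignment) with Adam; validation
#' loss is monitored for early stopping. Cross-sectional mode classifies
#' single stories with the classification + encoder losses.
#'
#' @param features Story feature tibble: `subject_id`, `visit_index`,
#'   `story_index`, `label`, `acoustic` and `text_vec` list-columns, and
#'   the 9 linguistic feature columns (see [story_features()]).
#' @param config A [trajectory_config()].
#' @param seed Integer seed controlling initialization, triplet pairing,
#'   down-sampling and the train/validation split.
#' @param val_subjects Character vector of validation subject ids; when
#'   `NULL`, a stratified `val_fraction` of subjects is held out.
#' @param val_fraction Fraction of subjects held out for validation.
#' @param verbose Print per-epoch losses.
#' @return Object of class `cogtraj_fit`: best parameters, per-epoch
#'   `history`, config and split bookkeeping. Supports [predict()],
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_trajectory_model <- function(features, config = trajectory_config(),
                                 seed = 1, val_subjects = NULL,
                                 val_fraction = 0.2, verbose = FALSE) {
  cfg <- config
  mats <- story_feature_matrices(features)
  if (ncol(mats$Xa) != cfg$acoustic_dim ||
      ncol(mats$Xt) != cfg$text_dim) {
    abort(sprintf("Feature dims (acoustic %d, text %d) do not match config (%d, %d)",
                  ncol(mats$Xa), ncol(mats$Xt), cfg$acoustic_dim, cfg$text_dim))
  }
  subjects <- unique(features$subject_id)
  if (is.null(val_subjects)) {
    last_lab <- features |>
      dplyr::filter(.data$visit_index == max(.data$visit_index), .by = "subject_id") |>
      dplyr::distinct(.data$subject_id, .data$label)
    folds <- split_subject_kfold(last_lab$subject_id,
                                 n_folds = max(2L, round(1 / val_fraction)),
                                 seed = derive_seed(seed, "valsplit"),
                                 labels = last_lab$label)
    val_subjects <- folds$subject_id[folds$fold == 1L]
  }
  train_subjects <- setdiff(subjects, val_subjects)
  if (length(intersect(train_subjects, val_subjects)) > 0) {
    abort("Leakage guard: train and validation subjects overlap")
  }
  tr_rows <- which(features$subject_id %in% train_subjects)
  if (cfg$mode == "lg") {
    viol <- validate_longitudinal(features, visits = cfg$visits)
    if (nrow(viol) > 0) {
      abort(paste0("Longitudinal mode needs complete visit coverage; ",
                   nrow(viol), " violation(s) — see validate_longitudinal()"))
    }
  }

  model <- trajectory_model_init(cfg, seed)
  model$params$ling <- set_numeric_stats(model$params$ling,
                                         mats$X9[tr_rows, , drop = FALSE])
  opt <- adam_init(model$params)

  train_feats <- features[tr_rows, , drop = FALSE]
  val_feats <- features[features$subject_id %in% val_subjects, , drop = FALSE]
  val_trip <- if (cfg$mode == "lg" && nrow(val_feats) > 0) {
    make_triplets(val_feats, seed = derive_seed(seed, "valtrip"), epoch = 0L)
  } else NULL

  history <- list()
  best <- list(val = Inf, params = model$params, epoch = 0L)
  wait <- 0L

  eval_val <- function(model) {
    if (cfg$mode == "lg") {
      if (is.null(val_trip) || nrow(val_trip) == 0) return(NA_real_)
      vt <- val_trip
      vt$i1 <- match_rows(features, val_feats[vt$i1, ])
      vt$i2 <- match_rows(features, val_feats[vt$i2, ])
      vt$i3 <- match_rows(features, val_feats[vt$i3, ])
      lg_batch_pass(model, mats, vt, seq_len(nrow(vt)), training = FALSE,
                    want_grads = FALSE)$total
    } else {
      rows <- which(features$subject_id %in% val_subjects)
      if (length(rows) < 2) return(NA_real_)
      cs_batch_pass(model, mats, features, rows, training = FALSE,
                    want_grads = FALSE)$total
    }
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    set.seed(derive_seed(seed, "epoch_rng", epoch))
    if (cfg$mode == "lg") {
      trip <- make_triplets(train_feats, seed = seed, epoch = epoch)
      trip$i1 <- tr_rows[trip$i1]; trip$i2 <- tr_rows[trip$i2]; trip$i3 <- tr_rows[trip$i3]
      if (dplyr::n_distinct(trip$target) > 1) {
        trip <- downsample_majority(trip, "target",
                                    seed = derive_seed(seed, "downs", epoch))
      }
      order_idx <- with_seed(derive_seed(seed, "shuffle", epoch),
                             sample.int(nrow(trip)))
      trip <- trip[order_idx, ]
      n_items <- nrow(trip)
    } else {
      st_rows <- tibble::tibble(row = tr_rows, target = features$label[tr_rows])
      if (dplyr::n_distinct(st_rows$target) > 1) {
        st_rows <- downsample_majority(st_rows, "target",
                                       seed = derive_seed(seed, "downs", epoch))
      }
      rows_all <- with_seed(derive_seed(seed, "shuffle", epoch),
                            st_rows$row[sample.int(nrow(st_rows))])
      n_items <- length(rows_all)
    }
    batch_starts <- seq(1L, n_items, by = cfg$batch_size)
    ep_losses <- c(l_class = 0, l_e = 0, l_g = 0, l_s = 0)
    ep_total <- 0
    for (s in batch_starts) {
      rows <- s:min(s + cfg$batch_size - 1L, n_items)
      if (length(rows) < 2L) next
      bp <- if (cfg$mode == "lg") {
        lg_batch_pass(model, mats, trip, rows, training = TRUE)
      } else {
        cs_batch_pass(model, mats, features, rows_all[rows], training = TRUE)
      }
      model <- bp$model
      step <- adam_step(model$params, bp$grads, opt, lr = cfg$lr)
      model$params <- step$params
      opt <- step$state
      ep_losses <- ep_losses + bp$losses * length(rows)
      ep_total <- ep_total + bp$total * length(rows)
    }
    ep_losses <- ep_losses / n_items
    ep_total <- ep_total / n_items
    val_total <- eval_val(model)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, l_class = ep_losses[["l_class"]], l_e = ep_losses[["l_e"]],
      l_g = ep_losses[["l_g"]], l_s = ep_losses[["l_s"]],
      total = ep_total, val_total = val_total
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, ep_total,
                      ifelse(is.na(val_total), "NA", sprintf("%.4f", val_total))))
    }
    if (any(!is.finite(unlist(ep_losses)))) {
      abort(paste0("Training diverged (non-finite loss) at epoch ", epoch,
                   "; components: ",
                   paste(names(ep_losses), signif(ep_losses, 4),
                         sep = "=", collapse = ", ")))
    }
    monitor <- if (is.na(val_total)) ep_total else val_total
    if (monitor < best$val - 1e-6) {
      best <- list(val = monitor, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  structure(
    list(params = best$params, config = cfg,
         history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val = best$val,
         train_subjects = train_subjects, val_subjects = val_subjects,
         seed = seed),
    class = "cogtraj_fit"
  )
}

match_rows <- function(features, sub) {
  match(paste(sub$subject_id, sub$visit_index, sub$story_index),
        paste(features$subject_id, features$visit_index, features$story_index))
}

#' @export
print.cogtraj_fit <- function(x, ...) {
  n_par <- sum(vapply(tree_flatten(x$params), length, numeric(1)))
  cat(sprintf("<cogtraj_fit: mode=%s%s, %d epochs (best %d), %d parameters>\n",
              x$config$mode,
              if (x$config$ablate_direction) " (direction ablated)" else "",
              nrow(x$history), x$best_epoch, n_par))
  invisible(x)
}

#' Predict story-level probabilities
#'
#' Longitudinal mode scores one triplet per last-visit story (earlier-visit
#' stories paired deterministically under `seed`); cross-sectional mode
#' scores every story. Probabilities are for the impaired class of the
#' (last) visit.
#'
#' @param object A `cogtraj_fit`.
#' @param features Story feature tibble.
#' @param seed Seed for evaluation-time triplet pairing.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `story_index` (anchor story),
#'   `probability` and the true `label`.
#' @export
predict.cogtraj_fit <- function(object, features, seed = object$seed, ...) {
  cfg <- object$config
  mats <- story_feature_matrices(features)
  model <- structure(list(params = object$params, config = cfg),
                     class = "cogtraj_model")
  if (cfg$mode == "lg") {
    trip <- make_triplets(features, seed = derive_seed(seed, "predict"), epoch = 0L)
    bp <- lg_batch_pass(model, mats, trip, seq_len(nrow(trip)),
                        training = FALSE, want_grads = FALSE)
    tibble::tibble(subject_id = trip$subject_id,
                   story_index = features$story_index[trip$i3],
                   probability = as.numeric(bp$prob),
                   label = trip$target)
  } else {
    bp <- cs_batch_pass(model, mats, features, seq_len(nrow(features)),
                        training = FALSE, want_grads = FALSE)
    tibble::tibble(subject_id = features$subject_id,
                   story_index = features$story_index,
                   probability = as.numeric(bp$prob),
                   label = features$label)
  }
}

#' Subject-level soft-voted predictions
#'
#' Averages a subject's story/triplet probabilities ([soft_vote()]) into one
#' subject probability and predicted label.
#'
#' @param fit A `cogtraj_fit`.
#' @param features Story feature tibble.
#' @param seed Evaluation-time pairing seed.
#' @return Tibble with one row per subject: `subject_id`, `probability`,
#'   `predicted`, `label`.
#' @export
predict_subjects <- function(fit, features, seed = fit$seed) {
  predict(fit, features, seed = seed) |>
    dplyr::summarise(probability = mean(.data$probability),
                     label = .data$label[1], .by = "subject_id") |>
    dplyr::mutate(predicted = as.integer(.data$probability > 0.5))
}

#' Story embeddings from a fitted model
#'
#' Runs the fitted encoders in evaluation mode over every story.
#'
#' @param fit A `cogtraj_fit`.
#' @param features Story feature tibble.
#' @return `features`' id columns plus an `embedding` list-column.
#' @export
story_embeddings <- function(fit, features) {
  mats <- story_feature_matrices(features)
  model <- structure(list(params = fit$params, config = fit$config),
                     class = "cogtraj_model")
  E <- model_stories_forward(model, mats$Xa, mats$Xt, mats$X9,
                             training = FALSE)$E
  out <- features[, c("subject_id", "visit_index", "story_index", "label")]
  out$embedding <- lapply(seq_len(nrow(E)), function(i) E[i, ])
  out
}
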