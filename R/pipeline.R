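# Triplet construction, subject-wise cross-validation, class balancing,
# soft voting.

#' Build visit triplets by random story pairing
#'
#' One triplet per last-visit story of each subject: the anchor (last-visit)
#' story is paired with one story sampled uniformly and independently from
#' each earlier visit. Sampling is seeded by (seed, epoch, subject), so the
#' same call reproduces the same pairing while successive epochs see fresh
#' transitions. The triplet target is the label of the last visit.
#'
#' @param stories Story tibble (`subject_id`, `visit_index`, `story_index`,
#'   `label`), longitudinal-complete over `visits`.
#' @param seed,epoch Sampling stream identifiers.
#' @param visits Number of visits (default 3).
#' @return Tibble with one row per triplet: `subject_id`, row indices
#'   `i1..i3` into `stories`, per-visit labels `l1..l3`, and `target`.
#' @export
make_triplets <- function(stories, seed = 1, epoch = 0L, visits = 3L) {
  assert_cols(stories, c("subject_id", "visit_index", "story_index", "label"),
              "Story table")
  viol <- validate_longitudinal(stories, visits = visits)
  if (nrow(viol) > 0) {
    abort(paste0("Cannot build triplets: ", nrow(viol),
                 " completeness violation(s); see validate_longitudinal()"))
  }
  out <- lapply(unique(stories$subject_id), function(sj) {
    rows_v <- lapply(seq_len(visits), function(v) {
      which(stories$subject_id == sj & stories$visit_index == v)
    })
    anchors <- rows_v[[visits]]
    n_anchor <- length(anchors)
    picks <- with_seed(derive_seed(seed, epoch, sj), {
      lapply(seq_len(visits - 1L), function(v) {
        rows_v[[v]][sample.int(length(rows_v[[v]]), n_anchor, replace = TRUE)]
      })
    })
    labs <- function(rows) stories$label[rows]
    tibble::tibble(
      subject_id = sj,
      i1 = picks[[1]], i2 = picks[[2]], i3 = anchors,
      l1 = labs(picks[[1]]), l2 = labs(picks[[2]]), l3 = labs(anchors),
      target = labs(anchors)
    )
  })
  dplyr::bind_rows(out)
}

#' Subject-wise k-fold split
#'
#' Shuffles subjects under `seed` and deals them into `n_folds` near-equal
#' folds (sizes differ by at most one); with `labels`, subjects are dealt
#' within label strata so fold label composition is as balanced as the
#' counts allow. Splitting by subject keeps all visits/stories of a subject
#' on one side, preventing leakage.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param n_folds Number of folds (default 10).
#' @param seed Shuffle seed.
#' @param labels Optional per-subject label for stratification.
#' @return Tibble with `subject_id`, `fold`; every subject in exactly one
#'   fold.
#' @export
split_subject_kfold <- function(subject_ids, n_folds = 10L, seed = 1,
                                labels = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) abort("`subject_ids` must be unique")
  n <- length(subject_ids)
  if (n < n_folds) abort(sprintf("Cannot split %d subjects into %d folds", n, n_folds))
  # stratified dealing: shuffle within stratum, concatenate strata, then deal
  # round-robin over the concatenated order so overall fold sizes stay equal
  with_seed(derive_seed(seed, "kfold"), {
    if (is.null(labels)) {
      ord <- sample.int(n)
    } else {
      stopifnot(length(labels) == n)
      shuffle <- function(x) x[sample.int(length(x))]
      ord <- unlist(lapply(split(seq_len(n), labels), shuffle), use.names = FALSE)
    }
    fold_perm <- sample.int(n_folds)
  })
  fold <- integer(n)
  fold[ord] <- fold_perm[(seq_len(n) - 1L) %% n_folds + 1L]
  tibble::tibble(subject_id = subject_ids, fold = fold)
}

#' Down-sample the majority class
#'
#' Randomly subsamples the majority class without replacement to the
#' minority count, for use on training data only (validation is never
#' balanced).
#'
#' @param df Data frame with a class column.
#' @param label_col Name of the class column (two classes required).
#' @param seed Sampling seed.
#' @return The balanced subset of `df`, original row order preserved.
#' @export
downsample_majority <- function(df, label_col = "target", seed = 1) {
  y <- df[[label_col]]
  tab <- table(y)
  if (length(tab) < 2L) abort("Down-sampling needs both classes present")
  n_min <- min(tab)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(y == cl)
    if (length(idx) > n_min) {
      with_seed(derive_seed(seed, "downsample", cl),
                idx[sample.int(length(idx), n_min)])
    } else idx
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Soft voting over a subject's probabilities
#'
#' Averages story/triplet probabilities; the predicted label is impaired
#' when the mean exceeds 0.5 (ties go to HC).
#'
#' @param probs Numeric vector of probabilities (length >= 1).
#' @return List with `probability` (the mean) and `predicted` (0/1).
#' @export
soft_vote <- function(probs) {
  if (length(probs) < 1L) abort("soft_vote needs at least one probability")
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1]")
  p <- mean(probs)
  list(probability = p, predicted = as.integer(p > 0.5))
}

#' Subject-wise cross-validated training
#'
#' Runs [fit_trajectory_model()] over a subject-wise k-fold plan: each
#' fold's subjects form the validation set (never down-sampled, never used
#' for the numeric standardization statistics) and the rest train the
#' model. Metrics are computed on soft-voted subject probabilities per fold
#' and averaged at fold level.
#'
#' @param features Story feature tibble.
#' @param config A [trajectory_config()].
#' @param n_folds Number of folds (default 10).
#' @param seed Master seed (split, initialization, pairing).
#' @return Object of class `cogtraj_cv`: per-fold `metrics`, pooled subject
#'   `predictions`, the split `plan`, and fold-averaged `summary`.
#' @export
cv_trajectory <- function(features, config = trajectory_config(),
                          n_folds = 10L, seed = 1) {
  last_lab <- features |>
    dplyr::filter(.data$visit_index == max(.data$visit_index), .by = "subject_id") |>
    dplyr::distinct(.data$subject_id, .data$label)
  plan <- split_subject_kfold(last_lab$subject_id, n_folds = n_folds,
                              seed = seed, labels = last_lab$label)
  fold_metrics <- list()
  preds <- list()
  for (f in sort(unique(plan$fold))) {
    val_subjects <- plan$subject_id[plan$fold == f]
    fit <- fit_trajectory_model(features, config,
                                seed = derive_seed(seed, "fold", f),
                                val_subjects = val_subjects)
    val_feats <- features[features$subject_id %in% val_subjects, , drop = FALSE]
    sp <- predict_subjects(fit, val_feats)
    sp$fold <- f
    preds[[f]] <- sp
    fold_metrics[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      compute_metrics(sp$label, sp$probability)
    )
  }
  metrics <- dplyr::bind_rows(fold_metrics)
  structure(
    list(metrics = metrics,
         predictions = dplyr::bind_rows(preds),
         plan = plan,
         summary = dplyr::summarise(metrics, dplyr::across(-"fold",
                                                           ~ mean(.x, na.rm = TRUE)))),
    class = "cogtraj_cv"
  )
}

#' @export
print.cogtraj_cv <- function(x, ...) {
  cat(sprintf("<cogtraj_cv: %d folds>\n", nrow(x$metrics)))
  print(x$summary)
  invisible(x)
}
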