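#' Project per-visit embeddings into a 2-D trajectory map
#'
#' Averages story embeddings within each (subject, visit), fits principal
#' components on the mean-centered visit embeddings, and projects onto the
#' top two components. Arrows connect each subject's consecutive visits in
#' visit order, visualizing the aging trajectory through the latent space.
#'
#' @param emb Tibble with `subject_id`, `visit_index`, `label` and an
#'   `embedding` list-column (see [story_embeddings()]).
#' @return Object of class `cogtraj_trajectories`: `points` (one row per
#'   subject-visit with `pc1`, `pc2`), `arrows` (consecutive-visit segment
#'   endpoints), `var_explained` (length 2, non-increasing).
#' @export
project_trajectories <- function(emb) {
  assert_cols(emb, c("subject_id", "visit_index", "label", "embedding"),
              "Embedding table")
  visit_emb <- emb |>
    dplyr::summarise(
      embedding = list(colMeans(do.call(rbind, .data$embedding))),
      label = .data$label[1],
      .by = c("subject_id", "visit_index")
    ) |>
    dplyr::arrange(.data$subject_id, .data$visit_index)
  X <- do.call(rbind, visit_emb$embedding)
  if (nrow(X) < 3) abort("Need at least 3 embeddings to project")
  if (nrow(unique(X)) < 2) abort("Degenerate embeddings: fewer than 2 distinct vectors")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  points <- tibble::tibble(
    subject_id = visit_emb$subject_id,
    visit_index = visit_emb$visit_index,
    label = visit_emb$label,
    pc1 = pc$x[, 1],
    pc2 = if (k >= 2) pc$x[, 2] else 0
  )
  arrows <- points |>
    dplyr::arrange(.data$subject_id, .data$visit_index) |>
    dplyr::mutate(
      x = .data$pc1, y = .data$pc2,
      xend = dplyr::lead(.data$pc1), yend = dplyr::lead(.data$pc2),
      from_visit = .data$visit_index,
      .by = "subject_id"
    ) |>
    dplyr::filter(!is.na(.data$xend)) |>
    dplyr::select("subject_id", "from_visit", "label",
                  "x", "y", "xend", "yend")
  var2 <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  structure(list(points = points, arrows = arrows, var_explained = var2),
            class = "cogtraj_trajectories")
}

#' @export
print.cogtraj_trajectories <- function(x, ...) {
  cat(sprintf("<cogtraj_trajectories: %d points, %d arrows; var explained %.1f%% + %.1f%%>\n",
              nrow(x$points), nrow(x$arrows),
              100 * x$var_explained[1],
              100 * (if (length(x$var_explained) > 1) x$var_explained[2] else 0)))
  invisible(x)
}
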