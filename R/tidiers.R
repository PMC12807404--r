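#' Tidy a fitted trajectory model
#'
#' Returns the training history in long form: one row per epoch and loss
#' component (`l_class`, `l_e`, `l_g`, `l_s`, `total`, `val_total`).
#'
#' @param x A `cogtraj_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `component`, `value`.
#' @export
tidy.cogtraj_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "component", values_to = "value")
}

#' @rdname tidy.cogtraj_fit
#' @export
glance.cogtraj_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    ablate_direction = x$config$ablate_direction,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val,
    n_parameters = sum(vapply(tree_flatten(x$params), length, numeric(1))),
    n_train_subjects = length(x$train_subjects),
    n_val_subjects = length(x$val_subjects)
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cogtraj_cv`.
#' @param ... Unused.
#' @return Per-fold metrics in long form (`fold`, `metric`, `value`).
#' @export
tidy.cogtraj_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"fold",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.cogtraj_cv
#' @export
glance.cogtraj_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_folds = nrow(x$metrics)), x$summary)
}
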