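# Training losses: binary cross-entropy, supervised contrastive loss,
# subject alignment (cosine) loss, group alignment loss, and their weighted
# combination. Each returns the scalar loss and, when `return_grad = TRUE`,
# the analytic gradient with respect to its vector inputs (verified against
# finite differences and naive-loop oracles in the test suite).

#' Encode a label transition between consecutive visits
#'
#' Transitions are coded 0 = HC at both visits, 1 = HC then impaired,
#' 2 = impaired at both visits. Reverse transitions (impaired then HC) occur
#' in real cohorts but carry no transition class; they are returned as `NA`
#' and excluded from the group alignment loss.
#'
#' @param l_prev,l_curr Integer labels (0 = HC, 1 = impaired) at visits
#'   k-1 and k; vectorized.
#' @return Integer vector over \{0, 1, 2, NA\}.
#' @export
#' @examples
#' transition_code(c(0, 0, 1, 1), c(0, 1, 0, 1))
transition_code <- function(l_prev, l_curr) {
  stopifnot(all(l_prev %in% 0:1), all(l_curr %in% 0:1), length(l_prev) == length(l_curr))
  out <- rep(NA_integer_, length(l_prev))
  out[l_prev == 0L & l_curr == 0L] <- 0L
  out[l_prev == 0L & l_curr == 1L] <- 1L
  out[l_prev == 1L & l_curr == 1L] <- 2L
  out
}

bce_with_logits <- function(logits, y, return_grad = FALSE) {
  n <- length(logits)
  # log(1 + exp(z)) - y z, computed stably
  loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  if (!return_grad) return(loss)
  list(loss = loss, grad = (stats::plogis(logits) - y) / n)
}

#' Supervised contrastive loss
#'
#' Standard supervised contrastive loss: vectors are L2-normalized, each
#' anchor with at least one same-label positive contributes the mean over
#' its positives of `-log(exp(s_ip / tau) / sum_{a != i} exp(s_ia / tau))`,
#' and the result is the mean over contributing anchors. Anchors without
#' positives are skipped; if no anchor has a positive the loss is 0 and a
#' `no_positives` warning condition is signalled.
#'
#' @param z Numeric matrix, one vector per row (>= 2 rows).
#' @param labels Vector of categories, one per row.
#' @param tau Temperature (> 0), default 0.07.
#' @param return_grad Also return the gradient with respect to `z`.
#' @return The scalar loss, or (with `return_grad`) a list `loss`, `grad`.
#' @export
supcon_loss <- function(z, labels, tau = 0.07, return_grad = FALSE) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) abort("supcon_loss needs at least 2 vectors")
  if (length(labels) != n) abort("One label per row required")
  if (!is_scalar_number(tau) || tau <= 0) abort("`tau` must be > 0")

  r <- sqrt(rowSums(z^2))
  r <- pmax(r, 1e-12)
  U <- z / r
  S <- U %*% t(U)
  E <- exp(S / tau)
  diag(E) <- 0
  denom <- rowSums(E)

  P <- outer(labels, labels, `==`)
  diag(P) <- FALSE
  nP <- rowSums(P)
  anchors <- nP > 0L
  if (!any(anchors)) {
    warn("supcon_loss: no anchor has a positive; returning 0")
    if (return_grad) return(list(loss = 0, grad = 0 * z))
    return(0)
  }
  nA <- sum(anchors)
  per_anchor <- vapply(which(anchors), function(i) {
    -(sum(S[i, P[i, ]]) / tau) / nP[i] + log(denom[i])
  }, numeric(1))
  loss <- sum(per_anchor) / nA
  if (!return_grad) return(loss)

  # dL/dS[i, j] (j != i) = (1/(nA * tau)) * (E_ij / denom_i - P_ij / nP_i)
  G <- matrix(0, n, n)
  G[anchors, ] <- (E[anchors, , drop = FALSE] / denom[anchors] -
                     P[anchors, , drop = FALSE] / nP[anchors]) / (nA * tau)
  diag(G) <- 0
  dU <- (G + t(G)) %*% U
  # through the normalization u = z / |z|
  dZ <- (dU - U * rowSums(dU * U)) / r
  list(loss = loss, grad = dZ)
}

#' Subject alignment loss
#'
#' Pulls each subject's story-pair direction vectors toward that subject's
#' mean direction for the visit pair: for every subject and consecutive
#' visit pair, the mean direction over the story pairs present is computed,
#' and each story-pair direction contributes `1 - cos(mean, direction)`.
#' Cosine similarity is scale-free, so directions are not normalized first;
#' denominators are guarded at 1e-8. `reduction = "mean"` (default) divides
#' the sum by the number of contributing terms for batch-size independence;
#' `"sum"` is the raw double sum.
#'
#' @param directions Numeric matrix of direction vectors, one per row.
#' @param subject Subject id per row.
#' @param pair Visit-pair index per row (e.g. 1 for visits 1 to 2).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @param return_grad Also return the gradient with respect to `directions`.
#' @return Scalar loss (>= 0), or a list `loss`, `grad`.
#' @export
subject_alignment_loss <- function(directions, subject, pair = rep(1L, length(subject)),
                                   reduction = c("mean", "sum"),
                                   return_grad = FALSE) {
  reduction <- match.arg(reduction)
  D <- as.matrix(directions)
  n <- nrow(D)
  if (n < 1L) abort("Need at least one direction")
  if (length(subject) != n || length(pair) != n) abort("One subject and pair id per row required")
  eps <- 1e-8

  grp <- paste(subject, pair, sep = "\r")
  total <- 0
  grad <- if (return_grad) 0 * D else NULL
  for (g in unique(grp)) {
    idx <- which(grp == g)
    Dg <- D[idx, , drop = FALSE]
    M <- length(idx)
    m <- colMeans(Dg)
    nm <- max(sqrt(sum(m^2)), eps)
    nd <- pmax(sqrt(rowSums(Dg^2)), eps)
    cosines <- as.numeric(Dg %*% m) / (nm * nd)
    total <- total + sum(1 - cosines)
    if (return_grad) {
      # direct term: -d cos/d d_j; mean term: each row receives (1/M) of
      # -sum_j d cos_j / d m
      dcos_dd <- matrix(m, M, ncol(D), byrow = TRUE) / (nm * nd) -
        (cosines / nd^2) * Dg
      dm <- -(colSums(Dg / nd) / nm - sum(cosines) * m / nm^2)
      grad[idx, ] <- grad[idx, , drop = FALSE] - dcos_dd +
        matrix(dm / M, M, ncol(D), byrow = TRUE)
    }
  }
  if (reduction == "mean") {
    total <- total / n
    if (return_grad) grad <- grad / n
  }
  if (return_grad) list(loss = total, grad = grad) else total
}

#' Group alignment loss
#'
#' Supervised contrastive loss over direction vectors labeled by their
#' cognitive-status transition code ([transition_code()]); directions with
#' `NA` code (impaired-to-HC transitions) are excluded before the loss.
#' Returns 0 with a warning when fewer than 2 usable directions remain.
#'
#' @param directions Numeric matrix of direction vectors, one per row.
#' @param codes Transition codes per row (0/1/2 or `NA`).
#' @param tau Temperature.
#' @param return_grad Also return the gradient with respect to
#'   `directions` (zero rows for excluded directions).
#' @return Scalar loss, or a list `loss`, `grad`.
#' @export
group_alignment_loss <- function(directions, codes, tau = 0.07, return_grad = FALSE) {
  D <- as.matrix(directions)
  keep <- which(!is.na(codes))
  if (length(keep) < 2L) {
    warn("group_alignment_loss: fewer than 2 usable directions; returning 0")
    if (return_grad) return(list(loss = 0, grad = 0 * D))
    return(0)
  }
  res <- supcon_loss(D[keep, , drop = FALSE], codes[keep], tau, return_grad)
  if (!return_grad) return(res)
  grad <- 0 * D
  grad[keep, ] <- res$grad
  list(loss = res$loss, grad = grad)
}

#' Encoder loss
#'
#' Supervised contrastive loss over story embeddings labeled by their
#' visit's cognitive label, pulling same-status stories together in the
#' latent space. In its original formulation the loss runs over visits
#' 2..V; set
#' `include_visit1 = TRUE` to include first-visit embeddings.
#'
#' @param embeddings Numeric matrix of story embeddings, one per row.
#' @param labels Visit-level cognitive label (0/1) per row.
#' @param visit Visit index per row (used for the visit filter); defaults
#'   to including every row.
#' @param tau Temperature.
#' @param include_visit1 Include visit-1 embeddings (default `FALSE`).
#' @param return_grad Also return the gradient.
#' @return Scalar loss, or a list `loss`, `grad`.
#' @export
encoder_loss <- function(embeddings, labels, visit = NULL, tau = 0.07,
                         include_visit1 = FALSE, return_grad = FALSE) {
  E <- as.matrix(embeddings)
  keep <- if (is.null(visit) || include_visit1) seq_len(nrow(E)) else which(visit >= 2L)
  if (length(keep) < 2L) {
    warn("encoder_loss: fewer than 2 embeddings after the visit filter; returning 0")
    if (return_grad) return(list(loss = 0, grad = 0 * E)) else return(0)
  }
  res <- supcon_loss(E[keep, , drop = FALSE], labels[keep], tau, return_grad)
  if (!return_grad) return(res)
  grad <- 0 * E
  grad[keep, ] <- res$grad
  list(loss = res$loss, grad = grad)
}

#' Combine the four training losses
#'
#' `L = L_class + alpha * L_E + delta * L_G + gamma * L_S` with tuned
#' default weights alpha = 0.01, delta = 0.001, gamma = 0.001.
#'
#' @param l_class Binary cross-entropy classification loss.
#' @param l_e,l_g,l_s Encoder, group alignment and subject alignment losses.
#' @param weights A [loss_weights()] list.
#' @return Scalar total loss.
#' @export
total_loss <- function(l_class, l_e = 0, l_g = 0, l_s = 0, weights = loss_weights()) {
  comps <- c(l_class = l_class, l_e = l_e, l_g = l_g, l_s = l_s)
  if (any(is.na(comps)) || any(!is.finite(comps))) {
    bad <- names(comps)[is.na(comps) | !is.finite(comps)]
    abort(paste0("Non-finite loss component(s): ", paste(bad, collapse = ", ")))
  }
  l_class + weights$alpha * l_e + weights$delta * l_g + weights$gamma * l_s
}

#' @rdname total_loss
#' @param alpha Weight of the encoder loss (default 0.01).
#' @param delta Weight of the group alignment loss (default 0.001).
#' @param gamma Weight of the subject alignment loss (default 0.001).
#' @param tau Supervised-contrastive temperature (default 0.07).
#' @export
loss_weights <- function(alpha = 0.01, delta = 0.001, gamma = 0.001, tau = 0.07) {
  stopifnot(alpha >= 0, delta >= 0, gamma >= 0, tau > 0)
  list(alpha = alpha, delta = delta, gamma = gamma, tau = tau)
}
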