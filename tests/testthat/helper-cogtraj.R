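# Shared fixtures built in code.

toy_transcript <- function(starts, ends, texts) {
  tibble::tibble(start = starts, end = ends, text = texts)
}

tiny_config <- function(...) {
  trajectory_config(acoustic_dim = 16, text_dim = 8, numeric_dim = 4,
                    embed_dim = 16, direction_dim = 8, fd_hidden = 8,
                    filters = c(4, 8, 8), batch_size = 4, ...)
}

tiny_cohort <- function(n_subjects = 8, seed = 3, ...) {
  simulate_cohort(n_subjects = n_subjects, acoustic_dim = 16, text_dim = 8,
                  seed = seed, ...)
}

# Naive double-loop supervised-contrastive oracle, independent of the
# vectorized implementation.
supcon_naive <- function(z, labels, tau) {
  n <- nrow(z)
  u <- z / sqrt(rowSums(z^2))
  terms <- c()
  for (i in seq_len(n)) {
    pos <- setdiff(which(labels == labels[i]), i)
    if (length(pos) == 0) next
    denom <- 0
    for (a in setdiff(seq_len(n), i)) denom <- denom + exp(sum(u[i, ] * u[a, ]) / tau)
    li <- 0
    for (p in pos) li <- li - log(exp(sum(u[i, ] * u[p, ]) / tau) / denom)
    terms <- c(terms, li / length(pos))
  }
  if (length(terms) == 0) 0 else mean(terms)
}

# Direct-formula subject alignment oracle: explicit loops over subjects,
# visit pairs and story pairs.
subject_alignment_naive <- function(D, subject, pair) {
  total <- 0
  n_terms <- 0
  for (s in unique(subject)) {
    for (k in unique(pair[subject == s])) {
      idx <- which(subject == s & pair == k)
      m <- colMeans(D[idx, , drop = FALSE])
      for (j in idx) {
        cs <- sum(m * D[j, ]) / (sqrt(sum(m^2)) * sqrt(sum(D[j, ]^2)))
        total <- total + (1 - cs)
        n_terms <- n_terms + 1
      }
    }
  }
  list(sum = total, mean = total / n_terms)
}
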