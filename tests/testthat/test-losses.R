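test_that("transition codes follow the three-class scheme with reverse excluded", {
  expect_equal(transition_code(0L, 0L), 0L)
  expect_equal(transition_code(0L, 1L), 1L)
  expect_equal(transition_code(1L, 1L), 2L)
  expect_true(is.na(transition_code(1L, 0L)))
  expect_equal(transition_code(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               c(0L, 1L, NA, 2L))
})

test_that("supervised contrastive loss matches its degenerate cases", {
  z2 <- rbind(c(1, 0), c(1, 0))
  expect_equal(supcon_loss(z2, c("a", "a"), tau = 0.07), 0)

  expect_warning(v <- supcon_loss(rbind(c(1, 0), c(0, 1)), c("a", "b")),
                 "no anchor")
  expect_equal(v, 0)

  expect_error(supcon_loss(matrix(1, 1, 2), "a"), "at least 2")
  expect_error(supcon_loss(z2, c("a", "a"), tau = 0), "tau")
})

test_that("vectorized contrastive losses agree with the naive-loop oracle", {
  for (seed in 1:10) {
    z <- withr::with_seed(seed, matrix(rnorm(8 * 5), 8))
    labels <- withr::with_seed(seed + 100, sample(0:2, 8, replace = TRUE))
    expect_equal(supcon_loss(z, labels, tau = 0.07),
                 supcon_naive(z, labels, tau = 0.07), tolerance = 1e-6)
  }
  # the documented 4-vector case
  z4 <- withr::with_seed(42, matrix(rnorm(4 * 6), 4))
  z4 <- z4 / sqrt(rowSums(z4^2))
  expect_equal(supcon_loss(z4, c(0, 0, 1, 1), tau = 0.07),
               supcon_naive(z4, c(0, 0, 1, 1), tau = 0.07), tolerance = 1e-6)
})

test_that("subject alignment loss matches the hand-computed worked example", {
  # one subject, one visit pair, directions (1,0) and (0,1):
  # mean (0.5, 0.5), each term 1 - sqrt(2)/2, raw sum 2 * (1 - sqrt(2)/2)
  D <- rbind(c(1, 0), c(0, 1))
  raw <- subject_alignment_loss(D, c("s1", "s1"), c(1L, 1L), reduction = "sum")
  expect_equal(raw, 2 * (1 - sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(raw, 0.58579, tolerance = 1e-5)
  expect_equal(subject_alignment_loss(D, c("s1", "s1"), reduction = "mean"),
               raw / 2, tolerance = 1e-9)

  # identical directions align perfectly
  Did <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(subject_alignment_loss(Did, rep("s", 3)), 0, tolerance = 1e-12)

  # cosine is scale-free
  D2 <- withr::with_seed(2, matrix(rnorm(6 * 4), 6))
  subj <- c("a", "a", "a", "b", "b", "b")
  expect_equal(subject_alignment_loss(D2, subj),
               subject_alignment_loss(3 * D2, subj), tolerance = 1e-9)
})

test_that("subject alignment agrees with the direct-formula oracle on random batches", {
  for (seed in 1:8) {
    n_sub <- withr::with_seed(seed, sample(2:5, 1))
    rows <- withr::with_seed(seed + 10, sample(2:4, n_sub * 2, replace = TRUE))
    subject <- rep(rep(paste0("s", seq_len(n_sub)), each = 2), rows)
    pair <- rep(rep(1:2, n_sub), rows)
    D <- withr::with_seed(seed + 20, matrix(rnorm(length(subject) * 6), ncol = 6))
    naive <- subject_alignment_naive(D, subject, pair)
    expect_equal(subject_alignment_loss(D, subject, pair, reduction = "sum"),
                 naive$sum, tolerance = 1e-6)
    expect_equal(subject_alignment_loss(D, subject, pair, reduction = "mean"),
                 naive$mean, tolerance = 1e-6)
  }
})

test_that("group alignment filters excluded transitions without changing the rest", {
  D <- withr::with_seed(3, matrix(rnorm(6 * 4), 6))
  codes <- c(0L, 0L, 2L, 2L, NA, NA)
  with_na <- group_alignment_loss(D, codes)
  without <- supcon_loss(D[1:4, ], codes[1:4])
  expect_equal(with_na, without, tolerance = 1e-12)

  expect_equal(group_alignment_loss(rbind(c(1, 0), c(1, 0)), c(0L, 0L)), 0)
  expect_warning(group_alignment_loss(D, c(0L, rep(NA, 5))), "fewer than 2")
})

test_that("encoder loss respects the visit filter and the label partition", {
  E <- withr::with_seed(4, matrix(rnorm(9 * 5), 9))
  labels <- c(0, 0, 0, 1, 1, 1, 0, 1, 0)
  visit <- rep(1:3, each = 3)

  # as printed: visits 2..V only
  default <- suppressWarnings(encoder_loss(E, labels, visit))
  manual <- supcon_loss(E[visit >= 2, ], labels[visit >= 2])
  expect_equal(default, manual, tolerance = 1e-12)

  all_visits <- encoder_loss(E, labels, visit, include_visit1 = TRUE)
  expect_equal(all_visits, supcon_loss(E, labels), tolerance = 1e-12)

  # SupCon depends only on the label partition
  expect_equal(encoder_loss(E, 1 - labels, visit, include_visit1 = TRUE),
               all_visits, tolerance = 1e-12)
})

test_that("the total loss is the documented weighted sum", {
  expect_equal(total_loss(0.7, 1, 2, 3), 0.715)  # defaults 0.01/0.001/0.001
  expect_equal(total_loss(0.9, 5, 7, 9, loss_weights(0, 0, 0)), 0.9)
  # linear in each component
  w <- loss_weights(0.2, 0.3, 0.4)
  expect_equal(total_loss(1, 2, 3, 4, w) - total_loss(1, 0, 3, 4, w), 0.2 * 2)
  expect_error(total_loss(NaN, 1, 1, 1), "l_class")
})

test_that("analytic loss gradients match finite differences", {
  h <- 1e-6
  z <- withr::with_seed(5, matrix(rnorm(6 * 4), 6))
  labels <- c(0, 0, 1, 1, 2, 2)
  g <- supcon_loss(z, labels, tau = 0.2, return_grad = TRUE)
  for (j in withr::with_seed(6, sample(length(z), 6))) {
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    num <- (supcon_loss(zp, labels, tau = 0.2) -
              supcon_loss(zm, labels, tau = 0.2)) / (2 * h)
    expect_equal(g$grad[j], num, tolerance = 1e-4)
  }

  D <- withr::with_seed(7, matrix(rnorm(5 * 3), 5))
  subj <- c("a", "a", "a", "b", "b")
  gs <- subject_alignment_loss(D, subj, return_grad = TRUE)
  for (j in withr::with_seed(8, sample(length(D), 6))) {
    Dp <- D; Dp[j] <- Dp[j] + h
    Dm <- D; Dm[j] <- Dm[j] - h
    num <- (subject_alignment_loss(Dp, subj) -
              subject_alignment_loss(Dm, subj)) / (2 * h)
    expect_equal(gs$grad[j], num, tolerance = 1e-4)
  }
})
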