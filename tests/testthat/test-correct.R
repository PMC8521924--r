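# Self-supervised gap interpolation: pair geometry, per-offset ensemble
# training, prediction contracts, localization and splicing.

test_that("training pairs follow the 2h + G window geometry", {
  es <- sine_epoch_set(n_epochs = 5, n_channels = 3, n_samples = 200)
  pairs <- build_training_pairs(es, h = 32, G = 40, pairs_per_epoch = 2, seed = 1)
  expect_equal(dim(pairs$context), c(10, 3, 64))   # channels x 2h
  expect_equal(dim(pairs$target), c(10, 3, 40))    # channels x G
  expect_equal(pairs$h + pairs$G + pairs$h, 104)
  # the window really is context | gap | context from the source epoch
  ep <- epoch_data(es, pairs$epoch[1])
  win <- NULL
  for (s in 1:(200 - 104 + 1)) {
    if (all(ep[, s:(s + 31)] == pairs$context[1, , 1:32]) &&
        all(ep[, (s + 72):(s + 103)] == pairs$context[1, , 33:64])) { win <- s; break }
  }
  expect_false(is.null(win))
  expect_equal(pairs$target[1, , ], ep[, (win + 32):(win + 71)], ignore_attr = TRUE)
  # counts and determinism
  p2 <- build_training_pairs(es, h = 32, G = 40, pairs_per_epoch = 2, seed = 1)
  expect_identical(pairs$context, p2$context)
  expect_error(build_training_pairs(sine_epoch_set(n_samples = 80), h = 32, G = 40),
               class = "eegsweep_parameter_error")
})

test_that("the ensemble trains one network per offset and learns sinusoids", {
  es <- sine_epoch_set(n_epochs = 60, n_channels = 2, n_samples = 120,
                       freq = 10, amp = 10, seed = 2)
  pairs <- build_training_pairs(es, h = 16, G = 4, pairs_per_epoch = 3, seed = 3)
  ens <- train_interpolator(pairs, epochs = 300, seed = 4)
  expect_equal(length(ens$models), 4)
  expect_equal(ens$G, 4)
  # held-out epochs from the same deterministic family
  ho_es <- sine_epoch_set(n_epochs = 20, n_channels = 2, n_samples = 120,
                          freq = 10, amp = 10, seed = 99)
  ho <- build_training_pairs(ho_es, h = 16, G = 4, pairs_per_epoch = 1, seed = 5)
  err <- 0; tot <- 0
  for (i in seq_len(dim(ho$context)[1])) {
    pred <- predict_gap(ens, matrix(ho$context[i, , 1:16], nrow = 2),
                        matrix(ho$context[i, , 17:32], nrow = 2))
    err <- err + mean((pred - ho$target[i, , ])^2)
    tot <- tot + 1
  }
  expect_lt(err / tot, 0.1 * stats::var(as.vector(ho_es$data)))
  # determinism of training and inference
  ens2 <- train_interpolator(pairs, epochs = 300, seed = 4)
  expect_identical(ens$final_loss, ens2$final_loss)
  L <- matrix(ho$context[1, , 1:16], nrow = 2)
  R <- matrix(ho$context[1, , 17:32], nrow = 2)
  expect_identical(predict_gap(ens, L, R), predict_gap(ens, L, R))
  expect_equal(dim(predict_gap(ens, L, R)), c(2, 4))
  expect_error(predict_gap(ens, L[, 1:8], R), class = "eegsweep_contract_error")
  # tidy/glance expose per-offset losses
  td <- tidy(ens)
  expect_equal(td$offset, 0:3)
  expect_true(all(is.finite(td$final_loss)))
  expect_equal(glance(ens)$G, 4)
})

test_that("a constant-signal ensemble predicts the constant", {
  arr <- array(7, c(30, 2, 120)) + array(rnorm(30 * 2 * 120, 0, 0.01), c(30, 2, 120))
  es <- epoch_set(arr, 200)
  pairs <- build_training_pairs(es, h = 16, G = 4, pairs_per_epoch = 2, seed = 6)
  ens <- train_interpolator(pairs, epochs = 300, seed = 7)
  pred <- predict_gap(ens, matrix(7, 2, 16), matrix(7, 2, 16))
  expect_true(all(abs(pred - 7) / 7 < 0.05))
})

test_that("artifact localization finds the deviant window and clamps to the contexts", {
  es <- sine_epoch_set(n_epochs = 1, n_channels = 3, n_samples = 200, amp = 5, seed = 8)
  ep <- epoch_data(es, 1)
  ep[2, 81:120] <- ep[2, 81:120] + 60          # pop-like burst at samples [80, 120)
  gap <- locate_artifact_segment(ep, G = 40, h = 32)
  g0 <- gap$t_b + 1L
  overlap <- length(intersect(seq(g0, g0 + 39), 80:119))
  expect_gte(overlap, 20)
  expect_equal(gap$t_e - gap$t_b - 1L, 40)
  # clamping: deviation at the very start cannot start before h
  ep2 <- epoch_data(es, 1)
  ep2[1, 1:10] <- 100
  gap2 <- locate_artifact_segment(ep2, G = 40, h = 32)
  expect_equal(gap2$t_b + 1L, 32)              # 0-based gap start == h
  # clean epochs still return a well-formed window
  gap3 <- locate_artifact_segment(epoch_data(es, 1), G = 40, h = 32)
  expect_gte(gap3$t_b + 1L, 32)
  expect_lte(gap3$t_e + 32, 200)
  expect_error(locate_artifact_segment(ep[, 1:80], G = 40, h = 32),
               class = "eegsweep_parameter_error")
})

test_that("correction splices exactly G samples into flagged epochs only", {
  es <- sine_epoch_set(n_epochs = 12, n_channels = 2, n_samples = 120, seed = 9)
  pairs <- build_training_pairs(es, h = 16, G = 8, pairs_per_epoch = 2, seed = 10)
  ens <- train_interpolator(pairs, epochs = 60, seed = 11)
  det <- tibble::tibble(epoch_index = 1:12, flag = c(TRUE, rep(FALSE, 10), TRUE))
  out <- correct_epochs(es, det, ens)
  # no flag, no touch
  for (i in 2:11) expect_identical(out$data[i, , ], es$data[i, , ])
  for (i in c(1, 12)) {
    diffc <- which(colSums(abs(epoch_data(out, i) - epoch_data(es, i))) > 0)
    expect_equal(length(diffc), 8)
    expect_true(all(diff(diffc) == 1))
  }
  expect_equal(nrow(out$metadata$corrections), 2)
  # empty flag set: identity
  none <- correct_epochs(es, tibble::tibble(epoch_index = 1:12, flag = FALSE), ens)
  expect_identical(none$data, es$data)
  # geometry mismatch is refused
  es3 <- sine_epoch_set(n_epochs = 2, n_channels = 3, n_samples = 120)
  expect_error(correct_epochs(es3, det, ens), class = "eegsweep_contract_error")
})
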