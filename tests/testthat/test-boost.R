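test_that("initial weights follow the attention fraction with >= boundary", {
  M <- 512L
  lab <- matrix(0L, M, M); lab[seq_len(26215)] <- 1L   # ~10% positive
  expect_equal(init_weights(list(lab), alpha = 0.05), 1)
  none <- matrix(0L, 8, 8)
  expect_equal(init_weights(list(none), alpha = 0.05), 0)
  # fraction exactly alpha qualifies
  ex <- matrix(0L, 10, 10); ex[1:5] <- 1L
  expect_equal(init_weights(list(ex), alpha = 0.05), 1)
  # unknown pixels count toward the denominator only
  unk <- matrix(NA_integer_, 10, 10); unk[1:5] <- 1L
  expect_equal(init_weights(list(unk), alpha = 0.05), 1)
  expect_equal(init_weights(list(unk), alpha = 0.06), 0)
})

test_that("weight updates add chi at the misclassification boundary", {
  lab <- matrix(0L, 10, 10)
  pred10 <- matrix(FALSE, 10, 10); pred10[1:10] <- TRUE  # 10% wrong
  w <- update_weights(1, list(pred10), list(lab), alpha = 0.05, chi = 1)
  expect_equal(as.numeric(w), 2)
  perfect <- matrix(FALSE, 10, 10)
  expect_equal(as.numeric(update_weights(1, list(perfect), list(lab))), 1)
  pred5 <- matrix(FALSE, 10, 10); pred5[1:5] <- TRUE     # exactly alpha
  expect_equal(as.numeric(update_weights(1, list(pred5), list(lab))), 2)
  # ignored pixels are excluded from the error count
  lab_ig <- lab; lab_ig[1:10] <- NA_integer_
  expect_equal(as.numeric(update_weights(1, list(pred10), list(lab_ig))), 1)
})

test_that("weights never decrease across random update sequences", {
  withr::with_seed(2, {
    w <- rep(1, 5)
    labs <- replicate(5, matrix(sample(0:1, 64, TRUE), 8, 8),
                      simplify = FALSE)
    for (round in 1:4) {
      preds <- replicate(5, matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8),
                         simplify = FALSE)
      w2 <- update_weights(w, preds, labs, alpha = 0.05, chi = 0.5)
      expect_true(all(w2 >= w))
      w <- as.numeric(w2)
    }
  })
})

test_that("the ignore mask marks unknowns and excludes them from the loss", {
  lab <- matrix(c(1L, 0L, NA, NA), 2, 2)
  expect_identical(build_ignore_mask(lab), is.na(lab))
  expect_identical(build_ignore_mask(matrix(0L, 3, 3)),
                   matrix(FALSE, 3, 3))
  expect_identical(build_ignore_mask(matrix(NA_integer_, 3, 3)),
                   matrix(TRUE, 3, 3))

  # constant prediction on a half-masked tile: loss equals the loss of
  # the unmasked half alone
  full <- matrix(rep(c(1L, 0L), 32), 8, 8)
  half <- full; half[1:4, ] <- NA_integer_
  prob <- matrix(0.7, 8, 8)
  expect_equal(masked_pixel_loss(prob, half),
               masked_pixel_loss(prob[5:8, ], full[5:8, ]))
  expect_true(is.na(masked_pixel_loss(prob, matrix(NA_integer_, 8, 8))))
})

test_that("boosted augmentation emits ten seeded variants per boosted tile", {
  samples <- core_samples(.small_slide, core_row = 1L, M = 16L)[1:2]
  w0 <- c(1, 1)
  # only sample 1 is boosted
  out <- boosted_augment(samples, weights = c(2, 1), initial_weights = w0,
                         seed = 7)
  expect_length(out$samples, 2 + 10)
  expect_equal(out$weights, c(2, 1, rep(2, 10)))
  expect_true(all(vapply(out$samples[-(1:2)], `[[`, 0L,
                         "augmented_from") == 1L))

  again <- boosted_augment(samples, weights = c(2, 1), initial_weights = w0,
                           seed = 7)
  expect_identical(out, again)
  other <- boosted_augment(samples, weights = c(2, 1), initial_weights = w0,
                           seed = 8)
  expect_false(identical(out$samples[[3]]$tile$pixels,
                         other$samples[[3]]$tile$pixels))

  none <- boosted_augment(samples, weights = c(1, 1), initial_weights = w0)
  expect_length(none$samples, 2L)
})

test_that("masks and pixels share the geometric transform", {
  samples <- core_samples(.small_slide, core_row = 2L, M = 16L,
                          unknown_frac = 0.3)
  s <- samples[[1]]
  out <- boosted_augment(list(s), weights = 2, initial_weights = 1, seed = 1)
  # identify the vertical-flip variant (last op in the recipe)
  v <- out$samples[[length(out$samples)]]
  expect_identical(v$labels, s$labels[rev(seq_len(nrow(s$labels))), ])
  # right-angle rotations and flips are area-preserving for labels
  for (var in out$samples[-1]) {
    expect_identical(dim(var$labels), dim(s$labels))
    expect_identical(dim(var$tile$pixels), dim(s$tile$pixels))
  }
})

test_that("photometric jitter stays within the stated ranges", {
  expect_warning(augment_recipe(contrast_range = 0.5), "clamp")
  r <- suppressWarnings(augment_recipe(contrast_range = 0.5,
                                       brightness_range = 0.2))
  expect_equal(r$contrast_range, 0.20)
  expect_equal(r$brightness_range, 0.125)
})

test_that("boosting runs the schedule and refuses unlabeled input", {
  # near-noiseless slide: pixel classes are cleanly separable by stain
  sep <- generate_slide(small_spec(seed = 13, noise_sd = 0.005))
  samples <- core_samples(sep, core_row = 1L, M = 16L)
  cfg <- boost_config(U = 2L, seed = 3L)
  fit <- boost_fit(threshold_learner(), samples, cfg)
  expect_s3_class(fit, "boost_fit")
  expect_identical(ncol(fit$weight_history), 3L)
  # weights non-decreasing round over round
  expect_true(all(apply(fit$weight_history, 1, function(r) all(diff(r) >= 0))))
  # separable fixture: error does not grow from round 1 to round 2
  err <- colMeans(fit$mis_history)
  expect_lte(err[2], err[1] + 1e-9)

  # U = 1 is a single weighted fit
  fit1 <- boost_fit(threshold_learner(), samples, boost_config(U = 1L))
  expect_length(fit1$models, 1L)
  expect_identical(fit1$model, fit1$models[[1]])

  blank <- lapply(samples, function(s) {
    s$labels[] <- 0L
    s
  })
  expect_error(boost_fit(threshold_learner(), blank, cfg),
               "no supervised signal")
})

test_that("a misclassifying learner triggers boosting", {
  samples <- core_samples(.small_slide, core_row = 1L, M = 16L)
  fit <- boost_fit(pessimist_learner(), samples, boost_config(U = 2L))
  active <- fit$weight_history[, 1] > 0
  # every active tile has tumor fraction >= alpha, which the pessimist
  # misses entirely, so every active weight is incremented each round
  expect_true(all(fit$weight_history[active, 3] ==
                    fit$weight_history[active, 1] + 2))
})
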