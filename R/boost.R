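#' Weakly supervised boosting with attention reweighting
#'
#' Training tiles carry instance weights initialized from the fraction of
#' annotated-positive pixels (attention weighting): a tile enters the
#' first round with weight 1 iff its positive fraction reaches the
#' threshold alpha. After each round the weight of every tile whose
#' misclassified-pixel fraction reaches alpha is incremented by chi, and
#' boosted tiles (weight above their initial value) are expanded with a
#' deterministic set of geometric variants carrying seeded photometric
#' jitter. Unlabeled pixels are never used as negatives: an ignore mask
#' excludes them from losses and error fractions (focusing sampling).
#'
#' @name boost_train
NULL

#' Boosting configuration
#'
#' @param alpha attention threshold in (0, 1) (default 0.05).
#' @param chi weight increment per boosted round (> 0; default 1 so that
#'   weights read as counts of boosted rounds).
#' @param U number of boosting rounds (>= 1; default 3).
#' @param recipe augmentation recipe, see [augment_recipe()].
#' @param seed integer seed for the photometric jitter.
#' @return object of class `boost_config`.
#' @export
boost_config <- function(alpha = 0.05, chi = 1, U = 3L,
                         recipe = augment_recipe(), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, chi > 0, U >= 1)
  structure(list(alpha = alpha, chi = chi, U = as.integer(U),
                 recipe = recipe, seed = as.integer(seed)),
            class = "boost_config")
}

#' Augmentation recipe
#'
#' The geometric set applied to each boosted sample: five small rotations
#' in 5-degree steps, the right-angle rotations, and the two mirror flips
#' (10 variants). Each variant receives photometric jitter drawn uniformly
#' within the stated ranges: contrast and saturation within +/- 20%,
#' brightness within +/- 12.5%. Ranges wider than these are clamped with a
#' warning.
#'
#' @param small_rotations rotation angles in degrees.
#' @param right_angles right-angle rotations in degrees.
#' @param flips which mirror flips to apply.
#' @param contrast_range,saturation_range,brightness_range jitter
#'   half-ranges as fractions.
#' @return object of class `augment_recipe`.
#' @export
augment_recipe <- function(small_rotations = seq(5, 25, by = 5),
                           right_angles = c(90, 180, 270),
                           flips = c("horizontal", "vertical"),
                           contrast_range = 0.20,
                           saturation_range = 0.20,
                           brightness_range = 0.125) {
  clamp1 <- function(v, lim, what) {
    if (v > lim) {
      warning(sprintf("%s jitter range %.3f exceeds %.3f; clamping",
                      what, v, lim))
      lim
    } else v
  }
  structure(list(small_rotations = small_rotations,
                 right_angles = right_angles, flips = flips,
                 contrast_range = clamp1(contrast_range, 0.20, "contrast"),
                 saturation_range = clamp1(saturation_range, 0.20,
                                           "saturation"),
                 brightness_range = clamp1(brightness_range, 0.125,
                                           "brightness")),
            class = "augment_recipe")
}

# positive-pixel fraction of a label matrix (1 positive, 0 negative,
# NA unknown); denominator is the full tile area
positive_fraction <- function(labels) {
  sum(labels == 1L, na.rm = TRUE) / length(labels)
}

#' Initialize instance weights from sparse pixel annotations
#'
#' A tile's attention statistic is the fraction of its pixels annotated
#' positive (unknown pixels count as not positive, full tile area in the
#' denominator). The initial weight is 1 when the statistic reaches
#' `alpha`, else 0 — tiles without enough annotated tumor are excluded
#' from the first round.
#'
#' @param pixel_labels list of per-tile label matrices (1 positive, 0
#'   negative, NA unknown).
#' @param alpha attention threshold.
#' @return numeric weight vector.
#' @export
init_weights <- function(pixel_labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  vapply(pixel_labels, function(l) {
    if (positive_fraction(l) >= alpha) 1 else 0
  }, 0)
}

#' Misclassified-pixel fraction of a tile
#'
#' Pixels with unknown labels (the ignore mask) are excluded from the
#' error count; the denominator is the full tile area, matching the
#' attention statistic's scale.
#'
#' @param prediction integer/logical matrix of predicted positive pixels.
#' @param labels label matrix (1/0/NA).
#' @return fraction in `[0, 1]`.
#' @export
misclassified_fraction <- function(prediction, labels) {
  stopifnot(all(dim(prediction) == dim(labels)))
  known <- !is.na(labels)
  sum(prediction[known] != labels[known]) / length(labels)
}

#' Update instance weights from round predictions
#'
#' Weights of tiles whose misclassified fraction reaches `alpha` are
#' incremented by `chi`; all other weights are unchanged, so weights never
#' decrease across rounds.
#'
#' @param weights current weight vector.
#' @param predictions list of per-tile predicted positive-pixel matrices.
#' @param pixel_labels list of per-tile label matrices.
#' @param alpha attention threshold.
#' @param chi positive weight increment.
#' @return updated weight vector, with the per-tile misclassified
#'   fractions attached as attribute `"mis_fraction"`.
#' @export
update_weights <- function(weights, predictions, pixel_labels,
                           alpha = 0.05, chi = 1) {
  stopifnot(chi > 0, length(weights) == length(predictions),
            length(weights) == length(pixel_labels))
  mis <- mapply(misclassified_fraction, predictions, pixel_labels)
  out <- weights + chi * (mis >= alpha)
  attr(out, "mis_fraction") <- as.numeric(mis)
  out
}

#' Ignore mask for focusing sampling
#'
#' @param pixel_labels label matrix (1/0/NA).
#' @return logical matrix, TRUE exactly where the label is unknown.
#' @export
build_ignore_mask <- function(pixel_labels) {
  is.na(pixel_labels)
}

#' Pixel loss with ignore-mask exclusion
#'
#' Mean per-pixel loss over the pixels not excluded by the ignore mask.
#' `type = "ce"` is binary cross-entropy on the positive-class
#' probability; `type = "zero_one"` is the thresholded error rate.
#'
#' @param prob matrix of predicted positive-class probabilities.
#' @param labels label matrix (1/0/NA).
#' @param ignore_mask logical matrix; defaults to [build_ignore_mask()].
#' @param type loss type.
#' @return scalar loss; `NA` when every pixel is ignored.
#' @export
masked_pixel_loss <- function(prob, labels,
                              ignore_mask = build_ignore_mask(labels),
                              type = c("ce", "zero_one")) {
  type <- match.arg(type)
  use <- !ignore_mask & !is.na(labels)
  if (!any(use)) return(NA_real_)
  p <- pmin(pmax(prob[use], 1e-12), 1 - 1e-12)
  y <- labels[use]
  if (type == "ce") mean(-(y * log(p) + (1 - y) * log(1 - p)))
  else mean((p >= 0.5) != (y == 1L))
}

# ---- geometric ops ------------------------------------------------------

# nearest-neighbour rotation about the image centre; pixels falling
# outside the source get `fill`. Works for numeric, integer and NA-coded
# matrices, so pixels, labels and masks share one operator.
rotate_nn <- function(m, angle_deg, fill = 0) {
  if (angle_deg %% 360 == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  th <- -angle_deg * pi / 180  # inverse mapping
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sx <- cos(th) * gx - sin(th) * gy + cx
  sy <- sin(th) * gx + cos(th) * gy + cy
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- matrix(fill, h, w)
  out[cbind(rep(seq_len(h), times = w)[ok], rep(seq_len(w), each = h)[ok])] <-
    m[cbind(si[ok], sj[ok])]
  out
}

rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# apply one geometric op (list(kind, param)) to a matrix
apply_geom <- function(m, op, fill = 0) {
  switch(op$kind,
         rot_small = rotate_nn(m, op$param, fill = fill),
         rot90 = rot90k(m, op$param %/% 90L),
         fliph = flip_h(m),
         flipv = flip_v(m),
         stop("unknown geometric op"))
}

apply_geom_array <- function(px, op, fill = 0) {
  for (ch in seq_len(dim(px)[3])) px[, , ch] <- apply_geom(px[, , ch], op, fill)
  px
}

geom_ops <- function(recipe) {
  ops <- lapply(recipe$small_rotations,
                function(a) list(kind = "rot_small", param = a))
  ops <- c(ops, lapply(recipe$right_angles,
                       function(a) list(kind = "rot90", param = as.integer(a))))
  if ("horizontal" %in% recipe$flips) ops <- c(ops, list(list(kind = "fliph")))
  if ("vertical" %in% recipe$flips) ops <- c(ops, list(list(kind = "flipv")))
  ops
}

# photometric jitter with given factors; pixels only
jitter_pixels <- function(px, contrast, saturation, brightness) {
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  for (ch in 1:3) {
    v <- gray + saturation * (px[, , ch] - gray)   # saturation about gray
    v <- 0.5 + contrast * (v - 0.5)                # contrast about mid-gray
    px[, , ch] <- v * brightness
  }
  pmin(pmax(px, 0), 1)
}

#' Boosted data augmentation
#'
#' Samples whose current weight exceeds their initial weight are expanded
#' with the recipe's 10 geometric variants; each variant receives seeded
#' photometric jitter. Labels and ignore masks are transformed with the
#' identical geometric operator as the pixels (unknown fill), so geometry
#' stays consistent. Non-boosted samples pass through untouched. Output is
#' deterministic for a fixed seed.
#'
#' @param samples list of training samples, each a list with fields
#'   `tile` (a `tma_tile`) and `labels` (pixel label matrix, 1/0/NA).
#' @param weights current weight vector.
#' @param initial_weights weights at round 1 (same length); default all 1.
#' @param recipe an [augment_recipe()].
#' @param seed integer seed for the jitter draws.
#' @return list with `samples` (originals followed by variants) and
#'   `weights` (variants inherit their parent's weight).
#' @export
boosted_augment <- function(samples, weights,
                            initial_weights = rep(1, length(samples)),
                            recipe = augment_recipe(), seed = 1L) {
  stopifnot(length(samples) == length(weights),
            length(samples) == length(initial_weights))
  ops <- geom_ops(recipe)
  boosted <- which(weights > initial_weights)
  out <- samples
  out_w <- as.numeric(weights)
  withr::with_seed(seed, {
    for (i in boosted) {
      s <- samples[[i]]
      for (op in ops) {
        contrast <- 1 + stats::runif(1, -recipe$contrast_range,
                                     recipe$contrast_range)
        saturation <- 1 + stats::runif(1, -recipe$saturation_range,
                                       recipe$saturation_range)
        brightness <- 1 + stats::runif(1, -recipe$brightness_range,
                                       recipe$brightness_range)
        tile <- s$tile
        tile$pixels <- jitter_pixels(
          apply_geom_array(tile$pixels, op, fill = 0),
          contrast, saturation, brightness)
        labels <- apply_geom(s$labels, op, fill = NA_integer_)
        v <- s
        v$tile <- tile
        v$labels <- labels
        v$augmented_from <- i
        out[[length(out) + 1L]] <- v
        out_w <- c(out_w, weights[i])
      }
    }
  })
  list(samples = out, weights = out_w)
}

#' Run the U-round boosting schedule
#'
#' Each round fits the learner on the current weighted sample set,
#' predicts on the original tiles, updates weights by the misclassified
#' fraction rule, and expands boosted samples by augmentation for the next
#' round. The returned model is the final round's base model (sequential
#' refinement, not an ensemble vote).
#'
#' @param learner list with `fit(samples, weights) -> model` and
#'   `predict(model, tile) -> H x W x 3` probability array.
#' @param samples list of samples (fields `tile`, `labels`).
#' @param cfg a [boost_config()].
#' @return list of class `boost_fit`: `model` (round-U model), `models`
#'   (all rounds), `weight_history` (samples x rounds matrix, original
#'   samples only) and `mis_history`.
#' @export
boost_fit <- function(learner, samples, cfg = boost_config()) {
  stopifnot(is.function(learner$fit), is.function(learner$predict))
  n <- length(samples)
  labels <- lapply(samples, `[[`, "labels")
  w0 <- init_weights(labels, alpha = cfg$alpha)
  if (all(w0 == 0)) stop("no supervised signal: all initial weights are zero")
  weights <- w0
  cur <- list(samples = samples, weights = weights)
  weight_history <- matrix(NA_real_, n, cfg$U + 1L)
  weight_history[, 1] <- w0
  mis_history <- matrix(NA_real_, n, cfg$U)
  models <- vector("list", cfg$U)
  for (u in seq_len(cfg$U)) {
    model <- tryCatch(learner$fit(cur$samples, cur$weights),
                      error = function(e)
                        stop(sprintf("learner failed in round %d: %s",
                                     u, conditionMessage(e)), call. = FALSE))
    models[[u]] <- model
    preds <- lapply(samples, function(s) {
      p <- learner$predict(model, s$tile)
      class_map(p) > 1L
    })
    weights <- update_weights(weights, preds, labels,
                              alpha = cfg$alpha, chi = cfg$chi)
    mis_history[, u] <- attr(weights, "mis_fraction")
    weight_history[, u + 1L] <- weights
    if (u < cfg$U)
      cur <- boosted_augment(samples, as.numeric(weights),
                             initial_weights = w0, recipe = cfg$recipe,
                             seed = cfg$seed + u)
  }
  structure(list(model = models[[cfg$U]], models = models,
                 weight_history = weight_history,
                 mis_history = mis_history, config = cfg),
            class = "boost_fit")
}

#' Reference threshold learner
#'
#' A deliberately simple learner for fixtures and tests: it scans
#' candidate thresholds on the DAB-brown index and picks the one
#' minimizing the weighted, ignore-masked pixel error over the training
#' set; prediction emits one-hot 3-class maps (bright pixels background,
#' brown-above-threshold tumorlike, rest others).
#'
#' @param bg_threshold brightness above which a pixel is background.
#' @param n_candidates number of candidate thresholds scanned.
#' @return a learner list usable with [boost_fit()].
#' @export
threshold_learner <- function(bg_threshold = 0.88, n_candidates = 41L) {
  brown_index <- function(px) (px[, , 1] + px[, , 2]) / 2 - px[, , 3]
  list(
    fit = function(samples, weights) {
      vals <- numeric(0); ys <- integer(0); ws <- numeric(0)
      for (i in seq_along(samples)) {
        if (weights[i] <= 0) next
        s <- samples[[i]]
        known <- !is.na(s$labels)
        if (!any(known)) next
        vals <- c(vals, brown_index(s$tile$pixels)[known])
        ys <- c(ys, s$labels[known])
        ws <- c(ws, rep(weights[i], sum(known)))
      }
      if (length(vals) == 0L) stop("no labeled pixels with positive weight")
      cand <- stats::quantile(vals, probs = seq(0, 1,
                                                length.out = n_candidates),
                              names = FALSE)
      err <- vapply(cand, function(th)
        sum(ws * ((vals > th) != (ys == 1L))) / sum(ws), 0)
      list(threshold = cand[which.min(err)], bg_threshold = bg_threshold)
    },
    predict = function(model, tile) {
      px <- tile$pixels
      gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
      bg <- gray > model$bg_threshold
      tum <- !bg & brown_index(px) > model$threshold
      p <- array(0, c(dim(px)[1], dim(px)[2], 3))
      p[, , 1][bg] <- 1
      p[, , 3][tum] <- 1
      p[, , 2][!bg & !tum] <- 1
      p
    }
  )
}
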