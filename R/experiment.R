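#' End-to-end synthetic experiment
#'
#' Generates a batch of synthetic TMA slides, runs detection, tumor-tile
#' selection and treatment-effect prediction with the desk-scale reference
#' backends, and scores the result against the generator's ground truth.
#' This mirrors the full slide-to-decision pipeline: core detection at low
#' magnification, forward mapping to level 0, tile selection, backward
#' mapping to medium resolution, core-level classification and
#' evaluation.
#'
#' @name experiment
NULL

#' Match detections to ground-truth cores
#'
#' Greedy one-to-one matching by decreasing IoU at level 0.
#'
#' @param detections level-0 detection boxes.
#' @param truth_boxes level-0 ground-truth boxes.
#' @param iou_threshold minimum IoU for a match.
#' @return data frame: det_row, truth_row, truth_core_id, iou.
#' @export
match_detections <- function(detections, truth_boxes, iou_threshold = 0.5) {
  out <- data.frame(det_row = integer(), truth_row = integer(),
                    truth_core_id = character(), iou = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(detections) == 0L || nrow(truth_boxes) == 0L) return(out)
  m <- iou_matrix(detections, truth_boxes)
  repeat {
    best <- which(m == max(m), arr.ind = TRUE)[1, ]
    if (m[best[1], best[2]] < iou_threshold) break
    out <- rbind(out, data.frame(
      det_row = best[1], truth_row = best[2],
      truth_core_id = truth_boxes$core_id[best[2]],
      iou = m[best[1], best[2]], stringsAsFactors = FALSE))
    m[best[1], ] <- -1; m[, best[2]] <- -1
    if (all(m < 0)) break
  }
  out
}

#' Run the slide-to-decision pipeline on one slide
#'
#' @param slide output of [generate_slide()] (or a list with `pyramid`;
#'   `truth` optional, needed only for `segmenter = "oracle"`).
#' @param segmenter `"color"`, `"oracle"` or a segmenter function.
#' @param alpha tile qualification threshold.
#' @param tile_M tile size in level-0 pixels.
#' @param rho backward-mapping exponent.
#' @return list: `detections` (level-0 boxes), `cores` (per detected core:
#'   core_id, box and medium-resolution tumor tiles).
#' @export
process_slide <- function(slide, segmenter = "color", alpha = 0.05,
                          tile_M = 32L, rho = 3) {
  pyr <- slide$pyramid
  det <- detect_cores(pyr, backend = "classical")
  det0 <- forward_map(det, pyr)
  seg <- if (is.function(segmenter)) segmenter
  else switch(segmenter,
              color = segmenter_color(),
              oracle = segmenter_oracle(slide$truth, dim2(pyr$levels[[1]])),
              stop("unknown segmenter: ", segmenter))
  cores <- vector("list", nrow(det0))
  for (i in seq_len(nrow(det0))) {
    b <- det0[i, ]
    region <- extract_region(pyr, bbox(b$x, b$y, b$w, b$h, 0L), 0L)
    tiles <- select_tumor_tiles(region, seg, alpha = alpha, M = tile_M,
                                origin = c(b$x, b$y), core_id = b$core_id)
    tiles <- fetch_medium_res_tiles(tiles, pyr, b, rho = rho)
    cores[[i]] <- list(core_id = b$core_id, box = b, tiles = tiles)
  }
  list(detections = det0, cores = cores)
}

#' Detection, training and evaluation over a batch of synthetic slides
#'
#' Generates `n_slides` slides (seeds `seed`, `seed + 1`, ...), detects
#' and matches cores, selects tumor tiles, splits matched cores into
#' train/test, trains the reference logistic backend on the training
#' cores and evaluates core-level predictions on the test cores.
#'
#' @param n_slides number of slides (default 12, i.e. 720 cores with the
#'   default 6 x 10 grid).
#' @param seed base seed.
#' @param spec_args named list of overrides passed to [tma_spec()].
#' @param train_frac fraction of matched cores used for training (default
#'   0.66).
#' @param segmenter,alpha,tile_M,rho see [process_slide()].
#' @param delta decision threshold.
#' @return list: `recall` (detection recall at IoU 0.5), `auc`,
#'   `metrics` (at delta), `predictions` data frame, `n_cores_truth`,
#'   `n_cores_matched`.
#' @export
run_synthetic_experiment <- function(n_slides = 12L, seed = 1L,
                                     spec_args = list(),
                                     train_frac = 0.66,
                                     segmenter = "color", alpha = 0.05,
                                     tile_M = 32L, rho = 3, delta = 0.5) {
  all_cores <- list()
  labels <- integer(0)
  n_truth <- 0L
  recalls <- numeric(n_slides)
  for (s in seq_len(n_slides)) {
    spec <- do.call(tma_spec, c(spec_args, list(seed = seed + s - 1L)))
    slide <- generate_slide(spec, slide_id = sprintf("s%02d", s))
    res <- process_slide(slide, segmenter = segmenter, alpha = alpha,
                         tile_M = tile_M, rho = rho)
    truth_boxes <- slide$truth$boxes
    n_truth <- n_truth + nrow(truth_boxes)
    recalls[s] <- detection_recall(res$detections, truth_boxes, 0.5)
    mt <- match_detections(res$detections, truth_boxes, 0.5)
    lab_lookup <- stats::setNames(slide$truth$labels$outcome,
                                  slide$truth$labels$core_id)
    for (j in seq_len(nrow(mt))) {
      core <- res$cores[[mt$det_row[j]]]
      core$core_id <- sprintf("%s_%s", sprintf("s%02d", s),
                              mt$truth_core_id[j])
      all_cores[[length(all_cores) + 1L]] <- core
      labels <- c(labels, lab_lookup[[mt$truth_core_id[j]]])
    }
  }
  n <- length(all_cores)
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- max(1L, round(train_frac * n))
  train_idx <- idx[seq_len(n_train)]
  test_idx <- idx[-seq_len(n_train)]
  model <- train_effect_classifier(
    lapply(all_cores[train_idx], `[[`, "tiles"), labels[train_idx])
  backend <- effect_backend(model)
  preds <- do.call(rbind, lapply(test_idx, function(i)
    predict_core(all_cores[[i]]$tiles, backend, delta = delta,
                 core_id = all_cores[[i]]$core_id)))
  preds$truth <- labels[test_idx]
  auc <- if (length(unique(preds$truth)) == 2L)
    roc_auc(preds$beta, preds$truth)$auc else NA_real_
  metrics <- classification_metrics(
    confusion_counts(preds$decision, preds$truth))
  list(recall = mean(recalls), auc = auc, metrics = metrics,
       predictions = preds, n_cores_truth = n_truth, n_cores_matched = n)
}
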