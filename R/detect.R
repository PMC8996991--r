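#' TMA core detection
#'
#' Cores are located on a low-magnification pyramid level. Two backends are
#' provided: a classical detector (foreground thresholding + connected
#' components + circularity filtering) that runs on a CPU in seconds, and a
#' cascade orchestrator that composes pluggable per-stage box regressors
#' and classifiers under strictly increasing IoU thresholds, the
#' multistage refinement scheme used by cascade object detectors.
#'
#' @name core_detect
NULL

#' Intersection over union of two boxes
#'
#' @param a,b boxes as one-row data frames (see [bbox()]) or numeric
#'   vectors `c(x, y, w, h)`; must refer to the same level.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  av <- as_xywh(a); bv <- as_xywh(b)
  if (any(c(av[3:4], bv[3:4]) <= 0)) stop("degenerate box: w and h must be > 0")
  ix <- max(av[1], bv[1]); iy <- max(av[2], bv[2])
  ix2 <- min(av[1] + av[3], bv[1] + bv[3])
  iy2 <- min(av[2] + av[4], bv[2] + bv[4])
  inter <- max(0, ix2 - ix) * max(0, iy2 - iy)
  inter / (av[3] * av[4] + bv[3] * bv[4] - inter)
}

as_xywh <- function(b) {
  if (is.data.frame(b)) {
    stopifnot(nrow(b) == 1L)
    c(b$x, b$y, b$w, b$h)
  } else as.numeric(b[1:4])
}

# IoU matrix between two box data frames (rows of a x rows of b)
iou_matrix <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    out[i, j] <- iou(a[i, ], b[j, ])
  out
}

#' Cascade configuration
#'
#' @param num_stages number of refinement stages (eta).
#' @param iou_thresholds strictly increasing per-stage IoU thresholds in
#'   (0, 1); default the canonical `c(0.5, 0.6, 0.7)`.
#' @param lambda classification/localization trade-off weight (recorded,
#'   used by training backends).
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(num_stages = 3L,
                           iou_thresholds = c(0.5, 0.6, 0.7),
                           lambda = 1) {
  stopifnot(num_stages == length(iou_thresholds),
            all(iou_thresholds > 0), all(iou_thresholds < 1))
  if (num_stages > 1 && any(diff(iou_thresholds) <= 0))
    stop("iou_thresholds must be strictly increasing")
  structure(list(num_stages = as.integer(num_stages),
                 iou_thresholds = iou_thresholds, lambda = lambda),
            class = "cascade_config")
}

#' Label proposals against ground truth under an IoU threshold
#'
#' A proposal is positive iff its best IoU with any truth box reaches the
#' stage threshold; the index of the matched truth box is recorded.
#'
#' @param proposals,truth box data frames at the same level.
#' @param phi IoU threshold in (0, 1).
#' @return data frame: label (1 positive / 0 background), best_iou,
#'   matched (truth row index or NA).
#' @export
assign_stage_labels <- function(proposals, truth, phi) {
  stopifnot(phi > 0, phi < 1)
  if (nrow(proposals) == 0L)
    return(data.frame(label = integer(), best_iou = numeric(),
                      matched = integer()))
  if (nrow(truth) == 0L)
    return(data.frame(label = 0L, best_iou = 0,
                      matched = NA_integer_)[rep(1, nrow(proposals)), ])
  m <- iou_matrix(proposals, truth)
  best <- apply(m, 1L, max)
  who <- apply(m, 1L, which.max)
  pos <- best >= phi
  data.frame(label = as.integer(pos), best_iou = best,
             matched = ifelse(pos, who, NA_integer_))
}

#' Greedy non-maximum suppression
#'
#' @param boxes box data frame with a `score` column.
#' @param iou_threshold suppression threshold (default 0.3).
#' @return the surviving rows, highest score first.
#' @export
nms <- function(boxes, iou_threshold = 0.3) {
  if (nrow(boxes) <= 1L) return(boxes)
  ord <- order(boxes$score, decreasing = TRUE)
  keep <- logical(nrow(boxes))
  alive <- ord
  while (length(alive) > 0L) {
    i <- alive[1]
    keep[i] <- TRUE
    alive <- alive[-1]
    if (length(alive) > 0L) {
      ious <- vapply(alive, function(j) iou(boxes[i, ], boxes[j, ]), 0)
      alive <- alive[ious < iou_threshold]
    }
  }
  boxes[sort(which(keep)), , drop = FALSE]
}

#' Run boxes through a cascade of refinement stages
#'
#' Each stage is a list with a `regressor` `function(region, boxes) boxes`
#' and a `classifier` `function(region, boxes) scores`. Boxes pass through
#' all stages in order; when `truth` is supplied, proposals are relabelled
#' after every stage under that stage's IoU threshold and the labelling
#' history is attached as the `"stage_labels"` attribute. Final scores come
#' from the last stage's classifier and greedy NMS is applied last.
#'
#' @param region the image the stages may inspect.
#' @param boxes initial proposal boxes.
#' @param stages list of `num_stages` stage lists.
#' @param cfg a [cascade_config()].
#' @param truth optional ground-truth boxes for per-stage labelling.
#' @param nms_iou NMS threshold applied to the final boxes.
#' @return refined box data frame with a `score` column.
#' @export
cascade_refine <- function(region, boxes, stages, cfg = cascade_config(),
                           truth = NULL, nms_iou = 0.3) {
  stopifnot(length(stages) == cfg$num_stages)
  check_boxes(boxes)
  history <- vector("list", cfg$num_stages)
  cur <- boxes
  for (s in seq_len(cfg$num_stages)) {
    st <- stages[[s]]
    out <- st$regressor(region, cur)
    if (!is.data.frame(out) || nrow(out) != nrow(cur) ||
        any(out$w <= 0) || any(out$h <= 0))
      stop(sprintf("stage %d returned invalid boxes", s))
    cur <- out
    if (!is.null(truth))
      history[[s]] <- assign_stage_labels(cur, truth,
                                          cfg$iou_thresholds[s])
  }
  last <- stages[[cfg$num_stages]]
  cur$score <- as.numeric(last$classifier(region, cur))
  out <- nms(cur, iou_threshold = nms_iou)
  attr(out, "stage_labels") <- history
  out
}

#' Classical TMA core detector
#'
#' Background/foreground split by intensity threshold, connected
#' components, then filtering by area (within `[0.25, 4]` times the median
#' component area) and circularity `4 * pi * A / P^2 >= 0.6`; the
#' detection score is the circularity clipped to `[0, 1]`.
#'
#' @param level_image grayscale matrix or RGB array of the detection level.
#' @param threshold foreground threshold on mean intensity; pixels darker
#'   than this are tissue. `NULL` picks Otsu's threshold.
#' @param min_circularity circularity cut-off.
#' @param min_area absolute minimum component area in pixels.
#' @return detection data frame: core_id, level (filled by the caller; 0
#'   here), x, y, w, h, score. Empty data frame when nothing is found.
#' @export
detect_cores_classical <- function(level_image, threshold = NULL,
                                   min_circularity = 0.6, min_area = 16L) {
  gray <- if (length(dim(level_image)) == 3L)
    (level_image[, , 1] + level_image[, , 2] + level_image[, , 3]) / 3
  else level_image
  if (is.null(threshold)) {
    threshold <- tryCatch(EBImage::otsu(EBImage::Image(gray)),
                          error = function(e) 0.85)
    # degenerate all-background images make Otsu meaningless
    if (mean(gray < threshold) > 0.9 || mean(gray < threshold) == 0)
      threshold <- 0.85
  }
  fg <- gray < threshold
  empty <- data.frame(core_id = character(), level = integer(),
                      x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1,
                                           dimnames = list(NULL, names(feats)))
  area <- feats[, "s.area"]
  perim <- pmax(feats[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)
  med <- stats::median(area[area >= min_area])
  keep <- which(area >= min_area & area >= 0.25 * med & area <= 4 * med &
                  circ >= min_circularity)
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(k) {
    px <- which(labm == k, arr.ind = TRUE)
    y1 <- min(px[, 1]) - 1L; y2 <- max(px[, 1])
    x1 <- min(px[, 2]) - 1L; x2 <- max(px[, 2])
    data.frame(core_id = sprintf("det%03d", k), level = 0L,
               x = x1, y = y1, w = x2 - x1, h = y2 - y1,
               score = circ[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$y, out$x), , drop = FALSE]
}

#' Detect cores on a slide pyramid
#'
#' Runs the chosen backend on the detection level (smallest level whose
#' max dimension fits `max_dim`), drops detections below `min_score`, and
#' returns boxes at that level.
#'
#' @param pyr a `pyramid_image`.
#' @param backend `"classical"` or a `function(level_image)` returning a
#'   detection data frame.
#' @param min_score minimum detection score kept (default 0.5).
#' @param max_dim see [detection_level()].
#' @param ... passed to the backend.
#' @return detection data frame with the `level` column set.
#' @export
detect_cores <- function(pyr, backend = "classical", min_score = 0.5,
                         max_dim = 2048L, ...) {
  lev <- detection_level(pyr, max_dim)
  fn <- if (is.function(backend)) backend
  else switch(backend,
              classical = detect_cores_classical,
              stop("unknown backend: ", backend))
  det <- fn(pyr$levels[[lev + 1L]], ...)
  det <- det[det$score >= min_score, , drop = FALSE]
  det$level <- lev
  det$core_id <- sprintf("det%03d", seq_len(nrow(det)))
  rownames(det) <- NULL
  det
}

#' Detection recall against ground truth at an IoU threshold
#'
#' Each truth box is counted recalled when some detection overlaps it with
#' IoU at or above the threshold (greedy one-to-one matching by IoU).
#'
#' @param detections detection boxes at level 0.
#' @param truth_boxes ground-truth boxes at level 0.
#' @param iou_threshold matching threshold (default 0.5).
#' @return recall in `[0, 1]`.
#' @export
detection_recall <- function(detections, truth_boxes, iou_threshold = 0.5) {
  if (nrow(truth_boxes) == 0L) return(NA_real_)
  if (nrow(detections) == 0L) return(0)
  m <- iou_matrix(detections, truth_boxes)
  matched <- logical(nrow(truth_boxes))
  used <- logical(nrow(detections))
  repeat {
    m[used, ] <- -1; m[, matched] <- -1
    best <- which(m == max(m), arr.ind = TRUE)[1, ]
    if (m[best[1], best[2]] < iou_threshold) break
    used[best[1]] <- TRUE; matched[best[2]] <- TRUE
    if (all(matched) || all(used)) break
  }
  mean(matched)
}
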