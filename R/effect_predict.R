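#' Core-level treatment-effectiveness prediction
#'
#' Qualified tumor tiles selected at level 0 are fetched at a medium
#' magnification chosen by [backward_level()], scored by a pluggable
#' probabilistic classifier, aggregated into a core-level probability
#' beta, and thresholded at delta into Effective / Invalid.
#'
#' @name effect_predict
NULL

# downsample a logical mask by 2^l with area-preserving block means
downsample_mask <- function(mask, l) {
  m <- mask * 1
  for (i in seq_len(l)) m <- downsample2(m)
  m >= 0.5
}

#' Fetch selected tiles at the medium-resolution level
#'
#' The level is chosen per core from its level-0 extent via
#' [backward_level()]; each tile's footprint is extracted from that level
#' and its suppression mask is resampled (area-preserving block mean) so
#' the masked fraction is conserved. When the chosen level is 0 the tiles
#' are returned as-is.
#'
#' @param tiles list of suppressed tiles (with `keep_mask`), carrying
#'   absolute level-0 origins.
#' @param pyr the slide `pyramid_image`.
#' @param core_box one-row level-0 box of the core the tiles belong to.
#' @param rho resolution-budget exponent for [backward_level()].
#' @return list of tiles with `pixels`/`keep_mask` at the chosen level and
#'   a `level` field set.
#' @export
fetch_medium_res_tiles <- function(tiles, pyr, core_box, rho = 3) {
  l <- backward_level(core_box$w, core_box$h, rho = rho,
                      num_levels = n_levels(pyr))
  lapply(tiles, function(tl) {
    if (l == 0L) {
      tl$level <- 0L
      return(tl)
    }
    box <- bbox(tl$x, tl$y, tl$M, tl$M, level = 0L)
    px <- extract_region(pyr, box, target_level = l)
    mask <- downsample_mask(tl$keep_mask, l)
    d <- dim2(px)
    mask <- mask[seq_len(min(d[1], nrow(mask))),
                 seq_len(min(d[2], ncol(mask))), drop = FALSE]
    # re-apply suppression at the fetched level
    for (ch in seq_len(dim(px)[3])) {
      layer <- px[seq_len(nrow(mask)), seq_len(ncol(mask)), ch]
      layer[!mask] <- 0
      px[seq_len(nrow(mask)), seq_len(ncol(mask)), ch] <- layer
    }
    tl$pixels <- px
    tl$keep_mask <- mask
    tl$level <- l
    tl
  })
}

#' Aggregate tile probabilities into a core probability
#'
#' @param tile_probs numeric vector of per-tile Effective probabilities.
#' @param method `"mean"` (default), `"median"` or `"max"`.
#' @return scalar beta in `[0, 1]`.
#' @export
aggregate_beta <- function(tile_probs, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  if (length(tile_probs) == 0L) stop("no tile probabilities to aggregate")
  switch(method,
         mean = mean(tile_probs),
         median = stats::median(tile_probs),
         max = max(tile_probs))
}

#' Predict the treatment-effectiveness of one core
#'
#' Applies the classifier backend to every tile, aggregates to beta, and
#' decides Effective iff `beta >= delta`. A core with no qualified tumor
#' tiles is decided Invalid with beta 0 and flagged `no_tumor_tiles` so
#' whole-slide runs complete.
#'
#' @param tiles list of (medium-resolution) tumor tiles; may be empty.
#' @param classifier `function(tile) -> probability of Effective`.
#' @param delta decision threshold (default 0.5).
#' @param core_id identifier for the output row.
#' @param aggregate aggregation method, see [aggregate_beta()].
#' @return one-row data frame: core_id, beta, decision (1 Effective / 0
#'   Invalid), n_tiles_used, flags.
#' @export
predict_core <- function(tiles, classifier, delta = 0.5,
                         core_id = NA_character_, aggregate = "mean") {
  if (length(tiles) == 0L)
    return(data.frame(core_id = core_id, beta = 0, decision = 0L,
                      n_tiles_used = 0L, flags = "no_tumor_tiles",
                      stringsAsFactors = FALSE))
  probs <- vapply(tiles, function(tl) as.numeric(classifier(tl)), 0)
  if (any(probs < 0 | probs > 1 | is.na(probs)))
    stop("classifier returned a probability outside [0, 1]")
  beta <- aggregate_beta(probs, method = aggregate)
  data.frame(core_id = core_id, beta = beta,
             decision = as.integer(beta >= delta),
             n_tiles_used = length(tiles), flags = "",
             stringsAsFactors = FALSE)
}

#' Color/texture summary features of a tumor tile
#'
#' Means and SDs of the RGB channels and the DAB-brown index over the
#' unsuppressed pixels, plus the kept-pixel fraction. Used by the
#' reference logistic backend.
#'
#' @param tile a suppressed tile with a `keep_mask`.
#' @return named numeric vector of 9 features.
#' @export
effect_features <- function(tile) {
  keep <- tile$keep_mask
  if (is.null(keep)) keep <- matrix(TRUE, nrow(tile$pixels), ncol(tile$pixels))
  px <- tile$pixels
  if (!any(keep))
    return(c(mean_r = 0, mean_g = 0, mean_b = 0, mean_brown = 0,
             sd_r = 0, sd_g = 0, sd_b = 0, sd_brown = 0, kept_frac = 0))
  r <- px[, , 1][keep]; g <- px[, , 2][keep]; b <- px[, , 3][keep]
  brown <- (r + g) / 2 - b
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  c(mean_r = mean(r), mean_g = mean(g), mean_b = mean(b),
    mean_brown = mean(brown), sd_r = sd0(r), sd_g = sd0(g),
    sd_b = sd0(b), sd_brown = sd0(brown), kept_frac = mean(keep))
}

#' Train the reference logistic treatment-effect backend
#'
#' Fits a logistic regression of the core outcome on the tile
#' color/texture summaries; every tile inherits its core's label.
#' Separation warnings are suppressed: on cleanly separable synthetic
#' data the fitted probabilities saturate, which is fine for ranking.
#'
#' @param tile_sets list (one element per training core) of tile lists.
#' @param outcomes integer vector of core outcomes (1 Effective).
#' @return object of class `effect_classifier`.
#' @export
train_effect_classifier <- function(tile_sets, outcomes) {
  stopifnot(length(tile_sets) == length(outcomes))
  feats <- list(); ys <- integer(0)
  for (i in seq_along(tile_sets)) {
    for (tl in tile_sets[[i]]) {
      feats[[length(feats) + 1L]] <- effect_features(tl)
      ys <- c(ys, outcomes[i])
    }
  }
  if (length(feats) == 0L) stop("no tiles to train on")
  X <- do.call(rbind, feats)
  df <- as.data.frame(X)
  df$y <- ys
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  structure(list(fit = fit, feature_names = colnames(X)),
            class = "effect_classifier")
}

#' @export
predict.effect_classifier <- function(object, tile, ...) {
  f <- as.data.frame(t(effect_features(tile)))
  p <- stats::predict(object$fit, newdata = f, type = "response")
  # guard against numerically degenerate fits
  min(max(as.numeric(p), 0), 1)
}

#' Turn a trained effect classifier into a tile-probability backend
#'
#' @param model an `effect_classifier`.
#' @return `function(tile) -> probability`, suitable for [predict_core()].
#' @export
effect_backend <- function(model) {
  function(tile) predict(model, tile)
}
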