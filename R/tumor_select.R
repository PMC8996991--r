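#' Tumorlike tissue selection
#'
#' Each detected core is fetched at full resolution, tiled into M x M
#' patches, and every tile is scored by a pluggable segmenter into a
#' per-pixel probability map over three classes (0 background, 1 other
#' tissue, 2 tumorlike). The argmax class map drives suppression of
#' non-tumor pixels and a qualification rule keeps only tiles whose
#' tumorlike fraction exceeds the attention threshold alpha.
#'
#' @name tumor_select
NULL

#' Tile a core region into an M x M grid
#'
#' Tiles do not overlap; right/bottom edge tiles are padded with the
#' background value so every tile is exactly `M x M`. The tile count is
#' `ceiling(w / M) * ceiling(h / M)`.
#'
#' @param region level-0 raster of the core (matrix or H x W x C array).
#' @param M tile side in pixels (default 512, the standard patch size).
#' @param origin level-0 offset `c(x, y)` of the region, stored on each
#'   tile so tiles carry absolute coordinates.
#' @param core_id identifier propagated to the tiles.
#' @param pad_value background value used for edge padding.
#' @return list of tiles; each tile is a list with fields `core_id`,
#'   `tile_index`, `x`, `y` (absolute level-0 origin), `valid_w`,
#'   `valid_h` (unpadded extent) and `pixels` (`M x M x C`).
#' @export
tile_core <- function(region, M = 512L, origin = c(0, 0),
                      core_id = NA_character_, pad_value = 1) {
  d <- dim2(region)
  if (any(d == 0L)) stop("empty core region")
  nch <- if (length(dim(region)) == 3L) dim(region)[3] else 1L
  nx <- ceiling(d[2] / M); ny <- ceiling(d[1] / M)
  tiles <- vector("list", nx * ny)
  idx <- 0L
  for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
    idx <- idx + 1L
    x0 <- (tx - 1L) * M; y0 <- (ty - 1L) * M
    vw <- min(M, d[2] - x0); vh <- min(M, d[1] - y0)
    px <- array(pad_value, c(M, M, nch))
    if (nch == 1L) {
      px[seq_len(vh), seq_len(vw), 1] <-
        region[(y0 + 1):(y0 + vh), (x0 + 1):(x0 + vw)]
    } else {
      px[seq_len(vh), seq_len(vw), ] <-
        region[(y0 + 1):(y0 + vh), (x0 + 1):(x0 + vw), ]
    }
    tiles[[idx]] <- structure(
      list(core_id = core_id, tile_index = idx,
           x = origin[1] + x0, y = origin[2] + y0,
           valid_w = as.integer(vw), valid_h = as.integer(vh),
           M = as.integer(M), pixels = px),
      class = "tma_tile")
  }
  tiles
}

#' @export
print.tma_tile <- function(x, ...) {
  cat(sprintf("<tile %s #%d at (%d, %d), %d x %d px>\n",
              x$core_id, x$tile_index, x$x, x$y, x$M, x$M))
  invisible(x)
}

#' Per-pixel class map from a 3-class probability map
#'
#' The class of each pixel is the argmax over (background, others,
#' tumorlike); ties break toward the lowest class index.
#'
#' @param p `H x W x 3` probability array; per-pixel probabilities must sum
#'   to 1 within 1e-6.
#' @return integer `H x W` matrix with values in `{0, 1, 2}`.
#' @export
class_map <- function(p) {
  stopifnot(length(dim(p)) == 3L, dim(p)[3] == 3L)
  sums <- p[, , 1] + p[, , 2] + p[, , 3]
  if (any(abs(sums - 1) > 1e-6) || any(p < 0))
    stop("probabilities must be non-negative and sum to 1 per pixel")
  flat <- cbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
  kappa <- max.col(flat, ties.method = "first") - 1L
  matrix(kappa, dim(p)[1], dim(p)[2])
}

#' Suppress non-tumorlike pixels of a tile
#'
#' Pixels whose class-map value exceeds 1 (tumorlike) are kept; all other
#' pixels are set to the null value 0. A logical `keep_mask` field records
#' which pixels survived, so downstream code can distinguish suppressed
#' pixels from genuinely dark tissue. Idempotent for a fixed class map.
#'
#' @param tile a `tma_tile`.
#' @param kappa class map matching the tile dimensions.
#' @return the tile with suppressed `pixels` and a `keep_mask` field.
#' @export
suppress_non_tumor <- function(tile, kappa) {
  stopifnot(inherits(tile, "tma_tile"))
  if (!all(dim(kappa) == dim2(tile$pixels)))
    stop("class map dimensions do not match the tile")
  keep <- kappa > 1L
  px <- tile$pixels
  for (ch in seq_len(dim(px)[3])) {
    layer <- px[, , ch]
    layer[!keep] <- 0
    px[, , ch] <- layer
  }
  tile$pixels <- px
  tile$keep_mask <- keep
  tile$kappa <- kappa
  tile
}

#' Tile qualification rule
#'
#' Default mode: the tile qualifies iff the fraction of tumorlike pixels
#' (class-map value > 1) strictly exceeds `alpha`. Literal mode instead
#' thresholds the mean class-map value `sum(kappa) / card`, retaining the
#' printed form of the rule in which class codes enter the sum.
#'
#' @param kappa class map of the tile.
#' @param alpha qualification threshold in `[0, 1)` (default 0.05).
#' @param mode `"fraction"` (default) or `"literal"`.
#' @return `TRUE` when the tile qualifies.
#' @export
qualify_tile <- function(kappa, alpha = 0.05, mode = c("fraction", "literal")) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha < 1)
  stat <- if (mode == "fraction") mean(kappa > 1L) else mean(kappa)
  stat > alpha
}

#' Select tumorlike tiles of a core
#'
#' Composition of [tile_core()], the segmenter backend, [class_map()],
#' [suppress_non_tumor()] and [qualify_tile()]. Tiles come back ordered by
#' tile index; the result is reproducible for deterministic backends.
#'
#' @param region level-0 raster of the core.
#' @param segmenter `function(tile) -> H x W x 3` probability array.
#' @param alpha qualification threshold.
#' @param M tile size.
#' @param mode qualification mode, see [qualify_tile()].
#' @param origin,core_id passed to [tile_core()].
#' @return list of qualified, suppressed tiles; each gains a
#'   `tumor_fraction` field. Empty list when no tile qualifies.
#' @export
select_tumor_tiles <- function(region, segmenter, alpha = 0.05, M = 512L,
                               mode = "fraction", origin = c(0, 0),
                               core_id = NA_character_) {
  tiles <- tile_core(region, M = M, origin = origin, core_id = core_id)
  out <- list()
  for (tl in tiles) {
    p <- segmenter(tl)
    ok <- tryCatch({
      !is.null(dim(p)) && length(dim(p)) == 3L && dim(p)[3] == 3L &&
        all(dim(p)[1:2] == dim2(tl$pixels))
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("segmenter returned malformed output for tile %d",
                          tl$tile_index))
    kappa <- class_map(p)
    if (qualify_tile(kappa, alpha = alpha, mode = mode)) {
      tl <- suppress_non_tumor(tl, kappa)
      tl$tumor_fraction <- mean(kappa > 1L)
      out[[length(out) + 1L]] <- tl
    }
  }
  out
}

#' Ground-truth oracle segmenter
#'
#' Uses the synthetic slide's ground truth to emit one-hot probability
#' maps: tumor pixels get class 2, non-tumor pixels inside any core class
#' 1, and everything else class 0. Tiles must carry absolute level-0
#' origins.
#'
#' @param truth ground truth from [generate_slide()].
#' @param dims level-0 slide dimensions `c(H, W)`.
#' @return a segmenter `function(tile)`.
#' @export
segmenter_oracle <- function(truth, dims) {
  tumor <- truth_tumor_mask(truth, dims)
  core <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(truth$boxes))) {
    b <- truth$boxes[i, ]
    core[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)] <- TRUE
  }
  function(tile) {
    M <- tile$M
    tum <- matrix(FALSE, M, M); cor <- matrix(FALSE, M, M)
    vw <- min(tile$valid_w, dims[2] - tile$x)
    vh <- min(tile$valid_h, dims[1] - tile$y)
    if (vw > 0 && vh > 0) {
      tum[seq_len(vh), seq_len(vw)] <-
        tumor[(tile$y + 1):(tile$y + vh), (tile$x + 1):(tile$x + vw)]
      cor[seq_len(vh), seq_len(vw)] <-
        core[(tile$y + 1):(tile$y + vh), (tile$x + 1):(tile$x + vw)]
    }
    p <- array(0, c(M, M, 3))
    p[, , 3][tum] <- 1
    p[, , 2][cor & !tum] <- 1
    p[, , 1][!cor] <- 1
    p
  }
}

#' Color-threshold segmenter
#'
#' A simple stain-based reference backend for end-to-end CPU runs: bright
#' pixels are background, pixels with a DAB-brown color cast (red and
#' green high relative to blue) are tumorlike, the rest are other tissue.
#' Probabilities are one-hot.
#'
#' @param bg_threshold mean-intensity threshold above which a pixel is
#'   background.
#' @param brown_threshold brown-index threshold `( (R + G) / 2 - B )`
#'   above which a tissue pixel is called tumorlike.
#' @return a segmenter `function(tile)`.
#' @export
segmenter_color <- function(bg_threshold = 0.88, brown_threshold = 0.02) {
  function(tile) {
    px <- tile$pixels
    stopifnot(dim(px)[3] == 3L)
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    brown <- (px[, , 1] + px[, , 2]) / 2 - px[, , 3]
    bg <- gray > bg_threshold
    tum <- !bg & brown > brown_threshold
    oth <- !bg & !tum
    p <- array(0, dim = c(dim(px)[1], dim(px)[2], 3))
    p[, , 1][bg] <- 1
    p[, , 2][oth] <- 1
    p[, , 3][tum] <- 1
    p
  }
}
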