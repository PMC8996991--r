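#' Multiresolution image pyramids and level-to-level coordinate mapping
#'
#' A whole-slide image is handled as an ordered list of rasters, level 0
#' being the highest magnification and each further level a factor-2
#' downsample of the previous one, so that the dimensions of level m equal
#' `ceiling(dims_0 / 2^m)`. Bounding boxes are 0-based, top-left origin,
#' half-open: a box (x, y, w, h) covers pixel columns `[x, x+w)` and rows
#' `[y, y+h)` at its stated level.
#'
#' @name pyramid
NULL

#' Construct a pyramid image from explicit levels
#'
#' @param levels list of rasters (matrix for grayscale, or H x W x C array),
#'   ordered from level 0 (full resolution) downwards.
#' @return an object of class `pyramid_image`.
#' @export
pyramid_image <- function(levels) {
  if (!is.list(levels) || length(levels) < 1L)
    stop("a pyramid needs at least one level")
  for (m in seq_along(levels)[-1]) {
    d0 <- dim2(levels[[m - 1]])
    dm <- dim2(levels[[m]])
    if (!all(dm == ceiling(d0 / 2)))
      stop(sprintf("level %d dims (%d x %d) are not ceiling(previous / 2)",
                   m - 1L, dm[1], dm[2]))
  }
  structure(list(levels = levels), class = "pyramid_image")
}

#' @export
print.pyramid_image <- function(x, ...) {
  d0 <- dim2(x$levels[[1]])
  cat(sprintf("<pyramid_image: %d levels, level 0 = %d x %d px>\n",
              length(x$levels), d0[2], d0[1]))
  invisible(x)
}

n_levels <- function(pyr) length(pyr$levels)

# height/width of a raster regardless of channel count
dim2 <- function(img) dim(img)[1:2]

#' Downsample a raster by an exact factor of two
#'
#' 2x2 mean pooling; odd trailing rows/columns are handled by replicating
#' the last row/column so the output has `ceiling(dims / 2)` pixels.
#'
#' @param img matrix or H x W x C array with values in `[0, 1]`.
#' @return raster of half the size (per-axis ceiling).
#' @export
downsample2 <- function(img) {
  if (length(dim(img)) == 3L) {
    out <- vapply(seq_len(dim(img)[3]),
                  function(ch) downsample2(img[, , ch]),
                  matrix(0, ceiling(nrow(img) / 2), ceiling(ncol(img) / 2)))
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  if (h %% 2L == 1L) img <- rbind(img, img[h, , drop = FALSE])
  if (w %% 2L == 1L) img <- cbind(img, img[, w, drop = FALSE])
  odd_r <- seq(1L, nrow(img), by = 2L); odd_c <- seq(1L, ncol(img), by = 2L)
  (img[odd_r, odd_c, drop = FALSE] + img[odd_r + 1L, odd_c, drop = FALSE] +
     img[odd_r, odd_c + 1L, drop = FALSE] +
     img[odd_r + 1L, odd_c + 1L, drop = FALSE]) / 4
}

#' Build a pyramid by repeated factor-2 downsampling
#'
#' @param level0 full-resolution raster.
#' @param num_levels total number of levels (>= 1).
#' @return a `pyramid_image`.
#' @export
build_pyramid <- function(level0, num_levels) {
  stopifnot(num_levels >= 1)
  levels <- vector("list", num_levels)
  levels[[1]] <- level0
  for (m in seq_len(num_levels - 1L))
    levels[[m + 1L]] <- downsample2(levels[[m]])
  pyramid_image(levels)
}

#' Bounding box constructor
#'
#' @param x,y 0-based top-left pixel offsets.
#' @param w,h positive pixel extents (half-open box).
#' @param level pyramid level the coordinates refer to.
#' @param core_id optional identifier.
#' @return one-row data frame with columns core_id, level, x, y, w, h.
#' @export
bbox <- function(x, y, w, h, level = 0L, core_id = NA_character_) {
  if (any(w <= 0) || any(h <= 0)) stop("degenerate box: w and h must be > 0")
  data.frame(core_id = core_id, level = as.integer(level),
             x = x, y = y, w = w, h = h, stringsAsFactors = FALSE)
}

check_boxes <- function(boxes) {
  need <- c("level", "x", "y", "w", "h")
  if (!all(need %in% names(boxes)))
    stop("boxes need columns ", paste(need, collapse = ", "))
  if (any(boxes$w <= 0) || any(boxes$h <= 0))
    stop("degenerate box: w and h must be > 0")
  invisible(boxes)
}

#' Forward-map boxes from a low-magnification level to level 0
#'
#' All four box components are multiplied by `2^level`. When the pyramid is
#' supplied the result is clipped to the level-0 bounds.
#'
#' @param boxes data frame of boxes (see [bbox()]); all rows must share one
#'   level.
#' @param pyr optional `pyramid_image` used to validate the level and clip.
#' @return the boxes at level 0.
#' @export
forward_map <- function(boxes, pyr = NULL) {
  check_boxes(boxes)
  if (nrow(boxes) == 0L) return(boxes)
  xi <- unique(boxes$level)
  if (length(xi) != 1L) stop("all boxes must share one level")
  if (!is.null(pyr) && (xi < 0L || xi > n_levels(pyr) - 1L))
    stop(sprintf("level %d outside [0, %d]", xi, n_levels(pyr) - 1L))
  f <- 2^xi
  out <- boxes
  out$x <- boxes$x * f; out$y <- boxes$y * f
  out$w <- boxes$w * f; out$h <- boxes$h * f
  out$level <- 0L
  if (!is.null(pyr)) {
    d0 <- dim2(pyr$levels[[1]])
    out$x <- pmin(pmax(out$x, 0), d0[2])
    out$y <- pmin(pmax(out$y, 0), d0[1])
    out$w <- pmin(out$w, d0[2] - out$x)
    out$h <- pmin(out$h, d0[1] - out$y)
  }
  out
}

#' Pick the pyramid level for fetching medium-resolution tumor features
#'
#' For a core of level-0 extent `w0 x h0` the level is
#' `l = log2(w0 * h0 * 10^(-2 * rho)) / 2`, rounded to the nearest integer
#' and clamped to the valid level range. With the default `rho = 3`, a core
#' of `10^3 x 10^3` pixels maps to level 0; quadrupling the pixel count
#' raises the level by one.
#'
#' @param w0,h0 core extent in level-0 pixels (> 0).
#' @param rho resolution-budget exponent (default 3).
#' @param num_levels optional number of pyramid levels to clamp against.
#' @return integer level index (>= 0).
#' @export
backward_level <- function(w0, h0, rho = 3, num_levels = NULL) {
  if (any(w0 <= 0) || any(h0 <= 0)) stop("non-positive core dimensions")
  raw <- log2(w0 * h0 * 10^(-2 * rho)) / 2
  l <- as.integer(round(raw))
  l <- pmax(l, 0L)
  if (!is.null(num_levels)) l <- pmin(l, as.integer(num_levels) - 1L)
  l
}

#' Extract the footprint of a level-0 box at a chosen level
#'
#' The box is divided by `2^target_level` and rounded outward, then cropped
#' from that level (clipped to the image).
#'
#' @param pyr a `pyramid_image`.
#' @param box one-row box data frame at level 0.
#' @param target_level level index to extract from.
#' @return raster crop at `target_level`.
#' @export
extract_region <- function(pyr, box, target_level = 0L) {
  check_boxes(box)
  stopifnot(nrow(box) == 1L)
  if (box$level != 0L) stop("extract_region expects a level-0 box")
  if (target_level < 0L || target_level > n_levels(pyr) - 1L)
    stop("target_level outside pyramid")
  f <- 2^target_level
  x1 <- floor(box$x / f); y1 <- floor(box$y / f)
  x2 <- ceiling((box$x + box$w) / f); y2 <- ceiling((box$y + box$h) / f)
  img <- pyr$levels[[target_level + 1L]]
  d <- dim2(img)
  x1 <- max(x1, 0); y1 <- max(y1, 0)
  x2 <- min(x2, d[2]); y2 <- min(y2, d[1])
  if (x2 <= x1 || y2 <= y1) stop("box does not intersect the image")
  crop_raster(img, x1, y1, x2 - x1, y2 - y1)
}

# crop with 0-based half-open (x, y, w, h); no bounds checking
crop_raster <- function(img, x, y, w, h) {
  if (length(dim(img)) == 3L)
    img[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
  else
    img[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
}

#' Choose the detection level for a slide
#'
#' The smallest (highest-resolution) level whose largest dimension does not
#' exceed `max_dim` pixels; falls back to the top level.
#'
#' @param pyr a `pyramid_image`.
#' @param max_dim largest acceptable dimension at the detection level.
#' @return integer level index.
#' @export
detection_level <- function(pyr, max_dim = 2048L) {
  for (m in seq_len(n_levels(pyr))) {
    if (max(dim2(pyr$levels[[m]])) <= max_dim) return(m - 1L)
  }
  n_levels(pyr) - 1L
}

#' Read a pyramid from a directory of per-level PNG files
#'
#' Files must be named `level_0.png`, `level_1.png`, ...
#'
#' @param dir directory containing the level images.
#' @return a `pyramid_image`.
#' @export
read_pyramid <- function(dir) {
  files <- list.files(dir, pattern = "^level_\\d+\\.png$")
  if (length(files) == 0L) stop("no level_<m>.png files in ", dir)
  ord <- order(as.integer(sub("^level_(\\d+)\\.png$", "\\1", files)))
  levels <- lapply(files[ord], function(f) png::readPNG(file.path(dir, f)))
  pyramid_image(levels)
}

#' Write a pyramid as per-level PNG files
#'
#' @param pyr a `pyramid_image`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in seq_len(n_levels(pyr))) {
    img <- pyr$levels[[m]]
    img[] <- pmin(pmax(img, 0), 1)
    png::writePNG(img, file.path(dir, sprintf("level_%d.png", m - 1L)))
  }
  invisible(dir)
}
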