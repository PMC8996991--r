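# Shared fixtures, built in code at load time. Kept deliberately small so
# the unit suite stays fast; the end-to-end checks build full-size batches
# themselves.

small_spec <- function(seed = 1L, ...) {
  tma_spec(rows = 2L, cols = 3L, core_diameter_px = 32L, num_levels = 3L,
           seed = seed, ...)
}

# one small slide reused across read-only tests
.small_slide <- generate_slide(small_spec(seed = 42L))

# tiles + pixel labels for one core of a slide, for boosting tests;
# unknown_frac of the labeled pixels is blanked to NA to emulate sparse
# annotation
core_samples <- function(slide, core_row = 1L, M = 16L, unknown_frac = 0) {
  tm <- truth_tumor_mask(slide$truth, dim(slide$pyramid$levels[[1]])[1:2])
  b <- slide$truth$boxes[core_row, ]
  region <- extract_region(slide$pyramid, bbox(b$x, b$y, b$w, b$h, 0L), 0L)
  tiles <- tile_core(region, M = M, origin = c(b$x, b$y),
                     core_id = b$core_id)
  lapply(tiles, function(tl) {
    lab <- matrix(as.integer(tm[(tl$y + 1):(tl$y + M),
                                (tl$x + 1):(tl$x + M)]), M, M)
    if (unknown_frac > 0) {
      idx <- withr::with_seed(tl$tile_index,
                              sample(length(lab),
                                     round(unknown_frac * length(lab))))
      lab[idx] <- NA_integer_
    }
    list(tile = tl, labels = lab)
  })
}

# a learner that calls everything non-tumor; drives weight boosting
pessimist_learner <- function() {
  list(
    fit = function(samples, weights) list(),
    predict = function(model, tile) {
      d <- dim(tile$pixels)
      p <- array(0, c(d[1], d[2], 3))
      p[, , 1] <- 1
      p
    }
  )
}

random_boxes <- function(n, max_xy = 500, max_wh = 200, level = 0L) {
  data.frame(core_id = sprintf("b%04d", seq_len(n)), level = level,
             x = sample.int(max_xy, n), y = sample.int(max_xy, n),
             w = sample.int(max_wh, n), h = sample.int(max_wh, n),
             stringsAsFactors = FALSE)
}
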