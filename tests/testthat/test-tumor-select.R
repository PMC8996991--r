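test_that("tile counts follow the ceiling arithmetic", {
  reg <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  expect_length(tile_core(reg, M = 512), 4L)
  reg2 <- array(runif(512 * 1025 * 3), c(512, 1025, 3))
  tiles <- tile_core(reg2, M = 512)
  expect_length(tiles, 3L)
  expect_identical(tiles[[3]]$valid_w, 1L)
  expect_equal(dim(tiles[[3]]$pixels), c(512, 512, 3))
})

test_that("unpadded tile footprints partition the region", {
  withr::with_seed(5, {
    for (i in 1:20) {
      h <- sample(10:90, 1); w <- sample(10:90, 1); M <- sample(8:40, 1)
      reg <- matrix(runif(h * w), h, w)
      tiles <- tile_core(reg, M = M)
      cover <- matrix(0L, h, w)
      for (tl in tiles) {
        ys <- (tl$y + 1):(tl$y + tl$valid_h)
        xs <- (tl$x + 1):(tl$x + tl$valid_w)
        cover[ys, xs] <- cover[ys, xs] + 1L
      }
      expect_true(all(cover == 1L))
      expect_length(tiles, ceiling(w / M) * ceiling(h / M))
    }
  })
})

test_that("class_map takes the per-pixel argmax with low-index ties", {
  p <- array(0, c(1, 3, 3))
  p[1, 1, ] <- c(0.2, 0.3, 0.5)
  p[1, 2, ] <- c(0.4, 0.4, 0.2)
  p[1, 3, ] <- c(1 / 3, 1 / 3, 1 / 3)
  k <- class_map(p)
  expect_identical(as.integer(k), c(2L, 0L, 0L))
  bad <- array(0.5, c(2, 2, 3))
  expect_error(class_map(bad), "sum to 1")
})

test_that("suppression nulls exactly the non-tumor pixels and is idempotent", {
  tl <- tile_core(array(runif(8 * 8 * 3, 0.2, 0.9), c(8, 8, 3)), M = 8)[[1]]
  all_tumor <- matrix(2L, 8, 8)
  expect_equal(suppress_non_tumor(tl, all_tumor)$pixels, tl$pixels)
  all_bg <- matrix(0L, 8, 8)
  expect_true(all(suppress_non_tumor(tl, all_bg)$pixels == 0))
  checker <- matrix(rep(c(0L, 2L), length.out = 64), 8, 8)
  sup <- suppress_non_tumor(tl, checker)
  expect_identical(sum(sup$pixels[, , 1] == 0), 32L)
  expect_equal(suppress_non_tumor(sup, checker)$pixels, sup$pixels)
  expect_error(suppress_non_tumor(tl, matrix(0L, 4, 4)), "dimensions")
})

test_that("qualification is strict and supports the literal mode", {
  k <- matrix(0L, 10, 10)
  k[1:6] <- 2L                      # 6% tumorlike
  expect_true(qualify_tile(k, alpha = 0.05))
  expect_false(qualify_tile(matrix(0L, 10, 10), alpha = 0.05))
  k5 <- matrix(0L, 10, 10); k5[1:5] <- 2L   # exactly alpha
  expect_false(qualify_tile(k5, alpha = 0.05))
  # literal mode sums class codes: 5 pixels of class 2 -> mean 0.10 > 0.05
  expect_true(qualify_tile(k5, alpha = 0.05, mode = "literal"))
})

test_that("lowering alpha never drops a qualified tile", {
  withr::with_seed(6, {
    qual <- t(vapply(1:50, function(i) {
      k <- matrix(sample(0:2, 100, replace = TRUE,
                         prob = c(0.5, 0.2, 0.3)), 10, 10)
      c(hi = qualify_tile(k, alpha = 0.2),
        lo = qualify_tile(k, alpha = 0.05))
    }, c(hi = TRUE, lo = TRUE)))
  })
  expect_true(any(qual[, "hi"]))          # the property is exercised
  expect_true(all(!qual[, "hi"] | qual[, "lo"]))
})

test_that("oracle-backed selection equals a brute-force recount", {
  sl <- .small_slide
  d0 <- dim(sl$pyramid$levels[[1]])[1:2]
  seg <- segmenter_oracle(sl$truth, d0)
  tm <- truth_tumor_mask(sl$truth, d0)
  M <- 16L
  for (alpha in c(0, 0.05, 0.2)) {
    for (i in seq_len(nrow(sl$truth$boxes))) {
      b <- sl$truth$boxes[i, ]
      region <- extract_region(sl$pyramid, bbox(b$x, b$y, b$w, b$h, 0L), 0L)
      sel <- select_tumor_tiles(region, seg, alpha = alpha, M = M,
                                origin = c(b$x, b$y), core_id = b$core_id)
      got <- vapply(sel, `[[`, 0L, "tile_index")
      # brute-force: true tumor fraction of every tile footprint
      tiles <- tile_core(region, M = M, origin = c(b$x, b$y))
      want <- vapply(tiles, function(tl) {
        frac <- sum(tm[(tl$y + 1):(tl$y + tl$valid_h),
                       (tl$x + 1):(tl$x + tl$valid_w)]) / (M * M)
        frac > alpha
      }, TRUE)
      expect_identical(got, which(want))
    }
  }
})

test_that("a tumor-free core yields no tiles and alpha = 0 keeps any tumor", {
  blank_truth <- list(boxes = bbox(0, 0, 32, 32, core_id = "c1"),
                      masks = list(c1 = matrix(FALSE, 32, 32)),
                      labels = data.frame(core_id = "c1", slide_id = "s",
                                          outcome = 0L))
  seg <- segmenter_oracle(blank_truth, c(32, 32))
  region <- array(0.5, c(32, 32, 3))
  expect_length(select_tumor_tiles(region, seg, alpha = 0.05, M = 16), 0L)

  one_px <- blank_truth
  one_px$masks$c1[5, 5] <- TRUE
  seg2 <- segmenter_oracle(one_px, c(32, 32))
  sel <- select_tumor_tiles(region, seg2, alpha = 0, M = 16)
  expect_length(sel, 1L)
  expect_identical(sel[[1]]$tile_index, 1L)
})

test_that("malformed segmenter output names the offending tile", {
  region <- array(0.5, c(16, 16, 3))
  bad <- function(tile) matrix(1, 16, 16)
  expect_error(select_tumor_tiles(region, bad, M = 16), "tile 1")
})

test_that("the color segmenter separates background, tissue and stain", {
  tl <- tile_core(array(0, c(4, 4, 3)), M = 4)[[1]]
  px <- array(0, c(4, 4, 3))
  px[1, 1, ] <- c(0.95, 0.95, 0.95)  # background
  px[2, 2, ] <- c(0.74, 0.62, 0.78)  # counterstained tissue
  px[3, 3, ] <- c(0.82, 0.63, 0.55)  # brown tumorlike
  tl$pixels <- px
  k <- class_map(segmenter_color()(tl))
  expect_identical(k[1, 1], 0L)
  expect_identical(k[2, 2], 1L)
  expect_identical(k[3, 3], 2L)
})
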