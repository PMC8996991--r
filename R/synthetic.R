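#' Synthetic tissue-microarray slides, training traces and survival records
#'
#' The generator emulates the data shape the rest of the pipeline assumes:
#' a TMA slide is a grid of circular immunostained cores on a bright
#' background; each core contains a contiguous tumor-textured region whose
#' DAB-brown staining intensity carries the core-level treatment outcome
#' (Effective vs Invalid) at a configurable effect size. Everything is
#' seeded and bit-reproducible.
#'
#' @name synthetic_tma
NULL

#' Specification of a synthetic TMA slide
#'
#' Defaults describe the desk-scale study condition used throughout the
#' package: a 6 x 10 grid of 64 px cores (so 12 slides give 720 cores), a
#' 57.2% Effective class prevalence, and an outcome effect of two noise
#' standard deviations on the mean brown-channel intensity of the tumor
#' region.
#'
#' @param rows,cols grid layout of cores.
#' @param core_diameter_px core diameter in level-0 pixels.
#' @param num_levels number of pyramid levels (>= 1).
#' @param tumor_fraction_range range of the per-core tumor area fraction
#'   (fraction of the core disc).
#' @param effect_size mean brown-channel shift between outcome classes, in
#'   units of the pixel noise SD (non-negative).
#' @param effective_prob probability that a core is labelled Effective.
#' @param noise_sd pixel noise SD on each channel.
#' @param spacing_factor core-centre spacing as a multiple of the diameter;
#'   must leave room for the 10% grid jitter without core overlap.
#' @param seed integer seed.
#' @return object of class `tma_spec`.
#' @export
tma_spec <- function(rows = 6L, cols = 10L, core_diameter_px = 64L,
                     num_levels = 3L,
                     tumor_fraction_range = c(0.25, 0.6),
                     effect_size = 2, effective_prob = 0.572,
                     noise_sd = 0.05, spacing_factor = 1.5, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 1, num_levels >= 1,
            core_diameter_px >= 8, effect_size >= 0,
            effective_prob >= 0, effective_prob <= 1, noise_sd >= 0,
            length(tumor_fraction_range) == 2,
            all(tumor_fraction_range >= 0), all(tumor_fraction_range <= 1))
  spacing <- ceiling(spacing_factor * core_diameter_px)
  jitter_max <- floor(0.1 * spacing)
  # cores may approach each other by 2 * jitter; reject overlapping geometry
  if (spacing - 2 * jitter_max < core_diameter_px)
    stop("cores would overlap: increase spacing_factor or shrink cores")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 core_diameter_px = as.integer(core_diameter_px),
                 num_levels = as.integer(num_levels),
                 tumor_fraction_range = tumor_fraction_range,
                 effect_size = effect_size, effective_prob = effective_prob,
                 noise_sd = noise_sd, spacing = as.integer(spacing),
                 jitter_max = as.integer(jitter_max),
                 seed = as.integer(seed)),
            class = "tma_spec")
}

# smooth a matrix with a box kernel (odd size), replicate edges
smooth_field <- function(m, k) {
  k <- as.integer(k) + as.integer(k %% 2L == 0L)
  kern <- matrix(1, k, k) / (k * k)
  as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
}

# band-limited random blob mask inside a disc, hitting a target fraction
# of the disc area
tumor_blob <- function(d, target_frac) {
  field <- matrix(stats::rnorm(d * d), d, d)
  field <- smooth_field(field, max(3L, round(d / 6)))
  cx <- (d + 1) / 2
  dist2 <- outer(seq_len(d) - cx, seq_len(d) - cx,
                 function(a, b) a^2 + b^2)
  disc <- dist2 <= (d / 2)^2
  # bias the field toward the centre so the blob is contiguous-ish
  field <- field - sqrt(dist2) / d
  thr <- stats::quantile(field[disc], probs = 1 - target_frac, names = FALSE)
  blob <- field > thr & disc
  blob
}

#' Generate a synthetic TMA slide with ground truth
#'
#' Cores are laid on a `rows x cols` grid with uniform jitter of at most
#' 10% of the core spacing. Each core carries a binary outcome drawn with
#' probability `effective_prob`; the outcome shifts the mean brown-channel
#' intensity of the core's tumor region by `effect_size * noise_sd`, on top
#' of a per-core staining intercept (SD `0.5 * noise_sd`) and i.i.d. pixel
#' noise (SD `noise_sd`). Pyramid levels are factor-2 downsamples of
#' level 0. Identical seeds give bit-identical output.
#'
#' @param spec a [tma_spec()].
#' @param slide_id identifier stored with the cores.
#' @return list with elements `pyramid` (a `pyramid_image`) and `truth`
#'   (list: `boxes` level-0 box data frame, `masks` per-core binary tumor
#'   masks, `labels` data frame core_id/slide_id/outcome).
#' @export
generate_slide <- function(spec, slide_id = "slide1") {
  stopifnot(inherits(spec, "tma_spec"))
  withr::with_seed(spec$seed, generate_slide_impl(spec, slide_id))
}

generate_slide_impl <- function(spec, slide_id) {
  d <- spec$core_diameter_px
  sp <- spec$spacing
  W <- sp * spec$cols + sp
  H <- sp * spec$rows + sp
  # background: bright slide glass with faint noise
  img <- array(stats::rnorm(H * W * 3, 0, spec$noise_sd / 4), c(H, W, 3))
  img <- img + rep(c(0.94, 0.93, 0.95), each = H * W)

  tissue <- c(0.74, 0.62, 0.78)          # hematoxylin-like counterstain
  brown_vec <- c(0.18, 0.02, -0.28)      # DAB-brown direction in RGB

  n <- spec$rows * spec$cols
  boxes <- NULL
  masks <- vector("list", n)
  outcome <- integer(n)
  core_ids <- sprintf("%s_core%03d", slide_id, seq_len(n))
  idx <- 0L
  for (r in seq_len(spec$rows)) for (cc in seq_len(spec$cols)) {
    idx <- idx + 1L
    jx <- sample.int(2L * spec$jitter_max + 1L, 1L) - spec$jitter_max - 1L
    jy <- sample.int(2L * spec$jitter_max + 1L, 1L) - spec$jitter_max - 1L
    cx <- sp * cc + jx   # centre, 0-based-ish; box below keeps it inside
    cy <- sp * r + jy
    x0 <- cx - d %/% 2; y0 <- cy - d %/% 2
    lab <- stats::rbinom(1L, 1L, spec$effective_prob)
    outcome[idx] <- lab

    tf <- stats::runif(1L, spec$tumor_fraction_range[1],
                       spec$tumor_fraction_range[2])
    blob <- tumor_blob(d, tf)
    cxl <- (d + 1) / 2
    dist2 <- outer(seq_len(d) - cxl, seq_len(d) - cxl,
                   function(a, b) a^2 + b^2)
    disc <- dist2 <= (d / 2)^2

    # per-core staining heterogeneity + outcome effect on the brown mean
    brown0 <- 0.45 + stats::rnorm(1L, 0, 0.5 * spec$noise_sd)
    brown <- brown0 + lab * spec$effect_size * spec$noise_sd
    patch <- array(stats::rnorm(d * d * 3, 0, spec$noise_sd), c(d, d, 3))
    for (ch in 1:3) {
      base <- tissue[ch] + patch[, , ch]
      base[blob] <- base[blob] + brown * brown_vec[ch] +
        0.05 * brown_vec[ch] * smooth_field(matrix(stats::rnorm(d * d), d, d),
                                            3L)[blob]
      layer <- img[(y0 + 1):(y0 + d), (x0 + 1):(x0 + d), ch]
      layer[disc] <- base[disc]
      img[(y0 + 1):(y0 + d), (x0 + 1):(x0 + d), ch] <- layer
    }
    boxes <- rbind(boxes, bbox(x0, y0, d, d, level = 0L,
                               core_id = core_ids[idx]))
    masks[[idx]] <- blob
  }
  img[] <- pmin(pmax(img, 0), 1)
  truth <- list(boxes = boxes, masks = stats::setNames(masks, core_ids),
                labels = data.frame(core_id = core_ids, slide_id = slide_id,
                                    outcome = outcome,
                                    stringsAsFactors = FALSE))
  list(pyramid = build_pyramid(img, spec$num_levels), truth = truth)
}

#' Full-slide binary tumor mask from ground truth
#'
#' @param truth ground-truth list from [generate_slide()].
#' @param dims level-0 dimensions `c(H, W)`.
#' @return logical H x W matrix, TRUE on tumor pixels.
#' @export
truth_tumor_mask <- function(truth, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(truth$boxes))) {
    b <- truth$boxes[i, ]
    sub <- m[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    m[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)] <-
      sub | truth$masks[[b$core_id]]
  }
  m
}

#' Generate a synthetic training trace
#'
#' Loss follows a linear descent that flattens exactly at `plateau_start`;
#' the F-measure rises with the matching plateau. Both series are sampled
#' on an evaluation grid of `eval_period` iterations and perturbed with
#' Gaussian noise of SD `noise_sd`.
#'
#' @param num_iters final training iteration (> plateau_start).
#' @param plateau_start iteration at which both curves flatten.
#' @param noise_sd non-negative noise SD added to both series.
#' @param seed integer seed.
#' @param eval_period evaluation grid spacing in iterations.
#' @param loss_init,loss_floor loss endpoints of the descent.
#' @param f_init,f_max F-measure endpoints of the rise.
#' @return object of class `training_trace` (see [training_trace()]).
#' @export
generate_trace <- function(num_iters, plateau_start, noise_sd = 0, seed = 1L,
                           eval_period = 1000L, loss_init = 2, loss_floor = 0.1,
                           f_init = 0.3, f_max = 0.9) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (plateau_start >= num_iters) stop("plateau_start must be < num_iters")
  k <- seq(eval_period, num_iters, by = eval_period)
  prog <- pmin(k / plateau_start, 1)
  loss <- loss_floor + (loss_init - loss_floor) * (1 - prog)
  fm <- f_init + (f_max - f_init) * prog
  withr::with_seed(seed, {
    loss <- pmax(loss + stats::rnorm(length(k), 0, noise_sd), 0)
    fm <- pmin(pmax(fm + stats::rnorm(length(k), 0, noise_sd), 0), 1)
  })
  training_trace(k, loss, fm)
}

#' Generate synthetic two-group survival records
#'
#' Event times are exponential; group 1 ("effective") has hazard
#' `hazard_ratio` times the group-0 baseline. The default baseline gives a
#' 24-month median progression-free survival in the invalid group. Optional
#' uniform censoring on `[0, censor_max]`.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param hazard_ratio positive hazard ratio of group 1 vs group 0.
#' @param seed integer seed.
#' @param baseline_hazard events per month in group 0.
#' @param censor_max upper bound of uniform censoring times, or `NULL` for
#'   no censoring.
#' @return data frame: id, time (months), event (1 = progressed), group.
#' @export
generate_survival <- function(n_per_group, hazard_ratio = 0.18, seed = 1L,
                              baseline_hazard = log(2) / 24,
                              censor_max = NULL) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  withr::with_seed(seed, {
    n <- n_per_group
    t0 <- stats::rexp(n, rate = baseline_hazard)
    t1 <- stats::rexp(n, rate = baseline_hazard * hazard_ratio)
    time <- c(t0, t1)
    event <- rep(1L, 2L * n)
    if (!is.null(censor_max)) {
      cens <- stats::runif(2L * n, 0, censor_max)
      event <- as.integer(time <= cens)
      time <- pmin(time, cens)
    }
    data.frame(id = sprintf("s%03d", seq_len(2L * n)),
               time = time, event = event,
               group = rep(0:1, each = n), stringsAsFactors = FALSE)
  })
}

#' Write a synthetic slide and its ground truth to disk
#'
#' The pyramid goes to `level_<m>.png` files, boxes/ids/labels to
#' `truth.json`, per-core tumor masks to `mask_<core_id>.png`, and labels
#' to `labels.csv` (core_id, slide_id, outcome).
#'
#' @param slide result of [generate_slide()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pyramid(slide$pyramid, dir)
  truth <- slide$truth
  jsonlite::write_json(list(boxes = truth$boxes, labels = truth$labels),
                       file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(truth$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  for (cid in names(truth$masks))
    png::writePNG(truth$masks[[cid] ] * 1,
                  file.path(dir, sprintf("mask_%s.png", cid)))
  invisible(dir)
}
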