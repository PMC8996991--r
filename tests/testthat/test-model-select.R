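test_that("finite derivatives reproduce difference-calculus identities", {
  const <- rep(3, 10)
  d <- finite_derivatives(const)
  expect_true(all(d$first == 0) && all(d$second == 0))
  lin <- 2 + 0.5 * (0:9)
  d <- finite_derivatives(lin)
  expect_equal(d$first, rep(0.5, 9))
  expect_equal(d$second, rep(0, 8))
  quad <- (0:9)^2
  expect_equal(finite_derivatives(quad)$second, rep(2, 8))
  expect_error(finite_derivatives(c(1, 2)), "at least 3")
})

test_that("stable-window detection agrees with a brute-force window scan", {
  brute <- function(first, second, bound, run_length) {
    n <- length(second)
    ok <- abs(first[seq_len(n)]) <= bound & abs(second) <= bound
    for (i in seq_len(n - run_length + 1L)) {
      if (all(ok[i:(i + run_length - 1L)])) return(i)
    }
    NA_integer_
  }
  withr::with_seed(12, {
    for (rep in 1:100) {
      s <- cumsum(rnorm(sample(6:30, 1), sd = 0.5))
      d <- finite_derivatives(s)
      bound <- runif(1, 0.05, 1.5)
      rl <- sample(1:4, 1)
      expect_identical(find_stable_window(d$first, d$second, bound, rl),
                       brute(d$first, d$second, bound, rl))
    }
  })
})

test_that("steep monotone descent yields no stable window", {
  s <- seq(100, 10, by = -10)
  d <- finite_derivatives(s)
  expect_true(is.na(find_stable_window(d$first, d$second, 0.003, 3)))
})

test_that("early stop fires on flat series and falls back otherwise", {
  iters <- seq(1000, 10000, by = 1000)
  flat <- rep(0.8, 10)
  d <- finite_derivatives(flat)
  res <- early_stop_check(d$first, d$second, iters, tau = 0.1, run_length = 3)
  expect_true(res$early_stopped)
  expect_identical(res$ke, 3000)          # end of the first full run
  withr::with_seed(1, noisy <- runif(10))
  dn <- finite_derivatives(noisy)
  res2 <- early_stop_check(dn$first, dn$second, iters, tau = 1e-9)
  expect_false(res2$early_stopped)
  expect_identical(res2$ke, 10000)
  # an infinite bound stops at the earliest possible run
  res3 <- early_stop_check(dn$first, dn$second, iters, tau = Inf,
                           run_length = 3)
  expect_true(res3$early_stopped)
  expect_identical(res3$ke, 3000)
})

test_that("checkpoint choice prefers the latest of tied maxima", {
  tr <- training_trace(1:4 * 1000, rep(1, 4), c(0.5, 0.9, 0.7, 0.9))
  expect_identical(select_model(tr, 1000, 4000), 4000)
  tr2 <- training_trace(1:4 * 1000, rep(1, 4), c(0.5, 0.9, 0.7, 0.8))
  expect_identical(select_model(tr2, 1000, 4000), 2000)
  expect_error(select_model(tr, 5000, 6000), "empty")
})

test_that("selection agrees with an exhaustive scan on random traces", {
  exhaustive <- function(trace, ks, ke) {
    best_i <- NA; best_f <- -Inf
    for (j in seq_along(trace$iteration)) {
      it <- trace$iteration[j]
      if (it < ks || it > ke) next
      if (trace$f_measure[j] >= best_f) {   # >= keeps the later iteration
        best_f <- trace$f_measure[j]
        best_i <- it
      }
    }
    best_i
  }
  withr::with_seed(21, {
    for (rep in 1:300) {
      n <- sample(4:25, 1)
      tr <- training_trace(seq_len(n) * 1000, runif(n, 0, 2),
                           round(runif(n), 2))   # rounding forces ties
      ks_i <- sample.int(n, 1)
      ke_cand <- seq(ks_i, n)
      ke_i <- ke_cand[sample.int(length(ke_cand), 1)]
      ks <- ks_i * 1000; ke <- ke_i * 1000
      expect_identical(select_model(tr, ks, ke), exhaustive(tr, ks, ke))
    }
  })
})

test_that("the full procedure recovers a constructed plateau", {
  for (noise in c(0, 1e-4)) {
    tr <- generate_trace(20000, 5000, noise_sd = noise, seed = 5)
    res <- select_checkpoint(tr)
    expect_true(res$loss_converged)
    expect_lte(abs(res$ks - 5000), 1000)
    expect_gte(res$i_star, res$ks)
    expect_lte(res$i_star, res$ke)
    # selected F-measure dominates the window
    in_win <- tr$iteration >= res$ks & tr$iteration <= res$ke
    expect_gte(tr$f_measure[tr$iteration == res$i_star],
               max(tr$f_measure[in_win]))
  }
})

test_that("widening the window never lowers the selected F-measure", {
  withr::with_seed(9, {
    for (rep in 1:30) {
      n <- 15
      tr <- training_trace(seq_len(n) * 1000, runif(n, 0, 2), runif(n))
      f_at <- function(i) tr$f_measure[tr$iteration == i]
      narrow <- f_at(select_model(tr, 5000, 9000))
      wide <- f_at(select_model(tr, 3000, 12000))
      expect_gte(wide, narrow)
    }
  })
})

test_that("evaluations after an early stop do not change the result", {
  tr <- generate_trace(20000, 5000, noise_sd = 0, seed = 2)
  res <- select_checkpoint(tr)
  expect_true(res$early_stopped)
  longer <- generate_trace(40000, 5000, noise_sd = 0, seed = 2)
  res2 <- select_checkpoint(longer)
  expect_identical(res$ks, res2$ks)
  expect_identical(res$ke, res2$ke)
  expect_identical(res$i_star, res2$i_star)
})

test_that("traces validate their invariants and round-trip CSV", {
  expect_error(training_trace(c(1, 1, 2), 1:3, c(0.1, 0.2, 0.3)),
               "increasing")
  expect_error(training_trace(1:3, c(-1, 1, 1), c(0.1, 0.2, 0.3)), ">= 0")
  expect_error(training_trace(1:3, 1:3, c(0.1, 1.2, 0.3)), "f_measure")
  tr <- generate_trace(5000, 2000, 0.01, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), path, row.names = FALSE)
  expect_equal(as.data.frame(read_trace(path)), as.data.frame(tr),
               tolerance = 1e-12)
})
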