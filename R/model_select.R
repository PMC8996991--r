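#' Derivative-based model selection with early stopping
#'
#' Checkpoints are evaluated on a fixed iteration grid; the loss series
#' and its first/second finite differences define the start of a stable
#' window (both derivatives inside `[-epsilon, epsilon]` for a run of
#' consecutive evaluations), the F-measure derivatives define an early
#' stop (bound tau), and the checkpoint with the highest F-measure inside
#' the window is selected, later iterations winning ties.
#'
#' @name model_select
NULL

#' Training trace constructor
#'
#' @param iteration strictly increasing evaluation iterations.
#' @param loss non-negative loss values.
#' @param f_measure F-measure values in `[0, 1]`.
#' @return object of class `training_trace` (a data frame).
#' @export
training_trace <- function(iteration, loss, f_measure) {
  stopifnot(length(iteration) == length(loss),
            length(iteration) == length(f_measure))
  if (any(diff(iteration) <= 0)) stop("iterations must be strictly increasing")
  if (any(loss < 0)) stop("losses must be >= 0")
  if (any(f_measure < 0 | f_measure > 1)) stop("f_measure must be in [0, 1]")
  structure(data.frame(iteration = iteration, loss = loss,
                       f_measure = f_measure),
            class = c("training_trace", "data.frame"))
}

#' Read a training trace from CSV
#'
#' Expects columns iteration, loss, f_measure.
#' @param path CSV file.
#' @return a `training_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  training_trace(df$iteration, df$loss, df$f_measure)
}

#' First and second finite derivatives of a series
#'
#' Forward differences on the evaluation grid (unit grid step): the first
#' derivative has length `n - 1`, the second `n - 2`, both aligned to the
#' left grid point.
#'
#' @param series numeric vector with at least 3 points.
#' @return list with elements `first` and `second`.
#' @export
finite_derivatives <- function(series) {
  if (length(series) < 3L) stop("need at least 3 evaluations")
  first <- diff(series)
  list(first = first, second = diff(first))
}

#' Find the start of a stable-derivative window
#'
#' The window starts at the first grid index where both derivative series
#' stay within `[-bound, bound]` for `run_length` consecutive
#' evaluations.
#'
#' @param first,second derivative series from [finite_derivatives()].
#' @param bound convergence bound (epsilon for losses, tau for
#'   F-measures).
#' @param run_length required consecutive in-bound evaluations (>= 1).
#' @return 1-based grid index of the window start, or `NA` if no run
#'   exists.
#' @export
find_stable_window <- function(first, second, bound, run_length = 3L) {
  stopifnot(run_length >= 1)
  n <- length(second)
  if (n < 1L) return(NA_integer_)
  ok <- abs(first[seq_len(n)]) <= bound & abs(second) <= bound
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= run_length) return(i - run_length + 1L)
  }
  # allow runs that reach the end of the series but are cut short by the
  # derivative stencil: a trailing all-ok run shorter than run_length does
  # not qualify
  NA_integer_
}

#' Early-stop check on the F-measure derivatives
#'
#' Same run detection as [find_stable_window()] with bound `tau`; when no
#' stable run exists the search window ends at the final training
#' iteration.
#'
#' @param first,second F-measure derivative series.
#' @param iterations the evaluation grid.
#' @param tau convergence bound (default 0.1).
#' @param run_length required consecutive in-bound evaluations.
#' @return list: `ke` (end iteration of the search window) and
#'   `early_stopped` (logical).
#' @export
early_stop_check <- function(first, second, iterations, tau = 0.1,
                             run_length = 3L) {
  idx <- find_stable_window(first, second, bound = tau,
                            run_length = run_length)
  if (is.na(idx))
    list(ke = iterations[length(iterations)], early_stopped = FALSE)
  else
    list(ke = iterations[idx + run_length - 1L], early_stopped = TRUE)
}

#' Select the checkpoint with the best F-measure in a window
#'
#' Among evaluations with iteration in `[ks, ke]`, returns the iteration
#' of the maximal F-measure; ties go to the largest iteration.
#'
#' @param trace a `training_trace`.
#' @param ks,ke window bounds in iterations.
#' @return the selected iteration `i_star`.
#' @export
select_model <- function(trace, ks, ke) {
  in_win <- which(trace$iteration >= ks & trace$iteration <= ke)
  if (length(in_win) == 0L) stop("empty selection window")
  fm <- trace$f_measure[in_win]
  best <- in_win[fm == max(fm)]
  trace$iteration[max(best)]
}

#' Full model-selection procedure over a training trace
#'
#' Computes loss and F-measure derivatives, locates the stable-loss window
#' start `ks` (bound epsilon), the early-stop end `ke` (bound tau, falling
#' back to the last iteration), and selects the best checkpoint in
#' `[ks, ke]`. When the loss never stabilizes the search starts at the
#' first evaluation and the result is marked `loss_converged = FALSE`.
#'
#' @param trace a `training_trace`.
#' @param epsilon loss-derivative bound (default 0.003).
#' @param tau F-measure-derivative bound (default 0.1).
#' @param run_length consecutive in-bound evaluations defining a stable
#'   run (default 3).
#' @return list of class `selection_result`: `ks`, `ke`, `early_stopped`,
#'   `loss_converged`, `i_star`.
#' @export
select_checkpoint <- function(trace, epsilon = 0.003, tau = 0.1,
                              run_length = 3L) {
  stopifnot(inherits(trace, "training_trace"))
  dl <- finite_derivatives(trace$loss)
  df <- finite_derivatives(trace$f_measure)
  ks_idx <- find_stable_window(dl$first, dl$second, bound = epsilon,
                               run_length = run_length)
  loss_converged <- !is.na(ks_idx)
  ks <- if (loss_converged) trace$iteration[ks_idx] else trace$iteration[1]
  stop_res <- early_stop_check(df$first, df$second, trace$iteration,
                               tau = tau, run_length = run_length)
  ke <- max(stop_res$ke, ks)
  structure(list(ks = ks, ke = ke, early_stopped = stop_res$early_stopped,
                 loss_converged = loss_converged,
                 i_star = select_model(trace, ks, ke)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: window [%s, %s], i* = %s%s>\n",
              format(x$ks), format(x$ke), format(x$i_star),
              if (x$early_stopped) ", early stop" else ""))
  invisible(x)
}
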