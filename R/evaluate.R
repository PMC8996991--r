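#' Classification and survival-linked evaluation
#'
#' Core-level decisions are scored with the standard confusion-matrix
#' metrics (positive class = Effective) and threshold-free ROC/AUC;
#' predicted groups are compared on progression-free survival with
#' Kaplan-Meier curves, the two-sample log-rank test and Cox
#' proportional-hazards models.
#'
#' @name evaluate
NULL

#' Confusion counts from binary predictions
#'
#' @param predicted,actual integer/logical vectors (1 = Effective).
#' @return list of class `confusion_counts` with TP, FP, FN, TN.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  p <- as.integer(predicted); a <- as.integer(actual)
  structure(list(TP = sum(p == 1L & a == 1L), FP = sum(p == 1L & a == 0L),
                 FN = sum(p == 0L & a == 1L), TN = sum(p == 0L & a == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F-measure (harmonic mean of precision
#' and recall), positive class Effective. Ratios with empty denominators
#' are reported as `NA`, not zero. Full precision is returned; use
#' `digits = 2` to match the conventional 2-decimal reporting.
#'
#' @param counts a [confusion_counts()] or list with TP/FP/FN/TN.
#' @param digits optional rounding of the returned values.
#' @return named list: accuracy, precision, recall, f_measure.
#' @export
classification_metrics <- function(counts, digits = NULL) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- f_measure(prec, rec)
  out <- list(accuracy = acc, precision = prec, recall = rec, f_measure = f)
  if (!is.null(digits)) out <- lapply(out, round, digits = digits)
  out
}

#' F-measure from precision and recall
#'
#' @param precision,recall values in `[0, 1]`.
#' @return harmonic mean, `NA` when undefined.
#' @export
f_measure <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' The ROC curve sweeps all distinct score thresholds; the AUC is the
#' trapezoidal area under it, which with tied scores equals the
#' probability of correct ordering with half credit for ties (the
#' Mann-Whitney statistic divided by `n1 * n0`).
#'
#' @param scores numeric scores (higher = more Effective).
#' @param labels binary labels (1 = Effective); both classes must be
#'   present.
#' @return list: `auc`, `roc` (data frame threshold/fpr/tpr).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

check_records <- function(records) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (any(records$time <= 0)) stop("survival times must be > 0")
  invisible(records)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimate per predicted group and the 1-df
#' log-rank chi-square comparing them.
#'
#' @param records data frame with columns time, event (1 = progressed,
#'   0 = censored) and group (0 invalid / 1 effective).
#' @return list: `curves` (data frame group/time/survival/n_risk),
#'   `chisq`, `p`.
#' @export
km_logrank <- function(records) {
  check_records(records)
  if (length(unique(records$group)) != 2L)
    stop("exactly two groups are required")
  if (sum(records$event) == 0L) stop("no events: all subjects censored")
  if (any(table(records$group) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, survival = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  chisq <- sd$chisq
  list(curves = curves, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Standard partial-likelihood fit of the event hazard on the predicted
#' group plus optional covariates (delegated to the survival package);
#' hazard ratios are exponentiated coefficients with Wald 95% intervals.
#'
#' @param records data frame with time, event, group columns.
#' @param covariates optional character vector of extra covariate columns
#'   present in `records`.
#' @return data frame: term, hr, lower, upper, p.
#' @export
cox_ph <- function(records, covariates = NULL) {
  check_records(records)
  terms <- c("group", covariates)
  for (v in terms) {
    vals <- records[[v]]
    if (is.numeric(vals) && stats::var(vals) == 0)
      stop("zero-variance covariate: ", v)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = records)
  if (any(is.na(stats::coef(fit))))
    stop("Cox model did not converge to finite coefficients")
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = s$coefficients[, "exp(coef)"],
             lower = s$conf.int[, "lower .95"],
             upper = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
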