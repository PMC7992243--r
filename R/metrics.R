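#' Confusion matrix from predicted and gold-standard labels
#'
#' @param pred named logical vector: screen verdict per patient.
#' @param gold named logical vector: gold-standard (manual-review) label per
#'   patient.  Key sets must match exactly; a mismatch is fatal and lists the
#'   differing ids.
#' @return object of class `confusion_matrix`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' confusion(c(a = TRUE, b = FALSE), c(a = TRUE, b = FALSE))
#' @export
confusion <- function(pred, gold) {
  if (is.null(names(pred)) || is.null(names(gold))) {
    stop("pred and gold must be named by patient id", call. = FALSE)
  }
  only_pred <- setdiff(names(pred), names(gold))
  only_gold <- setdiff(names(gold), names(pred))
  if (length(only_pred) || length(only_gold)) {
    stop("patient id mismatch between predictions and gold standard",
         if (length(only_pred)) paste0("; only in predictions: ",
                                       paste(only_pred, collapse = ", ")),
         if (length(only_gold)) paste0("; only in gold: ",
                                       paste(only_gold, collapse = ", ")),
         call. = FALSE)
  }
  gold <- gold[names(pred)]
  if (any(is.na(pred)) || any(is.na(gold))) {
    stop("labels must be TRUE/FALSE with no missing values", call. = FALSE)
  }
  confusion_matrix(
    tp = sum(pred & gold), fp = sum(pred & !gold),
    fn = sum(!pred & gold), tn = sum(!pred & !gold)
  )
}

#' Construct a confusion matrix from cell counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("positive", "negative"),
                              gold = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic-accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive predictive value, and negative
#' predictive value as percentages, rounded half-up to one decimal to match
#' conventional published precision.  A metric with a zero denominator is
#' reported as `NA` (explicitly undefined), never silently 0 or 100.
#'
#' @param cm a `confusion_matrix` (or a list with tp/fp/fn/tn).
#' @return object of class `diagnostic_metrics`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent, one decimal, `NA` = undefined)
#'   and the input matrix `cm`.
#' @examples
#' diagnostics(confusion_matrix(tp = 21, fp = 0, fn = 2, tn = 27))
#' @export
diagnostics <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (is.na(n) || n <= 0) stop("empty confusion matrix", call. = FALSE)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  structure(list(
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv = pct(cm$tp, cm$tp + cm$fp),
    npv = pct(cm$tn, cm$tn + cm$fn),
    cm = cm
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f", v)
  cat(sprintf("sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Reconstruct integer confusion tables from published summary statistics
#'
#' Exhaustively enumerates all non-negative integer 2x2 tables with total
#' `n` and returns those whose one-decimal (half-up) rounded metrics match
#' every supplied target and whose cells match every fixed count.  Used to
#' recover the unique table behind a published sensitivity/specificity row
#' when only the summary percentages and cohort size are known.
#'
#' @param n cohort size (total of the four cells); at most 10,000.
#' @param fixed named list of fixed cell counts, e.g. `list(fn = 2, fp = 0)`.
#' @param targets named list of target percentages (one decimal), any of
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @return data frame with columns `tp`, `fp`, `fn`, `tn`, one row per
#'   matching table (possibly zero rows).
#' @examples
#' reconstruct_tables(50, fixed = list(fn = 2, fp = 0),
#'                    targets = list(sensitivity = 91.3))
#' @export
reconstruct_tables <- function(n, fixed = list(), targets = list()) {
  stopifnot(length(n) == 1, n >= 1, n <= 10000)
  bad <- setdiff(names(fixed), c("tp", "fp", "fn", "tn"))
  if (length(bad)) stop("unknown fixed cell(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(targets), c("sensitivity", "specificity", "ppv", "npv"))
  if (length(bad)) stop("unknown target metric(s): ", paste(bad, collapse = ", "))

  rng <- function(cell) if (!is.null(fixed[[cell]])) fixed[[cell]] else 0:n
  dims <- prod(vapply(c("tp", "fp", "fn"), function(c) length(rng(c)), numeric(1)))
  if (dims > 5e7) {
    stop("enumeration too large; fix at least one cell count", call. = FALSE)
  }
  g <- expand.grid(tp = rng("tp"), fp = rng("fp"), fn = rng("fn"),
                   KEEP.OUT.ATTRS = FALSE)
  g$tn <- n - g$tp - g$fp - g$fn
  g <- g[g$tn >= 0, , drop = FALSE]
  if (!is.null(fixed$tn)) g <- g[g$tn == fixed$tn, , drop = FALSE]

  match_target <- function(num, den, target) {
    ok <- den > 0
    ok[ok] <- abs(round_half_up(100 * num[ok] / den[ok], 1) - target) < 1e-9
    ok
  }
  keep <- rep(TRUE, nrow(g))
  if (!is.null(targets$sensitivity)) {
    keep <- keep & match_target(g$tp, g$tp + g$fn, targets$sensitivity)
  }
  if (!is.null(targets$specificity)) {
    keep <- keep & match_target(g$tn, g$tn + g$fp, targets$specificity)
  }
  if (!is.null(targets$ppv)) {
    keep <- keep & match_target(g$tp, g$tp + g$fp, targets$ppv)
  }
  if (!is.null(targets$npv)) {
    keep <- keep & match_target(g$tn, g$tn + g$fn, targets$npv)
  }
  out <- g[keep, c("tp", "fp", "fn", "tn"), drop = FALSE]
  rownames(out) <- NULL
  out
}
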