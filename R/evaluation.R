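#' ROC curve and AUC of a change score map against ground truth
#'
#' Sweeps every distinct score value as a decision threshold (`score >= t`
#' predicts "changed"; tied scores share a threshold) and returns the full
#' ROC curve with its trapezoidal AUC. With this tie handling the AUC equals
#' the Mann-Whitney statistic `P(score_pos > score_neg) + 0.5 * P(tie)`, so a
#' constant map scores exactly 0.5 and any strictly increasing transform of
#' the scores leaves the curve unchanged.
#'
#' @param scores a `"change_scores"` object, a numeric matrix, or a numeric
#'   vector of change scores.
#' @param truth a binary ground-truth change mask (matrix or vector, nonzero
#'   means changed) of the same spatial shape, with at least one changed and
#'   one unchanged pixel.
#' @param ... unused.
#' @return an object of class `"roc_curve"`: list with `thresholds`
#'   (descending; leading `Inf` for the empty-prediction point), `fpr`, `tpr`
#'   (both starting at 0 and ending at 1), `auc` (in `[0, 1]`), and the
#'   positive/negative counts.
#' @examples
#' roc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc # 1
#' @export
roc <- function(scores, truth, ...) UseMethod("roc")

#' @rdname roc
#' @export
roc.change_scores <- function(scores, truth, ...) {
  roc.default(scores$scores, truth, ...)
}

#' @rdname roc
#' @export
roc.default <- function(scores, truth, ...) {
  s <- as.numeric(if (is.matrix(scores)) scores else scores)
  y <- as.integer(as.numeric(truth) != 0)
  if (length(s) != length(y)) {
    stop("scores and truth have different sizes (", length(s), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (anyNA(s) || any(!is.finite(s))) {
    stop("scores must be finite", call. = FALSE)
  }
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("undefined AUC: ground truth has a single class (",
         npos, " positive, ", nneg, " negative)", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]
  y_ord <- y[ord]
  # collapse tied scores into one threshold step
  last_of_group <- c(s_ord[-length(s_ord)] != s_ord[-1L], TRUE)
  tp <- cumsum(y_ord)[last_of_group]
  fp <- cumsum(1L - y_ord)[last_of_group]
  thresholds <- c(Inf, s_ord[last_of_group])
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = npos, n_neg = nneg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d threshold steps\n",
              x$n_pos, x$n_neg, length(x$thresholds) - 1L))
  cat(sprintf("AUC = %.3f%%\n", 100 * x$auc))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a `"roc_curve"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f%%)", 100 * x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Tabulate AUC values for several detectors
#'
#' Builds the comparison table usually reported for change detectors: one row
#' per method with its AUC as a percentage (three decimals), the best
#' value(s) flagged. Ties for best are all flagged.
#'
#' @param curves a named list of `"roc_curve"` objects (names are the method
#'   labels), or a list of `list(method =, curve =)` pairs.
#' @param file optional path; when given, the table is also written as CSV.
#' @return a `data.frame` with columns `method`, `auc_pct`, `best`.
#' @export
auc_report <- function(curves, file = NULL) {
  if (length(curves) < 1L) stop("need at least one curve", call. = FALSE)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    if (all(vapply(curves, function(x)
      is.list(x) && !is.null(x$method) && !is.null(x$curve), logical(1)))) {
      nm <- vapply(curves, `[[`, character(1), "method")
      curves <- lapply(curves, `[[`, "curve")
      names(curves) <- nm
    } else {
      stop("curves must be a named list of roc_curve objects", call. = FALSE)
    }
  }
  aucs <- vapply(curves, function(x) {
    if (!inherits(x, "roc_curve")) stop("not an roc_curve", call. = FALSE)
    x$auc
  }, numeric(1))
  pct <- round(100 * aucs, 3)
  out <- data.frame(method = names(curves), auc_pct = pct,
                    best = aucs == max(aucs),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
  }
  class(out) <- c("auc_report", "data.frame")
  out
}

#' @export
print.auc_report <- function(x, ...) {
  cat("AUC comparison\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %8.3f%s\n", x$method[i], x$auc_pct[i],
                if (x$best[i]) "  *best*" else ""))
  }
  invisible(x)
}

#' Write an ROC curve as CSV
#'
#' Columns `threshold`, `fpr`, `tpr`, plus a footer row carrying the AUC
#' (threshold column `"AUC"`).
#'
#' @param x a `"roc_curve"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_roc_csv <- function(x, file) {
  if (!inherits(x, "roc_curve")) stop("x must be an roc_curve", call. = FALSE)
  df <- data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
  utils::write.csv(df, file, row.names = FALSE)
  cat(sprintf("AUC,%.12g,\n", x$auc), file = file, append = TRUE)
  invisible(file)
}
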