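# Per-class and macro-averaged evaluation in the one-vs-rest reduction:
# for each class, the 4-class problem collapses to "this class vs the
# rest", giving class-wise accuracy, precision, recall, F1 and AUC; the
# macro value is the unweighted mean over classes.

# Rank-based (Mann-Whitney) AUC of scores for a binary truth vector.
binary_auc <- function(truth, scores) {
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics report
#'
#' Builds the 4 x 4 confusion matrix (true classes on rows) and, for
#' each class in the one-vs-rest reduction, accuracy, precision, recall,
#' F1 and AUC (from the posterior ranking), plus their macro averages.
#' A class absent from `y_true` has undefined AUC; it is reported as
#' `NA`, excluded from the macro AUC, and a warning is emitted.
#'
#' @param y_true True labels (character or factor).
#' @param y_pred Predicted labels, same length.
#' @param posteriors Optional numeric matrix of class posteriors
#'   (samples x classes, columns in class order or named); required for
#'   AUC.
#' @param classes Class levels (default [nbi_classes()]).
#' @return An object of class `nbi_metrics`: `confusion`, `per_class`
#'   (data.frame), `macro` (named numeric), `n`.
#' @export
compute_metrics <- function(y_true, y_pred, posteriors = NULL,
                            classes = nbi_classes()) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    nbi_stop("y_true and y_pred must have equal length",
             class = "nbi_shape_error")
  }
  n <- length(y_true)
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  if (anyNA(ft) || anyNA(fp)) {
    nbi_stop("labels outside the class set", class = "nbi_bad_label")
  }
  confusion <- table(true = ft, predicted = fp)
  if (!is.null(posteriors)) {
    posteriors <- as.matrix(posteriors)
    if (nrow(posteriors) != n || ncol(posteriors) != length(classes)) {
      nbi_stop("posteriors must be n x ", length(classes),
               class = "nbi_shape_error")
    }
    if (!is.null(colnames(posteriors))) {
      posteriors <- posteriors[, classes, drop = FALSE]
    }
  }
  per <- lapply(seq_along(classes), function(k) {
    cl <- classes[k]
    tp <- sum(y_true == cl & y_pred == cl)
    fp_ <- sum(y_true != cl & y_pred == cl)
    fn_ <- sum(y_true == cl & y_pred != cl)
    tn <- n - tp - fp_ - fn_
    prec <- if (tp + fp_ == 0L) 0 else tp / (tp + fp_)
    rec <- if (tp + fn_ == 0L) 0 else tp / (tp + fn_)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    auc <- if (is.null(posteriors)) NA_real_ else
      binary_auc(y_true == cl, posteriors[, k])
    if (!any(y_true == cl)) {
      warning("class ", cl, " absent from y_true; AUC undefined",
              call. = FALSE)
      auc <- NA_real_
    }
    data.frame(class = cl, accuracy = (tp + tn) / n, precision = prec,
               recall = rec, f1 = f1, auc = auc,
               support = sum(y_true == cl))
  })
  per <- do.call(rbind, per)
  macro <- c(accuracy = mean(per$accuracy), precision = mean(per$precision),
             recall = mean(per$recall), f1 = mean(per$f1),
             auc = mean(per$auc, na.rm = TRUE))
  structure(list(confusion = confusion, per_class = per, macro = macro,
                 n = n),
            class = "nbi_metrics")
}

#' @export
print.nbi_metrics <- function(x, digits = 4, ...) {
  cat("Confusion matrix (true classes on rows):\n")
  print(x$confusion)
  cat("\nOne-vs-rest metrics:\n")
  tab <- x$per_class
  tab[2:6] <- lapply(tab[2:6], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("\nMacro averages:\n")
  print(round(x$macro, digits))
  invisible(x)
}

#' Flatten a metrics report for serialization
#'
#' @param x An `nbi_metrics` object.
#' @return A plain list suitable for [jsonlite::write_json()].
#' @export
metrics_as_list <- function(x) {
  stopifnot(inherits(x, "nbi_metrics"))
  list(n = x$n,
       macro = as.list(x$macro),
       per_class = x$per_class,
       confusion = as.data.frame.matrix(unclass(x$confusion)))
}
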