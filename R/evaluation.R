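#' Mann-Whitney AUC
#'
#' Rank-based (threshold-free) estimate of the area under the ROC curve:
#' the probability that a random positive scores higher than a random
#' negative, with half credit for ties. Invariant to strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param positive logical (or 0/1) indicator of the positive class.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one positive and one negative example")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted multi-class AUC (one-vs-rest)
#'
#' For each class c, the ROC of the class-c membership score against the
#' c-vs-rest labelling is summarised by its Mann-Whitney AUC; the per-class
#' AUCs are averaged with weights proportional to each class's size in the
#' test set, w_c = n_c / sum(n). A class absent from the test set is
#' excluded and the weights renormalised (with a warning).
#'
#' @param scores test-subjects x classes score matrix (named columns).
#' @param truth true labels.
#' @return list with \code{per_class_auc}, \code{weights},
#'   \code{weighted_auc}.
#' @export
weighted_multiclass_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  classes <- colnames(scores)
  if (is.null(classes)) stop("score matrix must have class column names")
  present <- classes[classes %in% truth]
  if (length(present) < length(classes))
    warning("class(es) absent from test set, weights renormalised: ",
            paste(setdiff(classes, present), collapse = ", "))
  n_c <- vapply(present, function(cl) sum(truth == cl), numeric(1))
  w <- n_c / sum(n_c)
  aucs <- vapply(present, function(cl)
    auc_mann_whitney(scores[, cl], truth == cl), numeric(1))
  list(per_class_auc = aucs, weights = w,
       weighted_auc = sum(w * aucs))
}

#' Confusion matrix and cobweb misclassification axes
#'
#' Builds the K x K confusion count matrix and, for the cobweb (radar)
#' representation, the K(K-1) ordered off-diagonal misclassification rates
#' "A -> B" = fraction of true-A subjects predicted B (row-normalised). For
#' three classes this is exactly 6 axes.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @param classes optional class order; defaults to sorted union.
#' @return list with \code{confusion} (counts), \code{rates}
#'   (row-normalised), \code{axes} (named numeric vector, names "A -> B").
#' @export
confusion_and_cobweb <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(union(truth, predicted))
  if (!all(predicted %in% classes))
    stop("unseen predicted label(s): ",
         paste(setdiff(predicted, classes), collapse = ", "))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  rs <- rowSums(cm)
  rates <- sweep(cm, 1L, pmax(rs, 1L), "/")
  axes <- c()
  for (a in classes) for (b in classes) if (a != b) {
    axes[paste(a, "->", b)] <- rates[a, b]
  }
  list(confusion = cm, rates = rates, axes = axes)
}

#' Binary classification metrics
#'
#' AUC (Mann-Whitney on the positive-class score), and sensitivity and
#' specificity at the classifier's own operating point, i.e. the argmax
#' (score >= 0.5) decision: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @param scores positive-class membership scores in [0, 1] (or a 2-column
#'   score matrix with named columns).
#' @param truth true labels.
#' @param positive name of the positive class.
#' @return list with \code{auc}, \code{sensitivity}, \code{specificity}.
#' @export
binary_metrics <- function(scores, truth, positive) {
  truth <- as.character(truth)
  if (is.matrix(scores)) scores <- scores[, positive]
  is_pos <- truth == positive
  if (all(is_pos) || !any(is_pos)) stop("both classes must be present")
  pred_pos <- scores >= 0.5
  list(auc = auc_mann_whitney(scores, is_pos),
       sensitivity = sum(pred_pos & is_pos) / sum(is_pos),
       specificity = sum(!pred_pos & !is_pos) / sum(!is_pos))
}

#' Full multi-class evaluation report
#'
#' Combines per-class one-vs-rest AUCs, class-size weights, weighted mean
#' AUC, the confusion matrix and the cobweb axes into one report.
#'
#' @param scores test-subjects x classes score matrix.
#' @param truth true labels.
#' @return object of class \code{evaluation_report}.
#' @export
evaluate_multiclass <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  predicted <- colnames(scores)[max.col(scores, ties.method = "first")]
  au <- weighted_multiclass_auc(scores, truth)
  cc <- confusion_and_cobweb(predicted, truth, classes = colnames(scores))
  structure(list(per_class_auc = au$per_class_auc, weights = au$weights,
                 weighted_auc = au$weighted_auc, confusion = cc$confusion,
                 rates = cc$rates, axes = cc$axes,
                 accuracy = mean(predicted == truth),
                 n_test = length(truth)),
            class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: weighted AUC %.3f, accuracy %.3f (n=%d)\n",
              x$weighted_auc, x$accuracy, x$n_test))
  cat("per-class AUC:", paste(sprintf("%s=%.3f", names(x$per_class_auc),
                                      x$per_class_auc), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cobweb (radar) plot of misclassification axes
#'
#' Draws one polygon per feature set over the ordered misclassification
#' axes, each axis running from 0 (centre, no misclassification) to 1.
#' Values outside [0, 1] are clipped with a warning.
#'
#' @param axes_list named list of axis vectors (all with the same axis
#'   names, e.g. from \code{\link{confusion_and_cobweb}}); a single vector
#'   is also accepted.
#' @param path output file (.png or .svg).
#' @param main plot title.
#' @return \code{path}, invisibly.
#' @export
render_cobweb <- function(axes_list, path, main = "Misclassification rates") {
  if (!is.list(axes_list)) axes_list <- list(feature = axes_list)
  axis_names <- names(axes_list[[1]])
  if (length(axis_names) < 3L) stop("need at least 3 axes for a cobweb plot")
  clipped <- FALSE
  axes_list <- lapply(axes_list, function(a) {
    if (any(a < 0 | a > 1)) clipped <<- TRUE
    pmin(pmax(a, 0), 1)
  })
  if (clipped) warning("rates clipped to [0, 1]")
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 7)
  else grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  k <- length(axis_names)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), axes = FALSE,
                 xlab = "", ylab = "", main = main, asp = 1)
  for (rr in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(rr * cos(ang), rr * sin(ang), border = "grey80")
  }
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey70")
  graphics::text(1.2 * cos(ang), 1.2 * sin(ang), axis_names, cex = 0.9)
  cols <- grDevices::hcl.colors(max(3L, length(axes_list)), "Dark 3")
  for (i in seq_along(axes_list)) {
    v <- axes_list[[i]][axis_names]
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = names(axes_list),
                   col = cols[seq_along(axes_list)], lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(path)
}
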