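#' Information gain of a feature for a class label
#'
#' Entropy reduction H(labels) - sum_b p(b) H(labels | bin b) in bits, with
#' the continuous feature discretised by equal-frequency binning. When the
#' requested number of bins cannot hold at least \code{min_per_bin} samples
#' each, the bin count is reduced. A constant feature (single bin) has zero
#' gain; a single-class label vector yields zero gain with a warning.
#'
#' @param x numeric feature values.
#' @param labels class labels, same length.
#' @param bins target number of equal-frequency bins (default 10).
#' @param min_per_bin minimum samples per bin (default 2).
#' @return gain in bits, in [0, H(labels)].
#' @export
information_gain <- function(x, labels, bins = 10L, min_per_bin = 2L) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    warning("single class: information gain is 0")
    return(0)
  }
  bins <- max(1L, min(bins, n %/% min_per_bin))
  b <- discretize_ef(x, bins)
  h0 <- entropy_bits(labels)
  hcond <- 0
  for (lev in unique(b)) {
    sel <- b == lev
    hcond <- hcond + mean(sel) * entropy_bits(labels[sel])
  }
  max(0, h0 - hcond)
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency discretisation; ties in x can merge bins, which is fine
discretize_ef <- function(x, bins) {
  if (bins <= 1L || length(unique(x)) == 1L) return(rep(1L, length(x)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               type = 7))
  if (length(qs) <= 2L) {
    # nearly-constant feature: split at the unique values instead
    return(as.integer(factor(x)))
  }
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

#' Select the top-k features by information gain
#'
#' Ranks every feature column by its information gain against the labels and
#' keeps the k best. Ties are broken by original column order. Must be
#' called on training rows only; the resampling loops in this package do so.
#'
#' @param features samples x features numeric matrix (named columns).
#' @param labels class labels.
#' @param k number of features to keep (default 5).
#' @param bins binning passed to \code{\link{information_gain}}.
#' @return character vector of the k selected feature names, in rank order.
#' @export
select_top_k <- function(features, labels, k = 5L, bins = 10L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("x%d", seq_len(ncol(features)))
  if (k > ncol(features))
    stop("k (", k, ") exceeds feature count (", ncol(features), ")")
  gains <- suppressWarnings(
    apply(features, 2L, information_gain, labels = labels, bins = bins))
  ord <- order(-gains, seq_along(gains))   # stable: ties by column order
  colnames(features)[ord[seq_len(k)]]
}
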