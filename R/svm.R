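#' Stratified train/test split
#'
#' Per diagnostic group, floor(train_fraction * n) subjects are drawn
#' (seeded) for training and the remainder form the test set, so class
#' proportions are preserved. With the study's class sizes (30, 34, 14) and
#' the default fraction 0.75 this yields 57 training and 21 test subjects.
#'
#' @param labels class label per subject.
#' @param train_fraction fraction per class in training (default 0.75).
#' @param seed RNG seed.
#' @return list with \code{train}, \code{test} (integer indices),
#'   \code{per_class} (train counts), \code{seed}, \code{train_fraction}.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 42L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class needs >= 2 members; got: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1): empty train or test set")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- floor(train_fraction * length(idx))
    if (n_tr == 0L || n_tr == length(idx))
      stop("class ", cl, " would have an empty train or test set")
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  list(train = train, test = test,
       per_class = table(labels[train]), seed = seed,
       train_fraction = train_fraction)
}

# swallow solver chatter printed to the console during extreme grid points
quiet <- function(expr) {
  out <- utils::capture.output(res <- expr, type = "output")
  res
}

# stratified fold ids (1..nfolds), seeded; assumes seed already set upstream
make_folds <- function(labels, nfolds) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Classifier specification
#'
#' Pluggable classifier contract used by the grid search and resampling
#' loops: \code{"rbf_svm"} (default; radial-basis-function SVM, grid over
#' cost C and kernel width gamma), \code{"linear_svm"} (grid over C only)
#' and \code{"nbayes"} (Gaussian naive Bayes baseline, no tuning grid).
#' Multi-class scores for the SVMs come from coupling of the pairwise
#' decision values (see \code{\link{predict_scores}}).
#'
#' @param name one of "rbf_svm", "linear_svm", "nbayes".
#' @return list with \code{name}, \code{fit(x, y, C, gamma)},
#'   \code{decision(model, x)} and \code{uses_grid}.
#' @export
classifier_spec <- function(name = c("rbf_svm", "linear_svm", "nbayes")) {
  name <- match.arg(name)
  switch(name,
    rbf_svm = list(
      name = name, uses_grid = c(C = TRUE, gamma = TRUE),
      fit = function(x, y, C, gamma)
        e1071::svm(x, y, type = "C-classification", kernel = "radial",
                   cost = C, gamma = gamma, scale = FALSE),
      predict_fun = svm_pairwise_scores),
    linear_svm = list(
      name = name, uses_grid = c(C = TRUE, gamma = FALSE),
      fit = function(x, y, C, gamma)
        e1071::svm(x, y, type = "C-classification", kernel = "linear",
                   cost = C, scale = FALSE),
      predict_fun = svm_pairwise_scores),
    nbayes = list(
      name = name, uses_grid = c(C = FALSE, gamma = FALSE),
      fit = function(x, y, C, gamma)
        e1071::naiveBayes(as.data.frame(x), y),
      predict_fun = function(model, x, levels) {
        p <- stats::predict(model, as.data.frame(x), type = "raw")
        p <- p[, levels, drop = FALSE]
        p / rowSums(p)
      }))
}

# class-membership scores from an e1071 SVM via pairwise coupling:
# decision values are mapped through a logistic link and the pairwise
# probabilities combined with the Wu-Lin iterative coupling scheme.
svm_pairwise_scores <- function(model, x, levels) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  k <- length(levels)
  n <- nrow(dv)
  clamp <- function(p) pmin(pmax(p, 1e-8), 1 - 1e-8)
  if (k == 2L) {
    cn <- colnames(dv)[1]
    pos <- strsplit(cn, "/")[[1]][1]
    p_pos <- clamp(stats::plogis(dv[, 1]))
    out <- cbind(p_pos, 1 - p_pos)
    colnames(out) <- c(pos, setdiff(levels, pos))
    return(out[, levels, drop = FALSE])
  }
  R <- array(0.5, c(n, k, k), dimnames = list(NULL, levels, levels))
  for (cn in colnames(dv)) {
    ab <- strsplit(cn, "/")[[1]]
    p <- clamp(stats::plogis(dv[, cn]))
    R[, ab[1], ab[2]] <- p
    R[, ab[2], ab[1]] <- 1 - p
  }
  out <- t(vapply(seq_len(n), function(i) couple_pairwise(R[i, , ]),
                  numeric(k)))
  colnames(out) <- levels
  out
}

# Wu-Lin (2004) second coupling method: minimise
# sum_i sum_{j != i} (r_ji p_i - r_ij p_j)^2 subject to sum p = 1
couple_pairwise <- function(R, max_iter = 200L, eps = 1e-12) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) Q[i, i] <- sum(R[-i, i]^2)
      else Q[i, j] <- -R[j, i] * R[i, j]
    }
  }
  p <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    pQp <- as.numeric(t(p) %*% Q %*% p)
    stop_now <- TRUE
    for (t in seq_len(k)) {
      diff <- (-sum(Q[t, -t] * p[-t]) + pQp) / Q[t, t]
      if (abs(diff - p[t]) > eps) stop_now <- FALSE
      p[t] <- diff
      p <- p / sum(p)
      pQp <- as.numeric(t(p) %*% Q %*% p)
    }
    if (stop_now) break
  }
  p
}

#' Default model-selection grid
#'
#' Integer exponents log10 C = -3..8 and log10 gamma = -3..3, i.e. 84
#' candidate (C, gamma) points for the RBF SVM.
#'
#' @param log10_C integer exponents for the penalty C.
#' @param log10_gamma integer exponents for the kernel width gamma.
#' @return data.frame with columns C and gamma, ordered by (C, gamma).
#' @export
default_grid <- function(log10_C = -3:8, log10_gamma = -3:3) {
  if (!length(log10_C) || !length(log10_gamma)) stop("empty grid range")
  g <- expand.grid(gamma = 10^sort(log10_gamma), C = 10^sort(log10_C))
  data.frame(C = g$C, gamma = g$gamma)[order(g$C, g$gamma), ]
}

#' Train a classifier with feature selection and grid search
#'
#' The protocol applied inside every resampling loop: (1) select the top-k
#' features by information gain on the training rows only; (2) for each
#' (C, gamma) grid point, estimate stratified 5-fold cross-validated
#' accuracy on the training set (falling back to 3-fold, then leave-one-out,
#' when a class is smaller than the fold count); (3) refit the best point on
#' all training rows. Ties are broken toward smaller C, then smaller gamma.
#'
#' @param x training samples x features matrix (named columns).
#' @param y training labels.
#' @param grid data.frame of candidate (C, gamma), see
#'   \code{\link{default_grid}}.
#' @param spec a \code{\link{classifier_spec}}.
#' @param k number of features kept by selection (capped at ncol(x)).
#' @param inner_folds folds of the inner CV (default 5).
#' @param seed RNG seed (inner fold construction).
#' @return object of class \code{trained_model}: selected \code{features},
#'   chosen \code{C}, \code{gamma}, \code{cv_accuracy}, fitted \code{model},
#'   \code{levels}, \code{scaling}.
#' @export
grid_search_train <- function(x, y, grid = default_grid(),
                              spec = classifier_spec("rbf_svm"),
                              k = 5L, inner_folds = 5L, seed = 42L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  y <- factor(as.character(y))
  if (nrow(x) == 0L) stop("empty training set")
  k <- min(k, ncol(x))
  feats <- select_top_k(x, y, k = k)
  xs <- x[, feats, drop = FALSE]
  sc <- feature_scaling(xs)
  xs <- apply_scaling(xs, sc)
  if (!spec$uses_grid[["C"]]) grid <- data.frame(C = 1, gamma = 1)
  else if (!spec$uses_grid[["gamma"]])
    grid <- unique(data.frame(C = grid$C, gamma = 1))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  min_class <- min(table(y))
  nf <- if (min_class >= inner_folds) inner_folds
        else if (min_class >= 3L) {
          warning("class smaller than ", inner_folds,
                  ": falling back to 3-fold inner CV")
          3L
        } else {
          warning("very small class: inner CV is leave-one-out")
          length(y)
        }
  fold <- if (nf == length(y)) seq_along(y) else make_folds(y, nf)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    total <- 0L
    ok <- TRUE
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- try(quiet(spec$fit(xs[tr, , drop = FALSE], droplevels(y[tr]),
                              grid$C[gi], grid$gamma[gi])), silent = TRUE)
      if (inherits(m, "try-error")) { ok <- FALSE; break }
      sc_f <- spec$predict_fun(m, xs[!tr, , drop = FALSE],
                               levels(droplevels(y[tr])))
      pred <- colnames(sc_f)[max.col(sc_f, ties.method = "first")]
      correct <- correct + sum(pred == as.character(y[!tr]))
      total <- total + sum(!tr)
    }
    acc[gi] <- if (ok && total > 0L) correct / total else -1
  }
  best <- which.max(acc)   # grid ordered by (C, gamma): first max wins ties
  model <- quiet(spec$fit(xs, y, grid$C[best], grid$gamma[best]))
  structure(list(features = feats, C = grid$C[best],
                 gamma = grid$gamma[best], cv_accuracy = acc[best],
                 model = model, spec = spec, levels = levels(y),
                 scaling = sc),
            class = "trained_model")
}

# training-set standardisation (constant columns left unscaled)
feature_scaling <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center), 2L, sc$scale, "/")
}

#' @method print trained_model
#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(paste0("trained_model (%s): features [%s], C = %g, ",
                     "gamma = %g, inner-CV accuracy %.3f\n"),
              x$spec$name, paste(x$features, collapse = ", "),
              x$C, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Per-class membership scores for new subjects
#'
#' Applies a trained model to a test table. Scores sum to 1 per subject;
#' the predicted label is the argmax column.
#'
#' @param model a \code{\link{grid_search_train}} result.
#' @param x test samples x features matrix containing at least the selected
#'   feature columns.
#' @return numeric matrix, one column per class, rows summing to 1, with
#'   attribute \code{"predicted"} (character labels).
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  x <- as.matrix(x)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) stop("missing selected feature columns: ",
                         paste(miss, collapse = ", "))
  xs <- apply_scaling(x[, model$features, drop = FALSE], model$scaling)
  s <- model$spec$predict_fun(model$model, xs, model$levels)
  s <- s / rowSums(s)
  attr(s, "predicted") <- colnames(s)[max.col(s, ties.method = "first")]
  s
}

#' Leave-one-out cross-validation of the full protocol
#'
#' For every subject: feature selection and grid search are redone on the
#' remaining N-1 subjects (no leakage), and the held-out subject is scored.
#'
#' @param x samples x features matrix.
#' @param y labels.
#' @param grid,spec,k,inner_folds,seed passed to
#'   \code{\link{grid_search_train}}.
#' @return list with \code{scores} (N x classes), \code{predicted},
#'   \code{truth}, \code{accuracy}.
#' @export
loocv <- function(x, y, grid = default_grid(),
                  spec = classifier_spec("rbf_svm"), k = 5L,
                  inner_folds = 5L, seed = 42L) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects for LOOCV")
  lv <- sort(unique(y))
  scores <- matrix(NA_real_, n, length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(n)) {
    tm <- suppressWarnings(
      grid_search_train(x[-i, , drop = FALSE], y[-i], grid = grid,
                        spec = spec, k = k, inner_folds = inner_folds,
                        seed = seed + i))
    s <- predict_scores(tm, x[i, , drop = FALSE])
    scores[i, colnames(s)] <- s
  }
  scores[is.na(scores)] <- 0
  predicted <- colnames(scores)[max.col(scores, ties.method = "first")]
  list(scores = scores, predicted = predicted, truth = y,
       accuracy = mean(predicted == y))
}

#' Repeated stratified hold-out
#'
#' Repeats the split -> select -> grid-search -> test protocol
#' \code{n_reps} times with fresh random splits and summarises the weighted
#' multi-class AUC across repetitions (its mean and SD quantify robustness
#' to the choice of training set).
#'
#' @param x samples x features matrix.
#' @param y labels.
#' @param n_reps repetitions (default 10).
#' @param train_fraction per-class training fraction.
#' @param seed master seed; repetition r uses seed + r.
#' @param grid,spec,k,inner_folds passed to \code{\link{grid_search_train}}.
#' @return list with \code{reports} (per repetition, see
#'   \code{\link{evaluate_multiclass}}), \code{weighted_auc} (vector),
#'   \code{mean_weighted_auc}, \code{sd_weighted_auc}.
#' @export
repeated_holdout <- function(x, y, n_reps = 10L, train_fraction = 0.75,
                             seed = 42L, grid = default_grid(),
                             spec = classifier_spec("rbf_svm"), k = 5L,
                             inner_folds = 5L) {
  x <- as.matrix(x)
  y <- as.character(y)
  reports <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sp <- stratified_split(y, train_fraction, seed = seed + r)
    tm <- suppressWarnings(
      grid_search_train(x[sp$train, , drop = FALSE], y[sp$train],
                        grid = grid, spec = spec, k = k,
                        inner_folds = inner_folds, seed = seed + r))
    s <- predict_scores(tm, x[sp$test, , drop = FALSE])
    reports[[r]] <- evaluate_multiclass(s, y[sp$test])
    reports[[r]]$model <- list(features = tm$features, C = tm$C,
                               gamma = tm$gamma, seed = seed + r)
  }
  wauc <- vapply(reports, function(r) r$weighted_auc, numeric(1))
  list(reports = reports, weighted_auc = wauc,
       mean_weighted_auc = mean(wauc), sd_weighted_auc = stats::sd(wauc))
}

#' Minimum sample size for a feature count and error probability
#'
#' The rule-of-thumb bound N_min >= d / (2 p(e)) linking the number of
#' features d fed to a classifier and the tolerated error probability p(e):
#' with d = 5 selected features and p(e) = 0.05 it requires 50 subjects.
#'
#' @param d number of features (>= 1).
#' @param p_e tolerated probability of error, in (0, 1).
#' @param n_available optionally, the available sample size; adds a
#'   \code{sufficient} flag to the result.
#' @return the minimum N (numeric); if \code{n_available} is given, a list
#'   with \code{n_min}, \code{n_available}, \code{sufficient}.
#' @export
sample_size_bound <- function(d, p_e, n_available = NULL) {
  if (d < 1) stop("d must be >= 1")
  if (p_e <= 0 || p_e >= 1) stop("p_e must be in (0, 1)")
  n_min <- d / (2 * p_e)
  if (is.null(n_available)) return(n_min)
  list(n_min = n_min, n_available = n_available,
       sufficient = n_available >= n_min)
}
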