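#' Extract the three biomarker feature tables from a cohort
#'
#' Runs the three extractors over a (typically synthetic) cohort for one
#' structure: ICV-normalised volume, Laplacian spectral invariants of the
#' mask, and patch-averaged surface displacement magnitudes relative to the
#' template.
#'
#' @param cohort_data a \code{\link{generate_cohort}} result, or a list with
#'   elements \code{cohort}, \code{masks}, \code{meshes}, \code{template}.
#' @param n_eigen eigenvalues per spectral descriptor (default 100).
#' @param family spectral family (default "F2").
#' @param n_patches displacement patches (default 300).
#' @param kmeans_seed seed of the surface partition (default 42).
#' @param prealign rigid pre-alignment of targets (default TRUE).
#' @param verbose print per-subject progress.
#' @return named list of subjects x features matrices:
#'   \code{volume}, \code{invariants}, \code{displacement}; plus
#'   \code{labels}, \code{partition}, \code{vertex_fields} (subjects x
#'   vertices magnitude matrix, for partition sweeps) and
#'   \code{signed_fields}.
#' @export
extract_biomarkers <- function(cohort_data, n_eigen = 100L, family = "F2",
                               n_patches = 300L, kmeans_seed = 42L,
                               prealign = TRUE, verbose = FALSE) {
  cohort <- cohort_data$cohort
  ids <- cohort$subject_id
  n <- length(ids)

  vol <- NULL
  if (!is.null(cohort_data$masks)) {
    vt <- volume_table(cohort_data$masks, cohort, structure = "structure")
    vol <- matrix(vt$v_norm_mm3, ncol = 1,
                  dimnames = list(ids, "v_norm_mm3"))
  }

  inv <- NULL
  if (!is.null(cohort_data$masks)) {
    inv <- matrix(NA_real_, n, n_eigen - 1L,
                  dimnames = list(ids, sprintf("f_%03d",
                                               seq_len(n_eigen - 1L))))
    for (i in seq_len(n)) {
      if (verbose) message("spectral descriptor ", i, "/", n)
      sd_i <- spectral_descriptor(cohort_data$masks[[ids[i]]], n = n_eigen,
                                  family = family)
      inv[i, ] <- sd_i$features
    }
  }

  tmpl <- cohort_data$template
  part <- partition_surface(tmpl, n_patches = n_patches, seed = kmeans_seed)
  fields <- matrix(NA_real_, n, nrow(tmpl$vertices))
  sfields <- matrix(NA_real_, n, nrow(tmpl$vertices))
  disp <- matrix(NA_real_, n, n_patches,
                 dimnames = list(ids, sprintf("patch_%03d",
                                              seq_len(n_patches))))
  for (i in seq_len(n)) {
    fld <- displacement_field(tmpl, cohort_data$meshes[[ids[i]]],
                              prealign = prealign)
    fields[i, ] <- fld$magnitudes
    sfields[i, ] <- fld$signed
    disp[i, ] <- patch_features(fld, part)
  }

  out <- list(volume = vol, invariants = inv, displacement = disp,
              labels = cohort$group, partition = part,
              vertex_fields = fields, signed_fields = sfields)
  out[!vapply(out, is.null, logical(1))]
}

#' Three-class biomarker comparison
#'
#' The package's headline experiment: for each biomarker feature table, run
#' the fixed protocol (stratified 75/25 split, top-k information-gain
#' selection, SVM grid search on the training set only, scoring of the
#' held-out test set) and report the size-weighted multi-class AUC and the
#' cobweb misclassification axes. With \code{reps > 1} the split is redrawn
#' each repetition and mean/SD of the weighted AUC summarise robustness.
#'
#' @param biomarkers named list of subjects x features matrices.
#' @param labels diagnostic label per subject.
#' @param reps repetitions (1 = single fixed split; 10 mirrors the
#'   robustness experiment).
#' @param train_fraction per-class training fraction (default 0.75).
#' @param seed master seed.
#' @param k selected features (default 5).
#' @param grid model-selection grid.
#' @param classifier classifier name, see \code{\link{classifier_spec}}.
#' @return list with \code{summary} (data.frame: biomarker, mean and SD of
#'   weighted AUC), \code{reports} (first-repetition
#'   \code{evaluation_report} per biomarker), \code{axes} (cobweb axes per
#'   biomarker), and the run configuration.
#' @export
run_threeclass <- function(biomarkers, labels, reps = 1L,
                           train_fraction = 0.75, seed = 42L, k = 5L,
                           grid = default_grid(),
                           classifier = "rbf_svm") {
  spec <- classifier_spec(classifier)
  rows <- list()
  reports <- list()
  axes <- list()
  for (bm in names(biomarkers)) {
    rh <- repeated_holdout(biomarkers[[bm]], labels, n_reps = reps,
                           train_fraction = train_fraction, seed = seed,
                           grid = grid, spec = spec, k = k)
    rows[[bm]] <- data.frame(biomarker = bm,
                             weighted_auc = rh$mean_weighted_auc,
                             sd_weighted_auc = if (reps > 1L)
                               rh$sd_weighted_auc else NA_real_,
                             reps = reps, stringsAsFactors = FALSE)
    reports[[bm]] <- rh$reports[[1]]
    axes[[bm]] <- rh$reports[[1]]$axes
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$weighted_auc), ]
  rownames(summary) <- NULL
  list(summary = summary, reports = reports, axes = axes,
       config = list(reps = reps, train_fraction = train_fraction,
                     seed = seed, k = k, classifier = classifier))
}

#' Pairwise (two-class) biomarker evaluation
#'
#' For each pair of diagnostic groups, evaluates each biomarker both by
#' LOOCV and by the stratified 75/25 hold-out, reporting AUC, sensitivity
#' and specificity (the second group of the pair is the positive,
#' disease-like class when the pair contains NC; otherwise the second label
#' is positive).
#'
#' @inheritParams run_threeclass
#' @param pairs list of length-2 character vectors; default: all pairs of
#'   the observed labels.
#' @return data.frame with columns biomarker, pair, scheme (loocv/holdout),
#'   auc, sensitivity, specificity.
#' @export
run_pairwise <- function(biomarkers, labels, pairs = NULL,
                         train_fraction = 0.75, seed = 42L, k = 5L,
                         grid = default_grid(), classifier = "rbf_svm") {
  spec <- classifier_spec(classifier)
  labels <- as.character(labels)
  if (is.null(pairs)) {
    lv <- sort(unique(labels))
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
  }
  rows <- list()
  for (bm in names(biomarkers)) {
    X <- as.matrix(biomarkers[[bm]])
    for (pr in pairs) {
      sel <- labels %in% pr
      xp <- X[sel, , drop = FALSE]
      yp <- labels[sel]
      positive <- pr[2]
      lo <- loocv(xp, yp, grid = grid, spec = spec, k = k, seed = seed)
      bm_lo <- binary_metrics(lo$scores[, positive], yp, positive)
      sp <- stratified_split(yp, train_fraction, seed = seed)
      tm <- suppressWarnings(
        grid_search_train(xp[sp$train, , drop = FALSE], yp[sp$train],
                          grid = grid, spec = spec, k = k, seed = seed))
      sc <- predict_scores(tm, xp[sp$test, , drop = FALSE])
      bm_ho <- binary_metrics(sc[, positive], yp[sp$test], positive)
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, pair = paste(pr, collapse = " vs "),
        scheme = c("loocv", "holdout"),
        auc = c(bm_lo$auc, bm_ho$auc),
        sensitivity = c(bm_lo$sensitivity, bm_ho$sensitivity),
        specificity = c(bm_lo$specificity, bm_ho$specificity),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition-count sweep for displacement features
#'
#' Re-partitions the template at each requested patch count, rebuilds the
#' patch-averaged displacement features from the stored per-vertex fields
#' and evaluates the three-class weighted AUC (mean over repetitions).
#' Coarse partitions average the focal signal away; the sweep quantifies
#' that loss.
#'
#' @param vertex_fields subjects x vertices matrix of displacement
#'   magnitudes (from \code{\link{extract_biomarkers}}).
#' @param template the template \code{\link{surface_mesh}}.
#' @param labels diagnostic labels.
#' @param n_patches_list patch counts to sweep (default the study list
#'   5, 10, 20, 50, 100, 200, 300, capped at the vertex count).
#' @param reps,train_fraction,seed,k,grid,classifier as in
#'   \code{\link{run_threeclass}}.
#' @param kmeans_seed seed of each partition.
#' @return data.frame with n_patches, weighted_auc (mean over reps), sd.
#' @export
run_partition_sweep <- function(vertex_fields, template, labels,
                                n_patches_list = c(5, 10, 20, 50, 100,
                                                   200, 300),
                                reps = 1L, train_fraction = 0.75,
                                seed = 42L, k = 5L, grid = default_grid(),
                                classifier = "rbf_svm", kmeans_seed = 42L) {
  if (!length(n_patches_list)) stop("empty sweep list")
  spec <- classifier_spec(classifier)
  nv <- nrow(template$vertices)
  rows <- list()
  for (np in unique(pmin(n_patches_list, nv))) {
    part <- partition_surface(template, n_patches = np, seed = kmeans_seed)
    raw <- apply(vertex_fields, 1L, patch_features, partition = part)
    feats <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = 1L)
    colnames(feats) <- sprintf("patch_%03d", seq_len(np))
    rh <- repeated_holdout(feats, labels, n_reps = reps,
                           train_fraction = train_fraction, seed = seed,
                           grid = grid, spec = spec, k = k)
    rows[[length(rows) + 1L]] <- data.frame(
      n_patches = np, weighted_auc = rh$mean_weighted_auc,
      sd_weighted_auc = if (reps > 1L) rh$sd_weighted_auc else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialise a run report to JSON
#'
#' @param result a \code{\link{run_threeclass}} (or similar) result.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
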