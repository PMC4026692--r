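#' Structure volume from a binary mask
#'
#' Volume is the foreground voxel count times the physical voxel volume
#' dx*dy*dz.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing)
}

#' Fit the head-size (ICV) normalisation model
#'
#' Removes head-size effects from structure volumes by the residual method:
#' the slope k of an ordinary least-squares regression of absolute structure
#' volume on intracranial volume is estimated over a reference group
#' (normal controls by default, to keep disease-driven atrophy out of the
#' slope), together with the reference-group mean ICV.
#'
#' @param v_abs absolute structure volumes (mm^3) of the reference subjects.
#' @param icv intracranial volumes (mm^3) of the same subjects.
#' @param reference_group label recorded in the model (bookkeeping only).
#' @return An object of class \code{normalization_model} with elements
#'   \code{k}, \code{icv_mean}, \code{reference_group}, \code{n}.
#' @export
fit_normalization <- function(v_abs, icv, reference_group = "NC") {
  if (length(v_abs) != length(icv)) stop("v_abs and icv lengths differ")
  if (length(icv) < 3L) stop("need at least 3 reference subjects")
  if (stats::sd(icv) == 0) stop("degenerate regression: ICV is constant")
  fit <- stats::lm(v_abs ~ icv)
  structure(list(k = unname(stats::coef(fit)[2]),
                 icv_mean = mean(icv),
                 reference_group = reference_group,
                 n = length(icv)),
            class = "normalization_model")
}

#' @method print normalization_model
#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf("ICV normalisation: k = %.6g, ICV_mean = %.6g mm^3 (%s, n=%d)\n",
              x$k, x$icv_mean, x$reference_group, x$n))
  invisible(x)
}

#' Normalise a structure volume for head size
#'
#' Applies V_norm = V_abs - k * (ICV - ICV_mean) with the slope and mean ICV
#' from a fitted \code{\link{fit_normalization}} model. Vectorised over
#' subjects.
#'
#' @param v_abs absolute volume(s), mm^3.
#' @param icv intracranial volume(s), mm^3.
#' @param model a \code{normalization_model}.
#' @return normalised volume(s), mm^3.
#' @export
normalize_volume <- function(v_abs, icv, model) {
  stopifnot(inherits(model, "normalization_model"))
  v_abs - model$k * (icv - model$icv_mean)
}

#' Volume feature table for a cohort
#'
#' Computes absolute and ICV-normalised volumes for a list of masks, fitting
#' the normalisation slope on the reference group.
#'
#' @param masks named list of \code{\link{binary_mask}}, names = subject ids.
#' @param cohort a \code{cohort_table} covering the same subjects.
#' @param structure structure name recorded in the output.
#' @param reference_group group used to fit the slope; \code{"all"} pools
#'   every subject.
#' @return data.frame with subject_id, structure, v_abs_mm3, v_norm_mm3.
#' @export
volume_table <- function(masks, cohort, structure = "structure",
                         reference_group = "NC") {
  ids <- cohort$subject_id
  if (!all(ids %in% names(masks)))
    stop("masks missing for subjects: ",
         paste(setdiff(ids, names(masks)), collapse = ", "))
  v_abs <- vapply(masks[ids], mask_volume, numeric(1))
  ref <- if (identical(reference_group, "all")) rep(TRUE, length(ids))
         else cohort$group == reference_group
  model <- fit_normalization(v_abs[ref], cohort$icv[ref],
                             reference_group = reference_group)
  data.frame(subject_id = ids, structure = structure,
             v_abs_mm3 = unname(v_abs),
             v_norm_mm3 = unname(normalize_volume(v_abs, cohort$icv, model)),
             stringsAsFactors = FALSE)
}
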