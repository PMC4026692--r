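#' Read a cohort table
#'
#' Loads the per-subject table driving a study run: subject identifiers,
#' diagnostic group, intracranial volume (ICV, mm^3) and any per-structure
#' file-path columns. Validation is strict because every downstream stage
#' trusts this table.
#'
#' @param path CSV file with header columns \code{subject_id}, \code{group},
#'   \code{icv}; further columns (typically file paths per structure) are
#'   carried through untouched.
#' @param groups character vector of allowed diagnostic labels.
#' @return A \code{data.frame} of class \code{cohort_table}.
#' @export
read_cohort <- function(path, groups = c("NC", "AD", "FTD")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, groups)
}

#' Validate a cohort data frame
#'
#' @param df data.frame with subject_id, group, icv columns.
#' @param groups allowed group labels.
#' @return the validated data.frame, classed \code{cohort_table}.
#' @export
validate_cohort <- function(df, groups = c("NC", "AD", "FTD")) {
  need <- c("subject_id", "group", "icv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    stop("unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(groups, collapse = ", "))
  if (any(!is.finite(df$icv)) || any(df$icv <= 0))
    stop("icv must be positive and finite (mm^3)")
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "groups") <- groups
  df
}

#' Write a cohort table to CSV
#' @param cohort a cohort_table (or plain data.frame).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
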