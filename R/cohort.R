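#' CSF analyte column names used throughout the pipeline
#'
#' `gmnet_analytes()` returns the ten CSF analyte columns; `gmnet_log_analytes()`
#' the eight that are log-transformed before modelling (amyloid peptides and
#' the amyloid ratio are used on their native scale).
#'
#' @return Character vector of column names.
#' @export
gmnet_analytes <- function() {
  c("abeta42", "abeta40", "ptau", "ttau", "snap25",
    "ng", "nfl", "vilip1", "ykl40", "strem2")
}

#' @rdname gmnet_analytes
#' @export
gmnet_log_analytes <- function() {
  c("ptau", "ttau", "snap25", "ng", "nfl", "vilip1", "ykl40", "strem2")
}

.required_cohort_cols <- c("subject_id", "mutation_status", "sex")

#' Read a cohort table from CSV
#'
#' Expects a header row and at least `subject_id`, `mutation_status`, `sex`.
#' Empty biomarker cells become `NA`. Duplicate subject ids are an error;
#' downstream stages check the optional columns they need.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  miss <- setdiff(.required_cohort_cols, names(df))
  if (length(miss)) stop("cohort table missing required column(s): ",
                         paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "))
  as_cohort_table(df)
}

#' @rdname read_cohort_table
#' @param table A cohort `data.frame`.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(format_cohort_for_csv(table), path, row.names = FALSE, na = "")
  invisible(path)
}

format_cohort_for_csv <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x) signif(x, 12))
  table
}

as_cohort_table <- function(df) {
  class(df) <- c("cohort_table", "data.frame")
  df
}
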