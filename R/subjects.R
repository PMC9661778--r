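#' Validate and normalize a subject record table
#'
#' One row per subject and timepoint: demographic fields used by the
#' percent-predicted RV normalization, catheter pressures used by the
#' stiffness metrics, RV volumetry, and (optionally) the end-diastolic /
#' end-systolic timepoints defining the cardiac windows.
#'
#' @param df data.frame with columns `id`, `timepoint` (`"pre"`/`"post"`),
#'   `sex` (`"F"`/`"M"`), `age` (years), `height` (cm), `weight` (kg), and
#'   optionally `SPAP`, `DPAP`, `mPAP` (mmHg), `TPR` (Wood units), `RVEF`
#'   (%), `RVEDV`, `RVESV`, `RVSV` (ml), `t_ED`, `t_ES` (s).
#' @return the validated data.frame, class `subject_records`.
#' @export
subject_records <- function(df) {
  req <- c("id", "timepoint", "sex", "age", "height", "weight")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing subject columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  for (col in c("age", "height", "weight"))
    if (any(df[[col]] <= 0, na.rm = TRUE))
      stop(col, " must be positive")
  if (all(c("SPAP", "DPAP") %in% names(df))) {
    both <- !is.na(df$SPAP) & !is.na(df$DPAP)
    if (any(df$SPAP[both] <= df$DPAP[both]))
      stop("SPAP must exceed DPAP")
  }
  if (anyDuplicated(df[c("id", "timepoint")]))
    stop("duplicate (id, timepoint) rows")
  class(df) <- c("subject_records", "data.frame")
  df
}

#' Read subject records from CSV
#' @param path CSV file.
#' @return a [subject_records()] data.frame.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  subject_records(utils::read.csv(path, stringsAsFactors = FALSE))
}
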