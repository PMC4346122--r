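# CSV readers/writers for the documented tabular schemas.

#' Read a clinical feature table
#'
#' One row per patient, a `patient_id` column plus every criterion column in
#' [feature_columns()] coded 0/1. Validation is strict: missing columns or
#' values, non-binary codes, or conflicting cognitive-profile criteria are
#' errors.
#'
#' @param path CSV file path.
#' @return Validated clinical feature data.frame (criteria as logical).
#' @export
read_features_csv <- function(path) {
  validate_features(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a clinical feature table
#'
#' @param features Clinical feature data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  features <- validate_features(features)
  bool_cols <- setdiff(all_feature_columns(), "patient_id")
  for (cl in bool_cols) features[[cl]] <- as.integer(features[[cl]])
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format ROI uptake table
#'
#' Columns `patient_id`, `roi` (frontal / temporoparietal / common / pons),
#' `side` (left / right), `mean_uptake` (positive, tracer units).
#'
#' @param path CSV file path.
#' @return Validated uptake data.frame.
#' @export
read_uptake_csv <- function(path) {
  validate_uptake(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a long-format ROI uptake table
#'
#' @param uptake Uptake data.frame (see [read_uptake_csv()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_uptake_csv <- function(uptake, path) {
  uptake <- validate_uptake(uptake)
  utils::write.csv(uptake, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-activity curve from frame-table CSV
#'
#' Columns `frame_start_min`, `frame_end_min`, `activity`; the frame mid-time
#' is the midpoint of each frame.
#'
#' @param path CSV file path.
#' @param role `"target"` or `"reference"`.
#' @return A [tac()] object.
#' @export
read_tac_csv <- function(path, role = c("target", "reference")) {
  role <- match.arg(role)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_min", "frame_end_min", "activity")
  if (!all(need %in% names(d))) {
    stop("TAC file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tac((d$frame_start_min + d$frame_end_min) / 2, d$activity, role)
}

#' Write variant calls to CSV
#'
#' @param calls Variant-call data.frame from [classify_variants()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
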