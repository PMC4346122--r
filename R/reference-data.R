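# Published reference results used as fixed inputs: per-modality confusion
# counts against amyloid status, APOE epsilon-4 carrier counts, and the
# autopsy/biopsy case table. These printed summaries are the only
# patient-level information released with the original cohort.

#' Published per-modality confusion counts
#'
#' Confusion counts of each assessment modality against amyloid (PIB) PET
#' status, as reported for the original 25-patient CBS cohort: modified
#' clinical criteria, visual FDG-PET reads, quantitative ROI-based FDG-PET,
#' and visual MRI reads. A positive prediction is a temporoparietal-variant
#' call; the reference positive is PIB+. Per-modality totals differ because
#' not every patient had every modality.
#'
#' @return data.frame with columns `modality`, `n`, `tn`, `tp`, `fn`, `fp`.
#' @export
reference_modality_counts <- function() {
  data.frame(
    modality = c("criteria", "fdg_visual", "fdg_quant", "mri"),
    n = c(25L, 23L, 22L, 24L),
    tn = c(10L, 6L, 7L, 6L),
    tp = c(9L, 10L, 9L, 8L),
    fn = c(2L, 1L, 1L, 3L),
    fp = c(4L, 6L, 5L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Per-patient calls consistent with the published confusion counts
#'
#' Expands [reference_modality_counts()] into a deterministic per-patient
#' call table. Individual patient-level calls were not released, so the
#' assignment of calls to synthetic patient ids is arbitrary — but any
#' assignment with the published per-modality cell counts yields identical
#' 2x2 tables, which is all downstream statistics consume. Patients lacking
#' a modality carry `NA` for that column.
#'
#' @return List with `calls` (data.frame: `patient_id` plus one `"FV"`/
#'   `"TPV"` column per modality) and `reference` (named logical PIB status;
#'   11 positive, 14 negative).
#' @export
reference_modality_calls <- function() {
  ids <- sprintf("P%02d", 1:25)
  pib <- stats::setNames(c(rep(TRUE, 11), rep(FALSE, 14)), ids)
  counts <- reference_modality_counts()
  calls <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  pos_ids <- ids[1:11]
  neg_ids <- ids[12:25]
  for (i in seq_len(nrow(counts))) {
    m <- counts$modality[i]
    # patients without this modality are dropped from the end of each group
    n_pos <- counts$tp[i] + counts$fn[i]
    n_neg <- counts$tn[i] + counts$fp[i]
    lab <- stats::setNames(rep(NA_character_, 25), ids)
    lab[pos_ids[seq_len(n_pos)]] <-
      c(rep("TPV", counts$tp[i]), rep("FV", counts$fn[i]))
    lab[neg_ids[seq_len(n_neg)]] <-
      c(rep("TPV", counts$fp[i]), rep("FV", counts$tn[i]))
    calls[[m]] <- unname(lab)
  }
  list(calls = calls, reference = pib)
}

#' Published APOE epsilon-4 carrier counts by amyloid status
#'
#' Six of ten genotyped PIB+ patients and one of ten genotyped PIB- patients
#' carried at least one APOE epsilon-4 allele.
#'
#' @return A [contingency_2x2()] with carrier-positive as the prediction and
#'   PIB+ as the reference positive (tp = 6, fp = 1, fn = 4, tn = 9).
#' @export
apoe_reference_table <- function() {
  contingency_2x2(tp = 6, fp = 1, fn = 4, tn = 9)
}

#' Autopsy/biopsy case table
#'
#' The eight patients with histopathology: amyloid PET status, primary
#' pathological diagnoses, and the variant call of each assessment modality.
#' Shipped as a plain-text table under `inst/extdata`.
#'
#' @return data.frame with columns `patient_id`, `pib_positive` (logical),
#'   `pathology`, `ad_containing` (logical: pathology includes Alzheimer's
#'   disease), `criteria`, `fdg_visual`, `fdg_quant`, `mri` (`"FV"`/`"TPV"`,
#'   `NA` where unavailable).
#' @export
pathology_cases <- function() {
  path <- system.file("extdata", "pathology_cases.csv",
                      package = "cbspredict", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$pib_positive <- as.logical(d$pib_positive)
  d$ad_containing <- grepl("\\bAD\\b", d$pathology)
  d[c("patient_id", "pib_positive", "pathology", "ad_containing",
      "criteria", "fdg_visual", "fdg_quant", "mri")]
}
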