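# Orchestration: modality-by-statistic reports against amyloid status, and
# predictor combination.

as_reference_status <- function(reference) {
  if (is.data.frame(reference)) {
    need <- c("patient_id", "pib_positive")
    if (!all(need %in% names(reference))) {
      stop("reference table needs columns patient_id and pib_positive",
           call. = FALSE)
    }
    reference <- stats::setNames(as.logical(reference$pib_positive),
                                 reference$patient_id)
  }
  if (is.null(names(reference)) || !is.logical(reference)) {
    stop("reference must be a named logical vector or a data.frame",
         call. = FALSE)
  }
  reference
}

#' Modality-by-statistic diagnostic report
#'
#' For each modality column in `calls`, cross-tabulates the binary variant
#' calls against amyloid (PIB) status and reports the full diagnostic
#' profile. Patients with a missing call for a modality are dropped pairwise
#' for that modality (logged via a message), never imputed.
#'
#' @param calls data.frame with a `patient_id` column plus one column per
#'   modality holding variant labels (`"FV"` / `"TPV"`, `NA` for patients
#'   lacking that modality).
#' @param reference Named logical vector of PIB status (`TRUE` = PIB+) or a
#'   data.frame with `patient_id` and `pib_positive` columns.
#' @param positive_label Call treated as the positive prediction
#'   (default `"TPV"`).
#' @param ci_method Passed to [performance()].
#' @param audit If `TRUE`, attach an `"audit"` attribute listing the
#'   contributing patient ids per cell and modality.
#' @return data.frame, one row per modality: `modality`, `n`, `tn`, `tp`,
#'   `fn`, `fp`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (with `*_lower`/`*_upper` 95% bounds), `or`, `or_lower`, `or_upper`,
#'   `fisher_p` (two-sided).
#' @examples
#' fx <- reference_modality_calls()
#' run_report(fx$calls, fx$reference)
#' @export
run_report <- function(calls, reference, positive_label = "TPV",
                       ci_method = c("clopper-pearson", "wald"),
                       audit = FALSE) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(calls), "patient_id" %in% names(calls))
  if (anyDuplicated(calls$patient_id)) {
    stop("duplicated patient_id in calls table", call. = FALSE)
  }
  reference <- as_reference_status(reference)
  modalities <- setdiff(names(calls), "patient_id")
  if (length(modalities) == 0L) stop("no modality columns", call. = FALSE)

  # stable order regardless of input row order
  calls <- calls[order(calls$patient_id), , drop = FALSE]
  rows <- list()
  audit_log <- list()
  for (m in modalities) {
    lab <- toupper(as.character(calls[[m]]))
    keep <- !is.na(lab)
    if (sum(keep) == 0L) {
      stop("no overlapping patients with calls for modality ", m,
           call. = FALSE)
    }
    if (any(!keep)) {
      message("modality ", m, ": dropped ", sum(!keep),
              " patient(s) without a call: ",
              paste(calls$patient_id[!keep], collapse = ", "))
    }
    pred <- stats::setNames(lab[keep] == toupper(positive_label),
                            calls$patient_id[keep])
    ref_m <- reference[names(pred)]
    if (anyNA(ref_m)) {
      stop("modality ", m, ": patients missing from reference: ",
           paste(names(pred)[is.na(ref_m)], collapse = ", "), call. = FALSE)
    }
    ct <- build_contingency(pred, ref_m)
    perf <- performance(ct, ci_method = ci_method)
    g <- function(stat, col) perf[[col]][perf$statistic == stat]
    or <- odds_ratio(ct)
    rows[[m]] <- data.frame(
      modality = m, n = total_2x2(ct), tn = ct$tn, tp = ct$tp, fn = ct$fn,
      fp = ct$fp,
      accuracy = g("accuracy", "estimate"),
      accuracy_lower = g("accuracy", "lower"),
      accuracy_upper = g("accuracy", "upper"),
      sensitivity = g("sensitivity", "estimate"),
      sensitivity_lower = g("sensitivity", "lower"),
      sensitivity_upper = g("sensitivity", "upper"),
      specificity = g("specificity", "estimate"),
      specificity_lower = g("specificity", "lower"),
      specificity_upper = g("specificity", "upper"),
      ppv = g("ppv", "estimate"), ppv_lower = g("ppv", "lower"),
      ppv_upper = g("ppv", "upper"),
      npv = g("npv", "estimate"), npv_lower = g("npv", "lower"),
      npv_upper = g("npv", "upper"),
      or = or$or_estimate, or_lower = or$ci95[["lower"]],
      or_upper = or$ci95[["upper"]],
      fisher_p = fisher_exact(ct, "two"),
      stringsAsFactors = FALSE)
    if (audit) {
      audit_log[[m]] <- list(
        tp = names(pred)[pred & ref_m], fp = names(pred)[pred & !ref_m],
        fn = names(pred)[!pred & ref_m], tn = names(pred)[!pred & !ref_m])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (audit) attr(out, "audit") <- audit_log
  out
}

#' Combine two binary predictors
#'
#' Conjunction rule: positive only when both inputs are positive (e.g.
#' temporoparietal clinical criteria AND temporoparietal-predominant
#' FDG-PET). Never increases the positive count relative to either input.
#'
#' @param calls_a,calls_b Named logical vectors over the same patient ids.
#' @param rule Combination rule; only `"both_positive"` is defined.
#' @return Named logical vector.
#' @export
combine_predictors <- function(calls_a, calls_b, rule = "both_positive") {
  rule <- match.arg(rule, "both_positive")
  calls_b <- align_labels(calls_a, calls_b, what = "calls_a")
  stopifnot(is.logical(calls_a), is.logical(calls_b))
  calls_a & calls_b
}
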