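# Rule engine for the modified CBS research criteria: core screening plus
# frontal-variant (fvCBS) vs temporoparietal-variant (tpvCBS) classification.

#' Clinical criterion column manifest
#'
#' Names of the boolean criterion columns a clinical feature table must carry,
#' grouped by role. Every column must be explicitly present and coded 0/1 (or
#' logical); missing values are rejected, never imputed, because each criterion
#' is chart-coded as present or absent.
#'
#' @return Named list of character vectors: `core` (the five core motor/sensory
#'   features), `exclusion` (six features that must all be absent),
#'   `fv` (four frontal-variant features), `tpv` (three temporoparietal-variant
#'   features), and `other` (`patient_id`, `progressive_course`).
#' @examples
#' feature_columns()$core
#' @export
feature_columns <- function() {
  list(
    other = c("patient_id", "progressive_course"),
    core = c("parkinsonism", "dystonia", "myoclonus",
             "impaired_voluntary_limb_control", "cortical_sensory_deficit"),
    exclusion = c("visual_hallucinations", "rbd", "cerebellar_ataxia",
                  "autonomic_dysfunction", "fluctuating_alertness",
                  "rest_tremor"),
    fv = c("nonfluent_or_motor_speech", "behavioral_change",
           "lower_extremity_apraxia", "executive_worse_than_mem_visuospatial"),
    tpv = c("logopenic_aphasia", "gerstmann_or_balint",
            "mem_visuospatial_worse_than_executive")
  )
}

all_feature_columns <- function() unlist(feature_columns(), use.names = FALSE)

#' Validate a clinical feature table
#'
#' Checks that every criterion column is present, coded in \{0, 1\} (or logical)
#' with no missing values, that patient ids are unique, and that the two
#' cognitive-profile criteria (`executive_worse_than_mem_visuospatial`,
#' `mem_visuospatial_worse_than_executive`) are never both positive — they are
#' mutually exclusive by construction and conflicting input is a hard error,
#' not a silent repair.
#'
#' @param features data.frame with one row per patient; see [feature_columns()].
#' @return The table with criterion columns coerced to logical, invisibly
#'   usable downstream.
#' @export
validate_features <- function(features) {
  stopifnot(is.data.frame(features))
  cols <- all_feature_columns()
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0L) {
    stop("malformed clinical feature table: missing field(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(features$patient_id)) {
    stop("duplicated patient_id in clinical feature table", call. = FALSE)
  }
  bool_cols <- setdiff(cols, "patient_id")
  for (cl in bool_cols) {
    v <- features[[cl]]
    if (anyNA(v)) {
      stop("malformed clinical feature table: missing value in field '",
           cl, "'", call. = FALSE)
    }
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) {
        stop("field '", cl, "' must be coded 0/1", call. = FALSE)
      }
      v <- v == 1
    }
    if (!is.logical(v)) {
      stop("field '", cl, "' must be logical or 0/1", call. = FALSE)
    }
    features[[cl]] <- v
  }
  conflict <- features$executive_worse_than_mem_visuospatial &
    features$mem_visuospatial_worse_than_executive
  if (any(conflict)) {
    stop("mutually exclusive cognitive-profile criteria both positive for ",
         "patient(s): ",
         paste(features$patient_id[conflict], collapse = ", "), call. = FALSE)
  }
  features
}

one_patient <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
  }
  features <- validate_features(features)
  if (nrow(features) != 1L) stop("expected exactly one patient", call. = FALSE)
  features
}

#' Core CBS eligibility screen
#'
#' A patient is core-eligible when the course is progressive, at least three of
#' the five core features are present, and every exclusion feature is absent.
#'
#' @param features One-row data.frame (or named list) of clinical criteria;
#'   see [feature_columns()].
#' @return Object of class `core_eligibility`: list with `eligible`,
#'   `n_core_features_met` (0-5) and `failed_exclusions` (names of every
#'   exclusion feature that is present).
#' @examples
#' f <- blank_features("p1")
#' f[c("progressive_course", "parkinsonism", "dystonia", "myoclonus")] <- TRUE
#' check_core(f)
#' @export
check_core <- function(features) {
  features <- one_patient(features)
  cols <- feature_columns()
  n_core <- sum(unlist(features[cols$core]))
  failed <- cols$exclusion[unlist(features[cols$exclusion])]
  out <- list(
    eligible = isTRUE(features$progressive_course) && n_core >= 3L &&
      length(failed) == 0L,
    n_core_features_met = as.integer(n_core),
    failed_exclusions = failed
  )
  class(out) <- "core_eligibility"
  out
}

#' @export
print.core_eligibility <- function(x, ...) {
  cat("Core CBS screen:", if (x$eligible) "eligible" else "NOT eligible",
      sprintf("(%d/5 core features)\n", x$n_core_features_met))
  if (length(x$failed_exclusions)) {
    cat("  exclusions present:", paste(x$failed_exclusions, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Evaluate variant-level criteria
#'
#' Counts how many frontal-variant and temporoparietal-variant features are
#' present; a variant is met when at least one of its features is present
#' (on top of core eligibility, which the caller must have established).
#'
#' @inheritParams check_core
#' @return List with `met_fv`, `n_fv_met`, `met_tpv`, `n_tpv_met`.
#' @export
evaluate_variants <- function(features) {
  features <- one_patient(features)
  if (!check_core(features)$eligible) {
    stop("evaluate_variants() called on a core-ineligible patient",
         call. = FALSE)
  }
  cols <- feature_columns()
  n_fv <- sum(unlist(features[cols$fv]))
  n_tpv <- sum(unlist(features[cols$tpv]))
  list(met_fv = n_fv >= 1L, n_fv_met = as.integer(n_fv),
       met_tpv = n_tpv >= 1L, n_tpv_met = as.integer(n_tpv))
}

#' Adjudicate a frontal vs temporoparietal variant call
#'
#' Deterministic replacement for the clinician's overall impression when a
#' patient meets criteria for both variants. Precedence:
#' \enumerate{
#'   \item `single_variant` — exactly one variant met;
#'   \item `cognitive_dominance` — both met and exactly one of the two
#'     cognitive-profile criteria (executive-worse vs
#'     memory/visuospatial-worse) is present: the relative pattern of
#'     cognitive impairment is the only individually predictive criterion,
#'     so it dominates;
#'   \item `count_majority` — both met, neither cognitive criterion: the
#'     variant with more features present;
#'   \item `default` — still tied: FV with equivocal confidence, because
#'     non-AD pathology is the prior majority in CBS.
#' }
#' Confidence uses the 5-point scale (1 = highest-confidence FV, 3 =
#' equivocal, 5 = highest-confidence TPV): `single_variant` maps to 1/5,
#' `cognitive_dominance` and `count_majority` to 2/4, `default` to 3.
#'
#' @param met_fv,met_tpv logical, variant met flags from [evaluate_variants()].
#' @param n_fv_met,n_tpv_met integer feature counts from [evaluate_variants()].
#' @param features The patient's clinical feature row (used for the
#'   cognitive-profile tie-breaker).
#' @return Object of class `variant_call`: list with `label` ("FV"/"TPV"),
#'   `met_fv`, `met_tpv`, `n_fv_met`, `n_tpv_met`, `adjudication_rule`,
#'   `confidence`.
#' @export
adjudicate <- function(met_fv, n_fv_met, met_tpv, n_tpv_met, features) {
  if (!met_fv && !met_tpv) {
    stop("no variant criteria met: nothing to adjudicate", call. = FALSE)
  }
  features <- one_patient(features)
  exec_worse <- isTRUE(features$executive_worse_than_mem_visuospatial)
  memvis_worse <- isTRUE(features$mem_visuospatial_worse_than_executive)

  if (xor(met_fv, met_tpv)) {
    label <- if (met_fv) "FV" else "TPV"
    rule <- "single_variant"
    confidence <- if (met_fv) 1L else 5L
  } else if (xor(exec_worse, memvis_worse)) {
    label <- if (exec_worse) "FV" else "TPV"
    rule <- "cognitive_dominance"
    confidence <- if (exec_worse) 2L else 4L
  } else if (n_fv_met != n_tpv_met) {
    label <- if (n_fv_met > n_tpv_met) "FV" else "TPV"
    rule <- "count_majority"
    confidence <- if (n_fv_met > n_tpv_met) 2L else 4L
  } else {
    label <- "FV"
    rule <- "default"
    confidence <- 3L
  }
  out <- list(label = label, met_fv = met_fv, met_tpv = met_tpv,
              n_fv_met = n_fv_met, n_tpv_met = n_tpv_met,
              adjudication_rule = rule, confidence = confidence)
  class(out) <- "variant_call"
  out
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("Variant call: %s (rule: %s, confidence %d/5)\n",
              x$label, x$adjudication_rule, x$confidence))
  cat(sprintf("  fv features met: %d; tpv features met: %d\n",
              x$n_fv_met, x$n_tpv_met))
  invisible(x)
}

#' Classify a cohort of patients into clinical variants
#'
#' Runs the full rule engine — core screen, variant evaluation, adjudication —
#' over a clinical feature table.
#'
#' @param features data.frame, one row per patient; see [feature_columns()].
#' @param on_ineligible What to do with patients failing the core screen:
#'   `"error"` (default) or `"drop"` (dropped ids reported via a message).
#' @return data.frame with one row per classified patient: `patient_id`,
#'   `label`, `met_fv`, `met_tpv`, `n_fv_met`, `n_tpv_met`,
#'   `adjudication_rule`, `confidence`.
#' @examples
#' f <- blank_features("p1")
#' f[c("progressive_course", "parkinsonism", "dystonia", "myoclonus",
#'     "logopenic_aphasia")] <- TRUE
#' classify_variants(f)
#' @export
classify_variants <- function(features, on_ineligible = c("error", "drop")) {
  on_ineligible <- match.arg(on_ineligible)
  features <- validate_features(features)
  rows <- vector("list", nrow(features))
  dropped <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    core <- check_core(f)
    if (!core$eligible) {
      if (on_ineligible == "error") {
        stop("patient ", f$patient_id, " does not meet core CBS criteria",
             call. = FALSE)
      }
      dropped <- c(dropped, f$patient_id)
      next
    }
    ev <- evaluate_variants(f)
    if (!ev$met_fv && !ev$met_tpv) {
      if (on_ineligible == "error") {
        stop("patient ", f$patient_id,
             " meets core criteria but neither variant", call. = FALSE)
      }
      dropped <- c(dropped, f$patient_id)
      next
    }
    vc <- adjudicate(ev$met_fv, ev$n_fv_met, ev$met_tpv, ev$n_tpv_met, f)
    rows[[i]] <- data.frame(
      patient_id = f$patient_id, label = vc$label,
      met_fv = vc$met_fv, met_tpv = vc$met_tpv,
      n_fv_met = vc$n_fv_met, n_tpv_met = vc$n_tpv_met,
      adjudication_rule = vc$adjudication_rule, confidence = vc$confidence,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    message("dropped ", length(dropped), " patient(s) failing criteria: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), label = character(0),
                      met_fv = logical(0), met_tpv = logical(0),
                      n_fv_met = integer(0), n_tpv_met = integer(0),
                      adjudication_rule = character(0),
                      confidence = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Blank clinical feature row
#'
#' Convenience constructor: all criteria absent for the given patient ids.
#'
#' @param patient_id character vector of ids.
#' @return data.frame with every criterion column set to `FALSE`.
#' @export
blank_features <- function(patient_id) {
  cols <- setdiff(all_feature_columns(), "patient_id")
  out <- data.frame(patient_id = patient_id, stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- rep(FALSE, length(patient_id))
  out
}
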