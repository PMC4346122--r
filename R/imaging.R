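# Quantitative PET measures: pons-normalized SUVR, control-referenced
# regional Z-scores, Z-difference classification, lateralization indices,
# and amyloid-positivity thresholding on a global DVR.

cortical_rois <- function() c("frontal", "temporoparietal", "common")

#' Standardized uptake value ratio
#'
#' Regional mean uptake divided by the mean uptake of the reference region
#' (pons for FDG in this pipeline).
#'
#' @param roi_mean,pons_mean Positive regional and reference mean uptake, same
#'   tracer units.
#' @return `roi_mean / pons_mean` (vectorized).
#' @examples
#' compute_suvr(1.2, 1.0)
#' @export
compute_suvr <- function(roi_mean, pons_mean) {
  if (any(!is.finite(pons_mean)) || any(pons_mean <= 0)) {
    stop("invalid reference: pons mean uptake must be positive", call. = FALSE)
  }
  if (any(!is.finite(roi_mean)) || any(roi_mean <= 0)) {
    stop("invalid uptake: ROI mean uptake must be positive", call. = FALSE)
  }
  roi_mean / pons_mean
}

#' Control-referenced Z-score
#'
#' Expresses a patient's regional SUVR in standard-deviation units of the
#' normal-control distribution for the same region. Negative values mean the
#' patient is hypometabolic relative to controls; "lowest Z" reads as most
#' negative.
#'
#' @param suvr Patient regional SUVR.
#' @param control_mean,control_sd Control-group mean and standard deviation of
#'   the same regional SUVR; `control_sd` must be positive.
#' @return `(suvr - control_mean) / control_sd` (vectorized).
#' @export
compute_z <- function(suvr, control_mean, control_sd) {
  if (any(!is.finite(control_sd)) || any(control_sd <= 0)) {
    stop("degenerate reference: control SD must be positive", call. = FALSE)
  }
  (suvr - control_mean) / control_sd
}

#' Frontal minus temporoparietal Z-difference
#'
#' `Z(frontal) - Z(temporoparietal)` on the bilateral composites. Positive
#' values indicate temporoparietal-predominant hypometabolism.
#'
#' @param z_frontal,z_temporoparietal Regional Z-scores.
#' @return Numeric difference (vectorized).
#' @export
z_difference <- function(z_frontal, z_temporoparietal) {
  z_frontal - z_temporoparietal
}

#' Quantitative FDG variant classification
#'
#' Classifies by the lowest (most negative) bilateral ROI Z-score: TPV when
#' the temporoparietal Z is lower than the frontal Z, FV when the frontal Z is
#' lower. An exact tie goes to FV, consistent with the clinical rule engine's
#' default (ties have measure zero on real data). The "common" peri-rolandic
#' ROI is shared across variants and takes no part in the decision.
#'
#' @param z_frontal,z_temporoparietal Bilateral composite Z-scores.
#' @return Character vector, `"FV"` or `"TPV"`.
#' @export
classify_fdg_quant <- function(z_frontal, z_temporoparietal) {
  if (anyNA(z_frontal) || anyNA(z_temporoparietal)) {
    stop("bilateral frontal and temporoparietal Z-scores required",
         call. = FALSE)
  }
  ifelse(z_temporoparietal < z_frontal, "TPV", "FV")
}

#' Lateralization index
#'
#' Percent hemispheric asymmetry of regional uptake, `|right/left - 1| * 100`.
#' Note the asymmetry of the formula itself: `lateralization_index(r, l)` and
#' `lateralization_index(l, r)` differ in general (e.g. 10 vs ~9.09 for a
#' 1.1:1 ratio); the right-over-left orientation is part of the definition.
#'
#' @param right,left Positive mean uptake of the right and left ROI.
#' @return Non-negative percent asymmetry (vectorized).
#' @examples
#' lateralization_index(1.1, 1.0)  # 10
#' lateralization_index(0.9, 1.0)  # 10
#' @export
lateralization_index <- function(right, left) {
  if (any(!is.finite(right)) || any(!is.finite(left)) ||
      any(right <= 0) || any(left <= 0)) {
    stop("invalid uptake: hemispheric means must be positive", call. = FALSE)
  }
  abs(right / left - 1) * 100
}

#' Amyloid positivity from a global DVR
#'
#' Thresholds a global cortical PIB distribution volume ratio at the
#' conventional cutoff; the boundary is inclusive (DVR >= threshold is
#' positive).
#'
#' @param global_dvr Positive global DVR.
#' @param threshold Positivity cutoff, default 1.20.
#' @param patient_id Optional id carried through to the result.
#' @return Object of class `pib_call`: list with `patient_id`, `positive`,
#'   `source = "dvr_threshold"`, `global_dvr`, `threshold`.
#' @examples
#' classify_pib_quant(1.20)$positive  # TRUE: boundary is inclusive
#' @export
classify_pib_quant <- function(global_dvr, threshold = 1.20,
                               patient_id = NA_character_) {
  stopifnot(length(global_dvr) == 1L)
  if (!is.finite(global_dvr) || global_dvr <= 0) {
    stop("global DVR must be positive", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  out <- list(patient_id = patient_id, positive = global_dvr >= threshold,
              source = "dvr_threshold", global_dvr = global_dvr,
              threshold = threshold)
  class(out) <- "pib_call"
  out
}

#' @export
print.pib_call <- function(x, ...) {
  cat(sprintf("PIB call: %s (global DVR %.3f, threshold %.2f, source %s)\n",
              if (x$positive) "positive" else "negative",
              x$global_dvr, x$threshold, x$source))
  invisible(x)
}

# ---- long-format uptake tables ------------------------------------------

validate_uptake <- function(uptake) {
  stopifnot(is.data.frame(uptake))
  need <- c("patient_id", "roi", "side", "mean_uptake")
  miss <- setdiff(need, names(uptake))
  if (length(miss)) {
    stop("uptake table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_roi <- setdiff(unique(uptake$roi), c(cortical_rois(), "pons"))
  if (length(bad_roi)) {
    stop("unknown ROI(s): ", paste(bad_roi, collapse = ", "), call. = FALSE)
  }
  if (!all(uptake$side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'", call. = FALSE)
  }
  if (anyNA(uptake$mean_uptake) || any(uptake$mean_uptake <= 0)) {
    stop("mean_uptake must be positive with no missing values", call. = FALSE)
  }
  uptake
}

#' Build a control reference from a control uptake table
#'
#' Computes, per ROI and side (left, right and their bilateral average), the
#' mean and standard deviation of pons-normalized SUVR across the control
#' cohort.
#'
#' @param controls Long-format data.frame with columns `patient_id`, `roi`
#'   (frontal / temporoparietal / common / pons), `side` (left / right),
#'   `mean_uptake`.
#' @return Object of class `control_reference`: data.frame with columns `roi`,
#'   `side`, `mean`, `sd`, and attribute `n_controls`.
#' @export
control_reference <- function(controls) {
  suvr <- patient_suvr(controls)
  n <- length(unique(suvr$patient_id))
  if (n < 2L) stop("need at least 2 controls", call. = FALSE)
  ref <- stats::aggregate(suvr ~ roi + side, data = suvr,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  ref <- data.frame(roi = ref$roi, side = ref$side,
                    mean = ref$suvr[, "mean"], sd = ref$suvr[, "sd"],
                    stringsAsFactors = FALSE)
  if (any(!is.finite(ref$sd)) || any(ref$sd <= 0)) {
    stop("degenerate reference: control SD must be positive for every ROI",
         call. = FALSE)
  }
  attr(ref, "n_controls") <- n
  class(ref) <- c("control_reference", "data.frame")
  ref
}

#' @export
print.control_reference <- function(x, ...) {
  cat("Control SUVR reference (n =", attr(x, "n_controls"), "controls)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-patient SUVR from a long uptake table
#'
#' Normalizes each cortical ROI mean by the patient's pons mean and adds the
#' bilateral (left/right average) composite per ROI. The bilateral uptake is
#' by construction the mean of the two sides.
#'
#' @inheritParams control_reference
#' @param uptake Long-format uptake table (same schema as `controls` in
#'   [control_reference()]).
#' @return data.frame with columns `patient_id`, `roi`, `side` (left / right /
#'   bilateral), `suvr`.
#' @export
patient_suvr <- function(uptake) {
  uptake <- validate_uptake(uptake)
  pieces <- lapply(split(uptake, uptake$patient_id), function(u) {
    pid <- u$patient_id[1]
    pons <- mean(u$mean_uptake[u$roi == "pons"])
    if (!is.finite(pons)) {
      stop("patient ", pid, ": no pons rows in uptake table", call. = FALSE)
    }
    u <- u[u$roi != "pons", , drop = FALSE]
    rois <- sort(unique(u$roi))
    rows <- lapply(rois, function(r) {
      l <- u$mean_uptake[u$roi == r & u$side == "left"]
      rt <- u$mean_uptake[u$roi == r & u$side == "right"]
      if (length(l) != 1L || length(rt) != 1L) {
        stop("patient ", pid, ", ROI ", r,
             ": need exactly one left and one right row", call. = FALSE)
      }
      data.frame(patient_id = pid, roi = r,
                 side = c("left", "right", "bilateral"),
                 suvr = compute_suvr(c(l, rt, (l + rt) / 2), pons),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Z-score profile for one patient
#'
#' Per-ROI, per-side control-referenced Z-scores, the bilateral Z-difference,
#' per-ROI lateralization indices, and the quantitative FDG variant label.
#'
#' @param uptake Long-format uptake rows for a single patient.
#' @param reference A [control_reference()] object.
#' @return Object of class `z_profile`: list with `patient_id`, `z`
#'   (data.frame roi x side), `z_difference`, `li` (named per-ROI percent
#'   asymmetry), `quant_label`.
#' @export
z_profile <- function(uptake, reference) {
  stopifnot(inherits(reference, "control_reference"))
  suvr <- patient_suvr(uptake)
  if (length(unique(suvr$patient_id)) != 1L) {
    stop("z_profile() expects a single patient's uptake rows", call. = FALSE)
  }
  m <- merge(suvr, as.data.frame(reference), by = c("roi", "side"))
  if (nrow(m) != nrow(suvr)) {
    stop("control reference lacks entries for some ROI/side", call. = FALSE)
  }
  m$z <- compute_z(m$suvr, m$mean, m$sd)
  zb <- function(roi) m$z[m$roi == roi & m$side == "bilateral"]
  li <- vapply(cortical_rois(), function(r) {
    lateralization_index(m$suvr[m$roi == r & m$side == "right"],
                         m$suvr[m$roi == r & m$side == "left"])
  }, numeric(1))
  out <- list(
    patient_id = suvr$patient_id[1],
    z = m[order(m$roi, m$side), c("roi", "side", "z")],
    z_difference = z_difference(zb("frontal"), zb("temporoparietal")),
    li = li,
    quant_label = classify_fdg_quant(zb("frontal"), zb("temporoparietal"))
  )
  rownames(out$z) <- NULL
  class(out) <- "z_profile"
  out
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("FDG Z profile for %s: %s (Z difference %+.2f)\n",
              x$patient_id, x$quant_label, x$z_difference))
  zb <- x$z[x$z$side == "bilateral", ]
  for (i in seq_len(nrow(zb))) {
    cat(sprintf("  %-16s Z = %6.2f   LI = %5.2f%%\n", zb$roi[i], zb$z[i],
                x$li[[zb$roi[i]]]))
  }
  invisible(x)
}

#' Quantify a cohort of patients against a control reference
#'
#' Runs [z_profile()] for every patient and assembles a wide per-patient
#' summary table.
#'
#' @param uptake Long-format patient uptake table (may contain many patients).
#' @param reference A [control_reference()] object, or a control uptake table
#'   from which one is built.
#' @return data.frame with one row per patient: bilateral `z_frontal`,
#'   `z_temporoparietal`, `z_common`, `z_difference`, per-ROI `li_*`, and
#'   `quant_label` ("FV"/"TPV").
#' @export
quantify_cohort <- function(uptake, reference) {
  if (!inherits(reference, "control_reference")) {
    reference <- control_reference(reference)
  }
  uptake <- validate_uptake(uptake)
  rows <- lapply(split(uptake, uptake$patient_id), function(u) {
    zp <- z_profile(u, reference)
    zb <- function(roi) zp$z$z[zp$z$roi == roi & zp$z$side == "bilateral"]
    data.frame(patient_id = zp$patient_id,
               z_frontal = zb("frontal"),
               z_temporoparietal = zb("temporoparietal"),
               z_common = zb("common"),
               z_difference = zp$z_difference,
               li_frontal = zp$li[["frontal"]],
               li_temporoparietal = zp$li[["temporoparietal"]],
               li_common = zp$li[["common"]],
               quant_label = zp$quant_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id), ]
}
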