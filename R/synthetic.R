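# Synthetic cohorts with the clinical-feature and imaging structure the
# analysis assumes, plus time-activity curves with known ground-truth DVR.
# Every pipeline stage can be exercised end to end without patient data.

#' Default synthetic-cohort parameter blocks
#'
#' Building blocks of the default [cohort_spec()]: published group means/SDs
#' of bilateral ROI Z-scores (`default_z_params()`) and lateralization
#' indices (`default_li_params()`), and the package's own (non-published)
#' per-criterion clinical feature prevalences
#' (`default_feature_prevalence()`). Exported so users can modify one block
#' without restating the others.
#'
#' @return A list of data.frames (Z and LI parameters: `roi`, `mean`, `sd`
#'   per group) or nested prevalence vectors (clinical features).
#' @name cohort-defaults
NULL

#' @rdname cohort-defaults
#' @export
default_z_params <- function() {
  # published group means +/- SD of bilateral ROI Z-scores (amyloid-positive
  # vs amyloid-negative CBS)
  list(
    pib_pos = data.frame(
      roi = c("frontal", "temporoparietal", "common"),
      mean = c(-1.26, -2.76, -1.89), sd = c(0.91, 1.65, 0.81),
      stringsAsFactors = FALSE),
    pib_neg = data.frame(
      roi = c("frontal", "temporoparietal", "common"),
      mean = c(-1.06, -0.93, -1.69), sd = c(1.61, 1.65, 1.37),
      stringsAsFactors = FALSE)
  )
}

#' @rdname cohort-defaults
#' @export
default_li_params <- function() {
  # published group lateralization-index means +/- SD (percent), plus a
  # small control asymmetry
  list(
    pib_pos = data.frame(
      roi = c("frontal", "temporoparietal", "common"),
      mean = c(6.53, 13.10, 10.42), sd = c(3.08, 8.20, 4.37),
      stringsAsFactors = FALSE),
    pib_neg = data.frame(
      roi = c("frontal", "temporoparietal", "common"),
      mean = c(10.52, 8.45, 8.82), sd = c(8.16, 6.95, 5.99),
      stringsAsFactors = FALSE),
    control = data.frame(
      roi = c("frontal", "temporoparietal", "common"),
      mean = c(1.70, 2.00, 2.83), sd = c(1.33, 1.41, 1.72),
      stringsAsFactors = FALSE)
  )
}

#' @rdname cohort-defaults
#' @export
default_feature_prevalence <- function() {
  # per-criterion prevalences are NOT published; these defaults are the
  # package's own choice, enriching the memory/visuospatial-worse criterion
  # in the amyloid-positive group and the executive-worse criterion in the
  # amyloid-negative group so the pipeline's discrimination is exercised
  list(
    core = c(parkinsonism = 0.90, dystonia = 0.45, myoclonus = 0.45,
             impaired_voluntary_limb_control = 0.55,
             cortical_sensory_deficit = 0.55),
    pib_pos = list(
      fv = c(nonfluent_or_motor_speech = 0.30, behavioral_change = 0.30,
             lower_extremity_apraxia = 0.15),
      tpv = c(logopenic_aphasia = 0.45, gerstmann_or_balint = 0.40),
      cognitive = c(executive_worse = 0.15, memvis_worse = 0.60)),
    pib_neg = list(
      fv = c(nonfluent_or_motor_speech = 0.50, behavioral_change = 0.50,
             lower_extremity_apraxia = 0.30),
      tpv = c(logopenic_aphasia = 0.20, gerstmann_or_balint = 0.20),
      cognitive = c(executive_worse = 0.60, memvis_worse = 0.15))
  )
}

#' Specification of a synthetic CBS cohort
#'
#' Defaults reproduce the published study conditions: 11 amyloid-positive and
#' 14 amyloid-negative CBS patients, 26 normal controls, and the published
#' group means/SDs for bilateral ROI Z-scores and lateralization indices.
#' Clinical-feature prevalences are not published; the shipped defaults are
#' documented package choices (see the package vignette).
#'
#' @param n_pib_pos,n_pib_neg,n_controls Group sizes (non-negative; controls
#'   at least 2).
#' @param z_params List with `pib_pos` and `pib_neg` data.frames (`roi`,
#'   `mean`, `sd`) of bilateral Z-score distributions.
#' @param li_params List with `pib_pos`, `pib_neg`, `control` data.frames
#'   (`roi`, `mean`, `sd`) of percent lateralization-index distributions.
#' @param feature_prevalence List of per-group clinical criterion
#'   prevalences; see `default_feature_prevalence()` in the package source.
#' @param control_suvr Data.frame (`roi`, `mean`, `sd`) of control
#'   pons-normalized SUVR per cortical ROI.
#' @param pons_mean,pons_sd Raw pons uptake distribution (arbitrary tracer
#'   units; the scale cancels in SUVR).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pib_pos = 11, n_pib_neg = 14, n_controls = 26,
                        z_params = default_z_params(),
                        li_params = default_li_params(),
                        feature_prevalence = default_feature_prevalence(),
                        control_suvr = data.frame(
                          roi = c("frontal", "temporoparietal", "common"),
                          mean = c(1.45, 1.40, 1.50), sd = c(0.12, 0.12, 0.12),
                          stringsAsFactors = FALSE),
                        pons_mean = 1.0, pons_sd = 0.05) {
  stopifnot(n_pib_pos >= 0, n_pib_neg >= 0, n_controls >= 2)
  for (g in c("pib_pos", "pib_neg")) {
    if (any(z_params[[g]]$sd <= 0)) {
      stop("Z-score SDs must be positive", call. = FALSE)
    }
  }
  if (any(control_suvr$sd <= 0) || pons_sd <= 0) {
    stop("control SUVR and pons SDs must be positive", call. = FALSE)
  }
  for (g in c("pib_pos", "pib_neg")) {
    pr <- unlist(feature_prevalence[[g]])
    if (any(pr < 0 | pr > 1)) stop("prevalences must be in [0, 1]",
                                   call. = FALSE)
    cg <- feature_prevalence[[g]]$cognitive
    if (sum(cg) > 1) {
      stop("infeasible spec: cognitive-profile probabilities exceed 1 ",
           "(the two criteria are mutually exclusive)", call. = FALSE)
    }
  }
  out <- list(n_pib_pos = n_pib_pos, n_pib_neg = n_pib_neg,
              n_controls = n_controls, z_params = z_params,
              li_params = li_params,
              feature_prevalence = feature_prevalence,
              control_suvr = control_suvr,
              pons_mean = pons_mean, pons_sd = pons_sd)
  class(out) <- "cohort_spec"
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d PIB+, %d PIB-, %d controls\n",
              x$n_pib_pos, x$n_pib_neg, x$n_controls))
  cat("Bilateral Z-score distributions (mean +/- SD):\n")
  for (g in c("pib_pos", "pib_neg")) {
    z <- x$z_params[[g]]
    cat(sprintf("  %-8s %s\n", g,
                paste(sprintf("%s %.2f+/-%.2f", z$roi, z$mean, z$sd),
                      collapse = ", ")))
  }
  invisible(x)
}

# split a bilateral uptake value into left/right with a given percent
# asymmetry magnitude; lower_side is the hypometabolic hemisphere
split_sides <- function(bilateral, li_pct, lower_side) {
  ratio <- 1 + abs(li_pct) / 100   # higher / lower
  lo <- 2 * bilateral / (1 + ratio)
  hi <- lo * ratio
  if (lower_side == "left") c(left = lo, right = hi) else c(left = hi, right = lo)
}

draw_uptake_rows <- function(pid, suvr_bilat, li, lower_sides, pons) {
  rois <- names(suvr_bilat)
  rows <- lapply(rois, function(r) {
    s <- split_sides(suvr_bilat[[r]], li[[r]], lower_sides[[r]])
    data.frame(patient_id = pid, roi = r, side = c("left", "right"),
               mean_uptake = unname(s[c("left", "right")]) * pons,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rbind(rows, data.frame(patient_id = pid, roi = "pons",
                         side = c("left", "right"),
                         mean_uptake = c(pons, pons),
                         stringsAsFactors = FALSE))
}

draw_features_row <- function(pid, prev_core, prev_group) {
  f <- blank_features(pid)
  f$progressive_course <- TRUE
  # core: rejection-sample until >= 3 of 5 features present (all synthetic
  # patients are core-eligible by construction)
  repeat {
    core <- stats::rbinom(length(prev_core), 1, prev_core) == 1
    if (sum(core) >= 3) break
  }
  f[names(prev_core)] <- as.list(core)
  f[names(prev_group$fv)] <-
    as.list(stats::rbinom(length(prev_group$fv), 1, prev_group$fv) == 1)
  f[names(prev_group$tpv)] <-
    as.list(stats::rbinom(length(prev_group$tpv), 1, prev_group$tpv) == 1)
  cg <- prev_group$cognitive
  u <- stats::runif(1)
  if (u < cg[["executive_worse"]]) {
    f$executive_worse_than_mem_visuospatial <- TRUE
  } else if (u < cg[["executive_worse"]] + cg[["memvis_worse"]]) {
    f$mem_visuospatial_worse_than_executive <- TRUE
  }
  f
}

#' Generate a synthetic CBS cohort
#'
#' Controls are drawn per ROI around the spec's base SUVR distributions and
#' split into hemispheres with small control-level asymmetry. Patient
#' bilateral Z-scores are drawn per ROI from the spec's group distributions
#' (independently across ROIs) and inverted to SUVR through the *generated*
#' control sample statistics, so that re-deriving Z against the generated
#' [control_reference()] returns exactly the drawn values. Hemispheric
#' asymmetry is injected by splitting each bilateral uptake at the spec's
#' lateralization magnitude, with the hypometabolic side chosen at random.
#' Clinical features are drawn per group prevalence with the two
#' cognitive-profile criteria kept mutually exclusive; patients who would
#' meet neither variant are given their group's typical cognitive criterion
#' so every synthetic patient is classifiable.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the generator is deterministic given
#'   `spec` and `seed`.
#' @return Object of class `synthetic_cohort`: list with `features`
#'   (clinical feature table), `uptake` (long patient uptake table),
#'   `controls` (long control uptake table), `pib_status` (named logical),
#'   `z_drawn` (the true bilateral Z draws, for validation).
#' @examples
#' coh <- generate_cohort(cohort_spec(), seed = 1)
#' table(coh$pib_status)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  rois <- spec$control_suvr$roi
  li_ctl <- spec$li_params$control

  # controls: bilateral SUVR per ROI, split with small asymmetry
  ctl_rows <- lapply(seq_len(spec$n_controls), function(i) {
    pid <- sprintf("C%03d", i)
    pons <- max(stats::rnorm(1, spec$pons_mean, spec$pons_sd), 0.2)
    sb <- stats::setNames(
      pmax(stats::rnorm(length(rois), spec$control_suvr$mean,
                        spec$control_suvr$sd), 0.1), rois)
    li <- stats::setNames(
      abs(stats::rnorm(length(rois), li_ctl$mean, li_ctl$sd)), rois)
    lower <- stats::setNames(sample(c("left", "right"), length(rois),
                                    replace = TRUE), rois)
    draw_uptake_rows(pid, as.list(sb), as.list(li), as.list(lower), pons)
  })
  controls <- do.call(rbind, ctl_rows)
  rownames(controls) <- NULL

  ref <- control_reference(controls)
  ref_b <- ref[ref$side == "bilateral", ]

  groups <- c(rep("pib_pos", spec$n_pib_pos), rep("pib_neg", spec$n_pib_neg))
  n_pat <- length(groups)
  pat_ids <- sprintf("P%03d", seq_len(n_pat))

  features <- NULL
  uptake <- NULL
  z_drawn <- NULL
  if (n_pat > 0) {
    feats <- vector("list", n_pat)
    upts <- vector("list", n_pat)
    zs <- vector("list", n_pat)
    for (i in seq_len(n_pat)) {
      g <- groups[i]
      zp <- spec$z_params[[g]]
      lp <- spec$li_params[[g]]
      z <- stats::setNames(stats::rnorm(nrow(zp), zp$mean, zp$sd), zp$roi)
      # invert to bilateral SUVR through the generated control sample stats
      sb <- vapply(zp$roi, function(r) {
        m <- ref_b$mean[ref_b$roi == r]
        s <- ref_b$sd[ref_b$roi == r]
        max(m + z[[r]] * s, 0.05)
      }, numeric(1))
      li <- stats::setNames(abs(stats::rnorm(nrow(lp), lp$mean, lp$sd)),
                            lp$roi)
      lower <- stats::setNames(sample(c("left", "right"), nrow(lp),
                                      replace = TRUE), lp$roi)
      pons <- max(stats::rnorm(1, spec$pons_mean, spec$pons_sd), 0.2)
      upts[[i]] <- draw_uptake_rows(pat_ids[i], as.list(sb), as.list(li),
                                    as.list(lower), pons)
      f <- draw_features_row(pat_ids[i], spec$feature_prevalence$core,
                             spec$feature_prevalence[[g]])
      if (!any(unlist(f[feature_columns()$fv])) &&
          !any(unlist(f[feature_columns()$tpv]))) {
        if (g == "pib_pos") {
          f$mem_visuospatial_worse_than_executive <- TRUE
          f$executive_worse_than_mem_visuospatial <- FALSE
        } else {
          f$executive_worse_than_mem_visuospatial <- TRUE
          f$mem_visuospatial_worse_than_executive <- FALSE
        }
      }
      feats[[i]] <- f
      zs[[i]] <- data.frame(patient_id = pat_ids[i], roi = names(z),
                            z = unname(z), stringsAsFactors = FALSE)
    }
    features <- do.call(rbind, feats)
    uptake <- do.call(rbind, upts)
    z_drawn <- do.call(rbind, zs)
    rownames(features) <- rownames(uptake) <- rownames(z_drawn) <- NULL
  } else {
    features <- blank_features(character(0))
    uptake <- controls[0, ]
    z_drawn <- data.frame(patient_id = character(0), roi = character(0),
                          z = numeric(0), stringsAsFactors = FALSE)
  }

  out <- list(features = features, uptake = uptake, controls = controls,
              pib_status = stats::setNames(groups == "pib_pos", pat_ids),
              z_drawn = z_drawn, spec = spec, seed = as.integer(seed))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic CBS cohort: %d patients (%d PIB+, %d PIB-), %d controls (seed %d)\n",
    length(x$pib_status), sum(x$pib_status), sum(!x$pib_status),
    length(unique(x$controls$patient_id)), x$seed))
  invisible(x)
}

#' Generate a target/reference time-activity curve pair with known DVR
#'
#' The reference curve is a bi-exponential decay (a fast vascular/delivery
#' component plus a slow washout tail). The target is the exact solution of a
#' one-tissue compartment model driven by the reference,
#' `dC_t/dt = DVR * k2 * C_ref - k2 * C_t`, whose equilibrium
#' target-to-reference distribution-volume ratio equals `true_dvr`; for this
#' model the Logan transform is exactly linear with slope `true_dvr` and
#' intercept `-1/k2`. Frame mid-times use a quadratically spaced grid (finer
#' early frames, as in dynamic PET protocols). Optional additive Gaussian
#' noise is applied to both curves (floored at zero).
#'
#' @param true_dvr Ground-truth distribution volume ratio, positive.
#' @param duration_min Scan duration, minutes; default 90.
#' @param n_frames Number of frames (>= 6); default 30.
#' @param noise_sd Additive Gaussian noise SD in activity units; default 0
#'   (noise-free).
#' @param k2 Target tissue efflux rate constant, 1/min; default 0.15.
#' @param ref_amp,ref_lambda Amplitudes and decay constants (1/min) of the
#'   bi-exponential reference.
#' @return List with `target` and `reference` [tac()] objects and `true_dvr`.
#' @export
generate_tac_pair <- function(true_dvr, duration_min = 90, n_frames = 30,
                              noise_sd = 0, k2 = 0.15,
                              ref_amp = c(6, 3), ref_lambda = c(0.25, 0.012)) {
  stopifnot(true_dvr > 0, n_frames >= 6, duration_min > 0, k2 > 0,
            length(ref_amp) == length(ref_lambda), all(ref_lambda > 0),
            all(abs(ref_lambda - k2) > 1e-9))
  bounds <- duration_min * (seq(0, 1, length.out = n_frames + 1))^2
  mid <- (utils::head(bounds, -1) + utils::tail(bounds, -1)) / 2
  mid <- mid[mid > 0]
  ref_act <- rowSums(vapply(seq_along(ref_amp), function(j) {
    ref_amp[j] * exp(-ref_lambda[j] * mid)
  }, numeric(length(mid))))
  # exact convolution of each exponential with the 1TC impulse response
  tgt_act <- rowSums(vapply(seq_along(ref_amp), function(j) {
    true_dvr * k2 * ref_amp[j] *
      (exp(-ref_lambda[j] * mid) - exp(-k2 * mid)) / (k2 - ref_lambda[j])
  }, numeric(length(mid))))
  if (noise_sd > 0) {
    ref_act <- pmax(ref_act + stats::rnorm(length(mid), 0, noise_sd), 0)
    tgt_act <- pmax(tgt_act + stats::rnorm(length(mid), 0, noise_sd), 0)
  }
  list(target = tac(mid, tgt_act, "target"),
       reference = tac(mid, ref_act, "reference"),
       true_dvr = true_dvr)
}
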