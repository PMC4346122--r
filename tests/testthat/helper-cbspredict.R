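# Shared helpers for the cbspredict test suite.

# a core-eligible patient (progressive + 3 core features, no exclusions)
# with the requested variant features switched on
eligible_features <- function(id = "p1", on = character(0)) {
  f <- blank_features(id)
  f[c("progressive_course", "parkinsonism", "dystonia", "myoclonus")] <- TRUE
  if (length(on)) f[on] <- TRUE
  f
}

variant_feature_names <- function() {
  c(feature_columns()$fv, feature_columns()$tpv)
}

# all 2^7 variant-feature on/off combinations that respect the mutual
# exclusivity of the two cognitive-profile criteria
variant_combinations <- function() {
  nm <- variant_feature_names()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))
  names(grid) <- nm
  ok <- !(grid$executive_worse_than_mem_visuospatial &
            grid$mem_visuospatial_worse_than_executive)
  grid[ok, , drop = FALSE]
}

# independent re-statement of the adjudication precedence, written directly
# from the rule table (used as the brute-force oracle for the rule engine)
oracle_label <- function(row) {
  fv_n <- sum(unlist(row[feature_columns()$fv]))
  tpv_n <- sum(unlist(row[feature_columns()$tpv]))
  if (fv_n == 0 && tpv_n == 0) return(NA_character_)
  if (fv_n > 0 && tpv_n == 0) return("FV")
  if (tpv_n > 0 && fv_n == 0) return("TPV")
  ex <- isTRUE(row$executive_worse_than_mem_visuospatial)
  mv <- isTRUE(row$mem_visuospatial_worse_than_executive)
  if (ex && !mv) return("FV")
  if (mv && !ex) return("TPV")
  if (fv_n > tpv_n) return("FV")
  if (tpv_n > fv_n) return("TPV")
  "FV"
}

# exhaustive hypergeometric enumeration of the Fisher probability-mass
# two-sided p-value (independent of stats::fisher.test)
fisher_enum_two_sided <- function(tp, fp, fn, tn) {
  m <- tp + fn          # reference positives
  n <- fp + tn          # reference negatives
  k <- tp + fp          # predicted positives
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

fisher_enum_one_sided_greater <- function(tp, fp, fn, tn) {
  m <- tp + fn
  n <- fp + tn
  k <- tp + fp
  sum(stats::dhyper(tp:min(k, m), m, n, k))
}
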