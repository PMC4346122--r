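test_that("core screen applies the 1-plus-2 inclusion and exclusion rules", {
  f <- blank_features("p1")
  f[c("progressive_course", "parkinsonism", "dystonia", "myoclonus")] <- TRUE
  core <- check_core(f)
  expect_true(core$eligible)
  expect_identical(core$n_core_features_met, 3L)
  expect_length(core$failed_exclusions, 0)

  # two core features is below the at-least-three threshold
  f2 <- blank_features("p2")
  f2[c("progressive_course", "parkinsonism", "dystonia")] <- TRUE
  expect_false(check_core(f2)$eligible)
  expect_identical(check_core(f2)$n_core_features_met, 2L)

  # a non-progressive course fails regardless of features
  f3 <- f
  f3$progressive_course <- FALSE
  expect_false(check_core(f3)$eligible)

  # any exclusion feature vetoes, even with all five core features
  f4 <- blank_features("p4")
  f4[c("progressive_course", feature_columns()$core)] <- TRUE
  f4$visual_hallucinations <- TRUE
  core4 <- check_core(f4)
  expect_false(core4$eligible)
  expect_identical(core4$failed_exclusions, "visual_hallucinations")
  expect_identical(core4$n_core_features_met, 5L)
})

test_that("malformed feature tables are rejected with the offending field", {
  f <- eligible_features()
  expect_error(check_core(f[, setdiff(names(f), "dystonia")]),
               "dystonia")
  f_na <- f
  f_na$myoclonus <- NA
  expect_error(check_core(f_na), "myoclonus")
  f_bad <- f
  f_bad$parkinsonism <- 2
  expect_error(check_core(f_bad), "0/1")
  f_conflict <- f
  f_conflict$executive_worse_than_mem_visuospatial <- TRUE
  f_conflict$mem_visuospatial_worse_than_executive <- TRUE
  expect_error(check_core(f_conflict), "mutually exclusive")
})

test_that("variant evaluation counts features and requires core eligibility", {
  f <- eligible_features(on = "logopenic_aphasia")
  ev <- evaluate_variants(f)
  expect_false(ev$met_fv)
  expect_true(ev$met_tpv)
  expect_identical(ev$n_tpv_met, 1L)

  f2 <- eligible_features(on = "behavioral_change")
  ev2 <- evaluate_variants(f2)
  expect_true(ev2$met_fv)
  expect_false(ev2$met_tpv)

  f3 <- eligible_features(
    on = c("behavioral_change", "mem_visuospatial_worse_than_executive"))
  ev3 <- evaluate_variants(f3)
  expect_true(ev3$met_fv && ev3$met_tpv)

  ineligible <- blank_features("px")
  expect_error(evaluate_variants(ineligible), "core-ineligible")
})

test_that("adjudication follows the documented precedence and confidence map", {
  # unopposed variant
  f <- eligible_features(on = "logopenic_aphasia")
  ev <- evaluate_variants(f)
  vc <- adjudicate(ev$met_fv, ev$n_fv_met, ev$met_tpv, ev$n_tpv_met, f)
  expect_identical(vc$label, "TPV")
  expect_identical(vc$adjudication_rule, "single_variant")
  expect_identical(vc$confidence, 5L)

  # both met, memory/visuospatial-worse present -> cognitive dominance
  f2 <- eligible_features(
    on = c("behavioral_change", "mem_visuospatial_worse_than_executive"))
  ev2 <- evaluate_variants(f2)
  vc2 <- adjudicate(ev2$met_fv, ev2$n_fv_met, ev2$met_tpv, ev2$n_tpv_met, f2)
  expect_identical(vc2$label, "TPV")
  expect_identical(vc2$adjudication_rule, "cognitive_dominance")
  expect_identical(vc2$confidence, 4L)

  # both met, no cognitive criterion, fv count 2 vs tpv count 1
  f3 <- eligible_features(
    on = c("behavioral_change", "nonfluent_or_motor_speech",
           "logopenic_aphasia"))
  ev3 <- evaluate_variants(f3)
  vc3 <- adjudicate(ev3$met_fv, ev3$n_fv_met, ev3$met_tpv, ev3$n_tpv_met, f3)
  expect_identical(vc3$label, "FV")
  expect_identical(vc3$adjudication_rule, "count_majority")
  expect_identical(vc3$confidence, 2L)

  # full tie -> default FV at equivocal confidence
  f4 <- eligible_features(on = c("behavioral_change", "logopenic_aphasia"))
  ev4 <- evaluate_variants(f4)
  vc4 <- adjudicate(ev4$met_fv, ev4$n_fv_met, ev4$met_tpv, ev4$n_tpv_met, f4)
  expect_identical(vc4$label, "FV")
  expect_identical(vc4$adjudication_rule, "default")
  expect_identical(vc4$confidence, 3L)

  expect_error(adjudicate(FALSE, 0L, FALSE, 0L, eligible_features()),
               "no variant criteria met")
})

test_that("rule engine matches the brute-force oracle over every variant combination", {
  grid <- variant_combinations()
  for (i in seq_len(nrow(grid))) {
    on <- names(grid)[unlist(grid[i, ])]
    f <- eligible_features(sprintf("c%03d", i), on = on)
    expected <- oracle_label(f)
    if (is.na(expected)) {
      expect_error(classify_variants(f), "neither variant")
    } else {
      call <- classify_variants(f)
      expect_identical(call$label, expected)
      # confidence semantics: FV in 1..3, TPV in 3..5
      if (call$label == "FV") expect_lte(call$confidence, 3L)
      if (call$label == "TPV") expect_gte(call$confidence, 3L)
      # determinism: a second run is identical
      expect_identical(classify_variants(f), call)
    }
  }
})

test_that("adding a supporting feature never flips an established label", {
  grid <- variant_combinations()
  tpv_feats <- feature_columns()$tpv
  fv_feats <- feature_columns()$fv
  for (i in seq_len(nrow(grid))) {
    on <- names(grid)[unlist(grid[i, ])]
    f <- eligible_features("m1", on = on)
    if (is.na(oracle_label(f))) next
    label <- classify_variants(f)$label
    if (label == "TPV") {
      for (feat in setdiff(tpv_feats, on)) {
        if (feat == "mem_visuospatial_worse_than_executive" &&
            isTRUE(f$executive_worse_than_mem_visuospatial)) next
        f2 <- f
        f2[[feat]] <- TRUE
        expect_identical(classify_variants(f2)$label, "TPV")
      }
    } else {
      for (feat in setdiff(fv_feats, on)) {
        if (feat == "executive_worse_than_mem_visuospatial" &&
            isTRUE(f$mem_visuospatial_worse_than_executive)) next
        f2 <- f
        f2[[feat]] <- TRUE
        expect_identical(classify_variants(f2)$label, "FV")
      }
    }
  }
})

test_that("the cognitive-profile criterion dominates both-met ties", {
  # flipping executive-worse to memory/visuospatial-worse flips the label
  f <- eligible_features(
    on = c("behavioral_change", "logopenic_aphasia",
           "executive_worse_than_mem_visuospatial"))
  expect_identical(classify_variants(f)$label, "FV")
  f$executive_worse_than_mem_visuospatial <- FALSE
  f$mem_visuospatial_worse_than_executive <- TRUE
  expect_identical(classify_variants(f)$label, "TPV")
})

test_that("cohort classification reports and drops ineligible patients on request", {
  f <- rbind(eligible_features("a", on = "logopenic_aphasia"),
             blank_features("b"))
  expect_error(classify_variants(f), "core CBS criteria")
  expect_message(out <- classify_variants(f, on_ineligible = "drop"),
                 "dropped 1")
  expect_identical(out$patient_id, "a")
})
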