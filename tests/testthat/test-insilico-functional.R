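# Computational criteria (PP3/BP4), functional pass-through (PS3/BS3) and
# the discontinued reputable-source codes.

test_that("missense predictor thresholds and the no-call band are exact", {
  lab <- function(revel) {
    call <- evaluate_pp3_bp4(t_missense(), insilico_scores(revel = revel),
                             t_gene())
    if (is.null(call)) NA_character_ else paste0(call$criterion, "_", call$strength)
  }
  expect_equal(lab(0.75), "PP3_P")
  expect_equal(lab(0.35), "BP4_P")
  expect_true(is.na(lab(0.55)))
  # boundaries are strict: exactly 0.7 / 0.4 stay inside the band
  expect_true(is.na(lab(0.7)))
  expect_true(is.na(lab(0.4)))
  expect_true(is.na(lab(NA_real_)))
})

test_that("noncoding variants use the splice delta score with inclusive bounds", {
  lab <- function(cons, delta) {
    call <- evaluate_pp3_bp4(variant_descriptor(cons),
                             insilico_scores(spliceai_delta = delta), t_gene())
    if (is.null(call)) NA_character_ else paste0(call$criterion, "_", call$strength)
  }
  expect_equal(lab("other", 0.85), "PP3_P")
  expect_equal(lab("other", 0.8), "PP3_P")
  expect_equal(lab("other", 0.2), "BP4_P")
  expect_true(is.na(lab("other", 0.5)))
  # null variants are PVS1 territory, not computational evidence
  expect_true(is.na(lab("nonsense", 0.9)))
})

test_that("per-gene overrides replace the default thresholds", {
  g <- t_gene(insilico_overrides = list(revel_pp3 = 0.6, revel_bp4 = 0.3))
  call <- evaluate_pp3_bp4(t_missense(), insilico_scores(revel = 0.65), g)
  expect_equal(call$criterion, "PP3")
  expect_null(evaluate_pp3_bp4(t_missense(), insilico_scores(revel = 0.35), g))
})

test_that("PP3, BP4 and BP7 are pairwise exclusive on a score grid", {
  cfg <- engine_config()
  for (cons in c("missense", "synonymous", "other")) {
    for (revel in seq(0, 1, by = 0.05)) {
      for (delta in seq(0, 1, by = 0.1)) {
        for (gerp in c(-1, 1)) {
          v <- if (cons == "missense") t_missense() else variant_descriptor(cons)
          scores <- insilico_scores(revel = revel, spliceai_delta = delta,
                                    gerp = gerp)
          calls <- resolve_conflicts(Filter(Negate(is.null), list(
            evaluate_pp3_bp4(v, scores, t_gene()),
            evaluate_bp7(v, scores))))
          hits <- Filter(function(x) x$criterion %in% c("PP3", "BP4", "BP7"),
                         applied_calls(calls))
          expect_lte(length(hits), 1)
        }
      }
    }
  }
})

test_that("functional evidence passes through with the proband-derived guard", {
  expect_equal(labels_of(list(evaluate_ps3_bs3(
    functional_assay("damaging", "S")))), "PS3_S")
  expect_equal(labels_of(list(evaluate_ps3_bs3(
    functional_assay("damaging", "VS")))), "PS3_VS")
  rejected <- evaluate_ps3_bs3(functional_assay("damaging", "S",
                                                proband_derived = TRUE))
  expect_false(rejected$applied)
  expect_match(rejected$rationale, "PP4")
  expect_equal(labels_of(list(evaluate_ps3_bs3(
    functional_assay("benign", "M")))), "BS3_M")
  expect_null(evaluate_ps3_bs3(functional_assay()))
  # the benign direction is capped at strong
  expect_error(functional_assay("benign", "VS"), "capped at strong")
})

test_that("discontinued and policy-unapplied criteria stay in the audit trail", {
  disc <- discontinued_criteria()
  expect_equal(vapply(disc, function(x) x$criterion, character(1)),
               c("PP5", "BP6"))
  expect_false(any(vapply(disc, function(x) x$applied, logical(1))))
  audit <- evaluate_criteria(t_record(), engine_config())
  expect_length(audit, 28)
  expect_setequal(names(audit), acmg_criteria())
  for (code in c("PP5", "BP6", "BP1", "BP2", "BP3")) {
    expect_false(audit[[code]]$applied)
  }
})
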