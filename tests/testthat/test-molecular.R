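# Variant-type criteria: PVS1, PS1/PM5, PM1, PM4, PP2, BP7.

test_that("PVS1 requires an established loss-of-function mechanism", {
  v <- variant_descriptor("nonsense", nmd_predicted = TRUE)
  expect_equal(strength_of(evaluate_pvs1(v, t_gene(pli = 0.99))), "VS")
  expect_equal(strength_of(evaluate_pvs1(v, t_gene(o_e = 0.2))), "VS")
  expect_equal(strength_of(evaluate_pvs1(v, t_gene(lof_mechanism = "established"))),
               "VS")
  # constraint metrics below the gates leave the mechanism unestablished
  off <- evaluate_pvs1(v, t_gene(pli = 0.2, o_e = 0.8))
  expect_false(off$applied)
  # curation overrides the metrics
  off2 <- evaluate_pvs1(v, t_gene(lof_mechanism = "not_established", pli = 0.99))
  expect_false(off2$applied)
  # non-null variants never receive the criterion
  expect_null(evaluate_pvs1(t_missense(), t_gene(pli = 0.99)))
})

test_that("PVS1 strength follows the decision table", {
  g <- t_gene(pli = 0.99)
  s_of <- function(...) strength_of(evaluate_pvs1(variant_descriptor(...), g))
  expect_equal(s_of("frameshift", nmd_predicted = TRUE), "VS")
  expect_equal(s_of("nonsense", nmd_predicted = FALSE,
                    affected_region_critical = TRUE), "S")
  expect_equal(s_of("nonsense", nmd_predicted = FALSE,
                    affected_region_critical = FALSE), "M")
  expect_equal(s_of("initiation_codon"), "M")
  expect_equal(s_of("canonical_splice", exon_skip_inframe = TRUE,
                    affected_region_critical = TRUE), "S")
  expect_equal(s_of("canonical_splice", exon_skip_inframe = TRUE,
                    affected_region_critical = FALSE), "M")
  expect_equal(s_of("single_multi_exon_deletion", nmd_predicted = TRUE), "VS")
  expect_error(s_of("nonsense"), "nmd_predicted")
})

test_that("PS1/PM5 match the report-count clauses and a brute-force oracle", {
  scores <- insilico_scores(spliceai_delta = 0.1)
  # independent clause oracle over aggregated report counts
  oracle <- function(eq_path, eq_lp, ot_path, ot_lp) {
    if (eq_path >= 1 || eq_lp >= 2) "PS1_S"
    else if (eq_lp == 1) "PS1_M"
    else if (ot_path >= 1 || ot_lp >= 2) "PM5_M"
    else if (ot_lp == 1) "PM5_P"
    else NA_character_
  }
  build <- function(eq_path, eq_lp, ot_path, ot_lp) {
    known <- list()
    if (eq_path > 0) known <- c(known, list(
      prior_variant(100L, "V", TRUE, "pathogenic", eq_path)))
    if (eq_lp > 0) known <- c(known, list(
      prior_variant(100L, "V", TRUE, "likely_pathogenic", eq_lp)))
    if (ot_path > 0) known <- c(known, list(
      prior_variant(100L, "K", FALSE, "pathogenic", ot_path)))
    if (ot_lp > 0) known <- c(known, list(
      prior_variant(100L, "K", FALSE, "likely_pathogenic", ot_lp)))
    known
  }
  for (eq_path in 0:3) for (eq_lp in 0:3) for (ot_path in 0:3) for (ot_lp in 0:3) {
    call <- evaluate_ps1_pm5(t_missense(), build(eq_path, eq_lp, ot_path, ot_lp),
                             scores)
    got <- if (is.null(call) || !call$applied) NA_character_
    else paste0(call$criterion, "_", call$strength)
    expect_identical(got, oracle(eq_path, eq_lp, ot_path, ot_lp),
                     info = paste(eq_path, eq_lp, ot_path, ot_lp))
  }
})

test_that("a deleterious splice prediction suppresses PS1/PM5", {
  known <- list(prior_variant(100L, "K", FALSE, "likely_pathogenic", 1))
  hi <- insilico_scores(spliceai_delta = 0.9)
  call <- evaluate_ps1_pm5(t_missense(), known, hi)
  expect_false(call$applied)
  # functional evidence of aberrant splicing suppresses too
  call2 <- evaluate_ps1_pm5(t_missense(splicing_functional_aberrant = TRUE),
                            known, insilico_scores(spliceai_delta = 0.1))
  expect_false(call2$applied)
})

test_that("PM1 weighs special domains strong and constraint moderate", {
  expect_equal(strength_of(evaluate_pm1(
    t_missense(ref_aa = "G"),
    t_gene(special_domain_class = "collagen_glycine"))), "S")
  expect_equal(strength_of(evaluate_pm1(
    t_missense(cysteine_parity_change = TRUE),
    t_gene(special_domain_class = "notch3_egf"))), "S")
  expect_null(evaluate_pm1(t_missense(),
                           t_gene(special_domain_class = "notch3_egf")))
  expect_equal(strength_of(evaluate_pm1(
    t_missense(ref_aa = "H"),
    t_gene(special_domain_class = "c2h4_zinc_finger"))), "S")
  expect_equal(strength_of(evaluate_pm1(
    t_missense(), t_gene(decipher_missense_constraint = 0.3))), "M")
  expect_null(evaluate_pm1(t_missense(),
                           t_gene(decipher_missense_constraint = 0.6)))
  hs <- data.frame(gene = "TEST1", start = 90L, end = 110L)
  expect_equal(strength_of(evaluate_pm1(t_missense(), t_gene(),
                                        hotspots = hs)), "M")
  expect_null(evaluate_pm1(t_missense(codon_index = 10L), t_gene(),
                           hotspots = hs))
})

test_that("PM4 weighs indel length, blocks repeats and needs rarity", {
  pm2 <- criterion_call("PM2", "M")
  indel <- function(len, rep = FALSE) {
    variant_descriptor("inframe_indel", indel_aa_length = len,
                       in_repeat_region = rep)
  }
  expect_equal(strength_of(evaluate_pm4(indel(1), pm2)), "P")
  expect_equal(strength_of(evaluate_pm4(indel(2), pm2)), "P")
  expect_equal(strength_of(evaluate_pm4(indel(3), pm2)), "M")
  expect_equal(strength_of(evaluate_pm4(indel(5), pm2)), "M")
  expect_equal(strength_of(evaluate_pm4(variant_descriptor("stop_loss"), pm2)),
               "M")
  expect_false(evaluate_pm4(indel(5, rep = TRUE), pm2)$applied)
  expect_false(evaluate_pm4(indel(5), NULL)$applied)
  expect_null(evaluate_pm4(t_missense(), pm2))
})

test_that("PP2 needs both the missense record count and the constraint Z", {
  expect_equal(strength_of(evaluate_pp2(
    t_missense(), t_gene(pathogenic_missense_count = 5,
                         missense_constraint_z = 3.5))), "P")
  expect_null(evaluate_pp2(
    t_missense(), t_gene(pathogenic_missense_count = 2,
                         missense_constraint_z = 4.0)))
  # the Z comparison is strict
  expect_null(evaluate_pp2(
    t_missense(), t_gene(pathogenic_missense_count = 5,
                         missense_constraint_z = 3.09)))
})

test_that("BP7 requires a silent variant, low splice impact and low conservation", {
  syn <- variant_descriptor("synonymous")
  expect_equal(strength_of(evaluate_bp7(
    syn, insilico_scores(spliceai_delta = 0.05, gerp = -1.2))), "P")
  expect_null(evaluate_bp7(syn, insilico_scores(spliceai_delta = 0.5,
                                                gerp = -1.2)))
  expect_null(evaluate_bp7(syn, insilico_scores(spliceai_delta = 0.05,
                                                gerp = 0.5)))
  expect_null(evaluate_bp7(t_missense(),
                           insilico_scores(spliceai_delta = 0.05, gerp = -1.2)))
  expect_false(evaluate_bp7(syn, insilico_scores())$applied)
})
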