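# Synthetic evidence fixtures: a hand-built gold set exercising every
# clause of every implemented criterion and every combining rule, and a
# seeded random cohort generator for property tests.

# Compact builders -----------------------------------------------------------

fx_gene <- function(inheritance = "AD", ...) {
  args <- utils::modifyList(
    list(symbol = "DEMO1", inheritance = inheritance,
         clinical_validity = "definitive"),
    list(...))
  do.call(gene_context, args)
}

fx_var <- function(consequence = "missense", ...) {
  defaults <- list(codon_index = 100L, ref_aa = "A", alt_aa = "V")
  args <- utils::modifyList(defaults, list(...))
  if (!(consequence %in% c("missense"))) {
    args$ref_aa <- NULL; args$alt_aa <- NULL
    if (consequence != "missense") args$codon_index <- NULL
  }
  do.call(variant_descriptor, c(list(consequence = consequence), args))
}

# One overall population with AN 200,000.  af = NULL means no data.
fx_freq <- function(ac, an = 200000, founder = FALSE, pop = "overall") {
  list(frequency_record(pop, ac, an, founder))
}

# Frequencies producing no frequency call for a general AD gene
# (0.0005 sits between the rarity and the benign cut-offs).
fx_freq_midband <- function() fx_freq(100)

fx_record <- function(id, gene = fx_gene(), variant = fx_var(),
                      frequencies = fx_freq_midband(), ...) {
  evidence_record(id = id, gene = gene, variant = variant,
                  frequencies = frequencies, ...)
}

fx_case <- function(...) case_level_data(...)

# expected_calls is the complete applied call set after conflict
# resolution, as "PM2_M"-style labels.
fx_expect <- function(record, calls, tier, rule = NA_character_,
                      status = "classified") {
  list(id = record$id, record = record, expected_calls = sort(calls),
       expected_tier = tier, expected_rule = rule, expected_status = status)
}

#' Configuration used by the gold fixture set
#'
#' The shipped defaults plus a literature hotspot interval for the demo
#' hotspot gene, so the hotspot clause of PM1 is exercisable.
#'
#' @return An [engine_config()].
#' @export
gold_fixture_config <- function() {
  engine_config(hotspots = data.frame(gene = "HOTGENE", start = 50L,
                                      end = 150L, stringsAsFactors = FALSE))
}

#' The gold fixture set
#'
#' Hand-built evidence records, each paired with its expected applied
#' criterion calls (after conflict resolution) and expected rule-based
#' tier.  Together the records exercise every clause tag of
#' [clause_tags()] and every combining rule.  Classify them with
#' [gold_fixture_config()].
#'
#' @return List of fixtures; each has `id`, `record`, `expected_calls`,
#'   `expected_tier`, `expected_rule`, `expected_status`.
#' @export
gold_fixture_set <- function() {
  fx <- list()
  add <- function(x) fx[[length(fx) + 1]] <<- x

  # -- population frequency ---------------------------------------------
  add(fx_expect(fx_record("ba1_standalone", frequencies = fx_freq(12000)),
                c("BA1_A"), "benign", "1A"))
  add(fx_expect(fx_record(
    "ba1_exception_withheld",
    gene = fx_gene(ba1_exception = TRUE,
                   frequency_overrides = list(ba1 = 0.05, bs1_s = 0.001,
                                              pm2_p = 1e-5, pm2_m = NULL)),
    frequencies = fx_freq(12000)),
    c("BS1_S"), "VUS"))
  add(fx_expect(fx_record("bs1_general_ad", frequencies = fx_freq(400)),
                c("BS1_S"), "VUS"))
  add(fx_expect(fx_record("bs1_cancer_ar",
                          gene = fx_gene("AR", category = "cancer"),
                          frequencies = fx_freq(4000)),
                c("BS1_S"), "VUS"))
  add(fx_expect(fx_record("pm2_absent_ad", frequencies = fx_freq(0)),
                c("PM2_M"), "VUS"))
  add(fx_expect(fx_record("pm2_freqm_general_ar", gene = fx_gene("AR"),
                          frequencies = fx_freq(1)),
                c("PM2_M"), "VUS"))
  add(fx_expect(fx_record("pm2_p_general_ad", frequencies = fx_freq(1)),
                c("PM2_P"), "VUS"))
  add(fx_expect(fx_record("pm2_p_cancer_ar",
                          gene = fx_gene("AR", category = "cancer"),
                          frequencies = fx_freq(60)),
                c("PM2_P"), "VUS"))
  add(fx_expect(fx_record("freq_midband"), character(0), "VUS"))
  add(fx_expect(fx_record("freq_no_data",
                          frequencies = fx_freq(0, founder = TRUE)),
                character(0), "VUS"))

  # -- PVS1 --------------------------------------------------------------
  nullvar <- function(cons = "nonsense", ...) fx_var(cons, ...)
  lofgene <- function(...) fx_gene(pli = 0.99, ...)
  add(fx_expect(fx_record("pvs1_vs_pm2m", gene = lofgene(),
                          variant = nullvar(nmd_predicted = TRUE),
                          frequencies = fx_freq(0)),
                c("PVS1_VS", "PM2_M"), "likely_pathogenic", "3A"))
  add(fx_expect(fx_record("pvs1_vs_pm2p", gene = lofgene(),
                          variant = nullvar(nmd_predicted = TRUE),
                          frequencies = fx_freq(1)),
                c("PVS1_VS", "PM2_P"), "likely_pathogenic", "3B"))
  add(fx_expect(fx_record(
    "pvs1_escape_critical", gene = fx_gene(o_e = 0.2),
    variant = nullvar("frameshift", nmd_predicted = FALSE,
                      last_exon_or_50nt_rule = TRUE,
                      affected_region_critical = TRUE),
    frequencies = fx_freq(0)),
    c("PVS1_S", "PM2_M"), "likely_pathogenic", "3C"))
  add(fx_expect(fx_record(
    "pvs1_escape_moderate", gene = fx_gene(lof_mechanism = "established"),
    variant = nullvar(nmd_predicted = FALSE, last_exon_or_50nt_rule = TRUE,
                      affected_region_critical = FALSE),
    frequencies = fx_freq(0)),
    c("PVS1_M", "PM2_M"), "VUS"))
  add(fx_expect(fx_record(
    "pvs1_exonskip_critical", gene = lofgene(),
    variant = nullvar("canonical_splice", exon_skip_inframe = TRUE,
                      affected_region_critical = TRUE)),
    c("PVS1_S"), "VUS"))
  add(fx_expect(fx_record(
    "pvs1_exonskip_moderate", gene = lofgene(),
    variant = nullvar("canonical_splice", exon_skip_inframe = TRUE,
                      affected_region_critical = FALSE),
    frequencies = fx_freq(0)),
    c("PVS1_M", "PM2_M"), "VUS"))
  add(fx_expect(fx_record("pvs1_initiation", gene = lofgene(),
                          variant = nullvar("initiation_codon"),
                          frequencies = fx_freq(0)),
                c("PVS1_M", "PM2_M"), "VUS"))
  add(fx_expect(fx_record("pvs1_not_established",
                          gene = fx_gene(pli = 0.2, o_e = 0.8),
                          variant = nullvar(nmd_predicted = TRUE),
                          frequencies = fx_freq(0)),
                c("PM2_M"), "VUS"))

  # -- PS1 / PM5 ---------------------------------------------------------
  prior_eq <- function(class, n) list(prior_variant(100L, "V", TRUE, class, n))
  prior_other <- function(class, n) list(prior_variant(100L, "K", FALSE, class, n))
  lowsplice <- insilico_scores(spliceai_delta = 0.1, gerp = 2)
  add(fx_expect(fx_record("ps1_s_pathogenic",
                          prior_variants = prior_eq("pathogenic", 1),
                          insilico = lowsplice),
                c("PS1_S"), "VUS"))
  add(fx_expect(fx_record("ps1_s_lp_two",
                          prior_variants = prior_eq("likely_pathogenic", 2),
                          insilico = lowsplice),
                c("PS1_S"), "VUS"))
  add(fx_expect(fx_record("ps1_m_lp_one",
                          prior_variants = prior_eq("likely_pathogenic", 1),
                          insilico = lowsplice),
                c("PS1_M"), "VUS"))
  add(fx_expect(fx_record("pm5_m_pathogenic",
                          prior_variants = prior_other("pathogenic", 1),
                          insilico = lowsplice),
                c("PM5_M"), "VUS"))
  add(fx_expect(fx_record("pm5_m_lp_two",
                          prior_variants = prior_other("likely_pathogenic", 2),
                          insilico = lowsplice),
                c("PM5_M"), "VUS"))
  add(fx_expect(fx_record("pm5_p_lp_one",
                          prior_variants = prior_other("likely_pathogenic", 1),
                          insilico = lowsplice),
                c("PM5_P"), "VUS"))
  add(fx_expect(fx_record("ps1_splice_suppressed",
                          prior_variants = prior_eq("pathogenic", 1),
                          insilico = insilico_scores(spliceai_delta = 0.9,
                                                     gerp = 2)),
                character(0), "VUS"))

  # -- PM1 ---------------------------------------------------------------
  add(fx_expect(fx_record("pm1_collagen",
                          gene = fx_gene(special_domain_class = "collagen_glycine"),
                          variant = fx_var(ref_aa = "G")),
                c("PM1_S"), "VUS"))
  add(fx_expect(fx_record("pm1_notch3",
                          gene = fx_gene(special_domain_class = "notch3_egf"),
                          variant = fx_var(cysteine_parity_change = TRUE)),
                c("PM1_S"), "VUS"))
  add(fx_expect(fx_record("pm1_zinc_finger",
                          gene = fx_gene(special_domain_class = "c2h4_zinc_finger"),
                          variant = fx_var(ref_aa = "C")),
                c("PM1_S"), "VUS"))
  add(fx_expect(fx_record("pm1_decipher",
                          gene = fx_gene(decipher_missense_constraint = 0.3)),
                c("PM1_M"), "VUS"))
  add(fx_expect(fx_record("pm1_hotspot",
                          gene = gene_context("HOTGENE", "AD")),
                c("PM1_M"), "VUS"))

  # -- PM4 ---------------------------------------------------------------
  indel <- function(len, rep = FALSE) {
    fx_var("inframe_indel", indel_aa_length = len, in_repeat_region = rep)
  }
  add(fx_expect(fx_record("pm4_small_indel", variant = indel(2),
                          frequencies = fx_freq(0)),
                c("PM2_M", "PM4_P"), "VUS"))
  add(fx_expect(fx_record("pm4_large_indel", variant = indel(5),
                          frequencies = fx_freq(1)),
                c("PM2_P", "PM4_M"), "VUS"))
  add(fx_expect(fx_record("pm4_stop_loss", variant = fx_var("stop_loss"),
                          frequencies = fx_freq(0)),
                c("PM2_M", "PM4_M"), "VUS"))
  add(fx_expect(fx_record("pm4_repeat_region", variant = indel(5, rep = TRUE),
                          frequencies = fx_freq(0)),
                c("PM2_M"), "VUS"))
  add(fx_expect(fx_record("pm4_not_rare", variant = indel(5)),
                character(0), "VUS"))

  # -- PP2 / BP7 ---------------------------------------------------------
  add(fx_expect(fx_record("pp2_constrained",
                          gene = fx_gene(pathogenic_missense_count = 5,
                                         missense_constraint_z = 3.5)),
                c("PP2_P"), "VUS"))
  add(fx_expect(fx_record("bp7_silent", variant = fx_var("synonymous"),
                          insilico = insilico_scores(spliceai_delta = 0.05,
                                                     gerp = -1.2)),
                c("BP7_P"), "VUS"))
  add(fx_expect(fx_record("bp7_missing_scores",
                          variant = fx_var("synonymous")),
                character(0), "VUS"))

  # -- PM3 / de novo / PP1 ----------------------------------------------
  ar_gene <- fx_gene("AR")
  obs_in_trans <- recessive_obs("in_trans_with_PLP")
  add(fx_expect(fx_record("pm3_moderate", gene = ar_gene,
                          frequencies = fx_freq(0),
                          case_data = fx_case(recessive_obs = list(obs_in_trans))),
                c("PM3_M", "PM2_M"), "VUS"))
  add(fx_expect(fx_record(
    "pm3_strong_mixed", gene = ar_gene, frequencies = fx_freq(200),
    case_data = fx_case(recessive_obs = list(
      obs_in_trans, obs_in_trans, recessive_obs("phase_unknown"),
      recessive_obs("homozygous"), recessive_obs("homozygous")))),
    c("PM3_S"), "VUS"))
  add(fx_expect(fx_record(
    "pm3_very_strong", gene = ar_gene, frequencies = fx_freq(0),
    case_data = fx_case(recessive_obs = c(
      rep(list(obs_in_trans), 4),
      list(recessive_obs("homozygous", consanguineous = TRUE))))),
    c("PM3_VS", "PM2_M"), "likely_pathogenic", "3A"))
  add(fx_expect(fx_record(
    "pm3_below_threshold", gene = ar_gene, frequencies = fx_freq(200),
    case_data = fx_case(recessive_obs = list(
      recessive_obs("homozygous", consanguineous = TRUE)))),
    character(0), "VUS"))
  add(fx_expect(fx_record(
    "pm3_dominant_refused",
    case_data = fx_case(recessive_obs = list(obs_in_trans))),
    character(0), "VUS"))
  add(fx_expect(fx_record(
    "ps2_strong", case_data = fx_case(denovo_obs = list(
      denovo_obs(TRUE, "highly_specific")))),
    c("PS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "pm6_supporting", case_data = fx_case(denovo_obs = list(
      denovo_obs(FALSE, "consistent")))),
    c("PM6_P"), "VUS"))
  add(fx_expect(fx_record(
    "pm6_moderate", case_data = fx_case(denovo_obs = list(
      denovo_obs(FALSE, "highly_specific")))),
    c("PM6_M"), "VUS"))
  add(fx_expect(fx_record(
    "denovo_mixed_pools", case_data = fx_case(denovo_obs = list(
      denovo_obs(TRUE, "consistent"),
      denovo_obs(FALSE, "highly_specific")))),
    c("PS2_M", "PM6_M"), "VUS"))
  add(fx_expect(fx_record(
    "denovo_inconsistent", case_data = fx_case(denovo_obs = list(
      denovo_obs(FALSE, "inconsistent"), denovo_obs(FALSE, "inconsistent")))),
    character(0), "VUS"))
  add(fx_expect(fx_record("pp1_ad_supporting",
                          case_data = fx_case(segregating_meioses = 3)),
                c("PP1_P"), "VUS"))
  add(fx_expect(fx_record("pp1_ad_moderate",
                          case_data = fx_case(segregating_meioses = 5)),
                c("PP1_M"), "VUS"))
  add(fx_expect(fx_record("pp1_ad_strong",
                          case_data = fx_case(segregating_meioses = 7)),
                c("PP1_S"), "VUS"))
  add(fx_expect(fx_record("pp1_ar_strong", gene = ar_gene,
                          frequencies = fx_freq(200),
                          case_data = fx_case(segregating_meioses = 3)),
                c("PP1_S"), "VUS"))

  # -- PS4 ---------------------------------------------------------------
  add(fx_expect(fx_record(
    "ps4_case_control", case_data = fx_case(
      case_control = list(odds_ratio = 8, ci_low = 1.4))),
    c("PS4_S"), "VUS"))
  add(fx_expect(fx_record("ps4_founder",
                          case_data = fx_case(founder_variant = TRUE)),
                c("PS4_S"), "VUS"))
  add(fx_expect(fx_record("ps4_vcep_pathogenic",
                          case_data = fx_case(vcep_pathogenic = TRUE)),
                c("PS4_S"), "VUS"))
  add(fx_expect(fx_record("ps4_general_moderate", frequencies = fx_freq(1),
                          case_data = fx_case(proband_count = 3)),
                c("PM2_P", "PS4_M"), "VUS"))
  add(fx_expect(fx_record("ps4_cancer_moderate",
                          gene = fx_gene(category = "cancer"),
                          frequencies = fx_freq(0),
                          case_data = fx_case(proband_count = 7)),
                c("PM2_M", "PS4_M"), "VUS"))
  add(fx_expect(fx_record("ps4_cancer_strong",
                          gene = fx_gene(category = "cancer"),
                          frequencies = fx_freq(0),
                          case_data = fx_case(proband_count = 10)),
                c("PM2_M", "PS4_S"), "likely_pathogenic", "3C"))
  add(fx_expect(fx_record("ps4_blocked_not_rare",
                          case_data = fx_case(proband_count = 6)),
                character(0), "VUS"))

  # -- BS2 / BS4 / PP4 / BP5 --------------------------------------------
  carriers <- function(het = 0, hom = 0, hemi = 0) {
    list(het = het, hom = hom, hemi = hemi)
  }
  add(fx_expect(fx_record(
    "bs2_inhouse", gene = fx_gene(high_penetrance_early_onset = TRUE),
    case_data = fx_case(in_house_positive_genotype_no_phenotype = TRUE)),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs2_cancer_hom", gene = fx_gene(category = "cancer"),
    case_data = fx_case(healthy_carrier_counts = carriers(hom = 1))),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs2_recessive_hom", gene = fx_gene("AR", complete_penetrance = TRUE),
    frequencies = fx_freq(200),
    case_data = fx_case(healthy_carrier_counts = carriers(hom = 1))),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs2_green_list", gene = fx_gene(pediatric_green_list = TRUE),
    case_data = fx_case(healthy_carrier_counts = carriers(het = 5))),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs2_xl_hemizygous", gene = fx_gene("XLR"), frequencies = fx_freq(200),
    case_data = fx_case(healthy_carrier_counts = carriers(hemi = 1))),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs2_xld_het", gene = fx_gene("XLD"), frequencies = fx_freq(200),
    case_data = fx_case(healthy_carrier_counts = carriers(het = 5))),
    c("BS2_S"), "VUS"))
  add(fx_expect(fx_record(
    "bs4_nonsegregation", gene = fx_gene(high_penetrance_early_onset = TRUE),
    case_data = fx_case(nonsegregation_observed = TRUE)),
    c("BS4_S"), "VUS"))
  pp4_case <- function(...) {
    fx_case(comprehensive_test = TRUE, family_history_consistent = TRUE,
            phenotype_specific_single_etiology = TRUE, ...)
  }
  add(fx_expect(fx_record("pp4_supporting", frequencies = fx_freq(0),
                          case_data = pp4_case()),
                c("PM2_M", "PP4_P"), "VUS"))
  add(fx_expect(fx_record("pp4_strong", frequencies = fx_freq(0),
                          case_data = pp4_case(pathognomonic_extra_evidence = TRUE)),
                c("PM2_M", "PP4_S"), "likely_pathogenic", "3C"))
  add(fx_expect(fx_record(
    "bp5_alternate_cause", gene = fx_gene(ad_childhood_onset = TRUE),
    case_data = fx_case(alternate_molecular_cause = TRUE,
                        variant_noncontributory = TRUE)),
    c("BP5_P"), "VUS"))

  # -- PP3 / BP4 / PS3 / BS3 --------------------------------------------
  add(fx_expect(fx_record("pp3_missense",
                          insilico = insilico_scores(revel = 0.75)),
                c("PP3_P"), "VUS"))
  add(fx_expect(fx_record("bp4_missense",
                          insilico = insilico_scores(revel = 0.35)),
                c("BP4_P"), "VUS"))
  add(fx_expect(fx_record("revel_no_call_band",
                          insilico = insilico_scores(revel = 0.55)),
                character(0), "VUS"))
  add(fx_expect(fx_record("pp3_noncoding", variant = fx_var("other"),
                          insilico = insilico_scores(spliceai_delta = 0.85)),
                c("PP3_P"), "VUS"))
  add(fx_expect(fx_record(
    "pp3_gene_override",
    gene = fx_gene(insilico_overrides = list(revel_pp3 = 0.6)),
    insilico = insilico_scores(revel = 0.65)),
    c("PP3_P"), "VUS"))
  add(fx_expect(fx_record("ps3_strong",
                          functional = functional_assay("damaging", "S")),
                c("PS3_S"), "VUS"))
  add(fx_expect(fx_record("ps3_proband_rejected",
                          functional = functional_assay("damaging", "S",
                                                        proband_derived = TRUE)),
                character(0), "VUS"))
  add(fx_expect(fx_record("bs3_moderate",
                          functional = functional_assay("benign", "M")),
                c("BS3_M"), "VUS"))

  # -- combining rules not yet covered ----------------------------------
  bs2_flags <- function(...) {
    fx_case(in_house_positive_genotype_no_phenotype = TRUE, ...)
  }
  add(fx_expect(fx_record(
    "benign_two_strong", gene = fx_gene(high_penetrance_early_onset = TRUE),
    frequencies = fx_freq(400), case_data = bs2_flags()),
    c("BS1_S", "BS2_S"), "benign", "1B"))
  add(fx_expect(fx_record("lb_strong_plus_supporting",
                          frequencies = fx_freq(400),
                          insilico = insilico_scores(revel = 0.35)),
                c("BS1_S", "BP4_P"), "likely_benign", "2A"))
  add(fx_expect(fx_record(
    "lb_two_supporting", gene = fx_gene(ad_childhood_onset = TRUE),
    insilico = insilico_scores(revel = 0.35),
    case_data = fx_case(alternate_molecular_cause = TRUE,
                        variant_noncontributory = TRUE)),
    c("BP4_P", "BP5_P"), "likely_benign", "2B"))
  add(fx_expect(fx_record("lp_3d", frequencies = fx_freq(1),
                          insilico = insilico_scores(revel = 0.8),
                          functional = functional_assay("damaging", "S")),
                c("PS3_S", "PM2_P", "PP3_P"), "likely_pathogenic", "3D"))
  add(fx_expect(fx_record(
    "lp_3e", gene = fx_gene("AR", decipher_missense_constraint = 0.3),
    frequencies = fx_freq(0),
    case_data = fx_case(recessive_obs = list(obs_in_trans))),
    c("PM1_M", "PM2_M", "PM3_M"), "likely_pathogenic", "3E"))
  add(fx_expect(fx_record(
    "lp_3f", gene = fx_gene(decipher_missense_constraint = 0.3),
    frequencies = fx_freq(0), insilico = insilico_scores(revel = 0.8),
    case_data = fx_case(segregating_meioses = 3)),
    c("PM1_M", "PM2_M", "PP3_P", "PP1_P"), "likely_pathogenic", "3F"))
  add(fx_expect(fx_record(
    "lp_3g", frequencies = fx_freq(0),
    insilico = insilico_scores(revel = 0.8),
    case_data = pp4_case(segregating_meioses = 3,
                         denovo_obs = list(denovo_obs(FALSE, "consistent")))),
    c("PM2_M", "PM6_P", "PP1_P", "PP3_P", "PP4_P"),
    "likely_pathogenic", "3G"))
  add(fx_expect(fx_record("p_4a", gene = lofgene(),
                          variant = nullvar(nmd_predicted = TRUE),
                          frequencies = fx_freq(0),
                          functional = functional_assay("damaging", "S")),
                c("PVS1_VS", "PS3_S", "PM2_M"), "pathogenic", "4A"))
  add(fx_expect(fx_record(
    "p_4b", gene = lofgene(), variant = nullvar(nmd_predicted = TRUE),
    frequencies = fx_freq(0),
    case_data = fx_case(denovo_obs = list(denovo_obs(FALSE, "highly_specific")))),
    c("PVS1_VS", "PM2_M", "PM6_M"), "pathogenic", "4B"))
  add(fx_expect(fx_record(
    "p_4c", gene = lofgene(), variant = nullvar(nmd_predicted = TRUE),
    frequencies = fx_freq(0),
    case_data = fx_case(segregating_meioses = 3)),
    c("PVS1_VS", "PM2_M", "PP1_P"), "pathogenic", "4C"))
  add(fx_expect(fx_record(
    "p_4d", gene = lofgene(), variant = nullvar(nmd_predicted = TRUE),
    frequencies = fx_freq(1),
    case_data = fx_case(segregating_meioses = 3)),
    c("PVS1_VS", "PM2_P", "PP1_P"), "pathogenic", "4D"))
  add(fx_expect(fx_record(
    "p_4e", functional = functional_assay("damaging", "S"),
    case_data = fx_case(founder_variant = TRUE)),
    c("PS3_S", "PS4_S"), "pathogenic", "4E"))
  add(fx_expect(fx_record(
    "p_4f", gene = fx_gene(decipher_missense_constraint = 0.3),
    frequencies = fx_freq(0), insilico = lowsplice,
    prior_variants = prior_other("pathogenic", 1),
    functional = functional_assay("damaging", "S")),
    c("PS3_S", "PM1_M", "PM2_M", "PM5_M"), "pathogenic", "4F"))
  add(fx_expect(fx_record(
    "p_4g", frequencies = fx_freq(0), insilico = insilico_scores(revel = 0.8),
    functional = functional_assay("damaging", "S"),
    case_data = fx_case(segregating_meioses = 3,
                        denovo_obs = list(denovo_obs(FALSE, "highly_specific")))),
    c("PS3_S", "PM2_M", "PM6_M", "PP1_P", "PP3_P"), "pathogenic", "4G"))
  add(fx_expect(fx_record(
    "p_4h", frequencies = fx_freq(0), insilico = insilico_scores(revel = 0.8),
    functional = functional_assay("damaging", "S"),
    case_data = pp4_case(segregating_meioses = 3,
                         denovo_obs = list(denovo_obs(FALSE, "consistent")))),
    c("PS3_S", "PM2_M", "PM6_P", "PP1_P", "PP3_P", "PP4_P"),
    "pathogenic", "4H"))
  add(fx_expect(fx_record(
    "conflicting_directions",
    gene = fx_gene(high_penetrance_early_onset = TRUE),
    frequencies = fx_freq(400),
    functional = functional_assay("damaging", "S"),
    case_data = bs2_flags(denovo_obs = list(denovo_obs(TRUE, "highly_specific")))),
    c("BS1_S", "BS2_S", "PS3_S", "PS2_S"), "VUS"))
  add(fx_expect(fx_record("no_evidence"), character(0), "VUS"))

  # -- gating ------------------------------------------------------------
  add(fx_expect(fx_record("gate_disputed",
                          gene = fx_gene(clinical_validity = "disputed")),
                character(0), NA_character_, status = "not_classifiable"))
  add(fx_expect(fx_record("gate_vcep_delegate",
                          gene = fx_gene(vcep_curated = TRUE)),
                character(0), NA_character_, status = "vcep_delegate"))

  fx
}

# Random cohorts --------------------------------------------------------------

# Injectors: each adds evidence that makes one clause fire on the base
# record.  Frequency clauses are mutually exclusive; when several are
# drawn the strongest wins (BA1 > BS1 > PM2_M > PM2_P).
cohort_clauses <- c("BA1", "BS1", "PM2_M", "PM2_P", "PVS1", "PS1", "PM5",
                    "PM1", "PP2", "BP7", "PM3", "PS2", "PM6", "PP1", "PS4",
                    "BS2", "BS4", "PP4", "BP5", "PP3", "BP4", "PS3", "BS3")

#' Generate a reproducible random evidence cohort
#'
#' Builds `n` synthetic evidence records from a fixed seed.  Each clause
#' named in `clause_prevalence` is injected independently with its
#' configured probability; mutually exclusive frequency clauses resolve to
#' the strongest drawn.  Useful for property tests and throughput checks;
#' the cohort makes no attempt to emulate realistic human allele-frequency
#' spectra.
#'
#' @param n Number of records (> 0).
#' @param seed Integer seed.
#' @param clause_prevalence Named numeric vector/list of per-clause firing
#'   probabilities in `[0, 1]`; names among BA1, BS1, PM2_M, PM2_P, PVS1,
#'   PS1, PM5, PM1, PP2, BP7, PM3, PS2, PM6, PP1, PS4, BS2, BS4, PP4, BP5,
#'   PP3, BP4, PS3, BS3.
#' @return List of [evidence_record()]s.
#' @export
random_cohort <- function(n, seed = 20230101,
                          clause_prevalence = c(PM2_P = 0.3, PP3 = 0.2,
                                                BP4 = 0.2, PP1 = 0.1)) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be > 0")
  prev <- unlist(clause_prevalence)
  if (length(prev) > 0) {
    bad <- setdiff(names(prev), cohort_clauses)
    if (length(bad) > 0) stop("unknown clause name(s): ",
                              paste(bad, collapse = ", "))
    if (any(prev < 0 | prev > 1)) {
      stop("clause prevalence values must lie in [0, 1]")
    }
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())
  lapply(seq_len(n), function(i) {
    active <- names(prev)[stats::runif(length(prev)) < prev]
    build_cohort_record(paste0("r", i), active)
  })
}

# Save/restore RNG state so cohort generation does not perturb callers.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}

build_cohort_record <- function(id, active) {
  gene_args <- list(symbol = "COHORT1", inheritance = "AD",
                    clinical_validity = "definitive")
  var_args <- list(consequence = "missense", codon_index = 100L,
                   ref_aa = "A", alt_aa = "V")
  freq_ac <- 100                       # mid-band: no frequency call
  insilico_args <- list()
  functional <- functional_assay()
  case_args <- list()
  priors <- list()

  if ("PVS1" %in% active) {
    gene_args$pli <- 0.99
    var_args <- list(consequence = "nonsense", nmd_predicted = TRUE)
  } else if ("BP7" %in% active) {
    var_args <- list(consequence = "synonymous")
    insilico_args$spliceai_delta <- 0.05
    insilico_args$gerp <- -1.5
  }
  # frequency family: strongest drawn wins
  if ("BA1" %in% active) freq_ac <- 12000
  else if ("BS1" %in% active) freq_ac <- 400
  else if ("PM2_M" %in% active) freq_ac <- 0
  else if ("PM2_P" %in% active) freq_ac <- 1
  if (var_args$consequence == "missense") {
    if ("PS1" %in% active) {
      priors <- c(priors, list(prior_variant(100L, "V", TRUE, "pathogenic", 1)))
    } else if ("PM5" %in% active) {
      priors <- c(priors, list(prior_variant(100L, "K", FALSE, "pathogenic", 1)))
    }
    if ("PM1" %in% active) gene_args$decipher_missense_constraint <- 0.3
    if ("PP2" %in% active) {
      gene_args$pathogenic_missense_count <- 5
      gene_args$missense_constraint_z <- 3.5
    }
    if ("PP3" %in% active) insilico_args$revel <- 0.8
    else if ("BP4" %in% active) insilico_args$revel <- 0.3
  }
  if ("PM3" %in% active) {
    gene_args$inheritance <- "AR"
    case_args$recessive_obs <- list(recessive_obs("in_trans_with_PLP"))
  }
  if ("PS2" %in% active) {
    case_args$denovo_obs <- c(case_args$denovo_obs,
                              list(denovo_obs(TRUE, "highly_specific")))
  }
  if ("PM6" %in% active) {
    case_args$denovo_obs <- c(case_args$denovo_obs,
                              list(denovo_obs(FALSE, "highly_specific")))
  }
  if ("PP1" %in% active) {
    case_args$segregating_meioses <-
      if (gene_args$inheritance == "AR") 1L else 3L
  }
  if ("PS4" %in% active) case_args$founder_variant <- TRUE
  if ("BS2" %in% active) {
    gene_args$high_penetrance_early_onset <- TRUE
    case_args$in_house_positive_genotype_no_phenotype <- TRUE
  }
  if ("BS4" %in% active) {
    gene_args$high_penetrance_early_onset <- TRUE
    case_args$nonsegregation_observed <- TRUE
  }
  if ("PP4" %in% active) {
    case_args$comprehensive_test <- TRUE
    case_args$family_history_consistent <- TRUE
    case_args$phenotype_specific_single_etiology <- TRUE
    if (freq_ac == 100) freq_ac <- 0   # PP4 needs the rarity precondition
  }
  if ("BP5" %in% active) {
    gene_args$ad_childhood_onset <- TRUE
    case_args$alternate_molecular_cause <- TRUE
    case_args$variant_noncontributory <- TRUE
  }
  if ("PS3" %in% active) functional <- functional_assay("damaging", "S")
  else if ("BS3" %in% active) functional <- functional_assay("benign", "S")

  evidence_record(
    id = id, gene = do.call(gene_context, gene_args),
    variant = do.call(variant_descriptor, var_args),
    frequencies = list(frequency_record("overall", freq_ac, 200000)),
    prior_variants = priors,
    insilico = do.call(insilico_scores, insilico_args),
    functional = functional,
    case_data = do.call(case_level_data, case_args))
}
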