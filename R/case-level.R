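# Case-level criteria: the PM3/PM6/PS2 scoring systems, PS4 proband
# counting, PP1 meiosis counting, PP4, BS2, BS4, BP5.  BP2 is not applied.

#' Construct a recessive (in-trans) observation
#'
#' One unrelated affected individual counted by the recessive scoring
#' system: the variant seen in trans with a known pathogenic or likely
#' pathogenic variant (score 1.0), with unknown phase (0.5), or in
#' homozygosity (0.5; 0.25 when the parents are consanguineous).
#'
#' @param phase `"in_trans_with_PLP"`, `"phase_unknown"` or `"homozygous"`.
#' @param consanguineous Logical; meaningful only for homozygous
#'   observations.
#' @return An object of class `recessive_obs`.
#' @export
recessive_obs <- function(phase, consanguineous = FALSE) {
  phase <- match.arg(phase, c("in_trans_with_PLP", "phase_unknown",
                              "homozygous"))
  structure(list(phase = phase, consanguineous = isTRUE(consanguineous)),
            class = "recessive_obs")
}

#' Construct a de novo observation
#'
#' One unrelated affected individual with a (confirmed or assumed) de novo
#' occurrence, scored by how specific the phenotype is for the gene.
#'
#' @param confirmed Logical; `TRUE` when both maternity and paternity are
#'   confirmed (counts toward PS2), `FALSE` for assumed de novo (PM6).
#' @param phenotype_match `"highly_specific"`, `"consistent"`,
#'   `"consistent_high_heterogeneity"` or `"inconsistent"`.
#' @return An object of class `denovo_obs`.
#' @export
denovo_obs <- function(confirmed, phenotype_match) {
  phenotype_match <- match.arg(phenotype_match,
    c("highly_specific", "consistent", "consistent_high_heterogeneity",
      "inconsistent"))
  structure(list(confirmed = isTRUE(confirmed),
                 phenotype_match = phenotype_match),
            class = "denovo_obs")
}

#' Construct the case-level evidence block
#'
#' @param recessive_obs List of [recessive_obs()] (PM3).
#' @param denovo_obs List of [denovo_obs()] (PS2/PM6).
#' @param segregating_meioses Informative meioses segregating with disease
#'   (PP1).
#' @param nonsegregation_observed Logical; affected family member lacking
#'   the genotype (BS4).
#' @param proband_count Unrelated previously described probands with a
#'   confirmed phenotype (PS4 counting).
#' @param case_control Optional list with `odds_ratio` and `ci_low`.
#' @param founder_variant Logical; known founder pathogenic variant (PS4).
#' @param vcep_pathogenic Logical; curated pathogenic by a recognised
#'   expert panel (PS4).
#' @param healthy_carrier_counts List with `het`, `hom`, `hemi` counts of
#'   healthy carriers in control databases (BS2).
#' @param phenotype_specific_single_etiology,comprehensive_test,family_history_consistent,pathognomonic_extra_evidence
#'   Logical conditions of PP4.
#' @param alternate_molecular_cause Logical; case has an alternate primary
#'   molecular finding (BP5).
#' @param variant_noncontributory Logical; the variant is deemed unlikely
#'   to contribute to or modify the primary finding (BP5).
#' @param in_house_positive_genotype_no_phenotype Logical; in-house
#'   positive genotype without the phenotype (BS2).
#' @return An object of class `case_level_data`.
#' @export
case_level_data <- function(recessive_obs = list(),
                            denovo_obs = list(),
                            segregating_meioses = 0L,
                            nonsegregation_observed = FALSE,
                            proband_count = 0L,
                            case_control = NULL,
                            founder_variant = FALSE,
                            vcep_pathogenic = FALSE,
                            healthy_carrier_counts = list(het = 0L, hom = 0L,
                                                          hemi = 0L),
                            phenotype_specific_single_etiology = FALSE,
                            comprehensive_test = FALSE,
                            family_history_consistent = FALSE,
                            pathognomonic_extra_evidence = FALSE,
                            alternate_molecular_cause = FALSE,
                            variant_noncontributory = FALSE,
                            in_house_positive_genotype_no_phenotype = FALSE) {
  if (segregating_meioses < 0 || proband_count < 0) {
    stop("counts must be nonnegative")
  }
  cc <- healthy_carrier_counts
  for (k in c("het", "hom", "hemi")) {
    if (is.null(cc[[k]])) cc[[k]] <- 0L
    if (cc[[k]] < 0) stop("healthy carrier counts must be nonnegative")
  }
  if (!is.null(case_control)) {
    if (is.null(case_control$odds_ratio) || case_control$odds_ratio <= 0) {
      stop("case_control$odds_ratio must be > 0")
    }
  }
  structure(
    list(recessive_obs = recessive_obs, denovo_obs = denovo_obs,
         segregating_meioses = as.integer(segregating_meioses),
         nonsegregation_observed = isTRUE(nonsegregation_observed),
         proband_count = as.integer(proband_count),
         case_control = case_control,
         founder_variant = isTRUE(founder_variant),
         vcep_pathogenic = isTRUE(vcep_pathogenic),
         healthy_carrier_counts = cc,
         phenotype_specific_single_etiology =
           isTRUE(phenotype_specific_single_etiology),
         comprehensive_test = isTRUE(comprehensive_test),
         family_history_consistent = isTRUE(family_history_consistent),
         pathognomonic_extra_evidence = isTRUE(pathognomonic_extra_evidence),
         alternate_molecular_cause = isTRUE(alternate_molecular_cause),
         variant_noncontributory = isTRUE(variant_noncontributory),
         in_house_positive_genotype_no_phenotype =
           isTRUE(in_house_positive_genotype_no_phenotype)),
    class = "case_level_data"
  )
}

# Shared scoring-system ladder: supporting at SS >= 0.5, moderate >= 1,
# strong >= 2, very strong >= 4.
ss_ladder <- function(ss) {
  if (ss >= 4) "VS" else if (ss >= 2) "S" else if (ss >= 1) "M"
  else if (ss >= 0.5) "P" else NA_character_
}

pm3_obs_score <- function(o) {
  switch(o$phase,
         in_trans_with_PLP = 1.0,
         phase_unknown = 0.5,
         homozygous = if (o$consanguineous) 0.25 else 0.5)
}

pm3_obs_tag <- function(o) {
  switch(o$phase,
         in_trans_with_PLP = "[PM3.in_trans]",
         phase_unknown = "[PM3.phase_unknown]",
         homozygous = if (o$consanguineous) "[PM3.hom_consang]" else "[PM3.hom]")
}

#' Score PM3 (recessive proband counting)
#'
#' Additive scoring system over unrelated affected individuals: 1.0 for an
#' observation in trans with a pathogenic/likely pathogenic variant, 0.5
#' for unknown phase, 0.5 for homozygosity (0.25 with consanguineous
#' parents).  Strength by the shared SS ladder (P >= 0.5, M >= 1, S >= 2,
#' VS >= 4).  Restricted to genes with a recessive inheritance component.
#'
#' @param obs List of [recessive_obs()].
#' @param inheritance Inheritance mode of the gene.
#' @return List with elements `ss` (numeric total) and `call` (a PM3
#'   [criterion_call()], an unapplied call for non-recessive genes, or
#'   `NULL`).
#' @export
score_pm3 <- function(obs, inheritance) {
  if (!includes_recessive(inheritance)) {
    if (length(obs) == 0) return(list(ss = 0, call = NULL))
    return(list(ss = 0, call = unapplied_call("PM3", paste(
      "[PM3.not_recessive] recessive proband counting does not apply to",
      inheritance, "inheritance"))))
  }
  if (length(obs) == 0) return(list(ss = 0, call = NULL))
  scores <- vapply(obs, pm3_obs_score, numeric(1))
  ss <- sum(scores)
  s <- ss_ladder(ss)
  if (is.na(s)) return(list(ss = ss, call = NULL))
  tags <- paste(unique(vapply(obs, pm3_obs_tag, character(1))), collapse = " ")
  list(ss = ss, call = criterion_call("PM3", s, score = ss, rationale =
    sprintf("[PM3.call] %s scoring-system total %.2f over %d observation(s)",
            tags, ss, length(obs))))
}

denovo_obs_score <- function(o) {
  base <- switch(o$phenotype_match,
                 highly_specific = 1.0,
                 consistent = 0.5,
                 consistent_high_heterogeneity = 0.25,
                 inconsistent = 0)
  if (o$confirmed) 2 * base else base
}

#' Score PS2 / PM6 (de novo observations)
#'
#' Confirmed de novo observations (maternity and paternity confirmed)
#' score 2.0 / 1.0 / 0.5 / 0 by phenotype specificity and accumulate
#' toward PS2; assumed de novo observations score 1.0 / 0.5 / 0.25 / 0 and
#' accumulate toward PM6.  Both criteria use the shared SS ladder.  Both
#' calls may be emitted for mixed cohorts; the classifier's caution policy
#' caps their joint use.
#'
#' @param obs List of [denovo_obs()].
#' @return List with `ps2_ss`, `pm6_ss` and `calls` (list of PS2/PM6
#'   [criterion_call()]s, possibly empty).
#' @export
score_de_novo <- function(obs) {
  confirmed <- Filter(function(o) o$confirmed, obs)
  assumed <- Filter(function(o) !o$confirmed, obs)
  ps2_ss <- sum(vapply(confirmed, denovo_obs_score, numeric(1)), 0)
  pm6_ss <- sum(vapply(assumed, denovo_obs_score, numeric(1)), 0)
  calls <- list()
  s2 <- ss_ladder(ps2_ss)
  if (!is.na(s2)) {
    calls <- c(calls, list(criterion_call("PS2", s2, score = ps2_ss,
      rationale = sprintf(
        "[PS2.call] confirmed de novo scoring-system total %.2f over %d observation(s)",
        ps2_ss, length(confirmed)))))
  }
  s6 <- ss_ladder(pm6_ss)
  if (!is.na(s6)) {
    calls <- c(calls, list(criterion_call("PM6", s6, score = pm6_ss,
      rationale = sprintf(
        "[PM6.call] assumed de novo scoring-system total %.2f over %d observation(s)",
        pm6_ss, length(assumed)))))
  }
  list(ps2_ss = ps2_ss, pm6_ss = pm6_ss, calls = calls)
}

#' Score PP1 (cosegregation meiosis counting)
#'
#' For dominant conditions: supporting at 3-4 segregating meioses,
#' moderate at 5-6, strong at 7 or more.  For conditions with a recessive
#' component: supporting at 1, moderate at 2, strong at 3 or more.
#'
#' @param meioses Nonnegative count of informative segregating meioses.
#' @param inheritance Inheritance mode of the gene.
#' @return A PP1 [criterion_call()] or `NULL`.
#' @export
score_pp1 <- function(meioses, inheritance) {
  stopifnot(meioses >= 0)
  if (includes_recessive(inheritance)) {
    s <- if (meioses >= 3) "S" else if (meioses == 2) "M"
    else if (meioses == 1) "P" else NA_character_
    tag <- "[PP1.ar]"
  } else {
    s <- if (meioses >= 7) "S" else if (meioses >= 5) "M"
    else if (meioses >= 3) "P" else NA_character_
    tag <- "[PP1.ad]"
  }
  if (is.na(s)) return(NULL)
  criterion_call("PP1", s, rationale = sprintf(
    "%s variant segregates with %d informative meioses", tag, meioses))
}

#' Evaluate PS4 (prevalence in affected individuals)
#'
#' Strong weight for case-control studies with odds ratio (or relative
#' risk) above 5 and a confidence interval excluding 1, for known founder
#' pathogenic variants, and for variants curated pathogenic by recognised
#' expert panels.  Otherwise unrelated previously described probands are
#' counted, but only for dominant conditions and only for variants rare
#' enough to hold a PM2 call at either level: cancer genes reach
#' supporting at 2-5, moderate at 6-9 and strong at >= 10 probands; other
#' genes reach supporting at 1-2, moderate at 3-4 and strong at >= 5.
#'
#' @param data A [case_level_data()].
#' @param gene A [gene_context()].
#' @param pm2_call The frequency-module call (or `NULL`).
#' @return A PS4 [criterion_call()], an unapplied call when the rarity
#'   precondition blocks counting, or `NULL`.
#' @export
evaluate_ps4 <- function(data, gene, pm2_call = NULL) {
  cc <- data$case_control
  if (!is.null(cc) && cc$odds_ratio > 5 && !is.null(cc$ci_low) &&
      cc$ci_low > 1) {
    return(criterion_call("PS4", "S", rationale = sprintf(
      "[PS4.case_control] odds ratio %.2f > 5 with confidence interval excluding 1",
      cc$odds_ratio)))
  }
  if (data$founder_variant) {
    return(criterion_call("PS4", "S",
      rationale = "[PS4.founder] known founder pathogenic variant"))
  }
  if (data$vcep_pathogenic) {
    return(criterion_call("PS4", "S",
      rationale = "[PS4.vcep] curated pathogenic by a recognised expert panel"))
  }
  if (data$proband_count == 0) return(NULL)
  if (!includes_dominant(gene$inheritance)) return(NULL)
  pm2_met <- !is.null(pm2_call) && pm2_call$applied &&
    pm2_call$criterion == "PM2"
  if (!pm2_met) {
    return(unapplied_call("PS4", paste(
      "[PS4.no_pm2] proband counting requires the variant to meet the",
      "rarity criterion at either level")))
  }
  n <- data$proband_count
  if (gene$category == "cancer") {
    s <- if (n >= 10) "S" else if (n >= 6) "M" else if (n >= 2) "P"
    else NA_character_
    tag <- "[PS4.probands_cancer]"
  } else {
    s <- if (n >= 5) "S" else if (n >= 3) "M" else if (n >= 1) "P"
    else NA_character_
    tag <- "[PS4.probands_general]"
  }
  if (is.na(s)) return(NULL)
  criterion_call("PS4", s, rationale = sprintf(
    "%s %d unrelated previously described probands", tag, n))
}

#' Evaluate BS2 (observed in healthy individuals)
#'
#' Strong benign weight when healthy carriers contradict the expected
#' genotype-phenotype relationship: in-house positive genotype without the
#' phenotype for high-penetrance early-onset conditions; homozygotes in
#' control databases for cancer genes or fully penetrant recessive genes;
#' at least five carrier alleles for green-list pediatric dominant genes;
#' hemizygous/homozygous controls for XL recessive genes; or at least five
#' heterozygous controls for XL dominant genes.
#'
#' @param data A [case_level_data()].
#' @param gene A [gene_context()].
#' @return A BS2 [criterion_call()] or `NULL`.
#' @export
evaluate_bs2 <- function(data, gene) {
  cc <- data$healthy_carrier_counts
  if (data$in_house_positive_genotype_no_phenotype &&
      gene$high_penetrance_early_onset) {
    return(criterion_call("BS2", "S", rationale = paste(
      "[BS2.inhouse] in-house positive genotype without phenotype for a",
      "high-penetrance early-onset condition")))
  }
  if (gene$category == "cancer" && cc$hom >= 1) {
    return(criterion_call("BS2", "S", rationale =
      "[BS2.cancer_hom] homozygous control individual for a cancer gene"))
  }
  if (gene$inheritance %in% c("AR", "AD_AR") && gene$complete_penetrance &&
      cc$hom >= 1) {
    return(criterion_call("BS2", "S", rationale =
      "[BS2.ar_hom] homozygous control for a fully penetrant recessive condition"))
  }
  if (gene$pediatric_green_list && gene$inheritance == "AD" &&
      (cc$het + 2 * cc$hom) >= 5) {
    return(criterion_call("BS2", "S", rationale =
      "[BS2.greenlist] at least five carrier alleles for a green-list pediatric dominant gene"))
  }
  if (gene$inheritance %in% c("XL", "XLR") && (cc$hemi >= 1 || cc$hom >= 1)) {
    return(criterion_call("BS2", "S", rationale =
      "[BS2.xl_hemi] hemizygous or homozygous control for an X-linked recessive condition"))
  }
  if (gene$inheritance == "XLD" && cc$het >= 5) {
    return(criterion_call("BS2", "S", rationale =
      "[BS2.xld_het] at least five heterozygous controls for an X-linked dominant condition"))
  }
  NULL
}

#' Evaluate BS4 (lack of segregation)
#'
#' Strong benign weight for nonsegregation, restricted to genes linked to
#' high-penetrance early-onset conditions where an affected family member
#' lacks the genotype.
#'
#' @param data A [case_level_data()].
#' @param gene A [gene_context()].
#' @return A BS4 [criterion_call()] or `NULL`.
#' @export
evaluate_bs4 <- function(data, gene) {
  if (data$nonsegregation_observed && gene$high_penetrance_early_onset) {
    return(criterion_call("BS4", "S", rationale = paste(
      "[BS4.call] affected family member lacks the genotype in a",
      "high-penetrance early-onset condition")))
  }
  NULL
}

#' Evaluate PP4 (phenotype highly specific for a single-etiology disease)
#'
#' Requires a comprehensive test covering all relevant genes and
#' mechanisms, a rare variant (a PM2 call at any level) without other
#' candidates, a family history consistent with the inheritance pattern,
#' and a phenotype specific for a single genetic etiology.  Supporting
#' weight; upgraded to strong with pathognomonic extra evidence (e.g.
#' muscle biopsy or biochemistry).
#'
#' @param data A [case_level_data()].
#' @param pm2_call The frequency-module call (or `NULL`).
#' @return A PP4 [criterion_call()] or `NULL`.
#' @export
evaluate_pp4 <- function(data, pm2_call = NULL) {
  pm2_met <- !is.null(pm2_call) && pm2_call$applied &&
    pm2_call$criterion == "PM2"
  if (!(data$comprehensive_test && pm2_met &&
        data$family_history_consistent &&
        data$phenotype_specific_single_etiology)) {
    return(NULL)
  }
  if (data$pathognomonic_extra_evidence) {
    criterion_call("PP4", "S", rationale = paste(
      "[PP4.strong] all conditions met with pathognomonic additional",
      "clinical evidence"))
  } else {
    criterion_call("PP4", "P", rationale =
      "[PP4.supporting] comprehensive testing, rarity, family history and phenotype specificity all met")
  }
}

#' Evaluate BP5 (alternate molecular cause)
#'
#' Supporting benign weight, used exclusively for variants linked to
#' dominant highly penetrant childhood-onset diseases when the case has a
#' clear alternate primary molecular finding and the variant is deemed
#' unlikely to contribute to or modify it.
#'
#' @param data A [case_level_data()].
#' @param gene A [gene_context()].
#' @return A BP5 [criterion_call()] or `NULL`.
#' @export
evaluate_bp5 <- function(data, gene) {
  if (data$alternate_molecular_cause && gene$ad_childhood_onset &&
      gene$inheritance %in% c("AD", "AD_AR") && data$variant_noncontributory) {
    return(criterion_call("BP5", "P", rationale = paste(
      "[BP5.call] alternate primary molecular finding explains the phenotype;",
      "variant deemed non-contributory")))
  }
  NULL
}
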