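# Criterion catalogue, strength ladder, and evidence-point arithmetic shared
# by every module of the engine.

#' The 28 ACMG/AMP criterion codes
#'
#' All pathogenic (PVS1, PS1-4, PM1-6, PP1-5) and benign (BA1, BS1-4, BP1-7)
#' criterion codes recognised by the engine, including codes that are carried
#' in the audit trail but never applied (BP1, BP2, BP3 outside curated
#' overrides; PP5 and BP6, which are discontinued).
#'
#' @return Character vector of the 28 criterion codes.
#' @export
acmg_criteria <- function() {
  c("PVS1", "PS1", "PS2", "PS3", "PS4",
    "PM1", "PM2", "PM3", "PM4", "PM5", "PM6",
    "PP1", "PP2", "PP3", "PP4", "PP5",
    "BA1", "BS1", "BS2", "BS3", "BS4",
    "BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7")
}

#' Direction of a criterion code
#'
#' @param criterion Criterion code (e.g. `"PM2"`, `"BS1"`).
#' @return `"pathogenic"` for P* codes, `"benign"` for B* codes.
#' @export
criterion_direction <- function(criterion) {
  stopifnot(criterion %in% acmg_criteria())
  ifelse(substr(criterion, 1, 1) == "P", "pathogenic", "benign")
}

# Strength codes in decreasing order of weight: stand-alone, very strong,
# strong, moderate, supporting.
strength_levels <- c("A", "VS", "S", "M", "P")

# Rank for conflict resolution (higher wins).
strength_rank <- c(A = 5, VS = 4, S = 3, M = 2, P = 1)

# Evidence points of the naturally scaled point system: supporting 1,
# moderate 2, strong 4, very strong 8.  Stand-alone (BA1) is given the
# very-strong weight on the Bayesian path by default (configurable in
# compute_posterior()).
strength_points <- c(P = 1, M = 2, S = 4, VS = 8, A = 8)

# Strength modulations permitted for each criterion.  NULL means the
# criterion is never applied (carried in the audit trail only).
criterion_strengths <- list(
  PVS1 = c("P", "M", "S", "VS"),
  PS1  = c("M", "S"),
  PS2  = c("P", "M", "S", "VS"),
  PS3  = c("P", "M", "S", "VS"),
  PS4  = c("P", "M", "S"),
  PM1  = c("M", "S"),
  PM2  = c("P", "M"),
  PM3  = c("P", "M", "S", "VS"),
  PM4  = c("P", "M"),
  PM5  = c("P", "M"),
  PM6  = c("P", "M", "S", "VS"),
  PP1  = c("P", "M", "S"),
  PP2  = "P",
  PP3  = "P",
  PP4  = c("P", "S"),
  PP5  = NULL,
  BA1  = "A",
  BS1  = "S",
  BS2  = "S",
  BS3  = c("P", "M", "S"),
  BS4  = "S",
  BP1  = NULL,
  BP2  = NULL,
  BP3  = "P",
  BP4  = "P",
  BP5  = "P",
  BP6  = NULL,
  BP7  = "P"
)

#' Allowed strength modulations for a criterion
#'
#' @param criterion Criterion code.
#' @return Character vector of allowed strength codes (`"A"`, `"VS"`, `"S"`,
#'   `"M"`, `"P"`), or `NULL` for criteria that are never applied.
#' @export
allowed_strengths <- function(criterion) {
  stopifnot(criterion %in% acmg_criteria())
  criterion_strengths[[criterion]]
}

# Registry of clause tags.  Every branch of every criterion that can emit
# (or deliberately withhold) a call stamps its rationale with one of these
# tags; the gold fixture set is required to exercise all of them.
clause_registry <- c(
  # population frequency
  "BA1.default", "BA1.exception_skip", "BS1.table2",
  "PM2.absent_ad", "PM2.freq_m", "PM2.freq_p", "PM2.no_data",
  # variant type and location
  "PVS1.nmd_vs", "PVS1.escape_critical_s", "PVS1.escape_m",
  "PVS1.initiation_m", "PVS1.exonskip_critical_s", "PVS1.exonskip_m",
  "PVS1.lof_not_established",
  "PS1.s_path", "PS1.s_lp2", "PS1.m_lp1",
  "PM5.m_path", "PM5.m_lp2", "PM5.p_lp1", "PS1PM5.splice_suppressed",
  "PM1.notch3", "PM1.collagen", "PM1.zinc_finger", "PM1.decipher",
  "PM1.hotspot",
  "PM4.indel_small", "PM4.indel_large", "PM4.stoploss",
  "PM4.repeat_skip", "PM4.no_pm2",
  "PP2.constraint",
  "BP7.synonymous", "BP7.missing_scores",
  # case-level
  "PM3.call", "PM3.not_recessive",
  "PM3.in_trans", "PM3.phase_unknown", "PM3.hom", "PM3.hom_consang",
  "PS2.call", "PM6.call",
  "PP1.ad", "PP1.ar",
  "PS4.case_control", "PS4.founder", "PS4.vcep",
  "PS4.probands_cancer", "PS4.probands_general", "PS4.no_pm2",
  "BS2.inhouse", "BS2.cancer_hom", "BS2.ar_hom", "BS2.greenlist",
  "BS2.xl_hemi", "BS2.xld_het",
  "BS4.call",
  "PP4.supporting", "PP4.strong",
  "BP5.call",
  # in-silico / functional
  "PP3.missense", "PP3.splice", "BP4.missense", "BP4.splice",
  "PP3BP4.override",
  "PS3.passthrough", "PS3.proband_rejected", "BS3.passthrough",
  # unapplied / discontinued
  "PP5.discontinued", "BP6.discontinued",
  "BP1.not_applied", "BP2.not_applied", "BP3.not_applied"
)

#' Clause tags tracked for branch coverage
#'
#' Stable identifiers for every decision clause of the engine.  Rationale
#' strings open with the tag of the clause that produced them, which lets
#' the fixture suite verify that the gold records exercise every branch.
#'
#' @return Character vector of clause tags.
#' @export
clause_tags <- function() clause_registry
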