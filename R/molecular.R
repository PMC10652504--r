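# Variant-type and location criteria: PVS1 (decision-table modulation),
# PS1/PM5, PM1, PM4, PP2, BP7.  BP1 and BP3 are deliberately not applied.

null_consequences <- c("nonsense", "frameshift", "canonical_splice",
                       "initiation_codon", "single_multi_exon_deletion")
all_consequences <- c(null_consequences, "missense", "synonymous",
                      "inframe_indel", "stop_loss", "other")

#' Construct a variant descriptor
#'
#' Molecular consequence and location context of the variant on the
#' primary transcript.
#'
#' @param consequence One of `"nonsense"`, `"frameshift"`,
#'   `"canonical_splice"`, `"initiation_codon"`,
#'   `"single_multi_exon_deletion"`, `"missense"`, `"synonymous"`,
#'   `"inframe_indel"`, `"stop_loss"`, `"other"`.
#' @param codon_index Affected residue index on the primary transcript
#'   (missense context), or `NA`.
#' @param ref_aa,alt_aa One-letter amino-acid codes for missense variants.
#' @param indel_aa_length Residues inserted or deleted (in-frame indels).
#' @param in_repeat_region Logical; region with more than 3 identical
#'   sequence units (bases or sets of bases).
#' @param nmd_predicted Logical; transcript predicted to undergo
#'   nonsense-mediated decay (null variants).
#' @param last_exon_or_50nt_rule Logical; premature stop in the last exon
#'   or the last 50 nt of the penultimate exon (NMD escape).
#' @param affected_region_critical Logical; truncated/affected region is
#'   critical to protein function.
#' @param exon_skip_inframe Logical; splice variant predicted to cause
#'   in-frame exon skipping.
#' @param cysteine_parity_change Logical; substitution alters the cysteine
#'   count of an EGF-like repeat (supplied by the annotator; used by the
#'   NOTCH3 PM1 clause).
#' @param splicing_functional_aberrant Logical; functional studies indicate
#'   aberrant splicing (suppresses PS1/PM5).
#' @return An object of class `variant_descriptor`.
#' @export
variant_descriptor <- function(consequence,
                               codon_index = NA_integer_,
                               ref_aa = NA_character_,
                               alt_aa = NA_character_,
                               indel_aa_length = 0L,
                               in_repeat_region = FALSE,
                               nmd_predicted = NA,
                               last_exon_or_50nt_rule = NA,
                               affected_region_critical = NA,
                               exon_skip_inframe = NA,
                               cysteine_parity_change = FALSE,
                               splicing_functional_aberrant = FALSE) {
  consequence <- match.arg(consequence, all_consequences)
  indel_aa_length <- as.integer(indel_aa_length)
  if (indel_aa_length > 0 && consequence != "inframe_indel") {
    stop("indel_aa_length > 0 is only meaningful for inframe_indel variants")
  }
  if (consequence == "inframe_indel" && indel_aa_length < 1) {
    stop("inframe_indel variants require indel_aa_length >= 1")
  }
  structure(
    list(consequence = consequence, codon_index = codon_index,
         ref_aa = ref_aa, alt_aa = alt_aa,
         indel_aa_length = indel_aa_length,
         in_repeat_region = isTRUE(in_repeat_region),
         nmd_predicted = nmd_predicted,
         last_exon_or_50nt_rule = last_exon_or_50nt_rule,
         affected_region_critical = affected_region_critical,
         exon_skip_inframe = exon_skip_inframe,
         cysteine_parity_change = isTRUE(cysteine_parity_change),
         splicing_functional_aberrant = isTRUE(splicing_functional_aberrant)),
    class = "variant_descriptor"
  )
}

#' Construct a prior classified variant record
#'
#' A previously classified missense variant at the same residue, used by
#' PS1 (equivalent protein change) and PM5 (different change, same codon).
#'
#' @param codon_index Residue index shared with the assessed variant.
#' @param alt_aa Alternate amino acid of the prior variant.
#' @param protein_change_equivalent Logical; same amino-acid change as the
#'   assessed variant (regardless of nucleotide change).
#' @param classification `"pathogenic"` or `"likely_pathogenic"`.
#' @param independent_report_count Number of independent reports (>= 1).
#' @return An object of class `prior_variant`.
#' @export
prior_variant <- function(codon_index, alt_aa, protein_change_equivalent,
                          classification, independent_report_count = 1L) {
  classification <- match.arg(classification,
                              c("pathogenic", "likely_pathogenic"))
  if (independent_report_count < 1) stop("report counts must be >= 1")
  structure(
    list(codon_index = codon_index, alt_aa = alt_aa,
         protein_change_equivalent = isTRUE(protein_change_equivalent),
         classification = classification,
         independent_report_count = as.integer(independent_report_count)),
    class = "prior_variant"
  )
}

#' Construct an in-silico score set
#'
#' @param revel Missense meta-predictor score in `[0, 1]`, or `NA`.
#' @param spliceai_delta Splice-impact delta score in `[0, 1]`, or `NA`.
#' @param gerp Nucleotide conservation score, or `NA`.
#' @return An object of class `insilico_scores`.
#' @export
insilico_scores <- function(revel = NA_real_, spliceai_delta = NA_real_,
                            gerp = NA_real_) {
  if (!is.na(revel) && (revel < 0 || revel > 1)) stop("revel must lie in [0, 1]")
  if (!is.na(spliceai_delta) && (spliceai_delta < 0 || spliceai_delta > 1)) {
    stop("spliceai_delta must lie in [0, 1]")
  }
  structure(list(revel = revel, spliceai_delta = spliceai_delta, gerp = gerp),
            class = "insilico_scores")
}

#' Default loss-of-function decision table
#'
#' The decision table that modulates PVS1 strength, keyed on consequence
#' and the NMD/region context flags.  `NA` in a key column is a wildcard;
#' the first matching row wins.  The shipped default assigns very strong to
#' NMD-predicted truncating variants, strong to NMD-escaping truncations of
#' a critical region, moderate otherwise, and moderate to initiation-codon
#' variants; in-frame exon skipping is weighted by region criticality.  A
#' user-edited CSV with the same columns may be supplied instead.
#'
#' @param path Optional path to a CSV replacing the built-in table.
#' @return A data frame with columns `consequence`, `nmd_predicted`,
#'   `affected_region_critical`, `exon_skip_inframe`, `strength`, `tag`.
#' @export
pvs1_decision_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pvs1_decision_table.csv",
                        package = "acmgrules", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(consequence = "character",
                                        nmd_predicted = "logical",
                                        last_exon_or_50nt_rule = "logical",
                                        affected_region_critical = "logical",
                                        exon_skip_inframe = "logical",
                                        strength = "character",
                                        tag = "character"))
  stopifnot(all(tab$strength %in% strength_levels | is.na(tab$strength)))
  tab
}

#' Evaluate PVS1 (null variant, loss-of-function mechanism)
#'
#' PVS1 applies only to null variants (nonsense, frameshift, canonical
#' splice site, initiation codon, single/multi-exon deletion) in genes
#' where loss of function is the established disease mechanism.  The
#' mechanism counts as established when curated as such, or - absent
#' curation - when `pli > 0.9` or `o_e < 0.35`.  Strength is modulated by
#' the loss-of-function decision table.
#'
#' @param v A [variant_descriptor()].
#' @param gene A [gene_context()].
#' @param table Decision table from [pvs1_decision_table()].
#' @return A PVS1 [criterion_call()], an unapplied call (mechanism not
#'   established), or `NULL` for non-null variants.
#' @export
evaluate_pvs1 <- function(v, gene, table = pvs1_decision_table()) {
  if (!(v$consequence %in% null_consequences)) return(NULL)
  established <- gene$lof_mechanism == "established" ||
    (gene$lof_mechanism == "unknown" &&
       ((!is.na(gene$pli) && gene$pli > 0.9) ||
          (!is.na(gene$o_e) && gene$o_e < 0.35)))
  if (!established) {
    return(unapplied_call("PVS1", paste(
      "[PVS1.lof_not_established] loss of function is not an established",
      "disease mechanism for", gene$symbol)))
  }
  if (v$consequence %in% c("nonsense", "frameshift", "canonical_splice",
                           "single_multi_exon_deletion")) {
    needs_nmd <- !(v$consequence == "canonical_splice" &&
                     isTRUE(v$exon_skip_inframe))
    if (needs_nmd && is.na(v$nmd_predicted)) {
      stop("validation error: null variant of consequence '", v$consequence,
           "' requires the nmd_predicted field")
    }
  }
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (row$consequence != v$consequence) next
    if (!is.na(row$nmd_predicted) &&
        !identical(row$nmd_predicted, isTRUE(v$nmd_predicted))) next
    if (!is.na(row$last_exon_or_50nt_rule) &&
        !identical(row$last_exon_or_50nt_rule,
                   isTRUE(v$last_exon_or_50nt_rule))) next
    if (!is.na(row$affected_region_critical) &&
        !identical(row$affected_region_critical,
                   isTRUE(v$affected_region_critical))) next
    if (!is.na(row$exon_skip_inframe) &&
        !identical(row$exon_skip_inframe, isTRUE(v$exon_skip_inframe))) next
    return(criterion_call("PVS1", row$strength, rationale = sprintf(
      "[%s] decision-table row %d for %s", row$tag, i, v$consequence)))
  }
  NULL
}

# Aggregate prior-variant report counts for one matching subset.
prior_counts <- function(known, keep) {
  kept <- Filter(keep, known)
  path <- sum(vapply(kept, function(k) {
    if (k$classification == "pathogenic") k$independent_report_count else 0L
  }, numeric(1)))
  lp <- sum(vapply(kept, function(k) {
    if (k$classification == "likely_pathogenic") k$independent_report_count else 0L
  }, numeric(1)))
  list(path = path, lp = lp)
}

#' Evaluate PS1 / PM5 (previously classified changes at the same residue)
#'
#' PS1 covers the equivalent protein change (same amino-acid substitution,
#' any nucleotide change); PM5 covers a different missense change at the
#' same codon.  Both require the pathogenic mechanism to act through the
#' missense effect, so they are suppressed whenever a deleterious splicing
#' prediction (SpliceAI delta >= 0.8) or functional evidence of aberrant
#' splicing is present.  PS1 and PM5 are mutually exclusive; PS1 pre-empts.
#'
#' @param v A missense [variant_descriptor()].
#' @param known List of [prior_variant()] records at the same codon.
#' @param scores An [insilico_scores()].
#' @return One of PS1_S, PS1_M, PM5_M, PM5_P as a [criterion_call()], an
#'   unapplied call when the splice caution suppresses, or `NULL`.
#' @export
evaluate_ps1_pm5 <- function(v, known = list(), scores = insilico_scores()) {
  if (v$consequence != "missense") return(NULL)
  if (length(known) == 0) return(NULL)
  if ((!is.na(scores$spliceai_delta) && scores$spliceai_delta >= 0.8) ||
      isTRUE(v$splicing_functional_aberrant)) {
    return(unapplied_call("PS1", paste(
      "[PS1PM5.splice_suppressed] suppressed: predicted or demonstrated",
      "aberrant splicing makes a pure missense mechanism uncertain")))
  }
  eq <- prior_counts(known, function(k) k$protein_change_equivalent)
  if (eq$path >= 1) {
    return(criterion_call("PS1", "S", rationale =
      "[PS1.s_path] equivalent missense change pathogenic in at least one prior report"))
  }
  if (eq$lp >= 2) {
    return(criterion_call("PS1", "S", rationale =
      "[PS1.s_lp2] equivalent missense change likely pathogenic in two or more independent reports"))
  }
  if (eq$lp == 1) {
    return(criterion_call("PS1", "M", rationale =
      "[PS1.m_lp1] equivalent missense change likely pathogenic in a single prior report"))
  }
  other <- prior_counts(known, function(k) {
    !k$protein_change_equivalent &&
      !is.na(k$codon_index) && !is.na(v$codon_index) &&
      k$codon_index == v$codon_index
  })
  if (other$path >= 1) {
    return(criterion_call("PM5", "M", rationale =
      "[PM5.m_path] different missense change at this codon pathogenic in at least one prior report"))
  }
  if (other$lp >= 2) {
    return(criterion_call("PM5", "M", rationale =
      "[PM5.m_lp2] different missense change at this codon likely pathogenic in two or more independent reports"))
  }
  if (other$lp == 1) {
    return(criterion_call("PM5", "P", rationale =
      "[PM5.p_lp1] different missense change at this codon likely pathogenic in a single prior report"))
  }
  NULL
}

#' Evaluate PM1 (mutational hotspot / critical functional domain)
#'
#' Strong weight for three curated domain classes (cysteine-parity-altering
#' substitutions in EGF-like repeats of NOTCH3, glycine substitutions in
#' collagen genes, Cys/His substitutions in C2H4 zinc fingers); moderate
#' weight for residues under regional missense constraint < 0.4 or inside
#' a configured literature hotspot interval.
#'
#' @param v A missense [variant_descriptor()].
#' @param gene A [gene_context()].
#' @param hotspots Optional data frame with columns `gene`, `start`, `end`
#'   (codon intervals curated from the literature).
#' @return A PM1 [criterion_call()] or `NULL`.
#' @export
evaluate_pm1 <- function(v, gene, hotspots = NULL) {
  if (v$consequence != "missense") return(NULL)
  if (gene$special_domain_class == "notch3_egf" &&
      isTRUE(v$cysteine_parity_change)) {
    return(criterion_call("PM1", "S", rationale =
      "[PM1.notch3] substitution alters the cysteine count of an EGF-like repeat"))
  }
  if (gene$special_domain_class == "collagen_glycine" &&
      !is.na(v$ref_aa) && v$ref_aa == "G") {
    return(criterion_call("PM1", "S", rationale =
      "[PM1.collagen] glycine substitution in a collagen gene"))
  }
  if (gene$special_domain_class == "c2h4_zinc_finger" &&
      !is.na(v$ref_aa) && v$ref_aa %in% c("C", "H")) {
    return(criterion_call("PM1", "S", rationale =
      "[PM1.zinc_finger] cysteine/histidine substitution in a C2H4 zinc finger"))
  }
  if (!is.na(gene$decipher_missense_constraint) &&
      gene$decipher_missense_constraint < 0.4) {
    return(criterion_call("PM1", "M", rationale = sprintf(
      "[PM1.decipher] regional missense constraint %.2f < 0.4",
      gene$decipher_missense_constraint)))
  }
  if (!is.null(hotspots) && !is.na(v$codon_index)) {
    hit <- hotspots$gene == gene$symbol &
      hotspots$start <= v$codon_index & v$codon_index <= hotspots$end
    if (any(hit)) {
      return(criterion_call("PM1", "M", rationale =
        "[PM1.hotspot] codon inside a curated literature hotspot interval"))
    }
  }
  NULL
}

#' Evaluate PM4 (protein-length change)
#'
#' In-frame indels in non-repeat regions and stop-loss variants, applied
#' only to variants rare enough to hold a PM2 call at either level.
#' Insertions/deletions of 1-2 residues carry supporting weight; 3 or more
#' residues - and stop-loss variants, which extend the protein - carry
#' moderate weight.  Repeat regions (more than 3 identical units) are
#' excluded.
#'
#' @param v A [variant_descriptor()].
#' @param pm2_call The frequency-module call (or `NULL`).
#' @return A PM4 [criterion_call()], an unapplied call when blocked, or
#'   `NULL` for other consequences.
#' @export
evaluate_pm4 <- function(v, pm2_call = NULL) {
  if (!(v$consequence %in% c("inframe_indel", "stop_loss"))) return(NULL)
  if (isTRUE(v$in_repeat_region)) {
    return(unapplied_call("PM4",
      "[PM4.repeat_skip] repetitive region (> 3 identical sequence units)"))
  }
  pm2_met <- !is.null(pm2_call) && pm2_call$applied &&
    pm2_call$criterion == "PM2"
  if (!pm2_met) {
    return(unapplied_call("PM4",
      "[PM4.no_pm2] requires the variant to meet the rarity criterion at either level"))
  }
  if (v$consequence == "stop_loss") {
    return(criterion_call("PM4", "M", rationale =
      "[PM4.stoploss] stop-loss variant extends the protein"))
  }
  if (v$indel_aa_length <= 2) {
    criterion_call("PM4", "P", rationale = sprintf(
      "[PM4.indel_small] in-frame change of %d amino acid(s)", v$indel_aa_length))
  } else {
    criterion_call("PM4", "M", rationale = sprintf(
      "[PM4.indel_large] in-frame change of %d amino acids", v$indel_aa_length))
  }
}

#' Evaluate PP2 (constrained missense region)
#'
#' Supporting weight for missense variants in genes with at least three
#' previously reported pathogenic missense variants and a regional missense
#' constraint Z score above 3.09.
#'
#' @param v A [variant_descriptor()].
#' @param gene A [gene_context()].
#' @return A PP2 [criterion_call()] or `NULL`.
#' @export
evaluate_pp2 <- function(v, gene) {
  if (v$consequence != "missense") return(NULL)
  if (gene$pathogenic_missense_count >= 3 &&
      !is.na(gene$missense_constraint_z) && gene$missense_constraint_z > 3.09) {
    return(criterion_call("PP2", "P", rationale = sprintf(
      "[PP2.constraint] %d pathogenic missense variants reported and constraint Z %.2f > 3.09",
      gene$pathogenic_missense_count, gene$missense_constraint_z)))
  }
  NULL
}

#' Evaluate BP7 (silent variant without splice impact or conservation)
#'
#' Supporting benign weight for synonymous variants with a SpliceAI delta
#' score of at most 0.2 and a negative conservation score.
#'
#' @param v A [variant_descriptor()].
#' @param scores An [insilico_scores()].
#' @return A BP7 [criterion_call()], an unapplied call when a score is
#'   missing, or `NULL`.
#' @export
evaluate_bp7 <- function(v, scores) {
  if (v$consequence != "synonymous") return(NULL)
  if (is.na(scores$spliceai_delta) || is.na(scores$gerp)) {
    return(unapplied_call("BP7",
      "[BP7.missing_scores] splice or conservation score unavailable"))
  }
  if (scores$spliceai_delta <= 0.2 && scores$gerp < 0) {
    return(criterion_call("BP7", "P", rationale = sprintf(
      "[BP7.synonymous] SpliceAI delta %.2f <= 0.2 and conservation %.2f < 0",
      scores$spliceai_delta, scores$gerp)))
  }
  NULL
}
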