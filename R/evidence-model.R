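# Domain model: gene context, transcripts, gene gating and transcript
# prioritisation.

inheritance_modes <- c("AD", "AR", "AD_AR", "XL", "XLR", "XLD")
validity_levels <- c("definitive", "strong", "moderate", "limited",
                     "disputed", "refuted", "none")
classifiable_validities <- c("limited", "moderate", "strong", "definitive")
special_domain_classes <- c("notch3_egf", "collagen_glycine",
                            "c2h4_zinc_finger", "none")
lof_mechanism_levels <- c("established", "not_established", "unknown")

# Does the inheritance mode include a recessive component?  AD_AR genes are
# grouped with AR wherever the thresholds distinguish AD from
# "AR, AD/AR or XL".
includes_recessive <- function(inheritance) {
  inheritance %in% c("AR", "AD_AR", "XLR")
}

# Dominant side used by proband counting: AD, AD_AR (on its AD side) and XLD.
includes_dominant <- function(inheritance) {
  inheritance %in% c("AD", "AD_AR", "XLD")
}

# Frequency-threshold grouping: AD row vs the "AR, AD/AR or XL" row.  XLR
# and XLD are refinements of XL and use the XL grouping.
frequency_group <- function(inheritance) {
  if (inheritance == "AD") "AD" else "AR_XL"
}

#' Construct a gene context
#'
#' Per-gene facts that parameterise every criterion: inheritance mode, gene
#' category (cancer vs general), clinical validity of the gene-disease
#' association, loss-of-function mechanism with its constraint metrics,
#' missense constraint, special-domain membership, and the boolean
#' penetrance/onset flags used by the case-level criteria.  Per-gene
#' frequency and in-silico threshold overrides stand in for gene-specific
#' curated recommendations.
#'
#' @param symbol Gene symbol.
#' @param inheritance One of `"AD"`, `"AR"`, `"AD_AR"`, `"XL"`, `"XLR"`,
#'   `"XLD"`.
#' @param category `"cancer"` or `"general"`.
#' @param clinical_validity Gene-disease validity: `"definitive"`,
#'   `"strong"`, `"moderate"`, `"limited"`, `"disputed"`, `"refuted"`,
#'   `"none"`.
#' @param vcep_curated Logical; `TRUE` when a Variant Curation Expert Panel
#'   owns the gene, in which case the engine delegates rather than applying
#'   its general rules.
#' @param ba1_exception Logical; membership of the stand-alone-frequency
#'   exception list.  Exception genes require explicit frequency overrides.
#' @param lof_mechanism `"established"`, `"not_established"` or `"unknown"`.
#'   When unknown, `pli > 0.9` or `o_e < 0.35` establishes the mechanism.
#' @param pli Probability of loss-of-function intolerance, in `[0, 1]` or `NA`.
#' @param o_e Observed/expected loss-of-function ratio, or `NA`.
#' @param missense_constraint_z Regional missense constraint Z score, or `NA`.
#' @param pathogenic_missense_count Number of previously reported pathogenic
#'   missense variants in the gene.
#' @param decipher_missense_constraint Regional missense-constraint ratio
#'   used by PM1, or `NA`.
#' @param special_domain_class `"notch3_egf"`, `"collagen_glycine"`,
#'   `"c2h4_zinc_finger"` or `"none"`.
#' @param pediatric_green_list Logical; gene associated exclusively with
#'   high-penetrance pediatric-onset dominant disease (severe pediatric
#'   disorders green list).
#' @param high_penetrance_early_onset Logical; used by BS2/BS4.
#' @param complete_penetrance Logical; used by the recessive BS2 clause.
#' @param ad_childhood_onset Logical; AD highly penetrant childhood-onset
#'   disease, used by BP5.
#' @param frequency_overrides Optional list with elements `ba1`, `bs1_s`,
#'   `pm2_p`, `pm2_m` (fractions; `pm2_m = NA` means "absent required").
#' @param insilico_overrides Optional list with elements `revel_pp3`,
#'   `revel_bp4`, `spliceai_pp3`, `spliceai_bp4`.
#' @return An object of class `gene_context`.
#' @export
gene_context <- function(symbol,
                         inheritance,
                         category = "general",
                         clinical_validity = "definitive",
                         vcep_curated = FALSE,
                         ba1_exception = FALSE,
                         lof_mechanism = "unknown",
                         pli = NA_real_,
                         o_e = NA_real_,
                         missense_constraint_z = NA_real_,
                         pathogenic_missense_count = 0L,
                         decipher_missense_constraint = NA_real_,
                         special_domain_class = "none",
                         pediatric_green_list = FALSE,
                         high_penetrance_early_onset = FALSE,
                         complete_penetrance = FALSE,
                         ad_childhood_onset = FALSE,
                         frequency_overrides = NULL,
                         insilico_overrides = NULL) {
  if (missing(symbol) || !is.character(symbol) || !nzchar(symbol)) {
    stop("gene context requires a non-empty 'symbol'")
  }
  if (is.null(clinical_validity) || is.na(clinical_validity)) {
    stop("gene context validation error: missing field 'clinical_validity'")
  }
  clinical_validity <- match.arg(clinical_validity, validity_levels)
  inheritance <- match.arg(inheritance, inheritance_modes)
  category <- match.arg(category, c("general", "cancer"))
  lof_mechanism <- match.arg(lof_mechanism, lof_mechanism_levels)
  special_domain_class <- match.arg(special_domain_class, special_domain_classes)
  if (!is.na(pli) && (pli < 0 || pli > 1)) stop("pli must lie in [0, 1]")
  if (pathogenic_missense_count < 0) {
    stop("pathogenic_missense_count must be nonnegative")
  }
  structure(
    list(symbol = symbol, inheritance = inheritance, category = category,
         clinical_validity = clinical_validity, vcep_curated = isTRUE(vcep_curated),
         ba1_exception = isTRUE(ba1_exception), lof_mechanism = lof_mechanism,
         pli = pli, o_e = o_e,
         missense_constraint_z = missense_constraint_z,
         pathogenic_missense_count = as.integer(pathogenic_missense_count),
         decipher_missense_constraint = decipher_missense_constraint,
         special_domain_class = special_domain_class,
         pediatric_green_list = isTRUE(pediatric_green_list),
         high_penetrance_early_onset = isTRUE(high_penetrance_early_onset),
         complete_penetrance = isTRUE(complete_penetrance),
         ad_childhood_onset = isTRUE(ad_childhood_onset),
         frequency_overrides = frequency_overrides,
         insilico_overrides = insilico_overrides),
    class = "gene_context"
  )
}

#' Gate a gene for classification
#'
#' Classification under the general rules is restricted to genes whose
#' gene-disease clinical validity is at least limited.  Genes curated by a
#' Variant Curation Expert Panel are delegated to that panel's workflow and
#' never classified by the general rules; genes with disputed, refuted or
#' uncurated validity are refused.
#'
#' @param gene A [gene_context()].
#' @return One of `"classifiable"`, `"not_classifiable"`, `"vcep_delegate"`.
#' @export
gate_gene <- function(gene) {
  stopifnot(inherits(gene, "gene_context"))
  if (isTRUE(gene$vcep_curated)) return("vcep_delegate")
  if (gene$clinical_validity %in% classifiable_validities) "classifiable"
  else "not_classifiable"
}

#' Construct a transcript record
#'
#' @param id Transcript identifier.
#' @param flags Subset of `"mane_select"`, `"refseq_select"`,
#'   `"mane_clinical_plus"`, `"refseq"`; at least one required.
#' @param length Transcript length in nucleotides (> 0).
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, flags, length) {
  known <- c("mane_select", "refseq_select", "mane_clinical_plus", "refseq")
  if (length(flags) < 1 || !all(flags %in% known)) {
    stop("transcript flags must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  }
  if (!is.numeric(length) || length <= 0) stop("transcript length must be > 0")
  structure(list(id = id, flags = unique(flags), length = as.integer(length)),
            class = "transcript_record")
}

#' Select the primary transcript
#'
#' Transcript references are prioritised in the order MANE Select, RefSeq
#' Select, MANE Clinical Plus, RefSeq.  When only plain RefSeq transcripts
#' are available the largest transcript is chosen; equal-length ties (and
#' ties within the higher flag tiers) are broken toward the
#' lexicographically smallest identifier so the choice is deterministic.
#'
#' @param transcripts Non-empty list of [transcript_record()] objects.
#' @return The selected `transcript_record`.
#' @export
select_primary_transcript <- function(transcripts) {
  if (length(transcripts) == 0) stop("transcript list must be non-empty")
  stopifnot(all(vapply(transcripts, inherits, logical(1), "transcript_record")))
  priority <- c(mane_select = 1, refseq_select = 2, mane_clinical_plus = 3,
                refseq = 4)
  best <- vapply(transcripts, function(tx) min(priority[tx$flags]), numeric(1))
  cand <- transcripts[best == min(best)]
  if (min(best) == priority[["refseq"]]) {
    lens <- vapply(cand, function(tx) tx$length, numeric(1))
    cand <- cand[lens == max(lens)]
  }
  ids <- vapply(cand, function(tx) tx$id, character(1))
  cand[[order(ids)[1]]]
}
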