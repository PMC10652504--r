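# The per-variant evidence record: the engine's single input object.

#' Construct an evidence record
#'
#' One variant's complete pre-annotated evidence: the gene context, the
#' molecular descriptor, per-population frequencies, previously classified
#' variants at the same residue, in-silico scores, curated functional
#' evidence and the case-level block.  The engine consumes curated
#' evidence; it never queries databases or touches reference genomes.
#'
#' @param id Record identifier (used in reports).
#' @param gene A [gene_context()].
#' @param variant A [variant_descriptor()].
#' @param frequencies List of [frequency_record()]s.
#' @param prior_variants List of [prior_variant()]s.
#' @param insilico An [insilico_scores()].
#' @param functional A [functional_assay()].
#' @param case_data A [case_level_data()].
#' @return An object of class `evidence_record`.
#' @export
evidence_record <- function(id, gene, variant,
                            frequencies = list(),
                            prior_variants = list(),
                            insilico = insilico_scores(),
                            functional = functional_assay(),
                            case_data = case_level_data()) {
  stopifnot(inherits(gene, "gene_context"),
            inherits(variant, "variant_descriptor"),
            inherits(insilico, "insilico_scores"),
            inherits(functional, "functional_assay"),
            inherits(case_data, "case_level_data"))
  stopifnot(all(vapply(frequencies, inherits, logical(1), "frequency_record")))
  stopifnot(all(vapply(prior_variants, inherits, logical(1), "prior_variant")))
  structure(
    list(id = as.character(id), gene = gene, variant = variant,
         frequencies = frequencies, prior_variants = prior_variants,
         insilico = insilico, functional = functional, case_data = case_data),
    class = "evidence_record"
  )
}

#' @export
print.evidence_record <- function(x, ...) {
  cat("<evidence_record>", x$id, "-", x$gene$symbol,
      paste0("(", x$gene$inheritance, ", ", x$gene$category, "), "),
      x$variant$consequence, "\n")
  invisible(x)
}
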