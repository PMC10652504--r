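# Computational and functional criteria: PP3/BP4 from REVEL and SpliceAI
# with per-gene overrides, curated PS3/BS3 pass-through, and the
# discontinued reputable-source criteria.

#' Construct functional-assay evidence
#'
#' Curated outcome of well-established functional studies, with the
#' strength pre-assessed by an assay-validation framework upstream of the
#' engine.
#'
#' @param direction `"damaging"`, `"benign"` or `"none"`.
#' @param strength Strength code; pathogenic direction allows `"P"`, `"M"`,
#'   `"S"`, `"VS"`, benign direction is capped at `"S"`.
#' @param proband_derived Logical; assays performed on the proband's own
#'   material must not support PS3.
#' @return An object of class `functional_assay`.
#' @export
functional_assay <- function(direction = "none", strength = NA_character_,
                             proband_derived = FALSE) {
  direction <- match.arg(direction, c("none", "damaging", "benign"))
  if (direction != "none") {
    if (is.na(strength) || !(strength %in% c("P", "M", "S", "VS"))) {
      stop("functional evidence with direction '", direction,
           "' requires a strength among P, M, S, VS")
    }
    if (direction == "benign" && strength == "VS") {
      stop("validation error: benign functional evidence is capped at strong")
    }
  } else if (!is.na(strength)) {
    stop("strength must be absent when direction is 'none'")
  }
  structure(list(direction = direction, strength = strength,
                 proband_derived = isTRUE(proband_derived)),
            class = "functional_assay")
}

#' Evaluate PP3 / BP4 (computational evidence)
#'
#' Missense variants use the meta-predictor score: supporting pathogenic
#' above 0.7, supporting benign below 0.4, no call inside the `[0.4, 0.7]`
#' band.  Noncoding (non-missense, non-null) variants use the splice delta
#' score: supporting pathogenic at >= 0.8, supporting benign at <= 0.2.
#' Per-gene override thresholds (the stand-in for gene-specific curated
#' recommendations) replace the defaults when configured.  Exclusivity
#' with BP7 is enforced by the classifier.
#'
#' @param v A [variant_descriptor()].
#' @param scores An [insilico_scores()].
#' @param gene A [gene_context()] (consulted for `insilico_overrides`).
#' @return A PP3 or BP4 [criterion_call()], or `NULL`.
#' @export
evaluate_pp3_bp4 <- function(v, scores, gene) {
  ov <- gene$insilico_overrides
  thr <- list(revel_pp3 = 0.7, revel_bp4 = 0.4,
              spliceai_pp3 = 0.8, spliceai_bp4 = 0.2)
  tag_extra <- ""
  if (!is.null(ov)) {
    for (k in names(thr)) if (!is.null(ov[[k]])) thr[[k]] <- ov[[k]]
    tag_extra <- "[PP3BP4.override] "
  }
  if (v$consequence == "missense") {
    if (is.na(scores$revel)) return(NULL)
    if (scores$revel > thr$revel_pp3) {
      return(criterion_call("PP3", "P", rationale = sprintf(
        "%s[PP3.missense] meta-predictor score %.2f > %.2f",
        tag_extra, scores$revel, thr$revel_pp3)))
    }
    if (scores$revel < thr$revel_bp4) {
      return(criterion_call("BP4", "P", rationale = sprintf(
        "%s[BP4.missense] meta-predictor score %.2f < %.2f",
        tag_extra, scores$revel, thr$revel_bp4)))
    }
    return(NULL)
  }
  if (v$consequence %in% null_consequences) return(NULL)
  if (is.na(scores$spliceai_delta)) return(NULL)
  if (scores$spliceai_delta >= thr$spliceai_pp3) {
    return(criterion_call("PP3", "P", rationale = sprintf(
      "%s[PP3.splice] splice delta score %.2f >= %.2f",
      tag_extra, scores$spliceai_delta, thr$spliceai_pp3)))
  }
  if (scores$spliceai_delta <= thr$spliceai_bp4) {
    return(criterion_call("BP4", "P", rationale = sprintf(
      "%s[BP4.splice] splice delta score %.2f <= %.2f",
      tag_extra, scores$spliceai_delta, thr$spliceai_bp4)))
  }
  NULL
}

#' Evaluate PS3 / BS3 (functional evidence pass-through)
#'
#' The curated assay direction and strength pass through unchanged, except
#' that assays derived from the proband's own material are rejected for
#' the damaging direction (patient-derived evidence belongs with the
#' phenotype criterion instead).
#'
#' @param func A [functional_assay()].
#' @return A PS3 or BS3 [criterion_call()], an unapplied call when
#'   proband-derived evidence is rejected, or `NULL`.
#' @export
evaluate_ps3_bs3 <- function(func) {
  if (is.null(func) || func$direction == "none") return(NULL)
  if (func$direction == "damaging") {
    if (func$proband_derived) {
      return(unapplied_call("PS3", paste(
        "[PS3.proband_rejected] proband-derived assay rejected for the",
        "damaging direction; consider the phenotype criterion (PP4)")))
    }
    return(criterion_call("PS3", func$strength, rationale =
      "[PS3.passthrough] curated damaging functional evidence"))
  }
  criterion_call("BS3", func$strength, rationale =
    "[BS3.passthrough] curated benign functional evidence")
}

#' Discontinued reputable-source criteria
#'
#' PP5 and BP6 have been discontinued; they are carried in the audit trail
#' as permanently unapplied calls so every report enumerates all 28
#' criteria.
#'
#' @return List of two unapplied [criterion_call()]s (PP5, BP6).
#' @export
discontinued_criteria <- function() {
  list(
    unapplied_call("PP5", "[PP5.discontinued] criterion discontinued"),
    unapplied_call("BP6", "[BP6.discontinued] criterion discontinued")
  )
}

# Criteria retained in the enumeration but not applied by policy.
unapplied_policy_criteria <- function() {
  list(
    unapplied_call("BP1", paste(
      "[BP1.not_applied] not applied: deleterious effect of rare missense",
      "variants outside functional studies is too uncertain")),
    unapplied_call("BP2", paste(
      "[BP2.not_applied] not applied: rare variants in cis/trans with a",
      "pathogenic variant are not treated as evidence of benignity")),
    unapplied_call("BP3", paste(
      "[BP3.not_applied] not applied routinely: repetitive regions and",
      "critical domains are too poorly defined; curated override available"))
  )
}
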