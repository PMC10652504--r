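# The per-variant pipeline: criterion evaluation, conflict resolution,
# combining rules and posterior, with a 28-criterion audit trail.

#' Evaluate all criteria for one evidence record
#'
#' Runs every criterion module on the record and returns one
#' [criterion_call()] per criterion code (28 entries): applied calls where
#' evidence supports them, unapplied audit entries elsewhere.  Conflict
#' resolution is *not* applied here; see [resolve_conflicts()].
#'
#' @param record An [evidence_record()].
#' @param config An [engine_config()].
#' @return Named list of 28 calls, in the order of [acmg_criteria()].
#' @export
evaluate_criteria <- function(record, config = engine_config()) {
  gene <- record$gene
  v <- record$variant
  scores <- record$insilico
  calls <- list()
  add <- function(x) {
    if (is.null(x)) return()
    if (inherits(x, "criterion_call")) x <- list(x)
    for (cl in x) calls[[cl$criterion]] <<- cl
  }

  freq_call <- evaluate_frequency(record$frequencies, gene, config = config)
  add(freq_call)
  pm2_call <- if (!is.null(freq_call) && freq_call$criterion == "PM2" &&
                  freq_call$applied) freq_call else NULL

  add(evaluate_pvs1(v, gene, table = config$pvs1_table))
  add(evaluate_ps1_pm5(v, record$prior_variants, scores))
  add(evaluate_pm1(v, gene, hotspots = config$hotspots))
  add(evaluate_pm4(v, pm2_call))
  add(evaluate_pp2(v, gene))
  add(evaluate_bp7(v, scores))

  cd <- record$case_data
  add(score_pm3(cd$recessive_obs, gene$inheritance)$call)
  add(score_de_novo(cd$denovo_obs)$calls)
  add(score_pp1(cd$segregating_meioses, gene$inheritance))
  add(evaluate_ps4(cd, gene, pm2_call))
  add(evaluate_bs2(cd, gene))
  add(evaluate_bs4(cd, gene))
  add(evaluate_pp4(cd, pm2_call))
  add(evaluate_bp5(cd, gene))

  add(evaluate_pp3_bp4(v, scores, gene))
  add(evaluate_ps3_bs3(record$functional))
  add(discontinued_criteria())
  add(unapplied_policy_criteria())

  out <- lapply(acmg_criteria(), function(code) {
    if (!is.null(calls[[code]])) calls[[code]]
    else unapplied_call(code, "criterion not met")
  })
  names(out) <- acmg_criteria()
  out
}

#' Classify a batch of evidence records
#'
#' The end-to-end pipeline: gene gating, criterion evaluation, conflict
#' resolution, the combining rules and the Bayesian posterior, producing
#' one classification per record in input order.  Records whose gene is
#' owned by an expert panel emit a delegation marker; genes failing the
#' validity gate emit a refusal marker; per-record validation errors are
#' captured without aborting the batch.
#'
#' @param records List of [evidence_record()]s.
#' @param config An [engine_config()].
#' @return List of `classification` objects.
#' @export
classify_variants <- function(records, config = engine_config()) {
  lapply(records, function(rec) classify_variant(rec, config))
}

#' Classify a single evidence record
#'
#' @param record An [evidence_record()].
#' @param config An [engine_config()].
#' @return An object of class `classification` with fields `id`, `status`
#'   (`"classified"`, `"vcep_delegate"`, `"not_classifiable"` or
#'   `"error"`), `tier` (rule-based five-tier call), `matched_rule`,
#'   `post_p` (full precision), `post_p_reported` (3 decimals),
#'   `posterior_tier`, `prior` and the 28-entry `audit` list.
#' @export
classify_variant <- function(record, config = engine_config()) {
  stopifnot(inherits(record, "evidence_record"))
  gate <- gate_gene(record$gene)
  if (gate != "classifiable") {
    status <- if (gate == "vcep_delegate") "vcep_delegate" else "not_classifiable"
    msg <- if (gate == "vcep_delegate") {
      "gene is curated by an expert panel; its specific workflow supersedes the general rules"
    } else {
      paste0("gene-disease validity '", record$gene$clinical_validity,
             "' is below the classification gate (at least limited required)")
    }
    return(structure(
      list(id = record$id, status = status, tier = NA_character_,
           matched_rule = NA_character_, pathogenic_rules = character(0),
           benign_rules = character(0), post_p = NA_real_,
           post_p_reported = NA_real_, posterior_tier = NA_character_,
           prior = config$prior, note = msg, audit = list()),
      class = "classification"))
  }
  res <- tryCatch({
    calls <- evaluate_criteria(record, config)
    calls <- resolve_conflicts(calls, caution_cap = config$caution_cap)
    rb <- classify_rule_based(calls)
    pp <- compute_posterior(calls, prior = config$prior,
                            ba1_points = config$ba1_points)
    structure(
      list(id = record$id, status = "classified", tier = rb$tier,
           matched_rule = rb$matched_rule,
           pathogenic_rules = rb$pathogenic_rules,
           benign_rules = rb$benign_rules,
           post_p = pp, post_p_reported = round(pp, 3),
           posterior_tier = posterior_category(round(pp, 3),
                                               config$posterior_bounds),
           prior = config$prior, note = NA_character_, audit = calls),
      class = "classification")
  }, error = function(e) {
    structure(
      list(id = record$id, status = "error", tier = NA_character_,
           matched_rule = NA_character_, pathogenic_rules = character(0),
           benign_rules = character(0), post_p = NA_real_,
           post_p_reported = NA_real_, posterior_tier = NA_character_,
           prior = config$prior, note = conditionMessage(e), audit = list()),
      class = "classification")
  })
  res
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification>", x$id, "-", x$status, "\n")
  if (x$status == "classified") {
    cat("  tier:", x$tier,
        if (!is.na(x$matched_rule)) paste0("(rule ", x$matched_rule, ")") else "",
        "\n  Post_P:", format(x$post_p_reported, nsmall = 3),
        paste0("(", x$posterior_tier, " range, prior ", x$prior, ")"), "\n")
    lab <- call_labels(x$audit)
    if (length(lab) > 0) cat("  applied:", paste(lab, collapse = ", "), "\n")
  } else if (!is.na(x$note)) {
    cat(" ", x$note, "\n")
  }
  invisible(x)
}
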