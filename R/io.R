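# Readers and writers: nested JSON, flat TSV and minimally annotated VCF
# encodings of the evidence record, plus the report writers.

# ---- JSON (nested) ---------------------------------------------------------

drop_null <- function(x) Filter(Negate(is.null), x)

na_or <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NULL else x

evidence_to_list <- function(rec) {
  g <- rec$gene
  v <- rec$variant
  list(
    id = rec$id,
    gene = drop_null(list(
      symbol = g$symbol, inheritance = g$inheritance, category = g$category,
      clinical_validity = g$clinical_validity, vcep_curated = g$vcep_curated,
      ba1_exception = g$ba1_exception, lof_mechanism = g$lof_mechanism,
      pli = na_or(g$pli), o_e = na_or(g$o_e),
      missense_constraint_z = na_or(g$missense_constraint_z),
      pathogenic_missense_count = g$pathogenic_missense_count,
      decipher_missense_constraint = na_or(g$decipher_missense_constraint),
      special_domain_class = g$special_domain_class,
      pediatric_green_list = g$pediatric_green_list,
      high_penetrance_early_onset = g$high_penetrance_early_onset,
      complete_penetrance = g$complete_penetrance,
      ad_childhood_onset = g$ad_childhood_onset,
      frequency_overrides = g$frequency_overrides,
      insilico_overrides = g$insilico_overrides)),
    variant = drop_null(list(
      consequence = v$consequence, codon_index = na_or(v$codon_index),
      ref_aa = na_or(v$ref_aa), alt_aa = na_or(v$alt_aa),
      indel_aa_length = v$indel_aa_length,
      in_repeat_region = v$in_repeat_region,
      nmd_predicted = na_or(v$nmd_predicted),
      last_exon_or_50nt_rule = na_or(v$last_exon_or_50nt_rule),
      affected_region_critical = na_or(v$affected_region_critical),
      exon_skip_inframe = na_or(v$exon_skip_inframe),
      cysteine_parity_change = v$cysteine_parity_change,
      splicing_functional_aberrant = v$splicing_functional_aberrant)),
    frequencies = lapply(rec$frequencies, function(f) {
      list(population = f$population, allele_count = f$allele_count,
           allele_number = f$allele_number, founder_effect = f$founder_effect)
    }),
    prior_variants = lapply(rec$prior_variants, function(k) {
      list(codon_index = k$codon_index, alt_aa = k$alt_aa,
           protein_change_equivalent = k$protein_change_equivalent,
           classification = k$classification,
           independent_report_count = k$independent_report_count)
    }),
    insilico = drop_null(list(revel = na_or(rec$insilico$revel),
                              spliceai_delta = na_or(rec$insilico$spliceai_delta),
                              gerp = na_or(rec$insilico$gerp))),
    functional = drop_null(list(direction = rec$functional$direction,
                                strength = na_or(rec$functional$strength),
                                proband_derived = rec$functional$proband_derived)),
    case_data = {
      cd <- rec$case_data
      drop_null(list(
        recessive_obs = lapply(cd$recessive_obs, function(o)
          list(phase = o$phase, consanguineous = o$consanguineous)),
        denovo_obs = lapply(cd$denovo_obs, function(o)
          list(confirmed = o$confirmed, phenotype_match = o$phenotype_match)),
        segregating_meioses = cd$segregating_meioses,
        nonsegregation_observed = cd$nonsegregation_observed,
        proband_count = cd$proband_count,
        case_control = cd$case_control,
        founder_variant = cd$founder_variant,
        vcep_pathogenic = cd$vcep_pathogenic,
        healthy_carrier_counts = cd$healthy_carrier_counts,
        phenotype_specific_single_etiology = cd$phenotype_specific_single_etiology,
        comprehensive_test = cd$comprehensive_test,
        family_history_consistent = cd$family_history_consistent,
        pathognomonic_extra_evidence = cd$pathognomonic_extra_evidence,
        alternate_molecular_cause = cd$alternate_molecular_cause,
        variant_noncontributory = cd$variant_noncontributory,
        in_house_positive_genotype_no_phenotype =
          cd$in_house_positive_genotype_no_phenotype))
    }
  )
}

pluck <- function(x, name, default = NULL) {
  if (is.null(x[[name]])) default else x[[name]]
}

evidence_from_list <- function(x, where = "record") {
  id <- pluck(x, "id", "unnamed")
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("validation error in ", where, " '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  g <- x$gene
  if (is.null(g)) stop("validation error in ", where, " '", id,
                       "': missing field 'gene'", call. = FALSE)
  gene <- wrap(do.call(gene_context, drop_null(g)))
  v <- x$variant
  if (is.null(v)) stop("validation error in ", where, " '", id,
                       "': missing field 'variant'", call. = FALSE)
  variant <- wrap(do.call(variant_descriptor, drop_null(v)))
  freqs <- wrap(lapply(pluck(x, "frequencies", list()), function(f)
    do.call(frequency_record, drop_null(f))))
  priors <- wrap(lapply(pluck(x, "prior_variants", list()), function(k)
    do.call(prior_variant, drop_null(k))))
  scores <- wrap(do.call(insilico_scores, drop_null(pluck(x, "insilico", list()))))
  fn <- drop_null(pluck(x, "functional", list()))
  if (is.null(fn$strength)) fn$strength <- NA_character_
  functional <- wrap(do.call(functional_assay, fn))
  cd <- drop_null(pluck(x, "case_data", list()))
  if (!is.null(cd$recessive_obs)) {
    cd$recessive_obs <- lapply(cd$recessive_obs, function(o)
      do.call(recessive_obs, drop_null(o)))
  }
  if (!is.null(cd$denovo_obs)) {
    cd$denovo_obs <- lapply(cd$denovo_obs, function(o)
      do.call(denovo_obs, drop_null(o)))
  }
  case_data <- wrap(do.call(case_level_data, cd))
  evidence_record(id = id, gene = gene, variant = variant,
                  frequencies = freqs, prior_variants = priors,
                  insilico = scores, functional = functional,
                  case_data = case_data)
}

#' Write evidence records to JSON
#'
#' @param records List of [evidence_record()]s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evidence <- function(records, path) {
  jsonlite::write_json(lapply(records, evidence_to_list), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# ---- TSV (flat) ------------------------------------------------------------

tsv_columns <- c(
  "id", "gene_symbol", "inheritance", "category", "clinical_validity",
  "vcep_curated", "ba1_exception", "lof_mechanism", "pli", "o_e",
  "missense_constraint_z", "pathogenic_missense_count",
  "decipher_missense_constraint", "special_domain_class",
  "pediatric_green_list", "high_penetrance_early_onset",
  "complete_penetrance", "ad_childhood_onset",
  "consequence", "codon_index", "ref_aa", "alt_aa", "indel_aa_length",
  "in_repeat_region", "nmd_predicted", "last_exon_or_50nt_rule",
  "affected_region_critical", "exon_skip_inframe", "cysteine_parity_change",
  "splicing_functional_aberrant",
  "frequencies", "prior_variants",
  "revel", "spliceai_delta", "gerp",
  "functional_direction", "functional_strength", "functional_proband_derived",
  "recessive_obs", "denovo_obs", "segregating_meioses",
  "nonsegregation_observed", "proband_count", "odds_ratio", "ci_low",
  "founder_variant", "vcep_pathogenic", "carriers_het", "carriers_hom",
  "carriers_hemi", "phenotype_specific_single_etiology",
  "comprehensive_test", "family_history_consistent",
  "pathognomonic_extra_evidence", "alternate_molecular_cause",
  "variant_noncontributory", "in_house_positive_genotype_no_phenotype"
)

enc_bool <- function(x) if (is.null(x) || is.na(x)) "." else if (isTRUE(x)) "1" else "0"
enc_num <- function(x) if (is.null(x) || is.na(x)) "." else format(x, digits = 15)
enc_chr <- function(x) if (is.null(x) || is.na(x) || !nzchar(x)) "." else x

dec_bool <- function(x) if (x == ".") NA else x %in% c("1", "TRUE", "true")
dec_num <- function(x) if (x == ".") NA_real_ else as.numeric(x)
dec_chr <- function(x) if (x == ".") NA_character_ else x

phase_tokens <- c(in_trans = "in_trans_with_PLP", unknown = "phase_unknown",
                  hom = "homozygous")

evidence_to_row <- function(rec, sep = ";") {
  g <- rec$gene; v <- rec$variant; cd <- rec$case_data
  enc_freqs <- paste(vapply(rec$frequencies, function(f) {
    paste(f$population, f$allele_count, f$allele_number,
          as.integer(f$founder_effect), sep = ":")
  }, character(1)), collapse = sep)
  enc_priors <- paste(vapply(rec$prior_variants, function(k) {
    paste(k$codon_index, k$alt_aa, as.integer(k$protein_change_equivalent),
          if (k$classification == "pathogenic") "P" else "LP",
          k$independent_report_count, sep = ":")
  }, character(1)), collapse = sep)
  enc_rec_obs <- paste(vapply(cd$recessive_obs, function(o) {
    if (o$phase == "homozygous" && o$consanguineous) "hom_consang"
    else names(phase_tokens)[match(o$phase, phase_tokens)]
  }, character(1)), collapse = sep)
  enc_dn_obs <- paste(vapply(cd$denovo_obs, function(o) {
    paste(if (o$confirmed) "confirmed" else "assumed", o$phenotype_match,
          sep = ":")
  }, character(1)), collapse = sep)
  vals <- c(
    rec$id, g$symbol, g$inheritance, g$category, g$clinical_validity,
    enc_bool(g$vcep_curated), enc_bool(g$ba1_exception), g$lof_mechanism,
    enc_num(g$pli), enc_num(g$o_e), enc_num(g$missense_constraint_z),
    enc_num(g$pathogenic_missense_count),
    enc_num(g$decipher_missense_constraint), g$special_domain_class,
    enc_bool(g$pediatric_green_list), enc_bool(g$high_penetrance_early_onset),
    enc_bool(g$complete_penetrance), enc_bool(g$ad_childhood_onset),
    v$consequence, enc_num(v$codon_index), enc_chr(v$ref_aa),
    enc_chr(v$alt_aa), enc_num(v$indel_aa_length),
    enc_bool(v$in_repeat_region), enc_bool(v$nmd_predicted),
    enc_bool(v$last_exon_or_50nt_rule), enc_bool(v$affected_region_critical),
    enc_bool(v$exon_skip_inframe), enc_bool(v$cysteine_parity_change),
    enc_bool(v$splicing_functional_aberrant),
    enc_chr(enc_freqs), enc_chr(enc_priors),
    enc_num(rec$insilico$revel), enc_num(rec$insilico$spliceai_delta),
    enc_num(rec$insilico$gerp),
    rec$functional$direction, enc_chr(rec$functional$strength),
    enc_bool(rec$functional$proband_derived),
    enc_chr(enc_rec_obs), enc_chr(enc_dn_obs),
    enc_num(cd$segregating_meioses), enc_bool(cd$nonsegregation_observed),
    enc_num(cd$proband_count),
    enc_num(if (is.null(cd$case_control)) NA else cd$case_control$odds_ratio),
    enc_num(if (is.null(cd$case_control)) NA else cd$case_control$ci_low),
    enc_bool(cd$founder_variant), enc_bool(cd$vcep_pathogenic),
    enc_num(cd$healthy_carrier_counts$het),
    enc_num(cd$healthy_carrier_counts$hom),
    enc_num(cd$healthy_carrier_counts$hemi),
    enc_bool(cd$phenotype_specific_single_etiology),
    enc_bool(cd$comprehensive_test), enc_bool(cd$family_history_consistent),
    enc_bool(cd$pathognomonic_extra_evidence),
    enc_bool(cd$alternate_molecular_cause),
    enc_bool(cd$variant_noncontributory),
    enc_bool(cd$in_house_positive_genotype_no_phenotype)
  )
  stats::setNames(vals, tsv_columns)
}

split_entries <- function(x, sep) {
  if (is.na(x) || x == ".") character(0) else strsplit(x, sep, fixed = TRUE)[[1]]
}

row_to_evidence <- function(row, where = "row", sep = ";") {
  get <- function(k) if (k %in% names(row)) row[[k]] else "."
  id <- get("id")
  freqs <- lapply(split_entries(get("frequencies"), sep), function(e) {
    p <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(p) < 3) stop("validation error in ", where, " '", id,
                            "': malformed frequency entry '", e, "'")
    frequency_record(p[1], as.numeric(p[2]), as.numeric(p[3]),
                     length(p) >= 4 && p[4] == "1")
  })
  priors <- lapply(split_entries(get("prior_variants"), sep), function(e) {
    p <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(p) < 5) stop("validation error in ", where, " '", id,
                            "': malformed prior-variant entry '", e, "'")
    prior_variant(as.integer(p[1]), p[2], p[3] == "1",
                  if (p[4] == "P") "pathogenic" else "likely_pathogenic",
                  as.integer(p[5]))
  })
  rec_obs <- lapply(split_entries(get("recessive_obs"), sep), function(e) {
    if (e == "hom_consang") recessive_obs("homozygous", consanguineous = TRUE)
    else if (e %in% names(phase_tokens)) recessive_obs(phase_tokens[[e]])
    else stop("validation error in ", where, " '", id,
              "': unknown recessive-observation token '", e, "'")
  })
  dn_obs <- lapply(split_entries(get("denovo_obs"), sep), function(e) {
    p <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(p) != 2 || !(p[1] %in% c("confirmed", "assumed"))) {
      stop("validation error in ", where, " '", id,
           "': malformed de novo observation '", e, "'")
    }
    denovo_obs(p[1] == "confirmed", p[2])
  })
  orr <- dec_num(get("odds_ratio"))
  cc <- if (is.na(orr)) NULL else list(odds_ratio = orr,
                                       ci_low = dec_num(get("ci_low")))
  b <- function(k, default = FALSE) {
    val <- dec_bool(get(k)); if (is.na(val)) default else val
  }
  nb <- function(k) { val <- dec_bool(get(k)); if (is.na(val)) NA else val }
  n0 <- function(k) { val <- dec_num(get(k)); if (is.na(val)) 0L else val }
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("validation error in ", where, " '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  gene <- wrap(gene_context(
    symbol = get("gene_symbol"), inheritance = get("inheritance"),
    category = get("category"), clinical_validity = get("clinical_validity"),
    vcep_curated = b("vcep_curated"), ba1_exception = b("ba1_exception"),
    lof_mechanism = if (get("lof_mechanism") == ".") "unknown" else get("lof_mechanism"),
    pli = dec_num(get("pli")), o_e = dec_num(get("o_e")),
    missense_constraint_z = dec_num(get("missense_constraint_z")),
    pathogenic_missense_count = n0("pathogenic_missense_count"),
    decipher_missense_constraint = dec_num(get("decipher_missense_constraint")),
    special_domain_class = if (get("special_domain_class") == ".") "none"
      else get("special_domain_class"),
    pediatric_green_list = b("pediatric_green_list"),
    high_penetrance_early_onset = b("high_penetrance_early_onset"),
    complete_penetrance = b("complete_penetrance"),
    ad_childhood_onset = b("ad_childhood_onset")))
  variant <- wrap(variant_descriptor(
    consequence = get("consequence"),
    codon_index = { ci <- dec_num(get("codon_index"))
                    if (is.na(ci)) NA_integer_ else as.integer(ci) },
    ref_aa = dec_chr(get("ref_aa")), alt_aa = dec_chr(get("alt_aa")),
    indel_aa_length = n0("indel_aa_length"),
    in_repeat_region = b("in_repeat_region"),
    nmd_predicted = nb("nmd_predicted"),
    last_exon_or_50nt_rule = nb("last_exon_or_50nt_rule"),
    affected_region_critical = nb("affected_region_critical"),
    exon_skip_inframe = nb("exon_skip_inframe"),
    cysteine_parity_change = b("cysteine_parity_change"),
    splicing_functional_aberrant = b("splicing_functional_aberrant")))
  functional <- wrap(functional_assay(
    direction = if (get("functional_direction") == ".") "none"
      else get("functional_direction"),
    strength = dec_chr(get("functional_strength")),
    proband_derived = b("functional_proband_derived")))
  case_data <- wrap(case_level_data(
    recessive_obs = rec_obs, denovo_obs = dn_obs,
    segregating_meioses = n0("segregating_meioses"),
    nonsegregation_observed = b("nonsegregation_observed"),
    proband_count = n0("proband_count"), case_control = cc,
    founder_variant = b("founder_variant"),
    vcep_pathogenic = b("vcep_pathogenic"),
    healthy_carrier_counts = list(het = n0("carriers_het"),
                                  hom = n0("carriers_hom"),
                                  hemi = n0("carriers_hemi")),
    phenotype_specific_single_etiology = b("phenotype_specific_single_etiology"),
    comprehensive_test = b("comprehensive_test"),
    family_history_consistent = b("family_history_consistent"),
    pathognomonic_extra_evidence = b("pathognomonic_extra_evidence"),
    alternate_molecular_cause = b("alternate_molecular_cause"),
    variant_noncontributory = b("variant_noncontributory"),
    in_house_positive_genotype_no_phenotype =
      b("in_house_positive_genotype_no_phenotype")))
  evidence_record(
    id = id, gene = gene, variant = variant, frequencies = freqs,
    prior_variants = priors,
    insilico = wrap(insilico_scores(dec_num(get("revel")),
                                    dec_num(get("spliceai_delta")),
                                    dec_num(get("gerp")))),
    functional = functional, case_data = case_data)
}

#' Write evidence records to TSV
#'
#' Tab-separated, UTF-8, header row, `"."` for missing values; list-valued
#' fields use compact `:`-delimited entries joined with `;`.
#'
#' @param records List of [evidence_record()]s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evidence_tsv <- function(records, path) {
  rows <- vapply(records, function(r) paste(evidence_to_row(r), collapse = "\t"),
                 character(1))
  writeLines(c(paste(tsv_columns, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

# ---- VCF (optional) --------------------------------------------------------

# INFO keys mirror the TSV columns (uppercased); list-valued fields join
# entries with "|" because ";" and "," are reserved in INFO.
read_evidence_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF evidence requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  n <- nrow(info)
  ids <- rownames(info)
  lapply(seq_len(n), function(i) {
    row <- stats::setNames(rep(".", length(tsv_columns)), tsv_columns)
    row[["id"]] <- if (!is.null(ids)) ids[i] else paste0("vcf_", i)
    for (col in tsv_columns) {
      key <- toupper(col)
      if (!(key %in% colnames(info))) next
      val <- info[[key]][i]
      if (is.list(val)) val <- unlist(val)
      if (length(val) == 0 || all(is.na(val))) next
      row[[col]] <- paste(as.character(val), collapse = "|")
    }
    row_to_evidence(as.list(row), where = paste0("VCF record ", i), sep = "|")
  })
}

#' Read evidence records
#'
#' Accepts nested JSON (one record or an array), flat TSV with the
#' documented columns, or - optionally - a minimal VCF whose INFO fields
#' carry the flat columns (uppercased, entries joined with `|`).
#' Malformed records are rejected with diagnostics naming the record and
#' offending field.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"json"`, `"tsv"` or `"vcf"`.
#' @return List of [evidence_record()]s.
#' @export
read_evidence <- function(path, format = c("auto", "json", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf"
    else "tsv"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(raw$id) || !is.null(raw$gene)) raw <- list(raw)
    return(lapply(seq_along(raw), function(i) {
      evidence_from_list(raw[[i]], where = paste0("JSON record ", i))
    }))
  }
  if (format == "vcf") return(read_evidence_vcf(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) return(list())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  lapply(seq_along(lines[-1]), function(i) {
    fields <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop("validation error in TSV line ", i + 1, ": expected ",
           length(header), " fields, found ", length(fields))
    }
    row_to_evidence(stats::setNames(as.list(fields), header),
                    where = paste0("TSV line ", i + 1))
  })
}

# ---- reports ---------------------------------------------------------------

classification_to_list <- function(cl) {
  list(
    id = cl$id, status = cl$status, tier = na_or(cl$tier),
    matched_rule = na_or(cl$matched_rule),
    pathogenic_rules = as.list(cl$pathogenic_rules),
    benign_rules = as.list(cl$benign_rules),
    post_p = na_or(cl$post_p_reported), prior = cl$prior,
    posterior_tier = na_or(cl$posterior_tier), note = na_or(cl$note),
    audit = lapply(cl$audit, function(x) {
      drop_null(list(criterion = x$criterion, direction = x$direction,
                     strength = na_or(x$strength), applied = x$applied,
                     score = x$score, rationale = x$rationale))
    })
  )
}

#' Write classification reports
#'
#' Writes the JSON audit report (one object per variant with tier, matched
#' rule, posterior, prior and the 28-entry criterion audit) and/or the
#' human-readable TSV summary.  Output is byte-identical across repeated
#' runs on identical input and configuration.
#'
#' @param classifications List of `classification` objects from
#'   [classify_variants()].
#' @param json_path Path for the JSON audit report, or `NULL` to skip.
#' @param tsv_path Path for the TSV summary, or `NULL` to skip.
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(classifications, json_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(classifications, classification_to_list),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    written <- c(written, json_path)
  }
  if (!is.null(tsv_path)) {
    hdr <- paste(c("id", "status", "tier", "matched_rule", "post_p",
                   "posterior_tier", "prior", "applied_criteria", "note"),
                 collapse = "\t")
    rows <- vapply(classifications, function(cl) {
      lab <- if (length(cl$audit) > 0) paste(call_labels(cl$audit),
                                             collapse = ",") else "."
      paste(c(cl$id, cl$status, enc_chr(cl$tier), enc_chr(cl$matched_rule),
              enc_num(cl$post_p_reported), enc_chr(cl$posterior_tier),
              enc_num(cl$prior), if (nzchar(lab)) lab else ".",
              enc_chr(cl$note)), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), tsv_path, useBytes = TRUE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
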