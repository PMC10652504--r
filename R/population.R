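# Population-frequency criteria: BA1, BS1 and PM2 under gene-category- and
# inheritance-specific allele-frequency thresholds.

#' Construct a per-population frequency record
#'
#' @param population Population label (e.g. `"overall"`, `"AFR"`, `"AMR"`,
#'   `"EAS"`, `"NFE"`, `"SAS"`, `"internal"`).
#' @param allele_count Alternate allele count (>= 0).
#' @param allele_number Total alleles tested (>= allele_count).
#' @param founder_effect Logical; populations with a known founder effect
#'   are ineligible for frequency criteria.
#' @return An object of class `frequency_record`.
#' @export
frequency_record <- function(population, allele_count, allele_number,
                             founder_effect = FALSE) {
  allele_count <- as.numeric(allele_count)
  allele_number <- as.numeric(allele_number)
  if (is.na(allele_count) || allele_count < 0 ||
      is.na(allele_number) || allele_number < 0) {
    stop("allele_count and allele_number must be nonnegative")
  }
  if (allele_count > allele_number) {
    stop("invalid frequency record for population '", population,
         "': allele_count (", allele_count, ") exceeds allele_number (",
         allele_number, ")")
  }
  structure(
    list(population = population, allele_count = allele_count,
         allele_number = allele_number, founder_effect = isTRUE(founder_effect)),
    class = "frequency_record"
  )
}

record_frequency <- function(rec) {
  if (rec$allele_number == 0) return(NA_real_)
  rec$allele_count / rec$allele_number
}

#' Construct a frequency-threshold set
#'
#' Thresholds are exact fractions: `ba1` is the stand-alone benign cut-off,
#' `bs1_s` the strong benign cut-off, and `pm2_p`/`pm2_m` the supporting and
#' moderate rarity cut-offs.  `pm2_m = NA` encodes the "absent from
#' controls" requirement used for dominant conditions.
#'
#' @param ba1,bs1_s,pm2_p Fractions with `ba1 > bs1_s > pm2_p`.
#' @param pm2_m Fraction below `pm2_p`, or `NA` for "absent required".
#' @return An object of class `frequency_thresholds`.
#' @export
frequency_thresholds <- function(ba1, bs1_s, pm2_p, pm2_m = NA_real_) {
  if (!(ba1 > bs1_s && bs1_s > pm2_p)) {
    stop("threshold ordering violated: need ba1 > bs1_s > pm2_p")
  }
  if (!is.na(pm2_m) && !(pm2_p >= pm2_m)) {
    stop("threshold ordering violated: need pm2_p >= pm2_m")
  }
  structure(list(ba1 = ba1, bs1_s = bs1_s, pm2_p = pm2_p, pm2_m = pm2_m),
            class = "frequency_thresholds")
}

# Built-in threshold table keyed by (category, frequency group).  Rows:
#   cancer    AD        BS1 > 0.1%, PM2_P < 0.004%, PM2_M absent
#   cancer    AR/AD_AR/XL  BS1 > 1%, PM2_P < 0.04%, PM2_M < 0.004%
#   general   AD        BS1 > 0.1%, PM2_P < 0.001%, PM2_M absent
#   general   AR/AD_AR/XL  BS1 > 1%, PM2_P < 0.01%, PM2_M < 0.001%
# BA1 is 0.05 for every non-exception gene.
builtin_threshold_table <- list(
  cancer = list(
    AD    = list(bs1_s = 0.001, pm2_p = 0.00004, pm2_m = NA_real_),
    AR_XL = list(bs1_s = 0.01,  pm2_p = 0.0004,  pm2_m = 0.00004)
  ),
  general = list(
    AD    = list(bs1_s = 0.001, pm2_p = 0.00001, pm2_m = NA_real_),
    AR_XL = list(bs1_s = 0.01,  pm2_p = 0.0001,  pm2_m = 0.00001)
  )
)

#' Filter populations eligible for frequency criteria
#'
#' Frequency criteria only consider founder-effect-free populations with
#' more than 2,000 alleles tested.  Benign-direction criteria (BA1/BS1)
#' additionally require the variant to be present in at least 5 alleles;
#' the rarity criterion (PM2) must remain evaluable for absent variants, so
#' the 5-allele requirement is not applied in the pathogenic direction.
#'
#' @param records List of [frequency_record()] objects.
#' @param for_benign Logical; apply the 5-allele presence requirement.
#' @return The eligible subset (possibly empty).
#' @export
eligible_populations <- function(records, for_benign = FALSE) {
  Filter(function(r) {
    ok <- !r$founder_effect && r$allele_number > 2000
    if (for_benign) ok <- ok && r$allele_count >= 5
    ok
  }, records)
}

#' Resolve frequency thresholds for a gene
#'
#' Per-gene overrides (the stand-in for gene-specific curated threshold
#' tables) take precedence; otherwise the built-in table row selected by
#' gene category and inheritance grouping applies, with the stand-alone
#' cut-off fixed at 0.05 for non-exception genes.  Exception-list genes
#' have no default and must carry an explicit override.
#'
#' @param gene A [gene_context()].
#' @param config Optional engine configuration (see [engine_config()]);
#'   per-gene overrides in `config$frequency_overrides[[symbol]]` apply when
#'   the gene itself carries none.
#' @return A [frequency_thresholds()] object.
#' @export
resolve_thresholds <- function(gene, config = NULL) {
  ov <- gene$frequency_overrides
  if (is.null(ov) && !is.null(config)) {
    ov <- config$frequency_overrides[[gene$symbol]]
  }
  if (!is.null(ov)) {
    return(frequency_thresholds(
      ba1 = ov$ba1, bs1_s = ov$bs1_s, pm2_p = ov$pm2_p,
      pm2_m = if (is.null(ov$pm2_m)) NA_real_ else ov$pm2_m))
  }
  if (isTRUE(gene$ba1_exception)) {
    stop("configuration error: gene '", gene$symbol,
         "' is on the stand-alone-frequency exception list and requires ",
         "explicit frequency overrides")
  }
  row <- builtin_threshold_table[[gene$category]][[frequency_group(gene$inheritance)]]
  frequency_thresholds(ba1 = 0.05, bs1_s = row$bs1_s, pm2_p = row$pm2_p,
                       pm2_m = row$pm2_m)
}

#' Evaluate the frequency criteria (BA1 / BS1 / PM2)
#'
#' BA1, BS1 and PM2 are mutually exclusive; at most one call is returned,
#' chosen in strength order.  Benign calls use the maximum frequency over
#' benign-eligible populations; the rarity check uses the maximum over
#' pathogenic-eligible populations.  Comparisons follow the printed
#' symbols: stand-alone at `>= ba1`, strong benign at `> bs1_s`, rarity at
#' strict `<`.  When the moderate cut-off is "absent", PM2_M requires an
#' allele count of zero in every eligible population.
#'
#' @param records List of [frequency_record()] objects.
#' @param gene A [gene_context()].
#' @param thresholds Optional pre-resolved [frequency_thresholds()].
#' @param config Optional engine configuration forwarded to
#'   [resolve_thresholds()].
#' @return A single applied [criterion_call()] (BA1_A, BS1_S, PM2_M or
#'   PM2_P), or an unapplied PM2 call when no population is evaluable, or
#'   `NULL` when frequencies fall between the cut-offs.
#' @export
evaluate_frequency <- function(records, gene, thresholds = NULL, config = NULL) {
  if (is.null(thresholds)) thresholds <- resolve_thresholds(gene, config)
  path_pop <- eligible_populations(records, for_benign = FALSE)
  if (length(path_pop) == 0) {
    return(unapplied_call(
      "PM2", "[PM2.no_data] insufficient population data: no eligible populations"))
  }
  benign_pop <- eligible_populations(records, for_benign = TRUE)

  if (length(benign_pop) > 0) {
    f_max <- max(vapply(benign_pop, record_frequency, numeric(1)), na.rm = TRUE)
    if (f_max >= thresholds$ba1) {
      if (!gene$ba1_exception) {
        return(criterion_call(
          "BA1", "A", rationale = sprintf(
            "[BA1.default] maximum eligible allele frequency %.4g >= %.4g",
            f_max, thresholds$ba1)))
      }
      # exception-list genes never receive the stand-alone call; fall
      # through to BS1 which remains assessable at its own cut-off
      if (f_max > thresholds$bs1_s) {
        return(criterion_call(
          "BS1", "S", rationale = sprintf(
            "[BA1.exception_skip] stand-alone call withheld (exception list); frequency %.4g > %.4g",
            f_max, thresholds$bs1_s)))
      }
    }
    if (f_max > thresholds$bs1_s) {
      return(criterion_call(
        "BS1", "S", rationale = sprintf(
          "[BS1.table2] maximum eligible allele frequency %.4g > %.4g",
          f_max, thresholds$bs1_s)))
    }
  }

  f_chk <- max(vapply(path_pop, record_frequency, numeric(1)), na.rm = TRUE)
  if (is.na(thresholds$pm2_m)) {
    absent <- all(vapply(path_pop, function(r) r$allele_count == 0, logical(1)))
    if (absent) {
      return(criterion_call(
        "PM2", "M",
        rationale = "[PM2.absent_ad] absent from every eligible population (absent required)"))
    }
  } else if (f_chk < thresholds$pm2_m) {
    return(criterion_call(
      "PM2", "M", rationale = sprintf(
        "[PM2.freq_m] maximum eligible allele frequency %.4g < %.4g",
        f_chk, thresholds$pm2_m)))
  }
  if (f_chk < thresholds$pm2_p) {
    return(criterion_call(
      "PM2", "P", rationale = sprintf(
        "[PM2.freq_p] maximum eligible allele frequency %.4g < %.4g",
        f_chk, thresholds$pm2_p)))
  }
  NULL
}
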