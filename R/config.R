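# Engine configuration: priors, caps, threshold overrides, decision table
# and hotspot intervals, loadable from YAML or JSON.

#' Construct an engine configuration
#'
#' @param prior Prior probability of pathogenicity (default 0.10, the value
#'   under which the framework's published posterior checks reproduce).
#' @param caution_cap Maximum co-counting members per caution group.
#' @param ba1_points Benign evidence points carried by the stand-alone
#'   frequency call on the Bayesian path.
#' @param frequency_overrides Named list (by gene symbol) of frequency
#'   threshold overrides, each with `ba1`, `bs1_s`, `pm2_p`, `pm2_m`.
#' @param pvs1_table Loss-of-function decision table (defaults to the
#'   shipped table; see [pvs1_decision_table()]).
#' @param hotspots Optional data frame of literature hotspot intervals
#'   with columns `gene`, `start`, `end`.
#' @param posterior_bounds Posterior category boundaries (see
#'   [posterior_category()]).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(prior = 0.10,
                          caution_cap = 2,
                          ba1_points = 8,
                          frequency_overrides = list(),
                          pvs1_table = NULL,
                          hotspots = NULL,
                          posterior_bounds = list(pathogenic = 0.99,
                                                  lp_low = 0.90,
                                                  lb_high = 0.10,
                                                  benign_high = 0.001)) {
  if (prior <= 0 || prior >= 1) stop("prior must lie strictly inside (0, 1)")
  if (is.null(pvs1_table)) pvs1_table <- pvs1_decision_table()
  structure(
    list(prior = prior, caution_cap = caution_cap, ba1_points = ba1_points,
         frequency_overrides = frequency_overrides, pvs1_table = pvs1_table,
         hotspots = hotspots, posterior_bounds = posterior_bounds),
    class = "engine_config"
  )
}

#' Load an engine configuration from YAML or JSON
#'
#' Recognised top-level keys: `prior`, `caution_cap`, `ba1_points`,
#' `frequency_overrides` (a map from gene symbol to `ba1`/`bs1_s`/`pm2_p`/
#' `pm2_m`), `pvs1_table` (path to a CSV), `hotspots` (list of
#' `gene`/`start`/`end` entries) and `posterior_bounds`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [engine_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  hotspots <- NULL
  if (!is.null(raw$hotspots)) {
    hotspots <- do.call(rbind, lapply(raw$hotspots, function(h) {
      data.frame(gene = h$gene, start = h$start, end = h$end,
                 stringsAsFactors = FALSE)
    }))
  }
  args <- list()
  for (k in c("prior", "caution_cap", "ba1_points")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$frequency_overrides)) {
    args$frequency_overrides <- lapply(raw$frequency_overrides, function(o) {
      list(ba1 = o$ba1, bs1_s = o$bs1_s, pm2_p = o$pm2_p,
           pm2_m = if (is.null(o$pm2_m) ||
                       identical(o$pm2_m, "absent")) NA_real_ else o$pm2_m)
    })
  }
  if (!is.null(raw$pvs1_table)) args$pvs1_table <- pvs1_decision_table(raw$pvs1_table)
  if (!is.null(hotspots)) args$hotspots <- hotspots
  if (!is.null(raw$posterior_bounds)) args$posterior_bounds <- raw$posterior_bounds
  do.call(engine_config, args)
}

# Coerce one gene entry (named list from YAML/JSON) to a gene_context.
gene_from_list <- function(symbol, entry) {
  args <- entry
  args$symbol <- symbol
  known <- names(formals(gene_context))
  bad <- setdiff(names(args), known)
  if (length(bad) > 0) {
    stop("unknown gene-config field(s) for ", symbol, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(gene_context, args)
}

#' Load a gene-context table from YAML or JSON
#'
#' One entry per gene symbol; fields follow the [gene_context()]
#' arguments.  A small demo table ships with the package at
#' `system.file("extdata", "genes_demo.yaml", package = "acmgrules")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [gene_context()] objects.
#' @export
read_gene_config <- function(path) {
  if (!file.exists(path)) stop("gene config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  out <- lapply(names(raw), function(sym) gene_from_list(sym, raw[[sym]]))
  names(out) <- names(raw)
  out
}

#' Validate configuration files
#'
#' Loads and schema-checks an engine configuration and (optionally) a
#' gene-context table, reporting the first violation found.
#'
#' @param config_path Path to an engine configuration file, or `NULL`.
#' @param genes_path Path to a gene-context table, or `NULL`.
#' @return Invisibly `TRUE` on success; errors describe the offending
#'   field.
#' @export
validate_config <- function(config_path = NULL, genes_path = NULL) {
  if (!is.null(config_path)) load_config(config_path)
  if (!is.null(genes_path)) read_gene_config(genes_path)
  invisible(TRUE)
}
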