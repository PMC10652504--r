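# Shared builders for unit tests: minimal genes, variants and evidence
# records constructed in code.

t_gene <- function(inheritance = "AD", ...) {
  args <- utils::modifyList(
    list(symbol = "TEST1", inheritance = inheritance,
         clinical_validity = "definitive"),
    list(...))
  do.call(gene_context, args)
}

t_missense <- function(...) {
  args <- utils::modifyList(
    list(consequence = "missense", codon_index = 100L,
         ref_aa = "A", alt_aa = "V"),
    list(...))
  do.call(variant_descriptor, args)
}

t_freq <- function(ac, an = 200000, founder = FALSE, pop = "overall") {
  list(frequency_record(pop, ac, an, founder))
}

t_record <- function(id = "t1", gene = t_gene(), variant = t_missense(),
                     frequencies = t_freq(100), ...) {
  evidence_record(id = id, gene = gene, variant = variant,
                  frequencies = frequencies, ...)
}

# Applied "PM2_M"-style labels of a call list.
labels_of <- function(calls) sort(call_labels(calls))

# Strength label of a single call (or NA).
strength_of <- function(call) {
  if (is.null(call) || !call$applied) NA_character_ else call$strength
}

# Write a minimal annotated VCF whose INFO fields carry the flat evidence
# encoding (entries joined with "|").
write_demo_vcf <- function(records, path) {
  rows <- lapply(records, function(r) acmgrules:::evidence_to_row(r, sep = "|"))
  used <- sort(unique(unlist(lapply(rows, function(row) {
    names(row)[row != "." & names(row) != "id"]
  }))))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000000>",
           vapply(used, function(col) {
             sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
                     toupper(col), col)
           }, character(1)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    keep <- names(row)[row != "." & names(row) != "id"]
    info <- paste(sprintf("%s=%s", toupper(keep), unlist(row[keep])),
                  collapse = ";")
    sprintf("1\t%d\t%s\tA\tT\t.\t.\t%s", i * 100, row[["id"]], info)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
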