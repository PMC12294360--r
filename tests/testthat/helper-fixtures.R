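# shared in-code fixtures

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(Map(function(id, seq) c(paste0(">", id), seq),
    names(records), records), use.names = FALSE)
  writeLines(lines, path)
  path
}

# a gene using exactly one codon per amino-acid family (extreme bias)
one_codon_per_family_counts <- function(count = 50) {
  code <- standardGeneticCode()
  fams <- codonFamilies(code)
  fams <- fams[names(fams) != "*"]
  cods <- vapply(fams, `[[`, character(1L), 1L)
  stats::setNames(rep(count, length(cods)), cods)
}

# exactly uniform usage within every family
uniform_counts <- function(count = 60) {
  code <- standardGeneticCode()
  fams <- codonFamilies(code)
  sense <- unlist(fams[names(fams) != "*"], use.names = FALSE)
  stats::setNames(rep(count, length(sense)), sense)
}

# CDS string from a codon-count vector (deterministic codon order)
counts_to_cds <- function(counts, stop_codon = "UAA") {
  cods <- rep(names(counts), times = counts)
  paste0(paste(cods, collapse = ""), stop_codon)
}
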