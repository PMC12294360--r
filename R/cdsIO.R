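#' Filtering policy for CDS ingestion
#'
#' @param dropPartialLength Drop records whose length is not a multiple of
#'   3 (`TRUE`, default). When `FALSE`, sequences are truncated to the last
#'   complete codon and retain the `PARTIAL_LENGTH` flag.
#' @param dropInternalStop Drop records with a stop codon before the final
#'   codon (default `TRUE`).
#' @param dropAmbiguous Drop records containing ambiguity codes (default
#'   `FALSE`; ambiguous codons are instead skipped during counting and
#'   tallied per gene).
#' @param minCodons Minimum codon count (after terminal-stop removal) for a
#'   gene to receive ENC/CAI/CBI/FOP values in [addCubIndices()]; shorter
#'   genes keep their counts but get `NA` indices. Default 30.
#' @return A named list of class `cds_filter_policy`.
#' @export
cdsFilterPolicy <- function(dropPartialLength = TRUE,
                            dropInternalStop = TRUE,
                            dropAmbiguous = FALSE,
                            minCodons = 30L) {
  structure(
    list(
      dropPartialLength = isTRUE(dropPartialLength),
      dropInternalStop = isTRUE(dropInternalStop),
      dropAmbiguous = isTRUE(dropAmbiguous),
      minCodons = as.integer(minCodons)
    ),
    class = "cds_filter_policy"
  )
}

#' Read and validate a CDS FASTA file
#'
#' Reads coding sequences from a (possibly gzipped) FASTA file, transcribes
#' DNA to the RNA alphabet, uppercases, flags records that are not a
#' multiple of 3 long (`PARTIAL_LENGTH`), contain an internal stop codon
#' (`INTERNAL_STOP`) or ambiguity codes (`AMBIGUOUS_BASE`), and applies the
#' filter `policy`. Duplicate ids are made unique by appending an ordinal
#' suffix, with a warning.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param policy A [cdsFilterPolicy()] list.
#' @return A [Biostrings::RNAStringSet-class] of surviving records in file
#'   order. Per-record flags are in `mcols(x)$flags` (comma-separated);
#'   `metadata(x)$filterLog` is a data.frame of excluded records and
#'   reasons, and `metadata(x)$policy` records the policy applied.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGAAATAA"), tf)
#' cds <- readCdsFasta(tf)
#' length(cds)  # 1
#' @export
readCdsFasta <- function(path, policy = cdsFilterPolicy()) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  ids[ids == ""] <- sprintf("unnamed_%d", which(ids == ""))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate FASTA ids made unique with ordinal suffixes: ",
      paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    ids <- make.unique(ids, sep = "_dup")
  }
  seqs <- chartr("Tt", "Uu", toupper(as.character(raw)))
  names(seqs) <- ids

  len <- nchar(seqs)
  partial <- len %% 3L != 0L
  ambiguous <- grepl("[^ACGU]", seqs)
  bad_alpha <- grepl("[^ACGURYSWKMBDHVN]", seqs)
  if (any(bad_alpha))
    stop("non-IUPAC characters in record(s): ",
      paste(utils::head(ids[bad_alpha], 5L), collapse = ", "),
      call. = FALSE)

  trimmed <- substr(seqs, 1L, len - len %% 3L)
  rna <- Biostrings::RNAStringSet(trimmed)
  aa <- suppressWarnings(
    Biostrings::translate(rna, if.fuzzy.codon = "X")
  )
  aach <- as.character(aa)
  star <- regexpr("\\*", aach)
  internal <- star > 0L & star < nchar(aach)

  flags <- mapply(function(p, s, a) {
    paste(c(
      if (p) "PARTIAL_LENGTH", if (s) "INTERNAL_STOP",
      if (a) "AMBIGUOUS_BASE"
    ), collapse = ",")
  }, partial, internal, ambiguous)

  drop <- (partial & policy$dropPartialLength) |
    (internal & policy$dropInternalStop) |
    (ambiguous & policy$dropAmbiguous)

  log <- data.frame(
    id = ids[drop],
    reason = flags[drop],
    stringsAsFactors = FALSE
  )
  keep_seq <- if (policy$dropPartialLength) seqs[!drop] else trimmed[!drop]
  if (length(keep_seq) == 0L)
    stop("no records survive filtering in ", path, call. = FALSE)
  out <- Biostrings::RNAStringSet(keep_seq)
  mcols(out) <- DataFrame(
    flags = unname(flags[!drop]),
    nCodons = as.integer(nchar(keep_seq) %/% 3L)
  )
  metadata(out) <- list(
    filterLog = log,
    policy = unclass(policy),
    nRead = length(raw), nKept = length(out)
  )
  out
}

#' Count codons per gene
#'
#' Counts consecutive, non-overlapping triplets from position 1 of each
#' sequence. Codons containing ambiguity codes are skipped and tallied in
#' `skippedCodons`. If `dropTerminalStop` and the final codon is a stop, it
#' is omitted, so under the default ingestion policy stop-codon counts are
#' zero everywhere.
#'
#' @param x A [Biostrings::RNAStringSet-class] or
#'   [Biostrings::DNAStringSet-class] from [readCdsFasta()], or a character
#'   vector of in-frame sequences.
#' @param code A [GeneticCode-class].
#' @param dropTerminalStop Drop a terminal stop codon before counting
#'   (default `TRUE`).
#' @return A [CodonUsageSet-class] with one column per input sequence.
#' @examples
#' cc <- countCodons(c(g = "AUGAAAUAA"))
#' sum(codonCounts(cc))  # 2: terminal stop dropped
#' @export
countCodons <- function(x, code = standardGeneticCode(),
                        dropTerminalStop = TRUE) {
  if (is.character(x)) {
    nm <- names(x)
    x <- Biostrings::RNAStringSet(chartr("Tt", "Uu", toupper(x)))
    names(x) <- nm
  }
  if (is(x, "DNAStringSet"))
    x <- Biostrings::RNAStringSet(
      chartr("T", "U", as.character(x))
    )
  stopifnot(is(x, "RNAStringSet"))
  len <- Biostrings::width(x)
  if (any(len %% 3L != 0L))
    x <- IRanges::narrow(x, start = 1L, end = len - len %% 3L)
  if (dropTerminalStop) {
    len <- Biostrings::width(x)
    last <- as.character(
      IRanges::narrow(x, start = pmax(len - 2L, 1L), end = len)
    )
    is_stop <- last %in% code@families[["*"]] & len >= 3L
    if (any(is_stop))
      x[is_stop] <- IRanges::narrow(
        x[is_stop], start = 1L, end = Biostrings::width(x[is_stop]) - 3L
      )
  }
  tab <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  counts <- t(tab)  # 64 x genes, rows already AAA..UUU canonical order
  colnames(counts) <- if (!is.null(names(x))) names(x) else
    sprintf("gene_%04d", seq_along(x))
  skipped <- as.integer(Biostrings::width(x) %/% 3L - colSums(counts))
  CodonUsageSet(counts, code = code, skippedCodons = skipped)
}

#' Write a per-gene codon count table
#'
#' @param x A [CodonUsageSet-class].
#' @param path Output TSV path; columns are `gene_id`, the 64 codons in
#'   canonical order, and `total_codons`.
#' @return `path`, invisibly.
#' @export
writeCodonCountsTsv <- function(x, path) {
  m <- t(codonCounts(x))
  df <- data.frame(
    gene_id = rownames(m), m,
    total_codons = rowSums(m),
    check.names = FALSE, row.names = NULL
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
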