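#' CodonUsageSet: per-gene codon counts and derived statistics
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one column
#' per gene and one row per codon (all 64, fixed alphabetical RNA order).
#' The `"counts"` assay stores non-negative integer codon counts; row
#' metadata annotates each codon with its amino acid, family size and
#' whether it belongs to the 59-codon analysis set; column metadata
#' accumulates per-gene statistics as pipeline steps
#' ([addComposition()], [addCubIndices()]) are applied. The
#' [GeneticCode-class] used for counting lives in `metadata(x)$geneticCode`.
#'
#' @seealso [countCodons()], [addComposition()], [addCubIndices()]
#' @export
setClass("CodonUsageSet", contains = "SummarizedExperiment")

setValidity("CodonUsageSet", function(object) {
  msg <- character()
  if (nrow(object) != 64L)
    msg <- c(msg, "a CodonUsageSet must have exactly 64 codon rows")
  if (!identical(rownames(object), .codonOrder()))
    msg <- c(msg, "rows must be the 64 RNA codons in canonical order")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "codon counts must be non-negative")
  if (!is(metadata(object)$geneticCode, "GeneticCode"))
    msg <- c(msg, "metadata(x)$geneticCode must be a GeneticCode")
  if (length(msg)) msg else TRUE
})

#' Construct a CodonUsageSet from a codon count matrix
#'
#' @param counts Numeric matrix, 64 codon rows (canonical RNA order; row
#'   names may be DNA or RNA codons) by one column per gene.
#' @param code A [GeneticCode-class]; defaults to the standard code.
#' @param skippedCodons Optional integer vector, per-gene count of codons
#'   skipped for ambiguity during counting.
#' @return A [CodonUsageSet-class].
#' @export
CodonUsageSet <- function(counts, code = standardGeneticCode(),
                          skippedCodons = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- chartr("T", "U", toupper(rownames(counts)))
  counts <- counts[.codonOrder(), , drop = FALSE]
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene_%04d", seq_len(ncol(counts)))
  fam <- codonToAa(code)
  sz <- .familySizes(code)
  rd <- DataFrame(
    codon = rownames(counts),
    aa = unname(fam[rownames(counts)]),
    familySize = unname(sz[rownames(counts)]),
    isStop = unname(fam[rownames(counts)] == "*"),
    isAnalysis = rownames(counts) %in% analysisCodons(code)
  )
  if (is.null(skippedCodons)) skippedCodons <- integer(ncol(counts))
  cd <- DataFrame(
    totalCodons = unname(colSums(counts)),
    skippedCodons = skippedCodons
  )
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd,
    metadata = list(geneticCode = code)
  )
  new("CodonUsageSet", se)
}

#' @describeIn CodonUsageSet Codon count matrix (64 x genes).
#' @param x A [CodonUsageSet-class].
#' @export
codonCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn CodonUsageSet The genetic code attached to the set.
#' @export
geneticCode <- function(x) metadata(x)$geneticCode

#' @describeIn CodonUsageSet Per-gene statistics accumulated so far, as a
#'   base data.frame (gene ids in `gene_id`).
#' @export
geneStats <- function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(gene_id = colnames(x), df, row.names = NULL,
    check.names = FALSE)
}

setMethod("show", "CodonUsageSet", function(object) {
  cat("CodonUsageSet with", ncol(object), "genes\n")
  cat("  total codons:", sum(codonCounts(object)), "\n")
  extra <- setdiff(colnames(SummarizedExperiment::colData(object)),
    c("totalCodons", "skippedCodons"))
  if (length(extra))
    cat("  gene statistics:", paste(extra, collapse = ", "), "\n")
})

# normalize input to a 64 x g matrix in canonical order; accepts a
# CodonUsageSet, a 64-row matrix, or a named numeric vector for one gene
.asCountMatrix <- function(x) {
  if (is(x, "CodonUsageSet")) return(codonCounts(x))
  if (is.matrix(x)) {
    rownames(x) <- chartr("T", "U", toupper(rownames(x)))
    stopifnot(all(.codonOrder() %in% rownames(x)))
    return(x[.codonOrder(), , drop = FALSE])
  }
  if (is.numeric(x)) {
    v <- stats::setNames(numeric(64L), .codonOrder())
    nm <- chartr("T", "U", toupper(names(x)))
    bad <- setdiff(nm, .codonOrder())
    if (length(bad))
      stop("invalid codon: '", bad[[1L]], "'", call. = FALSE)
    v[nm] <- v[nm] + as.numeric(x)
    return(matrix(v, ncol = 1L, dimnames = list(.codonOrder(), "gene")))
  }
  stop("cannot interpret 'x' as codon counts", call. = FALSE)
}
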