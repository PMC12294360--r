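#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<- rowData
NULL

#' GeneticCode: the standard nuclear genetic code as an analysis object
#'
#' Table-driven model of a genetic code in the RNA alphabet: the 64-codon
#' to amino-acid map, the synonymous families, the degeneracy classes
#' (family sizes 1, 2, 3, 4, 6) and the ordered 59-codon analysis set used
#' for RSCU tables and heatmaps (all sense codons minus the two
#' non-synonymous ones, Met/AUG and Trp/UGG; stop codons UAA, UAG, UGA are
#' excluded as well).
#'
#' @slot codonToAa named character(64); names are RNA codons in fixed
#'   alphabetical order (A < C < G < U), values are one-letter amino-acid
#'   symbols with `"*"` for stop.
#' @slot families named list; one entry per amino acid (and `"*"`), each an
#'   alphabetically ordered character vector of its codons.
#' @slot degeneracyClasses named list keyed `"1","2","3","4","6"`; each a
#'   character vector of the amino acids whose family has that size.
#' @slot analysisCodons character(59); the ordered synonymous-codon set.
#'
#' @seealso [standardGeneticCode()], [synonymousFamily()]
#' @export
setClass("GeneticCode",
  representation(
    codonToAa = "character",
    families = "list",
    degeneracyClasses = "list",
    analysisCodons = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  cta <- object@codonToAa
  if (length(cta) != 64L || is.null(names(cta)) || anyDuplicated(names(cta)))
    msg <- c(msg, "codonToAa must map exactly 64 distinct codons")
  stops <- names(cta)[cta == "*"]
  if (!setequal(stops, c("UAA", "UAG", "UGA")))
    msg <- c(msg, "stop codons must be UAA, UAG, UGA")
  singles <- names(object@families)[lengths(object@families) == 1L &
    names(object@families) != "*"]
  if (length(singles) != 2L)
    msg <- c(msg, "exactly two single-codon amino acids expected (Met, Trp)")
  if (length(object@analysisCodons) != 59L)
    msg <- c(msg, "analysis codon set must contain 59 codons")
  all_fam <- unlist(object@families, use.names = FALSE)
  if (length(all_fam) != 64L || anyDuplicated(all_fam))
    msg <- c(msg, "families must partition the 64 codons")
  sense <- sum(lengths(object@families[names(object@families) != "*"]))
  if (sense != 61L)
    msg <- c(msg, "sense codons must number 61")
  if (length(msg)) msg else TRUE
})

# canonical codon order: alphabetical over A,C,G,U (matches
# Biostrings::oligonucleotideFrequency column order on RNA input)
.codonOrder <- function() {
  b <- c("A", "C", "G", "U")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

#' Build the standard nuclear genetic code
#'
#' Constructs a validated [GeneticCode-class] object for the standard
#' nuclear code in the RNA alphabet. Families are ordered alphabetically so
#' every downstream table is deterministic.
#'
#' @return A [GeneticCode-class] object with 64 codons, 20 amino acids plus
#'   stop, and a 59-codon analysis set.
#' @examples
#' gc <- standardGeneticCode()
#' length(analysisCodons(gc))  # 59
#' @export
standardGeneticCode <- function() {
  codons <- .codonOrder()
  dna <- chartr("U", "T", codons)
  aa <- unname(Biostrings::GENETIC_CODE[dna])
  names(aa) <- codons
  fams <- split(codons, aa)
  fams <- lapply(fams, sort)
  sizes <- lengths(fams[names(fams) != "*"])
  deg <- split(names(sizes), sizes)
  names(deg) <- as.character(names(deg))
  keep <- codons[aa != "*" & !(codons %in% c("AUG", "UGG"))]
  new("GeneticCode",
    codonToAa = aa, families = fams,
    degeneracyClasses = deg, analysisCodons = keep
  )
}

#' @describeIn standardGeneticCode Ordered 59-codon synonymous analysis set.
#' @param code A [GeneticCode-class] object.
#' @export
analysisCodons <- function(code) code@analysisCodons

#' @describeIn standardGeneticCode Named codon-to-amino-acid map (RNA
#'   codons; `"*"` marks stop).
#' @export
codonToAa <- function(code) code@codonToAa

#' @describeIn standardGeneticCode Named list of synonymous families.
#' @export
codonFamilies <- function(code) code@families

#' @describeIn standardGeneticCode Amino acids grouped by family size.
#' @export
degeneracyClasses <- function(code) code@degeneracyClasses

#' Synonymous family of a codon
#'
#' Returns the full, alphabetically ordered synonymous family containing
#' `codon` (including the codon itself). Stop codons return the stop set.
#' DNA-alphabet input (T for U) is transcribed; case is ignored.
#'
#' @param code A [GeneticCode-class] object.
#' @param codon A single codon string, RNA or DNA alphabet.
#' @return Character vector of codons encoding the same amino acid.
#' @examples
#' code <- standardGeneticCode()
#' synonymousFamily(code, "AUG")  # "AUG" only: Met is non-degenerate
#' synonymousFamily(code, "AGA")  # the six-codon Arg family
#' @export
synonymousFamily <- function(code, codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  rna <- chartr("T", "U", toupper(codon))
  if (!rna %in% names(code@codonToAa))
    stop("invalid codon: '", codon, "'", call. = FALSE)
  code@families[[code@codonToAa[[rna]]]]
}

# position-wise base of each codon in canonical order
.codonBase <- function(pos) {
  substr(.codonOrder(), pos, pos)
}

# family size per codon (named integer over canonical order)
.familySizes <- function(code) {
  fam <- code@codonToAa
  sz <- lengths(code@families)[fam]
  names(sz) <- names(fam)
  sz
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (standard nuclear, RNA alphabet)\n")
  cat("  64 codons; stops:",
    paste(object@families[["*"]], collapse = " "), "\n")
  cat("  analysis set:", length(object@analysisCodons),
    "synonymous codons\n")
  sz <- lengths(object@families[names(object@families) != "*"])
  cat("  degeneracy classes:",
    paste(sprintf("%d-fold x%d", sort(unique(sz)),
      table(sz)[as.character(sort(unique(sz)))]), collapse = ", "), "\n")
})
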