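#' Positional GC content
#'
#' GC fraction at each codon position across all counted codons of a gene:
#' `gcK = (#G + #C at position K) / total codons`, the mean of positions
#' 1 and 2 (`gc12`), and the overall GC fraction (`gcAll`).
#'
#' @param x A [CodonUsageSet-class], a 64-row count matrix, or a named
#'   numeric vector of codon counts for a single gene.
#' @return A data.frame with one row per gene and columns `gc1`, `gc2`,
#'   `gc3`, `gc12`, `gcAll`. Genes with zero counted codons get `NA`.
#' @examples
#' positionalGC(c(AUG = 5))  # gc1 0, gc2 0, gc3 1
#' @export
positionalGC <- function(x) {
  m <- .asCountMatrix(x)
  tot <- colSums(m)
  gcpos <- vapply(1:3, function(p) {
    sel <- .codonBase(p) %in% c("G", "C")
    colSums(m[sel, , drop = FALSE])
  }, numeric(ncol(m)))
  gcpos <- matrix(gcpos, ncol = 3L)  # genes x positions
  frac <- gcpos / tot
  frac[tot == 0, ] <- NA_real_
  data.frame(
    gene_id = colnames(m),
    gc1 = frac[, 1L], gc2 = frac[, 2L], gc3 = frac[, 3L],
    gc12 = (frac[, 1L] + frac[, 2L]) / 2,
    gcAll = rowSums(gcpos) / (3 * tot),
    row.names = NULL
  )
}

# codons of amino acids with >= 2 synonyms (stops excluded)
.synonymousMask <- function(code) {
  sz <- .familySizes(code)
  aa <- codonToAa(code)
  unname(sz >= 2L & aa != "*")
}

#' Synonymous third-position GC (GC3s)
#'
#' GC fraction at third codon positions computed only over codons of amino
#' acids with two or more synonyms; Met, Trp and stop codons are excluded.
#' This is the composition variable the expected-ENC curve
#' ([encExpected()]) is parameterised by.
#'
#' @inheritParams positionalGC
#' @param code A [GeneticCode-class]; taken from `x` when `x` is a
#'   [CodonUsageSet-class].
#' @return Numeric vector of GC3s per gene; `NA` when a gene has no
#'   synonymous codons.
#' @examples
#' gc3s(c(AAA = 2, AAG = 2))  # 0.5
#' gc3s(c(AUG = 10))          # NA: Met is excluded
#' @export
gc3s <- function(x, code = standardGeneticCode()) {
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  syn <- .synonymousMask(code)
  gc3 <- .codonBase(3L) %in% c("G", "C")
  num <- colSums(m[syn & gc3, , drop = FALSE])
  den <- colSums(m[syn, , drop = FALSE])
  out <- num / den
  out[den == 0] <- NA_real_
  unname(out)
}

# fourfold-degenerate codon mask: first-two-base blocks whose four codons
# all encode the same amino acid (Ala/Gly/Pro/Thr/Val plus the CUN, UCN,
# CGN blocks of Leu/Ser/Arg)
.fourfoldMask <- function(code) {
  aa <- codonToAa(code)
  block <- substr(.codonOrder(), 1L, 2L)
  ok <- vapply(split(aa, block), function(a) length(unique(a)) == 1L,
    logical(1L))
  unname(ok[block])
}

#' PR2 (parity rule 2) coordinates
#'
#' Third-position base ratios `pr2x = G3/(G3 + C3)` and
#' `pr2y = A3/(A3 + U3)` over the selected codon set. Under pure,
#' strand-symmetric mutation pressure both ratios sit at 0.5; departures
#' indicate selective (or strand-specific) influences on codon choice.
#' Genes with a zero denominator get `NA` coordinates and are excluded
#' from PR2 summaries.
#'
#' @inheritParams gc3s
#' @param siteSet `"all_synonymous"` (default) uses third positions of all
#'   synonymous codons; `"fourfold_only"` restricts to fourfold-degenerate
#'   blocks, the classic PR2 site set.
#' @return A data.frame with columns `gene_id`, `a3`, `u3`, `g3`, `c3`
#'   (integer third-position base counts over the site set), `pr2x`,
#'   `pr2y`.
#' @examples
#' pr2Coordinates(c(GGU = 1, GGC = 1, GGA = 1, GGG = 1))  # (0.5, 0.5)
#' @export
pr2Coordinates <- function(x, code = standardGeneticCode(),
                           siteSet = c("all_synonymous", "fourfold_only")) {
  siteSet <- match.arg(siteSet)
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  sel <- if (siteSet == "fourfold_only") .fourfoldMask(code) else
    .synonymousMask(code)
  b3 <- .codonBase(3L)
  cnt <- vapply(c("A", "U", "G", "C"), function(b) {
    colSums(m[sel & b3 == b, , drop = FALSE])
  }, numeric(ncol(m)))
  cnt <- matrix(cnt, ncol = 4L, dimnames = list(NULL, c("A", "U", "G", "C")))
  gx <- cnt[, "G"] + cnt[, "C"]
  ay <- cnt[, "A"] + cnt[, "U"]
  data.frame(
    gene_id = colnames(m),
    a3 = cnt[, "A"], u3 = cnt[, "U"], g3 = cnt[, "G"], c3 = cnt[, "C"],
    pr2x = ifelse(gx > 0, cnt[, "G"] / gx, NA_real_),
    pr2y = ifelse(ay > 0, cnt[, "A"] / ay, NA_real_),
    row.names = NULL
  )
}

#' Attach per-gene composition statistics to a CodonUsageSet
#'
#' Runs [positionalGC()], [gc3s()] and [pr2Coordinates()] and stores the
#' results in `colData`.
#'
#' @param x A [CodonUsageSet-class].
#' @param pr2SiteSet Passed to [pr2Coordinates()].
#' @return `x` with columns `gc1`, `gc2`, `gc3`, `gc12`, `gcAll`, `gc3s`,
#'   `a3`, `u3`, `g3`, `c3`, `pr2x`, `pr2y` added to its gene statistics.
#' @export
addComposition <- function(x, pr2SiteSet = "all_synonymous") {
  stopifnot(is(x, "CodonUsageSet"))
  gc <- positionalGC(x)
  pr2 <- pr2Coordinates(x, siteSet = pr2SiteSet)
  cd <- SummarizedExperiment::colData(x)
  for (col in c("gc1", "gc2", "gc3", "gc12", "gcAll"))
    cd[[col]] <- gc[[col]]
  cd$gc3s <- gc3s(x)
  for (col in c("a3", "u3", "g3", "c3", "pr2x", "pr2y"))
    cd[[col]] <- pr2[[col]]
  SummarizedExperiment::colData(x) <- cd
  metadata(x)$pr2SiteSet <- pr2SiteSet
  x
}

#' Species-level composition summary
#'
#' Aggregates per-gene composition either as the unweighted mean across
#' genes (`"gene_mean"`) or as the value of the concatenated CDS set
#' (`"concatenated"`, codon-count weighted). Both aggregations are
#' reported by [runSpecies()] since published species-level GC tables
#' rarely state which was used.
#'
#' @param x A [CodonUsageSet-class] after [addComposition()].
#' @param method Aggregation method.
#' @return One-row data.frame with `gc1`, `gc2`, `gc3`, `gc12`, `gcAll`,
#'   `gc3s` as percentages.
#' @export
speciesComposition <- function(x, method = c("gene_mean", "concatenated")) {
  method <- match.arg(method)
  if (method == "gene_mean") {
    st <- geneStats(x)
    vals <- colMeans(st[, c("gc1", "gc2", "gc3", "gc12", "gcAll", "gc3s")],
      na.rm = TRUE)
  } else {
    pooled <- rowSums(codonCounts(x))
    gc <- positionalGC(pooled)
    vals <- c(gc1 = gc$gc1, gc2 = gc$gc2, gc3 = gc$gc3, gc12 = gc$gc12,
      gcAll = gc$gcAll, gc3s = gc3s(pooled, geneticCode(x)))
  }
  out <- as.data.frame(as.list(100 * vals))
  names(out) <- c("gc1", "gc2", "gc3", "gc12", "gcAll", "gc3s")
  out$aggregation <- method
  out
}
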