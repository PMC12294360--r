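#' Relative synonymous codon usage (RSCU)
#'
#' For codon *j* of amino acid *i*, `RSCU_ij = X_ij / mean(X_i.)`: the
#' observed count divided by the count expected if all synonyms of the
#' amino acid were used equally. RSCU is 1 under uniform usage, above 1
#' for over-used codons. Single-codon amino acids (Met, Trp) and stop
#' codons are excluded; families with no observed codons yield `NA`
#' (undefined, not zero).
#'
#' @inheritParams gc3s
#' @param pool Pool counts over all genes before computing (one RSCU
#'   vector for the whole set, e.g. a species)? Default `FALSE`.
#' @return If `pool` or a single gene: a named numeric vector over the 59
#'   analysis codons. Otherwise a 59 x genes matrix.
#' @examples
#' r <- rscu(c(AAA = 3, AAG = 1))
#' r[c("AAA", "AAG")]  # 1.5, 0.5
#' @export
rscu <- function(x, code = standardGeneticCode(), pool = FALSE) {
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  if (pool) m <- matrix(rowSums(m), ncol = 1L,
    dimnames = list(rownames(m), "pooled"))
  aa <- codonToAa(code)
  keep <- analysisCodons(code)
  ms <- m[keep, , drop = FALSE]
  fam <- aa[keep]
  famTotals <- rowsum(ms, fam)           # families x genes
  famSize <- lengths(codonFamilies(code))[rownames(famTotals)]
  expd <- famTotals[fam, , drop = FALSE] / famSize[fam]
  out <- ms / expd
  out[expd == 0] <- NA_real_
  if (ncol(out) == 1L) out[, 1L] else out
}

#' Observed effective number of codons (ENC)
#'
#' Wright-style estimator of the effective number of codons. For each
#' synonymous family with `n >= 2` observed codons the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; `F` is averaged within each
#' degeneracy class and `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. ENC ranges
#' from 20 (one codon per amino acid) to 61 (uniform usage); values above
#' 61 arising from sampling noise are clamped to 61. A missing 3-fold
#' class average (Ile unobserved) is imputed as `(F2 + F4) / 2`; any other
#' missing or non-positive class average yields `NA`.
#'
#' @inheritParams gc3s
#' @return Numeric vector of ENC per gene (`NA` when undefined).
#' @examples
#' # extreme bias: a single codon per family
#' @export
encObserved <- function(x, code = standardGeneticCode()) {
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  fams <- codonFamilies(code)
  fams <- fams[names(fams) != "*"]
  fams <- fams[lengths(fams) >= 2L]
  sz <- lengths(fams)
  vapply(seq_len(ncol(m)), function(g) {
    v <- m[, g]
    Fhat <- vapply(fams, function(cod) {
      n <- sum(v[cod])
      if (n < 2) return(NA_real_)
      p <- v[cod] / n
      (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1L))
    Fbar <- tapply(Fhat, sz, mean, na.rm = TRUE)
    Fbar[is.nan(Fbar)] <- NA_real_
    f2 <- Fbar[["2"]]; f3 <- Fbar[["3"]]
    f4 <- Fbar[["4"]]; f6 <- Fbar[["6"]]
    if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
    fs <- c(f2, f3, f4, f6)
    if (anyNA(fs) || any(fs <= 0)) return(NA_real_)
    min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
  }, numeric(1L))
}

#' Expected ENC from synonymous third-position GC
#'
#' The null expectation for ENC when codon choice is driven only by the
#' GC content at synonymous third positions (mutation pressure, no
#' selection): `ENCexp = 2 + s + 29 / (s^2 + (1 - s)^2)` with `s = GC3s`.
#' Genes far below this curve use fewer codons than composition alone
#' predicts, the classic signature of translational selection.
#'
#' @param gc3s Numeric vector of GC3s fractions in `[0, 1]`.
#' @return Numeric vector of expected ENC values.
#' @examples
#' encExpected(0.5)  # 60.5
#' @export
encExpected <- function(gc3s) {
  bad <- !is.na(gc3s) & (gc3s < 0 | gc3s > 1)
  if (any(bad))
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Codon adaptation weights from a reference gene set
#'
#' Pools codon counts over the reference genes and sets each codon's
#' weight to its pooled RSCU divided by the maximum RSCU in its family,
#' so the most-used codon of every amino acid has weight 1. Codons unseen
#' in the reference are floored at `floor` to keep the geometric mean in
#' [cai()] finite; families entirely absent from the reference get weight
#' 1 with a warning. Met and Trp always carry weight 1.
#'
#' @param reference A [CodonUsageSet-class], count matrix or single-gene
#'   count vector for the reference set (typically highly expressed or
#'   highly biased genes).
#' @param code A [GeneticCode-class].
#' @param floor Weight floor for reference-absent codons (default 0.01).
#' @param description Provenance string recorded with the weights.
#' @return A named numeric vector of weights over the 61 sense codons,
#'   with attribute `reference_description`.
#' @examples
#' w <- caiWeights(c(AAA = 3, AAG = 1))
#' w[c("AAA", "AAG")]  # 1, 1/3
#' @export
caiWeights <- function(reference, code = standardGeneticCode(),
                       floor = 0.01, description = "user-supplied") {
  if (is(reference, "CodonUsageSet")) code <- geneticCode(reference)
  m <- .asCountMatrix(reference)
  pooled <- rowSums(m)
  aa <- codonToAa(code)
  sense <- names(aa)[aa != "*"]
  w <- stats::setNames(rep(1, length(sense)), sense)
  empty <- character()
  for (a in unique(aa[sense])) {
    cods <- codonFamilies(code)[[a]]
    if (length(cods) < 2L) next
    tot <- sum(pooled[cods])
    if (tot == 0) {
      empty <- c(empty, a)
      next
    }
    r <- pooled[cods] / (tot / length(cods))
    wfam <- r / max(r)
    wfam[wfam < floor] <- floor
    w[cods] <- wfam
  }
  if (length(empty))
    warning("no reference counts for ", length(empty),
      " amino acid(s) (", paste(empty, collapse = ", "),
      "); their weights set to 1", call. = FALSE)
  attr(w, "reference_description") <- description
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the reference weights over a gene's codons, excluding
#' Met, Trp and stop codons. CAI lies in (0, 1]; 1 means every codon is
#' the reference-preferred one.
#'
#' @inheritParams gc3s
#' @param weights Weights from [caiWeights()].
#' @return Numeric vector of CAI per gene (`NA` when a gene has no
#'   eligible codons).
#' @examples
#' w <- caiWeights(c(AAA = 3, AAG = 1))
#' cai(c(AAA = 10), w)  # 1
#' @export
cai <- function(x, weights, code = standardGeneticCode()) {
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  elig <- analysisCodons(code)
  lw <- log(weights[elig])
  cnt <- m[elig, , drop = FALSE]
  n <- colSums(cnt)
  out <- exp(colSums(cnt * lw) / n)
  out[n == 0] <- NA_real_
  unname(out)
}

#' Codon bias index (CBI) and frequency of optimal codons (FOP)
#'
#' Both indices score usage of a designated optimal-codon set over a
#' gene's synonymous codons: `FOP = Nopt / Ntot` and
#' `CBI = (Nopt - Nrand) / (Ntot - Nrand)`, where `Nrand` is the optimal
#' count expected under uniform usage within each family. CBI is 0 for
#' uniform usage, 1 when only optimal codons are used, and negative when
#' optimal codons are avoided.
#'
#' @inheritParams gc3s
#' @param optimal Character vector of optimal codons (a subset of the
#'   sense codons, at least one).
#' @return A data.frame with columns `gene_id`, `cbi`, `fop`.
#' @examples
#' cbiFop(c(AAA = 3, AAG = 1), optimal = "AAA")  # cbi 0.5, fop 0.75
#' @export
cbiFop <- function(x, optimal, code = standardGeneticCode()) {
  if (is(x, "CodonUsageSet")) code <- geneticCode(x)
  m <- .asCountMatrix(x)
  optimal <- chartr("T", "U", toupper(optimal))
  aa <- codonToAa(code)
  stopifnot(length(optimal) >= 1L,
    all(optimal %in% names(aa)[aa != "*"]))
  syn <- .synonymousMask(code)
  sz <- .familySizes(code)
  # per-codon expected-optimal rate under uniform family usage
  nOptInFam <- vapply(codonFamilies(code), function(cod)
    sum(cod %in% optimal), integer(1L))
  rate <- nOptInFam[aa] / sz
  opt <- names(aa) %in% optimal
  Ntot <- colSums(m[syn, , drop = FALSE])
  Nopt <- colSums(m[syn & opt, , drop = FALSE])
  Nrand <- colSums(m[syn, , drop = FALSE] * rate[syn])
  data.frame(
    gene_id = colnames(m),
    cbi = ifelse(Ntot - Nrand != 0, (Nopt - Nrand) / (Ntot - Nrand),
      NA_real_),
    fop = ifelse(Ntot > 0, Nopt / Ntot, NA_real_),
    row.names = NULL
  )
}

#' Preferred codons from an RSCU table
#'
#' Codons with RSCU strictly greater than 1 are called preferred
#' (over-used relative to their synonyms). Also tallies preferred codons
#' by ending base, separating A/U-ending from G-ending and C-ending
#' codons.
#'
#' @param rscuTable A named RSCU vector (e.g. `rscu(x, pool = TRUE)`).
#' @return A list with `codons` (character), `count` (integer) and
#'   `endingBase` (named integer: `AU`, `G`, `C`).
#' @export
preferredCodons <- function(rscuTable) {
  stopifnot(is.numeric(rscuTable), !is.null(names(rscuTable)))
  pref <- names(rscuTable)[!is.na(rscuTable) & rscuTable > 1]
  last <- substr(pref, 3L, 3L)
  list(
    codons = pref,
    count = length(pref),
    endingBase = c(
      AU = sum(last %in% c("A", "U")),
      G = sum(last == "G"),
      C = sum(last == "C")
    )
  )
}

#' Attach codon-usage-bias indices to a CodonUsageSet
#'
#' Computes per-gene amino-acid length, observed ENC, expected ENC (from
#' GC3s), the deviation ratio `(ENCexp - ENCobs) / ENCexp`, CAI, CBI and
#' FOP, storing them in the gene statistics. Genes with fewer than
#' `minCodons` counted codons get `NA` for all indices (short genes make
#' these estimators unstable).
#'
#' The default CAI reference (`caiReference = "lowEnc"`) pools the most
#' biased genes of the set itself: the lowest-ENC `referenceFraction` of
#' genes (at least 10). An external reference can be supplied as
#' `referenceCounts`. The default optimal-codon set for CBI/FOP is the
#' preferred-codon set (pooled RSCU > 1) of the whole gene set;
#' `optimalCodons` overrides it.
#'
#' @param x A [CodonUsageSet-class] (after [addComposition()], which
#'   supplies `gc3s`; it is computed on the fly otherwise).
#' @param caiReference `"lowEnc"` (default) or `"external"`.
#' @param referenceFraction Fraction of genes in the self-reference
#'   (default 0.05).
#' @param referenceCounts Reference counts for `caiReference = "external"`.
#' @param optimalCodons Optional optimal-codon set for CBI/FOP.
#' @param minCodons Minimum codons for index computation (default from the
#'   ingestion policy, 30).
#' @return `x` with columns `lAa`, `encObs`, `encExp`, `deviationRatio`,
#'   `cai`, `cbi`, `fop` added; the weights and optimal set used are
#'   recorded in `metadata(x)`.
#' @export
addCubIndices <- function(x, caiReference = c("lowEnc", "external"),
                          referenceFraction = 0.05,
                          referenceCounts = NULL,
                          optimalCodons = NULL, minCodons = 30L) {
  stopifnot(is(x, "CodonUsageSet"))
  caiReference <- match.arg(caiReference)
  code <- geneticCode(x)
  m <- codonCounts(x)
  cd <- SummarizedExperiment::colData(x)
  short <- cd$totalCodons < minCodons

  enc <- encObserved(x)
  s <- if ("gc3s" %in% colnames(cd)) cd$gc3s else gc3s(x)
  encExp <- encExpected(s)

  if (caiReference == "lowEnc") {
    ok <- which(!is.na(enc) & !short)
    if (length(ok) == 0L) ok <- seq_len(ncol(m))
    nref <- max(10L, ceiling(referenceFraction * length(ok)))
    ref <- ok[order(enc[ok])][seq_len(min(nref, length(ok)))]
    w <- caiWeights(m[, ref, drop = FALSE], code,
      description = sprintf(
        "self-reference: %d lowest-ENC genes (fraction %.3g)",
        length(ref), referenceFraction))
  } else {
    stopifnot(!is.null(referenceCounts))
    w <- caiWeights(referenceCounts, code,
      description = "external reference set")
  }

  if (is.null(optimalCodons)) {
    optimalCodons <- preferredCodons(rscu(x, pool = TRUE))$codons
    optProv <- "preferred codons (pooled RSCU > 1)"
  } else {
    optimalCodons <- chartr("T", "U", toupper(optimalCodons))
    optProv <- "user-supplied"
  }

  caiv <- cai(x, w)
  cf <- if (length(optimalCodons))
    cbiFop(x, optimalCodons, code)
  else
    data.frame(cbi = rep(NA_real_, ncol(m)), fop = NA_real_)

  mask <- function(v) { v[short] <- NA_real_; v }
  cd$lAa <- cd$totalCodons
  cd$encObs <- mask(enc)
  cd$encExp <- mask(encExp)
  cd$deviationRatio <- mask((encExp - enc) / encExp)
  cd$cai <- mask(caiv)
  cd$cbi <- mask(cf$cbi)
  cd$fop <- mask(cf$fop)
  SummarizedExperiment::colData(x) <- cd
  metadata(x)$caiWeights <- w
  metadata(x)$optimalCodons <- optimalCodons
  metadata(x)$optimalCodonProvenance <- optProv
  metadata(x)$minCodons <- as.integer(minCodons)
  x
}
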