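#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least-squares fit of per-gene GC12 (mean GC at codon positions
#' 1 and 2) on GC3, with Pearson correlation. A slope and correlation near
#' 1 indicate that a shared mutational pressure drives all three codon
#' positions; values near 0 indicate that selection pins positions 1-2
#' while position 3 drifts with composition.
#'
#' @param genes A data.frame with columns `gc12` and `gc3` (e.g.
#'   [geneStats()] after [addComposition()]), or a [CodonUsageSet-class].
#' @return A list of class `neutrality_fit` with `slope`, `intercept`,
#'   `r` (Pearson), `nGenes` and the plot-ready `table` (gene_id, gc3,
#'   gc12). A constant-GC3 input yields `NA` slope and `r`, flagged via
#'   `degenerate = TRUE`.
#' @export
neutralityFit <- function(genes) {
  if (is(genes, "CodonUsageSet")) genes <- geneStats(genes)
  df <- genes[stats::complete.cases(genes[, c("gc3", "gc12")]), ]
  if (nrow(df) < 3L)
    stop("need at least 3 genes with defined GC12 and GC3", call. = FALSE)
  degenerate <- stats::sd(df$gc3) == 0
  if (degenerate) {
    slope <- NA_real_; intercept <- mean(df$gc12); r <- NA_real_
  } else {
    fit <- stats::lm(gc12 ~ gc3, data = df)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r <- if (stats::sd(df$gc12) == 0) 0 else
      stats::cor(df$gc3, df$gc12)
  }
  structure(
    list(slope = slope, intercept = intercept, r = r,
      nGenes = nrow(df), degenerate = degenerate,
      table = df[, intersect(c("gene_id", "gc3", "gc12"), colnames(df))]),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (n = %d): GC12 = %.4f + %.4f * GC3, r = %.4f\n",
    x$nGenes, x$intercept, x$slope, x$r))
  invisible(x)
}

#' Canonical ENC deviation-ratio bin edges
#' @return Numeric vector of bin edges for [encDeviationSummary()].
#' @export
deviationBinEdges <- function() {
  c(-0.25, -0.15, -0.05, 0.05, 0.15, 0.25, 0.35)
}

#' Histogram of ENC deviation ratios
#'
#' Bins per-gene deviation ratios `(ENCexp - ENCobs) / ENCexp` into the
#' fixed edges `[-0.25, -0.15), [-0.15, -0.05), [-0.05, 0.05),
#' [0.05, 0.15), [0.15, 0.25), [0.25, 0.35]` (left-closed, right-open;
#' the last bin closed). Ratios outside the edges are tallied in
#' `nOutside`. Genes in the central bin `[-0.05, 0.05)` sit on or near
#' the expected ENC curve, i.e. are explained by composition alone.
#'
#' @param genes A data.frame with a `deviationRatio` column, a
#'   [CodonUsageSet-class] after [addCubIndices()], or a numeric vector
#'   of ratios.
#' @return A list of class `deviation_summary`: `table` (bin, frequency,
#'   proportion), `nOutside`, `nDefined` and `centralProportion` (share of
#'   defined ratios in `[-0.05, 0.05)`).
#' @export
encDeviationSummary <- function(genes) {
  if (is(genes, "CodonUsageSet")) genes <- geneStats(genes)
  ratio <- if (is.numeric(genes)) genes else genes$deviationRatio
  ratio <- ratio[!is.na(ratio)]
  edges <- deviationBinEdges()
  k <- length(edges) - 1L
  idx <- findInterval(ratio, edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= k
  freq <- tabulate(idx[inside], nbins = k)
  labs <- paste0("[", utils::head(edges, -1L), ", ", edges[-1L],
    c(rep(")", k - 1L), "]"))
  structure(
    list(
      table = data.frame(
        bin = labs, frequency = freq,
        proportion = if (length(ratio)) freq / length(ratio) else
          rep(NA_real_, k)
      ),
      nOutside = sum(!inside), nDefined = length(ratio),
      centralProportion = if (length(ratio))
        freq[3L] / length(ratio) else NA_real_
    ),
    class = "deviation_summary"
  )
}

#' @export
print.deviation_summary <- function(x, ...) {
  df <- x$table
  df$proportion <- sprintf("%.2f", df$proportion)
  print(df, row.names = FALSE)
  cat(sprintf("outside bins: %d of %d defined ratios\n",
    x$nOutside, x$nDefined))
  invisible(x)
}

#' Synonymous-permutation null for the ENC deviation ratio
#'
#' For each of `nPerm` permutations the gene's codons are resampled
#' uniformly at random within each synonymous family, conditional on the
#' family totals (a synonymous shuffle that preserves the amino-acid
#' sequence content). Observed ENC, GC3s, expected ENC and the deviation
#' ratio are recomputed on every draw, giving an empirical null for the
#' ratio under no codon preference, against which the observed ratio gets
#' a two-sided empirical p-value (with the add-one correction).
#'
#' @param counts Single-gene codon counts (named numeric vector).
#' @param code A [GeneticCode-class].
#' @param nPerm Number of permutations (>= 1); 5000 is the convention for
#'   reported tables.
#' @param seed Integer seed; the global RNG state is saved and restored.
#' @return A list with `observedRatio`, `null` (numeric of length
#'   `nPerm`, `NA` for draws with undefined ENC), `pValue` and `nPerm`,
#'   or `NULL` (with a warning) if the observed ENC is undefined.
#' @export
permutationNull <- function(counts, code = standardGeneticCode(),
                            nPerm = 5000L, seed = 1L) {
  stopifnot(nPerm >= 1L)
  m <- .asCountMatrix(counts)
  v <- m[, 1L]
  obsEnc <- encObserved(v, code)
  obsRatio <- (encExpected(gc3s(v, code)) - obsEnc) /
    encExpected(gc3s(v, code))
  if (is.na(obsEnc)) {
    warning("observed ENC undefined; permutation null skipped",
      call. = FALSE)
    return(NULL)
  }
  fams <- codonFamilies(code)
  fams <- fams[names(fams) != "*" & lengths(fams) >= 2L]
  famN <- vapply(fams, function(cod) sum(v[cod]), numeric(1L))
  fams <- fams[famN > 0]
  famN <- famN[famN > 0]

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  null <- vapply(seq_len(nPerm), function(b) {
    perm <- v
    for (i in seq_along(fams)) {
      cod <- fams[[i]]
      perm[cod] <- as.numeric(
        stats::rmultinom(1L, famN[[i]], rep(1 / length(cod), length(cod)))
      )
    }
    e <- encObserved(perm, code)
    if (is.na(e)) return(NA_real_)
    ee <- encExpected(gc3s(perm, code))
    (ee - e) / ee
  }, numeric(1L))

  ok <- null[!is.na(null)]
  p <- if (length(ok)) {
    lo <- (1 + sum(ok <= obsRatio)) / (1 + length(ok))
    hi <- (1 + sum(ok >= obsRatio)) / (1 + length(ok))
    min(1, 2 * min(lo, hi))
  } else NA_real_
  list(observedRatio = obsRatio, null = null, pValue = p,
    nPerm = as.integer(nPerm))
}

#' Classify genes by ENC bias strength
#'
#' Partition genes into the conventional strength classes: strong bias
#' (`ENC < 35`), moderate-to-weak bias (`35 <= ENC <= 50`, boundary values
#' inclusive) and very weak bias (`ENC > 50`).
#'
#' @param genes A data.frame with an `encObs` column, a
#'   [CodonUsageSet-class] after [addCubIndices()], or a numeric vector.
#' @return A list with `nStrong`, `nModerate`, `nWeak`, `nDefined` and a
#'   one-row `table` mirroring the conventional report layout.
#' @export
classifyEncStrength <- function(genes) {
  if (is(genes, "CodonUsageSet")) genes <- geneStats(genes)
  enc <- if (is.numeric(genes)) genes else genes$encObs
  enc <- enc[!is.na(enc)]
  out <- list(
    nStrong = sum(enc < 35),
    nModerate = sum(enc >= 35 & enc <= 50),
    nWeak = sum(enc > 50),
    nDefined = length(enc)
  )
  out$table <- data.frame(
    `ENC < 35` = out$nStrong, `35 <= ENC <= 50` = out$nModerate,
    `50 < ENC` = out$nWeak, check.names = FALSE
  )
  out
}

#' PR2 quadrant summary
#'
#' Counts genes per PR2 quadrant: Quadrant I is `pr2x > 0.5, pr2y > 0.5`
#' (G over C, A over U at third positions), numbering counter-clockwise.
#' Points with either coordinate exactly 0.5 fall in the `onAxis` bucket
#' and are excluded from quadrant counts (deterministic tie rule); genes
#' with undefined coordinates are excluded and counted.
#'
#' @param genes A data.frame with `pr2x`, `pr2y` columns or a
#'   [CodonUsageSet-class] after [addComposition()].
#' @return A list with `quadrants` (named integer Q1..Q4), `onAxis`,
#'   `nUndefined` and a plot-ready `table`.
#' @export
pr2QuadrantSummary <- function(genes) {
  if (is(genes, "CodonUsageSet")) genes <- geneStats(genes)
  x <- genes$pr2x; y <- genes$pr2y
  undef <- is.na(x) | is.na(y)
  xs <- x[!undef]; ys <- y[!undef]
  axis <- xs == 0.5 | ys == 0.5
  q <- integer(4L)
  q[1L] <- sum(!axis & xs > 0.5 & ys > 0.5)
  q[2L] <- sum(!axis & xs < 0.5 & ys > 0.5)
  q[3L] <- sum(!axis & xs < 0.5 & ys < 0.5)
  q[4L] <- sum(!axis & xs > 0.5 & ys < 0.5)
  names(q) <- paste0("Q", 1:4)
  list(
    quadrants = q, onAxis = sum(axis), nUndefined = sum(undef),
    table = data.frame(
      gene_id = if ("gene_id" %in% colnames(genes))
        genes$gene_id[!undef] else which(!undef),
      pr2x = xs, pr2y = ys, row.names = NULL
    )
  )
}

#' CAI-ENC association table
#'
#' Pairs per-gene CAI (x) with observed ENC (y) and reports Spearman and
#' Pearson correlations. Under translational selection the association is
#' negative: more-adapted genes use fewer codons.
#'
#' @param genes A data.frame with `cai`, `encObs` columns or a
#'   [CodonUsageSet-class] after [addCubIndices()].
#' @return A list with `table` (gene_id, cai, enc), `spearman`, `pearson`
#'   and `nGenes`. A constant margin flags the correlation `NA`.
#' @export
caiEncTable <- function(genes) {
  if (is(genes, "CodonUsageSet")) genes <- geneStats(genes)
  df <- genes[stats::complete.cases(genes[, c("cai", "encObs")]), ]
  sp <- pe <- NA_real_
  if (nrow(df) >= 3L && stats::sd(df$cai) > 0 && stats::sd(df$encObs) > 0) {
    sp <- stats::cor(df$cai, df$encObs, method = "spearman")
    pe <- stats::cor(df$cai, df$encObs, method = "pearson")
  }
  list(
    table = data.frame(
      gene_id = if ("gene_id" %in% colnames(df)) df$gene_id else
        seq_len(nrow(df)),
      cai = df$cai, enc = df$encObs, row.names = NULL
    ),
    spearman = sp, pearson = pe, nGenes = nrow(df)
  )
}

#' Cross-species RSCU heatmap matrix
#'
#' Lays out RSCU values for visual comparison across species: 16 rows for
#' the first two codon bases (AA, AC, ..., UU) and, for each species, four
#' columns for the third base (A, C, G, U) -- so `n` species give
#' `4 * n` value columns. Cells for stop codons are marked `"(-)"` and
#' non-synonymous codons (AUG, UGG) `"(+)"` in the companion `labels`
#' matrix; their values are `NA`. Row and column order are deterministic.
#'
#' @param tables Named list of per-species RSCU vectors
#'   (`rscu(x, pool = TRUE)`).
#' @return A list of class `rscu_heatmap` with numeric `values`
#'   (16 x 4n), character `labels` of the same shape, and `species`.
#' @export
rscuHeatmapMatrix <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)))
    names(tables) <- sprintf("species_%d", seq_along(tables))
  code <- standardGeneticCode()
  bases <- c("A", "C", "G", "U")
  first2 <- as.vector(t(outer(bases, bases, paste0)))
  cols <- as.vector(vapply(names(tables), function(s)
    paste(s, bases, sep = "."), character(4L)))
  vals <- matrix(NA_real_, 16L, length(cols),
    dimnames = list(first2, cols))
  labs <- matrix("", 16L, length(cols), dimnames = list(first2, cols))
  aa <- codonToAa(code)
  for (si in seq_along(tables)) {
    r <- tables[[si]]
    for (b in bases) {
      cn <- paste(names(tables)[si], b, sep = ".")
      for (f2 in first2) {
        codon <- paste0(f2, b)
        if (aa[[codon]] == "*") {
          labs[f2, cn] <- "(-)"
        } else if (codon %in% c("AUG", "UGG")) {
          labs[f2, cn] <- "(+)"
        } else {
          vals[f2, cn] <- unname(r[codon])
        }
      }
    }
  }
  structure(list(values = vals, labels = labs, species = names(tables)),
    class = "rscu_heatmap")
}
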