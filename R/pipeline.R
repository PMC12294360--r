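#' Run configuration for a single-species analysis
#'
#' Collects every knob of the per-species pipeline so a run is fully
#' reproducible from its serialized config alone ([runSpecies()] writes
#' it as `config.json` in the output directory). The conventional
#' thresholds (ENC strength cut-offs 35/50, RSCU > 1 for preferred
#' codons, the deviation-ratio bin edges) are fixed analysis constants
#' surfaced in the serialized config for the record, not options.
#'
#' @param fasta Path to the CDS FASTA file.
#' @param species Species label used in output tables.
#' @param outDir Output directory (created if needed).
#' @param policy A [cdsFilterPolicy()].
#' @param caiReference,referenceFraction,referenceFasta CAI reference
#'   mode: `"lowEnc"` self-reference (default) or `"external"` with a
#'   reference FASTA.
#' @param pr2SiteSet Passed to [addComposition()].
#' @param nPerm Permutations per gene for the deviation-ratio null; 0
#'   (default) reports only the direct per-gene ratios, which are always
#'   reported regardless.
#' @param seed Integer seed for the permutation null.
#' @return A list of class `run_config`.
#' @export
runConfig <- function(fasta, species, outDir,
                      policy = cdsFilterPolicy(),
                      caiReference = "lowEnc", referenceFraction = 0.05,
                      referenceFasta = NULL,
                      pr2SiteSet = "all_synonymous",
                      nPerm = 0L, seed = 1L) {
  structure(
    list(
      fasta = fasta, species = species, outDir = outDir,
      policy = policy, caiReference = caiReference,
      referenceFraction = referenceFraction,
      referenceFasta = referenceFasta, pr2SiteSet = pr2SiteSet,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      thresholds = list(
        encStrong = 35, encWeak = 50, preferredRscu = 1,
        deviationBins = deviationBinEdges()
      )
    ),
    class = "run_config"
  )
}

.writeTsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) sprintf("%.*f", digits, v))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Run the full single-species codon usage analysis
#'
#' Reads and filters the CDS FASTA, counts codons, computes per-gene
#' composition and bias indices, pools RSCU, calls preferred codons, and
#' writes the result bundle to `config$outDir`: per-gene tables (full
#' precision), species summaries shaped like the conventional report
#' tables (2-decimal variants alongside), the preferred-codon JSON, the
#' neutrality fit, the deviation-ratio histogram, the ENC strength
#' summary, the PR2 scatter and quadrant counts, the CAI-ENC table, a
#' filter log, and the serialized config. Reruns on unchanged input are
#' byte-identical.
#'
#' @param config A [runConfig()] list.
#' @return The result bundle, invisibly: a list with the
#'   [CodonUsageSet-class] and every summary object.
#' @export
runSpecies <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  cds <- readCdsFasta(config$fasta, config$policy)
  cu <- countCodons(cds)
  cu <- addComposition(cu, pr2SiteSet = config$pr2SiteSet)
  refCounts <- NULL
  mode <- if (config$caiReference == "external") "external" else "lowEnc"
  if (mode == "external") {
    stopifnot(!is.null(config$referenceFasta))
    refCounts <- countCodons(readCdsFasta(config$referenceFasta,
      config$policy))
  }
  cu <- addCubIndices(cu, caiReference = mode,
    referenceFraction = config$referenceFraction,
    referenceCounts = refCounts,
    minCodons = config$policy$minCodons)

  st <- geneStats(cu)
  pooled <- rscu(cu, pool = TRUE)
  pref <- preferredCodons(pooled)
  fit <- neutralityFit(st)
  dev <- encDeviationSummary(st)
  strength <- classifyEncStrength(st)
  pr2 <- pr2QuadrantSummary(st)
  caiEnc <- caiEncTable(st)

  perm <- NULL
  if (config$nPerm > 0L) {
    m <- codonCounts(cu)
    ok <- which(!is.na(st$encObs))
    perm <- data.frame(
      gene_id = st$gene_id[ok],
      observedRatio = NA_real_, pValue = NA_real_
    )
    for (i in seq_along(ok)) {
      pn <- permutationNull(m[, ok[[i]]], geneticCode(cu),
        nPerm = config$nPerm, seed = config$seed + ok[[i]])
      if (!is.null(pn)) {
        perm$observedRatio[[i]] <- pn$observedRatio
        perm$pValue[[i]] <- pn$pValue
      }
    }
  }

  summary2 <- data.frame(
    species = config$species,
    cbi = mean(st$cbi, na.rm = TRUE),
    fop = mean(st$fop, na.rm = TRUE),
    lAa = round(mean(st$lAa, na.rm = TRUE)),
    speciesComposition(cu, "gene_mean")[
      , c("gc1", "gc2", "gc3", "gcAll")]
  )
  summary3 <- data.frame(
    species = config$species,
    enc = mean(st$encObs, na.rm = TRUE),
    cai = mean(st$cai, na.rm = TRUE),
    strength$table, check.names = FALSE
  )
  summary4 <- as.data.frame(
    t(stats::setNames(dev$table$frequency, dev$table$bin)),
    optional = TRUE)
  summary4 <- cbind(data.frame(species = config$species), summary4)

  out <- function(f) file.path(config$outDir, f)
  .writeTsv(st, out("per_gene_stats.tsv"))
  .writeTsv(data.frame(codon = names(pooled), rscu = pooled,
    row.names = NULL), out("rscu_species.tsv"))
  .writeTsv(summary2, out("species_summary.tsv"))
  .writeTsv(summary2, out("species_summary_2dp.tsv"), digits = 2L)
  .writeTsv(summary3, out("enc_cai_summary.tsv"))
  .writeTsv(summary4, out("deviation_bins.tsv"))
  .writeTsv(dev$table, out("deviation_histogram.tsv"))
  .writeTsv(fit$table, out("neutrality_table.tsv"))
  .writeTsv(pr2$table, out("pr2_table.tsv"))
  .writeTsv(caiEnc$table, out("cai_enc_table.tsv"))
  .writeTsv(metadata(cds)$filterLog, out("filter_log.tsv"))
  if (!is.null(perm)) .writeTsv(perm, out("permutation_null.tsv"))
  jsonlite::write_json(
    list(codons = pref$codons, count = pref$count,
      endingBase = as.list(pref$endingBase)),
    out("preferred_codons.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
      nGenes = fit$nGenes),
    out("neutrality_fit.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(config[setdiff(names(config), "policy")],
      list(policy = unclass(config$policy),
        caiReferenceUsed = attr(metadata(cu)$caiWeights,
          "reference_description"),
        optimalCodonsUsed = metadata(cu)$optimalCodons,
        nRead = metadata(cds)$nRead, nKept = metadata(cds)$nKept)),
    out("config.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    species = config$species, cu = cu, stats = st, rscu = pooled,
    preferred = pref, neutrality = fit, deviation = dev,
    encStrength = strength, pr2 = pr2, caiEnc = caiEnc,
    permutation = perm,
    summaries = list(composition = summary2, encCai = summary3,
      deviationBins = summary4)
  ))
}

#' Cross-species comparison report
#'
#' Runs (or accepts) per-species bundles and writes a comparative report:
#' merged species summaries, per-species gene-level correlation matrices
#' among GC1/GC2/GC3/GCall, the pooled RSCU heatmap matrix (4 third-base
#' columns per species), and a preferred-codon comparison across species.
#'
#' @param configs A list of [runConfig()] objects (or ready bundles from
#'   [runSpecies()]). Species labels must be unique.
#' @param outDir Output directory for the comparison report.
#' @return The comparison bundle, invisibly.
#' @export
runCompare <- function(configs, outDir) {
  stopifnot(is.list(configs), length(configs) >= 2L)
  bundles <- lapply(configs, function(cf) {
    if (inherits(cf, "run_config")) runSpecies(cf) else cf
  })
  labels <- vapply(bundles, `[[`, character(1L), "species")
  if (anyDuplicated(labels))
    stop("species labels must be unique: ",
      paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  comp <- do.call(rbind, lapply(bundles, function(b)
    b$summaries$composition))
  encCai <- do.call(rbind, lapply(bundles, function(b)
    b$summaries$encCai))
  devBins <- do.call(rbind, lapply(bundles, function(b)
    b$summaries$deviationBins))

  gcCor <- do.call(rbind, lapply(bundles, function(b) {
    st <- b$stats
    m <- stats::cor(st[, c("gc1", "gc2", "gc3", "gcAll")],
      use = "pairwise.complete.obs")
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(
      species = b$species,
      var1 = rownames(m)[pairs[, 1L]], var2 = colnames(m)[pairs[, 2L]],
      r = m[pairs], row.names = NULL
    )
  }))

  heat <- rscuHeatmapMatrix(stats::setNames(
    lapply(bundles, `[[`, "rscu"), labels))
  heatDf <- data.frame(first_two = rownames(heat$values), heat$values,
    check.names = FALSE, row.names = NULL)

  prefDf <- do.call(rbind, lapply(bundles, function(b) data.frame(
    species = b$species, nPreferred = b$preferred$count,
    endAU = b$preferred$endingBase[["AU"]],
    endG = b$preferred$endingBase[["G"]],
    endC = b$preferred$endingBase[["C"]],
    codons = paste(b$preferred$codons, collapse = ","),
    row.names = NULL
  )))

  out <- function(f) file.path(outDir, f)
  .writeTsv(comp, out("species_composition.tsv"))
  .writeTsv(encCai, out("species_enc_cai.tsv"))
  .writeTsv(devBins, out("species_deviation_bins.tsv"))
  .writeTsv(gcCor, out("gc_correlations.tsv"))
  .writeTsv(heatDf, out("rscu_heatmap_matrix.tsv"))
  .writeTsv(prefDf, out("preferred_codons_by_species.tsv"))

  invisible(list(
    species = labels, bundles = bundles, composition = comp,
    encCai = encCai, gcCorrelations = gcCor, heatmap = heat,
    preferred = prefDf
  ))
}
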