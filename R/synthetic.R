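#' SyntheticSpec: parameters for the synthetic CDS generator
#'
#' Describes a set of coding sequences with known compositional and
#' selective structure, so every downstream statistic can be checked
#' against ground truth. Genes draw an amino-acid length, amino acids iid
#' from `aaFrequencies`, and each codon from its synonymous family with
#' probability proportional to a third-base composition weight (targeting
#' `gc3Target` at synonymous third positions exactly, family by family)
#' times `exp(selectionStrength)` for codons in `optimalSet` (exponential
#' tilting -- the simplest one-parameter selection mechanism with a
#' monotone ENC response). A terminal UAA stop is appended.
#'
#' Per-gene variation comes from a Beta-distributed GC3 driver with mean
#' `gc3Target` and standard deviation `gc3Spread`; `gc12Coupling` in
#' `[0, 1]` tilts each gene's amino-acid usage so that expected GC12
#' tracks the gene's driver with that slope, which makes the neutrality
#' regression slope/correlation tunable (coupling 1: mutation-pressure
#' regime, r near 1; coupling 0: selection regime, r near 0).
#'
#' @slot nGenes,lengthMean,lengthSd,minLength gene count and amino-acid
#'   length distribution (Gaussian, rounded, floored at `minLength`).
#' @slot aaFrequencies named numeric(20) summing to 1.
#' @slot gc3Target,gc3Spread mean and sd of the per-gene GC3 driver.
#' @slot selectionStrength non-negative tilt toward `optimalSet`
#'   (0 = mutation-only).
#' @slot optimalSet character; one favored codon per family by default.
#' @slot gc12Coupling real in `[0, 1]`.
#' @slot seed integer RNG seed.
#' @seealso [syntheticSpec()], [generateCdsSet()], [recoverySuite()]
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes = "integer", lengthMean = "numeric", lengthSd = "numeric",
    minLength = "integer", aaFrequencies = "numeric",
    gc3Target = "numeric", gc3Spread = "numeric",
    selectionStrength = "numeric", optimalSet = "character",
    gc12Coupling = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@aaFrequencies) != 20L ||
    abs(sum(object@aaFrequencies) - 1) > 1e-8 ||
    any(object@aaFrequencies < 0))
    msg <- c(msg, "aaFrequencies must be 20 non-negative values summing to 1")
  if (object@gc3Target < 0 || object@gc3Target > 1)
    msg <- c(msg, "gc3Target must lie in [0, 1]")
  if (object@selectionStrength < 0)
    msg <- c(msg, "selectionStrength must be >= 0")
  if (object@gc12Coupling < 0 || object@gc12Coupling > 1)
    msg <- c(msg, "gc12Coupling must lie in [0, 1]")
  if (object@lengthMean < object@minLength)
    msg <- c(msg, "lengthMean must be >= minLength")
  if (length(msg)) msg else TRUE
})

# default optimal set: one codon per synonymous family, preferring a
# U-ending codon, then A-ending (mimics the A/U preference typical of
# AT-rich insect transcriptomes)
.defaultOptimalSet <- function(code = standardGeneticCode()) {
  fams <- codonFamilies(code)
  fams <- fams[names(fams) != "*" & lengths(fams) >= 2L]
  vapply(fams, function(cod) {
    last <- substr(cod, 3L, 3L)
    if (any(last == "U")) cod[last == "U"][1L]
    else if (any(last == "A")) cod[last == "A"][1L]
    else cod[1L]
  }, character(1L), USE.NAMES = FALSE)
}

#' Construct a validated SyntheticSpec
#'
#' Defaults describe a desk-scale, ant-transcriptome-like set: 500 genes,
#' mean length 380 amino acids, uniform amino-acid usage, GC3 target 0.46
#' with spread 0.08, no selection, and GC12 coupling 0.3.
#'
#' @param nGenes,lengthMean,lengthSd,minLength,aaFrequencies,gc3Target,gc3Spread,selectionStrength,optimalSet,gc12Coupling,seed
#'   See [SyntheticSpec-class].
#' @return A [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(nGenes = 500L, lengthMean = 380, lengthSd = 120,
                          minLength = 50L, aaFrequencies = NULL,
                          gc3Target = 0.46, gc3Spread = 0.08,
                          selectionStrength = 0, optimalSet = NULL,
                          gc12Coupling = 0.3, seed = 1L) {
  code <- standardGeneticCode()
  if (is.null(aaFrequencies)) {
    aas <- setdiff(names(codonFamilies(code)), "*")
    aaFrequencies <- stats::setNames(rep(1 / 20, 20L), sort(aas))
  }
  if (is.null(optimalSet)) optimalSet <- .defaultOptimalSet(code)
  new("SyntheticSpec",
    nGenes = as.integer(nGenes), lengthMean = as.numeric(lengthMean),
    lengthSd = as.numeric(lengthSd), minLength = as.integer(minLength),
    aaFrequencies = aaFrequencies, gc3Target = as.numeric(gc3Target),
    gc3Spread = as.numeric(gc3Spread),
    selectionStrength = as.numeric(selectionStrength),
    optimalSet = chartr("T", "U", toupper(optimalSet)),
    gc12Coupling = as.numeric(gc12Coupling), seed = as.integer(seed)
  )
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    paste0("SyntheticSpec: %d genes, length ~N(%g, %g) aa, GC3 target ",
      "%.3f (spread %.3f)\n  selection strength %.2f on %d optimal ",
      "codons, GC12 coupling %.2f, seed %d\n"),
    object@nGenes, object@lengthMean, object@lengthSd, object@gc3Target,
    object@gc3Spread, object@selectionStrength, length(object@optimalSet),
    object@gc12Coupling, object@seed))
})

# per-family codon sampling weights for driver d and selection strength s:
# GC-ending codons share probability d, A/U-ending share 1 - d (before the
# exponential selection tilt), family by family
.familyWeights <- function(code, d, s, optimal) {
  fams <- codonFamilies(code)
  fams <- fams[names(fams) != "*"]
  lapply(fams, function(cod) {
    if (length(cod) == 1L) return(stats::setNames(1, cod))
    gc <- substr(cod, 3L, 3L) %in% c("G", "C")
    w <- numeric(length(cod))
    if (any(gc)) w[gc] <- d / sum(gc)
    if (any(!gc)) w[!gc] <- (1 - d) / sum(!gc)
    if (all(gc) || all(!gc)) w <- rep(1 / length(cod), length(cod))
    w <- w * exp(s * (cod %in% optimal))
    stats::setNames(w / sum(w), cod)
  })
}

# expected GC fraction at codon positions 1-2 per amino acid, under the
# given family weights
.aaGc12 <- function(weights) {
  vapply(weights, function(w) {
    cod <- names(w)
    gc12 <- (substr(cod, 1L, 1L) %in% c("G", "C")) +
      (substr(cod, 2L, 2L) %in% c("G", "C"))
    sum(w * gc12) / 2
  }, numeric(1L))
}

# exponential tilt of amino-acid frequencies achieving a target expected
# GC12; theta solved by uniroot, clamped at the achievable range
.tiltAaFreq <- function(f, gcAa, target) {
  f <- f[names(gcAa)]
  obj <- function(theta) {
    w <- f * exp(theta * gcAa)
    sum(w * gcAa) / sum(w) - target
  }
  lo <- obj(-60); hi <- obj(60)
  if (lo >= 0) theta <- -60
  else if (hi <= 0) theta <- 60
  else theta <- stats::uniroot(obj, c(-60, 60), tol = 1e-8)$root
  w <- f * exp(theta * gcAa)
  w / sum(w)
}

#' Generate a synthetic CDS set with ground truth
#'
#' Draws coding sequences under the generative model described in
#' [SyntheticSpec-class]. Output always passes the default
#' [readCdsFasta()] policy: in-frame, no ambiguity codes, a single
#' terminal stop. Byte-identical output for identical specs (the global
#' RNG state is saved and restored).
#'
#' @param spec A [SyntheticSpec-class].
#' @return A list with `sequences` (named
#'   [Biostrings::RNAStringSet-class], terminal UAA included) and `truth`:
#'   the spec, the per-gene data.frame (`gene_id`, `lengthAa`, `driver`,
#'   `expectedGc3s` -- the analytical GC3s expectation under that gene's
#'   codon-weight model), the optimal set and the base GC12 anchor.
#' @examples
#' sim <- generateCdsSet(syntheticSpec(nGenes = 5, seed = 42))
#' names(sim$truth$perGene)
#' @export
generateCdsSet <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  code <- standardGeneticCode()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)

  n <- spec@nGenes
  len <- pmax(spec@minLength,
    as.integer(round(stats::rnorm(n, spec@lengthMean, spec@lengthSd))))

  # per-gene GC3 driver
  mu <- spec@gc3Target
  v <- min(spec@gc3Spread^2, 0.9 * mu * (1 - mu))
  d <- if (v <= 0) rep(mu, n) else {
    k <- mu * (1 - mu) / v - 1
    stats::rbeta(n, mu * k, (1 - mu) * k)
  }
  d <- pmin(pmax(d, 1e-4), 1 - 1e-4)

  # GC12 anchor: expected GC12 under untilted aa usage at the mean driver
  w0 <- .familyWeights(code, mu, spec@selectionStrength, spec@optimalSet)
  gcAa <- .aaGc12(w0)
  f0 <- spec@aaFrequencies[names(gcAa)]
  baseGc12 <- sum(f0 * gcAa) / sum(f0)

  syn <- names(codonFamilies(code))[
    lengths(codonFamilies(code)) >= 2L &
      names(codonFamilies(code)) != "*"]

  seqs <- character(n)
  expGc3s <- numeric(n)
  for (g in seq_len(n)) {
    wts <- .familyWeights(code, d[[g]], spec@selectionStrength,
      spec@optimalSet)
    target12 <- baseGc12 + spec@gc12Coupling * (d[[g]] - mu)
    f <- .tiltAaFreq(spec@aaFrequencies, .aaGc12(wts), target12)
    aas <- sample(names(f), len[[g]], replace = TRUE, prob = f)
    codons <- character(len[[g]])
    for (a in unique(aas)) {
      pos <- which(aas == a)
      w <- wts[[a]]
      codons[pos] <- if (length(w) == 1L) names(w) else
        sample(names(w), length(pos), replace = TRUE, prob = w)
    }
    seqs[[g]] <- paste0(paste(codons, collapse = ""), "UAA")
    pGc <- vapply(wts[syn], function(w)
      sum(w[substr(names(w), 3L, 3L) %in% c("G", "C")]), numeric(1L))
    expGc3s[[g]] <- sum(f[syn] * pGc) / sum(f[syn])
  }
  ids <- sprintf("synth_%05d", seq_len(n))
  out <- Biostrings::RNAStringSet(stats::setNames(seqs, ids))
  list(
    sequences = out,
    truth = list(
      spec = spec,
      perGene = data.frame(gene_id = ids, lengthAa = len, driver = d,
        expectedGc3s = expGc3s, row.names = NULL),
      optimalSet = spec@optimalSet,
      baseGc12 = baseGc12
    )
  )
}

#' Write a synthetic CDS set to FASTA with a truth sidecar
#'
#' @param sim Result of [generateCdsSet()].
#' @param fasta Output FASTA path.
#' @param truthJson Optional path for a JSON ground-truth sidecar.
#' @return `fasta`, invisibly.
#' @export
writeCdsSet <- function(sim, fasta, truthJson = NULL) {
  Biostrings::writeXStringSet(sim$sequences, fasta)
  if (!is.null(truthJson)) {
    sp <- sim$truth$spec
    jsonlite::write_json(
      list(
        nGenes = sp@nGenes, gc3Target = sp@gc3Target,
        gc3Spread = sp@gc3Spread,
        selectionStrength = sp@selectionStrength,
        gc12Coupling = sp@gc12Coupling, seed = sp@seed,
        optimalSet = sp@optimalSet, baseGc12 = sim$truth$baseGc12,
        perGene = sim$truth$perGene
      ),
      truthJson, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(fasta)
}

#' Parameter-recovery suite over a grid of synthetic specs
#'
#' Runs the full pipeline (generate, count, composition, ENC, pooled
#' RSCU) on each spec and evaluates recovery checks: realized mean GC3s
#' within 3 standard errors of its analytical expectation; mean ENC
#' strictly decreasing in selection strength (across specs differing only
#' in strength); neutrality correlation increasing in GC12 coupling; and
#' the optimal set contained in the preferred-codon call at the highest
#' strength in the grid.
#'
#' @param specGrid A list of [SyntheticSpec-class] objects.
#' @return A list with `perSpec` (one row per spec: parameters, realized
#'   and expected GC3s with its standard error, mean ENC, neutrality r,
#'   preferred-codon count, optimal-set recovery) and `checks`
#'   (data.frame of pass/fail rows).
#' @export
recoverySuite <- function(specGrid) {
  stopifnot(is.list(specGrid), length(specGrid) >= 1L)
  rows <- lapply(specGrid, function(sp) {
    sim <- generateCdsSet(sp)
    cu <- countCodons(sim$sequences)
    cu <- addComposition(cu)
    st <- geneStats(cu)
    enc <- encObserved(cu)
    fit <- neutralityFit(st)
    pref <- preferredCodons(rscu(cu, pool = TRUE))
    g <- st$gc3s
    data.frame(
      nGenes = sp@nGenes, gc3Target = sp@gc3Target,
      selectionStrength = sp@selectionStrength,
      gc12Coupling = sp@gc12Coupling, seed = sp@seed,
      meanGc3s = mean(g, na.rm = TRUE),
      expectedGc3s = mean(sim$truth$perGene$expectedGc3s),
      seGc3s = stats::sd(g, na.rm = TRUE) / sqrt(sum(!is.na(g))),
      meanEnc = mean(enc, na.rm = TRUE),
      neutralityR = fit$r,
      nPreferred = pref$count,
      optimalRecovered = all(sp@optimalSet %in% pref$codons)
    )
  })
  perSpec <- do.call(rbind, rows)

  checks <- list()
  dev <- abs(perSpec$meanGc3s - perSpec$expectedGc3s)
  checks[["gc3_recovery_within_3se"]] <- all(dev <= 3 * perSpec$seGc3s)
  key <- interaction(perSpec$gc3Target, perSpec$gc12Coupling, drop = TRUE)
  mono <- vapply(split(perSpec, key), function(grp) {
    grp <- grp[order(grp$selectionStrength), ]
    if (nrow(grp) < 2L) return(NA)
    all(diff(grp$meanEnc) < 0)
  }, logical(1L))
  checks[["enc_monotone_in_strength"]] <-
    if (all(is.na(mono))) NA else all(mono, na.rm = TRUE)
  keyR <- interaction(perSpec$gc3Target, perSpec$selectionStrength,
    drop = TRUE)
  incr <- vapply(split(perSpec, keyR), function(grp) {
    grp <- grp[order(grp$gc12Coupling), ]
    if (nrow(grp) < 2L) return(NA)
    all(diff(grp$neutralityR) > 0)
  }, logical(1L))
  checks[["neutrality_r_increasing_in_coupling"]] <-
    if (all(is.na(incr))) NA else all(incr, na.rm = TRUE)
  hi <- which.max(perSpec$selectionStrength)
  checks[["optimal_set_recovered_at_max_strength"]] <-
    if (max(perSpec$selectionStrength) > 0)
      perSpec$optimalRecovered[hi] else NA
  list(
    perSpec = perSpec,
    checks = data.frame(
      check = names(checks),
      pass = unlist(checks, use.names = FALSE)
    )
  )
}
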