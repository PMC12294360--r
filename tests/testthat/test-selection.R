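test_that("neutrality fit recovers the identity and degenerate cases", {
  df <- data.frame(gene_id = letters[1:6],
    gc3 = seq(0.2, 0.7, by = 0.1))
  df$gc12 <- df$gc3
  fit <- neutralityFit(df)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_identical(fit$nGenes, 6L)

  flat <- df; flat$gc12 <- 0.4
  f2 <- neutralityFit(flat)
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_equal(f2$r, 0)

  const <- df; const$gc3 <- 0.5
  f3 <- neutralityFit(const)
  expect_true(f3$degenerate)
  expect_true(is.na(f3$slope))

  expect_error(neutralityFit(df[1:2, ]), "at least 3")
})

test_that("coupling regimes separate neutrality correlations", {
  r_of <- function(coupling, seed) {
    sim <- generateCdsSet(syntheticSpec(nGenes = 120, lengthMean = 250,
      lengthSd = 30, gc12Coupling = coupling, seed = seed))
    neutralityFit(addComposition(countCodons(sim$sequences)))$r
  }
  r1 <- r_of(1, 41)
  r0 <- r_of(0, 42)
  expect_gt(r1, 0.8)
  expect_lt(abs(r0), 0.3)
})

test_that("deviation ratios bin on the fixed edges", {
  s <- encDeviationSummary(c(0, 0, 0))
  expect_equal(s$table$frequency, c(0, 0, 3, 0, 0, 0))
  expect_equal(s$centralProportion, 1)

  # (60 - 54) / 60 = 0.1 -> bin [0.05, 0.15)
  s2 <- encDeviationSummary((60 - 54) / 60)
  expect_equal(s2$table$frequency[4], 1)

  # enc_obs > enc_exp -> negative ratio, left of zero
  s3 <- encDeviationSummary((55 - 58) / 55)
  expect_equal(s3$table$frequency[2], 1)

  # boundary handling: left-closed bins, last bin closed, outside tallied
  s4 <- encDeviationSummary(c(-0.25, -0.05, 0.05, 0.35, 0.36, -0.26))
  expect_equal(s4$table$frequency, c(1, 0, 1, 1, 0, 1))
  expect_identical(s4$nOutside, 2L)
  expect_identical(s4$nDefined, 6L)
  # conservation: bins plus outside partition the defined set
  expect_equal(sum(s4$table$frequency) + s4$nOutside, s4$nDefined)
})

test_that("ENC strength classes use inclusive moderate boundaries", {
  s <- classifyEncStrength(c(20, 40, 55))
  expect_equal(c(s$nStrong, s$nModerate, s$nWeak), c(1, 1, 1))
  expect_equal(classifyEncStrength(35)$nModerate, 1)
  expect_equal(classifyEncStrength(50)$nModerate, 1)
  expect_equal(classifyEncStrength(34.999)$nStrong, 1)
  expect_equal(classifyEncStrength(50.001)$nWeak, 1)
  s2 <- classifyEncStrength(c(NA, 35, 50, 61))
  expect_identical(s2$nDefined, 3L)
  expect_equal(s2$nStrong + s2$nModerate + s2$nWeak, s2$nDefined)
})

test_that("PR2 quadrants follow the tie rule", {
  df <- data.frame(
    gene_id = 1:6,
    pr2x = c(0.6, 0.4, 0.4, 0.6, 0.5, NA),
    pr2y = c(0.6, 0.6, 0.4, 0.4, 0.7, 0.5)
  )
  q <- pr2QuadrantSummary(df)
  expect_equal(unname(q$quadrants), c(1, 1, 1, 1))
  expect_identical(q$onAxis, 1L)
  expect_identical(q$nUndefined, 1L)
  allaxis <- data.frame(pr2x = rep(0.5, 3), pr2y = rep(0.5, 3))
  q2 <- pr2QuadrantSummary(allaxis)
  expect_equal(sum(q2$quadrants), 0)
  expect_identical(q2$onAxis, 3L)
})

test_that("U/C-skewed third positions concentrate in quadrant III", {
  sim <- generateCdsSet(syntheticSpec(nGenes = 80, lengthMean = 200,
    lengthSd = 20, seed = 12))
  cu <- countCodons(sim$sequences)
  m <- codonCounts(cu)
  # push counts toward U- and C-ending codons within each family
  third <- substr(rownames(m), 3, 3)
  m[third %in% c("U", "C"), ] <- m[third %in% c("U", "C"), ] * 4L
  q <- pr2QuadrantSummary(pr2Coordinates(m))
  expect_gt(q$quadrants[["Q3"]], sum(q$quadrants[c("Q1", "Q2", "Q4")]))
})

test_that("CAI-ENC table reports rank correlation and flags constants", {
  df <- data.frame(gene_id = 1:5, cai = c(0.1, 0.2, 0.3, 0.4, 0.5),
    encObs = c(60, 55, 50, 45, 40))
  tab <- caiEncTable(df)
  expect_equal(tab$spearman, -1)
  expect_identical(tab$nGenes, 5L)
  const <- df; const$cai <- 0.3
  expect_true(is.na(caiEncTable(const)$spearman))
})

test_that("permutation null is seed-deterministic and centred for uniform genes", {
  cnt <- uniform_counts(8)
  a <- permutationNull(cnt, nPerm = 50, seed = 7)
  b <- permutationNull(cnt, nPerm = 50, seed = 7)
  expect_identical(a$null, b$null)
  expect_identical(a$pValue, b$pValue)
  c2 <- permutationNull(cnt, nPerm = 50, seed = 8)
  expect_false(identical(a$null, c2$null))
  # a gene already uniform within families is typical under its own null
  qs <- stats::quantile(a$null, c(0.025, 0.975), na.rm = TRUE)
  expect_gte(a$observedRatio, qs[[1]])
  expect_lte(a$observedRatio, qs[[2]])
  expect_gt(a$pValue, 0.05)
  # single draw with a fixed seed is reproducible
  d1 <- permutationNull(cnt, nPerm = 1, seed = 3)
  d2 <- permutationNull(cnt, nPerm = 1, seed = 3)
  expect_identical(d1$null, d2$null)
  expect_warning(permutationNull(c(AAA = 3, AAG = 1), nPerm = 5),
    "undefined")
})

test_that("mutation-only genes sit nearer the expected curve than selected ones", {
  frac_central <- function(strength, seed) {
    sim <- generateCdsSet(syntheticSpec(nGenes = 80, lengthMean = 200,
      lengthSd = 20, selectionStrength = strength, seed = seed))
    cu <- addCubIndices(addComposition(countCodons(sim$sequences)))
    encDeviationSummary(geneStats(cu))$centralProportion
  }
  expect_gt(frac_central(0, 61), frac_central(4, 62))
})

test_that("heatmap matrix has the documented layout", {
  uni <- rscu(uniform_counts())
  h1 <- rscuHeatmapMatrix(list(sp1 = uni))
  expect_identical(dim(h1$values), c(16L, 4L))
  expect_equal(unname(h1$values[!is.na(h1$values)]), rep(1, 59))
  expect_identical(sum(h1$labels == "(-)"), 3L)
  expect_identical(sum(h1$labels == "(+)"), 2L)
  expect_true(is.na(h1$values["UA", "sp1.A"]))  # UAA is a stop

  lys <- rscu(c(AAA = 3, AAG = 1))
  h2 <- rscuHeatmapMatrix(list(s = lys))
  expect_equal(h2$values["AA", "s.A"], 1.5)
  expect_equal(h2$values["AA", "s.G"], 0.5)

  tabs <- stats::setNames(rep(list(uni), 8), paste0("sp", 1:8))
  h8 <- rscuHeatmapMatrix(tabs)
  expect_identical(ncol(h8$values), 32L)
  expect_identical(rownames(h8$values)[1:4], c("AA", "AC", "AG", "AU"))
})
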