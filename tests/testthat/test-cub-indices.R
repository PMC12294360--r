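test_that("RSCU matches hand-computed families and conserves sums", {
  r <- rscu(c(UUA = 2, UUG = 4))
  leu <- synonymousFamily(standardGeneticCode(), "UUA")
  expect_equal(unname(r["UUA"]), 2)
  expect_equal(unname(r["UUG"]), 4)
  expect_equal(unname(r[setdiff(leu, c("UUA", "UUG"))]), rep(0, 4))

  r2 <- rscu(c(AAA = 3, AAG = 1))
  expect_equal(unname(r2[c("AAA", "AAG")]), c(1.5, 0.5))

  # uniform usage: RSCU exactly 1 on all 59 analysis codons
  r3 <- rscu(uniform_counts())
  expect_length(r3, 59L)
  expect_equal(unname(r3), rep(1, 59))

  # family-sum conservation for fully observed families
  set.seed(21)
  code <- standardGeneticCode()
  for (i in 1:10) {
    cnt <- stats::setNames(rpois(59, 5) + 1L, analysisCodons(code))
    rr <- rscu(cnt)
    aa <- codonToAa(code)[names(rr)]
    sums <- tapply(rr, aa, sum)
    sizes <- lengths(codonFamilies(code))[names(sums)]
    expect_equal(as.vector(sums), unname(sizes), tolerance = 1e-9)
  }

  # unobserved families are NA, not zero
  r4 <- rscu(c(AAA = 1, AAG = 1))
  expect_true(all(is.na(r4[c("GGA", "GGC", "GGG", "GGU")])))
})

test_that("ENC attains its limits", {
  expect_equal(encObserved(one_codon_per_family_counts()), 20)
  expect_equal(encObserved(uniform_counts()), 61)
})

test_that("ENC matches a hand-evaluated toy gene", {
  # Lys biased 3:1; all other families uniform with 12 per codon
  cnt <- uniform_counts(12)
  cnt["AAA"] <- 18; cnt["AAG"] <- 6
  # hand evaluation of the estimator:
  f_unif <- function(c0, k) (c0 - 1) / (c0 * k - 1)
  fl <- (24 * ((18 / 24)^2 + (6 / 24)^2) - 1) / 23
  f2 <- (fl + 8 * f_unif(12, 2)) / 9
  f3 <- f_unif(12, 3)
  f4 <- f_unif(12, 4)
  f6 <- f_unif(12, 6)
  expect_equal(encObserved(cnt),
    min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61), tolerance = 1e-12)
})

test_that("ENC imputes a missing Ile class and handles short genes", {
  # no Ile observed: F3 imputed as (F2+F4)/2, ENC still defined
  cnt <- uniform_counts(10)
  cnt[c("AUA", "AUC", "AUU")] <- 0
  expect_false(is.na(encObserved(cnt)))
  # a gene with only Lys cannot support the 4- and 6-fold classes
  expect_true(is.na(encObserved(c(AAA = 3, AAG = 1))))
})

test_that("expected ENC curve evaluates the closed form", {
  expect_equal(encExpected(0.5), 60.5)
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(1), 32)
  # symmetry: f(s) and f(1-s) differ only by the linear term
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(encExpected(s) - s, encExpected(1 - s) - (1 - s))
  expect_error(encExpected(1.2), "0, 1")
})

test_that("CAI weights normalize within families and floor zeros", {
  w <- suppressWarnings(caiWeights(c(AAA = 3, AAG = 1)))
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3, tolerance = 1e-12)

  w2 <- suppressWarnings(caiWeights(c(AAA = 5)))
  expect_equal(unname(w2["AAG"]), 0.01)

  w3 <- caiWeights(uniform_counts())
  expect_equal(as.numeric(w3), rep(1, length(w3)))

  expect_warning(caiWeights(c(AAA = 2, AAG = 2)), "set to 1")
})

test_that("CAI is a geometric mean with the documented exclusions", {
  w <- caiWeights(uniform_counts())  # all weights 1
  expect_equal(cai(c(AAA = 10, GGG = 4), w), 1)

  # all weights equal to c -> CAI = c
  wc <- w
  code <- standardGeneticCode()
  wc[analysisCodons(code)] <- 0.37
  expect_equal(cai(c(AAA = 3, GGC = 9), wc), 0.37)

  # two codons with weights 1 and 0.25 -> sqrt(0.25)
  wmix <- w
  wmix["AAG"] <- 0.25
  expect_equal(cai(c(AAA = 1, AAG = 1), wmix), 0.5)

  # Met/Trp-only gene has no eligible codons
  expect_true(is.na(cai(c(AUG = 5, UGG = 2), w)))
})

test_that("CBI and FOP match hand computation", {
  cf <- cbiFop(c(AAA = 3, AAG = 1), optimal = "AAA")
  expect_equal(cf$fop, 0.75)
  expect_equal(cf$cbi, 0.5)

  opt <- cubkit:::.defaultOptimalSet(standardGeneticCode())
  all_opt <- stats::setNames(rep(7, length(opt)), opt)
  cf2 <- cbiFop(all_opt, optimal = opt)
  expect_equal(cf2$fop, 1)
  expect_equal(cf2$cbi, 1)

  cf3 <- cbiFop(uniform_counts(), optimal = opt)
  expect_equal(cf3$cbi, 0)
  expect_error(cbiFop(c(AAA = 1), optimal = "UAA"))
})

test_that("preferred codons use strict RSCU > 1", {
  expect_identical(preferredCodons(rscu(uniform_counts()))$count, 0L)
  p <- preferredCodons(rscu(c(AAA = 3, AAG = 1)))
  expect_identical(p$codons, "AAA")
  expect_identical(unname(p$endingBase["AU"]), 1L)
  # synthetic A/U bias: preferred codons all end A or U
  sim <- generateCdsSet(syntheticSpec(nGenes = 40, gc3Target = 0.2,
    lengthMean = 200, lengthSd = 20, seed = 5))
  pr <- preferredCodons(rscu(countCodons(sim$sequences), pool = TRUE))
  last <- substr(pr$codons, 3, 3)
  expect_gt(pr$count, 0)
  expect_true(all(last %in% c("A", "U")))
})

test_that("RSCU and CAI are exactly invariant to count scaling", {
  set.seed(33)
  w <- suppressWarnings(caiWeights(c(AAA = 6, AAG = 2, UUA = 4, UUG = 1)))
  for (i in 1:5) {
    cnt <- random_count_table()
    for (k in c(2L, 5L)) {
      expect_equal(rscu(cnt * k), rscu(cnt))
      expect_equal(cai(cnt * k, w), cai(cnt, w), tolerance = 1e-12)
    }
  }
})

test_that("ENC scaling effect vanishes with depth", {
  # the homozygosity estimator carries a finite-sample correction, so
  # ENC is only asymptotically scale-invariant: the shift must shrink
  # as counts grow and be negligible at realistic depth
  set.seed(34)
  cnt <- random_count_table() + 40
  shift_small <- abs(encObserved(cnt * 2L) - encObserved(cnt))
  tiny <- pmax(random_count_table(), 1)
  shift_tiny <- abs(encObserved(tiny * 2L) - encObserved(tiny))
  expect_lt(shift_small, 0.5)
  if (!is.na(shift_tiny)) expect_lt(shift_small, shift_tiny + 1e-9)
})

test_that("ENC decreases monotonically with selection strength", {
  encs <- vapply(c(0, 1, 2, 4), function(s) {
    sim <- generateCdsSet(syntheticSpec(nGenes = 60, lengthMean = 250,
      lengthSd = 30, selectionStrength = s, seed = 100 + s))
    mean(encObserved(countCodons(sim$sequences)), na.rm = TRUE)
  }, numeric(1L))
  expect_true(all(diff(encs) < 0))
})

test_that("rscu, enc and cai agree with brute-force oracles", {
  set.seed(99)
  w <- suppressWarnings(caiWeights(c(
    AAA = 6, AAG = 2, GGA = 3, GGC = 1, GGG = 1, GGU = 1,
    UUA = 4, UUG = 1)))
  for (i in 1:100) {
    cnt <- random_count_table()
    ref <- oracle_rscu(cnt)
    got <- rscu(cnt)[names(ref)]
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
    expect_equal(encObserved(cnt), oracle_enc(cnt), tolerance = 1e-9)
    expect_equal(cai(cnt, w), oracle_cai(cnt, w), tolerance = 1e-9)
  }
})

test_that("addCubIndices populates per-gene indices coherently", {
  sim <- generateCdsSet(syntheticSpec(nGenes = 50, lengthMean = 150,
    lengthSd = 20, seed = 8))
  cu <- addCubIndices(addComposition(countCodons(sim$sequences)))
  st <- geneStats(cu)
  ok <- !is.na(st$encObs)
  expect_true(any(ok))
  expect_true(all(st$encObs[ok] >= 20 & st$encObs[ok] <= 61))
  expect_true(all(st$cai >= 0 & st$cai <= 1, na.rm = TRUE))
  expect_true(all(st$fop >= 0 & st$fop <= 1, na.rm = TRUE))
  expect_true(all(st$cbi >= -1 & st$cbi <= 1, na.rm = TRUE))
  expect_equal(st$deviationRatio[ok],
    (st$encExp[ok] - st$encObs[ok]) / st$encExp[ok])
  # short genes get NA indices
  cu2 <- suppressWarnings(addCubIndices(addComposition(countCodons(
    c(tiny = "AUGAAAUAA"))), minCodons = 30L))
  expect_true(is.na(geneStats(cu2)$encObs))
})
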