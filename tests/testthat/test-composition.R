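test_that("positional GC matches hand-computed cases", {
  g <- positionalGC(c(AUG = 5))
  expect_equal(g$gc1, 0)
  expect_equal(g$gc2, 0)
  expect_equal(g$gc3, 1)
  expect_equal(g$gcAll, 1 / 3)
  expect_equal(g$gc12, 0)

  g2 <- positionalGC(c(GCG = 4))
  expect_equal(unlist(g2[, c("gc1", "gc2", "gc3", "gcAll")]),
    c(gc1 = 1, gc2 = 1, gc3 = 1, gcAll = 1))

  g3 <- positionalGC(c(AAA = 1, GGG = 1))
  expect_equal(unlist(g3[, c("gc1", "gc2", "gc3", "gcAll", "gc12")]),
    c(gc1 = 0.5, gc2 = 0.5, gc3 = 0.5, gcAll = 0.5, gc12 = 0.5))
})

test_that("gc12 is exactly the mean of gc1 and gc2", {
  set.seed(11)
  for (i in 1:10) {
    cnt <- random_count_table()
    g <- positionalGC(cnt)
    expect_identical(g$gc12, (g$gc1 + g$gc2) / 2)
  }
})

test_that("gc3s excludes non-degenerate amino acids", {
  expect_true(is.na(gc3s(c(AUG = 10))))
  expect_equal(gc3s(c(AAA = 2, AAG = 2)), 0.5)
  expect_equal(gc3s(c(UUA = 1, UUG = 1, AUG = 7)), 0.5)
  # on a gene of only fourfold families, gc3s equals gc3 of those codons
  cnt <- c(GCA = 3, GCC = 2, GCG = 5, GCU = 1, GGA = 4, GGC = 2)
  expect_equal(gc3s(cnt), positionalGC(cnt)$gc3)
})

test_that("PR2 coordinates behave at parity, boundary and undefined", {
  p <- pr2Coordinates(c(GGU = 1, GGC = 1, GGA = 1, GGG = 1))
  expect_equal(c(p$pr2x, p$pr2y), c(0.5, 0.5))
  expect_identical(c(p$a3, p$u3, p$g3, p$c3), c(1, 1, 1, 1))

  b <- pr2Coordinates(c(GGG = 2, GGA = 1))
  expect_equal(b$pr2x, 1)

  # Lys only: no C3 or G3... AAA/AAG have G; no C -> pr2x = 1
  k <- pr2Coordinates(c(AAA = 2, AAG = 1))
  expect_equal(k$pr2x, 1)
  # Met only: no synonymous codons at all -> undefined
  m <- pr2Coordinates(c(AUG = 5))
  expect_true(is.na(m$pr2x) && is.na(m$pr2y))
})

test_that("third-position A<->U swap fixes pr2x and reflects pr2y", {
  swap3 <- function(cnt) {
    nm <- names(cnt)
    third <- substr(nm, 3, 3)
    third <- chartr("AU", "UA", third)
    swapped <- paste0(substr(nm, 1, 2), third)
    # keep only codons that remain in the same synonymous family
    code <- standardGeneticCode()
    aa <- codonToAa(code)
    ok <- aa[swapped] == aa[nm] & !is.na(aa[swapped])
    stats::setNames(as.numeric(cnt[ok]), swapped[ok])
  }
  # fourfold families: the swap always stays within family
  set.seed(3)
  for (i in 1:10) {
    base <- c("GC", "GG", "CC", "AC", "GU", "CU", "UC", "CG")
    cods <- as.vector(outer(base, c("A", "C", "G", "U"), paste0))
    cnt <- stats::setNames(rpois(length(cods), 4), cods)
    p1 <- pr2Coordinates(cnt)
    p2 <- pr2Coordinates(swap3(cnt))
    expect_equal(p2$pr2x, p1$pr2x)
    expect_equal(p2$pr2y, 1 - p1$pr2y)
  }
})

test_that("fourfold_only site set restricts to fourfold blocks", {
  # Lys (twofold) contributes under all_synonymous but not fourfold_only
  cnt <- c(AAA = 5, AAG = 5, GCA = 1, GCC = 1, GCG = 1, GCU = 1)
  all_sites <- pr2Coordinates(cnt, siteSet = "all_synonymous")
  ff <- pr2Coordinates(cnt, siteSet = "fourfold_only")
  expect_identical(ff$a3 + ff$u3 + ff$g3 + ff$c3, 4)
  expect_identical(all_sites$a3 + all_sites$u3 + all_sites$g3 +
    all_sites$c3, 14)
  # Leu CUN block is fourfold, UUA/UUG is not
  cnt2 <- c(CUA = 1, CUC = 1, CUG = 1, CUU = 1, UUA = 10, UUG = 10)
  ff2 <- pr2Coordinates(cnt2, siteSet = "fourfold_only")
  expect_identical(ff2$a3 + ff2$u3 + ff2$g3 + ff2$c3, 4)
})

test_that("addComposition stores per-gene columns on the set", {
  cu <- countCodons(c(a = "AUGAAAUAA", b = "GCGGCUCCCUAG"))
  cu <- addComposition(cu)
  st <- geneStats(cu)
  expect_true(all(c("gc1", "gc2", "gc3", "gc12", "gcAll", "gc3s",
    "pr2x", "pr2y") %in% colnames(st)))
  expect_equal(st$gc12, (st$gc1 + st$gc2) / 2)
  # third-position base counts partition the synonymous codons
  syn_total <- st$a3 + st$u3 + st$g3 + st$c3
  expect_true(all(syn_total <= st$totalCodons))
})

test_that("species composition aggregations are labelled and consistent", {
  cu <- addComposition(countCodons(c(a = "AAAAAAUAA", b = "GGGGGGUAG")))
  gm <- speciesComposition(cu, "gene_mean")
  cc <- speciesComposition(cu, "concatenated")
  expect_identical(gm$aggregation, "gene_mean")
  expect_identical(cc$aggregation, "concatenated")
  # equal-length genes: the two aggregations coincide for gcAll
  expect_equal(gm$gcAll, cc$gcAll)
  expect_equal(gm$gcAll, 50)
})
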