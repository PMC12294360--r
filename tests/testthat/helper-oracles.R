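# Independent brute-force oracles, written directly from the index
# definitions with explicit loops. They share nothing with the package
# implementation except the standard genetic code table itself, which is
# taken from Biostrings.

oracle_code_table <- function() {
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("T", "U", names(tab))
  tab
}

oracle_families <- function() {
  tab <- oracle_code_table()
  split(names(tab), unname(tab))
}

# RSCU_ij = X_ij / ((1/Ni) * sum_j X_ij), synonymous families only
oracle_rscu <- function(counts) {
  fams <- oracle_families()
  out <- c()
  for (aa in names(fams)) {
    if (aa == "*") next
    cods <- sort(fams[[aa]])
    if (length(cods) < 2) next
    x <- sapply(cods, function(cd) {
      if (cd %in% names(counts)) counts[[cd]] else 0
    })
    total <- sum(x)
    r <- if (total == 0) rep(NA_real_, length(x)) else
      x / (total / length(x))
    names(r) <- cods
    out <- c(out, r)
  }
  out
}

# Wright-style ENC with per-family homozygosity, class averages, the
# (F2+F4)/2 imputation for a missing 3-fold class, and clamping at 61
oracle_enc <- function(counts) {
  fams <- oracle_families()
  Fs <- list()
  sizes <- list()
  for (aa in names(fams)) {
    if (aa == "*") next
    cods <- fams[[aa]]
    if (length(cods) < 2) next
    x <- sapply(cods, function(cd) {
      if (cd %in% names(counts)) counts[[cd]] else 0
    })
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    Fs[[aa]] <- (n * sum(p^2) - 1) / (n - 1)
    sizes[[aa]] <- length(cods)
  }
  f_by_class <- function(k) {
    vals <- unlist(Fs[unlist(sizes) == k])
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  f2 <- f_by_class(2); f3 <- f_by_class(3)
  f4 <- f_by_class(4); f6 <- f_by_class(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (any(is.na(c(f2, f3, f4, f6))) || any(c(f2, f3, f4, f6) <= 0))
    return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# CAI as an explicit product over codons (excluding Met, Trp, stops)
oracle_cai <- function(counts, weights) {
  tab <- oracle_code_table()
  excl <- c("AUG", "UGG", names(tab)[tab == "*"])
  prod_w <- 1
  n <- 0
  for (cd in names(counts)) {
    if (cd %in% excl) next
    k <- counts[[cd]]
    if (k == 0) next
    prod_w <- prod_w * weights[[cd]]^k
    n <- n + k
  }
  if (n == 0) return(NA_real_)
  prod_w^(1 / n)
}

# random small codon-count table over a random subset of sense codons
random_count_table <- function() {
  tab <- oracle_code_table()
  sense <- names(tab)[tab != "*"]
  k <- sample(10:61, 1)
  cods <- sample(sense, k)
  stats::setNames(stats::rpois(k, lambda = 6), cods)
}
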