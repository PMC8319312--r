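# Shared fixtures and independent oracles, built in code.

loci1 <- function() locus_set(transgene_locus("ACOS", c("mCe", "mVe")))

loci2 <- function() {
  locus_set(
    transgene_locus("AGOC", c("mO", "mC")),
    transgene_locus("ACOS", c("mCe", "mVe"))
  )
}

# independent brute-force crossing oracle: enumerates all 4^L ordered
# transmissions (2 maternal x 2 paternal choices per locus) and accumulates
# double-precision probabilities per unordered class key. Shares nothing
# with the engine's gamete/cross path.
oracle_cross <- function(parent_a, parent_b) {
  ids <- names(parent_a$loci)
  L <- length(ids)
  rank_of <- function(a) {
    r <- match(a, c("mO", "mC", "mCe", "mVe"))
    r[a == "D"] <- 5L
    r[a == "+"] <- 6L
    r
  }
  choices <- expand.grid(rep(list(1:2), 2L * L), KEEP.OUT.ATTRS = FALSE)
  acc <- list()
  for (row in seq_len(nrow(choices))) {
    parts <- character(L)
    for (l in seq_len(L)) {
      a <- parent_a$alleles[[ids[[l]]]][[choices[row, 2L * l - 1L]]]
      b <- parent_b$alleles[[ids[[l]]]][[choices[row, 2L * l]]]
      pair <- c(a, b)
      pair <- pair[order(rank_of(pair))]
      parts[[l]] <- paste0(ids[[l]], ":", pair[[1]], "/", pair[[2]])
    }
    key <- paste(parts, collapse = ";")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 0.25^L
  }
  acc
}

# random genotype over a locus set (no dual alleles unless asked): used for
# property tests under a fixed seed
random_genotype <- function(loci, include_dual = TRUE) {
  alleles <- lapply(loci, function(lc) {
    pool <- c("+", lc$markers, if (include_dual && length(lc$markers) == 2L) "D")
    sample(pool, 2L, replace = TRUE)
  })
  names(alleles) <- names(loci)
  genotype(loci, alleles)
}

# compare an engine genotype_dist with an oracle list of key -> prob
expect_matches_oracle <- function(dist, oracle, tol = 1e-12) {
  expect_setequal(names(dist$p), names(oracle))
  for (key in names(oracle)) {
    expect_equal(unname(as.numeric(dist$p[key])), oracle[[key]], tolerance = tol)
  }
}
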