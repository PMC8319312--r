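# Exact model of alleles, Cre resolution, gametes, crossing and phenotype.

test_that("phenotype is the union of visible markers", {
  loci <- loci2()
  expect_identical(phenotype_of(wildtype_genotype(loci)), "wt")
  expect_identical(phenotype_of(genotype(loci, "AGOC:mO/mC")), "mO+mC")
  expect_identical(phenotype_of(genotype(loci, "AGOC:mO/mO;ACOS:mCe/mCe")), "mO+mCe")
  # dual cassette shows both markers of its pair
  expect_identical(phenotype_of(genotype(loci, "AGOC:D/+")), "mO+mC")
  # invariant under maternal/paternal swap at every locus
  g1 <- genotype(loci, list(AGOC = c("mO", "mC"), ACOS = c("+", "mVe")))
  g2 <- genotype(loci, list(AGOC = c("mC", "mO"), ACOS = c("mVe", "+")))
  expect_identical(phenotype_of(g1), phenotype_of(g2))
  expect_identical(genotype_class(g1), genotype_class(g2))
})

test_that("zygosity distinguishes wild type, hemi-, hetero- and homozygotes", {
  loci <- loci1()
  expect_identical(classify_zygosity(genotype(loci, ""), "ACOS"), "wildtype")
  expect_identical(classify_zygosity(genotype(loci, "ACOS:mCe/+"), "ACOS"), "hemizygous")
  expect_identical(classify_zygosity(genotype(loci, "ACOS:mCe/mVe"), "ACOS"), "heterozygous")
  expect_identical(classify_zygosity(genotype(loci, "ACOS:mVe/mVe"), "ACOS"), "homozygous")
  # dual/dual alleles carry identical marker sets: homozygous
  expect_identical(classify_zygosity(genotype(loci, "ACOS:D/D"), "ACOS"), "homozygous")
  # dual/single differ in marker content: heterozygous
  expect_identical(classify_zygosity(genotype(loci, "ACOS:D/mCe"), "ACOS"), "heterozygous")
})

test_that("Cre resolution splits dual alleles and leaves others alone", {
  agoc <- transgene_locus("AGOC", c("mO", "mC"))
  full <- cre_resolve("D", agoc, efficiency = 1)
  expect_setequal(full$allele, c("mO", "mC"))
  expect_true(all(full$p == rational(1, 2)))
  expect_true(sum(full$p) == rational(1))
  none <- cre_resolve("D", agoc, efficiency = 0)
  expect_identical(none$allele, "D")
  part <- cre_resolve("D", agoc, efficiency = "3/4")
  expect_true(part$p[part$allele == "D"] == rational(1, 4))
  expect_true(sum(part$p) == rational(1))
  single <- cre_resolve("mCe", transgene_locus("ACOS", c("mCe", "mVe")))
  expect_identical(single$allele, "mCe")
  expect_true(single$p == rational(1))
  expect_error(cre_resolve("D", agoc, efficiency = 1.5), "efficiency")
})

test_that("gamete formation obeys Mendel's first law and independent assortment", {
  loci <- loci1()
  het <- genotype(loci, "ACOS:mCe/mVe")
  g <- gametes(het)
  expect_length(g$haplotypes, 2L)
  expect_true(all(g$p == rational(1, 2)))
  homo <- gametes(genotype(loci, "ACOS:mCe/mCe"))
  expect_length(homo$haplotypes, 1L)
  expect_true(homo$p == rational(1))
  dhet <- genotype(loci2(), "AGOC:mO/mC;ACOS:mCe/mVe")
  g2 <- gametes(dhet)
  expect_length(g2$haplotypes, 4L)
  expect_true(all(g2$p == rational(1, 4)))
  expect_true(sum(g2$p) == rational(1))
})

test_that("hemizygote sibling cross yields the classic 1/4, 1/2, 1/4", {
  loci <- loci1()
  hemi <- genotype(loci, "ACOS:mCe/+")
  d <- cross(hemi, hemi)
  expect_equal(count_genotype_classes(d), 3L)
  expect_true(d$p["ACOS:mCe/mCe"] == rational(1, 4))
  expect_true(d$p["ACOS:mCe/+"] == rational(1, 2))
  expect_true(d$p["ACOS:+/+"] == rational(1, 4))
})

test_that("two-locus crosses reproduce the exact textbook counts", {
  loci <- loci2()
  # double hemizygote sibling cross: nine genotype classes
  dh <- genotype(loci, "AGOC:mO/+;ACOS:mCe/+")
  expect_equal(count_genotype_classes(cross(dh, dh)), 9L)
  # homozygote x homozygote: a single class, 100% of progeny
  a <- genotype(loci, "AGOC:mO/mO;ACOS:mCe/mCe")
  b <- genotype(loci, "AGOC:mC/mC;ACOS:mVe/mVe")
  d <- cross(a, b)
  expect_equal(count_genotype_classes(d), 1L)
  expect_true(d$p["AGOC:mO/mC;ACOS:mCe/mVe"] == rational(1))
  # double heterozygote sibling cross: each double homozygote at 1/16
  dhet <- genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe")
  dd <- cross(dhet, dhet)
  expect_true(dd$p["AGOC:mO/mO;ACOS:mCe/mCe"] == rational(1, 16))
  expect_true(sum(dd$p) == rational(1))
})

test_that("cross is symmetric in parent order and matches the brute-force oracle", {
  set.seed(42)
  loci3 <- locus_set(
    transgene_locus("AGOC", c("mO", "mC")),
    transgene_locus("ACOS", c("mCe", "mVe")),
    transgene_locus("FIRE", "mO") # marker reuse is fine for pure segregation
  )
  locus_sets <- list(loci1(), loci2(), loci3)
  for (i in 1:60) {
    loci <- locus_sets[[1 + (i %% length(locus_sets))]]
    pa <- random_genotype(loci)
    pb <- random_genotype(loci)
    ab <- cross(pa, pb)
    ba <- cross(pb, pa)
    expect_setequal(names(ab$p), names(ba$p))
    for (key in names(ab$p)) expect_true(ab$p[key] == ba$p[key])
    expect_true(sum(ab$p) == rational(1))
    expect_matches_oracle(ab, oracle_cross(pa, pb))
  }
})

test_that("mismatched locus sets and invalid alleles are rejected", {
  expect_error(cross(genotype(loci1(), ""), genotype(loci2(), "")),
               "configuration error")
  expect_error(genotype(loci1(), "ACOS:mO/+"), "invalid allele")
  expect_error(genotype(loci1(), list(ACOS = "mCe")), "two alleles")
  # helper locus has one marker: no dual allele possible
  helper <- locus_set(transgene_locus("FIRE", "mC"))
  expect_error(genotype(helper, "FIRE:D/+"), "invalid allele")
})

test_that("Cre-active crosses resolve transmitted dual alleles", {
  loci <- loci1()
  master <- genotype(loci, "ACOS:D/+")
  d <- cross(master, wildtype_genotype(loci), cre_active = TRUE, efficiency = 1)
  expect_true(d$p["ACOS:mCe/+"] == rational(1, 4))
  expect_true(d$p["ACOS:mVe/+"] == rational(1, 4))
  expect_true(d$p["ACOS:+/+"] == rational(1, 2))
  expect_false("ACOS:D/+" %in% names(d$p))
  partial <- cross(master, wildtype_genotype(loci), cre_active = TRUE, efficiency = "1/2")
  expect_true(partial$p["ACOS:D/+"] == rational(1, 4))
  expect_true(sum(partial$p) == rational(1))
})
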