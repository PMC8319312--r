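# Scheme propagation, selection, identifiability, testcrosses, collisions.

test_that("phenotype distribution is the exact pushforward of the genotype distribution", {
  loci <- loci2()
  # double hemizygote sibling cross: both markers visible in 9/16 of progeny
  dh <- genotype(loci, "AGOC:mO/+;ACOS:mCe/+")
  pd <- phenotype_distribution(cross(dh, dh))
  expect_true(pd["mO+mCe"] == rational(9, 16))
  expect_true(sum(pd) == rational(1))
  # degenerate cases
  expect_identical(names(phenotype_distribution(as_genotype_dist(wildtype_genotype(loci)))), "wt")
  a <- genotype(loci, "AGOC:mO/mO;ACOS:mCe/mCe")
  b <- genotype(loci, "AGOC:mC/mC;ACOS:mVe/mVe")
  pd2 <- phenotype_distribution(cross(a, b))
  expect_true(pd2["mO+mC+mCe+mVe"] == rational(1))
})

test_that("scoring map separates deterministic from ambiguous phenotypes", {
  loci <- loci1()
  # heterozygote sibling cross: single-marker phenotypes reveal homozygotes
  het <- genotype(loci, "ACOS:mCe/mVe")
  sm <- scoring_map(cross(het, het))
  expect_identical(sm[["mCe"]], "ACOS:mCe/mCe")
  expect_true(attr(sm, "deterministic")[["mCe"]])
  # hemizygote sibling cross: the marker phenotype cannot separate hemi from homo
  hemi <- genotype(loci, "ACOS:mCe/+")
  sm2 <- scoring_map(cross(hemi, hemi))
  expect_setequal(sm2[["mCe"]], c("ACOS:mCe/mCe", "ACOS:mCe/+"))
  expect_false(attr(sm2, "deterministic")[["mCe"]])
  # two-locus heterozygote sibling cross: mO+mCe pins the double homozygote
  dhet <- genotype(loci2(), "AGOC:mO/mC;ACOS:mCe/mVe")
  sm3 <- scoring_map(cross(dhet, dhet))
  expect_identical(sm3[["mO+mCe"]], "AGOC:mO/mO;ACOS:mCe/mCe")
  expect_true(attr(sm3, "deterministic")[["mO+mCe"]])
})

test_that("scoring map covers exactly the support of the phenotype distribution", {
  set.seed(7)
  for (i in 1:20) {
    d <- cross(random_genotype(loci2()), random_genotype(loci2()))
    pd <- phenotype_distribution(d)
    sm <- scoring_map(d)
    expect_setequal(names(sm), names(pd))
    expect_true(sum(pd) == rational(1))
  }
})

test_that("selection conditions exactly and errors on impossible rules", {
  loci <- loci1()
  het <- genotype(loci, "ACOS:mCe/mVe")
  d <- cross(het, het)
  sel <- apply_selection(d, selection_rule(require = c("mCe", "mVe")))
  expect_identical(names(sel$p), "ACOS:mCe/mVe")
  expect_true(sel$p == rational(1))
  # empty rule is the identity
  idd <- apply_selection(d, selection_rule())
  expect_setequal(names(idd$p), names(d$p))
  expect_true(sum(idd$p) == rational(1))
  # renormalization is exact
  sel2 <- apply_selection(d, selection_rule(forbid = "mVe"))
  expect_true(sel2$p["ACOS:mCe/mCe"] == rational(1))
  expect_error(apply_selection(d, selection_rule(require = "mO"), context = "F7"),
               "empty selection at step 'F7'")
  expect_error(selection_rule(require = "mO", forbid = "mO"), "disjoint")
})

test_that("the double scheme reproduces every theoretical ratio box", {
  run <- run_scheme(builtin_scheme("agoc_acos_double"))
  expect_true(run[["F8a"]]$phenotype_dist["mO+mCe"] == rational(1))
  expect_true(run[["F8b"]]$phenotype_dist["mC+mVe"] == rational(1))
  # double heterozygotes among F9: 1/16
  expect_true(run[["F9"]]$genotype_dist$p["AGOC:mO/mC;ACOS:mCe/mVe"] == rational(1, 16))
  # all four double-homozygous combinations at 1/16 each in F10
  f10 <- run[["F10"]]$genotype_dist
  combos <- c("AGOC:mO/mO;ACOS:mCe/mCe", "AGOC:mC/mC;ACOS:mCe/mCe",
              "AGOC:mO/mO;ACOS:mVe/mVe", "AGOC:mC/mC;ACOS:mVe/mVe")
  for (key in combos) expect_true(f10$p[key] == rational(1, 16))
  # their phenotypes identify them outright
  det <- attr(run[["F10"]]$scoring, "deterministic")
  expect_true(all(det[c("mO+mCe", "mC+mCe", "mO+mVe", "mC+mVe")]))
})

test_that("the single scheme ends with homozygote-revealing phenotypes", {
  run <- run_scheme(builtin_scheme("agoc_single"))
  # suitable heterozygotes arise at the Mendelian 25% in F6
  f6 <- run[["F6"]]$genotype_dist
  expect_true(f6$p["ACOS:mCe/mVe;FIRE:+/+"] == rational(1, 4))
  sm <- run[["F7"]]$scoring
  det <- attr(sm, "deterministic")
  expect_identical(sm[["mCe"]], "ACOS:mCe/mCe;FIRE:+/+")
  expect_identical(sm[["mVe"]], "ACOS:mVe/mVe;FIRE:+/+")
  expect_true(all(det[c("mCe", "mVe")]))
  # helper has been selected away before the final cross
  expect_true(run[["F7"]]$phenotype_dist["mCe+mVe"] == rational(1, 2))
})

test_that("the resegregation scheme rebuilds the original double homozygotes", {
  run <- run_scheme(builtin_scheme("resegregation"))
  # F13 pools carry the alternative marker pairings
  expect_true(run[["F13a"]]$genotype_dist$p["AGOC:mO/+;ACOS:mVe/+"] == rational(1, 4))
  expect_true(run[["F13b"]]$genotype_dist$p["AGOC:mC/+;ACOS:mCe/+"] == rational(1, 4))
  # F15 progeny are genotypically identical to the original F10 generation
  f15 <- run[["F15"]]$genotype_dist
  f10 <- run_scheme(builtin_scheme("agoc_acos_double"))[["F10"]]$genotype_dist
  expect_setequal(names(f15$p), names(f10$p))
  for (key in names(f10$p)) expect_true(f15$p[key] == f10$p[key])
})

test_that("testcross expectations verify parental genotypes", {
  loci <- loci2()
  homo <- genotype(loci, "AGOC:mO/mO;ACOS:mCe/mCe")
  expect_true(testcross_expectation(homo)["mO+mCe"] == rational(1))
  dhet <- genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe")
  td <- testcross_expectation(dhet)
  expect_length(td, 4L)
  expect_true(all(as.numeric(td) == 0.25))
  expect_true(testcross_expectation(wildtype_genotype(loci))["wt"] == rational(1))
})

test_that("parental genotypes are inferred from testcross support", {
  loci <- loci2()
  candidates <- all_genotype_classes(loci, include_dual = FALSE)
  hit <- infer_parent_from_testcross("mO+mCe", candidates)
  expect_identical(names(hit), "AGOC:mO/mO;ACOS:mCe/mCe")
  dhet <- genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe")
  hit2 <- infer_parent_from_testcross(names(testcross_expectation(dhet)), candidates)
  expect_identical(names(hit2), genotype_class(dhet))
  hit3 <- infer_parent_from_testcross("wt", candidates)
  expect_identical(names(hit3), genotype_class(wildtype_genotype(loci)))
  expect_error(
    infer_parent_from_testcross(c("mO", "mCe+mVe"), candidates["AGOC:mO/mO;ACOS:mCe/mCe"]),
    "inconsistent scoring"
  )
})

test_that("testcross inference inverts expectation on support-distinct classes", {
  loci <- loci2()
  candidates <- all_genotype_classes(loci, include_dual = FALSE)
  supports <- lapply(candidates, function(g) sort(names(testcross_expectation(g))))
  support_keys <- vapply(supports, paste, "", collapse = "|")
  unique_support <- names(candidates)[support_keys %in% names(which(table(support_keys) == 1L))]
  for (key in unique_support) {
    hit <- infer_parent_from_testcross(supports[[key]], candidates)
    expect_identical(names(hit), key)
  }
  # every two-locus class without dual alleles has a distinct support
  expect_length(unique_support, length(candidates))
})

test_that("marker collisions are detected between loci sharing a marker", {
  expect_equal(nrow(check_marker_collisions(builtin_scheme("agoc_acos_double"))), 0L)
  expect_equal(nrow(check_marker_collisions(builtin_scheme("agoc_single"))), 0L)
  clash <- locus_set(
    transgene_locus("ACOS", c("mCe", "mVe")),
    transgene_locus("ICE", "mCe") # helper recolored in practice for this reason
  )
  conflicts <- check_marker_collisions(clash)
  expect_equal(nrow(conflicts), 1L)
  expect_identical(conflicts$shared_markers, "mCe")
  expect_equal(nrow(check_marker_collisions(loci1())), 0L)
})

test_that("scheme validation rejects dangling references and bad steps", {
  loci <- loci1()
  expect_error(
    mating_scheme("bad", loci, list(
      scheme_step("F2", from_generation("F1"), fixed_parent(wildtype_genotype(loci)))
    )),
    "does not precede"
  )
  expect_error(
    mating_scheme("dup", loci, list(
      scheme_step("F1", fixed_parent("ACOS:mCe/+"), fixed_parent("")),
      scheme_step("F1", fixed_parent("ACOS:mCe/+"), fixed_parent(""))
    )),
    "duplicate"
  )
})
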