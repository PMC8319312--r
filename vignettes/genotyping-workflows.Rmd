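---
title: "Deterministic genotyping workflows for dual-marker Cre-Lox transgenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic genotyping workflows for dual-marker Cre-Lox transgenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxcross)
```

## The problem

Transformation markers tell you whether a transgene is present in a diploid
animal, but a single marker cannot tell a hemizygote (one transgene-bearing
chromosome) from a homozygote (two). Establishing a homozygous transgenic
line therefore usually needs invasive genetic assays, and because those
assays lag far behind nascence, breeders overproduce progeny so that enough
suitable animals will exist once the assay results arrive.

The dual-marker Cre-Lox cassette design removes that bottleneck. A transgene
is flanked by *two* distinguishable eye-specific fluorescent markers embedded
in interweaved but mutually incompatible Lox site pairs. Crossing to a
Cre-expressing helper resolves each transmitted cassette to carry exactly one
of the two markers. From then on zygosity is readable by eye: an individual
showing *both* markers of a pair is heterozygous for the two resolved allele
flavours, and its sibling-cross progeny that show only *one* marker are
revealed homozygotes. With two color-complementary cassette pairs
(mO/mC and mCe/mVe — four markers, all separable under filter sets), the same
logic covers two independent transgenes at once.

`loxcross` models this machinery exactly, propagates it through
multi-generation mating schemes, and quantifies the production economics of
scoring-at-nascence ("deterministic") versus pre-committed batch
("stochastic") workflows.

## The exact crossing engine

Alleles at a transgene locus take three states: wild type (`+`), unresolved
dual-marker cassette (`D`), or resolved single-marker (`mO`, `mC`, `mCe`,
`mVe`). Genotypes are (maternal, paternal) allele pairs over a set of
unlinked loci; all reporting collapses to unordered genotype classes.

Every probability in the engine is an exact rational (`R/rational.R`
implements a small reduced-fraction type; numerators and denominators live in
doubles and operations abort beyond 2^53 rather than lose exactness). The
rules are Mendelian:

* each parental allele is transmitted with probability exactly 1/2;
* loci assort independently (free recombination — linkage is out of scope,
  and sex is a pure label: no X-linked transmission is modelled even though
  helper insertions may sit on a sex chromosome);
* with a Cre helper present (`cre_active`), every transmitted dual allele is
  resolved to each single-marker state with probability `efficiency/2`,
  remaining dual with probability `1 - efficiency`.

The equal split between the two resolution outcomes is an assumption (both
Lox pairs are taken to be equally reactive), and `efficiency` defaults to 1;
both are configurable in `cre_resolve()` and `run_scheme()`. No quantitative
Cre efficiency is established for this design, which is why the parameter is
exposed rather than fixed.

```{r engine}
loci <- locus_set(
  transgene_locus("AGOC", c("mO", "mC")),
  transgene_locus("ACOS", c("mCe", "mVe"))
)
dhet <- genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe")
cross(dhet, dhet)
```

The two-locus heterozygote sibling cross above shows the engine's core
outputs: nine genotype classes, the double homozygote at exactly 1/16, and a
phenotype pushforward (`phenotype_distribution()`) plus an identifiability
map (`scoring_map()`) that marks which phenotypes pin down a genotype
uniquely. Crossing is verified in the test suite against an independent
brute-force oracle that enumerates all 4^L ordered transmissions.

## Mating schemes

A `mating_scheme()` is a list of steps; each step crosses two parents —
explicit genotypes or phenotype-selected draws from an earlier generation —
and produces the next generation's exact genotype distribution. Selection
rules see only phenotypes (required and forbidden markers), never genotypes:
that is the non-invasive screening premise, enforced structurally. A rule
matching an ambiguous phenotype still runs, but the report flags the
selection as non-deterministic.

Three built-ins ship as YAML configs (the same reader handles user configs):

* `agoc_single` — creation of a single homozygous line. This is a
  reconstruction of the canonical four-generation procedure: dual-cassette
  founder × Cre helper; helper-carrying carriers outcrossed to wild type
  with germline resolution; the two single-marker hemizygote classes
  intercrossed (suitable heterozygotes at the Mendelian 25%); heterozygote
  sibling cross whose single-marker progeny are homozygotes. The helper is
  modelled as a third, one-marker locus that later selections breed away.
* `agoc_acos_double` — two parallel homozygote × homozygote crosses give
  100% double hemizygotes; intercrossing yields four-marker double
  heterozygotes (6.25%); the final sibling cross yields each of the four
  double-homozygous marker combinations at 1/16.
* `resegregation` — wild-type outcrosses split a double line back into
  singles, which are recombined with the alternative marker pairing and
  driven back to double homozygosity, demonstrating reversibility.

```{r scheme}
run <- run_scheme(builtin_scheme("agoc_acos_double"))
run[["F10"]]$phenotype_dist
```

`check_marker_collisions()` reports locus pairs sharing a marker — the
design reason a Cre helper line gets recolored before being combined with a
cassette that already uses its marker. `testcross_expectation()` and
`infer_parent_from_testcross()` implement genotype verification by wild-type
outcross: a candidate genotype is confirmed when the observed progeny
phenotype support matches its expectation, and over all resolved two-locus
classes those supports are pairwise distinct.

## Production economics

Producing a suitable descendant is a Bernoulli trial with the Mendelian
probability `p` the engine computes (1/4 single, 1/16 double). The planner
contrasts:

* **stochastic**: pre-commit to `n` descendants with
  `P(X >= k) >= confidence` under `X ~ Binomial(n, p)` — the complementary
  cumulative binomial, `min_required()`. "Higher than 95%" is implemented as
  a non-strict tail threshold (`>= 0.95`); with either reading the canonical
  batch sizes are 11 (p = 1/4) and 47 (p = 1/16).
* **deterministic**: score at nascence and stop at the `k`-th success;
  trials are negative-binomial with mean `k/p` (`expected_deterministic()`),
  i.e. 4 and 16 on average.

Waste is produced-minus-needed, and the headline reduction is
`1 - (k/p)/n`: 1 − 16/47 ≈ 66%, about two-thirds. `scaling_with_transgenes()`
compounds per-locus probabilities (`p^i` for `i` transgenes), showing the
absolute saving growing geometrically — wasted animals decrease
exponentially in the number of distinct transgenes.

```{r plan}
compare_workflows("1/16")
scaling_with_transgenes(3)
```

## Synthetic scoring tables and their statistics

Real scoring data arrive as per-vial phenotype counts (a few female–male
pair vials per cross, every progeny scored). `simulate_vials()` emulates
exactly that statistical structure: one independent multinomial draw per
vial from the exact phenotype distribution, defaulting to 6 vials of 100
progeny (up to six pairs per cross is the usual practice; published "total"
columns do not disclose per-vial sizes, so 100 is a realistic round default,
not a reproduction). Per-vial seeds derive from the top-level seed as
`(seed + 1000003 * i) mod 2147483647`, so adding vials never perturbs
earlier ones and a table is regenerable from its seed alone. Progeny sex,
when a scheme rule asks for it, is 1:1 independent of genotype, so sex
labels never change a distribution.

What the generator does *not* emulate: vial-to-vial overdispersion,
mortality, or fertility differences — simulated counts are exactly
multinomial. Passing calibration tests therefore demonstrates internal
consistency of the engine, generator and tests, not that real vials are
multinomial.

`mendelian_ttest()` reproduces the conventional verification of such
tables: per-vial ratios, one-sample two-tailed t against the theoretical
Mendelian ratio, `n - 1` degrees of freedom. Ratios are plain arithmetic
means (no variance-stabilising transform), no multiple-testing correction by
default (a Bonferroni flag exists as an extension), and α defaults to 0.05 —
the customary level where none is printed alongside "n.s." tables.
Degenerate zero-variance samples follow an explicit contract: all ratios
equal to the target give `t = 0, p = 1`; all equal but off-target is
reported significant (`p = 0`) and flagged.

```{r verify}
d <- cross(genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe"),
           genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe"))
tab <- simulate_vials(d, n_vials = 6, progeny_per_vial = 100, seed = 1,
                      generation = "F10")
head(mendelian_tests(tab, d), 3)
```

## Numerical choices and problem sizes

* Exact rationals everywhere in probability propagation; doubles only at
  presentation and in the statistics layer (`binomial_tail()` sums `k`
  complementary `dbinom` terms — finite summation, no approximation beyond
  double precision).
* The planner's search for `n` is a simple upward scan from `k`; it always
  terminates for `p > 0` and matches `ceiling(log(1-c)/log(1-p))` for
  `k = 1`.
* Ties and ambiguity are reported, never resolved silently: scoring maps
  flag ambiguous phenotypes, scheme runs flag non-deterministic selections,
  and zero-probability selections are errors naming the step.
* Test problem sizes are chosen to make Monte-Carlo error negligible at
  desk scale: 200 random parent pairs against the brute-force crossing
  oracle, 1000 seeded tables for t-test type-I calibration (3
  standard-error acceptance band around α), 200 seeds for chi-square
  goodness-of-fit calibration, and 10^5 replicates for workflow simulation
  (3 SE bands around the analytic mean and tail).

## Limitations

Linked loci, X-linked transmission, somatic Cre mosaicism, genotype-dependent
viability or fertility, vial capacity and husbandry timing are all out of
scope. The single-transgene built-in is a documented reconstruction, not a
transcription of a published crossing chart; its invariants (25% suitable
heterozygotes, homozygote-revealing single-marker phenotypes) are what the
tests pin down.
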