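# loxcross

Exact Mendelian modelling and production planning for transgenic breeding
schemes built on dual-marker Cre-Lox cassettes.

## What problem this solves

In diploid model organisms, a transformation marker shows whether a
transgene is present but cannot separate hemizygous from homozygous
carriers, so establishing homozygous lines normally requires invasive
genetic assays — and, because assay results lag far behind birth, breeders
hedge by overproducing animals. Dual-marker cassette designs fix this at
the vector level: the transgene carries two distinguishable eye-specific
fluorescent markers (mO/mC for one cassette pair, mCe/mVe for the
color-shifted one) inside interweaved, incompatible Lox site pairs. After
Cre-mediated resolution each transmitted allele keeps exactly one marker,
and zygosity becomes readable under a stereo microscope in seconds:
individuals showing both markers of a pair are heterozygous for the two
allele flavours, and their sibling-cross progeny showing only one marker
are revealed homozygotes. Genotyping at nascence makes a *deterministic*
workflow possible — stop producing as soon as the needed animals exist.

`loxcross` is for people designing or verifying such schemes: it computes
exact genotype/phenotype distributions for arbitrary crosses, propagates
whole multi-generation schemes with phenotype-based selection, analyses
which phenotypes identify genotypes uniquely, sizes production batches, and
verifies observed vial counts against Mendelian expectations.

## The core calculus

* **Segregation.** Unlinked loci, each parental allele transmitted with
  probability 1/2; with a Cre helper in the cross, a transmitted dual
  cassette resolves to each single-marker state with probability `e/2`
  (efficiency `e`, default 1). All probabilities are exact rationals.
* **Planning.** Producing a suitable descendant is Bernoulli with the
  Mendelian probability `p` (1/4 for one transgene, 1/16 for two). A
  stochastic workflow pre-commits to the smallest `n` with
  `P(Binomial(n, p) >= k) >= 0.95` — giving n = 11 (p = 1/4) and
  n = 47 (p = 1/16) for k = 1. A deterministic workflow stops at the k-th
  success after negative-binomial `k/p` trials on average — 4 and 16.
  The waste reduction `1 - (k/p)/n` is about two-thirds.
* **Verification.** Per-vial phenotype ratios are tested against the
  theoretical ratio with a one-sample two-tailed t-test (df = vials − 1).

## Worked example

```r
library(loxcross)
loci <- locus_set(
  transgene_locus("AGOC", c("mO", "mC")),
  transgene_locus("ACOS", c("mCe", "mVe"))
)
dhet <- genotype(loci, "AGOC:mO/mC;ACOS:mCe/mVe")
cross(dhet, dhet)
#> <genotype distribution, 9 classes>
#>                    class     phenotype probability decimal
#>  AGOC:mO/mC;ACOS:mCe/mVe mO+mC+mCe+mVe         1/4  0.2500
#>  AGOC:mC/mC;ACOS:mCe/mVe    mC+mCe+mVe         1/8  0.1250
#>  AGOC:mO/mC;ACOS:mCe/mCe     mO+mC+mCe         1/8  0.1250
#>  AGOC:mO/mC;ACOS:mVe/mVe     mO+mC+mVe         1/8  0.1250
#>  AGOC:mO/mO;ACOS:mCe/mVe    mO+mCe+mVe         1/8  0.1250
#>  AGOC:mC/mC;ACOS:mCe/mCe        mC+mCe        1/16  0.0625
#>  AGOC:mC/mC;ACOS:mVe/mVe        mC+mVe        1/16  0.0625
#>  AGOC:mO/mO;ACOS:mCe/mCe        mO+mCe        1/16  0.0625
#>  AGOC:mO/mO;ACOS:mVe/mVe        mO+mVe        1/16  0.0625
```

The sibling cross of two-locus marker heterozygotes yields the nine
genotype classes expected with two transgenes. Each two-marker phenotype
(e.g. `mO+mCe`) appears in exactly one class — a double homozygote at
exactly 1/16 — so scoring those phenotypes identifies double homozygotes
without any genetic assay.

```r
compare_workflows("1/16")
#> Workflow comparison (p = 0.0625, k = 1, confidence = 0.95)
#>   stochastic batch size     : 47 (achieves 0.9518)
#>   deterministic expectation : 16
#>   progeny reduction         : 66.0%
```

A genetic-assay workflow must produce 47 descendants to be 95% sure of one
double homozygote; scoring at nascence stops after 16 on average — a 66%
(about two-thirds) reduction in animals produced.

Whole schemes run declaratively — `run_scheme(builtin_scheme("agoc_acos_double"))`
reproduces every theoretical ratio of the standard double-homozygote
procedure (100% double hemizygotes from the parallel founder crosses, four
double-homozygote classes at 1/16 each) — and a thin CLI wraps the same
functions (`inst/cli/loxcross expect|plan|simulate|verify|identify`).

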