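Package: loxcross
Title: Exact Mendelian Modelling and Planning for Dual-Marker Cre-Lox
    Breeding Schemes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and verifying deterministic genotyping
    workflows for transgenic lines that carry dual-marker Cre-Lox transgene
    cassettes. Provides an exact rational-arithmetic engine for Mendelian
    segregation, Cre-mediated marker resolution and phenotype computation;
    declarative multi-generation mating schemes with phenotype-based
    selection, testcross verification and genotype identifiability
    analysis; production planning that contrasts stochastic overproduction
    (complementary cumulative binomial) with deterministic stopping
    (negative-binomial expectation); seeded multinomial simulation of
    vial-level scoring tables; and one-sample t-tests of observed progeny
    ratios against theoretical Mendelian expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
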