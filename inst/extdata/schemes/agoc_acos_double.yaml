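# Double-transgene scheme: combining two color-complementary single
# homozygous lines (AGOC: mO/mC cassette, ACOS: mCe/mVe cassette) into a
# double homozygous line. Two parallel F7 homozygote crosses give 100%
# double hemizygotes; intercrossing them yields four-marker double
# heterozygotes (6.25% of progeny); the final sibling cross yields each of
# the four double-homozygous marker combinations at 1/16.
name: agoc_acos_double
loci:
  - id: AGOC
    markers: [mO, mC]
  - id: ACOS
    markers: [mCe, mVe]
steps:
  - label: F8a
    parent_a: {genotype: "AGOC:mO/mO"}
    parent_b: {genotype: "ACOS:mCe/mCe"}
  - label: F8b
    parent_a: {genotype: "AGOC:mC/mC"}
    parent_b: {genotype: "ACOS:mVe/mVe"}
  - label: F9
    parent_a: {from: F8a, require: [mO, mCe], sex: female}
    parent_b: {from: F8b, require: [mC, mVe], sex: male}
  - label: F10
    parent_a: {from: F9, require: [mO, mC, mCe, mVe], sex: female}
    parent_b: {from: F9, require: [mO, mC, mCe, mVe], sex: male}
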