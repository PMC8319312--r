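# Resegregation scheme: a double-transgenic line is split back into single
# hemizygotes by wild-type outcrosses, then double homozygotes are rebuilt
# with the alternative marker pairing (mO with mVe, mC with mCe), ending in
# progeny genotypically identical to the original double homozygotes.
name: resegregation
loci:
  - id: AGOC
    markers: [mO, mC]
  - id: ACOS
    markers: [mCe, mVe]
steps:
  - label: F12a
    parent_a: {genotype: "AGOC:mO/+;ACOS:mCe/+"}
    parent_b: {genotype: ""}
  - label: F12b
    parent_a: {genotype: "AGOC:mC/+;ACOS:mVe/+"}
    parent_b: {genotype: ""}
  - label: F13a
    parent_a: {from: F12a, require: [mO], forbid: [mCe]}
    parent_b: {from: F12b, require: [mVe], forbid: [mC]}
  - label: F13b
    parent_a: {from: F12b, require: [mC], forbid: [mVe]}
    parent_b: {from: F12a, require: [mCe], forbid: [mO]}
  - label: F14
    parent_a: {from: F13a, require: [mO, mVe]}
    parent_b: {from: F13b, require: [mC, mCe]}
  - label: F15
    parent_a: {from: F14, require: [mO, mC, mCe, mVe]}
    parent_b: {from: F14, require: [mO, mC, mCe, mVe]}
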