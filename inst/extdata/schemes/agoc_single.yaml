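# Single-transgene scheme (reconstruction): systematic creation of a
# homozygous line from a dual-cassette founder. The dual ACOS cassette (D)
# carries mCe and mVe; the FIRE helper expresses Cre and carries mC, chosen
# not to collide with the cassette markers. Suitable heterozygotes arise in
# F6 at the Mendelian 25%.
name: agoc_single
loci:
  - id: ACOS
    markers: [mCe, mVe]
  - id: FIRE
    markers: [mC]
    chromosome: ChLGX
steps:
  - label: F4
    parent_a: {genotype: "ACOS:D/+"}
    parent_b: {genotype: "FIRE:mC/+"}
  - label: F5
    parent_a: {from: F4, require: [mCe, mVe, mC]}
    parent_b: {genotype: ""}
    cre: true
  - label: F6
    parent_a: {from: F5, require: [mCe], forbid: [mVe, mC]}
    parent_b: {from: F5, require: [mVe], forbid: [mCe, mC]}
  - label: F7
    parent_a: {from: F6, require: [mCe, mVe]}
    parent_b: {from: F6, require: [mCe, mVe]}
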