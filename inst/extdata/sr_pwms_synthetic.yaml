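# Synthetic SR-protein position-weight matrices.
#
# These are NOT the published ESEfinder matrices: they are constructed
# stand-ins (match +1 / mismatch -1 over a degenerate consensus) built so
# that the enhancer motifs active in the bundled BRCA2 exon 17/18 fixture
# (SF2/ASF heptamers GATACGG and CAGAAGA; SC35 octamer GGCTATAA) score
# above threshold. Supply the published matrices as a user config for
# real scanning work.
pwms:
  - name: SF2/ASF (synthetic)
    threshold: 5.5
    matrix:
      A: [-1,  1, -1,  1,  1, -1,  1]
      C: [ 1, -1, -1, -1,  1, -1, -1]
      G: [ 1, -1,  1, -1, -1,  1,  1]
      T: [-1, -1,  1, -1, -1, -1, -1]
  - name: SC35 (synthetic)
    threshold: 6
    matrix:
      A: [-1, -1, -1, -1,  1, -1,  1,  1]
      C: [-1, -1,  1, -1, -1, -1, -1, -1]
      G: [ 1,  1, -1, -1, -1, -1, -1,  1]
      T: [-1, -1, -1,  1, -1,  1, -1, -1]
  - name: SRp40 (synthetic)
    threshold: 5.5
    matrix:
      A: [ 1, -1,  1,  1, -1,  1,  1]
      C: [-1,  1, -1, -1, -1, -1, -1]
      G: [-1, -1, -1, -1,  1, -1, -1]
      T: [ 1, -1, -1, -1, -1, -1, -1]
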