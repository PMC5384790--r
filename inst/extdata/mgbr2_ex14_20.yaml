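# Seven-exon BRCA2 splicing-reporter construct (exons 14-20 cloned
# between the two reporter vector exons V1/V2). Slash-shortened introns
# appear as two consecutive intron segments (suffixes a/b); the removed
# middle is not represented. Exon c. anchors follow coding-DNA (HGVS c.)
# numbering. Vector-exon lengths and primer tail splits are calibration
# constants: only the sums (fwd tail + rev tail) affect any amplicon
# size, fixed so the wild-type EX16_FW/PSAD_RV product is 1,012 nt and
# the SD6_FW/PSAD_RV product is 1,806 nt.
name: MGBR2_ex14-20
segments:
  - {role: vector_exon, label: V1, length: 150}
  - {role: intron, label: IVS13, length: 328}
  - {role: exon, label: EX14, length: 428, c_start: 7008, c_end: 7435}
  - {role: intron, label: IVS14, length: 1139}
  - {role: exon, label: EX15, length: 182, c_start: 7436, c_end: 7617}
  - {role: intron, label: IVS15a, length: 358}
  - {role: intron, label: IVS15b, length: 333}
  - {role: exon, label: EX16, length: 188, c_start: 7618, c_end: 7805}
  - {role: intron, label: IVS16a, length: 234}
  - {role: intron, label: IVS16b, length: 181}
  - {role: exon, label: EX17, length: 171, c_start: 7806, c_end: 7976}
  - {role: intron, label: IVS17, length: 485}
  - {role: exon, label: EX18, length: 355, c_start: 7977, c_end: 8331}
  - {role: intron, label: IVS18a, length: 314}
  - {role: intron, label: IVS18b, length: 235}
  - {role: exon, label: EX19, length: 156, c_start: 8332, c_end: 8487}
  - {role: intron, label: IVS19, length: 398}
  - {role: exon, label: EX20, length: 145, c_start: 8488, c_end: 8632}
  - {role: intron, label: IVS20, length: 207}
  - {role: vector_exon, label: V2, length: 80}
primers:
  - {name: SD6_FW, segment_label: V1, offset: 131, direction: forward}
  - {name: EX16_FW, segment_label: EX16, offset: 135, direction: forward}
  - {name: PSAD_RV, segment_label: V2, offset: 50, direction: reverse}
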