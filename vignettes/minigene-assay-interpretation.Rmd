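---
title: "Interpreting splicing reporter minigene assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting splicing reporter minigene assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minigene)
```

## The assay this package models

A hybrid minigene is a plasmid construct in which a block of genomic
sequence — several exons with their (often shortened) introns — is cloned
between two reporter "vector exons". Transfected into cultured cells, the
construct is transcribed and spliced; RT-PCR with primers anchored in the
vector exons (or in a cloned exon) amplifies every processed transcript,
and capillary electrophoresis of fluorescently labelled products resolves
the transcript mixture as peaks whose sizes identify splice isoforms and
whose areas measure their relative abundance. Because each tested DNA
variant is introduced into an otherwise wild-type construct by site-directed
mutagenesis, the assay reads out the splicing consequence of a single
allele in isolation, and because cells are treated with cycloheximide,
nonsense-mediated decay (NMD) is blocked, so PTC-bearing transcripts are
quantified rather than degraded.

`minigene` implements the full desk-side half of that workflow:

1. **Construct model** — ordered segments with lengths and HGVS c. anchors,
   primer sites, amplicon arithmetic (`build_construct()`,
   `total_insert_length()`, `amplicon_length()`).
2. **Splice-event engine** — exon skipping, alternative acceptor/donor use,
   partial intron retention, and their compositions, producing transcript
   structures, sizes and HGVS r. descriptions (`apply_splice_events()`,
   `rna_hgvs()`, `candidate_transcript_table()`).
3. **Consequence annotation** — reading frame, premature termination
   codons, protein HGVS by translation against a coding context
   (`frame_status()`, `protein_consequence()`, `count_ptc_transcripts()`).
4. **Fragment quantification** — RFU filtering, nearest-size peak
   assignment, area-based fractions with replicate means and SDs
   (`filter_peaks()`, `assign_peaks()`, `quantify()`).
5. **Classification** — the spliceogenicity rule and a codified
   splicing-viewpoint decision table (`classify_variant()`,
   `cohort_summary()`).
6. **ESE mapping** — microdeletion design and PWM motif scanning
   (`design_microdeletions()`, `pwm_scan()`, `map_hits_to_deletions()`).
7. **Simulation** — synthetic minigenes and electropherograms so every
   stage is testable without external data (`make_synthetic_minigene()`,
   `simulate_peak_table()`, `simulate_assay()`).

The bundled fixture is a seven-exon BRCA2 reporter (exons 14–20, insert
5,837 bp) with a 52-variant cohort centred on exons 17 and 18, transcribed
from the published results of that assay.

## Coordinates and the construct model

Positions are HGVS c. (coding DNA), 1-based inclusive; intronic positions
are written `c.X+n` (donor side) and `c.Y-n` (acceptor side) relative to
the flanking exon ends. Internally every position maps to a
`(segment, offset)` pair and all interval arithmetic is done there;
conversion back to HGVS happens only at the I/O boundary.

Two modelling choices matter:

* **Shortened introns.** Cloned constructs routinely delete the middle of
  long introns. The model represents such an intron as two consecutive
  intron segments; intronic coordinates are only addressable inside the
  half adjacent to their anchor exon, and positions falling in the removed
  middle raise a coordinate error rather than silently mapping somewhere.
* **Calibration constants.** Vector-exon lengths and the split of the
  RT-PCR tail lengths between forward and reverse primers are not
  observable from product sizes — only their sums are. The fixture fixes
  the exon-16-forward plus vector-reverse tails at 185 nt (split 135/50)
  so the wild-type amplicon is exactly 1,012 nt, and the vector-forward
  tail at 131 nt so the vector–vector product is 1,806 nt. Any other split
  with the same sums would give identical results everywhere.

Sequences are optional: all size and frame arithmetic is length-only, and
operations that genuinely need sequence (translation, retained-intron
consequences) fail loudly when it is absent.

## The event model

Splicing outcomes are described structurally, as offsets from annotated
exon boundaries: an alternative acceptor at `+k` removes the exon's first
`k` nt; at `-k` it appends the last `k` nt of the upstream intron; donors
are symmetric at the 3' end; exon skipping removes the exon. Whether a
site is "cryptic" or "de novo" is deliberately not part of the model —
transcript names like `ex18-del309` are pure offset descriptions, and the
engine only applies stated events, never predicts them. Composite
outcomes (e.g. a donor shift on one exon plus skipping of the next) are
plain event sets; the engine resolves them to a single ordered list of
retained intervals, which is why composition order can never change the
result (a property the test suite checks on random event pairs).

Uncharacterised species observed in real assays ("others", a transcript
known only by its 878-nt size) are representable as size-only
placeholders so that quantification never drops observed mass; they are
excluded from structural annotation and from distinct-species counts.

The r. writer supports single deletions (merged across exons when
contiguous in c. numbering), single insertions (sequence form when the
inserted bases are known, coordinate form such as
`r.7805_7806ins7806-8_7806-1` otherwise), and deletion-plus-adjacent-
retention as `delins`. Event sets outside that grammar raise an
unsupported-description error rather than emitting something wrong. One
deliberate non-resolution: the fixture's published table writes
`r.7806_7807del` for the 1-nt-deletion transcript `ex17-del1`; the fixture
stores that string verbatim while the engine's structural emission is
`r.7806del`, and the two are kept side by side rather than silently
harmonised.

## Consequence annotation

A transcript's frame status is its net length change modulo 3. Protein
consequences come from actually translating the mutant coding sequence
implied by the retained intervals (reference head + body + reference
tail, the tail including the natural terminator). A premature termination
codon is a stop that is not the final codon of the mutant CDS; `fs*N`
counts residues from the first altered residue to the stop inclusive, and
in-frame indels are written after prefix-first trimming, which implements
the HGVS 3'-most convention at the protein level. No NMD rules (50-nt
boundary and the like) are applied, because the assay this models
inhibits NMD pharmacologically — degradation is out of model by design.

Because a full-length reference CDS for the fixture gene would have to be
downloaded, protein-level strings are exercised on synthetic coding
contexts, and PTC classification is property-tested against a brute-force
hand-coded-codon-table oracle on over a thousand random construct/event
combinations instead of being spot-checked on a single gene.

## Quantification

Peak area, not height, is the abundance measure; height is used only for
the detection filter (default floor 50 RFU, inclusive). With a single
end-labelled fluorophore per amplicon the signal is proportional to molar
amount, so no fragment-length correction is applied. Assignment maps each
peak to the nearest candidate size within a tolerance (default 0.4 nt —
candidates in this assay differ by at least 1 nt); a tolerance of half
the minimum candidate gap or more is refused outright as an ambiguity
error. Unassigned peaks are kept as `unidentified-<size>` buckets and
count as aberrant mass downstream. A transcript absent from one replicate
contributes zero there before averaging (the alternative — renormalising
each replicate over its own labels — would bias minor species upward);
fewer than three replicates warns, since the assay convention is
triplicate.

## The synthetic-data generator

`make_synthetic_minigene()` builds multi-exon genes whose introns carry
AG acceptors, GT or GC donors (GC donors occur in a small minority of
real introns, including one in the fixture gene), and a polypyrimidine
tract; the concatenated exons form a start-to-stop CDS with no internal
stop, so every transcript is translatable. `simulate_peak_table()` draws,
per replicate and species, an area equal to `rfu_scale x fraction` times
unit-mean lognormal noise, a called size equal to the candidate size plus
Gaussian jitter, and a height derived from area and peak width.

Defaults, chosen once as realistic for this instrument class and not
revisited: `area_cv = 0.05`, `size_jitter_sd_nt = 0.15`,
`peak_sigma_nt = 0.25`, `n_replicates = 3`. The area CV is the
calibrated quantity: by the delta method a two-species fraction has
replicate SD `p(1-p)·sqrt(2)·cv ≤ 0.25·sqrt(2)·0.05 ≈ 1.8` percentage
points at worst, matching the sub-1.8-point reproducibility the modelled
assay reports; the test suite verifies the empirical SD at a
representative strong-skip mixture with size jitter disabled, because
jitter stresses a different mechanism (assignment dropout, visible as
`unidentified` flags) rather than area dispersion. An optional NMD
attenuation factor exists but defaults to off, consistent with
cycloheximide treatment.

What the simulator does **not** emulate: PCR amplification bias,
heteroduplexes, stutter peaks, baseline drift, or size-standard
miscalibration. Passing recovery tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to those
artefacts in real traces.

## Classification

The spliceogenicity rule is aberrant fraction ≥ 5% (inclusive), where the
aberrant fraction is one minus the mean full-length fraction,
unidentified mass included. The splicing-viewpoint decision table is this
package's codification (the published evidence mapping is not in the main
text it draws on), with thresholds in `classification_thresholds()`:

| rule | condition | label |
|---|---|---|
| R1 | canonical ±1/±2 site variant, aberrant ≥ 0.95 | pathogenic |
| R2 | predicted nonsense/frameshift variant, aberrant ≥ 0.95 | pathogenic |
| R3 | aberrant ≥ 0.55 | likely_pathogenic |
| R4 | aberrant ≥ 0.05 | vus (or `likely_pathogenic_prior` with prior evidence) |
| R5 | otherwise | not_spliceogenic |

The 0.95 threshold reflects that every fully penetrant splice-site
variant in the fixture shows ≥ 96% aberrant mass; 0.55 sits just under
the ~60% level cited in the clinical splicing literature as the mark of a
severe splicing aberration, so that a 59.3%-aberrant exon-terminal
variant lands in `likely_pathogenic`. Site class is derived from the
construct: canonical means the edit touches (or duplicates) intronic
±1/±2 positions; other intronic positions and the protected exon ends
(first two, last three nucleotides) are `splice_region`; the rest is
`exonic`.

Prior, non-splicing evidence (e.g. an established protein-function or
truncation classification) is an explicit input, never inferred. A
variant that R4 would leave as VUS but that carries such a prior receives
the distinct label `likely_pathogenic_prior`, with the prior recorded in
the triggered rules. Keeping it distinct from `likely_pathogenic` was a
deliberate choice: the splicing evidence alone does not support the
upgrade, and collapsing the two labels would silently inflate the
splicing-based likely-pathogenic count. The decision table is monotone in
the aberrant fraction by construction (and property-tested): raising the
aberrant fraction can only move a variant up the severity order.

## ESE scanning

`pwm_scan()` is a standard additive position-weight-matrix scanner (all
windows at or above the matrix threshold are reported; N is not allowed
in scan windows), and `map_hits_to_deletions()` intersects hits with
microdeletion windows, flagging motifs shared by overlapping deletions —
the logic used to triangulate enhancer elements from a deletion series.
The shipped matrices (`sr_protein_pwms()`) are **synthetic stand-ins**,
constructed so the enhancer motifs active in the bundled fixture score
above threshold; they are not the published ESEfinder matrices, which
were not redistributable here and should be supplied as a user config
(`read_pwms()`) for real scanning. All scanner correctness tests run
against a brute-force window-enumeration oracle on random matrices, so
nothing in the test suite depends on the stand-in values.

The microdeletion designer enforces the wet-lab constraint that the first
two and last three nucleotides of an exon are never deleted (they belong
to the acceptor/donor definitions); requested windows may deliberately
overlap, as in the fixture's exon-18 series where two adjacent windows
share 5 nt.

## Numerical and degenerate-input choices

* Fractions are renormalised to sum to exactly 1 after averaging;
  per-replicate sums are exact by construction.
* Zero total area in a replicate, catalogs without the canonical
  transcript, duplicate catalog labels, incompatible event sets (two
  acceptor-side events on one exon), offsets at or beyond the exon
  length, and coordinates in removed intron middles are all hard errors
  with typed messages, not warnings.
* Transcripts that lose a primer's anchor report `NA` ("no
  amplification"), never a number, and are excluded from candidate
  tables.
* RNG: every stochastic routine seeds a local generator from its
  parameter object and restores the caller's RNG state, so simulations
  are reproducible and side-effect free.

## Fixture provenance and limits

The 52-variant cohort table mixes three sources, marked in its `source`
column: the published per-variant transcript percentages
(`published_results`), the three weak variants stated in the assay's
running text (`published_text`), and 19
`synthetic_negative` placeholder rows standing in for splice-neutral
variants whose identities are not printed in the main text — only their
count (19) and region split (7 exon-17, 12 exon-18) are meaningful, and
their HGVS strings are arbitrary interior positions. Test sizes
throughout (20–30 random constructs per property, ~1,000 translation
oracle cases, 3-replicate recovery simulations) are the package's chosen
balance between coverage and a fast default test run.

Known limitations: the classifier is a splicing-viewpoint codification,
not a full ACMG/AMP engine (no population frequency, segregation, or
multifactorial likelihood evidence); protein-domain impact is only an
externally supplied flag; the r. grammar covers single del/ins/delins
outcomes, not arbitrary multi-event descriptions; and minigene results,
as the assay's own literature stresses, are supportive evidence to be
confirmed in patient RNA where possible.

## A worked example

```{r example, eval = FALSE}
con <- mgbr2_construct()
total_insert_length(con)        # 5837
catalog <- mgbr2_event_catalog()

# expected amplicon sizes for peak assignment
candidate_transcript_table(con, catalog["FL" == names(catalog) |
  names(catalog) %in% c("ex17 skipping", "ex18 skipping")],
  "EX16_FW", "PSAD_RV")         # 1012 / 841 / 657 nt

# simulate one variant's triplicate assay and classify it
truth <- list("c.8331+2T>C" = list(
  catalog = catalog[c("FL", "ex18 skipping", "ex17-del151+ex18 skipping")],
  fractions = c("ex18 skipping" = 0.871,
                "ex17-del151+ex18 skipping" = 0.129)))
bundle <- simulate_assay(con, truth, simulation_params(c(FL = 1), seed = 4),
                         "EX16_FW", "PSAD_RV")[[1]]
q <- quantify(assign_peaks(filter_peaks(bundle$peaks), bundle$candidates))
classify_variant(variant_assay("c.8331+2T>C", q, construct = con))
# pathogenic via R1 (canonical +2 donor, 100% aberrant)

# the full bundled cohort
s <- cohort_summary(mgbr2_cohort(con)$assays)
s$n_spliceogenic                # 30 of 52
s$class_counts                  # 12 P / 8 LP / 8 VUS / 2 prior-upgraded
```
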