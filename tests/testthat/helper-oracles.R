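# Independent oracles used by the property-style tests. These stay
# deliberately naive (string chopping, exhaustive enumeration, a
# hand-written codon table) so they share no code path with the package.

# hand-written standard genetic code (independent of any translation
# machinery used by the package)
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(ORACLE_CODON[codons])
}

# position (codon index) of the first stop in a naive translation, NA if
# none among complete codons
oracle_first_stop <- function(dna) {
  aa <- oracle_translate(dna)
  hit <- which(aa == "*")
  if (length(hit)) hit[1] else NA_integer_
}

# exhaustive PWM window enumeration
oracle_pwm_hits <- function(sequence, pwm) {
  bases <- strsplit(sequence, "")[[1]]
  w <- ncol(pwm$matrix)
  out <- list()
  for (s in seq_len(max(0L, length(bases) - w + 1L))) {
    sc <- 0
    for (j in seq_len(w)) sc <- sc + pwm$matrix[bases[s + j - 1L], j]
    if (sc >= pwm$threshold) {
      out[[length(out) + 1L]] <- list(start = s, score = sc)
    }
  }
  out
}

# a small random construct with anchored exons (length-only, no sequences)
random_length_construct <- function(n_exons = 3L) {
  ex_len <- sample(30:200, n_exons, replace = TRUE)
  in_len <- sample(50:400, n_exons + 1L, replace = TRUE)
  starts <- cumsum(c(1L, ex_len[-n_exons]))
  segs <- list(list(role = "vector_exon", label = "V1", length = 120L))
  for (i in seq_len(n_exons)) {
    segs[[length(segs) + 1L]] <- list(role = "intron",
                                      label = paste0("IVS", i - 1L),
                                      length = in_len[i])
    segs[[length(segs) + 1L]] <- list(role = "exon", label = paste0("EX", i),
                                      length = ex_len[i],
                                      c_start = starts[i],
                                      c_end = starts[i] + ex_len[i] - 1L)
  }
  segs[[length(segs) + 1L]] <- list(role = "intron",
                                    label = paste0("IVS", n_exons),
                                    length = in_len[n_exons + 1L])
  segs[[length(segs) + 1L]] <- list(role = "vector_exon", label = "V2",
                                    length = 90L)
  primers <- list(
    list(name = "FW", segment_label = "V1", offset = 40L,
         direction = "forward"),
    list(name = "RV", segment_label = "V2", offset = 35L,
         direction = "reverse"))
  build_construct(segs, primers, name = "random")
}

# random compatible event set on a construct (deletion-flavoured alt
# sites and skips, at most one acceptor/donor event per exon)
random_event_set <- function(construct, max_events = 2L) {
  ex <- construct_exons(construct)
  n <- sample(seq_len(max_events), 1L)
  picks <- sample(ex$label, min(n, nrow(ex)))
  purrr::map(picks, function(lbl) {
    len <- ex$length[ex$label == lbl]
    kind <- sample(c("exon_skip", "alt_acceptor", "alt_donor"), 1L)
    if (kind == "exon_skip") {
      splice_event("exon_skip", lbl)
    } else {
      splice_event(kind, lbl, offset = sample(seq_len(len - 1L), 1L))
    }
  })
}
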