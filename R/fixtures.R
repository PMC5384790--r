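# Bundled BRCA2 exon 14-20 reporter fixture: the construct description,
# the splicing-event catalog behind the observed transcript labels, the
# printed microdeletion series, and the 52-variant cohort table with
# per-transcript percentages.
#
# The cohort file mixes three sources (column `source`): the published
# per-variant results (`published_results`), the three weak variants
# stated in the assay's running text (`published_text`), and 19
# synthetic placeholder negatives
# (`synthetic_negative`) standing in for the splice-neutral variants
# whose identities are not printed; only their count and exon region are
# meaningful.

mg_extdata <- function(file) {
  system.file("extdata", file, package = "minigene", mustWork = TRUE)
}

#' The seven-exon BRCA2 reporter construct
#'
#' Reads the bundled MGBR2_ex14-20 construct description: 18 cloned
#' segments (7 exons, 11 intron pieces including shortened-intron halves)
#' between the vector exons V1/V2, with the three RT-PCR primer sites.
#'
#' @return A `minigene_construct`.
#' @export
mgbr2_construct <- function() {
  read_construct(mg_extdata("mgbr2_ex14_20.yaml"))
}

#' Splicing-event catalog of the BRCA2 exon 17/18 fixture
#'
#' Named list mapping every characterised transcript label observed in
#' the fixture cohort to its structural event set (the canonical
#' transcript is the empty set), plus the size-only placeholder for the
#' uncharacterised 878-nt species.
#'
#' @return Named list suitable for [candidate_transcript_table()].
#' @export
mgbr2_event_catalog <- function() {
  list(
    "FL" = list(),
    "ex17 skipping" = list(splice_event("exon_skip", "EX17")),
    "ex17-ins8" = list(splice_event("alt_acceptor", "EX17", offset = -8L)),
    "ex17-del1" = list(splice_event("alt_acceptor", "EX17", offset = 1L)),
    "ex17-del20" = list(splice_event("alt_acceptor", "EX17", offset = 20L)),
    "ex17-del69" = list(splice_event("alt_acceptor", "EX17", offset = 69L)),
    "ex17-insAG" = list(splice_event("alt_acceptor", "EX17", offset = -2L,
                                     inserted_sequence = "AG")),
    "ex18 skipping" = list(splice_event("exon_skip", "EX18")),
    "ex18-ins6" = list(splice_event("alt_acceptor", "EX18", offset = -6L)),
    "ex18-del191" = list(splice_event("alt_acceptor", "EX18", offset = 191L)),
    "ex18-del236" = list(splice_event("alt_acceptor", "EX18", offset = 236L)),
    "ex18-del309" = list(splice_event("alt_donor", "EX18", offset = 309L)),
    "ex18-del298" = list(splice_event("alt_donor", "EX18", offset = 298L)),
    "ex18-del164" = list(splice_event("alt_donor", "EX18", offset = 164L)),
    "ex18-del157" = list(splice_event("alt_donor", "EX18", offset = 157L)),
    "ex17-del151+ex18 skipping" = list(
      splice_event("alt_donor", "EX17", offset = 151L),
      splice_event("exon_skip", "EX18")),
    "ivs17-ret58+ex18 skipping" = list(
      splice_event("alt_donor", "EX17", offset = -58L),
      splice_event("exon_skip", "EX18")),
    "878nt" = 878
  )
}

#' The printed exon 17/18 microdeletion mapping series
#'
#' Reproduces the published 10-nt fine-mapping deletions: three windows
#' tiled across the exon-17 enhancer region from c.7944, and six
#' exon-18 windows from c.7979 including the deliberate 5-nt-overlap
#' window starting at c.8004.
#'
#' @param construct The reporter construct (defaults to
#'   [mgbr2_construct()]).
#' @return A list with elements `ex17` and `ex18`, each a named list of
#'   deletion variants from [design_microdeletions()].
#' @export
mgbr2_microdeletion_series <- function(construct = mgbr2_construct()) {
  list(
    ex17 = design_microdeletions(construct, "EX17", window = 10L,
                                 from = 7944L, n = 3L),
    ex18 = design_microdeletions(construct, "EX18", window = 10L,
                                 starts = c(7979L, 7989L, 7999L, 8004L,
                                            8014L, 8024L))
  )
}

parse_transcript_field <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  fr <- purrr::map_dbl(kv, function(p) as.numeric(p[2])) / 100
  names(fr) <- normalize_transcript_label(purrr::map_chr(kv, 1))
  fr
}

#' The 52-variant fixture cohort
#'
#' Reads the bundled cohort table (variant, source, per-transcript mean
#' percentages, direct coding prediction, prior evidence) and builds one
#' [variant_assay()] per variant, deriving splice-site class and exon
#' region from the construct.
#'
#' @param construct The reporter construct (defaults to
#'   [mgbr2_construct()]).
#' @return A list with `table` (the raw tibble) and `assays` (named list
#'   of `variant_assay` objects).
#' @export
mgbr2_cohort <- function(construct = mgbr2_construct()) {
  tbl <- readr::read_tsv(mg_extdata("mgbr2_cohort.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  assays <- purrr::pmap(tbl, function(variant, source, transcripts,
                                      direct_coding_prediction, prior_class,
                                      prior_reason, ...) {
    fr <- parse_transcript_field(transcripts)
    prior <- if (!is.na(prior_class) && nzchar(prior_class)) {
      list(class = prior_class, reason = prior_reason)
    } else {
      NULL
    }
    variant_assay(
      variant,
      quant_from_fractions(fr, n_replicates = 3L),
      direct_coding_prediction = if (is.na(direct_coding_prediction)) NULL else
        direct_coding_prediction,
      prior_evidence = prior,
      construct = construct)
  })
  names(assays) <- tbl$variant
  list(table = tbl, assays = assays)
}
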