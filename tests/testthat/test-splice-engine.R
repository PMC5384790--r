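# Splice-event engine: transcript structure, sizes, labels, r. strings,
# composition invariants and the candidate size table.

test_that("single events change transcript length by the expected delta", {
  con <- mgbr2_construct()
  cat <- mgbr2_event_catalog()
  fl <- apply_splice_events(con, list())
  deltas <- c("ex17 skipping" = -171L, "ex18 skipping" = -355L,
              "ex18-ins6" = 6L, "ex18-del309" = -309L, "ex17-ins8" = 8L,
              "ex17-insAG" = 2L, "ex18-del191" = -191L,
              "ex17-del151+ex18 skipping" = -506L,
              "ivs17-ret58+ex18 skipping" = -297L)
  for (lbl in names(deltas)) {
    tr <- apply_splice_events(con, cat[[lbl]])
    expect_equal(tr$length_nt - fl$length_nt, unname(deltas[lbl]), info = lbl)
  }
})

test_that("derived labels follow the field convention and normalise", {
  con <- mgbr2_construct()
  expect_equal(apply_splice_events(con,
    list(splice_event("exon_skip", "EX17")))$label, "ex17 skipping")
  expect_equal(apply_splice_events(con,
    list(splice_event("alt_donor", "EX18", offset = 309L)))$label,
    "ex18-del309")
  expect_equal(apply_splice_events(con,
    list(splice_event("alt_acceptor", "EX18", offset = -6L)))$label,
    "ex18-ins6")
  expect_equal(normalize_transcript_label(
    c("Ex17 skipping", "exon 18 skipping", "CT", "Ivs16-ins8",
      "Ex18-del309", "ex17-del151+Ex18 skipping")),
    c("ex17 skipping", "ex18 skipping", "FL", "ex17-ins8",
      "ex18-del309", "ex17-del151+ex18 skipping"))
})

test_that("incompatible or out-of-range events are refused", {
  con <- mgbr2_construct()
  expect_error(apply_splice_events(con, list(
    splice_event("alt_acceptor", "EX17", offset = 10L),
    splice_event("alt_acceptor", "EX17", offset = 20L))),
    "composition error")
  expect_error(apply_splice_events(con, list(
    splice_event("exon_skip", "EX17"),
    splice_event("alt_donor", "EX17", offset = 5L))),
    "composition error")
  expect_error(apply_splice_events(con, list(
    splice_event("alt_acceptor", "EX17", offset = 171L))),
    "span error")
})

test_that("r. descriptions match the published strings for the fixture events", {
  con <- mgbr2_construct()
  cat <- mgbr2_event_catalog()
  expected <- c(
    "FL" = "r.(=)",
    "ex17 skipping" = "r.7806_7976del",
    "ex17-del20" = "r.7806_7825del",
    "ex17-del69" = "r.7806_7874del",
    "ex18-del309" = "r.8023_8331del",
    "ex18-del298" = "r.8034_8331del",
    "ex18-del191" = "r.7977_8167del",
    "ex18-del236" = "r.7977_8212del",
    "ex18-del164" = "r.8168_8331del",
    "ex18-del157" = "r.8175_8331del",
    "ex17-insAG" = "r.7805_7806insAG",
    "ex17-ins8" = "r.7805_7806ins7806-8_7806-1",
    "ex18 skipping" = "r.7977_8331del",
    "ex17-del151+ex18 skipping" = "r.7826_8331del",
    "ivs17-ret58+ex18 skipping" = "r.7977_8331delins7976+1_7976+58")
  for (lbl in names(expected)) {
    tr <- apply_splice_events(con, cat[[lbl]])
    expect_equal(rna_hgvs(tr), unname(expected[lbl]), info = lbl)
  }
})

test_that("composition order never changes the resulting transcript", {
  set.seed(11)
  for (i in 1:20) {
    rc <- random_length_construct(4L)
    evs <- random_event_set(rc, max_events = 3L)
    if (length(evs) < 2L) next
    a <- apply_splice_events(rc, evs)
    b <- apply_splice_events(rc, rev(evs))
    expect_identical(a$pieces, b$pieces)
    expect_identical(a$length_nt, b$length_nt)
  }
})

test_that("transcript length equals canonical length plus summed event deltas", {
  set.seed(13)
  for (i in 1:30) {
    rc <- random_length_construct(sample(2:5, 1))
    evs <- random_event_set(rc, max_events = 2L)
    tr <- apply_splice_events(rc, evs)
    # brute-force: signed per-event delta from the segment table
    delta <- sum(purrr::map_int(evs, function(ev) {
      len <- rc$segments$length[rc$segments$label == ev$exon_label]
      if (ev$kind == "exon_skip") -len else -as.integer(ev$offset)
    }))
    expect_equal(tr$length_nt, tr$canonical_length_nt + delta)
  }
})

test_that("r. strings round-trip to the same retained exonic intervals", {
  con <- mgbr2_construct()
  cat <- mgbr2_event_catalog()
  canon <- construct_exons(con)
  canon_iv <- purrr::map2(canon$c_start, canon$c_end, c)
  subtract <- function(ivs, del) {
    out <- list()
    for (iv in ivs) {
      if (del[2] < iv[1] || del[1] > iv[2]) {
        out[[length(out) + 1L]] <- iv
      } else {
        if (del[1] > iv[1]) out[[length(out) + 1L]] <- c(iv[1], del[1] - 1L)
        if (del[2] < iv[2]) out[[length(out) + 1L]] <- c(del[2] + 1L, iv[2])
      }
    }
    out
  }
  structural <- setdiff(names(cat), "878nt")
  for (lbl in structural) {
    tr <- apply_splice_events(con, cat[[lbl]])
    parsed <- parse_rna_hgvs(rna_hgvs(tr))
    implied <- canon_iv
    for (d in parsed$dels) implied <- subtract(implied, d)
    got <- minigene:::transcript_retained_c(tr)
    expect_equal(purrr::map(got, as.integer), purrr::map(implied, as.integer),
                 info = lbl)
  }
})

test_that("the candidate size table reproduces the expected amplicons", {
  con <- mgbr2_construct()
  cat <- mgbr2_event_catalog()
  tbl <- candidate_transcript_table(con, cat, "EX16_FW", "PSAD_RV")
  sizes <- setNames(tbl$amplicon_size, tbl$label)
  expect_equal(sizes[["FL"]], 1012)
  expect_equal(sizes[["ex17 skipping"]], 841)
  expect_equal(sizes[["ex18 skipping"]], 657)
  expect_equal(sizes[["ex17-del1"]], 1011) # resolvable 1 nt from FL
  expect_equal(sizes[["878nt"]], 878)
  expect_true(tbl$placeholder[tbl$label == "878nt"])
  # losing the forward-primer exon flags the transcript unamplifiable
  cat2 <- list(FL = list(),
               noamp = list(splice_event("exon_skip", "EX16")))
  tbl2 <- candidate_transcript_table(con, cat2, "EX16_FW", "PSAD_RV")
  expect_false(tbl2$amplifiable[tbl2$label == "noamp"])
  # catalogs must be labelled uniquely and contain the canonical set
  expect_error(candidate_transcript_table(con, cat[-1], "EX16_FW", "PSAD_RV"),
               "catalog error")
})
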