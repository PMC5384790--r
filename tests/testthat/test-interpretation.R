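# Aberrant fraction, the 5% spliceogenicity rule, the decision table and
# cohort summaries on the bundled fixture.

fixture_assay <- function(variant, fractions, ...) {
  variant_assay(variant, quant_from_fractions(fractions),
                construct = mgbr2_construct(), ...)
}

test_that("aberrant fraction is one minus the canonical mean fraction", {
  a <- fixture_assay("c.7975A>G", c(FL = 73.8, "ex17 skipping" = 26.2))
  expect_equal(aberrant_fraction(a), 0.262, tolerance = 1e-9)
  b <- fixture_assay("c.7976G>A", c("ex17 skipping" = 100))
  expect_equal(aberrant_fraction(b), 1)
  c0 <- fixture_assay("c.8009C>T", c(FL = 100))
  expect_equal(aberrant_fraction(c0), 0)
  # unidentified mass counts as aberrant
  d <- fixture_assay("c.8035G>T", c(FL = 90, "unidentified-878" = 10))
  expect_equal(aberrant_fraction(d), 0.1, tolerance = 1e-9)
})

test_that("the 5% spliceogenicity rule is inclusive at the boundary", {
  expect_true(is_spliceogenic(
    fixture_assay("c.8072C>T", c(FL = 94.9, "ex18 skipping" = 5.1))))
  expect_false(is_spliceogenic(
    fixture_assay("c.7875A>G", c(FL = 95.3, others = 4.7))))
  expect_true(is_spliceogenic(
    fixture_assay("c.8072C>T", c(FL = 95, "ex18 skipping" = 5))))
})

test_that("the decision table reproduces the published example calls", {
  # canonical acceptor, fully aberrant -> pathogenic via R1
  cl <- classify_variant(fixture_assay("c.7806-1G>A", c("ex17-del1" = 100),
                                       direct_coding_prediction = "intronic"))
  expect_equal(cl$label, "pathogenic")
  expect_match(cl$triggered_rules[1], "^R1")
  # predicted nonsense with 96% aberrant mass -> pathogenic via R2
  cl <- classify_variant(fixture_assay(
    "c.8009C>A", c("ex18 skipping" = 91.2, "ex18-del191" = 4.8, FL = 4),
    direct_coding_prediction = "nonsense"))
  expect_equal(cl$label, "pathogenic")
  expect_match(cl$triggered_rules[1], "^R2")
  # exon-terminal substitution at 59.3% aberrant -> likely pathogenic
  cl <- classify_variant(fixture_assay(
    "c.8331G>A", c("ex18 skipping" = 52, FL = 40.7, others = 7.3),
    direct_coding_prediction = "synonymous"))
  expect_equal(cl$label, "likely_pathogenic")
  # exonic, 26.2% aberrant -> VUS
  cl <- classify_variant(fixture_assay(
    "c.7975A>G", c(FL = 73.8, "ex17 skipping" = 26.2),
    direct_coding_prediction = "missense"))
  expect_equal(cl$label, "vus")
  # prior evidence upgrades out of VUS and is recorded
  cl <- classify_variant(fixture_assay(
    "c.8168A>G", c(FL = 69.6, "ex18-del164" = 25.9, "ex18 skipping" = 4.5),
    direct_coding_prediction = "missense",
    prior_evidence = list(class = "likely_pathogenic",
                          reason = "protein function")))
  expect_equal(cl$label, "likely_pathogenic_prior")
  expect_true(any(grepl("R4-prior", cl$triggered_rules)))
})

test_that("classification is monotone in aberrant fraction", {
  site_cases <- list(
    list(site = NULL, variant = "c.7806-1G>A", pred = "intronic"),
    list(site = NULL, variant = "c.8009C>T", pred = "missense"),
    list(site = NULL, variant = "c.8249_8250del", pred = "frameshift"))
  rank <- c(not_spliceogenic = 0, vus = 1, likely_pathogenic = 2,
            likely_pathogenic_prior = 2, pathogenic = 3)
  for (case in site_cases) {
    prev <- -1
    for (ab in seq(0, 1, by = 0.05)) {
      a <- fixture_assay(case$variant,
                         c(FL = 100 * (1 - ab), aberrant = 100 * ab),
                         direct_coding_prediction = case$pred)
      r <- rank[[classify_variant(a)$label]]
      expect_gte(r, prev)
      prev <- r
    }
  }
})

test_that("thresholds are configurable and validated", {
  a <- fixture_assay("c.8009C>T", c(FL = 40, "ex18 skipping" = 60),
                     direct_coding_prediction = "missense")
  expect_equal(classify_variant(a)$label, "likely_pathogenic")
  strict <- classification_thresholds(likely_pathogenic = 0.8)
  expect_equal(classify_variant(a, strict)$label, "vus")
  expect_error(classification_thresholds(spliceogenic = 0.5,
                                         likely_pathogenic = 0.3))
})

test_that("the fixture cohort reproduces the published partition exactly", {
  co <- mgbr2_cohort()
  expect_equal(length(co$assays), 52L)
  s <- cohort_summary(co$assays)
  expect_equal(s$n_variants, 52L)
  expect_equal(s$n_spliceogenic, 30L)
  expect_equal(s$n_spliceogenic / s$n_variants, 0.577, tolerance = 1e-3)
  counts <- s$class_counts
  expect_equal(unname(counts[["pathogenic"]]), 12L)
  expect_equal(unname(counts[["likely_pathogenic"]]), 8L)
  expect_equal(unname(counts[["vus"]]), 8L)
  expect_equal(unname(counts[["likely_pathogenic_prior"]]), 2L)

  pv <- s$per_variant
  expect_setequal(pv$variant[pv$label == "pathogenic"],
    c("c.7806-2A>G", "c.7806-1G>A", "c.7806-1G>T", "c.7806-1_7806-2dup",
      "c.7976+1G>A", "c.7977-3_7978del", "c.7977-2A>T", "c.7977-1G>T",
      "c.7977-1G>C", "c.8009C>A", "c.8331+1G>T", "c.8331+2T>C"))
  expect_setequal(pv$variant[pv$label == "likely_pathogenic"],
    c("c.7806-9T>G", "c.7976G>C", "c.7976G>A", "c.7977-7C>G", "c.7985C>G",
      "c.8023A>G", "c.8035G>T", "c.8331G>A"))
  expect_setequal(pv$variant[pv$label == "vus"],
    c("c.7975A>G", "c.7977-6T>G", "c.7988A>T", "c.7992T>A", "c.8007A>G",
      "c.8009C>T", "c.8009C>G", "c.8072C>T"))
  expect_setequal(pv$variant[pv$label == "likely_pathogenic_prior"],
    c("c.8168A>G", "c.8249_8250del"))
})

test_that("regional summaries match brute-force recomputation of the fixture", {
  co <- mgbr2_cohort()
  s <- cohort_summary(co$assays)
  br <- s$by_region
  expect_equal(br$n_variants[br$region == "EX17"], 17L)
  expect_equal(br$n_variants[br$region == "EX18"], 35L)
  # 19 of the 21 spliceogenic exon-18-region variants include full skipping
  expect_equal(br$n_spliceogenic[br$region == "EX18"], 21L)
  expect_equal(br$n_full_exon_skip[br$region == "EX18"], 19L)
  # exon-17 variants yield exactly 6 distinct characterised species
  expect_equal(br$n_distinct_aberrant[br$region == "EX17"], 6L)

  # oracle: recompute from the raw table
  tbl <- co$table
  labs <- strsplit(tbl$transcripts, ";")
  aberrant <- purrr::map_dbl(labs, function(x) {
    kv <- strsplit(x, ":")
    sum(purrr::map_dbl(kv, function(p) {
      if (p[1] == "FL") 0 else as.numeric(p[2])
    }))
  })
  expect_equal(sum(aberrant >= 5), s$n_spliceogenic)
})

test_that("an empty cohort gives an all-zero summary", {
  s <- cohort_summary(list())
  expect_equal(s$n_variants, 0L)
  expect_equal(s$n_spliceogenic, 0L)
})

test_that("the cohort report renders one labelled row per variant", {
  co <- mgbr2_cohort()
  rep <- cohort_report(co$assays[1:5])
  expect_equal(nrow(rep), 5L)
  expect_true(all(c("variant", "transcripts", "classification",
                    "rules") %in% names(rep)))
  path <- withr::local_tempfile(fileext = ".tsv")
  cohort_report(co$assays[1:5], path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 5L)
})
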