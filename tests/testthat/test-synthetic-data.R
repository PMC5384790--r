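# Synthetic minigene and electropherogram simulation: determinism,
# splice-site grammar, CDS integrity, and estimator recovery.

test_that("generation is deterministic under the spec seed", {
  spec <- synthetic_gene_spec(n_exons = 3L, seed = 7L)
  g1 <- make_synthetic_minigene(spec)
  g2 <- make_synthetic_minigene(spec)
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$cds$cds, g2$cds$cds)
  g3 <- make_synthetic_minigene(synthetic_gene_spec(n_exons = 3L, seed = 8L))
  expect_false(identical(g1$segments$sequence, g3$segments$sequence))
})

test_that("introns carry the requested donor dinucleotide and AG acceptors", {
  spec <- synthetic_gene_spec(n_exons = 3L, seed = 7L,
                              donor_style = c("GT", "GC", "GT", "GT"))
  g <- make_synthetic_minigene(spec)
  introns <- g$segments[g$segments$role == "intron", ]
  expect_equal(substr(introns$sequence[2], 1, 2), "GC")
  for (i in seq_len(nrow(introns))) {
    expect_true(substr(introns$sequence[i], 1, 2) %in% c("GT", "GC"))
    expect_equal(substr(introns$sequence[i],
                        introns$length[i] - 1L, introns$length[i]), "AG")
  }
})

test_that("the generated CDS translates end-to-end without internal stops", {
  for (seed in c(1L, 7L, 23L)) {
    g <- make_synthetic_minigene(synthetic_gene_spec(n_exons = 4L,
                                                     seed = seed))
    aa <- oracle_translate(g$cds$cds)
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
    # exon sequences concatenate to the CDS
    ex <- construct_exons(g)
    expect_equal(paste(ex$sequence, collapse = ""), g$cds$cds)
  }
})

test_that("noise-free simulation recovers fractions exactly", {
  cand <- c(FL = 1012, skip = 841, minor = 715)
  p <- simulation_params(c(FL = 0.6, skip = 0.3, minor = 0.1),
                         area_cv = 0, size_jitter_sd_nt = 0,
                         n_replicates = 3L, seed = 5L)
  pk <- simulate_peak_table(cand, p)
  expect_equal(sort(unique(pk$size_nt)), sort(unname(cand)))
  q <- quantify(assign_peaks(filter_peaks(pk), cand))
  truth <- p$true_fractions[q$label]
  expect_equal(q$mean_fraction, unname(truth), tolerance = 1e-9)
  expect_equal(q$sd, rep(0, 3), tolerance = 1e-9)
})

test_that("a single-species mixture with no jitter sits exactly on its size", {
  p <- simulation_params(c(FL = 1), size_jitter_sd_nt = 0, n_replicates = 1L,
                         seed = 2L)
  pk <- suppressWarnings(simulate_peak_table(c(FL = 1012), p))
  expect_equal(pk$size_nt, 1012)
  expect_equal(nrow(pk), 1L)
})

test_that("default-noise simulations recover 1-5 species within 2 points", {
  set.seed(0)
  mixtures <- list(
    c(FL = 1),
    c(skip = 0.871, combo = 0.129),
    c(FL = 0.738, skip = 0.262),
    c(FL = 0.667, a = 0.31, b = 0.023),
    c(FL = 0.81, a = 0.064, b = 0.061, cc = 0.037, d = 0.028))
  sizes <- c(FL = 1012, skip = 657, combo = 506, a = 841, b = 821,
             cc = 715, d = 878)
  for (m in mixtures) {
    p <- simulation_params(m, n_replicates = 3L, seed = 17L)
    pk <- simulate_peak_table(sizes[names(m)], p)
    q <- quantify(assign_peaks(filter_peaks(pk), sizes[names(m)]))
    truth <- m[q$label]
    expect_lt(max(abs(q$mean_fraction - truth)), 0.02)
  }
})

test_that("species one nucleotide apart are still recovered", {
  cand <- c(FL = 1012, del1 = 1011)
  p <- simulation_params(c(FL = 0.9, del1 = 0.1), size_jitter_sd_nt = 0.1,
                         n_replicates = 3L, seed = 19L)
  pk <- simulate_peak_table(cand, p)
  q <- quantify(assign_peaks(filter_peaks(pk), cand, tolerance_nt = 0.4))
  expect_lt(abs(q$mean_fraction[q$label == "del1"] - 0.1), 0.02)
})

test_that("replicate SDs driven by the default area CV stay below 1.8 points", {
  # size-calling jitter is disabled so the dispersion measured is the one
  # the area CV calibrates; worst case is the 50/50 mixture
  p <- simulation_params(c(FL = 0.7, skip = 0.3), size_jitter_sd_nt = 0,
                         n_replicates = 50L, seed = 23L)
  pk <- simulate_peak_table(c(FL = 1012, skip = 841), p)
  q <- quantify(assign_peaks(filter_peaks(pk), c(FL = 1012, skip = 841)))
  expect_lt(max(q$sd), 0.018)
  # analytic worst-case bound of the delta method at p = 0.5
  expect_lt(0.25 * sqrt(2) * 0.05, 0.018)
})

test_that("mean recovered fraction converges to truth (law of large numbers)", {
  p <- simulation_params(c(FL = 0.7, skip = 0.3), n_replicates = 200L,
                         seed = 29L)
  pk <- simulate_peak_table(c(FL = 1012, skip = 841), p)
  q <- quantify(assign_peaks(filter_peaks(pk), c(FL = 1012, skip = 841)))
  se <- q$sd / sqrt(200)
  expect_lt(abs(q$mean_fraction[q$label == "FL"] - 0.7), 3 * se[q$label == "FL"])
})

test_that("sub-threshold minor species drop out and mass renormalises", {
  p <- simulation_params(c(FL = 0.999, tiny = 0.001), area_cv = 0,
                         size_jitter_sd_nt = 0, n_replicates = 3L, seed = 3L,
                         rfu_scale = 1e4)
  pk <- simulate_peak_table(c(FL = 1012, tiny = 900), p)
  kept <- suppressMessages(filter_peaks(pk, min_height_rfu = 50))
  expect_false(any(abs(kept$size_nt - 900) < 1))
  q <- quantify(assign_peaks(kept, c(FL = 1012, tiny = 900)))
  expect_equal(q$mean_fraction[q$label == "FL"], 1)
})

test_that("simulated assay bundles feed the whole downstream path", {
  con <- mgbr2_construct()
  truth <- list(
    "c.8331+2T>C" = list(
      catalog = list(FL = list(),
                     "ex18 skipping" = mgbr2_event_catalog()[["ex18 skipping"]],
                     "ex17-del151+ex18 skipping" =
                       mgbr2_event_catalog()[["ex17-del151+ex18 skipping"]]),
      fractions = c("ex18 skipping" = 0.871,
                    "ex17-del151+ex18 skipping" = 0.129)),
    "wt" = list(catalog = list(FL = list()), fractions = c(FL = 1)))
  p <- simulation_params(c(FL = 1), seed = 37L)
  bundles <- simulate_assay(con, truth, p, "EX16_FW", "PSAD_RV")
  # two species -> two peaks per replicate
  expect_equal(nrow(bundles[["c.8331+2T>C"]]$peaks), 6L)
  q <- quantify(assign_peaks(filter_peaks(bundles[["c.8331+2T>C"]]$peaks),
                             bundles[["c.8331+2T>C"]]$candidates))
  a1 <- variant_assay("c.8331+2T>C", q, construct = con)
  expect_true(is_spliceogenic(a1))
  q2 <- quantify(assign_peaks(filter_peaks(bundles[["wt"]]$peaks),
                              bundles[["wt"]]$candidates))
  a2 <- variant_assay("c.8009C>T", q2, construct = con)
  expect_false(is_spliceogenic(a2))
  expect_equal(classify_variant(a2)$label, "not_spliceogenic")
})

test_that("the naive caller recovers simulated trace peaks", {
  p <- simulation_params(c(FL = 0.8, skip = 0.2), size_jitter_sd_nt = 0,
                         n_replicates = 1L, seed = 41L)
  pk <- suppressWarnings(simulate_peak_table(c(FL = 1012, skip = 841), p))
  tr <- simulate_trace(pk)
  called <- call_peaks(tr)
  expect_equal(nrow(called), 2L)
  expect_equal(sort(round(called$size_nt)), c(841, 1012))
  frac <- called$area / sum(called$area)
  expect_lt(abs(max(frac) - 0.8), 0.05)
})
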