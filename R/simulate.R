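# Synthetic data generation: minigene constructs with valid splice sites
# and a translatable CDS, and simulated fragment-analysis peak tables
# with controlled mixture proportions and noise.
#
# Noise model: per-peak multiplicative lognormal area noise (unit mean,
# coefficient of variation `area_cv`) and additive Gaussian size-calling
# jitter. This is the simplest model reproducing the replicate-level
# reproducibility of capillary assays; the default CV of 0.05 keeps
# replicate standard deviations of two-species fractions below about
# 1.8 percentage points.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Specification for a synthetic minigene
#'
#' @param n_exons Number of cloned exons.
#' @param exon_length_range Integer length-2 vector; exon lengths are
#'   drawn uniformly from this range (minimum 6, to honour protected
#'   exon ends).
#' @param intron_length_range Integer length-2 vector (minimum 20).
#' @param donor_style `"GT"` or `"GC"` per intron (recycled); GC donors
#'   occur naturally in a small minority of introns.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_gene_spec`.
#' @export
synthetic_gene_spec <- function(n_exons = 3L,
                                exon_length_range = c(60L, 180L),
                                intron_length_range = c(80L, 300L),
                                donor_style = "GT",
                                seed = 1L) {
  stopifnot(n_exons >= 1L,
            exon_length_range[1] >= 6L,
            intron_length_range[1] >= 20L,
            exon_length_range[2] >= exon_length_range[1],
            intron_length_range[2] >= intron_length_range[1],
            all(donor_style %in% c("GT", "GC")))
  structure(list(n_exons = as.integer(n_exons),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 donor_style = rep_len(donor_style, n_exons + 1L),
                 seed = as.integer(seed)),
            class = "synthetic_gene_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intron with donor dinucleotide, random core, polypyrimidine tract and
# acceptor AG
random_intron <- function(n, donor = "GT") {
  stopifnot(n >= 20L)
  ppt <- paste(sample(c("C", "T"), 12L, replace = TRUE, prob = c(0.4, 0.6)),
               collapse = "")
  core <- random_dna(n - nchar(donor) - nchar(ppt) - 2L)
  paste0(donor, core, ppt, "AG")
}

#' Generate a synthetic minigene construct with sequences
#'
#' Builds a vector-exon-flanked multi-exon gene whose introns carry AG
#' acceptors and GT (or GC) donors, together with a coding context: the
#' concatenated exons form a CDS starting with ATG, free of internal
#' stops, and ending with a stop codon, so consequence annotation can
#' translate any transcript. Exon c. anchors are contiguous from c.1.
#'
#' @param spec A [synthetic_gene_spec()].
#' @return A `minigene_construct` with sequences; its `cds` field holds
#'   the matching [coding_context()].
#' @export
make_synthetic_minigene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gene_spec"))
  withr_seed(spec$seed, {
    ex_len <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]),
                     spec$n_exons, replace = TRUE)
    # make the CDS a codon multiple
    total <- sum(ex_len)
    ex_len[spec$n_exons] <- ex_len[spec$n_exons] + (3L - total %% 3L) %% 3L
    n_codons <- sum(ex_len) %/% 3L
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    starts <- cumsum(c(1L, ex_len[-spec$n_exons]))
    ends <- cumsum(ex_len)
    in_len <- sample(seq(spec$intron_length_range[1],
                         spec$intron_length_range[2]),
                     spec$n_exons + 1L, replace = TRUE)
    segs <- list(list(role = "vector_exon", label = "V1", length = 100L,
                      sequence = random_dna(100L)))
    for (i in seq_len(spec$n_exons)) {
      segs[[length(segs) + 1L]] <-
        list(role = "intron", label = paste0("IVS", i - 1L),
             length = in_len[i],
             sequence = random_intron(in_len[i], spec$donor_style[i]))
      segs[[length(segs) + 1L]] <-
        list(role = "exon", label = paste0("EX", i), length = ex_len[i],
             c_start = starts[i], c_end = ends[i],
             sequence = substr(cds, starts[i], ends[i]))
    }
    segs[[length(segs) + 1L]] <-
      list(role = "intron", label = paste0("IVS", spec$n_exons),
           length = in_len[spec$n_exons + 1L],
           sequence = random_intron(in_len[spec$n_exons + 1L],
                                    spec$donor_style[spec$n_exons + 1L]))
    segs[[length(segs) + 1L]] <-
      list(role = "vector_exon", label = "V2", length = 80L,
           sequence = random_dna(80L))
    primers <- list(
      list(name = "V1_FW", segment_label = "V1", offset = 30L,
           direction = "forward"),
      list(name = "V2_RV", segment_label = "V2", offset = 30L,
           direction = "reverse"))
    x <- build_construct(segs, primers, name = sprintf("synthetic_%d_exon",
                                                       spec$n_exons))
    x$cds <- coding_context(cds, name = x$name)
    x
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation parameters for fragment-analysis peak tables
#'
#' @param true_fractions Named numeric vector of molar transcript
#'   fractions (must sum to 1 within 1e-6; renormalised).
#' @param peak_sigma_nt Gaussian peak width (nt); height is derived from
#'   area as `area / (sigma * sqrt(2*pi))`.
#' @param area_cv Coefficient of variation of the multiplicative
#'   lognormal area noise, per peak per replicate.
#' @param size_jitter_sd_nt Standard deviation of the size-calling error.
#' @param n_replicates Number of replicates to simulate.
#' @param seed Integer seed.
#' @param rfu_scale Total signal scale (sum of expected areas).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(true_fractions,
                              peak_sigma_nt = 0.25,
                              area_cv = 0.05,
                              size_jitter_sd_nt = 0.15,
                              n_replicates = 3L,
                              seed = 1L,
                              rfu_scale = 1e5) {
  stopifnot(!is.null(names(true_fractions)), all(true_fractions >= 0),
            abs(sum(true_fractions) - 1) < 1e-6,
            peak_sigma_nt > 0, area_cv >= 0, size_jitter_sd_nt >= 0,
            n_replicates >= 1L)
  structure(list(true_fractions = true_fractions / sum(true_fractions),
                 peak_sigma_nt = peak_sigma_nt, area_cv = area_cv,
                 size_jitter_sd_nt = size_jitter_sd_nt,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), rfu_scale = rfu_scale),
            class = "simulation_params")
}

#' Simulate per-replicate peak tables for a transcript mixture
#'
#' One peak per nonzero-fraction transcript per replicate: expected area
#' is `rfu_scale * fraction`, multiplied by unit-mean lognormal noise;
#' the called size is the candidate size plus Gaussian jitter; height is
#' derived from area and peak width. Deterministic under the seed.
#'
#' @param candidates Named numeric vector of amplicon sizes (or the
#'   tibble from [candidate_transcript_table()]).
#' @param params A [simulation_params()]; `true_fractions` names must be
#'   a subset of the candidate labels.
#' @return A peak tibble (`replicate_id`, `size_nt`, `height_rfu`,
#'   `area`) with the seed recorded in the `seed` attribute.
#' @export
simulate_peak_table <- function(candidates, params) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.data.frame(candidates)) {
    candidates <- stats::setNames(candidates$amplicon_size, candidates$label)
  }
  fr <- params$true_fractions[params$true_fractions > 0]
  miss <- setdiff(names(fr), names(candidates))
  if (length(miss)) {
    stop("no candidate size for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sdlog <- sqrt(log(1 + params$area_cv^2))
  withr_seed(params$seed, {
    rows <- purrr::map(seq_len(params$n_replicates), function(r) {
      noise <- exp(stats::rnorm(length(fr), -sdlog^2 / 2, sdlog))
      area <- params$rfu_scale * unname(fr) * noise
      size <- unname(candidates[names(fr)]) +
        stats::rnorm(length(fr), 0, params$size_jitter_sd_nt)
      tibble::tibble(replicate_id = sprintf("rep%d", r),
                     size_nt = size,
                     height_rfu = area / (params$peak_sigma_nt * sqrt(2 * pi)),
                     area = area)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "seed") <- params$seed
    out
  })
}

#' Simulate a full assay bundle for a set of variants
#'
#' For each variant, applies its true event-set catalog to the construct,
#' derives candidate amplicon sizes, and simulates replicate peak tables
#' at the stated true mixture, yielding inputs directly consumable by
#' [assign_peaks()]/[quantify()] and downstream interpretation.
#'
#' @param construct A minigene construct with primers.
#' @param truth Named list: variant id -> list with elements `catalog`
#'   (named list of event sets; must include `FL = list()`) and
#'   `fractions` (named numeric, summing to 1).
#' @param params A [simulation_params()] template; its `true_fractions`
#'   are replaced per variant and its seed is offset per variant.
#' @param fwd,rev Primer names.
#' @return Named list per variant with elements `candidates` (size table)
#'   and `peaks` (simulated peak tibble).
#' @export
simulate_assay <- function(construct, truth, params, fwd, rev) {
  purrr::imap(truth, function(tr, id) {
    cand <- candidate_transcript_table(construct, tr$catalog, fwd, rev)
    cand <- cand[cand$amplifiable, ]
    p <- params
    p$true_fractions <- tr$fractions / sum(tr$fractions)
    p$seed <- params$seed + match(id, names(truth))
    list(candidates = cand, peaks = simulate_peak_table(cand, p))
  })
}

#' Render a simulated electropherogram trace from peaks
#'
#' Sums Gaussian peaks on a size grid; intended for plotting and for
#' exercising the naive peak caller on simulated raw traces.
#'
#' @param peaks A peak tibble for one replicate.
#' @param sigma_nt Gaussian peak width.
#' @param grid_step Grid spacing in nt.
#' @param pad Grid padding beyond the outermost peaks.
#' @return A tibble with `size_nt` and `rfu`.
#' @export
simulate_trace <- function(peaks, sigma_nt = 0.25, grid_step = 0.05,
                           pad = 5) {
  grid <- seq(min(peaks$size_nt) - pad, max(peaks$size_nt) + pad,
              by = grid_step)
  rfu <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks))) {
    h <- peaks$area[i] / (sigma_nt * sqrt(2 * pi))
    rfu <- rfu + h * exp(-(grid - peaks$size_nt[i])^2 / (2 * sigma_nt^2))
  }
  tibble::tibble(size_nt = grid, rfu = rfu)
}

#' Naive Gaussian peak caller for simulated traces
#'
#' Finds local maxima above a height floor and integrates the trace
#' around each; adequate for simulated traces only (no baseline
#' correction or size-standard calibration).
#'
#' @param trace Output of [simulate_trace()].
#' @param min_height_rfu Minimum apex height.
#' @param min_separation_nt Minimum spacing between called apexes.
#' @return A peak tibble (single replicate `"called"`).
#' @export
call_peaks <- function(trace, min_height_rfu = 50, min_separation_nt = 0.5) {
  y <- trace$rfu
  n <- length(y)
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] >= min_height_rfu]
  apex <- apex[order(-y[apex])]
  kept <- integer(0)
  for (a in apex) {
    if (all(abs(trace$size_nt[a] - trace$size_nt[kept]) >= min_separation_nt)) {
      kept <- c(kept, a)
    }
  }
  kept <- sort(kept)
  step <- if (n > 1) trace$size_nt[2] - trace$size_nt[1] else 1
  purrr::map_dfr(kept, function(a) {
    lo <- a; hi <- a
    while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
    while (hi < n && y[hi + 1L] < y[hi]) hi <- hi + 1L
    tibble::tibble(replicate_id = "called",
                   size_nt = trace$size_nt[a],
                   height_rfu = y[a],
                   area = sum(y[lo:hi]) * step)
  })
}
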