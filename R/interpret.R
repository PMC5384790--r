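# Variant-level interpretation: aberrant-transcript fraction, the
# spliceogenicity rule, a codified splicing-viewpoint classification, and
# cohort summaries.
#
# The decision table reproduces the ACMG-style splicing-viewpoint calls
# this package codifies:
#   R1  canonical +/-1/+/-2 dinucleotide variant with >= 95% aberrant
#       transcript mass                                   -> pathogenic
#   R2  variant whose direct coding prediction is nonsense/frameshift,
#       with >= 95% aberrant mass                         -> pathogenic
#   R3  otherwise >= 55% aberrant mass                    -> likely_pathogenic
#   R4  otherwise >= 5% aberrant mass                     -> vus, unless
#       supplied prior (non-splicing) evidence upgrades it, in which case
#       the label is likely_pathogenic_prior and the prior is recorded
#   R5  otherwise                                         -> not_spliceogenic
# All thresholds are configurable; triggered rules are always reported.

#' Classification thresholds
#'
#' @param spliceogenic Minimum aberrant fraction to call a variant
#'   spliceogenic (inclusive).
#' @param likely_pathogenic Aberrant fraction above which a spliceogenic
#'   variant without canonical-site/truncation support is still likely
#'   pathogenic (severe splicing aberration).
#' @param pathogenic Aberrant fraction required (with canonical-site or
#'   predicted-truncation support) for a pathogenic call.
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(spliceogenic = 0.05,
                                      likely_pathogenic = 0.55,
                                      pathogenic = 0.95) {
  stopifnot(spliceogenic <= likely_pathogenic,
            likely_pathogenic <= pathogenic)
  list(spliceogenic = spliceogenic,
       likely_pathogenic = likely_pathogenic,
       pathogenic = pathogenic)
}

#' Bundle a variant's assay evidence
#'
#' @param variant A [parse_variant()] object or HGVS c. string.
#' @param quant A `quant_result` ([quantify()] or
#'   [quant_from_fractions()]); labels should be normalised
#'   ([normalize_transcript_label()]); a missing `FL` row is added with
#'   fraction 0 provided at least one transcript was quantified.
#' @param site_class `"canonical_dinucleotide"`, `"splice_region"` or
#'   `"exonic"`; derived with [variant_site_class()] when a construct is
#'   given.
#' @param direct_coding_prediction One of `"nonsense"`, `"frameshift"`,
#'   `"missense"`, `"synonymous"`, `"in_frame"`, `"intronic"`.
#' @param consequences Optional named list of [protein_consequence()]
#'   results per transcript label.
#' @param prior_evidence Optional list with `class` (e.g.
#'   `"likely_pathogenic"`) and `reason` for non-splicing prior evidence.
#' @param construct Optional construct used to derive `site_class` and
#'   the variant's exon region.
#' @return An object of class `variant_assay`.
#' @export
variant_assay <- function(variant, quant, site_class = NULL,
                          direct_coding_prediction = NULL,
                          consequences = NULL, prior_evidence = NULL,
                          construct = NULL) {
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(quant, "quant_result"))
  if (!"FL" %in% quant$label) {
    if (nrow(quant) == 0L) {
      stop("configuration error: quantification holds no transcripts",
           call. = FALSE)
    }
    quant <- dplyr::bind_rows(
      quant, tibble::tibble(label = "FL", mean_fraction = 0, sd = NA_real_,
                            n = quant$n[1]))
    class(quant) <- c("quant_result", class(tibble::tibble()))
  }
  if (is.null(site_class)) {
    if (is.null(construct)) {
      stop("annotation error: site_class required (or give a construct)",
           call. = FALSE)
    }
    site_class <- variant_site_class(construct, variant)
  }
  region <- if (!is.null(construct)) {
    variant_region(construct, variant)
  } else {
    NA_character_
  }
  structure(list(variant = variant, quant = quant, site_class = site_class,
                 direct_coding_prediction = direct_coding_prediction,
                 consequences = consequences, prior_evidence = prior_evidence,
                 region = region),
            class = "variant_assay")
}

#' @export
print.variant_assay <- function(x, ...) {
  cat("<variant_assay> ", x$variant$c_hgvs, " (", x$site_class, "), ",
      sprintf("%.1f%%", 100 * aberrant_fraction(x)), " aberrant\n", sep = "")
  invisible(x)
}

#' Aberrant transcript fraction of an assay
#'
#' One minus the mean fraction of the canonical (full-length) transcript;
#' unidentified species count as aberrant mass.
#'
#' @param assay A [variant_assay()].
#' @return Fraction in `[0, 1]`.
#' @export
aberrant_fraction <- function(assay) {
  q <- assay$quant
  fl <- q$mean_fraction[q$label == "FL"]
  if (length(fl) != 1L) {
    stop("configuration error: no (unique) FL transcript in quantification",
         call. = FALSE)
  }
  max(0, min(1, 1 - fl))
}

#' Is a variant spliceogenic?
#'
#' @param assay A [variant_assay()].
#' @param threshold Minimum aberrant fraction (inclusive).
#' @return Logical.
#' @export
is_spliceogenic <- function(assay, threshold = 0.05) {
  aberrant_fraction(assay) >= threshold
}

#' Classify a variant from the splicing viewpoint
#'
#' Applies the decision table documented above. Thresholds are
#' configurable; the rules that fired (including recorded prior
#' evidence) are always reported.
#'
#' @param assay A [variant_assay()] with `site_class` and (for R2)
#'   `direct_coding_prediction` populated.
#' @param thresholds A [classification_thresholds()] list.
#' @return An object of class `variant_classification`: list with
#'   `label`, `aberrant_fraction`, `triggered_rules`.
#' @export
classify_variant <- function(assay, thresholds = classification_thresholds()) {
  if (is.null(assay$site_class)) {
    stop("annotation error: site_class missing", call. = FALSE)
  }
  ab <- aberrant_fraction(assay)
  rules <- character(0)
  label <- NULL

  if (ab < thresholds$spliceogenic) {
    label <- "not_spliceogenic"
    rules <- sprintf("R5: aberrant %.1f%% < %.0f%% spliceogenicity threshold",
                     100 * ab, 100 * thresholds$spliceogenic)
  } else if (assay$site_class == "canonical_dinucleotide" &&
             ab >= thresholds$pathogenic) {
    label <- "pathogenic"
    rules <- sprintf(
      "R1: canonical +/-1/+/-2 site variant with %.1f%% aberrant mass",
      100 * ab)
  } else if (!is.null(assay$direct_coding_prediction) &&
             assay$direct_coding_prediction %in% c("nonsense", "frameshift") &&
             ab >= thresholds$pathogenic) {
    label <- "pathogenic"
    rules <- sprintf(
      "R2: predicted %s variant with %.1f%% aberrant mass",
      assay$direct_coding_prediction, 100 * ab)
  } else if (ab >= thresholds$likely_pathogenic) {
    label <- "likely_pathogenic"
    rules <- sprintf("R3: severe splicing aberration (%.1f%% >= %.0f%%)",
                     100 * ab, 100 * thresholds$likely_pathogenic)
  } else {
    label <- "vus"
    rules <- sprintf("R4: partial splicing anomaly (%.1f%% aberrant)",
                     100 * ab)
    if (!is.null(assay$prior_evidence)) {
      label <- paste0(assay$prior_evidence$class, "_prior")
      rules <- c(rules, sprintf("R4-prior: upgraded to %s on prior evidence (%s)",
                                assay$prior_evidence$class,
                                assay$prior_evidence$reason))
    }
  }
  structure(list(label = label, aberrant_fraction = ab,
                 triggered_rules = rules),
            class = "variant_classification")
}

#' @export
print.variant_classification <- function(x, ...) {
  cat("<classification> ", x$label, " (",
      sprintf("%.1f%%", 100 * x$aberrant_fraction), " aberrant)\n", sep = "")
  for (r in x$triggered_rules) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Summarise a cohort of variant assays
#'
#' @param assays A list of [variant_assay()] objects.
#' @param thresholds A [classification_thresholds()] list.
#' @param placeholder_labels Transcript labels that denote
#'   uncharacterised species (excluded from distinct-species counts).
#' @return A list with `n_variants`, `n_spliceogenic`, `class_counts`
#'   (named integer vector over classification labels), `per_variant`
#'   (tibble), and `by_region` (tibble with per-exon-region variant
#'   counts, full-exon-skip counts and distinct characterised aberrant
#'   species).
#' @export
cohort_summary <- function(assays, thresholds = classification_thresholds(),
                           placeholder_labels = c("others")) {
  if (length(assays) == 0L) {
    return(list(n_variants = 0L, n_spliceogenic = 0L,
                class_counts = integer(0),
                per_variant = tibble::tibble(),
                by_region = tibble::tibble()))
  }
  per <- purrr::map_dfr(assays, function(a) {
    cl <- classify_variant(a, thresholds)
    q <- a$quant
    ab_labels <- q$label[q$label != "FL" & q$mean_fraction > 0]
    tibble::tibble(
      variant = a$variant$c_hgvs,
      region = a$region %||% NA_character_,
      site_class = a$site_class,
      aberrant_fraction = cl$aberrant_fraction,
      spliceogenic = is_spliceogenic(a, thresholds$spliceogenic),
      label = cl$label,
      species = list(ab_labels))
  })
  is_placeholder <- function(lbl) {
    lbl %in% placeholder_labels | grepl("^unidentified-", lbl) |
      grepl("^[0-9]+nt$", lbl)
  }
  by_region <- per |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_spliceogenic = sum(.data$spliceogenic),
      n_full_exon_skip = sum(purrr::map2_lgl(
        .data$species, .data$region,
        function(sp, reg) {
          n <- exon_number(reg %||% "")
          !is.na(n) && any(sp == sprintf("ex%d skipping", n))
        }) & .data$spliceogenic),
      n_distinct_aberrant = {
        sp <- unlist(.data$species[.data$spliceogenic])
        length(unique(sp[!is_placeholder(sp)]))
      },
      .groups = "drop")
  list(n_variants = nrow(per),
       n_spliceogenic = sum(per$spliceogenic),
       class_counts = table(per$label),
       per_variant = per,
       by_region = by_region)
}

#' Write a results-table style cohort report
#'
#' One row per variant: region, site class, transcript labels with mean
#' percentages, aberrant fraction, classification and triggered rules.
#'
#' @param assays A list of [variant_assay()] objects.
#' @param path Output TSV path (use `NULL` to return the tibble only).
#' @param thresholds A [classification_thresholds()] list.
#' @return The report tibble, invisibly when written.
#' @export
cohort_report <- function(assays, path = NULL,
                          thresholds = classification_thresholds()) {
  tbl <- purrr::map_dfr(assays, function(a) {
    cl <- classify_variant(a, thresholds)
    q <- a$quant[a$quant$mean_fraction > 0, ]
    tibble::tibble(
      variant = a$variant$c_hgvs,
      region = a$region %||% NA_character_,
      site_class = a$site_class,
      transcripts = paste(sprintf("%s (%.1f%%)", q$label,
                                  100 * q$mean_fraction), collapse = "; "),
      aberrant_pct = round(100 * cl$aberrant_fraction, 1),
      classification = cl$label,
      rules = paste(cl$triggered_rules, collapse = " | "))
  })
  if (!is.null(path)) {
    readr::write_tsv(tbl, path, progress = FALSE)
    return(invisible(tbl))
  }
  tbl
}
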