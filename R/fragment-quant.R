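# Capillary-electrophoresis fragment quantification: peak filtering by
# height, nearest-size assignment of peaks to candidate transcripts, and
# area-based relative abundance with replicate means and dispersions.
#
# Peak area (not height) is the abundance measure; height is used only
# for the detection filter. With a single end-labelled fluorophore per
# amplicon, signal is proportional to molar amount, so no fragment-length
# correction is applied.

#' Read a peak table
#'
#' Expects columns `replicate_id`, `size_nt`, `height_rfu`, `area`
#' (tab- or comma-separated; the dialect is detected from the extension
#' and falls back to tab).
#'
#' @param path Path to a TSV/CSV peak export.
#' @return A tibble with the four peak columns.
#' @export
read_peak_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("replicate_id", "size_nt", "height_rfu", "area")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tbl[need]
  tbl$replicate_id <- as.character(tbl$replicate_id)
  validate_peaks(tbl)
  tbl
}

#' Write a peak table
#'
#' @param peaks A peak tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  if (any(peaks$size_nt < 0 | peaks$height_rfu < 0 | peaks$area < 0,
          na.rm = TRUE)) {
    stop("peak sizes, heights and areas must be nonnegative", call. = FALSE)
  }
  invisible(peaks)
}

#' Filter peaks by detection height
#'
#' Removes peaks strictly below the RFU detection floor; the count of
#' removed peaks is reported as a message.
#'
#' @param peaks A peak tibble (columns `replicate_id`, `size_nt`,
#'   `height_rfu`, `area`).
#' @param min_height_rfu Detection floor in relative fluorescence units;
#'   peaks with height >= this value are kept.
#' @return The filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_height_rfu = 50) {
  validate_peaks(peaks)
  keep <- peaks$height_rfu >= min_height_rfu
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " peak(s) below ", min_height_rfu, " RFU removed")
  }
  peaks[keep, , drop = FALSE]
}

#' Assign peaks to candidate transcripts by size
#'
#' Each peak is assigned to the nearest candidate size within
#' `tolerance_nt`; peaks without a candidate in range are kept as
#' `unidentified-<size>` buckets (they stay in the denominator as
#' aberrant mass). Two peaks mapping to the same candidate within one
#' replicate have their areas summed with a warning.
#'
#' @param peaks A peak tibble.
#' @param candidates Named numeric vector (or two-column table
#'   `label`/`amplicon_size`) of expected amplicon sizes; sizes must be
#'   pairwise distinct.
#' @param tolerance_nt Maximum size-call deviation; must be smaller than
#'   half the minimum gap between candidate sizes, otherwise an ambiguity
#'   error is raised.
#' @return A tibble with columns `replicate_id`, `label`, `size_nt`,
#'   `area`, `identified`.
#' @export
assign_peaks <- function(peaks, candidates, tolerance_nt = 0.4) {
  validate_peaks(peaks)
  if (is.data.frame(candidates)) {
    cand <- stats::setNames(candidates$amplicon_size, candidates$label)
  } else {
    cand <- candidates
  }
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) stop("no candidate sizes", call. = FALSE)
  if (anyDuplicated(unname(cand))) {
    stop("candidate sizes must be pairwise distinct", call. = FALSE)
  }
  if (length(cand) > 1L) {
    gap <- min(diff(sort(unname(cand))))
    if (tolerance_nt >= gap / 2) {
      stop("ambiguity error: tolerance ", tolerance_nt,
           " nt >= half the minimum candidate gap (", gap,
           " nt); tighten the tolerance", call. = FALSE)
    }
  }
  assigned <- peaks
  lab <- character(nrow(peaks))
  idf <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(cand - peaks$size_nt[i])
    j <- which.min(d)
    if (d[j] <= tolerance_nt) {
      lab[i] <- names(cand)[j]
      idf[i] <- TRUE
    } else {
      lab[i] <- sprintf("unidentified-%d", round(peaks$size_nt[i]))
      idf[i] <- FALSE
    }
  }
  assigned$label <- lab
  assigned$identified <- idf
  dup <- assigned |>
    dplyr::count(.data$replicate_id, .data$label) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    warning("multiple peaks assigned to one candidate; areas summed for: ",
            paste(unique(dup$label), collapse = ", "), call. = FALSE)
  }
  assigned |>
    dplyr::group_by(.data$replicate_id, .data$label) |>
    dplyr::summarise(size_nt = stats::weighted.mean(.data$size_nt, .data$area),
                     area = sum(.data$area),
                     identified = .data$identified[1L],
                     .groups = "drop")
}

#' Quantify relative transcript abundance from assigned peaks
#'
#' Per replicate, each transcript's fraction is its peak area divided by
#' the replicate's total area; a transcript absent from a replicate
#' contributes 0 there. Across replicates, the arithmetic mean and sample
#' standard deviation are reported per label. Fewer than three replicates
#' triggers a warning (assays are expected at least in triplicate).
#'
#' @param assigned Output of [assign_peaks()] (columns `replicate_id`,
#'   `label`, `area`).
#' @return An object of class `quant_result`: tibble with `label`,
#'   `mean_fraction`, `sd`, `n`, plus a `replicates` attribute holding
#'   per-replicate fractions.
#' @export
quantify <- function(assigned) {
  reps <- unique(assigned$replicate_id)
  if (length(reps) == 0L) stop("no replicates to quantify", call. = FALSE)
  if (length(reps) < 3L) {
    warning("only ", length(reps),
            " replicate(s); assays are expected at least in triplicate",
            call. = FALSE)
  }
  totals <- assigned |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::summarise(total = sum(.data$area), .groups = "drop")
  if (any(totals$total <= 0)) {
    stop("quantification error: replicate with zero total area", call. = FALSE)
  }
  per_rep <- assigned |>
    dplyr::left_join(totals, by = "replicate_id") |>
    dplyr::mutate(fraction = .data$area / .data$total) |>
    dplyr::select("replicate_id", "label", "fraction") |>
    tidyr::complete(.data$replicate_id, .data$label,
                    fill = list(fraction = 0)) |>
    dplyr::rename(replicate_id = "replicate_id", label = "label")
  out <- per_rep |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction),
                     sd = stats::sd(.data$fraction),
                     n = dplyr::n(), .groups = "drop")
  # renormalise so mean fractions sum to exactly 1
  out$mean_fraction <- out$mean_fraction / sum(out$mean_fraction)
  res <- structure(out, class = c("quant_result", class(out)))
  attr(res, "replicates") <- per_rep
  attr(res, "n_replicates") <- length(reps)
  res
}

#' Build a quantification result from stated mean fractions
#'
#' Used when per-replicate peak data are not available but mean transcript
#' percentages are (e.g. a published results table used as fixture input).
#'
#' @param fractions Named numeric vector of mean fractions (will be
#'   renormalised to sum to 1).
#' @param n_replicates Stated replicate count.
#' @param sd Optional named numeric vector of standard deviations.
#' @return A `quant_result`.
#' @export
quant_from_fractions <- function(fractions, n_replicates = 3L, sd = NULL) {
  stopifnot(!is.null(names(fractions)), all(fractions >= 0))
  if (sum(fractions) <= 0) stop("fractions sum to zero", call. = FALSE)
  fractions <- fractions / sum(fractions)
  out <- tibble::tibble(label = names(fractions),
                        mean_fraction = unname(fractions),
                        sd = if (is.null(sd)) NA_real_ else
                          unname(sd[names(fractions)]),
                        n = as.integer(n_replicates))
  res <- structure(out, class = c("quant_result", class(out)))
  attr(res, "n_replicates") <- as.integer(n_replicates)
  res
}

#' Write a quantification result to TSV
#'
#' @param quant A `quant_result`.
#' @param path Output path.
#' @param variant Optional variant id prepended as a column.
#' @return `path`, invisibly.
#' @export
write_quant_result <- function(quant, path, variant = NULL) {
  tbl <- tibble::as_tibble(quant)
  if (!is.null(variant)) tbl <- dplyr::mutate(tbl, variant = variant,
                                              .before = 1L)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
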