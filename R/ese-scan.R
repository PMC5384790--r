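# Exonic splicing enhancer scanning: additive position-weight-matrix
# scores over exonic sequence, and intersection of motif hits with
# microdeletion windows for functional ESE mapping.

#' Create a position-weight matrix for SR-protein motif scanning
#'
#' @param name Matrix name (e.g. an SR protein).
#' @param matrix Numeric matrix, 4 rows named `A`, `C`, `G`, `T`, one
#'   column per motif position (width >= 6).
#' @param threshold Minimal reportable additive score.
#' @return An object of class `splice_pwm`.
#' @export
splice_pwm <- function(name, matrix, threshold) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)) || !setequal(rownames(matrix),
                                             c("A", "C", "G", "T"))) {
    stop("PWM rows must be named A, C, G, T", call. = FALSE)
  }
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(matrix) < 6L) stop("PWM width must be >= 6", call. = FALSE)
  if (!all(is.finite(matrix)) || !is.finite(threshold)) {
    stop("PWM scores and threshold must be finite", call. = FALSE)
  }
  structure(list(name = name, matrix = matrix, threshold = threshold),
            class = "splice_pwm")
}

#' Read PWMs from a YAML config
#'
#' The file holds a `pwms` list; each entry has `name`, `threshold` and
#' a `matrix` mapping each base to a vector of per-position scores.
#'
#' @param path Path to the YAML file.
#' @return A list of [splice_pwm()] objects.
#' @export
read_pwms <- function(path) {
  cfg <- yaml::read_yaml(path)
  purrr::map(cfg$pwms, function(p) {
    m <- do.call(rbind, p$matrix[c("A", "C", "G", "T")])
    rownames(m) <- c("A", "C", "G", "T")
    splice_pwm(p$name, m, p$threshold)
  })
}

#' Bundled synthetic SR-protein PWMs
#'
#' Loads the synthetic stand-in matrices shipped with the package
#' (`sr_pwms_synthetic.yaml`). These are constructed matrices calibrated
#' to recognise the enhancer heptamers/octamers active in the bundled
#' BRCA2 exon 17/18 fixture; they are not the published ESEfinder
#' matrices, which should be supplied as a user config when available.
#'
#' @return A list of [splice_pwm()] objects.
#' @export
sr_protein_pwms <- function() {
  read_pwms(system.file("extdata", "sr_pwms_synthetic.yaml",
                        package = "minigene", mustWork = TRUE))
}

#' Scan a sequence with PWMs
#'
#' Every window whose additive per-position score reaches the matrix
#' threshold is reported, sorted by position then score. Coordinates are
#' reported on the HGVS c. axis via the `c_start` anchor of the first
#' base.
#'
#' @param sequence Nucleotide string (A/C/G/T only; N is not allowed in
#'   scan windows).
#' @param pwms A list of [splice_pwm()] objects (possibly empty).
#' @param c_start c. coordinate of the first base of `sequence`.
#' @return A tibble with `pwm_name`, `c_start`, `c_end`, `sequence`,
#'   `score`.
#' @export
pwm_scan <- function(sequence, pwms, c_start = 1L) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("alphabet error: sequence must contain only A/C/G/T", call. = FALSE)
  }
  bases <- strsplit(sequence, "")[[1]]
  base_idx <- match(bases, c("A", "C", "G", "T"))
  n <- length(bases)
  hits <- purrr::map(pwms, function(p) {
    w <- ncol(p$matrix)
    if (n < w) return(NULL)
    starts <- seq_len(n - w + 1L)
    score <- vapply(starts, function(s) {
      sum(p$matrix[cbind(base_idx[s:(s + w - 1L)], seq_len(w))])
    }, numeric(1))
    keep <- which(score >= p$threshold)
    if (length(keep) == 0L) return(NULL)
    hit_start <- c_start + keep - 1L
    tibble::tibble(
      pwm_name = p$name,
      c_start = hit_start,
      c_end = hit_start + w - 1L,
      sequence = vapply(keep, function(s) {
        paste(bases[s:(s + w - 1L)], collapse = "")
      }, character(1)),
      score = score[keep])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pwm_name = character(), c_start = integer(),
                          c_end = integer(), sequence = character(),
                          score = numeric()))
  }
  dplyr::arrange(out, .data$c_start, dplyr::desc(.data$score))
}

#' Intersect motif hits with microdeletion windows
#'
#' For each deletion, reports the motif hits it fully or partially
#' removes, and flags motifs shared by more than one deletion (e.g. a
#' hit inside the overlap of two adjacent windows).
#'
#' @param hits Output of [pwm_scan()].
#' @param deletions A list of deletion `genomic_variant`s (or a tibble
#'   with `c_hgvs`, `start`, `end` exonic positions).
#' @return A tibble with `deletion`, `pwm_name`, `c_start`, `c_end`,
#'   `overlap_nt`, `fully_removed`, `shared`; deletions without hits get
#'   a single row with `NA` motif columns.
#' @export
map_hits_to_deletions <- function(hits, deletions) {
  del_tbl <- if (is.data.frame(deletions)) {
    tibble::as_tibble(deletions)
  } else {
    purrr::map_dfr(deletions, function(v) {
      tibble::tibble(c_hgvs = v$c_hgvs, start = v$start$base,
                     end = v$end$base)
    })
  }
  rows <- purrr::pmap(del_tbl, function(c_hgvs, start, end, ...) {
    if (nrow(hits) == 0L) {
      return(tibble::tibble(deletion = c_hgvs, pwm_name = NA_character_,
                            c_start = NA_integer_, c_end = NA_integer_,
                            overlap_nt = 0L, fully_removed = NA))
    }
    ov_lo <- pmax(hits$c_start, start)
    ov_hi <- pmin(hits$c_end, end)
    ov <- pmax(0L, ov_hi - ov_lo + 1L)
    keep <- ov > 0L
    if (!any(keep)) {
      return(tibble::tibble(deletion = c_hgvs, pwm_name = NA_character_,
                            c_start = NA_integer_, c_end = NA_integer_,
                            overlap_nt = 0L, fully_removed = NA))
    }
    tibble::tibble(deletion = c_hgvs,
                   pwm_name = hits$pwm_name[keep],
                   c_start = hits$c_start[keep],
                   c_end = hits$c_end[keep],
                   overlap_nt = as.integer(ov[keep]),
                   fully_removed = hits$c_start[keep] >= start &
                     hits$c_end[keep] <= end)
  })
  out <- dplyr::bind_rows(rows)
  motif_id <- paste(out$pwm_name, out$c_start, out$c_end)
  n_dels <- stats::ave(out$deletion, motif_id,
                       FUN = function(x) length(unique(x)))
  out$shared <- !is.na(out$pwm_name) & as.integer(n_dels) > 1L
  out
}
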