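# Genomic (DNA-level) variants on a minigene construct: HGVS c. parsing,
# splice-site classification, in-silico mutagenesis, and the microdeletion
# designer used for splicing-enhancer mapping.

#' Parse an HGVS c. variant description
#'
#' Supports substitutions (`c.7976G>A`), deletions (`c.7979_8008del`,
#' `c.7806-1del`), duplications (`c.7806-1_7806-2dup`), insertions
#' (`c.7805_7806insAG`) and deletion-insertions (`c.1_3delinsTT`).
#' Duplication spans written high-to-low are normalised.
#'
#' @param x Character scalar, e.g. `"c.7806-1G>A"`.
#' @return An object of class `genomic_variant` with fields `c_hgvs`,
#'   `edit_kind`, `start`, `end` ([c_pos()] objects), `ref`, `alt`.
#' @export
parse_variant <- function(x) {
  x0 <- trimws(x)
  x <- sub("^c\\.", "", x0)
  pos_re <- "\\d+(?:[+-]\\d+)?"
  re <- function(pattern) regmatches(x, regexec(pattern, x))[[1]]

  m <- re(sprintf("^(%s)([ACGT])>([ACGT])$", pos_re))
  if (length(m)) {
    p <- parse_c_pos(m[2])
    return(new_variant(x0, "substitution", p, p, ref = m[3], alt = m[4]))
  }
  m <- re(sprintf("^(%s)(?:_(%s))?del(?:[ACGT]+)?$", pos_re, pos_re))
  if (length(m)) {
    a <- parse_c_pos(m[2])
    b <- if (is.na(m[3]) || m[3] == "") a else parse_c_pos(m[3])
    return(new_variant(x0, "deletion", a, b))
  }
  m <- re(sprintf("^(%s)(?:_(%s))?dup$", pos_re, pos_re))
  if (length(m)) {
    a <- parse_c_pos(m[2])
    b <- if (is.na(m[3]) || m[3] == "") a else parse_c_pos(m[3])
    if (c_pos_key(b) < c_pos_key(a)) { tmp <- a; a <- b; b <- tmp }
    return(new_variant(x0, "duplication", a, b))
  }
  m <- re(sprintf("^(%s)_(%s)delins([ACGT]+)$", pos_re, pos_re))
  if (length(m)) {
    return(new_variant(x0, "delins", parse_c_pos(m[2]), parse_c_pos(m[3]),
                       alt = m[4]))
  }
  m <- re(sprintf("^(%s)_(%s)ins([ACGT]+)$", pos_re, pos_re))
  if (length(m)) {
    return(new_variant(x0, "insertion", parse_c_pos(m[2]), parse_c_pos(m[3]),
                       alt = m[4]))
  }
  stop("cannot parse HGVS c. variant: '", x0, "'", call. = FALSE)
}

new_variant <- function(c_hgvs, kind, start, end, ref = NA_character_,
                        alt = NA_character_) {
  if (!grepl("^c\\.", c_hgvs)) c_hgvs <- paste0("c.", c_hgvs)
  structure(list(c_hgvs = c_hgvs, edit_kind = kind, start = start, end = end,
                 ref = ref, alt = alt),
            class = "genomic_variant")
}

#' @export
print.genomic_variant <- function(x, ...) {
  cat("<genomic_variant> ", x$c_hgvs, " (", x$edit_kind, ")\n", sep = "")
  invisible(x)
}

# ---- absolute construct coordinates ------------------------------------

seg_bounds <- function(construct) {
  len <- construct$segments$length
  end <- cumsum(len)
  tibble::tibble(label = construct$segments$label,
                 role = construct$segments$role,
                 start = end - len + 1L, end = end)
}

c_to_abs <- function(construct, pos) {
  loc <- locate_c(construct, pos)
  b <- seg_bounds(construct)
  b$start[match(loc$label, b$label)] + loc$at - 1L
}

# donor/acceptor intron offsets of an absolute construct position, or
# NULL if the position is exonic. Offsets are only defined against an
# exon directly adjacent to the intron piece (the far half of a
# shortened intron carries no donor-side numbering and vice versa).
intron_offsets <- function(construct, abs_pos) {
  b <- seg_bounds(construct)
  j <- which(b$start <= abs_pos & b$end >= abs_pos)
  if (b$role[j] != "intron") return(NULL)
  exonish <- function(k) k >= 1L && k <= nrow(b) && b$role[k] != "intron"
  donor <- if (exonish(j - 1L)) abs_pos - b$start[j] + 1L else NA_integer_
  acceptor <- if (exonish(j + 1L)) b$end[j] - abs_pos + 1L else NA_integer_
  list(donor = donor, acceptor = acceptor)
}

variant_abs_span <- function(construct, variant) {
  a <- c_to_abs(construct, variant$start)
  b <- c_to_abs(construct, variant$end)
  if (b < a) stop("coordinate error: inverted span in ", variant$c_hgvs,
                  call. = FALSE)
  c(a, b)
}

#' Classify the splice-site context of a variant
#'
#' A variant is `canonical_dinucleotide` when it alters (or duplicates)
#' intronic positions +1/+2 of a donor or -1/-2 of an acceptor;
#' `splice_region` when it touches other intronic positions or the first
#' two / last three nucleotides of an exon; otherwise `exonic`.
#'
#' @param construct A minigene construct.
#' @param variant A [parse_variant()] object (or HGVS string).
#' @return One of `"canonical_dinucleotide"`, `"splice_region"`, `"exonic"`.
#' @export
variant_site_class <- function(construct, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  span <- variant_abs_span(construct, variant)
  positions <- seq.int(span[1], span[2])
  b <- seg_bounds(construct)
  intronic <- FALSE
  near_edge <- FALSE
  for (p in positions) {
    off <- intron_offsets(construct, p)
    if (!is.null(off)) {
      if ((!is.na(off$donor) && off$donor <= 2L) ||
          (!is.na(off$acceptor) && off$acceptor <= 2L)) {
        return("canonical_dinucleotide")
      }
      intronic <- TRUE
    } else {
      j <- which(b$start <= p & b$end >= p)
      if (b$role[j] == "exon") {
        at <- p - b$start[j] + 1L
        len <- b$end[j] - b$start[j] + 1L
        if (at <= 2L || at > len - 3L) near_edge <- TRUE
      }
    }
  }
  if (intronic || near_edge) "splice_region" else "exonic"
}

#' Exon region a variant belongs to
#'
#' Intron-offset positions are attributed to their anchor exon (the exon a
#' `c.X+n`/`c.Y-n` coordinate is written against); exonic positions to
#' their containing exon.
#'
#' @inheritParams variant_site_class
#' @return The exon label (e.g. `"EX17"`).
#' @export
variant_region <- function(construct, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  anchor_exon(construct, variant$start)$label
}

#' Introduce a DNA variant into a construct
#'
#' In-silico mutagenesis: returns a construct whose segment lengths (and
#' sequences, when present) reflect the edit. The original c. anchors are
#' kept as reference coordinates, so coordinate bookkeeping for unedited
#' positions is preserved; edited segments are recorded in the `edits`
#' attribute and exempted from the length-vs-anchor consistency check.
#'
#' @inheritParams variant_site_class
#' @return A `minigene_construct` with an `edits` attribute.
#' @export
apply_genomic_variant <- function(construct, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  span <- variant_abs_span(construct, variant)
  b <- seg_bounds(construct)
  seg <- construct$segments
  edited <- character()

  edit_segment <- function(label, dlen, splice_fun = NULL) {
    i <- match(label, seg$label)
    seg$length[i] <<- seg$length[i] + as.integer(dlen)
    if (seg$length[i] < 1L) {
      stop("edit removes segment '", label, "' entirely", call. = FALSE)
    }
    if (!is.na(seg$sequence[i]) && !is.null(splice_fun)) {
      seg$sequence[i] <<- splice_fun(seg$sequence[i])
    }
    edited <<- union(edited, label)
  }

  if (variant$edit_kind == "substitution") {
    j <- which(b$start <= span[1] & b$end >= span[1])
    at <- span[1] - b$start[j] + 1L
    i <- j
    if (!is.na(seg$sequence[i])) {
      s <- seg$sequence[i]
      if (substr(s, at, at) != variant$ref) {
        stop("reference mismatch at ", variant$c_hgvs, call. = FALSE)
      }
      substr(s, at, at) <- variant$alt
      seg$sequence[i] <- s
    }
  } else if (variant$edit_kind %in% c("deletion", "delins")) {
    for (j in seq_len(nrow(b))) {
      lo <- max(span[1], b$start[j]); hi <- min(span[2], b$end[j])
      if (lo > hi) next
      at <- lo - b$start[j] + 1L; to <- hi - b$start[j] + 1L
      edit_segment(b$label[j], -(to - at + 1L), function(s) {
        paste0(substr(s, 1L, at - 1L), substr(s, to + 1L, nchar(s)))
      })
    }
    if (variant$edit_kind == "delins") {
      j <- which(b$start <= span[1] & b$end >= span[1])
      at <- span[1] - b$start[j] + 1L
      edit_segment(b$label[j], nchar(variant$alt), function(s) {
        paste0(substr(s, 1L, at - 1L), variant$alt, substr(s, at, nchar(s)))
      })
    }
  } else if (variant$edit_kind == "duplication") {
    j <- which(b$start <= span[2] & b$end >= span[2])
    dup_len <- span[2] - span[1] + 1L
    to <- span[2] - b$start[j] + 1L
    edit_segment(b$label[j], dup_len, function(s) {
      # sequence duplication only supported within one segment
      at <- span[1] - b$start[j] + 1L
      paste0(substr(s, 1L, to), substr(s, at, to), substr(s, to + 1L, nchar(s)))
    })
  } else if (variant$edit_kind == "insertion") {
    j <- which(b$start <= span[1] & b$end >= span[1])
    at <- span[1] - b$start[j] + 1L
    edit_segment(b$label[j], nchar(variant$alt), function(s) {
      paste0(substr(s, 1L, at), variant$alt, substr(s, at + 1L, nchar(s)))
    })
  }

  out <- structure(list(name = construct$name, segments = seg,
                        primers = construct$primers),
                   class = "minigene_construct")
  attr(out, "edits") <- union(attr(construct, "edits") %||% character(), edited)
  validate_construct(out, edited = attr(out, "edits"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- microdeletion designer --------------------------------------------

#' Design exonic microdeletions for splicing-enhancer mapping
#'
#' Generates deletion variants inside one exon, always preserving the
#' exon's first two and last three nucleotides so the canonical acceptor
#' and donor sites are untouched. Windows can be supplied as explicit
#' start positions (allowing deliberate overlaps) or tiled consecutively
#' from a start position.
#'
#' @param construct A minigene construct.
#' @param exon_label Exon to dissect.
#' @param window Deletion width in nt (10 or 30 in typical designs).
#' @param starts Optional integer vector of c. start positions for each
#'   window (overrides tiling).
#' @param from Tiling start (c. position); defaults to the first allowed
#'   position, `c_start + 2`.
#' @param n Number of tiled windows; defaults to as many as fit before the
#'   protected 3' end.
#' @return A list of `genomic_variant` deletions, named by HGVS string.
#' @export
design_microdeletions <- function(construct, exon_label, window = 10L,
                                  starts = NULL, from = NULL, n = NULL) {
  ex <- segment_row(construct, exon_label)
  if (ex$role != "exon" || is.na(ex$c_start)) {
    stop("'", exon_label, "' is not a coordinate-anchored exon", call. = FALSE)
  }
  lo <- ex$c_start + 2L            # first deletable position
  hi <- ex$c_end - 3L              # last deletable position
  if (window > hi - lo + 1L) {
    stop("design error: ", window, "-nt window does not fit in ", exon_label,
         " once protected ends are excluded", call. = FALSE)
  }
  if (is.null(starts)) {
    if (is.null(from)) from <- lo
    if (is.null(n)) n <- (hi - from + 1L) %/% window
    starts <- from + window * (seq_len(n) - 1L)
  }
  purrr::map(starts, function(s) {
    e <- s + window - 1L
    if (s < lo || e > hi) {
      stop("design error: deletion c.", s, "_", e,
           " intersects the protected ends of ", exon_label, call. = FALSE)
    }
    parse_variant(sprintf("c.%d_%ddel", s, e))
  }) |> rlang::set_names(purrr::map_chr(starts, function(s) {
    sprintf("c.%d_%ddel", s, s + window - 1L)
  }))
}
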