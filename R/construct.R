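# Splicing-reporter construct model.
#
# A minigene construct is an ordered run of segments: a 5' vector exon,
# cloned genomic exons and introns, and a 3' vector exon. Shortened
# introns may appear as two consecutive intron segments (the removed
# middle is not represented). Exons carry HGVS c. coordinate anchors so
# that variants and splicing events can be described in coding-DNA
# coordinates; sequences are optional and all size/frame arithmetic is
# length-only.

SEGMENT_ROLES <- c("vector_exon", "exon", "intron")

as_segment_tbl <- function(segments) {
  if (is.data.frame(segments)) {
    tbl <- tibble::as_tibble(segments)
  } else {
    tbl <- purrr::map_dfr(segments, function(s) {
      tibble::tibble(
        role = s$role,
        label = s$label,
        length = as.integer(s$length),
        c_start = if (is.null(s$c_start)) NA_integer_ else as.integer(s$c_start),
        c_end = if (is.null(s$c_end)) NA_integer_ else as.integer(s$c_end),
        sequence = if (is.null(s$sequence)) NA_character_ else toupper(s$sequence)
      )
    })
  }
  for (col in c("c_start", "c_end")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_integer_
  }
  if (!"sequence" %in% names(tbl)) tbl$sequence <- NA_character_
  tbl$length <- as.integer(tbl$length)
  tbl$c_start <- as.integer(tbl$c_start)
  tbl$c_end <- as.integer(tbl$c_end)
  tbl
}

as_primer_tbl <- function(primers) {
  if (is.null(primers)) {
    return(tibble::tibble(name = character(), segment_label = character(),
                          offset = integer(), direction = character()))
  }
  if (is.data.frame(primers)) {
    tbl <- tibble::as_tibble(primers)
  } else {
    tbl <- purrr::map_dfr(primers, function(p) {
      tibble::tibble(name = p$name, segment_label = p$segment_label,
                     offset = as.integer(p$offset), direction = p$direction)
    })
  }
  tbl$offset <- as.integer(tbl$offset)
  tbl
}

#' Build and validate a minigene construct
#'
#' Assembles a splicing-reporter construct from an ordered segment
#' description and optional primer sites, and enforces the structural
#' invariants: vector exons at both ends, no two exons adjacent (shortened
#' introns may contribute consecutive intron segments), strictly increasing
#' exon c. anchors consistent with segment lengths, and sequences (when
#' given) matching their stated lengths.
#'
#' @param segments A data frame (or list of lists) with columns `role`
#'   (`"vector_exon"`, `"exon"` or `"intron"`), `label`, `length`, and for
#'   exons optionally `c_start`/`c_end` (HGVS c., 1-based inclusive) and
#'   `sequence`.
#' @param primers Optional data frame (or list) with columns `name`,
#'   `segment_label`, `offset`, `direction` (`"forward"`/`"reverse"`).
#'   For a forward primer `offset` is the number of amplicon nucleotides
#'   its segment contributes from the primer anchor to the segment 3' end;
#'   for a reverse primer, from the segment 5' end to the anchor.
#' @param name Construct name.
#' @return An object of class `minigene_construct`.
#' @examples
#' build_construct(
#'   tibble::tibble(
#'     role = c("vector_exon", "intron", "exon", "intron", "vector_exon"),
#'     label = c("V1", "IVS0", "EX1", "IVS1", "V2"),
#'     length = c(100L, 50L, 90L, 60L, 80L),
#'     c_start = c(NA, NA, 101L, NA, NA),
#'     c_end = c(NA, NA, 190L, NA, NA)
#'   )
#' )
#' @export
build_construct <- function(segments, primers = NULL, name = "construct") {
  seg <- as_segment_tbl(segments)
  prm <- as_primer_tbl(primers)
  x <- structure(list(name = name, segments = seg, primers = prm),
                 class = "minigene_construct")
  validate_construct(x)
  x
}

validate_construct <- function(x, edited = character()) {
  seg <- x$segments
  if (nrow(seg) < 3L) {
    stop("construct needs at least vector exon / segment / vector exon",
         call. = FALSE)
  }
  if (!all(seg$role %in% SEGMENT_ROLES)) {
    stop("unknown segment role(s): ",
         paste(setdiff(seg$role, SEGMENT_ROLES), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(seg$label)) {
    stop("segment labels must be unique", call. = FALSE)
  }
  if (any(seg$length < 1L)) {
    stop("segment lengths must be >= 1", call. = FALSE)
  }
  if (seg$role[1] != "vector_exon" || seg$role[nrow(seg)] != "vector_exon") {
    stop("structure error: first and last segments must be vector exons",
         call. = FALSE)
  }
  if (sum(seg$role == "vector_exon") != 2L) {
    stop("structure error: exactly two vector exons expected", call. = FALSE)
  }
  exonish <- seg$role %in% c("exon", "vector_exon")
  if (any(exonish[-1] & exonish[-length(exonish)])) {
    stop("structure error: adjacent exons without an intervening intron",
         call. = FALSE)
  }
  ex <- seg[seg$role == "exon", ]
  has_anchor <- !is.na(ex$c_start) & !is.na(ex$c_end)
  if (any(has_anchor)) {
    anc <- ex[has_anchor, ]
    bad_len <- !(anc$label %in% edited) &
      (anc$c_end - anc$c_start + 1L) != anc$length
    if (any(bad_len)) {
      stop("coordinate error: exon length inconsistent with c. anchors for ",
           paste(anc$label[bad_len], collapse = ", "), call. = FALSE)
    }
    if (nrow(anc) > 1L) {
      ord <- all(diff(anc$c_start) > 0) && all(anc$c_start[-1] > anc$c_end[-nrow(anc)])
      if (!ord) {
        stop("coordinate error: exon c. coordinates must be strictly increasing",
             call. = FALSE)
      }
    }
  }
  with_seq <- !is.na(seg$sequence) & !(seg$label %in% edited)
  if (any(nchar(seg$sequence[with_seq]) != seg$length[with_seq])) {
    stop("sequence length does not match stated segment length", call. = FALSE)
  }
  prm <- x$primers
  if (nrow(prm)) {
    if (!all(prm$direction %in% c("forward", "reverse"))) {
      stop("primer direction must be 'forward' or 'reverse'", call. = FALSE)
    }
    idx <- match(prm$segment_label, seg$label)
    if (anyNA(idx)) {
      stop("primer segment not found: ",
           paste(prm$segment_label[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    if (any(prm$offset < 1L | prm$offset > seg$length[idx])) {
      stop("primer offset outside its segment", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.minigene_construct <- function(x, ...) {
  seg <- x$segments
  cat("<minigene_construct> ", x$name, "\n", sep = "")
  cat("  ", nrow(seg), " segments (", sum(seg$role == "exon"), " exons), ",
      "insert ", total_insert_length(x), " nt\n", sep = "")
  if (nrow(x$primers)) {
    cat("  primers: ", paste(x$primers$name, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Total cloned-insert length of a construct
#'
#' Sum of all non-vector segment lengths, i.e. the size of the cloned
#' genomic insert between the two vector exons.
#'
#' @param construct A [build_construct()] object.
#' @return Integer nucleotide count.
#' @export
total_insert_length <- function(construct) {
  stopifnot(inherits(construct, "minigene_construct"))
  seg <- construct$segments
  sum(seg$length[seg$role != "vector_exon"])
}

#' Exon table of a construct
#'
#' @param construct A minigene construct.
#' @return A tibble of the exon segments (cloned exons only).
#' @export
construct_exons <- function(construct) {
  construct$segments[construct$segments$role == "exon", ]
}

segment_row <- function(construct, label) {
  i <- match(label, construct$segments$label)
  if (is.na(i)) stop("no segment labelled '", label, "'", call. = FALSE)
  construct$segments[i, ]
}

segment_idx <- function(construct, label) {
  i <- match(label, construct$segments$label)
  if (is.na(i)) stop("no segment labelled '", label, "'", call. = FALSE)
  i
}

# Exon row whose anchor matches a c_pos; for offset 0 the exon containing
# base, for -n the exon starting at base, for +n the exon ending at base.
anchor_exon <- function(construct, pos) {
  ex <- construct_exons(construct)
  ex <- ex[!is.na(ex$c_start), ]
  if (pos$offset == 0L) {
    hit <- which(ex$c_start <= pos$base & ex$c_end >= pos$base)
  } else if (pos$offset < 0L) {
    hit <- which(ex$c_start == pos$base)
    if (length(hit) == 0L) {
      # tolerate anchors written against the previous exon end + 1 etc.
      hit <- which(ex$c_start <= pos$base & ex$c_end >= pos$base)
    }
  } else {
    hit <- which(ex$c_end == pos$base)
    if (length(hit) == 0L) {
      hit <- which(ex$c_start <= pos$base & ex$c_end >= pos$base)
    }
  }
  if (length(hit) != 1L) {
    stop("coordinate error: c.", format_c_pos(pos),
         " is not anchored in this construct", call. = FALSE)
  }
  ex[hit, ]
}

#' Locate a coding-DNA position inside a construct
#'
#' Maps an HGVS c. position (exonic or intron-offset) to the segment and
#' 1-based offset within that segment. Intronic offsets that fall in the
#' removed middle of a shortened intron raise a coordinate error.
#'
#' @param construct A minigene construct.
#' @param pos A [c_pos()] object (or string accepted by [parse_c_pos()]).
#' @return A list with elements `label` (segment label) and `at`
#'   (position within the segment, 1-based).
#' @export
locate_c <- function(construct, pos) {
  if (is.character(pos)) pos <- parse_c_pos(pos)
  stopifnot(inherits(pos, "c_pos"))
  seg <- construct$segments
  if (pos$offset == 0L) {
    ex <- anchor_exon(construct, pos)
    return(list(label = ex$label, at = pos$base - ex$c_start + 1L))
  }
  ex <- anchor_exon(construct, pos)
  i <- segment_idx(construct, ex$label)
  # intron offsets are only addressable within the intron piece adjacent
  # to the anchor exon: for a shortened (split) intron the removed middle
  # and the far half are not covered by donor-side (+n) or acceptor-side
  # (-n) numbering respectively
  if (pos$offset > 0L) {
    j <- i + 1L
    if (j <= nrow(seg) && seg$role[j] == "intron" &&
        pos$offset <= seg$length[j]) {
      return(list(label = seg$label[j], at = pos$offset))
    }
  } else {
    j <- i - 1L
    need <- -pos$offset
    if (j >= 1L && seg$role[j] == "intron" && need <= seg$length[j]) {
      return(list(label = seg$label[j], at = seg$length[j] - need + 1L))
    }
  }
  stop("coordinate error: c.", format_c_pos(pos),
       " falls outside the cloned intronic sequence (shortened intron?)",
       call. = FALSE)
}

#' Read a construct description from a YAML file
#'
#' The file lists `name`, `segments` (ordered; each with `role`, `label`,
#' `length`, optionally `c_start`, `c_end`, `sequence`) and optionally
#' `primers` (each with `name`, `segment_label`, `offset`, `direction`).
#'
#' @param path Path to the YAML construct description.
#' @return A validated [build_construct()] object.
#' @export
read_construct <- function(path) {
  spec <- yaml::read_yaml(path)
  build_construct(spec$segments, spec$primers,
                  name = if (is.null(spec$name)) "construct" else spec$name)
}

construct_primer <- function(construct, name) {
  prm <- construct$primers
  i <- match(name, prm$name)
  if (is.na(i)) stop("no primer named '", name, "'", call. = FALSE)
  as.list(prm[i, ])
}
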