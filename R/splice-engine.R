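# Splice-event engine: applies sets of splicing alterations to a
# construct, producing transcript structures (ordered retained intervals),
# sizes, canonical labels and HGVS r. descriptions.
#
# Events are structural, described as offsets from annotated exon
# boundaries: an alternative acceptor with offset +k removes the exon's
# first k nt, offset -k appends the last k nt of the upstream intron;
# alternative donors are symmetric at the 3' end. Whether a site is
# "cryptic" or "de novo" is not part of the event model.

EVENT_KINDS <- c("exon_skip", "alt_acceptor", "alt_donor",
                 "intron_retention_partial", "exonic_insertion")

#' Create a splicing event
#'
#' @param kind One of `"exon_skip"`, `"alt_acceptor"`, `"alt_donor"`,
#'   `"intron_retention_partial"`, `"exonic_insertion"`.
#' @param exon_label Exon the event is anchored on.
#' @param offset Signed nt for alternative sites: positive trims into the
#'   exon (deletion), negative extends into the flanking intron
#'   (insertion/retention). Not used for `exon_skip`.
#' @param inserted_sequence Optional nucleotide string for intronic or
#'   exonic insertions (length must match `abs(offset)` for alt sites).
#' @param retained_span For `intron_retention_partial`: a length-2 list of
#'   [c_pos()] (or strings) delimiting the retained intronic interval.
#' @param at For `exonic_insertion`: 1-based position within the exon
#'   after which the sequence is inserted.
#' @return An object of class `splice_event`.
#' @examples
#' splice_event("exon_skip", "EX17")
#' splice_event("alt_acceptor", "EX18", offset = -6)
#' @export
splice_event <- function(kind, exon_label, offset = NULL,
                         inserted_sequence = NULL, retained_span = NULL,
                         at = NULL) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (kind == "exon_skip" && !is.null(offset)) {
    stop("exon_skip takes no offset", call. = FALSE)
  }
  if (kind %in% c("alt_acceptor", "alt_donor")) {
    if (is.null(offset) || offset == 0L) {
      stop(kind, " requires a nonzero offset", call. = FALSE)
    }
    offset <- as.integer(offset)
    if (!is.null(inserted_sequence)) {
      if (offset > 0L) stop("inserted_sequence only applies to negative offsets",
                            call. = FALSE)
      if (nchar(inserted_sequence) != abs(offset)) {
        stop("inserted_sequence length must equal |offset|", call. = FALSE)
      }
    }
  }
  if (kind == "intron_retention_partial") {
    if (is.null(retained_span)) stop("retained_span required", call. = FALSE)
    retained_span <- purrr::map(retained_span,
                                function(p) if (is.character(p)) parse_c_pos(p) else p)
  }
  if (kind == "exonic_insertion" && is.null(inserted_sequence)) {
    stop("exonic_insertion requires inserted_sequence", call. = FALSE)
  }
  structure(list(kind = kind, exon_label = exon_label,
                 offset = if (is.null(offset)) NA_integer_ else offset,
                 inserted_sequence = inserted_sequence,
                 retained_span = retained_span,
                 at = at),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat("<splice_event> ", x$kind, " @ ", x$exon_label,
      if (!is.na(x$offset)) paste0(" offset ", x$offset) else "", "\n", sep = "")
  invisible(x)
}

exon_number <- function(label) {
  m <- regmatches(label, regexec("([0-9]+)$", label))[[1]]
  if (length(m)) as.integer(m[2]) else NA_integer_
}

# signed length change a single event causes
event_delta <- function(construct, event) {
  ex <- segment_row(construct, event$exon_label)
  switch(event$kind,
    exon_skip = -ex$length,
    alt_acceptor = -event$offset,
    alt_donor = -event$offset,
    intron_retention_partial = {
      a <- event$retained_span[[1]]; b <- event$retained_span[[2]]
      abs(b$offset - a$offset) + 1L
    },
    exonic_insertion = nchar(event$inserted_sequence)
  )
}

# ---- applying events ----------------------------------------------------

#' Apply splicing events to a construct
#'
#' Produces the transcript implied by a (possibly empty) set of compatible
#' splicing events. The canonical transcript (no events) is the two vector
#' exons plus all cloned exons. At most one acceptor-side and one
#' donor-side alteration per exon are allowed, and exon skipping excludes
#' any other event on the same exon.
#'
#' @param construct A minigene construct.
#' @param events A list of [splice_event()]s (empty list for canonical).
#' @param label Optional transcript label; derived from the events when
#'   omitted (`"FL"`, `"ex17 skipping"`, `"ex18-del309"`, ...).
#' @return An object of class `minigene_transcript` with fields `label`,
#'   `events`, `pieces` (ordered retained intervals), `length_nt`,
#'   `canonical_length_nt` and `construct`.
#' @export
apply_splice_events <- function(construct, events = list(), label = NULL) {
  if (inherits(events, "splice_event")) events <- list(events)
  seg <- construct$segments
  exon_rows <- which(seg$role != "intron")
  canonical_length <- sum(seg$length[exon_rows])

  # per-exon modification plan, so that event order never matters
  plan <- list()
  get_plan <- function(lab) {
    plan[[lab]] %||% list(skip = FALSE, trim_start = 0L, trim_end = 0L,
                          prepend = NULL, append = NULL, inserts = list())
  }
  for (ev in events) {
    stopifnot(inherits(ev, "splice_event"))
    ex <- segment_row(construct, ev$exon_label)
    if (ex$role != "exon") {
      stop("events must reference cloned exons, not '", ev$exon_label, "'",
           call. = FALSE)
    }
    p <- get_plan(ev$exon_label)
    if (ev$kind == "exon_skip") {
      if (p$trim_start || p$trim_end || length(p$inserts) ||
          !is.null(p$prepend) || !is.null(p$append)) {
        stop("composition error: exon_skip combined with another event on ",
             ev$exon_label, call. = FALSE)
      }
      p$skip <- TRUE
    } else if (p$skip) {
      stop("composition error: exon_skip combined with another event on ",
           ev$exon_label, call. = FALSE)
    } else if (ev$kind == "alt_acceptor") {
      if (p$trim_start > 0L || !is.null(p$prepend)) {
        stop("composition error: two acceptor-side events on ", ev$exon_label,
             call. = FALSE)
      }
      if (ev$offset > 0L) {
        if (ev$offset >= ex$length) {
          stop("span error: acceptor offset ", ev$offset,
               " exceeds exon length ", ex$length, call. = FALSE)
        }
        p$trim_start <- ev$offset
      } else {
        k <- -ev$offset
        i <- segment_idx(construct, ev$exon_label)
        if (i == 1L || seg$role[i - 1L] != "intron") {
          stop("no upstream intron for acceptor extension on ", ev$exon_label,
               call. = FALSE)
        }
        if (k > seg$length[i - 1L]) {
          stop("span error: acceptor extension ", k,
               " exceeds cloned intron length", call. = FALSE)
        }
        p$prepend <- list(segment = seg$label[i - 1L],
                          from = seg$length[i - 1L] - k + 1L,
                          to = seg$length[i - 1L],
                          seq = ev$inserted_sequence,
                          origin = "acceptor", k = k)
      }
    } else if (ev$kind == "alt_donor") {
      if (p$trim_end > 0L || !is.null(p$append)) {
        stop("composition error: two donor-side events on ", ev$exon_label,
             call. = FALSE)
      }
      if (ev$offset > 0L) {
        if (ev$offset >= ex$length) {
          stop("span error: donor offset ", ev$offset,
               " exceeds exon length ", ex$length, call. = FALSE)
        }
        p$trim_end <- ev$offset
      } else {
        k <- -ev$offset
        i <- segment_idx(construct, ev$exon_label)
        if (i == nrow(seg) || seg$role[i + 1L] != "intron") {
          stop("no downstream intron for donor extension on ", ev$exon_label,
               call. = FALSE)
        }
        if (k > seg$length[i + 1L]) {
          stop("span error: donor extension ", k,
               " exceeds cloned intron length", call. = FALSE)
        }
        p$append <- list(segment = seg$label[i + 1L], from = 1L, to = k,
                         seq = ev$inserted_sequence, origin = "donor", k = k)
      }
    } else if (ev$kind == "intron_retention_partial") {
      a <- ev$retained_span[[1]]; b <- ev$retained_span[[2]]
      la <- locate_c(construct, a); lb <- locate_c(construct, b)
      if (la$label != lb$label) {
        stop("retained_span must lie within one cloned intron segment",
             call. = FALSE)
      }
      side <- if (a$offset > 0L) "append" else "prepend"
      piece <- list(segment = la$label, from = min(la$at, lb$at),
                    to = max(la$at, lb$at), seq = NULL,
                    origin = if (side == "append") "donor" else "acceptor",
                    k = abs(lb$at - la$at) + 1L)
      if (side == "append") {
        if (!is.null(p$append)) stop("composition error: two donor-side events on ",
                                     ev$exon_label, call. = FALSE)
        p$append <- piece
      } else {
        if (!is.null(p$prepend)) stop("composition error: two acceptor-side events on ",
                                      ev$exon_label, call. = FALSE)
        p$prepend <- piece
      }
    } else if (ev$kind == "exonic_insertion") {
      p$inserts <- c(p$inserts, list(list(at = ev$at %||% ex$length,
                                          seq = ev$inserted_sequence)))
    }
    plan[[ev$exon_label]] <- p
  }

  pieces <- list()
  add_piece <- function(segment, from, to, seq = NULL, origin = NA_character_,
                        anchor = NA_character_) {
    pieces[[length(pieces) + 1L]] <<- tibble::tibble(
      segment = segment %||% NA_character_, from = as.integer(from),
      to = as.integer(to),
      seq = if (is.null(seq)) NA_character_ else seq,
      origin = origin, anchor_exon = anchor)
  }
  for (i in seq_len(nrow(seg))) {
    if (seg$role[i] == "intron") next
    lab <- seg$label[i]
    p <- plan[[lab]]
    if (is.null(p)) {
      add_piece(lab, 1L, seg$length[i])
      next
    }
    if (p$skip) next
    if (p$trim_start + p$trim_end >= seg$length[i]) {
      stop("span error: combined trims remove all of ", lab, call. = FALSE)
    }
    if (!is.null(p$prepend)) {
      add_piece(p$prepend$segment, p$prepend$from, p$prepend$to,
                p$prepend$seq, "acceptor", lab)
    }
    from <- 1L + p$trim_start
    to <- seg$length[i] - p$trim_end
    if (length(p$inserts)) {
      ins <- p$inserts[[1L]]
      if (length(p$inserts) > 1L) {
        stop("at most one exonic insertion per exon is supported", call. = FALSE)
      }
      if (ins$at < from || ins$at >= to) {
        stop("span error: insertion point outside retained exon", call. = FALSE)
      }
      add_piece(lab, from, ins$at)
      add_piece(NA_character_, 1L, nchar(ins$seq), ins$seq, "exonic", lab)
      add_piece(lab, ins$at + 1L, to)
    } else {
      add_piece(lab, from, to)
    }
    if (!is.null(p$append)) {
      add_piece(p$append$segment, p$append$from, p$append$to,
                p$append$seq, "donor", lab)
    }
  }
  pieces <- dplyr::bind_rows(pieces)
  length_nt <- sum(pieces$to - pieces$from + 1L)

  structure(list(
    label = label %||% transcript_label(construct, events),
    events = events,
    pieces = pieces,
    length_nt = as.integer(length_nt),
    canonical_length_nt = as.integer(canonical_length),
    construct = construct
  ), class = "minigene_transcript")
}

#' @export
print.minigene_transcript <- function(x, ...) {
  cat("<minigene_transcript> ", x$label, ": ", x$length_nt, " nt (",
      sprintf("%+d", x$length_nt - x$canonical_length_nt),
      " vs canonical)\n", sep = "")
  invisible(x)
}

# canonical field-style label derived from the event set
transcript_label <- function(construct, events) {
  if (length(events) == 0L) return("FL")
  ord <- order(purrr::map_int(events, function(ev) {
    segment_idx(construct, ev$exon_label)
  }))
  parts <- purrr::map_chr(events[ord], function(ev) {
    n <- exon_number(ev$exon_label)
    exname <- if (is.na(n)) tolower(ev$exon_label) else paste0("ex", n)
    switch(ev$kind,
      exon_skip = paste0(exname, " skipping"),
      alt_acceptor = if (ev$offset > 0L) {
        paste0(exname, "-del", ev$offset)
      } else if (!is.null(ev$inserted_sequence)) {
        paste0(exname, "-ins", ev$inserted_sequence)
      } else {
        paste0(exname, "-ins", -ev$offset)
      },
      alt_donor = if (ev$offset > 0L) {
        paste0(exname, "-del", ev$offset)
      } else {
        paste0("ivs", n, "-ret", -ev$offset)
      },
      intron_retention_partial = {
        k <- abs(ev$retained_span[[2]]$offset - ev$retained_span[[1]]$offset) + 1L
        side <- if (ev$retained_span[[1]]$offset > 0L) n else n - 1L
        paste0("ivs", side, "-ret", k)
      },
      exonic_insertion = paste0(exname, "-ins", nchar(ev$inserted_sequence))
    )
  })
  paste(parts, collapse = "+")
}

#' Normalise a transcript label
#'
#' Maps the spellings found in assay reports onto one canonical form:
#' `"FL"` for the full-length/canonical transcript, `"exNN skipping"`,
#' `"exNN-delK"`, `"exNN-insK"`; acceptor-side intronic insertions written
#' against the intron (`"ivs16-ins8"`) are renamed to the downstream exon
#' (`"ex17-ins8"`). Composite labels joined with `"+"` are normalised
#' part-wise.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalised labels.
#' @export
normalize_transcript_label <- function(x) {
  one <- function(lbl) {
    lbl <- gsub("\\s+", " ", trimws(lbl))
    low <- tolower(lbl)
    if (low %in% c("ct", "fl", "canonical", "full-length", "full length",
                   "canonical transcript")) {
      return("FL")
    }
    parts <- strsplit(low, "\\s*\\+\\s*")[[1]]
    parts <- purrr::map_chr(parts, function(p) {
      p <- sub("^exon\\s*([0-9]+)\\s+skipping$", "ex\\1 skipping", p)
      p <- sub("^ex\\s*([0-9]+)\\s+skipping$", "ex\\1 skipping", p)
      m <- regmatches(p, regexec("^ivs([0-9]+)-ins([0-9]+)$", p))[[1]]
      if (length(m)) {
        p <- paste0("ex", as.integer(m[2]) + 1L, "-ins", m[3])
      }
      m <- regmatches(p, regexec("^ex([0-9]+)-ins([acgt]+)$", p))[[1]]
      if (length(m)) {
        p <- paste0("ex", m[2], "-ins", toupper(m[3]))
      }
      p
    })
    paste(parts, collapse = "+")
  }
  vapply(x, one, character(1), USE.NAMES = FALSE)
}

# ---- HGVS r. descriptions ----------------------------------------------

# retained exonic c-intervals of a transcript (cloned exons only)
transcript_retained_c <- function(transcript) {
  construct <- transcript$construct
  seg <- construct$segments
  out <- list()
  for (i in seq_len(nrow(transcript$pieces))) {
    p <- transcript$pieces[i, ]
    if (is.na(p$segment)) next
    j <- match(p$segment, seg$label)
    if (seg$role[j] != "exon" || is.na(seg$c_start[j])) next
    out[[length(out) + 1L]] <- c(seg$c_start[j] + p$from - 1L,
                                 seg$c_start[j] + p$to - 1L)
  }
  out
}

#' HGVS r. description of a transcript
#'
#' Derives the RNA-level change relative to the canonical transcript:
#' exon skips and alternative-site deletions become `r.A_Bdel` (merged
#' when contiguous in c. numbering), intronic extensions become
#' `r.A_BinsSEQ` (sequence known) or `r.A_BinsX-k_X-1` style coordinate
#' insertions, and deletion plus adjacent retention becomes
#' `r.A_BdelinsX+1_X+k`. Event sets outside this grammar raise an
#' unsupported-description error.
#'
#' @param transcript A [apply_splice_events()] transcript.
#' @param construct The construct (defaults to the one stored in the
#'   transcript).
#' @return Character scalar, e.g. `"r.7806_7976del"`.
#' @export
rna_hgvs <- function(transcript, construct = transcript$construct) {
  seg <- construct$segments
  ex <- construct_exons(construct)
  if (any(is.na(ex$c_start))) {
    stop("exon c. anchors required for r. descriptions", call. = FALSE)
  }

  dels <- list()
  inss <- list()
  retained <- transcript_retained_c(transcript)
  for (i in seq_len(nrow(ex))) {
    cs <- ex$c_start[i]; ce <- ex$c_end[i]
    hits <- purrr::keep(retained, function(r) r[1] >= cs && r[2] <= ce)
    if (length(hits) == 0L) {
      dels[[length(dels) + 1L]] <- c(cs, ce)
    } else {
      lo <- min(purrr::map_int(hits, function(r) as.integer(r[1])))
      hi <- max(purrr::map_int(hits, function(r) as.integer(r[2])))
      if (lo > cs) dels[[length(dels) + 1L]] <- c(cs, lo - 1L)
      if (hi < ce) dels[[length(dels) + 1L]] <- c(hi + 1L, ce)
    }
  }
  # merge deletions contiguous in c. numbering
  if (length(dels) > 1L) {
    dels <- dels[order(purrr::map_int(dels, function(d) as.integer(d[1])))]
    merged <- list(dels[[1]])
    for (d in dels[-1]) {
      last <- merged[[length(merged)]]
      if (d[1] == last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], d[2])
      } else {
        merged[[length(merged) + 1L]] <- d
      }
    }
    dels <- merged
  }

  for (i in seq_len(nrow(transcript$pieces))) {
    p <- transcript$pieces[i, ]
    if (is.na(p$origin) || !p$origin %in% c("acceptor", "donor", "exonic")) next
    axr <- ex[ex$label == p$anchor_exon, ]
    if (nrow(axr) == 0L) next
    k <- p$to - p$from + 1L
    if (p$origin == "acceptor") {
      anchor <- c(axr$c_start - 1L, axr$c_start)
      content <- if (!is.na(p$seq)) p$seq else
        sprintf("%d-%d_%d-1", axr$c_start, k, axr$c_start)
      edge <- axr$c_start
    } else if (p$origin == "donor") {
      anchor <- c(axr$c_end, axr$c_end + 1L)
      content <- if (!is.na(p$seq)) p$seq else
        sprintf("%d+1_%d+%d", axr$c_end, axr$c_end, k)
      edge <- axr$c_end
    } else {
      at_c <- axr$c_start + p$from - 1L # insertion point approximation
      anchor <- c(at_c - 1L, at_c)
      content <- p$seq
      edge <- at_c
    }
    inss[[length(inss) + 1L]] <- list(anchor = anchor, content = content,
                                      edge = edge)
  }

  if (length(dels) == 0L && length(inss) == 0L) return("r.(=)")
  fmt_del <- function(d) if (d[1] == d[2]) sprintf("%ddel", d[1]) else
    sprintf("%d_%ddel", d[1], d[2])
  if (length(dels) == 1L && length(inss) == 0L) {
    return(paste0("r.", fmt_del(dels[[1]])))
  }
  if (length(dels) == 0L && length(inss) == 1L) {
    a <- inss[[1]]$anchor
    return(sprintf("r.%d_%dins%s", a[1], a[2], inss[[1]]$content))
  }
  if (length(dels) == 1L && length(inss) == 1L) {
    d <- dels[[1]]; i1 <- inss[[1]]
    adjacent <- i1$anchor[2] == d[1] || i1$anchor[1] == d[2] ||
      (i1$anchor[1] >= d[1] && i1$anchor[2] <= d[2])
    if (adjacent) {
      return(sprintf("r.%d_%ddelins%s", d[1], d[2], i1$content))
    }
  }
  stop("unsupported-description error: event set not expressible as a ",
       "single r. del/ins/delins", call. = FALSE)
}

#' Parse an HGVS r. description emitted by [rna_hgvs()]
#'
#' Supports `r.(=)`, single deletions, single insertions (sequence or
#' intronic coordinate range) and delins forms. Used for round-trip
#' checks of the r. writer.
#'
#' @param x Character scalar.
#' @return A list with elements `dels` (list of integer `c(start, end)`)
#'   and `ins` (list with `anchor` and `content`), either possibly empty.
#' @export
parse_rna_hgvs <- function(x) {
  x <- sub("^r\\.", "", trimws(x))
  if (x == "(=)") return(list(dels = list(), ins = list()))
  m <- regmatches(x, regexec("^(\\d+)(?:_(\\d+))?del$", x))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- if (is.na(m[3]) || m[3] == "") a else as.integer(m[3])
    return(list(dels = list(c(a, b)), ins = list()))
  }
  m <- regmatches(x, regexec("^(\\d+)_(\\d+)ins(.+)$", x))[[1]]
  if (length(m)) {
    return(list(dels = list(),
                ins = list(list(anchor = c(as.integer(m[2]), as.integer(m[3])),
                                content = m[4]))))
  }
  m <- regmatches(x, regexec("^(\\d+)_(\\d+)delins(.+)$", x))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    return(list(dels = list(c(a, b)),
                ins = list(list(anchor = c(a - 1L, a), content = m[4]))))
  }
  stop("cannot parse r. description: '", x, "'", call. = FALSE)
}

# ---- amplicons ----------------------------------------------------------

#' RT-PCR amplicon length on a transcript
#'
#' Length from the forward primer anchor to the reverse primer anchor,
#' inclusive. Returns `NA` (no amplification) when either primer's
#' segment, or the primer anchor itself, is absent from the transcript
#' (e.g. a skipped exon carrying the forward primer).
#'
#' @param transcript A transcript from [apply_splice_events()].
#' @param fwd,rev Primer names (looked up in the transcript's construct)
#'   or primer descriptors as stored in `construct$primers`.
#' @return Integer nt count, or `NA_integer_`.
#' @export
amplicon_length <- function(transcript, fwd, rev) {
  construct <- transcript$construct
  if (is.character(fwd)) fwd <- construct_primer(construct, fwd)
  if (is.character(rev)) rev <- construct_primer(construct, rev)
  stopifnot(fwd$direction == "forward", rev$direction == "reverse")
  pieces <- transcript$pieces
  seg <- construct$segments

  fi <- which(!is.na(pieces$segment) & pieces$segment == fwd$segment_label)
  ri <- which(!is.na(pieces$segment) & pieces$segment == rev$segment_label)
  if (length(fi) == 0L || length(ri) == 0L) return(NA_integer_)
  fi <- fi[1L]; ri <- ri[length(ri)]
  if (fi > ri) return(NA_integer_)

  flen <- seg$length[match(fwd$segment_label, seg$label)]
  f_anchor <- flen - fwd$offset + 1L
  if (f_anchor < pieces$from[fi] || f_anchor > pieces$to[fi]) {
    return(NA_integer_)
  }
  r_anchor <- rev$offset
  if (r_anchor < pieces$from[ri] || r_anchor > pieces$to[ri]) {
    return(NA_integer_)
  }
  if (fi == ri) {
    return(as.integer(r_anchor - f_anchor + 1L))
  }
  f_part <- pieces$to[fi] - f_anchor + 1L
  r_part <- r_anchor - pieces$from[ri] + 1L
  mid <- 0L
  if (ri > fi + 1L) {
    mid_pieces <- pieces[(fi + 1L):(ri - 1L), ]
    mid <- sum(mid_pieces$to - mid_pieces$from + 1L)
  }
  as.integer(f_part + mid + r_part)
}

#' Expected amplicon sizes for a catalog of candidate transcripts
#'
#' Builds the label-to-size table used to assign electrophoresis peaks to
#' transcripts. Catalog entries are event-set lists (empty list = the
#' canonical transcript, which must be present) or bare numbers for
#' size-only placeholder species (uncharacterised transcripts whose size
#' is known but whose structure is not).
#'
#' @param construct A minigene construct.
#' @param catalog Named list: label -> list of [splice_event()]s, or
#'   label -> numeric size for placeholders.
#' @param fwd,rev Primer names or descriptors (see [amplicon_length()]).
#' @return A tibble with columns `label`, `length_nt`, `amplicon_size`,
#'   `amplifiable`, `placeholder`; transcripts that lose a primer are
#'   flagged unamplifiable and excluded from peak assignment.
#' @export
candidate_transcript_table <- function(construct, catalog, fwd, rev) {
  if (anyDuplicated(names(catalog))) {
    stop("catalog error: duplicate labels", call. = FALSE)
  }
  has_canonical <- any(purrr::map_lgl(catalog, function(x) {
    is.list(x) && length(x) == 0L
  }))
  if (!has_canonical) {
    stop("catalog error: must include the canonical (empty) event set",
         call. = FALSE)
  }
  rows <- purrr::imap(catalog, function(entry, lbl) {
    if (is.numeric(entry)) {
      return(tibble::tibble(label = lbl, length_nt = NA_integer_,
                            amplicon_size = as.numeric(entry),
                            amplifiable = TRUE, placeholder = TRUE))
    }
    tr <- apply_splice_events(construct, entry, label = lbl)
    amp <- amplicon_length(tr, fwd, rev)
    tibble::tibble(label = lbl, length_nt = tr$length_nt,
                   amplicon_size = as.numeric(amp),
                   amplifiable = !is.na(amp), placeholder = FALSE)
  })
  dplyr::bind_rows(rows)
}
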