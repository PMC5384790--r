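# Consequence annotation: reading-frame status, premature termination
# codons and protein-level HGVS for transcripts produced by the splice
# engine, against a coding-sequence context.
#
# No mRNA surveillance (NMD) rules are applied: the assay this models
# inhibits NMD pharmacologically, so every aberrant transcript is treated
# as translatable and degradation is out of model.

#' Create a coding context
#'
#' Holds the full reference CDS against which transcripts are translated.
#' Exon c. anchors of the construct index directly into this CDS
#' (`c.1` is the first CDS base).
#'
#' @param cds_sequence Character scalar or `Biostrings::DNAString`;
#'   length must be a multiple of 3.
#' @param name Optional context name.
#' @param check_ends Require an ATG start and a stop at the end
#'   (disable for partial CDS contexts).
#' @return An object of class `coding_context`.
#' @export
coding_context <- function(cds_sequence, name = "cds", check_ends = TRUE) {
  cds <- toupper(as.character(cds_sequence))
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS must contain only A/C/G/T", call. = FALSE)
  }
  if (check_ends) {
    if (substr(cds, 1L, 3L) != "ATG") {
      stop("CDS must start with ATG", call. = FALSE)
    }
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA")) {
      stop("CDS must end with a stop codon", call. = FALSE)
    }
  }
  structure(list(cds = cds, name = name), class = "coding_context")
}

#' @export
print.coding_context <- function(x, ...) {
  cat("<coding_context> ", x$name, ": ", nchar(x$cds), " nt (",
      nchar(x$cds) / 3L, " codons incl. stop)\n", sep = "")
  invisible(x)
}

translate_codons <- function(dna) {
  n <- nchar(dna) %/% 3L * 3L
  if (n == 0L) return(character(0))
  aa <- Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                              no.init.codon = TRUE)
  strsplit(as.character(aa), "")[[1]]
}

#' Reading-frame status of a transcript
#'
#' The net length change relative to the canonical transcript determines
#' the frame: in frame iff the signed delta is divisible by 3. Placeholder
#' (size-only) transcripts are rejected.
#'
#' @param transcript A transcript from [apply_splice_events()].
#' @return A list with `frame` (`"in_frame"` or `"frameshift"`) and
#'   `net_delta_nt`.
#' @export
frame_status <- function(transcript) {
  if (!inherits(transcript, "minigene_transcript") ||
      is.null(transcript$pieces)) {
    stop("not-annotatable: transcript lacks a structural event set",
         call. = FALSE)
  }
  delta <- transcript$length_nt - transcript$canonical_length_nt
  list(frame = if (delta %% 3L == 0L) "in_frame" else "frameshift",
       net_delta_nt = as.integer(delta))
}

#' Residues removed by an in-frame deletion transcript
#'
#' @param transcript A transcript whose events are pure deletions with a
#'   net length change divisible by 3.
#' @return Integer residue count (`abs(delta)/3`).
#' @export
deleted_residue_count <- function(transcript) {
  fs <- frame_status(transcript)
  if (fs$frame != "in_frame" || fs$net_delta_nt >= 0L) {
    stop("domain error: deleted_residue_count requires an in-frame net deletion",
         call. = FALSE)
  }
  deletes_only <- all(purrr::map_lgl(transcript$events, function(ev) {
    ev$kind == "exon_skip" ||
      (ev$kind %in% c("alt_acceptor", "alt_donor") && ev$offset > 0L)
  }))
  if (!deletes_only) {
    stop("domain error: transcript mixes insertions with deletions",
         call. = FALSE)
  }
  abs(fs$net_delta_nt) %/% 3L
}

# mutant CDS implied by a transcript: reference head, retained/inserted
# body in transcript order, reference tail (incl. the natural terminator)
mutant_cds <- function(transcript, ctx) {
  construct <- transcript$construct
  seg <- construct$segments
  ex <- construct_exons(construct)
  if (any(is.na(ex$c_start))) {
    stop("context error: exon c. anchors required", call. = FALSE)
  }
  cds <- ctx$cds
  cs_min <- min(ex$c_start); ce_max <- max(ex$c_end)
  if (ce_max > nchar(cds)) {
    stop("context error: CDS does not cover modeled exon coordinates",
         call. = FALSE)
  }
  body <- character(0)
  for (i in seq_len(nrow(transcript$pieces))) {
    p <- transcript$pieces[i, ]
    if (!is.na(p$segment)) {
      j <- match(p$segment, seg$label)
      if (seg$role[j] == "vector_exon") next
      if (seg$role[j] == "exon" && !is.na(seg$c_start[j])) {
        a <- seg$c_start[j] + p$from - 1L
        b <- seg$c_start[j] + p$to - 1L
        body <- c(body, substr(cds, a, b))
        next
      }
      # intron-derived piece: need sequence
      if (!is.na(p$seq)) {
        body <- c(body, p$seq)
      } else if (!is.na(seg$sequence[j])) {
        body <- c(body, substr(seg$sequence[j], p$from, p$to))
      } else {
        stop("context error: sequence required for retained intronic piece ",
             "from ", p$segment, call. = FALSE)
      }
    } else {
      if (is.na(p$seq)) stop("context error: insertion without sequence",
                             call. = FALSE)
      body <- c(body, p$seq)
    }
  }
  paste0(substr(cds, 1L, cs_min - 1L), paste(body, collapse = ""),
         substr(cds, ce_max + 1L, nchar(cds)))
}

# compare reference and mutant CDS translations; shared engine behind
# protein_consequence() and direct_coding_consequence()
compare_proteins <- function(ref_cds, mut_cds, net_delta_nt) {
  ref <- translate_codons(ref_cds)
  mut <- translate_codons(mut_cds)
  lr <- length(ref); lm <- length(mut)
  dangling <- nchar(mut_cds) %% 3L != 0L

  k <- match("*", mut)                       # first stop in mutant
  ptc <- !is.na(k) && (k < lm || dangling)

  if (identical(ref, mut)) {
    return(list(class = if (net_delta_nt == 0L) "synonymous" else "canonical",
                p_hgvs = "p.(=)", ptc = NA_integer_))
  }
  nmin <- min(lr, lm)
  diff_at <- which(ref[seq_len(nmin)] != mut[seq_len(nmin)])
  i <- if (length(diff_at)) diff_at[1L] else nmin + 1L

  if (ptc) {
    if (net_delta_nt == 0L && !is.na(k) && k == i &&
        identical(ref[-i], mut[-i])) {
      return(list(class = "nonsense_direct",
                  p_hgvs = sprintf("p.%s%d*", ref[i], i),
                  ptc = as.integer(i)))
    }
    if (is.na(k) || k < i) {
      # degenerate: divergence starts at the stop itself
      i <- k
    }
    if (k == i) {
      return(list(class = "ptc_introducing",
                  p_hgvs = sprintf("p.%s%d*", ref[i], i),
                  ptc = as.integer(k)))
    }
    return(list(class = "ptc_introducing",
                p_hgvs = sprintf("p.%s%d%sfs*%d", ref[i], i, mut[i], k - i + 1L),
                ptc = as.integer(k)))
  }

  if (net_delta_nt %% 3L != 0L) {
    # frameshift that never meets a stop before the modeled end
    return(list(class = "frameshift_no_stop",
                p_hgvs = sprintf("p.%s%dfs*?", ref[i], i),
                ptc = NA_integer_))
  }

  if (net_delta_nt == 0L) {
    return(list(class = "missense",
                p_hgvs = sprintf("p.%s%d%s", ref[i], i, mut[i]),
                ptc = NA_integer_))
  }

  # in-frame indel: maximal common prefix, then maximal common suffix
  # (prefix-first trimming implements the HGVS 3'-most convention)
  pre <- 0L
  while (pre < nmin && ref[pre + 1L] == mut[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre && ref[lr - suf] == mut[lm - suf]) suf <- suf + 1L
  ref_block <- if (lr - suf >= pre + 1L) (pre + 1L):(lr - suf) else integer(0)
  mut_block <- if (lm - suf >= pre + 1L) (pre + 1L):(lm - suf) else integer(0)

  if (length(mut_block) == 0L) {
    a <- ref_block[1L]; b <- ref_block[length(ref_block)]
    p <- if (a == b) sprintf("p.%s%ddel", ref[a], a) else
      sprintf("p.%s%d_%s%ddel", ref[a], a, ref[b], b)
    return(list(class = "in_frame_deletion", p_hgvs = p, ptc = NA_integer_))
  }
  if (length(ref_block) == 0L) {
    ins <- paste(mut[mut_block], collapse = "")
    p <- sprintf("p.%s%d_%s%dins%s", ref[pre], pre, ref[pre + 1L], pre + 1L, ins)
    return(list(class = "in_frame_delins", p_hgvs = p, ptc = NA_integer_))
  }
  a <- ref_block[1L]; b <- ref_block[length(ref_block)]
  p <- sprintf("p.%s%d_%s%ddelins%s", ref[a], a, ref[b], b,
               paste(mut[mut_block], collapse = ""))
  list(class = "in_frame_delins", p_hgvs = p, ptc = NA_integer_)
}

#' Protein-level consequence of a transcript
#'
#' Translates the mutant CDS implied by the transcript and reports the
#' consequence class, protein HGVS and premature-stop position. The first
#' novel stop upstream of the reference terminator is a PTC; `fs*N`
#' counts residues from the first altered residue to the stop inclusive
#' (HGVS convention).
#'
#' @param transcript A transcript from [apply_splice_events()].
#' @param ctx A [coding_context()].
#' @return An object of class `consequence`: list with `frame_status`,
#'   `net_delta_nt`, `ptc`, `p_hgvs`, `consequence_class`.
#' @export
protein_consequence <- function(transcript, ctx) {
  fs <- frame_status(transcript)
  mut <- mutant_cds(transcript, ctx)
  cmp <- compare_proteins(ctx$cds, mut, fs$net_delta_nt)
  cls <- cmp$class
  if (length(transcript$events) == 0L) cls <- "canonical"
  structure(list(frame_status = fs$frame,
                 net_delta_nt = fs$net_delta_nt,
                 ptc = cmp$ptc,
                 p_hgvs = cmp$p_hgvs,
                 consequence_class = cls),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat("<consequence> ", x$consequence_class, " ", x$p_hgvs,
      " (", x$frame_status, ", ", sprintf("%+d", x$net_delta_nt), " nt)\n",
      sep = "")
  invisible(x)
}

#' Count PTC-introducing transcripts
#'
#' @param transcripts A list of structurally characterised transcripts.
#' @param ctx A [coding_context()].
#' @return Integer count of transcripts whose consequence class is
#'   `ptc_introducing`.
#' @export
count_ptc_transcripts <- function(transcripts, ctx) {
  sum(purrr::map_lgl(transcripts, function(tr) {
    protein_consequence(tr, ctx)$consequence_class == "ptc_introducing"
  }))
}

#' Direct coding prediction of a DNA variant
#'
#' The consequence the variant would have on the protein if splicing were
#' unaffected: `"intronic"` for intron-offset variants, otherwise the
#' translated effect of editing the CDS (`"nonsense"`, `"frameshift"`,
#' `"missense"`, `"synonymous"`, `"in_frame"`).
#'
#' @param ctx A [coding_context()].
#' @param variant A [parse_variant()] object or HGVS c. string.
#' @return Character scalar prediction.
#' @export
direct_coding_consequence <- function(ctx, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  if (variant$start$offset != 0L || variant$end$offset != 0L) {
    return("intronic")
  }
  cds <- ctx$cds
  a <- variant$start$base; b <- variant$end$base
  mut <- switch(variant$edit_kind,
    substitution = {
      s <- cds; substr(s, a, a) <- variant$alt; s
    },
    deletion = paste0(substr(cds, 1L, a - 1L), substr(cds, b + 1L, nchar(cds))),
    duplication = paste0(substr(cds, 1L, b), substr(cds, a, b),
                         substr(cds, b + 1L, nchar(cds))),
    insertion = paste0(substr(cds, 1L, a), variant$alt,
                       substr(cds, a + 1L, nchar(cds))),
    delins = paste0(substr(cds, 1L, a - 1L), variant$alt,
                    substr(cds, b + 1L, nchar(cds)))
  )
  delta <- nchar(mut) - nchar(cds)
  cmp <- compare_proteins(cds, mut, delta)
  switch(cmp$class,
         nonsense_direct = "nonsense",
         ptc_introducing = if (delta %% 3L != 0L) "frameshift" else "in_frame",
         frameshift_no_stop = "frameshift",
         missense = "missense",
         synonymous = "synonymous",
         canonical = "synonymous",
         "in_frame")
}
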