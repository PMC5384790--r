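# HGVS c. coordinate handling.
#
# A coding-DNA position is a pair (base, offset): `base` is the 1-based
# position in the coding reference, `offset` is 0 for exonic positions,
# +n for intronic positions counted from the donor end of the exon ending
# at `base`, and -n for intronic positions counted back from the acceptor
# end of the exon starting at `base` (HGVS c.X+n / c.Y-n convention).

#' Create a coding-DNA position
#'
#' @param base Integer, exonic anchor position (HGVS c. numbering).
#' @param offset Integer intron offset: 0 (exonic), positive (donor side,
#'   `c.base+offset`) or negative (acceptor side, `c.base-offset`).
#' @return An object of class `c_pos`.
#' @examples
#' c_pos(7806, -1) # c.7806-1
#' @export
c_pos <- function(base, offset = 0L) {
  stopifnot(is.numeric(base), length(base) == 1L, base >= 1)
  stopifnot(is.numeric(offset), length(offset) == 1L)
  structure(list(base = as.integer(base), offset = as.integer(offset)),
            class = "c_pos")
}

#' Parse an HGVS c. position string
#'
#' Accepts plain exonic positions (`"7806"`) and intron-offset positions
#' (`"7806-1"`, `"7976+2"`).
#'
#' @param x Character scalar, without the leading `"c."`.
#' @return A [c_pos()] object.
#' @export
parse_c_pos <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(\\d+)([+-]\\d+)?$", x))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse c. position: '", x, "'", call. = FALSE)
  }
  off <- if (is.na(m[3]) || m[3] == "") 0L else as.integer(m[3])
  c_pos(as.integer(m[2]), off)
}

#' Format a coding-DNA position
#'
#' @param pos A [c_pos()] object.
#' @return Character scalar such as `"7806-1"`.
#' @export
format_c_pos <- function(pos) {
  stopifnot(inherits(pos, "c_pos"))
  if (pos$offset == 0L) {
    as.character(pos$base)
  } else {
    sprintf("%d%+d", pos$base, pos$offset)
  }
}

#' @export
print.c_pos <- function(x, ...) {
  cat("c.", format_c_pos(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.c_pos <- function(x, ...) format_c_pos(x)

# Total ordering key for positions anchored on a contiguous c. axis.
# Exonic positions sort by base; acceptor-side intronic positions (-n)
# sort just before their exon start, donor-side (+n) just after their
# exon end. The fractional part keeps intronic positions between the
# flanking exonic integers.
c_pos_key <- function(pos) {
  if (pos$offset == 0L) {
    pos$base
  } else if (pos$offset > 0L) {
    pos$base + pos$offset / (abs(pos$offset) + 1e6)
  } else {
    pos$base + pos$offset / (abs(pos$offset) + 1e6)
  }
}

c_pos_eq <- function(a, b) a$base == b$base && a$offset == b$offset
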