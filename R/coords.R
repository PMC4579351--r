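# Orientation arithmetic shared by every module.
#
# All genome coordinates in the package are 0-based, half-open (BED native).
# "Relative" offsets are signed base pairs in gene orientation: negative =
# upstream of the anchor, positive = downstream, whatever the gene strand.

#' Convert a relative offset to an absolute coordinate
#'
#' @param anchor absolute coordinate of the anchor base (0-based).
#' @param strand `"+"` or `"-"` orientation of the anchored feature.
#' @param rel signed offset in gene orientation (negative = upstream).
#' @return absolute 0-based coordinate(s).
#' @export
rel_to_abs <- function(anchor, strand, rel) {
  n <- max(length(anchor), length(strand), length(rel))
  anchor <- rep_len(anchor, n); rel <- rep_len(rel, n)
  ifelse(rep_len(strand, n) == "+", anchor + rel, anchor - rel)
}

#' Convert an absolute coordinate to a signed gene-orientation offset
#'
#' @inheritParams rel_to_abs
#' @param pos absolute 0-based coordinate(s).
#' @return signed offset(s); negative = upstream of the anchor.
#' @export
abs_to_rel <- function(anchor, strand, pos) {
  n <- max(length(anchor), length(strand), length(pos))
  anchor <- rep_len(anchor, n); pos <- rep_len(pos, n)
  ifelse(rep_len(strand, n) == "+", pos - anchor, anchor - pos)
}

#' Map a half-open relative window onto absolute coordinates
#'
#' The window `[lo, hi)` is interpreted in gene orientation; on the minus
#' strand it mirrors around the anchor and stays half-open.
#'
#' @inheritParams rel_to_abs
#' @param lo,hi half-open window bounds in relative coordinates (`lo < hi`).
#' @return integer vector `c(start, end)`, absolute and half-open.
#' @export
rel_window_abs <- function(anchor, strand, lo, hi) {
  stopifnot(lo < hi)
  if (strand == "+") c(anchor + lo, anchor + hi) else c(anchor - hi + 1L, anchor - lo + 1L)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# positions falling in half-open [lo, hi)
in_window <- function(pos, lo, hi) pos >= lo & pos < hi
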