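# Tag datasets: the pipeline's universal currency. A tag is the 0-based
# coordinate of a sequenced 5' end (an exonuclease stop site) on one strand.

#' Construct a tag dataset
#'
#' @param records data.frame with columns `chrom` (character), `pos`
#'   (0-based integer coordinate of the tag 5' end), `strand` (`"+"`/`"-"`)
#'   and optionally `weight` (numeric, defaults to 1; carries normalization
#'   scale factors).
#' @param factor,condition labels carried through the pipeline.
#' @param shifted logical; whether tags have already been shifted toward the
#'   cross-link point. A dataset can be shifted exactly once.
#' @return an object of class `tag_dataset`.
#' @export
tag_dataset <- function(records, factor = "", condition = "", shifted = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "strand")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("tag records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"weight" %in% names(records)) records$weight <- rep(1, nrow(records))
  records$pos <- as.integer(records$pos)
  if (nrow(records) && any(records$pos < 0L)) stop("tag coordinates must be >= 0")
  if (nrow(records) && !all(records$strand %in% c("+", "-"))) {
    stop("tag strand must be '+' or '-'")
  }
  structure(
    list(factor = factor, condition = condition,
         records = records[c("chrom", "pos", "strand", "weight")],
         shifted = isTRUE(shifted)),
    class = "tag_dataset")
}

#' @export
print.tag_dataset <- function(x, ...) {
  cat(sprintf("<tag_dataset> %s/%s: %d tags (total weight %.1f), %s\n",
              x$factor, x$condition, nrow(x$records), sum(x$records$weight),
              if (x$shifted) "shifted" else "unshifted"))
  invisible(x)
}

n_tags <- function(tags) nrow(tags$records)

#' Shift tag 5' ends toward the cross-link point
#'
#' Each tag is moved in its own 3' direction: forward-strand tags by `+shift`,
#' reverse-strand tags by `-shift`. With the default 6-bp exonuclease headroom
#' this collapses the opposite-strand stop-site doublet onto the cross-link
#' coordinate. Shifting is a one-shot state change; shifting an already
#' shifted dataset is an error. Tags shifted below coordinate 0 are dropped
#' and the drop count recorded in the `"n_clamped"` attribute.
#'
#' @param tags a [tag_dataset()], unshifted.
#' @param shift shift distance in bp (default 6).
#' @return the shifted `tag_dataset`.
#' @export
shift_tags <- function(tags, shift = 6L) {
  stopifnot(inherits(tags, "tag_dataset"))
  if (tags$shifted) stop("tags are already shifted; refusing to shift twice")
  shift <- as.integer(shift)
  rec <- tags$records
  rec$pos <- rec$pos + ifelse(rec$strand == "+", shift, -shift)
  keep <- rec$pos >= 0L
  out <- tag_dataset(rec[keep, , drop = FALSE], tags$factor, tags$condition,
                     shifted = TRUE)
  attr(out, "n_clamped") <- sum(!keep)
  out
}

#' Per-base strand-specific pileup over a window
#'
#' @param tags a [tag_dataset()].
#' @param chrom chromosome to pile up.
#' @param window half-open absolute interval `c(start, end)`.
#' @return a `pileup` object: per-base weighted tag 5'-end counts
#'   (`counts_fwd`, `counts_rev`, `counts_all`) over the window.
#' @export
tag_pileup <- function(tags, chrom, window) {
  stopifnot(inherits(tags, "tag_dataset"), length(window) == 2)
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (end <= start) stop("empty pileup window")
  len <- end - start
  rec <- tags$records
  rec <- rec[rec$chrom == chrom & in_window(rec$pos, start, end), , drop = FALSE]
  acc <- function(r) {
    v <- numeric(len)
    if (nrow(r)) {
      s <- rowsum(r$weight, r$pos - start + 1L)
      v[as.integer(rownames(s))] <- s[, 1]
    }
    v
  }
  fwd <- acc(rec[rec$strand == "+", , drop = FALSE])
  rev <- acc(rec[rec$strand == "-", , drop = FALSE])
  structure(list(chrom = chrom, start = start,
                 counts_fwd = fwd, counts_rev = rev, counts_all = fwd + rev),
            class = "pileup")
}

#' Read single-bp tag records from a BED6 file
#'
#' BED is 0-based half-open; each record must span exactly 1 bp; the score
#' column carries multiplicity and is expanded on read, so the in-memory
#' dataset has one row per tag.
#'
#' @param path BED6 file path.
#' @param factor,condition labels for the resulting dataset.
#' @param shifted whether the file holds already-shifted tags.
#' @return a [tag_dataset()].
#' @export
read_tags_bed <- function(path, factor = "", condition = "", shifted = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tag_dataset(data.frame(chrom = character(), pos = integer(),
                                  strand = character()),
                       factor, condition, shifted))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) stop(sprintf("malformed BED line %d: expected 6 fields", bad[1]))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  for (chk in list(list(is.na(start) | start < 0L, "invalid start coordinate"),
                   list(is.na(end) | end != start + 1L, "tag interval must span 1 bp"),
                   list(is.na(score) | score < 1, "invalid multiplicity score"),
                   list(!m[, 6] %in% c("+", "-"), "invalid strand"))) {
    if (any(chk[[1]])) stop(sprintf("malformed BED line %d: %s", which(chk[[1]])[1], chk[[2]]))
  }
  mult <- as.integer(round(score))
  idx <- rep.int(seq_along(start), mult)
  tag_dataset(data.frame(chrom = m[idx, 1], pos = start[idx],
                         strand = m[idx, 6], stringsAsFactors = FALSE),
              factor, condition, shifted)
}

#' Write tag records to a BED6 file
#'
#' Identical unit-weight tags are collapsed into one record with the
#' multiplicity in the score column (lossless round trip with
#' [read_tags_bed()]). Datasets carrying non-unit weights cannot be stored in
#' an integer score column and are refused.
#'
#' @param tags a [tag_dataset()].
#' @param path output file.
#' @export
write_tags_bed <- function(tags, path) {
  stopifnot(inherits(tags, "tag_dataset"))
  rec <- tags$records
  if (nrow(rec) && any(abs(rec$weight - 1) > 1e-9)) {
    stop("cannot write weighted tag datasets to BED (score column is a multiplicity)")
  }
  if (nrow(rec)) {
    key <- paste(rec$chrom, rec$pos, rec$strand, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1)
    pos <- as.integer(vapply(parts, `[`, "", 2))
    strand <- vapply(parts, `[`, "", 3)
    o <- order(chrom, pos, strand)
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom[o], pos[o], pos[o] + 1L,
                   if (nzchar(tags$factor)) tags$factor else "tag",
                   as.integer(tab)[o], strand[o])
  } else out <- character()
  writeLines(out, path)
  invisible(path)
}

#' Read fragment intervals from a BED file
#'
#' @param path BED (>= 3 columns) file of half-open intervals.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(), start = integer(), end = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop(sprintf("malformed BED line %d: expected >= 3 fields", bad[1]))
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  if (any(is.na(start) | is.na(end) | start < 0 | end <= start)) {
    stop(sprintf("malformed BED line %d: invalid interval",
                 which(is.na(start) | is.na(end) | start < 0 | end <= start)[1]))
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' @rdname read_fragments_bed
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_fragments_bed <- function(fragments, path) {
  writeLines(sprintf("%s\t%d\t%d\tfrag\t0\t+", fragments$chrom,
                     as.integer(fragments$start), as.integer(fragments$end)), path)
  invisible(path)
}

#' Export a pileup (or any per-base track) as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted.
#'
#' @param values numeric per-base vector.
#' @param chrom chromosome name.
#' @param start 0-based coordinate of `values[1]`.
#' @param path output file.
#' @export
write_bedgraph <- function(values, chrom, start, path) {
  r <- rle(values)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths
  keep <- r$values != 0
  writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom, start + lo[keep],
                     start + hi[keep], r$values[keep]), path)
  invisible(path)
}
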