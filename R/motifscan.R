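# Motif location: IUPAC consensus matching (Rap1/Fhl1/IFHL/poly(dA:dT)),
# PWM scanning with exact p-values by dynamic programming, peak-proximity
# retention and TSS assignment. All reported intervals are 0-based half-open.

DNA_BASES <- c("A", "C", "G", "T")

check_iupac <- function(pattern) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(toupper(pattern), "")[[1]], codes)
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  toupper(pattern)
}

#' Scan a sequence for an IUPAC consensus
#'
#' Degeneracy codes in the pattern (N, Y, K, W, ...) match their base sets;
#' the subject is matched literally. With `both_strands`, reverse-complement
#' matches are reported on the minus strand at their plus-strand coordinates.
#'
#' @param seq character scalar or `DNAString` to scan.
#' @param pattern IUPAC consensus, e.g. `"GGCNG"` (IFHL) or `"YKYGCGTC"`
#'   (Fhl1).
#' @param both_strands also scan the reverse complement (default TRUE).
#' @return data.frame with `motif`, `start`, `end` (0-based half-open),
#'   `strand`, `midpoint` (numeric, `(start + end - 1) / 2`).
#' @export
scan_iupac <- function(seq, pattern, both_strands = TRUE) {
  pattern <- check_iupac(pattern)
  subj <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(toupper(as.character(seq)))
  hit_df <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    st <- BiocGenerics::start(m) - 1L
    data.frame(motif = rep_len(pattern, length(st)), start = st,
               end = BiocGenerics::end(m), strand = rep_len(strand, length(st)),
               stringsAsFactors = FALSE)
  }
  out <- hit_df(pattern, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    out <- rbind(out, hit_df(rc, "-"))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$midpoint <- (out$start + out$end - 1) / 2
  rownames(out) <- NULL
  out
}

#' Locate poly(dA:dT) tracts
#'
#' Maximal runs of A, or of T, of at least `min_len` bp (a ">5-mer" rule is
#' `min_len = 6`). A and T runs are separate tracts: `"AAATTT"` contains no
#' 6-mer tract.
#'
#' @param seq character scalar or `DNAString`.
#' @param min_len minimum run length (default 6).
#' @return data.frame with `start`, `end` (half-open), `base` (`"A"`/`"T"`),
#'   `length`, `midpoint`.
#' @export
find_polyA <- function(seq, min_len = 6L) {
  stopifnot(min_len >= 2)
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  r <- rle(s)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths
  keep <- r$values %in% c("A", "T") & r$lengths >= min_len
  out <- data.frame(start = lo[keep], end = hi[keep], base = r$values[keep],
                    length = r$lengths[keep], stringsAsFactors = FALSE)
  out$midpoint <- (out$start + out$end - 1) / 2
  out
}

# Integer-score discretization of a log-odds matrix: one bin = 1/nbins of the
# total attainable score range (the documented precision of the exact DP).
# 1e5 bins keep the worst-case p-value discretization error below 1e-3 even
# for sharply peaked matrices (score-rounding can flip sequences whose true
# scores lie within w bins of the threshold).
discretize_llr <- function(llr, nbins = 100000L) {
  smin <- sum(apply(llr, 2, min)); smax <- sum(apply(llr, 2, max))
  delta <- (smax - smin) / nbins
  if (delta <= 0) delta <- 1      # degenerate: all scores equal
  list(r = round(llr / delta), delta = delta)
}

# Exact null tail probabilities of the discretized score by DP over columns.
# Returns a function t -> P(score_int >= t) under the 0-order background.
pwm_tail_fun <- function(r_mat, background) {
  w <- ncol(r_mat)
  cur <- c(1)                      # distribution over integer scores
  cur_lo <- 0L
  for (j in seq_len(w)) {
    rj <- r_mat[, j]
    new_lo <- cur_lo + min(rj)
    new_hi <- cur_lo + length(cur) - 1L + max(rj)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      idx <- seq_along(cur) + (cur_lo + rj[b] - new_lo)
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  tail <- pmin(tail, 1)
  function(t) {
    i <- t - cur_lo + 1L
    ifelse(i <= 1L, 1, ifelse(i > length(tail), 0, tail[pmax(i, 1L)]))
  }
}

#' Scan a sequence with a PWM, reporting exact p-values
#'
#' Windows are scored by the log2 likelihood ratio of the PWM against a
#' 0-order background (the FIMO default dialect). The p-value of a score is
#' the exact null probability of an equal or greater score, computed by
#' dynamic programming over column score distributions discretized to 1/1000
#' of the attainable score range per bin; p-values are therefore exact on
#' that grid and monotone non-increasing in score.
#'
#' @param seq character scalar or `DNAString`.
#' @param pwm 4 x w probability matrix, rows A, C, G, T; columns sum to 1.
#' @param background length-4 base frequencies (A, C, G, T). Default: 0-order
#'   frequencies of the scanned sequence.
#' @param p_threshold report windows with `p_value <= p_threshold`
#'   (default 0.001, the Rap1/Fhl1/poly(dA:dT) threshold; IFHL uses 1e-4).
#' @param both_strands also scan the reverse complement (default TRUE).
#' @param pseudocount added to PWM entries before log-odds (guards zeros).
#' @param motif label for the output.
#' @return data.frame with `motif`, `start`, `end`, `strand`, `llr_score`
#'   (on the discretization grid, so p-values are exactly monotone in it),
#'   `p_value`, `midpoint`.
#' @export
scan_pwm <- function(seq, pwm, background = NULL, p_threshold = 0.001,
                     both_strands = TRUE, pseudocount = 0.001, motif = "pwm") {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  pwm <- pwm[DNA_BASES, , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("pwm columns must sum to 1")
  s <- toupper(as.character(seq))
  x <- match(strsplit(s, "")[[1]], DNA_BASES)
  if (is.null(background)) {
    cnt <- tabulate(x, nbins = 4)
    background <- (cnt + 1) / sum(cnt + 1)
  }
  background <- background / sum(background)
  if (any(background <= 0)) stop("background frequencies must be positive")
  w <- ncol(pwm)
  q <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  llr <- log2(q / background)
  disc <- discretize_llr(llr)
  tailp <- pwm_tail_fun(disc$r, background)

  score_strand <- function(mat_r, mat_s) {
    n <- length(x)
    if (n < w) return(NULL)
    nwin <- n - w + 1L
    ri <- numeric(nwin); sc <- numeric(nwin)
    ok <- rep(TRUE, nwin)
    for (j in seq_len(w)) {
      b <- x[j:(j + nwin - 1L)]
      ok <- ok & !is.na(b)
      bi <- ifelse(is.na(b), 1L, b)
      ri <- ri + mat_r[cbind(bi, j)]
      sc <- sc + mat_s[cbind(bi, j)]
    }
    list(ri = ri, sc = sc, ok = ok)
  }
  collect <- function(mat_r, mat_s, strand) {
    z <- score_strand(mat_r, mat_s)
    if (is.null(z)) return(NULL)
    p <- tailp(z$ri)
    keep <- z$ok & p <= p_threshold
    if (!any(keep)) return(NULL)
    st <- which(keep) - 1L
    # scores are reported on the discretization grid, so p-values are
    # exactly monotone non-increasing in the reported score
    data.frame(motif = motif, start = st, end = st + w, strand = strand,
               llr_score = z$ri[keep] * disc$delta, p_value = p[keep],
               stringsAsFactors = FALSE)
  }
  out <- collect(disc$r, llr, "+")
  if (both_strands) {
    # reverse-complemented PWM: reverse columns, complement rows
    rc <- llr[4:1, w:1, drop = FALSE]; rownames(rc) <- DNA_BASES
    rc_r <- disc$r[4:1, w:1, drop = FALSE]; rownames(rc_r) <- DNA_BASES
    out <- rbind(out, collect(rc_r, rc, "-"))
  }
  if (is.null(out)) {
    out <- data.frame(motif = character(), start = integer(), end = integer(),
                      strand = character(), llr_score = numeric(),
                      p_value = numeric())
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$midpoint <- (out$start + out$end - 1) / 2
  rownames(out) <- NULL
  out
}

#' Exact PWM p-value of one window (helper around the DP)
#'
#' Scores the window with the same discretized log-odds matrix the DP uses,
#' so the reported p-value is exact on the discretization grid.
#'
#' @inheritParams scan_pwm
#' @param window character window of the motif's width (or vector of
#'   windows).
#' @return `P(score' >= score(window))` under the background.
#' @export
pwm_pvalue <- function(window, pwm, background, pseudocount = 0.001) {
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  pwm <- pwm[DNA_BASES, , drop = FALSE]
  background <- background / sum(background)
  q <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  llr <- log2(q / background)
  disc <- discretize_llr(llr)
  tailp <- pwm_tail_fun(disc$r, background)
  vapply(toupper(window), function(wseq) {
    b <- match(strsplit(wseq, "")[[1]], DNA_BASES)
    if (length(b) != ncol(pwm) || anyNA(b)) stop("window/pwm width mismatch")
    tailp(sum(disc$r[cbind(b, seq_along(b))]))
  }, 0, USE.NAMES = FALSE)
}

#' Retain motif matches near peaks
#'
#' Keeps matches whose midpoint lies within +/-`radius` bp (inclusive) of any
#' peak coordinate; set semantics — a match near several peaks is kept once.
#'
#' @param matches data.frame with a `midpoint` column.
#' @param peaks data.frame with a `pos` column (peak coordinates), or a
#'   numeric vector of coordinates.
#' @param radius retention radius in bp (default 40).
#' @return the retained matches.
#' @export
retain_near_peaks <- function(matches, peaks, radius = 40) {
  pos <- if (is.data.frame(peaks)) peaks$pos else peaks
  if (!length(pos) || !nrow(matches)) return(matches[integer(0), , drop = FALSE])
  keep <- vapply(matches$midpoint, function(m) any(abs(pos - m) <= radius), TRUE)
  matches[keep, , drop = FALSE]
}

#' Assign binding sites to their closest TSS
#'
#' Nearest neighbor by unsigned bp distance, retained only when strictly
#' closer than `max_dist`. The reported distance is signed in gene
#' orientation: negative = upstream of the TSS.
#'
#' @param sites data.frame with a `midpoint` (or `pos`) column.
#' @param tss_table data.frame with `gene_id`, `tss`, `strand`.
#' @param max_dist strict distance cutoff in bp (default 500).
#' @return data.frame `site_midpoint`, `gene_id`, `distance_to_tss`;
#'   out-of-range sites are omitted.
#' @export
assign_to_tss <- function(sites, tss_table, max_dist = 500) {
  mids <- if ("midpoint" %in% names(sites)) sites$midpoint else sites$pos
  if (!length(mids)) {
    return(data.frame(site_midpoint = numeric(), gene_id = character(),
                      distance_to_tss = numeric()))
  }
  gi <- vapply(mids, function(m) which.min(abs(tss_table$tss - m)), 1L)
  d_abs <- abs(tss_table$tss[gi] - mids)
  keep <- d_abs < max_dist
  data.frame(
    site_midpoint = mids[keep], gene_id = tss_table$gene_id[gi[keep]],
    distance_to_tss = abs_to_rel(tss_table$tss[gi[keep]],
                                 tss_table$strand[gi[keep]], mids[keep]),
    stringsAsFactors = FALSE)
}

#' Read PWMs from a MEME minimal-format text file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#'
#' @param path file path.
#' @return named list of 4 x w probability matrices (rows A, C, G, T).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][2]
    block_end <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    block <- lines[starts[k]:block_end]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr)) stop("MOTIF ", name, " has no letter-probability matrix")
    rows <- list()
    for (ln in block[-seq_len(hdr[1])]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) { if (length(rows)) break else next }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
    }
    m <- t(do.call(rbind, rows))
    rownames(m) <- DNA_BASES
    out[[name]] <- m
  }
  out
}

#' Write PWMs to a MEME minimal-format text file
#'
#' @param motifs named list of 4 x w probability matrices.
#' @param path output file.
#' @param background length-4 background frequencies recorded in the header.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                   background[3], background[4]), "")
  for (name in names(motifs)) {
    m <- motifs[[name]]
    out <- c(out, paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(m)),
             apply(m, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                               col[1], col[2], col[3], col[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
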