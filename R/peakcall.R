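# GeneTrack-style peak calling: Gaussian-smoothed per-strand stop-site
# densities, greedy maxima with an exclusion zone, opposite-strand pairing.

gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing of a per-base count vector
#'
#' Discrete Gaussian kernel convolution, mass-conserving: every impulse —
#' including one at the array edge, where the kernel is truncated and
#' renormalized to the in-window support — contributes its full count to the
#' smoothed density.
#'
#' @param counts numeric per-base counts.
#' @param sigma kernel standard deviation in bp (GeneTrack default 5).
#' @return numeric density vector of the same length.
#' @export
smooth_density <- function(counts, sigma = 5) {
  stopifnot(sigma > 0)
  n <- length(counts)
  if (!n) return(numeric())
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv <- function(x) {
    xp <- c(numeric(r), x, numeric(r))
    y <- stats::filter(xp, k, sides = 2)
    as.numeric(y[(r + 1L):(r + n)])
  }
  inside <- conv(rep(1, n))        # fraction of each source kernel in-window
  conv(counts / inside)
}

#' Call peaks from a smoothed density by greedy maxima with exclusion
#'
#' Repeatedly takes the global maximum of the density, emits a peak there,
#' and suppresses every position closer than `exclusion` bp (center to
#' center), until no position above `min_height` remains. Ties go to the
#' lower coordinate. Retained peaks are therefore always >= `exclusion` bp
#' apart.
#'
#' @param density numeric vector from [smooth_density()].
#' @param exclusion exclusion-zone width in bp (GeneTrack default 20),
#'   interpreted as the minimum center-to-center peak distance.
#' @param min_height peaks must exceed this density (default 0).
#' @param counts optional raw per-base counts aligned with `density`; when
#'   given, each peak's `tag_count` sums the counts within half the exclusion
#'   zone on each side of the peak.
#' @param start absolute coordinate of `density[1]` (default 0), so reported
#'   peak positions are genome coordinates.
#' @return data.frame with `pos`, `height`, `tag_count`.
#' @export
call_peaks <- function(density, exclusion = 20L, min_height = 0,
                       counts = NULL, start = 0L) {
  stopifnot(exclusion >= 1)
  n <- length(density)
  exclusion <- as.integer(exclusion)
  # Sorted-acceptance formulation: visiting positions in decreasing height
  # (ties: ascending coordinate) and accepting any not yet suppressed is
  # equivalent to the literal repeated-global-maximum greedy loop.
  ord <- order(-density, seq_len(n))
  suppressed <- logical(n)
  acc <- integer(0)
  for (i in ord) {
    if (density[i] <= min_height) break
    if (suppressed[i]) next
    acc <- c(acc, i)
    suppressed[max(1L, i - exclusion + 1L):min(n, i + exclusion - 1L)] <- TRUE
  }
  acc <- sort(acc)
  half <- exclusion %/% 2L
  tc <- if (is.null(counts)) rep(NA_real_, length(acc)) else
    vapply(acc, function(i) sum(counts[max(1L, i - half):min(n, i + half)]), 0)
  data.frame(pos = start + acc - 1L, height = density[acc], tag_count = tc)
}

#' Pair forward- and reverse-strand peaks across one cross-link point
#'
#' A forward peak may pair with a reverse peak at an equal or greater
#' coordinate within `max_span` bp (the stop sites flank the cross-link, so
#' the pair reads fwd -> rev in the 3' direction). Matching is one-to-one and
#' greedy by ascending span; each peak joins at most one pair, and unpaired
#' peaks are dropped.
#'
#' @param fwd_peaks,rev_peaks data.frames from [call_peaks()] for the two
#'   strands.
#' @param max_span maximum fwd-to-rev distance in bp (default 100).
#' @return data.frame with `fwd_pos`, `rev_pos`, `midpoint`, `span`, `count`
#'   (sum of the two peak tag counts), `fwd_height`, `rev_height`.
#' @export
pair_peaks <- function(fwd_peaks, rev_peaks, max_span = 100L) {
  empty <- data.frame(fwd_pos = integer(), rev_pos = integer(),
                      midpoint = numeric(), span = integer(), count = numeric(),
                      fwd_height = numeric(), rev_height = numeric())
  if (!nrow(fwd_peaks) || !nrow(rev_peaks)) return(empty)
  cand <- expand.grid(fi = seq_len(nrow(fwd_peaks)), ri = seq_len(nrow(rev_peaks)))
  cand$span <- rev_peaks$pos[cand$ri] - fwd_peaks$pos[cand$fi]
  cand <- cand[cand$span >= 0 & cand$span <= max_span, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$span, fwd_peaks$pos[cand$fi]), , drop = FALSE]
  used_f <- logical(nrow(fwd_peaks)); used_r <- logical(nrow(rev_peaks))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fi <- cand$fi[i]; ri <- cand$ri[i]
    if (!used_f[fi] && !used_r[ri]) {
      keep[i] <- TRUE; used_f[fi] <- TRUE; used_r[ri] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    fwd_pos = fwd_peaks$pos[cand$fi], rev_pos = rev_peaks$pos[cand$ri],
    midpoint = (fwd_peaks$pos[cand$fi] + rev_peaks$pos[cand$ri]) / 2,
    span = cand$span,
    count = fwd_peaks$tag_count[cand$fi] + rev_peaks$tag_count[cand$ri],
    fwd_height = fwd_peaks$height[cand$fi], rev_height = rev_peaks$height[cand$ri])
  out[order(out$fwd_pos), , drop = FALSE]
}

#' Keep peak pairs with more than `min_count` supporting tags
#'
#' The retention rule is strict: a pair is kept only if `count > min_count`
#' (with the default 2, pairs need at least 3 tags).
#'
#' @param pairs data.frame from [pair_peaks()].
#' @param min_count strict lower bound on the pair tag count (default 2).
#' @return the filtered pairs.
#' @export
filter_pairs <- function(pairs, min_count = 2) {
  pairs[!is.na(pairs$count) & pairs$count > min_count, , drop = FALSE]
}

#' Call and pair peaks for one tag dataset over a window
#'
#' Convenience wrapper running [tag_pileup()], [smooth_density()],
#' [call_peaks()] per strand, [pair_peaks()] and [filter_pairs()].
#'
#' @inheritParams tag_pileup
#' @param sigma,exclusion,max_span,min_count stage parameters.
#' @return list with `fwd`, `rev` (peak data.frames) and `pairs`.
#' @export
call_peak_pairs <- function(tags, chrom, window, sigma = 5, exclusion = 20L,
                            max_span = 100L, min_count = 2) {
  pu <- tag_pileup(tags, chrom, window)
  fwd <- call_peaks(smooth_density(pu$counts_fwd, sigma), exclusion,
                    counts = pu$counts_fwd, start = pu$start)
  rev <- call_peaks(smooth_density(pu$counts_rev, sigma), exclusion,
                    counts = pu$counts_rev, start = pu$start)
  list(fwd = fwd, rev = rev,
       pairs = filter_pairs(pair_peaks(fwd, rev, max_span), min_count))
}

#' Normalize one dataset's background tag total onto another's
#'
#' Background is the genome outside the +/-`flank` bp intervals around peak
#' pair midpoints. The second dataset's per-tag weights are multiplied by
#' `scale = bg_a / bg_b`, so that after scaling both datasets carry the same
#' total background signal.
#'
#' @param tags_a reference [tag_dataset()].
#' @param tags_b dataset to rescale.
#' @param pairs peak pairs (from the reference or pooled data) whose
#'   midpoints define the signal regions to exclude.
#' @param flank half-width of the excluded interval around each pair midpoint
#'   (default 100, i.e. a 200-bp interval).
#' @return list with `scale` and `tags_b` (reweighted).
#' @export
normalize_background <- function(tags_a, tags_b, pairs, flank = 100L) {
  mids <- sort(as.integer(floor(pairs$midpoint)))
  flank <- as.integer(flank)
  bg_total <- function(tags) {
    rec <- tags$records
    if (!nrow(rec)) return(0)
    if (!length(mids)) return(sum(rec$weight))
    # excluded iff some midpoint m satisfies pos in [m - flank, m + flank)
    i <- findInterval(rec$pos, mids)
    below <- i >= 1L & rec$pos - mids[pmax(i, 1L)] < flank
    above <- i < length(mids) & mids[pmin(i + 1L, length(mids))] - rec$pos <= flank
    sum(rec$weight[!(below | above)])
  }
  bg_a <- bg_total(tags_a); bg_b <- bg_total(tags_b)
  if (bg_b <= 0) stop("zero background total in dataset b; cannot normalize")
  scale <- bg_a / bg_b
  tags_b$records$weight <- tags_b$records$weight * scale
  list(scale = scale, tags_b = tags_b)
}
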