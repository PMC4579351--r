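# Independent oracles and small fixture builders shared across tests.

# Literal repeated-global-maximum greedy peak caller (the reference
# implementation of the exclusion-zone rule; O(n * peaks), fine at test n).
greedy_peaks_oracle <- function(density, exclusion = 20L, min_height = 0) {
  d <- density
  out <- integer(0)
  repeat {
    m <- max(d)
    if (m <= min_height) break
    i <- which.max(d)            # which.max takes the lowest tied index
    out <- c(out, i)
    lo <- max(1L, i - exclusion + 1L); hi <- min(length(d), i + exclusion - 1L)
    d[lo:hi] <- -Inf
  }
  sort(out)
}

# Greedy smallest-span one-to-one matching built straight from the candidate
# matrix (independent of the package's implementation details).
pair_oracle <- function(fwd_pos, rev_pos, max_span = 100L) {
  cand <- list()
  for (f in seq_along(fwd_pos)) {
    for (r in seq_along(rev_pos)) {
      sp <- rev_pos[r] - fwd_pos[f]
      if (sp >= 0 && sp <= max_span) cand[[length(cand) + 1L]] <- c(f, r, sp)
    }
  }
  if (!length(cand)) return(data.frame(fwd = integer(), rev = integer()))
  m <- do.call(rbind, cand)
  m <- m[order(m[, 3], fwd_pos[m[, 1]]), , drop = FALSE]
  used_f <- used_r <- integer(0)
  keep <- matrix(nrow = 0, ncol = 3)
  for (i in seq_len(nrow(m))) {
    if (!(m[i, 1] %in% used_f) && !(m[i, 2] %in% used_r)) {
      keep <- rbind(keep, m[i, ])
      used_f <- c(used_f, m[i, 1]); used_r <- c(used_r, m[i, 2])
    }
  }
  data.frame(fwd = fwd_pos[keep[, 1]], rev = rev_pos[keep[, 2]])
}

# All concrete expansions of an IUPAC pattern (exhaustive; small patterns).
iupac_expand <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(map[strsplit(pattern, "")[[1]]], "")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

make_tags <- function(pos, strand, chrom = "chrT", weight = 1, ...) {
  n <- length(pos)
  tag_dataset(data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                         strand = rep_len(strand, n),
                         weight = rep_len(weight, n), stringsAsFactors = FALSE),
              ...)
}

# one shared small genome for unit tests (built once per test run)
small_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_genome(n_genes = 24, seed = 101)
    g
  }
})
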