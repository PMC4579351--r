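# Factor occupancy quantification: window sums in gene orientation,
# log2-median and percent-rank normalization, Hmo1 breadth measurement and
# classification, heat-shock fold changes, ectopic PIC fractions, and the
# factor-factor Pearson matrix.

#' Canonical occupancy window for a factor
#'
#' TSS-relative half-open windows: upstream regulators (Rap1, FIS, Hmo1)
#' -400..0; Pol II (Rpb3) 0..+400; PIC components -200..+200.
#'
#' @param factor factor name.
#' @return numeric `c(lo, hi)` in gene-orientation bp.
#' @export
occupancy_window <- function(factor) {
  if (factor %in% c("Rap1", "Fhl1", "Ifh1", "Sfp1", "Hmo1")) c(-400, 0)
  else if (factor == "Rpb3") c(0, 400)
  else c(-200, 200)
}

#' Sum tag signal in a TSS-relative window, orientation-corrected
#'
#' The window `[lo, hi)` is interpreted in gene orientation and mirrored for
#' minus-strand genes. Tag weights are summed, so background-normalized
#' datasets contribute their scaled signal.
#'
#' @param tags a shifted [tag_dataset()].
#' @param gene one row of a gene table with `tss`, `strand`, `chrom`.
#' @param window numeric `c(lo, hi)`, half-open, in gene orientation.
#' @param require_shifted refuse unshifted tags (default TRUE).
#' @return the raw occupancy (weighted tag count).
#' @export
window_sum <- function(tags, gene, window, require_shifted = TRUE) {
  stopifnot(inherits(tags, "tag_dataset"))
  if (require_shifted && !tags$shifted) stop("window_sum expects shifted tags")
  w <- rel_window_abs(gene$tss, gene$strand, window[1], window[2])
  rec <- tags$records
  sel <- rec$chrom == gene$chrom & in_window(rec$pos, w[1], w[2])
  sum(rec$weight[sel])
}

#' Build a genes x factors raw occupancy table
#'
#' @param tag_list named list of shifted [tag_dataset()]s (one per factor).
#' @param genes gene table with `gene_id`, `chrom`, `tss`, `strand`.
#' @param windows optional named list of per-factor windows; defaults to
#'   [occupancy_window()].
#' @return an `occupancy_table` with the `raw` layer filled.
#' @export
occupancy_table <- function(tag_list, genes, windows = NULL) {
  factors <- names(tag_list)
  raw <- matrix(0, nrow(genes), length(factors),
                dimnames = list(genes$gene_id, factors))
  for (f in factors) {
    win <- if (!is.null(windows) && !is.null(windows[[f]])) windows[[f]] else
      occupancy_window(f)
    for (i in seq_len(nrow(genes))) {
      raw[i, f] <- window_sum(tag_list[[f]], genes[i, ], win)
    }
  }
  structure(list(raw = raw, log2 = NULL, pct_rank = NULL), class = "occupancy_table")
}

#' Add log2-median and percent-rank layers to an occupancy table
#'
#' Per factor column: values are divided by the cohort median and log2
#' transformed; columns containing zeros get a +1 pseudocount first (recorded
#' in the `"pseudocount_cols"` attribute). Percent rank is `rank / n * 100`
#' with average ranks for ties.
#'
#' @param tab an `occupancy_table` (or bare matrix).
#' @return the table with `log2` and `pct_rank` layers.
#' @export
normalize_table <- function(tab) {
  raw <- if (inherits(tab, "occupancy_table")) tab$raw else as.matrix(tab)
  if (nrow(raw) < 2) stop("need >= 2 genes to normalize")
  if (any(apply(raw, 2, function(x) all(x == 0)))) {
    stop("all-zero occupancy column; cannot normalize")
  }
  pseudo <- apply(raw, 2, function(x) any(x == 0))
  adj <- raw
  adj[, pseudo] <- adj[, pseudo, drop = FALSE] + 1
  log2l <- apply(adj, 2, function(x) log2(x / stats::median(x)))
  pct <- apply(raw, 2, function(x) rank(x, ties.method = "average") / length(x) * 100)
  dimnames(log2l) <- dimnames(pct) <- dimnames(raw)
  out <- structure(list(raw = raw, log2 = log2l, pct_rank = pct),
                   class = "occupancy_table")
  attr(out, "pseudocount_cols") <- colnames(raw)[pseudo]
  out
}

#' Occupancy at a Rap1 site and its downstream region
#'
#' Sums factor tags in the site-proximal window (-40..+40 bp around the Rap1
#' site midpoint) and the downstream window (+60..+180 bp, toward the TSS),
#' background-normalized by the local flanking rate (tags per bp in the
#' windows from -500..-100 and +300..+500, gene-oriented) unless
#' `background = "none"`.
#'
#' @param tags a shifted [tag_dataset()].
#' @param site list/row with `mid` (site midpoint), `strand` (gene
#'   orientation toward the TSS), `chrom`.
#' @param background `"flank"` (default) or `"none"`.
#' @return named numeric `c(at_site, downstream)`.
#' @export
rap1_site_occupancy <- function(tags, site, background = c("flank", "none")) {
  background <- match.arg(background)
  sum_rel <- function(lo, hi) {
    w <- rel_window_abs(site$mid, site$strand, lo, hi)
    rec <- tags$records
    sum(rec$weight[rec$chrom == site$chrom & in_window(rec$pos, w[1], w[2])])
  }
  at_site <- sum_rel(-40, 41)       # inclusive +/-40 -> 81 bp
  downstream <- sum_rel(60, 181)    # +60..+180 inclusive -> 121 bp
  if (background == "flank") {
    bg_rate <- (sum_rel(-500, -100) + sum_rel(300, 501)) / (400 + 201)
    at_site <- at_site - bg_rate * 81
    downstream <- downstream - bg_rate * 121
  }
  c(at_site = at_site, downstream = downstream)
}

#' Measure Hmo1 binding breadth at one gene
#'
#' Breadth is the number of bp between the most upstream Rap1 site and the
#' TSS whose smoothed Hmo1 tag density exceeds the threshold rule (default:
#' 3x the genome-wide mean rate of the dataset).
#'
#' @param hmo1_tags shifted Hmo1 [tag_dataset()].
#' @param gene row with `gene_id`, `chrom`, `tss`, `strand`.
#' @param rap1_site absolute coordinate of the gene's most upstream Rap1
#'   site midpoint.
#' @param threshold density threshold; default `3 * background_rate`.
#' @param background_rate genome-wide mean tag rate (tags per bp); computed
#'   from the dataset over `genome_length` when NULL.
#' @param genome_length chromosome length for the rate computation.
#' @param sigma smoothing sd in bp (default 5).
#' @return list with `gene_id`, `breadth`, `threshold`.
#' @export
hmo1_breadth <- function(hmo1_tags, gene, rap1_site, threshold = NULL,
                         background_rate = NULL, genome_length = NULL,
                         sigma = 5) {
  if (is.na(rap1_site)) stop("gene has no Rap1 site; breadth undefined")
  if (is.null(threshold)) {
    if (is.null(background_rate)) {
      if (is.null(genome_length)) stop("need threshold, background_rate or genome_length")
      background_rate <- sum(hmo1_tags$records$weight) / genome_length
    }
    threshold <- 3 * background_rate
  }
  lo <- min(rap1_site, gene$tss); hi <- max(rap1_site, gene$tss) + 1L
  pu <- tag_pileup(hmo1_tags, gene$chrom, c(lo, hi))
  dens <- smooth_density(pu$counts_all, sigma)
  list(gene_id = gene$gene_id, breadth = sum(dens > threshold),
       threshold = threshold)
}

#' Measure breadth for a cohort and classify genes
#'
#' Default cutoffs reproduce the planted classes: breadth >= `broad_min`
#' (135) is "broad", >= `narrow_min` (50) "narrow", below that "none".
#' Alternatively `groups = "rank"` takes the top `n_broad` as broad and the
#' next `n_narrow` as narrow, as in cohort-sorted heat maps.
#'
#' @param hmo1_tags shifted Hmo1 [tag_dataset()].
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param rap1_sites named vector or column of most-upstream Rap1 site
#'   midpoints per gene (NA = not Rap1-bound, classified "unassigned").
#' @param genome_length chromosome length (for the background rate).
#' @param groups `"cutoff"` (default) or `"rank"`.
#' @param broad_min,narrow_min breadth cutoffs in bp.
#' @param n_broad,n_narrow group sizes for rank grouping.
#' @inheritParams hmo1_breadth
#' @return data.frame with `gene_id`, `breadth`, `group`.
#' @export
breadth_table <- function(hmo1_tags, genes, rap1_sites, genome_length,
                          groups = c("cutoff", "rank"), broad_min = 135,
                          narrow_min = 50, n_broad = 30, n_narrow = 30,
                          sigma = 5, threshold = NULL) {
  groups <- match.arg(groups)
  if (is.null(threshold)) {
    threshold <- 3 * sum(hmo1_tags$records$weight) / genome_length
  }
  breadth <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (is.na(rap1_sites[i])) next
    breadth[i] <- hmo1_breadth(hmo1_tags, genes[i, ], rap1_sites[i],
                               threshold = threshold, sigma = sigma)$breadth
  }
  group <- rep("unassigned", nrow(genes))
  ok <- !is.na(breadth)
  if (groups == "cutoff") {
    group[ok] <- ifelse(breadth[ok] >= broad_min, "broad",
                        ifelse(breadth[ok] >= narrow_min, "narrow", "none"))
  } else {
    o <- order(-breadth, genes$gene_id)
    o <- o[ok[o]]
    group[o[seq_len(min(n_broad, length(o)))]] <- "broad"
    if (length(o) > n_broad) {
      group[o[(n_broad + 1):min(n_broad + n_narrow, length(o))]] <- "narrow"
    }
    group[ok & group == "unassigned"] <- "none"
  }
  data.frame(gene_id = genes$gene_id, breadth = breadth, group = group,
             stringsAsFactors = FALSE)
}

#' Per-group log2 occupancy fold change between two conditions
#'
#' @param occ_mock,occ_hs named numeric vectors of raw occupancies per gene
#'   (same gene order), already background-normalized to each other.
#' @param grouping factor/character vector of group labels per gene (e.g.
#'   Hmo1 breadth quartiles).
#' @param pseudocount added where an occupancy is zero (default 1).
#' @return list: `per_gene` data.frame (`gene`, `log2_fc`, `group`) and
#'   `per_group` data.frame (`group`, `mean`, `sd`, `n`).
#' @export
heatshock_fold_change <- function(occ_mock, occ_hs, grouping,
                                  pseudocount = 1) {
  stopifnot(length(occ_mock) == length(occ_hs),
            length(grouping) == length(occ_mock))
  m <- ifelse(occ_mock == 0, occ_mock + pseudocount, occ_mock)
  h <- ifelse(occ_hs == 0, occ_hs + pseudocount, occ_hs)
  fc <- log2(h / m)
  per_gene <- data.frame(gene = names(occ_mock) %||% seq_along(occ_mock),
                         log2_fc = fc, group = grouping,
                         stringsAsFactors = FALSE)
  agg_mean <- tapply(fc, grouping, mean)
  agg_sd <- tapply(fc, grouping, stats::sd)
  agg_n <- tapply(fc, grouping, length)
  per_group <- data.frame(group = names(agg_mean), mean = as.numeric(agg_mean),
                          sd = as.numeric(agg_sd), n = as.integer(agg_n),
                          stringsAsFactors = FALSE)
  list(per_gene = per_gene, per_group = per_group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ectopic upstream PIC fraction at one gene
#'
#' Fraction of PIC signal in the ectopic upstream window (TSS-200 to
#' TSS-70) over the total window (TSS-200 to TSS+60), gene-oriented.
#'
#' @param pic_tags shifted TFIIB/Pol II [tag_dataset()] (hmo1-null data).
#' @param gene gene row (`chrom`, `tss`, `strand`).
#' @return fraction in `[0, 1]`, or NA when the total window is empty.
#' @export
ectopic_fraction <- function(pic_tags, gene) {
  total <- window_sum(pic_tags, gene, c(-200, 60))
  if (total <= 0) return(NA_real_)
  window_sum(pic_tags, gene, c(-200, -70)) / total
}

#' Factor-factor Pearson correlation matrix of an occupancy layer
#'
#' @param tab a normalized `occupancy_table`.
#' @param layer which layer to correlate (default `"log2"`).
#' @return symmetric factors x factors matrix; constant columns give NA
#'   rows/columns (with a warning).
#' @export
correlation_matrix <- function(tab, layer = c("log2", "raw", "pct_rank")) {
  layer <- match.arg(layer)
  m <- tab[[layer]]
  if (is.null(m)) stop("layer not computed; run normalize_table() first")
  if (nrow(m) < 3) stop("need >= 3 genes for correlations")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) warning("constant column(s): ",
                          paste(colnames(m)[const], collapse = ", "))
  suppressWarnings(stats::cor(m))
}
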