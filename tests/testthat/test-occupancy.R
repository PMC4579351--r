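gene_plus <- data.frame(gene_id = "g1", chrom = "chrT", tss = 1000L, strand = "+")
gene_minus <- data.frame(gene_id = "g2", chrom = "chrT", tss = 1000L, strand = "-")

test_that("window_sum counts in orientation-corrected TSS windows", {
  tags <- shift_tags(make_tags(rep(944L, 10), "+"), 6)   # lands at TSS-50
  expect_equal(window_sum(tags, gene_plus, c(-400, 0)), 10)
  expect_equal(window_sum(tags, gene_plus, c(0, 400)), 0)
  # unshifted tags refused
  expect_error(window_sum(make_tags(950L, "+"), gene_plus, c(-400, 0)), "shifted")
  # minus-strand gene: tags 50 bp left of the TSS in genome coordinates are
  # downstream in gene orientation (hand-mirrored check)
  tags2 <- shift_tags(make_tags(rep(956L, 4), "+"), 6)   # genome 962 = rel +38
  expect_equal(window_sum(tags2, gene_minus, c(0, 400)), 4)
  expect_equal(window_sum(tags2, gene_minus, c(-400, 0)), 0)
})

test_that("window_sum is conserved under whole-dataset mirroring", {
  set.seed(31)
  pos <- sample(600:1400, 200, replace = TRUE)
  tags <- shift_tags(make_tags(pos, sample(c("+", "-"), 200, TRUE)), 0)
  mirrored <- shift_tags(make_tags(2000L - pos, sample(c("+", "-"), 200, TRUE)), 0)
  w <- c(-150, 250)
  expect_equal(window_sum(tags, gene_plus, w),
               window_sum(mirrored, gene_minus, w))
})

test_that("rap1_site_occupancy sums the at-site and downstream windows", {
  site <- list(mid = 5000L, strand = "+", chrom = "chrT")
  at <- shift_tags(make_tags(rep(4994L, 8), "+"), 6)     # all at the midpoint
  r <- rap1_site_occupancy(at, site, background = "none")
  expect_equal(unname(r), c(8, 0))
  # uniform tags: sums in the 81:121 width ratio
  uni <- shift_tags(make_tags(4000:6000, "+"), 0)
  r2 <- rap1_site_occupancy(uni, site, background = "none")
  expect_equal(unname(r2["at_site"] / r2["downstream"]), 81 / 121)
  # uniform tags: flank normalization cancels both windows
  r3 <- rap1_site_occupancy(uni, site, background = "flank")
  expect_lt(abs(r3["at_site"]), 1e-9)
  # simulated Fhl1: major cross-linking 100 bp downstream of Rap1
  g <- small_genome()
  fh <- shift_tags(simulate_chipexo(g, exo_model(), condition_spec("normal"),
                                    "Fhl1", seed = 21), 6)
  a <- g$arch[1, ]
  s <- list(mid = a$rap1_up, strand = a$strand, chrom = g$chrom)
  rf <- rap1_site_occupancy(fh, s, background = "none")
  expect_gt(rf["downstream"], 3 * rf["at_site"])
})

test_that("normalize_table builds log2-median and percent-rank layers", {
  raw <- cbind(f1 = c(1, 2, 4), f2 = c(5, 5, 5))
  rownames(raw) <- paste0("g", 1:3)
  tab <- normalize_table(raw)
  expect_equal(unname(tab$log2[, "f1"]), c(-1, 0, 1))
  expect_equal(unname(tab$log2[, "f2"]), c(0, 0, 0))
  # constant column: tied percent ranks
  expect_equal(unname(tab$pct_rank[, "f2"]), rep(200 / 3, 3))
  # scale invariance of the log2 layer
  tab2 <- normalize_table(raw * 2)
  expect_equal(tab$log2, tab2$log2)
  # median of the log2 layer is 0 per factor
  expect_equal(unname(apply(tab$log2, 2, median)), c(0, 0))
  # zeros get a pseudocount, all-zero columns refuse
  withz <- cbind(f1 = c(0, 1, 3))
  expect_equal(attr(normalize_table(withz), "pseudocount_cols"), "f1")
  expect_error(normalize_table(cbind(f1 = c(0, 0, 0))), "all-zero")
  expect_error(normalize_table(raw[1, , drop = FALSE]), ">= 2")
})

test_that("percent rank is invariant under monotone transforms of raw values", {
  set.seed(33)
  raw <- cbind(f = rpois(40, 20) + 1)
  t1 <- normalize_table(raw)
  t2 <- normalize_table(raw^3)
  t3 <- normalize_table(sqrt(raw))
  expect_equal(t1$pct_rank, t2$pct_rank)
  expect_equal(t1$pct_rank, t3$pct_rank)
})

test_that("hmo1_breadth thresholds behave at the extremes", {
  g <- small_genome()
  hm <- shift_tags(simulate_chipexo(g, exo_model(), condition_spec("normal"),
                                    "Hmo1", seed = 22), 6)
  a_none <- g$arch[g$arch$class == "none", ][1, ]
  b <- hmo1_breadth(hm, a_none, a_none$rap1_up, genome_length = g$length)
  expect_lte(b$breadth, 10)
  a_broad <- g$arch[g$arch$class == "broad", ][1, ]
  # infinite threshold: breadth 0 for every gene
  expect_equal(hmo1_breadth(hm, a_broad, a_broad$rap1_up, threshold = Inf)$breadth, 0)
  expect_error(hmo1_breadth(hm, a_broad, NA), "no Rap1 site")
})

test_that("heatshock_fold_change recovers programmed losses per group", {
  set.seed(34)
  mock <- rpois(300, 100); hs <- rpois(300, 30)   # 70% loss
  names(mock) <- names(hs) <- paste0("g", 1:300)
  fc <- heatshock_fold_change(mock, hs, rep("all", 300))
  # mean per-gene log2 ratio carries a small Jensen bias at Poisson counts
  expect_lt(abs(fc$per_group$mean - log2(0.3)), 0.08)
  # identical data: all zero
  fc0 <- heatshock_fold_change(mock, mock, rep("all", 300))
  expect_true(all(fc0$per_gene$log2_fc == 0))
})

test_that("simulated heat-shock TFIIB loss grows with Hmo1 breadth quartile", {
  g <- build_genome(n_genes = 80, seed = 17)
  exo <- exo_model()
  tn <- shift_tags(simulate_chipexo(g, exo, condition_spec("normal"), "Sua7",
                                    seed = 1), 6)
  th <- shift_tags(simulate_chipexo(g, exo, condition_spec("heat_shock"), "Sua7",
                                    seed = 2), 6)
  om <- sapply(seq_len(nrow(g$arch)), function(i) window_sum(tn, g$arch[i, ], c(-200, 200)))
  oh <- sapply(seq_len(nrow(g$arch)), function(i) window_sum(th, g$arch[i, ], c(-200, 200)))
  names(om) <- names(oh) <- g$arch$gene_id
  q <- cut(rank(g$arch$breadth, ties.method = "first"), 4, labels = paste0("Q", 1:4))
  fc <- heatshock_fold_change(om, oh, q)
  means <- fc$per_group$mean[match(paste0("Q", 1:4), fc$per_group$group)]
  expect_true(all(diff(means) < 0.05))   # monotone non-increasing
  expect_lt(means[4], means[1] - 0.5)    # and materially so
})

test_that("ectopic_fraction implements the stated windows", {
  tags <- shift_tags(make_tags(rep(894L, 6), "+"), 6)    # TSS-100
  expect_equal(ectopic_fraction(tags, gene_plus), 1)
  tags0 <- shift_tags(make_tags(rep(994L, 6), "+"), 6)   # at the TSS
  expect_equal(ectopic_fraction(tags0, gene_plus), 0)
  none <- shift_tags(make_tags(5000L, "+"), 6)           # outside both windows
  expect_true(is.na(ectopic_fraction(none, gene_plus)))
})

test_that("correlation matrix reflects co-recruitment structure", {
  raw <- cbind(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = c(9, 1, 4, 8))
  tab <- normalize_table(raw)
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm, t(cm))
  # PIC subunits share a latent per-gene mean: strongly correlated; the
  # FIS group is uncorrelated with the PIC group
  g <- build_genome(n_genes = 60, seed = 23)
  exo <- exo_model(depth = 100)
  cond <- condition_spec("normal")
  tl <- lapply(c(Sua7 = "Sua7", Toa2 = "Toa2", Taf5 = "Taf5", Fhl1 = "Fhl1",
                 Ifh1 = "Ifh1"),
               function(f) shift_tags(simulate_chipexo(g, exo, cond, f,
                                                       seed = match(f, exo_factors())), 6))
  tab2 <- normalize_table(occupancy_table(tl, g$arch))
  cm2 <- correlation_matrix(tab2)
  expect_gt(cm2["Sua7", "Toa2"], 0.7)
  expect_gt(cm2["Sua7", "Taf5"], 0.7)
  expect_gt(cm2["Toa2", "Taf5"], 0.7)
  expect_gt(cm2["Fhl1", "Ifh1"], 0.7)
  # across the two co-recruitment groups: no shared latent mean
  expect_lt(abs(cm2["Sua7", "Fhl1"]), 0.45)
  expect_lt(abs(cm2["Taf5", "Ifh1"]), 0.45)
})
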