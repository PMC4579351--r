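test_that("build_genome is deterministic and validates inputs", {
  g1 <- build_genome(n_genes = 10, seed = 42)
  g2 <- build_genome(n_genes = 10, seed = 42)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$arch, g2$arch)
  expect_error(build_genome(class_proportions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(build_genome(slot = 500), "slot")
})

test_that("build_genome plants the promoter grammar", {
  g <- small_genome()
  a <- g$arch
  # Rap1 pairs: midpoint distance = motif width + spacing, spacing in 5..15
  two <- a[a$n_rap1 == 2, ]
  expect_true(all(two$rap1_spacing >= 5 & two$rap1_spacing <= 15))
  expect_true(all(abs(two$rap1_site2_rel - two$rap1_up_rel) ==
                    13 + two$rap1_spacing))
  # Fhl1 core 100 bp downstream of the most upstream Rap1 site
  expect_true(all(a$fhl1_core_rel - a$rap1_up_rel == 100))
  # breadth classes respect their ranges
  expect_true(all(a$breadth[a$class == "none"] == 0))
  expect_true(all(a$breadth[a$class == "narrow"] >= 100 &
                    a$breadth[a$class == "narrow"] <= 120))
  expect_true(all(a$breadth[a$class == "broad"] >= 150 &
                    a$breadth[a$class == "broad"] <= 170))
  # active +1 dyad geometry: TSS 15 bp inside the upstream edge
  expect_true(all(a$dyad_active_rel == 58))
  # all planted coordinates within chromosome bounds
  expect_true(all(g$rap1_sites$start >= 0 & g$rap1_sites$end <= g$length))
  expect_true(all(na.omit(c(a$zone_lo, a$zone_hi)) <= g$length))
  # both strands exercised
  expect_true(all(table(a$strand) >= 2))
  # a broad gene carries GGCAG inside its zone and the Fhl1 instance at the
  # core (sequence-level check on the emitted chromosome)
  b <- a[a$class == "broad", ][1, ]
  zone_seq <- substr(g$seq, b$zone_lo + 1, b$zone_hi)
  if (b$strand == "-") {
    zone_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(zone_seq)))
  }
  expect_true(grepl("GGC.G", zone_seq))
  gc <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_gt(gc(zone_seq), 0.5)
})

test_that("simulate_chipexo is deterministic and validates the factor", {
  g <- small_genome()
  exo <- exo_model()
  cond <- condition_spec("normal")
  t1 <- simulate_chipexo(g, exo, cond, "Rap1", seed = 9)
  t2 <- simulate_chipexo(g, exo, cond, "Rap1", seed = 9)
  expect_identical(t1$records, t2$records)
  expect_error(simulate_chipexo(g, exo, cond, "Nop1", seed = 1), "unknown factor")
})

test_that("noiseless exo model puts stop sites exactly headroom from the point", {
  g <- small_genome()
  exo <- exo_model(stop_jitter_sd = 0, background_rate = 0, depth = 40)
  cond <- condition_spec("normal")
  tags <- simulate_chipexo(g, exo, cond, "Sua7", seed = 3)
  truth <- attr(tags, "crosslink_points")
  rec <- tags$records
  for (i in seq_len(nrow(truth))) {
    x <- truth$pos[i]
    near <- rec[abs(rec$pos - x) <= 10, ]
    expect_true(all(near$pos[near$strand == "+"] == x - 6))
    expect_true(all(near$pos[near$strand == "-"] == x + 6))
  }
  # strand symmetry: forward/reverse modes differ by exactly 2 * headroom
  md <- function(v) as.integer(names(which.max(table(v))))
  one <- rec[abs(rec$pos - truth$pos[1]) <= 10, ]
  expect_equal(md(one$pos[one$strand == "-"]) - md(one$pos[one$strand == "+"]), 12L)
})

test_that("heat shock removes ~70% of Hmo1 cross-linking", {
  g <- build_genome(n_genes = 60, seed = 13)
  exo <- exo_model(background_rate = 0)
  tn <- simulate_chipexo(g, exo, condition_spec("normal"), "Hmo1", seed = 1)
  th <- simulate_chipexo(g, exo, condition_spec("heat_shock"), "Hmo1", seed = 2)
  ratio <- nrow(th$records) / nrow(tn$records)
  # expected 0.30; allow ~4 sigma of Poisson error at these totals
  se <- sqrt(1 / nrow(th$records) + 1 / nrow(tn$records)) * ratio
  expect_lt(abs(ratio - 0.30), 4 * se + 0.01)
})

test_that("ground truth provenance is retained on simulated datasets", {
  g <- small_genome()
  tags <- simulate_chipexo(g, exo_model(), condition_spec("normal"), "Rap1",
                           seed = 4)
  truth <- attr(tags, "crosslink_points")
  expect_true(all(c("gene_id", "pos", "eff", "expected") %in% names(truth)))
  expect_equal(sort(unique(truth$gene_id)), sort(g$arch$gene_id))
  frags <- simulate_mnase(g, condition_spec("normal"), seed = 5)
  expect_equal(attr(frags, "dyads")$gene_id, g$arch$gene_id)
})

test_that("simulate_mnase emits dyad-centered fragments of ~147 bp", {
  g <- small_genome()
  frags <- simulate_mnase(g, condition_spec("normal"), seed = 6)
  len <- frags$end - frags$start
  expect_lt(abs(mean(len) - 147), 1.5)
  expect_identical(simulate_mnase(g, condition_spec("normal"), seed = 6), frags)
  # histone mode: NFR (Rap1 site to TSS-100) essentially free of midpoints
  mids <- frags$start + (len - 1) %/% 2
  nfr_hits <- 0; nfr_bp <- 0
  for (i in seq_len(nrow(g$arch))) {
    a <- g$arch[i, ]
    w <- rel_window_abs(a$tss, a$strand, a$rap1_up_rel + 20, -100)
    nfr_hits <- nfr_hits + sum(mids >= w[1] & mids < w[2])
    nfr_bp <- nfr_bp + diff(w)
  }
  # at background 1e-4/bp over ~4.3 kb of NFR, expect << 5 midpoints
  expect_lt(nfr_hits, 5)
})

test_that("non-histone MNase protection covers Hmo1 zones", {
  g <- small_genome()
  bg_rate <- 1e-4; protect_rate <- 0.2
  frags <- simulate_mnase(g, condition_spec("normal"), protect_nonhistone = TRUE,
                          seed = 7, background_rate = bg_rate,
                          protect_rate = protect_rate)
  mids <- frags$start + (frags$end - frags$start - 1) %/% 2
  hm <- g$arch[g$arch$class != "none", ]
  zone_hits <- sum(vapply(seq_len(nrow(hm)), function(i)
    sum(mids >= hm$zone_lo[i] & mids < hm$zone_hi[i]), 0))
  zone_bp <- sum(hm$zone_hi - hm$zone_lo)
  # flanking background: a window 600..300 bp upstream of each zone
  fl_hits <- sum(vapply(seq_len(nrow(hm)), function(i)
    sum(mids >= hm$zone_lo[i] - 600 & mids < hm$zone_lo[i] - 300), 0))
  fl_bp <- 300 * nrow(hm)
  # derived from generator settings: density ratio ~ protect_rate / bg_rate
  # (>> 5); assert the stated 5x enrichment with the flank floor guarded
  expect_gt((zone_hits / zone_bp) / max(fl_hits / fl_bp, bg_rate), 5)
})
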