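test_that("scan_iupac honors degeneracy codes and strands", {
  expect_equal(scan_iupac("TTGGCAGTT", "GGCNG", both_strands = FALSE)$start, 2L)
  expect_equal(nrow(scan_iupac("TTGGATGTT", "GGCNG", both_strands = FALSE)), 0L)
  # a planted YKYGCGTC instance matches (verified against the exhaustive
  # expansion of the code)
  expect_true("TGTGCGTC" %in% iupac_expand("YKYGCGTC"))
  expect_equal(scan_iupac("AATGTGCGTCAA", "YKYGCGTC", both_strands = FALSE)$start, 2L)
  # every expansion matches; a non-member does not
  for (s in iupac_expand("GGCNG")) {
    expect_equal(nrow(scan_iupac(s, "GGCNG", both_strands = FALSE)), 1L)
  }
  expect_error(scan_iupac("ACGT", "GGX"), "IUPAC")
})

test_that("scan_iupac strand symmetry: reverse complement mirrors coordinates", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  m1 <- scan_iupac(s, "GGCNG")
  m2 <- scan_iupac(rc, "GGCNG")
  key <- function(start, end, strand) sort(paste(start, end, strand))
  flip <- c("+" = "-", "-" = "+")
  expect_equal(key(m2$start, m2$end, m2$strand),
               key(300 - m1$end, 300 - m1$start, flip[m1$strand]))
})

test_that("find_polyA reports maximal A/T runs of the minimum length", {
  expect_equal(find_polyA("CCAAAAAACC")$start, 2L)
  expect_equal(find_polyA("CCAAAAAACC")$length, 6L)
  expect_equal(nrow(find_polyA("AAAAA")), 0L)      # 5-mer below threshold
  expect_equal(nrow(find_polyA("AAATTT")), 0L)     # two maximal 3-runs
  expect_equal(find_polyA("TTTTTTTG")$base, "T")
  # regex oracle on random sequences
  set.seed(6)
  for (i in 1:20) {
    s <- paste(sample(c("A", "T", "G"), 200, replace = TRUE, prob = c(.4, .4, .2)),
               collapse = "")
    got <- find_polyA(s)
    want <- integer(0)
    for (base in c("A", "T")) {
      m <- gregexpr(paste0(base, "{6,}"), s)[[1]]
      if (m[1] != -1) want <- c(want, as.integer(m) - 1L)
    }
    expect_equal(sort(got$start), sort(want))
  }
})

test_that("scan_pwm scores against background with exact DP p-values", {
  bases <- c("A", "C", "G", "T")
  pwm <- matrix(0.04, 4, 5, dimnames = list(bases, NULL))
  cons <- c("G", "G", "C", "A", "G")
  for (j in 1:5) pwm[cons[j], j] <- 0.88
  bg <- rep(0.25, 4)
  hits <- scan_pwm("TTTTGGCAGTTTT", pwm, bg, p_threshold = 0.01,
                   both_strands = FALSE)
  expect_equal(hits$start, 4L)
  # consensus window attains the matrix's minimum possible p-value
  all_p <- scan_pwm("GGCAG", pwm, bg, p_threshold = 1, both_strands = FALSE)
  expect_equal(hits$p_value, min(all_p$p_value))
  # uniform pwm equal to background: all scores 0, p-value 1
  u <- matrix(0.25, 4, 4, dimnames = list(bases, NULL))
  res <- scan_pwm("ACGTACGT", u, bg, p_threshold = 1, both_strands = FALSE,
                  pseudocount = 0)
  expect_true(all(abs(res$llr_score) < 1e-12))
  expect_true(all(res$p_value == 1))
  # reverse-strand hit found at mirrored coordinates
  rc_hits <- scan_pwm("TTTTCTGCCTTTT", pwm, bg, p_threshold = 0.01)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 4L)
})

test_that("PWM p-values are monotone non-increasing in score", {
  set.seed(8)
  pwm <- matrix(rgamma(4 * 6, 1), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  m <- scan_pwm(s, pwm, rep(0.25, 4), p_threshold = 1, both_strands = FALSE)
  o <- order(m$llr_score)
  expect_true(all(diff(m$p_value[o]) <= 1e-12))
})

test_that("retain_near_peaks keeps matches within the radius, set semantics", {
  m <- data.frame(motif = "x", midpoint = c(100, 141, 60))
  peaks <- c(60, 140)
  kept <- retain_near_peaks(m, peaks, radius = 40)
  # 100 is exactly 40 from both peaks: kept once; 141 is 1 bp inside of 140
  expect_equal(sort(kept$midpoint), c(60, 100, 141))
  expect_equal(nrow(retain_near_peaks(data.frame(midpoint = 181), peaks, 40)), 0L)
  expect_equal(nrow(retain_near_peaks(m, numeric(0), 40)), 0L)
})

test_that("assign_to_tss picks the nearest TSS under the strict cutoff", {
  tss <- data.frame(gene_id = c("g1", "g2"), tss = c(1000L, 2000L),
                    strand = c("+", "-"))
  a <- assign_to_tss(data.frame(midpoint = 880), tss)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance_to_tss, -120)   # upstream of a + gene
  # minus-strand gene: site at 2100 is upstream (gene orientation)
  b <- assign_to_tss(data.frame(midpoint = 2100), tss)
  expect_equal(b$gene_id, "g2")
  expect_equal(b$distance_to_tss, -100)
  # exactly max_dist away -> unassigned (strict <)
  expect_equal(nrow(assign_to_tss(data.frame(midpoint = 500), tss)), 0L)
  # between two TSSs: the closer one wins
  expect_equal(assign_to_tss(data.frame(midpoint = 1850), tss)$gene_id, "g2")
})

test_that("MEME minimal format round trips", {
  pwm <- matrix(c(.7, .1, .1, .1, .25, .25, .25, .25), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(list(rap1 = pwm, other = pwm[, 1, drop = FALSE]), path)
  got <- read_meme_motifs(path)
  expect_named(got, c("rap1", "other"))
  expect_equal(got$rap1, pwm, tolerance = 1e-5)
})

test_that("every planted motif instance is recovered at its coordinate", {
  g <- small_genome()
  # Rap1 consensus: exact planting, one hit per planted site
  rap1 <- scan_iupac(g$seq, "ACACCCATACATT")
  expect_true(all(g$rap1_sites$start %in% rap1$start[rap1$strand == "+"] |
                    g$rap1_sites$start %in% rap1$start[rap1$strand == "-"]))
  fhl1 <- scan_iupac(g$seq, "YKYGCGTC")
  expect_true(all(g$fhl1_sites$start %in% fhl1$start))
  ifhl <- scan_iupac(g$seq, "GGCNG")
  expect_true(all(g$ifhl_sites$start %in% ifhl$start))
  pa <- find_polyA(g$seq)
  # planted 8-bp tracts may extend by chance neighbors: containment check
  covered <- vapply(seq_len(nrow(g$polyA_sites)), function(i) {
    any(pa$start <= g$polyA_sites$start[i] & pa$end >= g$polyA_sites$end[i])
  }, TRUE)
  expect_true(all(covered))
})
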