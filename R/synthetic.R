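# Synthetic RPG promoter world: one artificial chromosome of regularly
# spaced promoters with planted Rap1 sites, a poly(dA:dT) tract, an Fhl1
# core motif, an optional G+C-rich Hmo1 zone carrying IFHL (GGCNG) sites,
# positioned nucleosomes, and per-factor ChIP-exo cross-link points. Ground
# truth is retained on every emitted object so recovery tests can compare
# estimates against the planted values.

RAP1_CONSENSUS <- "ACACCCATACATT"   # planted Rap1 site, 13 bp
FHL1_CONSENSUS <- "YKYGCGTC"        # degenerate Fhl1 motif
FHL1_PLANT <- "TGTGCGTC"            # concrete instance planted at the core
IFHL_CONSENSUS <- "GGCNG"
IFHL_PLANT <- "GGCAG"
POLYA_PLANT <- "AAAAAAAA"           # 8-bp tract in the Rap1-Fhl1 gap

#' The simulated factor panel
#' @return character vector of factor names the generator knows.
#' @export
exo_factors <- function() {
  c("Rap1", "Fhl1", "Ifh1", "Sfp1", "Hmo1", "Sua7", "Toa2",
    "Taf2", "Taf5", "Taf10", "Rpb3", "H4")
}

FIS_FACTORS <- c("Fhl1", "Ifh1", "Sfp1")
PIC_FACTORS <- c("Sua7", "Toa2", "Taf2", "Taf5", "Taf10")
# relative cross-linking efficiencies of FIS subunits (Fhl1 strongest;
# Ifh1 4.6-fold and Sfp1 24-fold lower)
FIS_EFF <- c(Fhl1 = 1, Ifh1 = 1 / 4.6, Sfp1 = 1 / 24)

#' Exonuclease stop-site model parameters
#'
#' @param headroom bp between the cross-link point and the exonuclease stop
#'   site on each strand (default 6); forward-strand stops sit `headroom` bp
#'   left of the cross-link, reverse-strand stops `headroom` bp right.
#' @param stop_jitter_sd sd (bp) of the discretized Gaussian stop-site
#'   jitter.
#' @param piggyback_fraction fraction of a FIS factor's per-point intensity
#'   re-emitted at Rap1-site cross-link points (indirect cross-linking
#'   through Rap1).
#' @param background_rate expected background tags per bp (both strands
#'   together).
#' @param depth expected tags per cross-link point at unit efficiency.
#' @return an `exo_model` list.
#' @export
exo_model <- function(headroom = 6L, stop_jitter_sd = 2, piggyback_fraction = 0.15,
                      background_rate = 0.005, depth = 50) {
  stopifnot(headroom >= 0, depth > 0, background_rate >= 0,
            piggyback_fraction >= 0, piggyback_fraction <= 1)
  structure(list(headroom = as.integer(headroom), stop_jitter_sd = stop_jitter_sd,
                 piggyback_fraction = piggyback_fraction,
                 background_rate = background_rate, depth = depth),
            class = "exo_model")
}

#' Condition specifications for the simulator
#'
#' Encodes the three simulated states. Heat shock dissociates ~70% of Hmo1
#' and most of Ifh1/Sfp1 and the PIC while Rap1 and Fhl1 stay; the hmo1-null
#' state removes Hmo1, constricts Fhl1 to its ~80-bp core, relocates ~23% of
#' TFIIB/Pol II to an ectopic upstream window and shifts the remainder 15 bp
#' upstream, and uses the repressed +1 dyad geometry at Hmo1-bound genes.
#'
#' @param name one of `"normal"`, `"heat_shock"`, `"hmo1_null"`.
#' @return a `condition_spec` list with `factor_retention`,
#'   `fhl1_breadth_override`, `pic_ectopic_fraction`, `pic_shift`,
#'   `dyad_choice`.
#' @export
condition_spec <- function(name = c("normal", "heat_shock", "hmo1_null")) {
  name <- match.arg(name)
  spec <- switch(name,
    normal = list(
      factor_retention = list(),           # everything at 1
      fhl1_breadth_override = NULL, pic_ectopic_fraction = 0,
      pic_shift = 0L, dyad_choice = "active"),
    heat_shock = list(
      factor_retention = list(Hmo1 = 0.3, Ifh1 = 0.2, Sfp1 = 0.2,
                              Rap1 = 1, Fhl1 = 1, H4 = 1),
      fhl1_breadth_override = NULL, pic_ectopic_fraction = 0,
      pic_shift = 0L, dyad_choice = "heat_shock"),
    hmo1_null = list(
      factor_retention = list(Hmo1 = 0),
      fhl1_breadth_override = 80, pic_ectopic_fraction = 0.23,
      pic_shift = 15L, dyad_choice = "repressed"))
  structure(c(list(name = name), spec), class = "condition_spec")
}

retention_of <- function(cond, factor) {
  r <- cond$factor_retention[[factor]]
  if (is.null(r)) 1 else r
}

# Heat-shock PIC/Pol II retention is breadth-dependent so that broader
# Hmo1/Fhl1 architectures repress more (larger TFIIB loss).
hs_pic_retention <- function(breadth) 0.5 * 2^(-breadth / 80)

# +1 dyad offset from the TSS in gene orientation under a given condition.
# Active geometry puts the TSS 15 bp inside the upstream nucleosome edge
# (dyad = TSS + 58); the repressed geometry is 20 bp further upstream; heat
# shock additionally retracts by the Hmo1-beyond-Fhl1 extension at
# Hmo1-bound genes.
resolve_dyad_rel <- function(class, hs_ext, cond_name) {
  active <- 58L
  switch(cond_name,
    normal = active,
    hmo1_null = if (class == "none") active else active - 20L,
    heat_shock = if (class == "none") active - 20L else active - 20L - as.integer(hs_ext))
}

revcomp_chars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

#' Build a synthetic genome and promoter architectures
#'
#' Lays out `n_genes` promoters on one chromosome, 2 kb apart, ~half on the
#' minus strand, with planted sequence elements per promoter: 1-2 Rap1
#' consensus sites (pairs 5-15 bp apart), a >=6-bp poly(dA:dT) tract between
#' Rap1 and the Fhl1 core, an Fhl1 consensus at the core (~100 bp downstream
#' of the most upstream Rap1 site), and — at Hmo1-class genes — a G+C-rich
#' zone starting ~90 bp downstream of Rap1 whose breadth is ~110 bp (narrow)
#' or ~160 bp (broad), tiled with IFHL (GGCNG) instances every 26 bp. Also
#' draws per-gene latent activity scalars shared within the Rap1/FIS/Hmo1
#' group, the PIC group, and Pol II, which scale simulated tag intensities.
#'
#' @param n_genes number of promoters (default 120).
#' @param class_proportions named or ordered fractions for the
#'   none/narrow/broad Hmo1 classes; default 58/30/30 normalized.
#' @param seed integer seed; runs are byte-identical under a fixed seed.
#' @param gc background G+C fraction (default 0.38, yeast-like).
#' @param two_site_prob probability a promoter carries a Rap1 site pair
#'   (default 107/127).
#' @param slot bp of chromosome allotted per promoter (default 2000).
#' @param activity_sdlog sdlog of the log-normal latent activity scalars.
#' @return a `synthetic_genome` list: `seq` (character), `chrom`, `arch`
#'   (one row per gene), `rap1_sites`, `fhl1_sites`, `ifhl_sites`,
#'   `polyA_sites` (planted-element tables, absolute 0-based coordinates).
#' @export
build_genome <- function(n_genes = 120L,
                         class_proportions = c(none = 58, narrow = 30, broad = 30) / 118,
                         seed = 1L, gc = 0.38, two_site_prob = 107 / 127,
                         slot = 2000L, activity_sdlog = 0.35) {
  stopifnot(n_genes >= 1)
  if (abs(sum(class_proportions) - 1) > 1e-6) {
    stop("class proportions must sum to 1")
  }
  if (slot < 1200L) stop("promoter slot too small for the fixed layout")
  set.seed(as.integer(seed))
  chrom <- "chrS"
  glen <- 2000L + n_genes * slot
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE, prob = base_probs)

  classes <- sample(c("none", "narrow", "broad"), n_genes, replace = TRUE,
                    prob = class_proportions)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  arch <- data.frame(
    gene_id = sprintf("RPG%03d", seq_len(n_genes)), chrom = chrom,
    strand = strands, class = classes, stringsAsFactors = FALSE)
  arch$breadth <- ifelse(classes == "none", 0L,
                         ifelse(classes == "narrow",
                                sample(100:120, n_genes, replace = TRUE),
                                sample(150:170, n_genes, replace = TRUE)))
  base0 <- 1000L + (seq_len(n_genes) - 1L) * slot
  arch$tss <- ifelse(strands == "+", base0 + 700L, base0 + 1300L)
  arch$n_rap1 <- 1L + stats::rbinom(n_genes, 1L, two_site_prob)
  arch$rap1_spacing <- ifelse(arch$n_rap1 == 2L, sample(5:15, n_genes, replace = TRUE), NA)
  arch$rap1_up_rel <- sample(-320:-280, n_genes, replace = TRUE)
  arch$rap1_site2_rel <- ifelse(arch$n_rap1 == 2L,
                                arch$rap1_up_rel + nchar(RAP1_CONSENSUS) + arch$rap1_spacing,
                                NA)
  arch$fhl1_core_rel <- arch$rap1_up_rel + 100L
  arch$zone_lo_rel <- ifelse(classes == "none", NA, arch$rap1_up_rel + 90L)
  arch$zone_hi_rel <- ifelse(classes == "none", NA, arch$zone_lo_rel + arch$breadth)
  arch$pic_rel <- -20L
  arch$dyad_active_rel <- 58L
  arch$hs_ext <- ifelse(classes == "none", 0L,
                        pmax(20L, pmin(50L, as.integer(round(0.6 * (arch$breadth - 80))))))
  arch$act_fis <- stats::rlnorm(n_genes, 0, activity_sdlog)
  arch$act_pic <- stats::rlnorm(n_genes, 0, activity_sdlog)
  arch$act_pol <- stats::rlnorm(n_genes, 0, activity_sdlog)
  pair_of <- seq_len(n_genes) + c(1L, -1L)   # consecutive genes are paralogs
  arch$paralog_id <- ifelse(pair_of <= n_genes, sprintf("RPG%03d", pair_of), NA)
  # absolute anchors
  arch$rap1_up <- rel_to_abs(arch$tss, arch$strand, arch$rap1_up_rel)
  arch$fhl1_core <- rel_to_abs(arch$tss, arch$strand, arch$fhl1_core_rel)
  arch$pic <- rel_to_abs(arch$tss, arch$strand, arch$pic_rel)
  arch$dyad_active <- rel_to_abs(arch$tss, arch$strand, arch$dyad_active_rel)
  zone_abs <- t(vapply(seq_len(n_genes), function(i) {
    if (classes[i] == "none") return(c(NA_integer_, NA_integer_))
    rel_window_abs(arch$tss[i], strands[i], arch$zone_lo_rel[i], arch$zone_hi_rel[i])
  }, integer(2)))
  arch$zone_lo <- zone_abs[, 1]; arch$zone_hi <- zone_abs[, 2]

  # --- plant sequence elements -------------------------------------------
  plant_rel <- function(tss, strand, rel_lo, motif) {
    w <- nchar(motif)
    chars <- strsplit(motif, "")[[1]]
    if (strand == "+") {
      lo <- tss + rel_lo
    } else {
      lo <- tss - (rel_lo + w) + 1L
      chars <- revcomp_chars(chars)
    }
    seq_chars[(lo + 1L):(lo + w)] <<- chars
    lo
  }
  rap1_sites <- list(); fhl1_sites <- list(); ifhl_sites <- list(); polya_sites <- list()
  gc_zone_probs <- c(0.175, 0.325, 0.325, 0.175)
  w_r <- nchar(RAP1_CONSENSUS)
  for (i in seq_len(n_genes)) {
    tss <- arch$tss[i]; strand <- arch$strand[i]
    mids_rel <- c(arch$rap1_up_rel[i],
                  if (arch$n_rap1[i] == 2L) arch$rap1_site2_rel[i])
    for (k in seq_along(mids_rel)) {
      lo <- plant_rel(tss, strand, mids_rel[k] - 6L, RAP1_CONSENSUS)
      rap1_sites[[length(rap1_sites) + 1L]] <- data.frame(
        gene_id = arch$gene_id[i], site_idx = k,
        mid = rel_to_abs(tss, strand, mids_rel[k]), mid_rel = mids_rel[k],
        start = lo, end = lo + w_r, strand = strand, stringsAsFactors = FALSE)
    }
    lo <- plant_rel(tss, strand, arch$rap1_up_rel[i] + 45L, POLYA_PLANT)
    polya_sites[[i]] <- data.frame(gene_id = arch$gene_id[i], start = lo,
                                   end = lo + nchar(POLYA_PLANT),
                                   stringsAsFactors = FALSE)
    fhl1_rel <- arch$fhl1_core_rel[i] - 4L       # the Fhl1 core sits inside
    w_f <- nchar(FHL1_PLANT)                     # the zone; plant it last
    if (arch$class[i] != "none") {
      # G+C-elevated zone mirroring the breadth of Hmo1 binding
      zl <- arch$zone_lo[i]; zh <- arch$zone_hi[i]
      seq_chars[(zl + 1L):zh] <- sample(c("A", "C", "G", "T"), zh - zl,
                                        replace = TRUE, prob = gc_zone_probs)
      w_i <- nchar(IFHL_PLANT)
      for (srel in seq(arch$zone_lo_rel[i] + 3L,
                       arch$zone_hi_rel[i] - w_i - 2L, by = 26L)) {
        if (srel < fhl1_rel + w_f && srel + w_i > fhl1_rel) next  # keep the core
        lo <- plant_rel(tss, strand, srel, IFHL_PLANT)
        ifhl_sites[[length(ifhl_sites) + 1L]] <- data.frame(
          gene_id = arch$gene_id[i], start = lo, end = lo + w_i,
          stringsAsFactors = FALSE)
      }
    }
    lo <- plant_rel(tss, strand, fhl1_rel, FHL1_PLANT)
    fhl1_sites[[i]] <- data.frame(gene_id = arch$gene_id[i], start = lo,
                                  end = lo + w_f, stringsAsFactors = FALSE)
  }
  structure(list(
    seq = paste(seq_chars, collapse = ""), chrom = chrom, length = glen,
    arch = arch,
    rap1_sites = do.call(rbind, rap1_sites),
    fhl1_sites = do.call(rbind, fhl1_sites),
    ifhl_sites = if (length(ifhl_sites)) do.call(rbind, ifhl_sites) else NULL,
    polyA_sites = do.call(rbind, polya_sites),
    params = list(n_genes = n_genes, class_proportions = class_proportions,
                  seed = seed, gc = gc, slot = slot,
                  activity_sdlog = activity_sdlog)),
    class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d bp, %d promoters (%s)\n", x$chrom,
              x$length, nrow(x$arch),
              paste(names(table(x$arch$class)), table(x$arch$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cross-link points of one factor at one promoter
#'
#' The deterministic part of the exo simulation: where a factor cross-links
#' and how efficiently, given the promoter architecture and condition.
#' Hmo1 points tile its zone every 13 bp (two molecules per ~26-bp unit);
#' FIS factors occupy a fixed ~80-bp core around the Fhl1 core plus, at
#' Hmo1-bound genes, a downstream extension stopping 20-30 bp short of the
#' Hmo1 border; FIS factors also piggyback at Rap1 points.
#'
#' @param genome a [build_genome()] result.
#' @param gene_idx row index into `genome$arch`.
#' @param factor factor name from [exo_factors()].
#' @param cond a [condition_spec()].
#' @param exo an [exo_model()].
#' @return data.frame with `rel` (gene-orientation offset from the TSS),
#'   `pos` (absolute), `eff` (relative efficiency), `ectopic_ok` (logical:
#'   point eligible for the hmo1-null ectopic split).
#' @export
crosslink_points <- function(genome, gene_idx, factor, cond, exo = exo_model()) {
  a <- genome$arch[gene_idx, ]
  if (!factor %in% exo_factors()) stop("unknown factor: ", factor)
  rel <- numeric(0); eff <- numeric(0); ect <- logical(0)
  add <- function(r, e, ok = FALSE) {
    rel <<- c(rel, r); eff <<- c(eff, rep_len(e, length(r)))
    ect <<- c(ect, rep_len(ok, length(r)))
  }
  rap1_rels <- c(a$rap1_up_rel, if (!is.na(a$rap1_site2_rel)) a$rap1_site2_rel)
  core <- a$fhl1_core_rel
  if (factor == "Rap1") {
    add(rap1_rels, 1)
  } else if (factor %in% FIS_FACTORS) {
    b <- FIS_EFF[[factor]]
    add(seq(core - 39L, core + 39L, by = 13L), b)
    if (a$class != "none" && is.null(cond$fhl1_breadth_override)) {
      ext_end <- a$zone_hi_rel - 25L
      if (ext_end >= core + 52L) add(seq(core + 52L, ext_end, by = 13L), 0.5 * b)
    }
    add(rap1_rels, exo$piggyback_fraction * b)
  } else if (factor == "Hmo1") {
    if (a$class != "none") add(seq(a$zone_lo_rel + 7L, a$zone_hi_rel - 7L, by = 13L), 1)
  } else if (factor == "Sua7") {
    add(a$pic_rel, 1, ok = TRUE)
  } else if (factor == "Toa2") {
    add(a$pic_rel - 5L, 1)
  } else if (factor == "Taf2") {
    add(33L, 1)
  } else if (factor == "Taf5") {
    add(-10L, 1)
  } else if (factor == "Taf10") {
    add(-42L, 1)
  } else if (factor == "Rpb3") {
    add(a$pic_rel + 10L, 1, ok = TRUE); add(c(100L, 250L), 0.6)
  } else if (factor == "H4") {
    d1 <- resolve_dyad_rel(a$class, a$hs_ext, cond$name)
    add(d1 + c(-30L, 30L), 1)
    add(a$rap1_up_rel - 150L + c(-30L, 30L), 0.7)
    add(d1 + 165L + c(-30L, 30L), 0.9)
  }
  # hmo1-null PIC relocation at Hmo1-bound genes
  if (cond$name == "hmo1_null" && a$class != "none" &&
      factor %in% c("Sua7", "Rpb3")) {
    rel[ect] <- rel[ect] - cond$pic_shift
  } else {
    ect[] <- FALSE
  }
  if (!length(rel)) {
    return(data.frame(rel = numeric(), pos = numeric(), eff = numeric(),
                      ectopic_ok = logical()))
  }
  data.frame(rel = rel, pos = rel_to_abs(a$tss, a$strand, rel), eff = eff,
             ectopic_ok = ect)
}

factor_activity <- function(a, factor) {
  if (factor %in% c("Rap1", FIS_FACTORS, "Hmo1")) a$act_fis
  else if (factor %in% PIC_FACTORS) a$act_pic
  else if (factor == "Rpb3") a$act_pol
  else 1
}

#' Simulate ChIP-exo stop-site tags for one factor under one condition
#'
#' For each cross-link point at efficiency `e`, the tag count is
#' `Poisson(depth * e * retention * activity)`; each tag lands with equal
#' probability on either strand, its 5' end at `x - headroom` (forward) or
#' `x + headroom` (reverse) plus integer-rounded Gaussian jitter. Uniform
#' background tags are added at `background_rate` per bp. Under hmo1_null,
#' `pic_ectopic_fraction` of TFIIB/Pol II core-point tags are instead drawn
#' uniformly from the (TSS-200, TSS-70) window and the rest emitted at the
#' 15-bp-upstream-shifted core point; under heat shock PIC retention decays
#' with Hmo1 breadth.
#'
#' @inheritParams crosslink_points
#' @param seed integer seed (deterministic, byte-identical reruns).
#' @return an unshifted [tag_dataset()]; the `"crosslink_points"` attribute
#'   retains the ground-truth point table (gene_id, pos, expected tags).
#' @export
simulate_chipexo <- function(genome, exo, cond, factor, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(exo, "exo_model"),
            inherits(cond, "condition_spec"))
  if (!factor %in% exo_factors()) stop("unknown factor: ", factor)
  set.seed(as.integer(seed))
  arch <- genome$arch
  pos_out <- integer(0); strand_out <- character(0)
  truth <- list()
  emit <- function(x, n) {
    # stop-site emission around cross-link coordinates x (one per tag)
    if (!n) return()
    fwd <- stats::runif(n) < 0.5
    jit <- as.integer(round(stats::rnorm(n, 0, exo$stop_jitter_sd)))
    p <- ifelse(fwd, x - exo$headroom, x + exo$headroom) + jit
    keep <- p >= 0L & p < genome$length
    pos_out <<- c(pos_out, as.integer(p[keep]))
    strand_out <<- c(strand_out, ifelse(fwd[keep], "+", "-"))
  }
  for (i in seq_len(nrow(arch))) {
    a <- arch[i, ]
    pts <- crosslink_points(genome, i, factor, cond, exo)
    if (!nrow(pts)) next
    ret <- retention_of(cond, factor)
    if (cond$name == "heat_shock" && factor %in% c(PIC_FACTORS, "Rpb3")) {
      ret <- hs_pic_retention(a$breadth)
    }
    lambda <- exo$depth * pts$eff * ret * factor_activity(a, factor)
    f_ect <- if (any(pts$ectopic_ok)) cond$pic_ectopic_fraction else 0
    for (j in seq_len(nrow(pts))) {
      lj <- lambda[j]
      if (pts$ectopic_ok[j] && f_ect > 0) {
        n_main <- stats::rpois(1, lj * (1 - f_ect))
        n_ect <- stats::rpois(1, lj * f_ect)
        emit(rep.int(pts$pos[j], n_main), n_main)
        if (n_ect) {
          rel_e <- sample(-200L:-71L, n_ect, replace = TRUE)
          emit(rel_to_abs(a$tss, a$strand, rel_e), n_ect)
        }
      } else {
        n <- stats::rpois(1, lj)
        emit(rep.int(pts$pos[j], n), n)
      }
    }
    truth[[i]] <- cbind(gene_id = a$gene_id, pts,
                        expected = lambda, stringsAsFactors = FALSE)
  }
  n_bg <- stats::rpois(1, genome$length * exo$background_rate)
  if (n_bg) {
    pos_out <- c(pos_out, sample.int(genome$length, n_bg, replace = TRUE) - 1L)
    strand_out <- c(strand_out, sample(c("+", "-"), n_bg, replace = TRUE))
  }
  out <- tag_dataset(
    data.frame(chrom = genome$chrom, pos = pos_out, strand = strand_out,
               stringsAsFactors = FALSE),
    factor = factor, condition = cond$name, shifted = FALSE)
  attr(out, "crosslink_points") <- do.call(rbind, truth)
  attr(out, "n_background") <- n_bg
  out
}

#' Simulate MNase-protected fragments
#'
#' Emits ~147-bp fragments centered on nucleosome dyads (+1 under the
#' condition's geometry, a -1 nucleosome upstream of Rap1, and a +2). With
#' `protect_nonhistone`, additional nucleosome-sized fragments are emitted
#' across the FIS/Hmo1 zone — MNase resistance without histone ChIP tracks
#' FIS/Hmo1, not nucleosomes; histone-ChIP mode (`protect_nonhistone =
#' FALSE`) emits dyad-centered fragments only.
#'
#' @inheritParams simulate_chipexo
#' @param protect_nonhistone emit non-histone protection over Hmo1 zones.
#' @param frag_depth expected fragments per +1 dyad.
#' @param len_mean,len_sd fragment length distribution (bp).
#' @param pos_sd sd of fragment-center placement around the dyad (bp).
#' @param background_rate expected background fragments per bp.
#' @param protect_rate expected non-histone fragments per zone bp.
#' @return data.frame with `chrom`, `start`, `end`; the `"dyads"` attribute
#'   carries the true per-gene dyad coordinates.
#' @export
simulate_mnase <- function(genome, cond, protect_nonhistone = FALSE, seed = 1L,
                           frag_depth = 200, len_mean = 147, len_sd = 10,
                           pos_sd = 10, background_rate = 1e-4,
                           protect_rate = 0.2) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(cond, "condition_spec"))
  set.seed(as.integer(seed))
  arch <- genome$arch
  centers <- integer(0)
  emit_at <- function(c0, n, jitter = TRUE) {
    if (!n) return()
    cc <- if (jitter) c0 + as.integer(round(stats::rnorm(n, 0, pos_sd))) else c0
    centers <<- c(centers, cc)
  }
  dyads <- data.frame(gene_id = arch$gene_id,
                      dyad_rel = vapply(seq_len(nrow(arch)), function(i)
                        resolve_dyad_rel(arch$class[i], arch$hs_ext[i], cond$name), 0L))
  dyads$dyad <- rel_to_abs(arch$tss, arch$strand, dyads$dyad_rel)
  for (i in seq_len(nrow(arch))) {
    a <- arch[i, ]
    d1 <- dyads$dyad[i]
    others <- rel_to_abs(a$tss, a$strand,
                         c(a$rap1_up_rel - 150L, dyads$dyad_rel[i] + 165L))
    n1 <- stats::rpois(1, frag_depth); emit_at(rep.int(d1, n1), n1)
    n2 <- stats::rpois(1, frag_depth * 0.8); emit_at(rep.int(others[1], n2), n2)
    n3 <- stats::rpois(1, frag_depth * 0.9); emit_at(rep.int(others[2], n3), n3)
    if (protect_nonhistone && a$class != "none") {
      zl <- a$zone_lo; zh <- a$zone_hi
      np <- stats::rpois(1, (zh - zl) * protect_rate)
      if (np) emit_at(zl + sample.int(zh - zl, np, replace = TRUE) - 1L, np,
                      jitter = FALSE)
    }
  }
  n_bg <- stats::rpois(1, genome$length * background_rate)
  if (n_bg) centers <- c(centers, sample.int(genome$length, n_bg, replace = TRUE) - 1L)
  lens <- pmax(100L, pmin(200L, as.integer(round(stats::rnorm(length(centers),
                                                              len_mean, len_sd)))))
  start <- centers - (lens - 1L) %/% 2L
  keep <- start >= 0L & start + lens <= genome$length
  out <- data.frame(chrom = genome$chrom, start = start[keep],
                    end = (start + lens)[keep], stringsAsFactors = FALSE)
  o <- order(out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dyads") <- dyads
  attr(out, "n_background") <- n_bg
  out
}

#' Write the synthetic genome as FASTA
#' @param genome a [build_genome()] result.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$chrom
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
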