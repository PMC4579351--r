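# Configuration-driven orchestration: simulate a dataset bundle to disk,
# then run the full analysis (shift -> pileup -> peaks -> pairs -> motifs ->
# occupancy -> breadth -> composites -> dyads -> shifts) over it, logging
# record counts at every stage boundary.

#' Default run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_genes promoters to simulate.
#' @param factors factor panel to simulate/analyze.
#' @param conditions condition names.
#' @return a nested config list; every field can be overridden via
#'   [load_config()].
#' @export
default_config <- function(out_dir = "exoarch_run", seed = 1L, n_genes = 120L,
                           factors = exo_factors(),
                           conditions = c("normal", "heat_shock", "hmo1_null")) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = list(
      n_genes = as.integer(n_genes),
      class_proportions = c(none = 58, narrow = 30, broad = 30) / 118,
      factors = factors, conditions = conditions,
      depth = 50, stop_jitter_sd = 2, headroom = 6, piggyback_fraction = 0.15,
      background_rate = 0.005, frag_depth = 200),
    analyze = list(
      shift = 6, sigma = 5, exclusion = 20, max_span = 100, min_count = 2,
      flank = 100, motif_p = 0.001, ifhl_p = 1e-4, motif_radius = 40,
      tss_max_dist = 500, breadth_broad_min = 135, breadth_narrow_min = 50,
      composite_half_width = 500, dyad_search = c(-50, 150)))
}

#' Load a run configuration from JSON
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path JSON config file.
#' @return merged config list.
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_into(default_config(), user)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_stage <- function(log, stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%s out=%s %s", stage, n_in, n_out, note))
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out, note = note,
                        stringsAsFactors = FALSE))
}

tags_path <- function(dir, factor, condition) {
  file.path(dir, sprintf("tags_%s_%s.bed", factor, condition))
}

#' Simulate a full dataset bundle to disk
#'
#' Writes the genome FASTA, annotation table, Rap1-site and Hmo1-zone BEDs,
#' per-factor/per-condition tag BEDs, MNase fragment BEDs per condition, a
#' machine-readable truth sidecar and a manifest with the config hash.
#'
#' @param config config list (see [default_config()]).
#' @return invisibly, the output directory.
#' @export
run_simulate <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  genome <- build_genome(n_genes = sim$n_genes,
                         class_proportions = sim$class_proportions,
                         seed = config$seed)
  exo <- exo_model(headroom = sim$headroom, stop_jitter_sd = sim$stop_jitter_sd,
                   piggyback_fraction = sim$piggyback_fraction,
                   background_rate = sim$background_rate, depth = sim$depth)
  write_genome_fasta(genome, file.path(config$out_dir, "genome.fa"))
  ann <- genome$arch[c("gene_id", "chrom", "tss", "strand", "class", "paralog_id")]
  utils::write.table(ann, file.path(config$out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rs <- genome$rap1_sites
  writeLines(sprintf("%s\t%d\t%d\t%s_rap1_%d\t0\t%s", genome$chrom, rs$start,
                     rs$end, rs$gene_id, rs$site_idx, rs$strand),
             file.path(config$out_dir, "rap1_sites.bed"))
  hz <- genome$arch[genome$arch$class != "none", ]
  writeLines(sprintf("%s\t%d\t%d\t%s_hmo1zone\t0\t%s", genome$chrom, hz$zone_lo,
                     hz$zone_hi, hz$gene_id, hz$strand),
             file.path(config$out_dir, "hmo1_zones.bed"))
  seed_i <- config$seed
  for (cn in sim$conditions) {
    cond <- condition_spec(cn)
    for (f in sim$factors) {
      seed_i <- seed_i + 1L
      tags <- simulate_chipexo(genome, exo, cond, f, seed = seed_i)
      write_tags_bed(tags, tags_path(config$out_dir, f, cn))
    }
    seed_i <- seed_i + 1L
    frags <- simulate_mnase(genome, cond, protect_nonhistone = FALSE,
                            seed = seed_i, frag_depth = sim$frag_depth)
    write_fragments_bed(frags, file.path(config$out_dir,
                                         sprintf("mnase_h3_%s.bed", cn)))
  }
  truth <- list(
    arch = genome$arch, rap1_sites = genome$rap1_sites,
    fhl1_sites = genome$fhl1_sites, ifhl_sites = genome$ifhl_sites,
    polyA_sites = genome$polyA_sites)
  jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                       dataframe = "columns", digits = NA, na = "null")
  manifest <- list(tool = "exoarch", version = "0.1.0", seed = config$seed,
                   config_hash = config_hash(config),
                   n_genes = sim$n_genes, factors = sim$factors,
                   conditions = sim$conditions)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Run the full analysis over a simulated (or equivalent) bundle
#'
#' Executes shift -> pileup -> smooth -> peaks -> pairs -> filter -> motifs
#' -> occupancy -> breadth -> composites -> dyads -> shifts on the files in
#' `config$out_dir`, writing TSV/BED outputs, a stage log, and a summary
#' report. Factors with empty tag files are marked missing and skipped;
#' the run completes.
#'
#' @param config config list; `out_dir` must hold a [run_simulate()] bundle.
#' @return invisibly, the report list.
#' @export
run_analyze <- function(config = default_config()) {
  dir <- config$out_dir
  an <- config$analyze
  if (!file.exists(file.path(dir, "genome.fa"))) {
    stop("config error: missing genome at ", file.path(dir, "genome.fa"))
  }
  genome_seq <- as.character(Biostrings::readDNAStringSet(
    file.path(dir, "genome.fa"))[[1]])
  glen <- nchar(genome_seq)
  genes <- utils::read.table(file.path(dir, "annotation.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  rap1_bed <- utils::read.table(file.path(dir, "rap1_sites.bed"), sep = "\t",
                                stringsAsFactors = FALSE)
  names(rap1_bed) <- c("chrom", "start", "end", "name", "score", "strand")
  rap1_bed$gene_id <- sub("_rap1_\\d+$", "", rap1_bed$name)
  rap1_bed$mid <- rap1_bed$start + (rap1_bed$end - rap1_bed$start) %/% 2L
  chrom <- genes$chrom[1]
  log <- data.frame()
  report <- list(missing = character(0))

  # most upstream Rap1 site per gene (gene orientation)
  up_site <- vapply(seq_len(nrow(genes)), function(i) {
    s <- rap1_bed[rap1_bed$gene_id == genes$gene_id[i], ]
    if (!nrow(s)) return(NA_integer_)
    rel <- abs_to_rel(genes$tss[i], genes$strand[i], s$mid)
    as.integer(s$mid[which.min(rel)])
  }, 1L)
  names(up_site) <- genes$gene_id

  conditions <- config$simulate$conditions
  factors <- config$simulate$factors
  shifted <- list(); all_pairs <- list()
  for (cn in conditions) {
    shifted[[cn]] <- list()
    for (f in factors) {
      path <- tags_path(dir, f, cn)
      if (!file.exists(path)) { report$missing <- c(report$missing, path); next }
      raw <- read_tags_bed(path, factor = f, condition = cn)
      if (!n_tags(raw)) {
        report$missing <- c(report$missing, sprintf("%s/%s (empty)", f, cn))
        log <- log_stage(log, paste0("read:", f, ":", cn), 0, 0, "empty; skipped")
        next
      }
      sh <- shift_tags(raw, an$shift)
      log <- log_stage(log, paste0("shift:", f, ":", cn), n_tags(raw), n_tags(sh))
      stopifnot(n_tags(sh) + attr(sh, "n_clamped") == n_tags(raw))
      shifted[[cn]][[f]] <- sh
      pk <- call_peak_pairs(raw, chrom, c(0, glen), sigma = an$sigma,
                            exclusion = an$exclusion, max_span = an$max_span,
                            min_count = an$min_count)
      log <- log_stage(log, paste0("pairs:", f, ":", cn),
                       nrow(pk$fwd) + nrow(pk$rev), nrow(pk$pairs))
      all_pairs[[paste(f, cn, sep = ":")]] <- pk$pairs
      utils::write.table(pk$pairs,
                         file.path(dir, sprintf("pairs_%s_%s.tsv", f, cn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # motifs over the genome, Rap1 motifs retained near Rap1 peak pairs
  rap1_pairs <- all_pairs[["Rap1:normal"]]
  rap1_m <- scan_iupac(genome_seq, RAP1_CONSENSUS)
  fhl1_m <- scan_iupac(genome_seq, FHL1_CONSENSUS)
  ifhl_m <- scan_iupac(genome_seq, IFHL_CONSENSUS)
  polyA <- find_polyA(genome_seq)
  if (!is.null(rap1_pairs) && nrow(rap1_pairs)) {
    rap1_kept <- retain_near_peaks(rap1_m, rap1_pairs$midpoint, an$motif_radius)
  } else rap1_kept <- rap1_m[integer(0), ]
  log <- log_stage(log, "motifs:rap1", nrow(rap1_m), nrow(rap1_kept),
                   "retained near peak pairs")
  assigned <- assign_to_tss(rap1_kept, genes, an$tss_max_dist)
  log <- log_stage(log, "motifs:assign", nrow(rap1_kept), nrow(assigned))
  for (nm in c("rap1_kept", "fhl1_m", "ifhl_m", "polyA", "assigned")) {
    utils::write.table(get(nm), file.path(dir, paste0("motifs_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # occupancy per condition
  occ <- list()
  for (cn in conditions) {
    avail <- names(shifted[[cn]])
    if (!length(avail)) next
    tab <- normalize_table(occupancy_table(shifted[[cn]], genes))
    occ[[cn]] <- tab
    for (layer in c("raw", "log2", "pct_rank")) {
      utils::write.table(round(tab[[layer]], 4),
                         file.path(dir, sprintf("occupancy_%s_%s.tsv", cn, layer)),
                         sep = "\t", quote = FALSE)
    }
  }

  # Hmo1 breadth and classes under normal conditions
  breadth <- NULL
  if (!is.null(shifted$normal$Hmo1)) {
    breadth <- breadth_table(shifted$normal$Hmo1, genes, up_site, glen,
                             broad_min = an$breadth_broad_min,
                             narrow_min = an$breadth_narrow_min)
    utils::write.table(breadth, file.path(dir, "breadth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- log_stage(log, "breadth", nrow(genes), sum(!is.na(breadth$breadth)))
    report$breadth_classes <- as.list(table(breadth$group))
  }

  # correlation matrix (normal condition)
  if (!is.null(occ$normal)) {
    cm <- correlation_matrix(occ$normal)
    utils::write.table(round(cm, 4), file.path(dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
  }

  # composites anchored at the most upstream Rap1 site (normal condition)
  anchors <- data.frame(gene_id = genes$gene_id, pos = up_site,
                        strand = genes$strand, stringsAsFactors = FALSE)
  anchors <- anchors[!is.na(anchors$pos), ]
  for (f in intersect(c("Rap1", "Fhl1", "Hmo1", "Sua7"), names(shifted$normal))) {
    cp <- composite_profile(shifted$normal[[f]], anchors,
                            an$composite_half_width, smooth_sigma = an$sigma)
    utils::write.table(
      data.frame(offset = cp$offset, fwd = cp$mean_fwd, rev = cp$mean_rev,
                 all = cp$mean_all),
      file.path(dir, sprintf("composite_%s_rap1anchor.tsv", f)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # dyads and shifts from MNase-H3 fragments
  shifts <- NULL
  frag_files <- file.path(dir, sprintf("mnase_h3_%s.bed", conditions))
  have <- file.exists(frag_files)
  if (sum(have) >= 2) {
    calls <- list()
    for (k in which(have)) {
      frags <- read_fragments_bed(frag_files[k])
      cc <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        w <- range(rel_window_abs(g$tss, g$strand, an$dyad_search[1],
                                  an$dyad_search[2]))
        # pad so kernel truncation at the window edge cannot bias the argmax
        dd <- dyads_from_fragments(frags, c(w[1] - 100L, w[2] + 101L))
        pc <- call_plus_one(dd, g, an$dyad_search)
        data.frame(gene_id = g$gene_id, dyad_rel = pc$dyad_rel %||% NA)
      })
      calls[[conditions[k]]] <- do.call(rbind, cc)
    }
    grouping <- if (!is.null(breadth)) stats::setNames(breadth$group, breadth$gene_id)
    for (cn in setdiff(names(calls), "normal")) {
      es <- estimate_shift(calls$normal, calls[[cn]], grouping)
      utils::write.table(es$per_group,
                         file.path(dir, sprintf("shift_%s_vs_normal.tsv", cn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report[[paste0("shift_", cn)]] <- es$per_group
      log <- log_stage(log, paste0("shift:", cn), nrow(calls$normal),
                       nrow(es$per_gene))
    }
  }

  utils::write.table(log, file.path(dir, "stage_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$config_hash <- config_hash(config)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `analyze`, `all`. Usage:
#' `exoarch <subcommand> [--config cfg.json] [--out dir] [--seed N]`.
#' Exit codes: 0 success, 2 configuration error, 3 data error.
#'
#' @param args character vector (default: the process command line).
#' @return exit status, invisibly.
#' @export
exoarch_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(code, msg) { message("error: ", msg); return(invisible(code)) }
  if (!length(args)) return(fail(2, "usage: exoarch <simulate|analyze|all> [--config f] [--out d] [--seed n]"))
  cmd <- args[1]; args <- args[-1]
  opt <- list(config = NULL, out = NULL, seed = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      return(fail(2, paste("bad argument:", args[i])))
    }
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  config <- tryCatch({
    cfg <- if (!is.null(opt$config)) load_config(opt$config) else default_config()
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    cfg
  }, error = function(e) NULL)
  if (is.null(config)) return(fail(2, "could not load configuration"))
  res <- tryCatch({
    switch(cmd,
      simulate = run_simulate(config),
      analyze = run_analyze(config),
      all = { run_simulate(config); run_analyze(config) },
      stop("unknown subcommand: ", cmd))
    0
  }, error = function(e) { message("error: ", conditionMessage(e)); 3 })
  invisible(res)
}
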