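# exoarch

Promoter-architecture analysis of coregulated yeast ribosomal protein
genes (RPGs) from ChIP-exo data, as a tested, reusable R pipeline.

## The problem

The ~137 RPGs of *Saccharomyces* are the textbook case of gene
coregulation: one master regulator (Rap1, usually at site pairs 5–15 bp
apart), a coactivator ensemble (Fhl1–Ifh1–Sfp1, "FIS") ~100 bp downstream,
an optional HMG-box protein (Hmo1) occupying a variable 110–160-bp zone, a
preinitiation complex (PIC) at the core promoter, and a +1 nucleosome whose
dyad sits ~58 bp past the TSS so that the TSS lies 15 bp inside the
nucleosome edge. ChIP-exo maps all of this at near base-pair resolution:
sequenced tag 5' ends are exonuclease stop sites ~6 bp 3'-ward of each
protein–DNA cross-link, so every binding event appears as an
opposite-strand *peak pair* whose midpoint estimates the cross-link
coordinate.

`exoarch` implements the full analysis chain for anyone working with this
kind of data — strand-specific stop-site tags in, biology out:

* **tagio** — BED-native tag/fragment I/O, 3' shifting, strand-specific
  pileups (`shift_tags()`, `tag_pileup()`);
* **peakcall** — GeneTrack-style Gaussian smoothing (σ = 5), greedy peak
  calling with a 20-bp exclusion zone, 3'-ward pairing within 100 bp,
  `count > 2` pair filtering, cross-condition background normalization;
* **motifscan** — IUPAC scanning (Rap1, `YKYGCGTC`, `GGCNG`), poly(dA:dT)
  tract detection, PWM scanning with *exact* p-values by dynamic
  programming, ±40-bp peak retention, <500-bp TSS assignment;
* **occupancy** — windowed occupancy tables (log2-median and percent-rank
  layers), Hmo1 binding-breadth measurement and broad/narrow/none
  classification, heat-shock fold changes, ectopic PIC fractions,
  factor–factor Pearson matrices;
* **composite** — anchor-aligned, orientation-corrected composite profiles
  and per-gene heat-map matrices; piggyback detection via pattern
  similarity to the Rap1 template;
* **nucpos** — nucleosome dyads from MNase fragment midpoints and from
  histone ChIP-exo (matched-filter), +1 calling, dyad-shift estimation,
  TSS-burial geometry;
* **synthetic_data** — a generator that emits genome, annotation, ChIP-exo
  tags and MNase fragments for ~120 promoters under three conditions
  (normal, heat shock, *hmo1*Δ) with full ground truth retained, so every
  estimator is tested by recovery against planted values;
* **pipeline** — a config-driven `simulate`/`analyze` orchestration with a
  CLI (`exec/exoarch`).

## Worked example

```r
library(exoarch)

genome <- build_genome(n_genes = 24, seed = 101)
genome
#> <synthetic_genome> chrS: 50000 bp, 24 promoters (broad=4, narrow=6, none=14)

tags <- simulate_chipexo(genome, exo_model(), condition_spec("normal"),
                         "Rap1", seed = 1)
tags
#> <tag_dataset> Rap1/normal: 2287 tags (total weight 2287.0), unshifted

pk <- call_peak_pairs(tags, genome$chrom, c(0, genome$length))
head(pk$pairs[c("fwd_pos", "rev_pos", "midpoint", "span", "count")], 3)
#>  fwd_pos rev_pos midpoint span count
#>     2559    2572   2565.5   13    38
#>     2587    2599   2593.0   12    40
#>     4591    4603   4597.0   12    46
```

Each pair is one Rap1 binding event: the forward stop cluster, the reverse
stop cluster 12–13 bp downstream (twice the 6-bp headroom), and the
midpoint as the cross-link estimate. Against the generator's ground truth:

```r
truth <- attr(tags, "crosslink_points")
mean(sapply(truth$pos, function(x) min(abs(pk$pairs$midpoint - x))))
#> 0.27   # bp — sub-base-pair localization over 43 planted sites
```

Hmo1 breadth classification recovers every planted class:

```r
hm <- shift_tags(simulate_chipexo(genome, exo_model(),
                                  condition_spec("normal"), "Hmo1", seed = 2), 6)
bt <- breadth_table(hm, genome$arch,
                    setNames(genome$arch$rap1_up, genome$arch$gene_id),
                    genome$length)
table(planted = genome$arch$class, called = bt$group)
#>         called
#> planted  broad narrow none
#>   broad      4      0    0
#>   narrow     0      6    0
#>   none       0      0   14
```

End-to-end from the command line:

```sh
exec/exoarch all --out run1 --seed 5     # simulate bundle + full analysis
```

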