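---
title: "Dissecting RPG promoter architecture from ChIP-exo stop sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting RPG promoter architecture from ChIP-exo stop sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoarch)
```

## The measurement model

ChIP-exo digests cross-linked chromatin with a 5'→3' exonuclease that stops
a few base pairs short of each protein–DNA cross-link. The 5' ends of
sequenced tags therefore mark strand-specific *stop sites*: a single
cross-link at coordinate $x$ produces a forward-strand stop cluster near
$x - h$ and a reverse-strand cluster near $x + h$, where $h \approx 6$ bp is
the exonuclease "headroom". Everything in this package follows from that
geometry:

* **shifting** tags by $h$ in their own 3' direction collapses the doublet
  onto the cross-link point (`shift_tags()`);
* a **peak pair** — a forward and a reverse peak within 100 bp, read
  3'-ward — marks one binding event, its midpoint estimating the cross-link
  coordinate (`pair_peaks()`);
* a factor that cross-links only *through* another protein ("piggybacking")
  reproduces the template's detailed stop-site pattern at lower amplitude,
  which `pattern_similarity()` quantifies as a Pearson correlation of
  strand-specific composite profiles plus an amplitude ratio.

Peak calling is GeneTrack-style: per-strand pileups are convolved with a
discrete Gaussian (`sigma = 5` bp, mass-conserving, edge-renormalized), and
peaks are taken greedily from the global maximum down while suppressing
anything closer than the exclusion zone. We interpret the exclusion zone of
20 as a minimum center-to-center distance (the original parameterization is
ambiguous between half- and full-width; the radius is configurable). Ties
break to the lower coordinate, and height filtering is deferred to the
pair-count filter (`count > 2`), which is where the published procedure
applies its cut.

## The promoter model the simulator states

The cohort is ~120–127 Rap1-bound ribosomal protein gene (RPG) promoters.
Each simulated promoter carries, in gene orientation:

| element | placement | default |
|---|---|---|
| Rap1 site(s) | most upstream site 280–320 bp upstream of the TSS | 1 or 2 sites; pairs 5–15 bp apart (prob. of a pair 107/127) |
| poly(dA:dT) tract | in the A/T-rich gap, Rap1 +45 bp | 8 bp |
| Fhl1 core | 100 bp downstream of the upstream Rap1 site | `YKYGCGTC` instance planted |
| Hmo1 zone | starts 90 bp downstream of Rap1 | breadth 0 / 100–120 ("narrow") / 150–170 bp ("broad"); G+C-elevated; `GGCNG` (IFHL) every 26 bp |
| PIC | TSS − 20 bp | TFIIB/TFIIA/TAF offsets spanning ~75 bp |
| +1 nucleosome | dyad at TSS + 58 (active) | TSS 15 bp inside the upstream edge |

Class proportions default to 58/30/30 (none/narrow/broad) over the cohort.
Hmo1 cross-link points tile the zone every 13 bp — two molecules per ~26-bp
binding unit — which yields the contiguous footprint that breadth sorting
relies on; the tiles are inset half a unit from the zone edges so that
smoothing tails do not systematically overshoot the planted breadth. FIS
factors (Fhl1, Ifh1, Sfp1) occupy a fixed ~80-bp core around the Fhl1 core
motif at relative efficiencies 1 : 1/4.6 : 1/24, extend toward (but 20–30 bp
short of) the Hmo1 border at Hmo1-bound genes, and piggyback at Rap1 points
with 15% of their per-point intensity.

Three conditions are stated, not tuned:

* **normal** — everything at unit retention, active +1 dyad.
* **heat shock** — Hmo1 retention 0.3 (~70% dissociation), Ifh1/Sfp1 0.2,
  Rap1/Fhl1 fully retained; the +1 dyad retracts 20 bp upstream at all
  genes plus the Hmo1-beyond-Fhl1 extension (20–50 bp, scaling with
  breadth) at Hmo1-bound genes.
* **hmo1-null** — Hmo1 absent; Fhl1 constricted to its 80-bp core; 23% of
  TFIIB/Pol II relocated uniformly into (TSS−200, TSS−70) with the
  remainder shifted 15 bp upstream; the +1 dyad moves 20 bp upstream at
  Hmo1-bound genes only.

Tag counts per cross-link point are Poisson with mean
`depth × efficiency × retention × activity`; stops are jittered by a
discretized Gaussian (sd 2 bp) because tags are base-pair events. Depth
defaults to 50 tags per point — the paper never states absolute sequencing
depth, so this is a free parameter fixed at the level the recovery
properties are stated at. Background tags are uniform at 0.005/bp.

**Latent activities.** Each gene draws three log-normal scalars (sdlog
0.35): one shared by Rap1/FIS/Hmo1, one by PIC components, one for Pol II.
Without them, per-gene occupancies would be independent Poisson draws and
the empirically observed correlation block structure (regulators correlate
with regulators, PIC with PIC, Pol II with neither) could not emerge from
the generator. Heat-shock PIC retention is breadth-dependent
($0.5 \cdot 2^{-\mathrm{breadth}/80}$) so that broader Hmo1 architectures
repress more — the quartile-monotone fold-change pattern is thereby a
property of the stated world rather than an accident of noise.

### What the generator does *not* emulate

Read-level errors, mappability, PCR duplication, copy-number structure,
chromatin context outside the 2-kb promoter slots, and any non-RPG genes.
A green recovery test therefore establishes that the *estimators* invert
the *stated* generative model at realistic depth — not that they would be
unbiased on arbitrary real libraries.

## Quantification conventions

* Coordinates are 0-based, half-open everywhere (BED-native); 1-based
  inputs must be converted at the boundary. Occupancy windows are
  half-open `[lo, hi)` in gene orientation; minus-strand genes mirror.
* Occupancy windows: upstream regulators (Rap1, FIS, Hmo1) −400..0; PIC
  −200..+200; Pol II 0..+400; ectopic PIC −200..−70 against a −200..+60
  total.
* Occupancy normalization: per factor, log2 of the ratio to the cohort
  median; columns containing zeros take a +1 pseudocount (recorded on the
  result). Percent rank is `rank/n × 100` with average ranks for ties —
  invariant under any monotone transform of the raw values.
* Hmo1 **breadth** is the number of bp between the most upstream Rap1 site
  and the TSS whose smoothed Hmo1 density exceeds a threshold. The
  published sorting does not define the threshold; the default is 3× the
  genome-wide mean tag rate, exposed in the interface. Default class
  cutoffs (≥135 bp broad, ≥50 narrow) reproduce the planted classes; a
  rank-based grouping (top 30 / next 30) is available for cohort-sorted
  displays. Genes without a Rap1 site are "unassigned", never forced into
  a group.
* Background normalization between conditions equalizes tag totals outside
  the ±100-bp intervals around peak-pair midpoints, implemented as a
  per-tag weight on the rescaled dataset so downstream window sums see the
  scaled signal; after scaling the background totals agree to machine
  precision.

## Nucleosome positioning choices

A canonical 147-bp core (half-width 73) is assumed. MNase fragment dyads
are size-filtered midpoints (120–180 bp; odd lengths round toward the 5'
end) smoothed with a 10-bp Gaussian: the raw histogram argmax is unstable
at realistic placement jitter, the smoothed mode recovers a 200-fragment
dyad within ±3 bp. Histone ChIP-exo cross-links flank the dyad in clusters
±30 bp away, so `dyads_from_exo()` applies a *matched filter* — a
symmetric pair of Gaussian lobes at ±30 bp — rather than a single wide
kernel: the sum of two clusters 60 bp apart has a flat top under plain
smoothing and its argmax wanders by ~10 bp, while the matched-filter
response peaks sharply at the dyad (exact recovery at depth 100 in the
test suite).

The +1 nucleosome is the density argmax in a −50..+150 window around the
TSS (ties toward the TSS); the reference-dyad atlas the published analysis
aligned to is out of scope, so the search-window rule replaces it. The
density is computed over a window padded by 100 bp so kernel truncation at
the search boundary cannot bias the argmax. For heat-shock geometries the
+1 moves far enough upstream that the +2 nucleosome enters a naive window;
analyses of that condition use −130..+120, which excludes the +2 while
covering every programmed position. Shifts are per-gene `dyad_b − dyad_a`
in gene orientation (negative = upstream), averaged within breadth groups;
composite-level mode shifts would be an alternative reading of a group
shift, and per-gene means were chosen as the default because they expose
dispersion.

TSS burial is measured from the nucleosome's upstream edge: dyad at TSS+58
puts the TSS 15 bp inside; a 20-bp upstream shift buries it 35 bp deep.

## Motif scanning numerics

IUPAC scanning delegates the degenerate matching to Biostrings; reverse
complement hits are reported on the minus strand at plus-strand
coordinates. Poly(dA:dT) tracts are maximal runs of A *or* of T of ≥6 bp
(">5-mer"); `AAATTT` contains none.

PWM p-values are exact by dynamic programming over column score
distributions under a 0-order background (the FIMO-default dialect;
estimated from the scanned sequence when not supplied). Scores are
discretized to 1/100,000 of the attainable score range; an earlier 1/1,000
grid was found to misplace up to ~2% of null mass around thresholds for
sharply peaked matrices, because rounding each matrix cell can reorder
sequences whose true scores lie within `w` bins of each other, so the grid
was refined until the enumeration disagreement stays below 10⁻³ for
continuous matrices. Reported scores live on the grid, which makes
p-values exactly monotone non-increasing in the reported score. For
degenerate matrices with heavy score ties the true-score-vs-grid
comparison is ill-posed at the tie boundary; the DP remains exact for the
grid scoring.

Rap1 motif retention keeps matches within ±40 bp (inclusive) of a peak,
once per match regardless of how many peaks are near. TSS assignment is
nearest-neighbor on unsigned distance, strictly below 500 bp, with the
reported distance signed in gene orientation. The published Rap1 weight
matrix lives in supplementary material not shipped here; the scanner takes
any PWM (MEME minimal format reader included) and the simulator plants a
synthetic Rap1 consensus for testing.

## Decisions on points the published procedure leaves open

* Strand information is removed after shifting in the published pipeline;
  we retain it with the shift recorded as a state flag, because unshifted
  strand-specific analyses (pattern similarity) coexist with shifted ones
  in the same session. Collapsing is a view (`counts_all`), not a
  destructive step.
* Tags shifted below coordinate 0 are dropped and counted, keeping
  conservation auditable.
* Whether composite traces are count- or density-normalized before
  averaging is unstated; we average per-anchor counts, and max-scaling to
  1 is an explicit flag.
* Smoothing before breadth thresholding uses the same Gaussian kernel as
  peak calling (sigma 5) — the published figure says "smoothed" without a
  value.
* The hmo1-null +1 geometry applies the repressed (−20 bp) dyad to
  Hmo1-bound classes only: the observation the generator emulates is
  explicit that Hmo1-independent genes do not move. Under heat shock all
  classes retract, Hmo1-bound ones further by the beyond-Fhl1 extension.

## Known limitations

* The breadth estimator's threshold rule interacts with smoothing tails:
  individual genes can over- or under-shoot by ~10 bp even when the class
  is right; the cohort mean error stays below 4 bp at default depth.
* `dyads_from_exo()` assumes the ±30-bp cross-link signature; nucleosomes
  with atypical exo footprints would need a different `flank`.
* The pipeline's peak calling runs genome-wide per strand per factor;
  on real genomes (12 Mb+) the greedy caller would want a compiled
  implementation.
* Occupancy statistics are descriptive; no significance testing is
  provided because the emulated analysis reports none.
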