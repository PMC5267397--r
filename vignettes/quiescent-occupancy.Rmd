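---
title: "Comparing chromatin occupancy and transcript content between growing and quiescent yeast cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chromatin occupancy and transcript content between growing and quiescent yeast cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qchromatin)
```

## The problem

When budding yeast exhausts glucose, part of the population enters
quiescence (G0): a stable, non-dividing state with globally repressed
transcription. Despite that repression, quiescent (Q) cells retain histone
methylation marks associated with active chromatin (H3K4me3 at 5' gene
regions, H3K36me3 and H3K79me3 in gene bodies), substantial amounts of RNA
polymerase II with a distinctive occupancy profile, and thousands of
transcripts. Characterizing how the Q-cell chromatin and transcriptome
differ from exponentially growing (log) cells requires a consistent set of
comparative analyses over binned IP/input signal tracks and per-transcript
abundance tables. `qchromatin` packages those analyses, together with a
synthetic-data generator whose ground truth makes every stage testable
without external array or sequencing data.

## The enrichment model

All occupancy statistics derive from one per-gene score. For gene $g$ with
window bins $B_g$ (gene body by default),

$$ s_g \;=\; \frac{1}{|B_g|} \sum_{b \in B_g}
   \log_2 \frac{\mathrm{IP}_b + c}{\mathrm{input}_b + c}, $$

with pseudocount $c = 1$ (negligible relative to the simulated background
intensity of 100 units, and protective against empty bins on real data).
This windowed mean log2 IP/input ratio reproduces the relative-occupancy
semantics of ChIP-on-tiling-array data without committing to any
probe-level normalization scheme; probe normalization is explicitly out of
scope, so genome-wide site counts obtained from raw array data by other
pipelines are not comparable quantities.

A gene is *marked* when $s_g \ge \tau$, with $\tau = 1$ (2-fold) by
default. Calling is independent per mark and per state. Marked sets from
the two states are partitioned by set algebra into log-only, Q-only and
common genes, and common genes are subdivided by the sign of
$s_g^{\mathrm{log}} - s_g^{\mathrm{Q}}$ (exact ties, which have measure
zero under the noise model, deterministically go to `common-higher-log`
with a recorded flag). The subdivision uses raw scores by default; whether
to use H3-normalized scores (`normalize_to_h3()`, a log-scale
ratio-of-ratios mirroring per-locus reporting of PTM IP/input relative to
H3 IP/input) is configurable because either convention is defensible.

## Profiles and matrices

`tss_tes_profile()` lays every gene onto a common grid: a 250 bp upstream
flank in real coordinates (at track-bin resolution), the gene body rescaled
to $B = 100$ bins, and a 250 bp downstream flank. Minus-strand genes are
reversed so the TSS is always on the left. Body rescaling uses
coverage-weighted averaging of the per-bp signal (each target bin averages
the base pairs mapped to it), which conserves mass; interpolation does not.
$B = 100$ is a resolution choice only - it is fine enough to localize a
TSS- or TES-proximal peak to a tenth of a gene body and coarse enough that
a 300 bp gene still populates every bin with at least 3 bp. Genes shorter
than two track bins are excluded with a logged count rather than an error,
since rescaling two bins to 100 is not meaningful.

`chromatra()` produces the transcript-length-sorted view: one TSS-aligned,
strand-oriented row per transcript over a fixed window (default -500 bp to
+5000 bp), rows sorted by ascending length with ties broken by id, and
cells whose column lies at or beyond the transcript's TES masked so column
statistics never mix gene-body with downstream signal.

## Co-occupancy, Venn partitions and Fisher tests

Genome-wide signal similarity uses Spearman's rank correlation (midranks
for ties) on log2 ratio tracks averaged into 500 bp analysis bins. The
analysis bin size is configurable; rank correlation makes the result
invariant to monotone transformations of either signal, which the test
suite asserts directly.

Co-enrichment of RNAP II, H3K4me3, H3K36me3 and H3K79me3 within a state is
summarized as the 15 membership regions of the 4-set Venn partition.
Between states, each region is compared with Fisher's exact test on the
2x2 table `[[count, union - count]] x [log, Q]` - i.e. whether the
region's share of co-enriched genes differs between states. This contrast
is a package choice: a region count can be contrasted against several
denominators, and the share-of-union contrast is the one that directly
expresses "more genes co-enriched for X in log than in Q". The odds ratio
reported is the sample odds ratio $ad/bc$, with infinite/zero/undefined
cases flagged rather than silently dropped; degenerate margins return
$p = 1$. Raw per-region p-values are primary; Benjamini-Hochberg
adjustment across the 15 regions is available but off by default.

## Divergent intergenic regions

`build_igr_partition()` classifies every base pair of the genome into
gene-containing regions (GCRs, the merged ORF spans), divergent intergenic
regions (IGRs: gaps whose left-flanking ORF is on "-" and right-flanking
ORF on "+", so both 5' ends face the gap), and "other" (tandem and
convergent gaps, chromosome ends). Only divergent gaps are IGRs because
only they can harbor a shared bidirectional promoter. Sites are assigned
to the class they overlap most, with exact ties resolved GCR > IGR >
other; the site definition is deliberately generic (any interval), because
in the pipeline a "site" is a marked gene's span for GCR logic and an
enriched inter-ORF interval for IGR logic. All fractions are reported with
explicit denominators, since "fraction of sites in IGRs" is sensitive to
what counts as a site.

## Transcriptome comparison

Detection is a simple threshold on normalized abundance (default 1.0
unit). No published cutoff exists for the counts this style of analysis
prints, so per-state totals are treated as worked-example arithmetic: the
package guarantees the set identities (state total = common +
state-specific) and the percentage reporting (half-up integer rounding,
matching the reporting style of the field) rather than any particular
total. Concordance between transcripts and polymerase is the fraction of a
state's detected ORF transcripts whose gene is in the same state's RNAP II
marked set; using the same-state marked set is an assumption recorded
here.

## What the generator emulates

The simulator is the package's test bed and defines the conditions under
which recovery is demonstrated:

* **Genome**: 16 chromosomes of 800 kb, 5000 non-overlapping ORFs with
  log-normal lengths truncated to [300, 8000] bp (meanlog 7.2, sdlog 0.55
  - a median of about 1.3 kb, yeast-like), placed with randomly scaled
  gaps so genes cover most of each chromosome. Strands follow a two-state
  Markov chain whose switch-to-facing probability $a = 2f$ yields a
  divergent-pair fraction $f$ (default 0.3, near the yeast genome's share
  of divergent pairs); the construction caps $f$ at 0.5. Noncoding
  features (CUT/SUT/snRNA/LTR) drop into intergenic gaps at configurable
  Poisson rates.
* **Signals**: per mark and state, a clean fold-enrichment surface - a
  gene-body plateau (default 4-fold, i.e. log2 effect 2) plus Gaussian TSS
  and/or TES bumps - multiplied by per-bin log-normal noise
  (`noise_sd = 0.3` on the natural-log scale by default). The noise is
  multiplicative because chromatin signal is heteroskedastic and
  nonnegative; additive Gaussian noise would produce negative
  intensities. H3K4me3 peaks at the TSS; H3K36me3/H3K79me3 are body-only;
  RNAP II has a 5' peak in log cells and, in Q cells, no promoter-proximal
  peak but a TES peak over a flat body. RNAP II signal additionally covers
  noncoding features whose transcript is present in the state, tying
  intergenic polymerase to noncoding transcription. Effect sizes are free
  parameters - no published effect-size estimates exist for these data -
  and the defaults were fixed once at 2 log2 units, comfortably above the
  1-unit calling threshold.
* **Two-state structure**: each gene gets a ground-truth category per mark
  (log-only / Q-only / common-higher-log / common-higher-Q / unmarked)
  sampled at configured fractions. Common genes receive the full effect in
  their higher state and `shared_effect_ratio` (default 0.7) of the log2
  effect in the other; 0.7 keeps the lower state's windowed score above
  the calling threshold even for short genes whose partially covered edge
  bins dilute the mean, while leaving a clear between-state difference for
  the subdivision to recover.
* **Transcripts**: present transcripts get `detection_threshold` plus a
  log-normal draw (state-specific meanlog, lower in Q so Q medians are
  lower), absent ones a sub-threshold value, and a small dropout fraction
  of present transcripts is pushed below threshold to emulate detection
  failure. The additive-threshold construction makes detection exact at
  dropout 0, which is what turns set-identity tests into ground-truth
  tests.

The generator deliberately does **not** emulate: sequence (no FASTA or
reads), probe effects or array normalization artifacts, nucleosome
positioning, copy-number or replication structure, overlapping or
intron-containing genes, or correlated noise along the chromosome. Passing
recovery tests therefore demonstrates the correctness of the analysis
logic under the declared statistical model, not robustness to every
artifact of real tiling-array or RNA-seq data.

## Numerical and design choices

* Coordinates are 0-based half-open internally; BED/bedGraph are written
  0-based half-open and GFF3 1-based closed, with conversion confined to
  the I/O layer.
* A bin belongs to a gene body when its center lies inside the gene;
  profile and matrix computations instead work per base pair, so windows
  need not align to the bin grid.
* Each generator operation draws from its own RNG stream seeded by
  `(seed, operation name)`, so any stage can be regenerated independently
  and reruns are byte-identical.
* Top-quartile selection takes the `ceiling(N/4)` highest scores with ties
  at the cutoff broken by lexicographic gene id (C locale) and flagged.
* Box-plot summaries use type-7 quantiles with whiskers at the most
  extreme values within 1.5 IQR.
* Unstranded noncoding features on input default to "+" with a recorded
  flag; IGR logic only consumes ORF strands.
* Off-grid bedGraph intervals are re-binned by coverage-weighted mean
  (uncovered base pairs count as zero), or rejected when re-binning is
  disabled.
* `NaN` statistics serialize to JSON `null` with an explicit flag listing
  their paths.

The command-line surface is the R API itself plus `run_all()`, which
chains every stage with per-stage error reporting, a deterministic
manifest (package version, seed, config hash) and a JSON report;
`scripts/acceptance.R` shows the intended non-interactive usage.

## Test problem sizes

The test suite runs entirely on simulated data: oracle-equivalence checks
use 20 randomized instances of 12 genes on a 60 kb chromosome;
ground-truth recovery uses 1000 genes on four 650 kb chromosomes at noise
0.3 across three seeds (sensitivity, specificity and category agreement
all at or above 0.95); profile-shape checks use noiseless 250-gene
genomes; Fisher calibration uses 2000 null tables with fixed margins.
These sizes were chosen to give stable statistics at interactive runtimes.

## Limitations

Scores are a declared stand-in for whatever probe-level processing
produced a given real dataset, so absolute marked-gene counts are not
comparable across processing pipelines; only relative, within-pipeline
comparisons are. The divergent-IGR analysis ignores nested genes and
annotates divergence purely by flanking ORF strands. Detection thresholds
on abundance tables are a crude stand-in for count-model-based presence
calls. GO-style functional enrichment of gene categories is out of scope.
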