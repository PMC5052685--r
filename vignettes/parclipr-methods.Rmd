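---
title: "Methods: conversion-density site calling, motif discovery and secretome integration"
author: "parclipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conversion-density site calling, motif discovery and secretome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`parclipr` reconstructs, at desk scale, the computational chain used to
identify the mRNA targets of a cytoplasmic RNA-binding protein from
PAR-CLIP data and to connect binding to regulation. PAR-CLIP marks
protein-bound uridines as T-to-C conversions introduced during reverse
transcription of 4-thiouridine-labelled, UV-crosslinked RNA, so the
conversion density along a transcript carries the positional information
that plain read coverage does not. Everything downstream of adapter
trimming and genome mapping is in scope: reads arrive already aligned to
transcript space (SAM with MD tags, or a simple TSV dialect), and the
package calls binding sites, filters them for replicate reproducibility,
ranks targets, discovers the RNA recognition element (RRE), and
integrates binding with transcriptome and secretome quantification.

All coordinates are 0-based, half-open, in transcript space, on the sense
strand. U and T are treated as identical; sequences are upper-cased on
ingestion.

# The synthetic study

Because the original sequencing and proteomics libraries cannot be
regenerated from a desk, every stage is exercised against a simulated
study whose generative assumptions mirror the biology:

* **Transcriptome.** `n_transcripts = 1000` mRNAs of 100 nt 5'UTR,
  600 nt CDS and 300 nt 3'UTR (uniform base composition). These sizes are
  a deliberate desk-scale compromise: large enough that chance k-mer
  structure behaves like a real transcriptome, small enough that a full
  study runs in seconds.
* **Targets.** 30% of transcripts are targets; each carries two planted
  tandem elements `CUUC-N5-CACC` (both halves are concrete members of the
  CHHC family) written into non-overlapping random CDS positions — CDS
  placement mirrors where such sites concentrate in vivo. Non-target CDS
  regions are rescanned and resampled wherever the exact planted tandem
  arises by chance, so ground truth is unambiguous; chance tandems at
  *other* spacings are left in, as they would be in a real transcriptome.
* **Reads.** Per replicate, each planted site draws
  `Poisson(reads_per_site = 30)` reads covering the site midpoint, with
  read lengths `Normal(32, 6)` truncated to [20, 50] nt (the mapping
  filter regime of short-read PAR-CLIP libraries). Every planted-site
  uridine a read covers converts T-to-C with `conversion_prob = 0.2`;
  background reads arrive at 1 read/kb with a 20-fold reduced conversion
  rate. The background conversion model is not reported for the original
  libraries; the divisor 20 was chosen once so that replicate filtering
  is a non-trivial operation, and is configurable.
* **mRNA counts.** Observed log2 fold changes are shrunken ratios of
  negative-binomial counts (dispersion 0.05) around each gene's true fold
  change, which is exactly 0 for targets — the regulator under study acts
  on translation, not on mRNA abundance.
* **Secretome.** Control intensities are log-normal. In knockdown, every
  protein receives protein-level log2 noise `Normal(0, 0.2)`, and targets
  are additionally shifted by `-0.5 * log10(1 + crosslinked reads)`, so
  more frequently bound targets are more strongly down-regulated. The
  noise term applies to all proteins so that a null slope leaves targets
  and non-targets exchangeable.

What the simulation does **not** model: sequencing indels, PCR
duplicates, mappability, RNA secondary structure, isoform ambiguity, and
protein-level missingness mechanisms (missing-not-at-random LFQ
dropouts). Passing tests therefore demonstrate that the algorithms
recover planted structure under their own assumptions, not that those
assumptions hold for any particular real library.

# Site calling

Reads are grouped into clusters as connected components of the
"share at least one base" overlap graph (half-open intervals: touching
reads do not connect — the same convention used when intersecting
replicates). Clusters need `min_cluster_reads = 5` members.

Within a cluster, two Gaussian kernel densities are evaluated at integer
positions: one over conversion events (each read contributes at most one
event per converted position), one over covered-but-unconverted
reference uridines, both read-weighted and normalized to unit mass over
the cluster. A binding site is each maximal run where conversion density
strictly exceeds non-conversion density; runs shorter than
`min_site_len = 8` nt are padded symmetrically and clipped to the
cluster, runs that then touch are merged, and a site must retain
`min_conversion_reads = 2` distinct conversion-carrying reads.
Normalizing both densities to unit mass is what makes the comparison a
*localization* test: conversions concentrated in a short interval beat
diffuse non-conversion coverage even though raw conversion counts are
the minority at a 20% conversion rate.

The kernel bandwidth is 3 nt, evaluated at integer offsets. The original
cluster-calling software's bandwidth is not restated in its published
description, so the value is exposed as `site_params(kde_bandwidth=)`;
3 nt keeps the kernel support comparable to the spacing of crosslinkable
uridines within an 8-13 nt element. `min_site_len = 8` is an engineering
default (roughly one RRE half plus spacer), also parameterized.

Replicate filtering keeps sites of replicate 1 that share >= 1 nt with a
replicate-2 site on the same transcript. Targets are then ranked by the
summed number of distinct conversion-carrying reads overlapping any
replicated site, per replicate; a target passes the headline filter when
*both* replicates contribute at least 4 such reads. "Crosslinked reads"
are counted as distinct reads, not conversion events, and by default only
reads overlapping replicated sites count (`mode = "all"` counts every
conversion read of the transcript). Ties in the total are broken
lexicographically by transcript id so ranking is a reproducible total
order.

# Motif discovery

4-mer frequencies are computed in 20-nt windows sliding with step 1 over
cluster sequences (sites extended by a 20 nt flank, matching the spatial
footprint of the read clusters); per-window frequencies are averaged
uniformly over windows, which up-weights interior k-mers — stated
explicitly because window averaging admits several readings. Background
is a set of coding ORFs (100 sampled CDS per study), each shuffled 1,000
times preserving mononucleotide composition (dinucleotide-preserving
Euler-path shuffling is available as `mode = "di"`). One thousand
shuffles is a runtime compromise over the 10,000 a production analysis
would use; the z-scores of planted 4-mers sit far outside either
resolution.

Each shuffle is scored on window *runs* sampled to match the observed
cluster windows in both number and contiguity. This matching matters:
overlapping windows within a short cluster are strongly correlated, and
a background scored on independent windows would understate its own
variance, inflating every z-score. With matched runs, null z-scores are
approximately unit-scale, and the enrichment ranking (z descending,
k-mer lexicographic on ties) is calibrated.

Top-ranking k-mers are collapsed position-wise into the minimal covering
IUPAC code (e.g. `{CACC, CUUC, CCAC}` gives `CHHC`). Tandem arrangement
is quantified by counting ordered pairs of motif matches whose second
match starts exactly `motif length + s` after the first, for spacers
`s = 0..8`; counts are compared as rates per scannable position against
the same counting on shuffled sequences. The pipeline shuffles the
cluster sequences themselves as the spacer background — lengths then
match exactly and rates are directly comparable; shuffled CDS can be
supplied instead, and the rate normalization keeps the comparison valid.

# Secretome integration

Intensities are normalized so each sample's median equals the grand
median of pre-normalization sample medians, then log2-transformed.
Differential secretion uses a SAM-style moderated statistic
`d = (mean_kd - mean_ctrl) / (se + s0)` with the pooled two-sample
standard error and fudge factor `s0 = 0.5`; the null is built from 250
group-label permutations (all distinct assignments when fewer exist, as
with 4 vs 4), and the significance cutoff is the smallest symmetric
threshold on `|d|` whose estimated FDR — median permuted exceedance count
over observed exceedance count — is at or below 0.01. This is a
compatible-in-spirit reimplementation of the classic SAM procedure, not
a bit-compatible clone of any GUI implementation; missing intensities
are ignored pairwise (no imputation), and proteins missing in more than
half the samples are dropped with a log entry.

Genes are stratified by crosslink rank: the top 100 targets, the
remaining replicated targets ("poor"), and expressed never-crosslinked
genes ("non"; expression floor 2 in FPKM-like units, genes below the
floor excluded from all strata). Strata are compared by ECDFs of log2
fold change, per-stratum medians, and two-sample Kolmogorov-Smirnov
tests against "non". Crosslink dose-response is the Pearson correlation
of secretion log2 fold change with `log10(1 + crosslinked reads)`; the
log10 transform is a package choice (the natural scale for counts that
span decades) and is applied before correlation.

One compositional caveat is worth knowing: median normalization assumes
most proteins are unshifted. When targets are a large fraction of the
matrix (as in small simulations), normalizing pulls non-targets slightly
upward; at the ~20% secretory-target fraction typical of real data the
effect is small.

# Determinism and numerics

Every generator is a pure function of its configuration and seed: RNG
state is set locally and restored, per-replicate streams are derived
from the master seed, and the pipeline writes byte-identical tables for
identical configuration and seed. Degenerate situations are defined
rather than left to chance: a zero-background-sd k-mer reports z = +Inf
(if enriched) or 0 and is flagged; constant proteins get d = 0; a
stratum with fewer than 3 members reports its KS p as undefined; a
cluster with no conversion events yields no sites without error.

# Problem sizes used by the tests

The test-suite study sizes are the package's default conditions: 1,000
transcripts for motif recovery (20 independent studies), 300 transcripts
for spacer recovery (40 studies per planted spacer of 2, 5 and 8 nt),
1,000 x 8 null intensity matrices (50 seeds) for FDR control, and
300-target secretomes for the integration direction checks. They were
chosen once, before testing, as the smallest sizes at which the
corresponding statistics are stable.

# Known limitations

* Genome-space analysis (antisense transcription, splicing, liftover) is
  out of scope; everything lives in transcript coordinates.
* The site caller assumes single-nucleotide substitution evidence only;
  indel-containing alignments are rejected on ingestion.
* The SAM test estimates FDR from the median permuted exceedance without
  a pi0 correction, which is conservative when many proteins are truly
  shifted.
* The k-mer background models composition, not higher-order sequence
  structure, unless dinucleotide shuffling is selected.
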