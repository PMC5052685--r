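# parclipr

PAR-CLIP binding-site discovery, RNA-recognition-element analysis and
secretome integration for RNA-binding proteins, in transcript
coordinates, with a fully simulated ground-truth study built in.

## The problem

PAR-CLIP experiments mark the uridines a protein is bound to: during
reverse transcription of 4-thiouridine-labelled, UV-crosslinked RNA, the
crosslinked positions read out as T-to-C conversions. Turning those reads
into biology requires a chain of analysis steps — calling binding sites
where conversion density concentrates, keeping only sites reproduced in
both biological replicates, ranking target transcripts by crosslinked
reads, discovering the degenerate recognition element and its tandem
spacing, and finally asking whether binding predicts regulation at the
mRNA and secreted-protein level. `parclipr` implements that chain for
analysts working with transcriptome-aligned CLIP data, and pairs every
stage with a synthetic-data generator so recovery of planted truth is a
routine test rather than an act of faith.

At its core:

* **Site calling.** Within each read cluster, a Gaussian kernel density
  over T-to-C conversion events is compared with the density over
  covered, unconverted uridines (both read-weighted and normalized to
  unit mass); sites are the maximal runs where conversion density wins,
  padded to a minimum length and required to hold >= 2 distinct
  conversion-carrying reads.
* **Target ranking.** A transcript passes the headline filter when >= 4
  distinct crosslinked reads overlap its replicated sites in *both*
  replicates; targets are ranked by the summed count.
* **Motif discovery.** 4-mer enrichment in sliding 20-nt windows over
  cluster sequences versus shuffled coding ORFs, z-scored against a
  variance-matched shuffle background; top k-mers collapse to the minimal
  covering IUPAC motif (e.g. CHHC, H = A/C/U), whose tandem arrangement
  is profiled over spacers of 0–8 nt.
* **Integration.** Median-normalized label-free intensities tested with a
  SAM-style moderated statistic `d = Δmean / (se + s0)` and a
  permutation-estimated FDR; fold changes stratified into top-100 / poor
  / non-targets and compared as ECDFs; secretion change correlated with
  `log10(1 + crosslinked reads)`.

See `vignettes/parclipr-methods.Rmd` for models, parameters and design
rationale.

## Worked example

```r
library(parclipr)

cfg <- pipeline_config(seed = 1)
cfg$sim <- list(n_transcripts = 200)   # desk-scale demo
cfg$motif$n_shuffles <- 300
cfg$integrate$top_n <- 30
res <- run_pipeline(cfg, outdir = "parclipr_demo")
#> [info] simulated 200 transcripts, 7496 reads
#> [info] 119 replicated sites on 60 transcripts
#> [info] pipeline complete: parclipr_demo

head(res$motif$enrichment[, c("kmer", "observed_freq", "background_mean",
                              "z_score", "ratio")], 4)
#>   kmer observed_freq background_mean z_score ratio
#> 1 CTTC        0.0337         0.00394    32.5  8.56
#> 2 CACC        0.0317         0.00379    31.7  8.38
#> 3 TTCT        0.0132         0.00385    10.9  3.43
#> 4 TCTT        0.0134         0.00391    10.9  3.43
```

The two planted 4-mers (CUUC and CACC, written as DNA) dominate the
enrichment ranking with z-scores an order of magnitude above the chance
tail, and the spacer profile peaks at the planted 5-nt spacing
(z = 11.0, enrichment 2.1x). The mRNA fold-change strata behave as a
null, as designed — targets are regulated translationally, not at the
mRNA level:

```r
res$integration$cmp$medians
#>    top   poor    non
#>  0.142  0.107 -0.011
res$integration$cmp$ks
#>    comparison statistic p_value undefined
#> 1  top_vs_non     0.177   0.378     FALSE
#> 2 poor_vs_non     0.146   0.631     FALSE
```

The report directory contains the transcript FASTA, reads (TSV, and SAM
on request), sites as BED6/TSV, the ranked target table, k-mer and
spacer enrichment tables, the discovered motif, the differential
secretion test, ECDF points, and a JSON run manifest. Identical
configuration and seed reproduce every table byte for byte. A thin CLI
wrapper lives at `inst/cli/parclipr.R`.

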