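#' Simulation configuration for the synthetic PAR-CLIP study
#'
#' Bundles every tunable of the synthetic-data generators: transcriptome
#' layout, planted tandem motif, PAR-CLIP read model, mRNA count noise and
#' secretome effect model. Defaults describe a desk-scale two-replicate
#' PAR-CLIP experiment on a 1,000-transcript transcriptome in which 30% of
#' transcripts are targets, each carrying two planted CUUC-N5-CACC tandem
#' recognition elements in the CDS.
#'
#' @param seed Integer master seed; identical seeds give bit-identical
#'   outputs from every generator.
#' @param n_transcripts Number of transcripts to simulate.
#' @param fraction_targets Proportion of transcripts designated targets.
#' @param region_lengths Integer triple: 5'UTR, CDS, 3'UTR lengths (nt).
#' @param base_composition Probabilities for A, C, G, T/U; must sum to 1.
#' @param motif_first,motif_second 4-mers (IUPAC-degenerate allowed) planted
#'   as a tandem; degenerate positions are realized per occurrence.
#' @param spacer_nt Spacer between the two tandem 4-mers (nt).
#' @param tandems_per_target Planted tandem occurrences per target.
#' @param reads_per_site Poisson mean of crosslink reads per planted site,
#'   per replicate.
#' @param background_read_rate Background reads per kilobase per transcript,
#'   per replicate.
#' @param conversion_prob Probability that a read covering a uridine inside
#'   a planted site records a T-to-C conversion there.
#' @param background_conversion_divisor Background reads convert covered
#'   uridines at `conversion_prob / background_conversion_divisor`.
#' @param read_length_mean,read_length_sd Read-length Normal parameters (nt);
#'   lengths are truncated to `read_length_range`.
#' @param read_length_range Hard bounds on simulated read lengths (nt).
#' @param n_replicates Number of PAR-CLIP replicates.
#' @param secretome_slope Knockdown log2 shift per log10(1 + crosslink reads)
#'   for target proteins (applied with negative sign: more binding, more
#'   down-regulation).
#' @param secretome_noise_sd SD of protein-level log2 noise around the true
#'   secretome shift.
#' @param lfq_samples_per_group Samples per group in the intensity matrix.
#' @param counts_dispersion Negative-binomial dispersion of the mRNA count
#'   model (`size = 1/dispersion`).
#' @param expression_depth Expected counts for a gene of unit abundance in
#'   the mRNA count model.
#' @param max_spacer Largest spacer considered downstream; `spacer_nt` must
#'   not exceed it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_transcripts = 50)
#' cfg$fraction_targets
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 1000L,
                       fraction_targets = 0.3,
                       region_lengths = c(utr5 = 100L, cds = 600L, utr3 = 300L),
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       motif_first = "CUUC",
                       motif_second = "CACC",
                       spacer_nt = 5L,
                       tandems_per_target = 2L,
                       reads_per_site = 30,
                       background_read_rate = 1,
                       conversion_prob = 0.2,
                       background_conversion_divisor = 20,
                       read_length_mean = 32,
                       read_length_sd = 6,
                       read_length_range = c(20L, 50L),
                       n_replicates = 2L,
                       secretome_slope = 0.5,
                       secretome_noise_sd = 0.2,
                       lfq_samples_per_group = 4L,
                       counts_dispersion = 0.05,
                       expression_depth = 50,
                       max_spacer = 8L) {
  cfg <- list(seed = as.integer(seed),
              n_transcripts = as.integer(n_transcripts),
              fraction_targets = fraction_targets,
              region_lengths = setNames(as.integer(region_lengths),
                                        c("utr5", "cds", "utr3")),
              base_composition = setNames(as.numeric(base_composition),
                                          c("A", "C", "G", "T")),
              motif_first = norm_seq(motif_first),
              motif_second = norm_seq(motif_second),
              spacer_nt = as.integer(spacer_nt),
              tandems_per_target = as.integer(tandems_per_target),
              reads_per_site = reads_per_site,
              background_read_rate = background_read_rate,
              conversion_prob = conversion_prob,
              background_conversion_divisor = background_conversion_divisor,
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              read_length_range = as.integer(read_length_range),
              n_replicates = as.integer(n_replicates),
              secretome_slope = secretome_slope,
              secretome_noise_sd = secretome_noise_sd,
              lfq_samples_per_group = as.integer(lfq_samples_per_group),
              counts_dispersion = counts_dispersion,
              expression_depth = expression_depth,
              max_spacer = as.integer(max_spacer))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly; errors on any violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(cfg$fraction_targets, cfg$conversion_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1")
  if (any(cfg$base_composition < 0)) stop("base_composition must be nonnegative")
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (any(cfg$region_lengths <= 0)) stop("region_lengths must be positive")
  if (nchar(cfg$motif_first) != 4 || nchar(cfg$motif_second) != 4)
    stop("tandem motif halves must be 4-mers")
  ok_iupac <- function(p) all(strsplit(p, "")[[1]] %in% names(IUPAC_SETS))
  if (!ok_iupac(cfg$motif_first) || !ok_iupac(cfg$motif_second))
    stop("motif halves must be IUPAC nucleotide codes")
  if (cfg$spacer_nt < 0) stop("spacer_nt must be >= 0")
  if (cfg$spacer_nt > cfg$max_spacer)
    stop("spacer_nt exceeds max_spacer (", cfg$max_spacer, ")")
  if (cfg$tandems_per_target < 1) stop("tandems_per_target must be >= 1")
  if (cfg$reads_per_site <= 0) stop("reads_per_site must be positive")
  if (cfg$background_read_rate < 0) stop("background_read_rate must be >= 0")
  if (cfg$background_conversion_divisor <= 0)
    stop("background_conversion_divisor must be positive")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (cfg$lfq_samples_per_group < 2)
    stop("lfq_samples_per_group must be >= 2 (within-group variance needed)")
  if (cfg$counts_dispersion < 0) stop("counts_dispersion must be >= 0")
  if (cfg$read_length_range[1] > cfg$read_length_range[2])
    stop("read_length_range must be increasing")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("PAR-CLIP simulation config\n")
  cat(sprintf("  transcripts: %d (%.0f%% targets), regions %d/%d/%d nt\n",
              x$n_transcripts, 100 * x$fraction_targets,
              x$region_lengths[1], x$region_lengths[2], x$region_lengths[3]))
  cat(sprintf("  tandem: %s-N%d-%s x%d per target\n", x$motif_first,
              x$spacer_nt, x$motif_second, x$tandems_per_target))
  cat(sprintf("  reads/site %.1f, background %.2f/kb, conversion p=%.2f, %d replicates\n",
              x$reads_per_site, x$background_read_rate, x$conversion_prob,
              x$n_replicates))
  invisible(x)
}
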