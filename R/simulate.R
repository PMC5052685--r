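## Synthetic PAR-CLIP study generator.
##
## All generators are pure functions of (cfg, replicate): they derive their
## RNG stream from cfg$seed and restore the caller's RNG state on exit.

# realize a (possibly degenerate) IUPAC pattern as one concrete oligomer
realize_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1) opts else opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

iupac_to_regex <- function(pattern) {
  chars <- strsplit(norm_seq(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, ""), collapse = "")
}

random_bases <- function(n, composition) {
  sample(names(composition), n, replace = TRUE, prob = composition)
}

#' Generate a transcriptome with planted tandem recognition elements
#'
#' Simulates `cfg$n_transcripts` mRNA transcript models (5'UTR / CDS / 3'UTR
#' of configured lengths, random sequence at the configured base
#' composition) and designates `round(fraction_targets * n)` of them as
#' targets. Each target receives `tandems_per_target` non-overlapping
#' occurrences of the tandem `motif_first + spacer + motif_second`, written
#' into random CDS positions; degenerate motif positions are realized per
#' occurrence. Non-target CDS regions are rescanned for chance occurrences
#' of the planted tandem pattern at the planted spacer and those windows are
#' resampled, so the ground truth cleanly separates targets from
#' non-targets (chance tandems at other spacings are left in, as in real
#' transcriptomes).
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{transcripts}{data frame: `id`, `sequence` (DNA alphabet),
#'       `utr5_len`, `cds_len`, `utr3_len`, `biotype`.}
#'     \item{truth}{ground-truth record: `target_ids`, `planted_sites`
#'       (data frame `transcript_id`, `start`, `end`; 0-based half-open,
#'       transcript coordinates, always inside the CDS), and
#'       `true_mrna_log2fc` (named vector, 0 for every gene by default).}
#'   }
#' @examples
#' sim <- generate_transcriptome(sim_config(seed = 7, n_transcripts = 20))
#' nrow(sim$truth$planted_sites)
#' @export
generate_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, 1L), {
    n <- cfg$n_transcripts
    rl <- cfg$region_lengths
    L <- sum(rl)
    tandem_len <- nchar(cfg$motif_first) + cfg$spacer_nt + nchar(cfg$motif_second)
    n_targets <- round(cfg$fraction_targets * n)
    ids <- sprintf("tx%05d", seq_len(n))
    target_idx <- if (n_targets > 0) sort(sample.int(n, n_targets)) else integer()

    if (n_targets > 0 && rl["cds"] < cfg$tandems_per_target * tandem_len) {
      stop("CDS too short to host ", cfg$tandems_per_target,
           " tandem(s) of ", tandem_len, " nt in transcript ", ids[target_idx[1]])
    }

    base_mat <- matrix(random_bases(n * L, cfg$base_composition), nrow = n)
    cds_start <- rl[["utr5"]]
    cds_end <- cds_start + rl[["cds"]]

    planted <- vector("list", n_targets)
    for (ti in seq_along(target_idx)) {
      i <- target_idx[ti]
      # rejection-sample non-overlapping tandem start positions in the CDS
      repeat {
        starts <- sort(cds_start +
                         sample.int(rl[["cds"]] - tandem_len + 1L,
                                    cfg$tandems_per_target) - 1L)
        if (cfg$tandems_per_target == 1 || all(diff(starts) >= tandem_len)) break
      }
      for (s in starts) {
        occ <- paste0(realize_pattern(cfg$motif_first),
                      paste(random_bases(cfg$spacer_nt, cfg$base_composition),
                            collapse = ""),
                      realize_pattern(cfg$motif_second))
        base_mat[i, (s + 1):(s + tandem_len)] <- strsplit(occ, "")[[1]]
      }
      planted[[ti]] <- data.frame(transcript_id = ids[i], start = starts,
                                  end = starts + tandem_len,
                                  stringsAsFactors = FALSE)
    }

    seqs <- apply(base_mat, 1, paste, collapse = "")

    # scrub chance planted-pattern tandems from non-target CDS windows
    tandem_re <- paste0(iupac_to_regex(cfg$motif_first),
                        ".{", cfg$spacer_nt, "}",
                        iupac_to_regex(cfg$motif_second))
    non_targets <- setdiff(seq_len(n), target_idx)
    for (i in non_targets) {
      repeat {
        cds_seq <- substr(seqs[i], cds_start + 1, cds_end)
        m <- gregexpr(paste0("(?=", tandem_re, ")"), cds_seq, perl = TRUE)[[1]]
        if (m[1] == -1) break
        for (pos in as.integer(m)) {
          abs_start <- cds_start + pos  # 1-based start in full sequence
          substr(seqs[i], abs_start, abs_start + tandem_len - 1) <-
            paste(random_bases(tandem_len, cfg$base_composition), collapse = "")
        }
      }
    }

    transcripts <- data.frame(id = ids, sequence = seqs,
                              utr5_len = rl[["utr5"]], cds_len = rl[["cds"]],
                              utr3_len = rl[["utr3"]], biotype = "mRNA",
                              stringsAsFactors = FALSE)
    planted_sites <- if (n_targets > 0) do.call(rbind, planted) else
      data.frame(transcript_id = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)
    truth <- list(target_ids = ids[target_idx],
                  planted_sites = planted_sites,
                  true_mrna_log2fc = setNames(numeric(n), ids),
                  true_secretome_log2fc = NULL)
    list(transcripts = transcripts, truth = truth)
  })
}

# draw truncated-normal read lengths, clipped to the transcript length
draw_read_lengths <- function(n, cfg, max_len) {
  len <- round(rnorm(n, cfg$read_length_mean, cfg$read_length_sd))
  len <- pmin(pmax(len, cfg$read_length_range[1]), cfg$read_length_range[2])
  as.integer(pmin(len, max_len))
}

#' Simulate one PAR-CLIP replicate
#'
#' Produces transcriptome-aligned reads with explicit mismatch records.
#' Each planted site receives `Poisson(reads_per_site)` reads whose spans
#' cover the site midpoint; every uridine (T) the read covers inside any
#' planted interval of its transcript is converted T-to-C independently
#' with `conversion_prob`. Each transcript additionally receives
#' `Poisson(background_read_rate * length / 1000)` uniformly placed
#' background reads whose covered uridines convert at the reduced rate
#' `conversion_prob / background_conversion_divisor`.
#'
#' @param transcripts Transcript table from [generate_transcriptome()].
#' @param truth Matching ground-truth record.
#' @param cfg The [sim_config()] used for generation.
#' @param replicate Replicate index in `[1, cfg$n_replicates]`; enters the
#'   RNG stream so replicates are independent but reproducible.
#' @return Data frame of aligned reads: `transcript_id`, `start`, `end`
#'   (0-based half-open), `mismatches` ("pos:ref>alt;..." with 0-based
#'   transcript positions, "" if none), `replicate`.
#' @export
simulate_parclip_replicate <- function(transcripts, truth, cfg, replicate = 1L) {
  validate_sim_config(cfg)
  if (nrow(transcripts) == 0) stop("empty transcript list")
  replicate <- as.integer(replicate)
  if (replicate < 1 || replicate > cfg$n_replicates)
    stop("replicate must lie in [1, n_replicates]")

  with_seed(child_seed(cfg$seed, 100L + replicate), {
    seq_by_id <- setNames(transcripts$sequence, transcripts$id)
    len_by_id <- setNames(nchar(transcripts$sequence), transcripts$id)
    # T positions per transcript, 0-based, sorted
    t_pos <- lapply(seq_by_id, function(s) {
      which(strsplit(s, "")[[1]] == "T") - 1L
    })

    out_tx <- character(); out_s <- integer(); out_e <- integer()
    ev_read <- integer(); ev_pos <- integer()
    n_out <- 0L

    ps <- truth$planted_sites
    if (nrow(ps) > 0) {
      # uridines inside any planted interval, per transcript: a bound
      # fragment converts every planted-site T it covers, so estimates of
      # the conversion rate from pooled coverage are unbiased
      planted_t <- lapply(split(ps, ps$transcript_id), function(d) {
        tp <- t_pos[[d$transcript_id[1]]]
        tp[vapply(tp, function(p) any(p >= d$start & p < d$end), TRUE)]
      })
      n_reads <- rpois(nrow(ps), cfg$reads_per_site)
      for (k in seq_len(nrow(ps))) {
        nk <- n_reads[k]
        if (nk == 0) next
        tx <- ps$transcript_id[k]
        L <- len_by_id[[tx]]
        mid <- (ps$start[k] + ps$end[k]) %/% 2L
        len <- draw_read_lengths(nk, cfg, L)
        off <- floor(runif(nk) * len)          # offset of midpoint in read
        s <- pmax(0L, pmin(as.integer(mid - off), L - len))
        e <- s + len
        # candidate conversion positions: planted-interval Ts the read covers
        tp <- planted_t[[tx]]
        if (length(tp) > 0) {
          covered <- outer(s, tp, "<=") & outer(e, tp, ">")
          conv <- covered & matrix(rbinom(nk * length(tp), 1,
                                          cfg$conversion_prob) == 1,
                                   nrow = nk)
          idx <- which(conv, arr.ind = TRUE)
          if (nrow(idx) > 0) {
            ev_read <- c(ev_read, n_out + idx[, 1])
            ev_pos <- c(ev_pos, tp[idx[, 2]])
          }
        }
        out_tx <- c(out_tx, rep(tx, nk)); out_s <- c(out_s, s)
        out_e <- c(out_e, e); n_out <- n_out + nk
      }
    }

    # background reads
    bg_rate <- cfg$conversion_prob / cfg$background_conversion_divisor
    n_bg <- rpois(nrow(transcripts),
                  cfg$background_read_rate * nchar(transcripts$sequence) / 1000)
    for (i in which(n_bg > 0)) {
      tx <- transcripts$id[i]
      L <- len_by_id[[tx]]
      nk <- n_bg[i]
      len <- draw_read_lengths(nk, cfg, L)
      s <- as.integer(floor(runif(nk) * (L - len + 1L)))
      e <- s + len
      if (bg_rate > 0) {
        tp <- t_pos[[tx]]
        for (j in seq_len(nk)) {
          lo <- findInterval(s[j] - 0.5, tp) + 1L
          hi <- findInterval(e[j] - 0.5, tp)
          if (hi >= lo) {
            cand <- tp[lo:hi]
            hit <- cand[rbinom(length(cand), 1, bg_rate) == 1]
            if (length(hit) > 0) {
              ev_read <- c(ev_read, rep(n_out + j, length(hit)))
              ev_pos <- c(ev_pos, hit)
            }
          }
        }
      }
      out_tx <- c(out_tx, rep(tx, nk)); out_s <- c(out_s, s)
      out_e <- c(out_e, e); n_out <- n_out + nk
    }

    events <- data.frame(read = ev_read, pos = ev_pos,
                         ref = rep("T", length(ev_read)),
                         alt = rep("C", length(ev_read)),
                         stringsAsFactors = FALSE)
    reads <- data.frame(transcript_id = out_tx, start = out_s, end = out_e,
                        mismatches = format_mismatches(events, n_out),
                        replicate = replicate, stringsAsFactors = FALSE)
    ord <- order(reads$transcript_id, reads$start, reads$end, reads$mismatches)
    reads <- reads[ord, , drop = FALSE]
    rownames(reads) <- NULL
    reads
  })
}

#' Simulate a gene-level mRNA fold-change table
#'
#' Draws per-gene abundances (log-normal, FPKM-like), simulates one
#' negative-binomial count per condition at dispersion
#' `cfg$counts_dispersion` (Poisson when 0), applies each gene's true log2
#' fold change to the perturbed condition, and reports the observed
#' shrunken log2 ratio. Targets have true fold change exactly 0 by
#' construction, mirroring a regulator that acts translationally rather
#' than on mRNA abundance.
#'
#' @param truth Ground-truth record (uses `true_mrna_log2fc`).
#' @param cfg A [sim_config()].
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   FPKM-like abundance distribution.
#' @return Data frame: `gene`, `log2fc` (observed), `mean_abundance`.
#' @export
simulate_expression <- function(truth, cfg,
                                abundance_meanlog = log(20),
                                abundance_sdlog = 1.2) {
  validate_sim_config(cfg)
  genes <- names(truth$true_mrna_log2fc)
  if (length(genes) == 0) stop("ground truth has no genes")
  with_seed(child_seed(cfg$seed, 300L), {
    n <- length(genes)
    abundance <- rlnorm(n, abundance_meanlog, abundance_sdlog)
    mu_ctrl <- cfg$expression_depth * abundance
    mu_pert <- mu_ctrl * 2^truth$true_mrna_log2fc
    draw <- function(mu) {
      if (cfg$counts_dispersion < 1e-12) rpois(n, mu)
      else rnbinom(n, size = 1 / cfg$counts_dispersion, mu = mu)
    }
    k_ctrl <- draw(mu_ctrl)
    k_pert <- draw(mu_pert)
    data.frame(gene = genes,
               log2fc = log2((k_pert + 0.5) / (k_ctrl + 0.5)),
               mean_abundance = abundance,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a secretome label-free intensity matrix
#'
#' Control-group intensities are log-normal around a per-protein baseline.
#' In the knockdown group, every protein receives a log2 shift of
#' `Normal(0, secretome_noise_sd)` (protein-level noise) and targets are
#' additionally shifted by `-secretome_slope * log10(1 + crosslink_reads)`
#' (non-targets have expected shift 0). All samples also carry independent
#' log2 measurement noise of the same SD, so more frequently crosslinked
#' targets are more strongly down-regulated on average and a zero slope
#' leaves targets and non-targets exchangeable.
#'
#' @param truth Ground-truth record (uses `target_ids`).
#' @param crosslink_reads Named nonnegative integer vector, protein ->
#'   total crosslinked read count.
#' @param cfg A [sim_config()].
#' @param baseline_mean,baseline_sd Per-protein baseline log2-intensity
#'   Normal parameters.
#' @return A list: `intensities` (raw-scale matrix, proteins x samples),
#'   `log2_intensities`, `groups` (factor "control"/"knockdown" per
#'   sample), `true_log2fc` (named, the realized protein-level shifts).
#' @export
simulate_secretome <- function(truth, crosslink_reads, cfg,
                               baseline_mean = 23, baseline_sd = 2) {
  validate_sim_config(cfg)
  if (any(crosslink_reads < 0)) stop("crosslink_reads must be nonnegative")
  if (is.null(names(crosslink_reads)) || anyNA(names(crosslink_reads)))
    stop("crosslink_reads must be a named vector")
  if (cfg$lfq_samples_per_group < 2)
    stop("lfq_samples_per_group must be >= 2")
  with_seed(child_seed(cfg$seed, 400L), {
    proteins <- names(crosslink_reads)
    n <- length(proteins)
    k <- cfg$lfq_samples_per_group
    is_target <- proteins %in% truth$target_ids
    # deterministic dose-response for targets plus protein-level noise for
    # every protein, so a null slope leaves targets and non-targets
    # exchangeable
    shift <- rnorm(n, 0, cfg$secretome_noise_sd)
    shift[is_target] <- shift[is_target] - cfg$secretome_slope *
      log10(1 + crosslink_reads[is_target])
    baseline <- rnorm(n, baseline_mean, baseline_sd)
    noise <- matrix(rnorm(n * 2 * k, 0, cfg$secretome_noise_sd), nrow = n)
    log2_mat <- baseline + noise +
      cbind(matrix(0, n, k), matrix(shift, n, k))
    groups <- factor(rep(c("control", "knockdown"), each = k),
                     levels = c("control", "knockdown"))
    colnames(log2_mat) <- paste0(rep(c("ctrl_", "kd_"), each = k),
                                 rep(seq_len(k), 2))
    rownames(log2_mat) <- proteins
    list(intensities = 2^log2_mat,
         log2_intensities = log2_mat,
         groups = groups,
         true_log2fc = setNames(shift, proteins))
  })
}
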