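## End-to-end pipeline: simulate -> sites -> motif -> integrate.
## Every stage writes plain TSV/BED/FASTA outputs into one report
## directory, plus a JSON manifest with seed, versions and record counts.
## Identical config + seed gives byte-identical table outputs.

#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration: one block per stage
#' (`sim` mirrors [sim_config()], `sites` mirrors [site_params()], `motif`
#' and `integrate` hold their stage parameters), plus the global `seed`
#' and `log_level`. A YAML file with the same nesting can override any
#' subset of keys; unknown keys are rejected.
#'
#' @param seed Global seed.
#' @return Nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    log_level = "info",
    sim = list(),            # overrides for sim_config()
    sites = list(),          # overrides for site_params()
    motif = list(k = 4L, window = 20L, n_shuffles = 1000L,
                 background_orfs = 100L, top_n_kmers = 4L,
                 max_spacer = 8L, cluster_flank = 20L),
    integrate = list(top_n = 100L, expression_floor = 2, s0 = 0.5,
                     n_perm = 250L, fdr = 0.01, min_reads = 4L,
                     missing_cap = 0.5)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# recursive override with unknown-key rejection
merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    full <- paste0(path, k)
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        length(base[[k]]) > 0) {
      if (!is.list(override[[k]])) stop("config key ", full, " must be a block")
      base[[k]] <- merge_config(base[[k]], override[[k]], paste0(full, "."))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()]. Unknown keys
#'   raise an error.
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  # sim/sites blocks default empty: accept any key their constructors know
  cfg <- base
  for (k in names(raw)) {
    if (!k %in% names(base)) stop("unknown config key: ", k)
  }
  cfg <- merge_config_outer(base, raw)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config_outer <- function(base, raw) {
  for (k in names(raw)) {
    if (k %in% c("sim", "sites")) {
      allowed <- names(formals(if (k == "sim") sim_config else site_params))
      bad <- setdiff(names(raw[[k]]), allowed)
      if (length(bad)) stop("unknown config key: ", k, ".", bad[1])
      base[[k]] <- raw[[k]]
    } else if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], raw[[k]], paste0(k, "."))
    } else {
      base[[k]] <- raw[[k]]
    }
  }
  base
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message("[", level, "] ", ...)
}

# extract cluster sequences around intervals, with flank, clipped
interval_sequences <- function(intervals, transcripts, flank = 0L) {
  seqs <- setNames(transcripts$sequence, transcripts$id)
  L <- nchar(seqs[intervals$transcript_id])
  a <- pmax(intervals$start - flank, 0L)
  b <- pmin(intervals$end + flank, L)
  substr(seqs[intervals$transcript_id], a + 1L, b)
}

#' Run the full analysis pipeline
#'
#' Chains the four stages - synthetic data generation, binding-site
#' calling with replicate filtering and target ranking, motif and
#' tandem-spacer discovery, and secretome/transcriptome integration - and
#' writes all outputs plus a JSON run manifest into `outdir`.
#'
#' @param config A `pipeline_config` ([pipeline_config()] /
#'   [load_pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @param dialect Read export format: "tsv" (default) or "sam" (also
#'   writes SAM next to the TSVs).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         dialect = c("tsv", "sam")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage 1: simulate
  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  res <- stage("simulate", {
    sim <- generate_transcriptome(cfg)
    reads <- lapply(seq_len(cfg$n_replicates), function(r)
      simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, r))
    expr_tab <- simulate_expression(sim$truth, cfg)
    list(sim = sim, reads = reads, expr = expr_tab)
  })
  log_msg(config, "info", "simulated ", nrow(res$sim$transcripts),
          " transcripts, ", sum(vapply(res$reads, nrow, 0L)), " reads")
  write_transcripts_fasta(res$sim$transcripts, file.path(outdir, "transcripts.fa"))
  write_regions_tsv(res$sim$transcripts, file.path(outdir, "regions.tsv"))
  write_truth_tsv(res$sim$truth, file.path(outdir, "truth_sites.tsv"))
  for (r in seq_along(res$reads)) {
    write_reads_tsv(res$reads[[r]],
                    file.path(outdir, sprintf("reads_rep%d.tsv", r)))
    if (dialect == "sam")
      write_reads_sam(res$reads[[r]], res$sim$transcripts,
                      file.path(outdir, sprintf("reads_rep%d.sam", r)))
  }
  write_tsv_with_header(res$expr, file.path(outdir, "expression.tsv"),
                        "# log2fc: perturbed vs control; mean_abundance: FPKM-like")
  counts$transcripts <- nrow(res$sim$transcripts)
  counts$reads <- vapply(res$reads, nrow, 0L)

  ## stage 2: sites
  params <- do.call(site_params, config$sites)
  sites_out <- stage("sites", {
    per_rep <- lapply(res$reads, call_sites, transcripts = res$sim$transcripts,
                      params = params)
    per_rep <- lapply(per_rep, annotate_region, transcripts = res$sim$transcripts)
    repl <- if (length(per_rep) >= 2)
      intersect_replicates(per_rep[[1]], per_rep[[2]])
    else { x <- per_rep[[1]]; x$replicates_supporting <- "1"; x }
    targets <- summarize_targets(res$reads, repl,
                                 min_reads = config$integrate$min_reads,
                                 transcripts = res$sim$transcripts)
    meta <- metagene_profile(repl, res$sim$transcripts)
    list(per_rep = per_rep, replicated = repl, targets = targets, meta = meta)
  })
  log_msg(config, "info", nrow(sites_out$replicated), " replicated sites on ",
          length(unique(sites_out$replicated$transcript_id)), " transcripts")
  for (r in seq_along(sites_out$per_rep))
    write_tsv_with_header(sites_out$per_rep[[r]],
                          file.path(outdir, sprintf("sites_rep%d.tsv", r)))
  write_tsv_with_header(sites_out$replicated,
                        file.path(outdir, "sites_replicated.tsv"))
  write_sites_bed(sites_out$replicated,
                  file.path(outdir, "sites_replicated.bed"))
  write_tsv_with_header(sites_out$targets, file.path(outdir, "targets.tsv"),
                        "# targets ranked by total crosslinked reads over replicates")
  meta_df <- as.data.frame(sites_out$meta$profile)
  names(meta_df) <- paste0("bin", seq_len(ncol(meta_df)))
  meta_df <- cbind(region = rownames(sites_out$meta$profile), meta_df)
  write_tsv_with_header(meta_df, file.path(outdir, "metagene.tsv"),
                        "# per-region positional density of site midpoints; rows sum to 1")
  counts$sites_per_replicate <- vapply(sites_out$per_rep, nrow, 0L)
  counts$replicated_sites <- nrow(sites_out$replicated)
  counts$targets_passing <- sum(sites_out$targets$passes_min_filter)

  ## stage 3: motif
  mo <- config$motif
  motif_out <- stage("motif", {
    if (nrow(sites_out$replicated) == 0) {
      log_msg(config, "warn", "no replicated sites; motif stage skipped")
      NULL
    } else {
      cluster_seqs <- interval_sequences(sites_out$replicated,
                                         res$sim$transcripts,
                                         flank = mo$cluster_flank)
      tr <- res$sim$transcripts
      cds <- substr(tr$sequence, tr$utr5_len + 1L, tr$utr5_len + tr$cds_len)
      with_seed(child_seed(config$seed, 21L), {
        bg_set <- cds[sample.int(length(cds), min(mo$background_orfs,
                                                  length(cds)))]
        bg <- shuffle_sequences(bg_set, mo$n_shuffles,
                                seed = child_seed(config$seed, 22L))
        enr <- kmer_enrichment(cluster_seqs, bg, k = mo$k, window = mo$window,
                               seed = child_seed(config$seed, 23L))
        motif <- collapse_kmers_to_iupac(enr$kmer[seq_len(mo$top_n_kmers)])
        cl_bg <- shuffle_sequences(cluster_seqs, mo$n_shuffles,
                                   seed = child_seed(config$seed, 24L))
        spacer <- tandem_spacer_enrichment(cluster_seqs, motif, cl_bg,
                                           max_spacer = mo$max_spacer)
        list(enrichment = enr, motif = motif, spacer = spacer)
      })
    }
  })
  if (!is.null(motif_out)) {
    write_tsv_with_header(motif_out$enrichment,
                          file.path(outdir, "kmer_enrichment.tsv"),
                          "# 4-mer sliding-window enrichment vs shuffled CDS background")
    write_tsv_with_header(motif_out$spacer,
                          file.path(outdir, "spacer_enrichment.tsv"),
                          "# tandem-motif pairs per spacer vs shuffled cluster background")
    writeLines(motif_out$motif$pattern, file.path(outdir, "motif.txt"))
    counts$top_kmer <- motif_out$enrichment$kmer[1]
    counts$motif <- motif_out$motif$pattern
  }

  ## stage 4: integrate
  it <- config$integrate
  integ <- stage("integrate", {
    targets <- sites_out$targets
    reads_per_protein <- setNames(rep(0L, nrow(res$sim$transcripts)),
                                  res$sim$transcripts$id)
    reads_per_protein[targets$transcript_id] <- targets$total_tc_reads
    sec <- simulate_secretome(res$sim$truth, reads_per_protein, cfg)
    norm <- median_normalize(filter_missing_proteins(sec$intensities,
                                                     it$missing_cap))
    sam <- sam_permutation_test(log2(norm), sec$groups, s0 = it$s0,
                                n_perm = it$n_perm, fdr = it$fdr,
                                seed = child_seed(config$seed, 31L))
    strata <- stratify_by_crosslink(targets, res$expr, top_n = it$top_n,
                                    expression_floor = it$expression_floor)
    cmp <- tryCatch(ecdf_compare(strata), error = function(e) NULL)
    passing <- targets$transcript_id[targets$passes_min_filter]
    corr <- if (length(passing) >= 3) {
      lfc <- sam$log2fc[match(passing, sam$protein)]
      tryCatch(correlate_regulation(lfc, reads_per_protein[passing]),
               error = function(e) NULL)
    } else NULL
    if (is.null(corr))
      log_msg(config, "warn",
              "too few passing targets; crosslink-regulation correlation skipped")
    list(sam = sam, strata = strata, cmp = cmp, corr = corr,
         secretome = sec)
  })
  write_tsv_with_header(integ$sam, file.path(outdir, "secretome_test.tsv"),
                        "# SAM-style permutation test, knockdown vs control log2 intensities")
  write_tsv_with_header(integ$strata, file.path(outdir, "strata.tsv"),
                        "# mRNA log2 fold changes stratified by crosslink rank")
  if (!is.null(integ$cmp)) {
    ecdf_pts <- do.call(rbind, lapply(names(integ$cmp$ecdfs), function(s) {
      v <- sort(integ$strata$log2fc[integ$strata$stratum == s])
      data.frame(stratum = s, log2fc = v, ecdf = integ$cmp$ecdfs[[s]](v))
    }))
    write_tsv_with_header(ecdf_pts, file.path(outdir, "ecdf_points.tsv"),
                          "# empirical CDF of mRNA log2fc per stratum")
  }
  corr_df <- if (!is.null(integ$corr)) {
    data.frame(pearson_r = integ$corr$r, p_value = integ$corr$p_value,
               n = integ$corr$n)
  } else data.frame(pearson_r = NA_real_, p_value = NA_real_, n = 0L)
  write_tsv_with_header(corr_df, file.path(outdir, "correlation.tsv"),
                        "# Pearson r of secretion log2fc vs log10(1 + crosslinked reads)")
  counts$significant_proteins <- sum(integ$sam$significant)

  ## manifest + resolved config
  manifest <- list(seed = config$seed,
                   package = "parclipr",
                   version = as.character(utils::packageVersion("parclipr")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  resolved <- unclass(config)
  yaml::write_yaml(resolved, file.path(outdir, "config_resolved.yaml"))
  log_msg(config, "info", "pipeline complete: ", outdir)
  invisible(list(sim = res$sim, reads = res$reads, expr = res$expr,
                 sites = sites_out, motif = motif_out, integration = integ,
                 manifest = manifest))
}
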