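test_that("planted target and interval counts follow the configuration", {
  cfg <- sim_config(seed = 2, n_transcripts = 10, fraction_targets = 0.3,
                    tandems_per_target = 2)
  sim <- generate_transcriptome(cfg)
  expect_length(sim$truth$target_ids, 3)
  expect_equal(nrow(sim$truth$planted_sites), 6)
  counts <- table(sim$truth$planted_sites$transcript_id)
  expect_true(all(counts == 2))

  cfg2 <- sim_config(seed = 2, n_transcripts = 10, spacer_nt = 5,
                     motif_first = "CUUC", motif_second = "CACC")
  sim2 <- generate_transcriptome(cfg2)
  expect_true(all(sim2$truth$planted_sites$end -
                    sim2$truth$planted_sites$start == 13))
})

test_that("planted intervals sit inside the CDS and carry the motif", {
  cfg <- sim_config(seed = 9, n_transcripts = 40)
  sim <- generate_transcriptome(cfg)
  ps <- sim$truth$planted_sites
  cds_start <- cfg$region_lengths[["utr5"]]
  cds_end <- cds_start + cfg$region_lengths[["cds"]]
  expect_true(all(ps$start >= cds_start & ps$end <= cds_end))
  seqs <- setNames(sim$transcripts$sequence, sim$transcripts$id)
  planted_seq <- substr(seqs[ps$transcript_id], ps$start + 1, ps$end)
  expect_true(all(grepl("^CTTC.{5}CACC$", planted_seq)))
  expect_equal(unname(sim$truth$true_mrna_log2fc[sim$truth$target_ids]),
               rep(0, length(sim$truth$target_ids)))
})

test_that("non-target CDS carries no planted tandem; chance tandems at other spacers match composition", {
  cfg <- sim_config(seed = 4, n_transcripts = 1000, fraction_targets = 0)
  sim <- generate_transcriptome(cfg)
  cds <- substr(sim$transcripts$sequence, cfg$region_lengths[["utr5"]] + 1,
                cfg$region_lengths[["utr5"]] + cfg$region_lengths[["cds"]])
  hits_planted <- sum(vapply(cds, function(s)
    length(gregexpr("(?=CTTC.{5}CACC)", s, perl = TRUE)[[1]][
      gregexpr("(?=CTTC.{5}CACC)", s, perl = TRUE)[[1]] > 0]), 0L,
    USE.NAMES = FALSE))
  expect_identical(hits_planted, 0L)
  # a different spacer is untouched: brute-force count over the 1,000
  # non-targets should match the analytic chance rate for an 8-base exact
  # tandem under uniform composition, p = (1/4)^8 per eligible position
  n_hits <- sum(vapply(cds, function(s) {
    m <- gregexpr("(?=CTTC.{3}CACC)", s, perl = TRUE)[[1]]
    sum(m > 0)
  }, 0L, USE.NAMES = FALSE))
  eligible <- 1000 * (cfg$region_lengths[["cds"]] - 11 + 1)
  expected <- eligible * (1 / 4)^8
  expect_lt(abs(n_hits - expected), 3 * sqrt(expected) + 3)
})

test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_config(seed = 77, n_transcripts = 30)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a, b)
  r1a <- simulate_parclip_replicate(a$transcripts, a$truth, cfg, 1)
  r1b <- simulate_parclip_replicate(b$transcripts, b$truth, cfg, 1)
  expect_identical(r1a, r1b)
  r2 <- simulate_parclip_replicate(a$transcripts, a$truth, cfg, 2)
  expect_false(identical(r1a, r2))
  expect_identical(simulate_expression(a$truth, cfg),
                   simulate_expression(a$truth, cfg))
  reads <- setNames(rep(10L, 30), a$transcripts$id)
  expect_identical(simulate_secretome(a$truth, reads, cfg),
                   simulate_secretome(a$truth, reads, cfg))
})

test_that("reads respect transcript bounds and mismatch positions lie in their spans", {
  for (s in c(3, 14)) {
    cfg <- sim_config(seed = s, n_transcripts = 25)
    sim <- generate_transcriptome(cfg)
    reads <- simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, 1)
    expect_silent(parclipr:::validate_reads(reads, sim$transcripts))
    L <- setNames(nchar(sim$transcripts$sequence), sim$transcripts$id)
    expect_true(all(reads$start >= 0 & reads$end <= L[reads$transcript_id]))
    rl <- reads$end - reads$start
    expect_true(all(rl >= cfg$read_length_range[1] &
                      rl <= cfg$read_length_range[2]))
  }
})

test_that("conversion_prob = 0 yields no conversions at planted positions", {
  cfg <- sim_config(seed = 5, n_transcripts = 20, conversion_prob = 0)
  sim <- generate_transcriptome(cfg)
  reads <- simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, 1)
  ev <- parclipr:::parse_mismatches(reads$mismatches)
  expect_identical(nrow(ev[ev$ref == "T" & ev$alt == "C", ]), 0L)
})

test_that("pooled site reads recover the configured conversion probability", {
  cfg <- sim_config(seed = 8, n_transcripts = 60, conversion_prob = 0.2,
                    reads_per_site = 40, background_read_rate = 0)
  sim <- generate_transcriptome(cfg)
  reads <- simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, 1)
  expect_gt(nrow(reads), 1000)
  # binomial oracle: over covered planted-T positions, the converted
  # fraction estimates conversion_prob
  ps <- sim$truth$planted_sites
  seqs <- setNames(sim$transcripts$sequence, sim$transcripts$id)
  n_cov <- 0; n_conv <- 0
  ev <- parclipr:::parse_mismatches(reads$mismatches)
  conv_key <- paste(reads$transcript_id[ev$read], ev$pos)
  conv_by_read <- split(ev$pos, ev$read)
  for (i in seq_len(nrow(reads))) {
    tx <- reads$transcript_id[i]
    sites <- ps[ps$transcript_id == tx, , drop = FALSE]
    for (j in seq_len(nrow(sites))) {
      lo <- max(reads$start[i], sites$start[j])
      hi <- min(reads$end[i], sites$end[j])
      if (hi <= lo) next
      span <- substr(seqs[tx], lo + 1, hi)
      tpos <- lo + which(strsplit(span, "")[[1]] == "T") - 1L
      n_cov <- n_cov + length(tpos)
      cb <- conv_by_read[[as.character(i)]]
      n_conv <- n_conv + sum(tpos %in% cb)
    }
  }
  p_hat <- n_conv / n_cov
  se <- sqrt(0.2 * 0.8 / n_cov)
  expect_lt(abs(p_hat - 0.2), 3 * se + 1e-9)
  expect_lt(abs(p_hat - 0.2), 0.02)
})

test_that("expression table is null for targets and nearly noiseless at tiny dispersion", {
  cfg <- sim_config(seed = 6, n_transcripts = 500, counts_dispersion = 0,
                    expression_depth = 2e5)
  sim <- generate_transcriptome(cfg)
  tab <- simulate_expression(sim$truth, cfg, abundance_meanlog = log(50),
                             abundance_sdlog = 0.3)
  expect_true(all(abs(tab$log2fc[tab$gene %in% sim$truth$target_ids]) < 0.05))
})

test_that("observed fold-change dispersion matches a resampling oracle", {
  cfg <- sim_config(seed = 10, n_transcripts = 2000, counts_dispersion = 0.05)
  sim <- generate_transcriptome(cfg)
  tab <- simulate_expression(sim$truth, cfg)
  med_obs <- median(abs(tab$log2fc[tab$gene %in% sim$truth$target_ids]))
  # independent resampling oracle with the same generative law
  set.seed(999)
  ab <- rlnorm(20000, log(20), 1.2)
  mu <- cfg$expression_depth * ab
  k1 <- rnbinom(20000, size = 1 / 0.05, mu = mu)
  k2 <- rnbinom(20000, size = 1 / 0.05, mu = mu)
  med_oracle <- median(abs(log2((k1 + 0.5) / (k2 + 0.5))))
  expect_lt(abs(med_obs - med_oracle), 0.03)
})

test_that("secretome shifts follow the crosslink-read dose-response", {
  cfg <- sim_config(seed = 3, secretome_slope = 0.5, secretome_noise_sd = 0.2)
  truth <- list(target_ids = sprintf("t%03d", 1:300),
                true_mrna_log2fc = setNames(numeric(600),
                                            c(sprintf("t%03d", 1:300),
                                              sprintf("n%03d", 1:300))))
  set.seed(21)
  reads <- setNames(c(round(rlnorm(300, log(60), 1.8)), rep(0L, 300)),
                    names(truth$true_mrna_log2fc))
  sec <- simulate_secretome(truth, reads, cfg)
  obs_shift <- rowMeans(sec$log2_intensities[, sec$groups == "knockdown"]) -
    rowMeans(sec$log2_intensities[, sec$groups == "control"])
  tgt <- truth$target_ids
  r <- cor(obs_shift[tgt], log10(1 + reads[tgt]))
  expect_lte(r, -0.8)

  # zero-read target: with no protein-level noise the true shift is exactly 0
  cfg0 <- sim_config(seed = 3, secretome_noise_sd = 0)
  reads0 <- reads; reads0["t001"] <- 0L
  sec0 <- simulate_secretome(truth, reads0, cfg0)
  expect_identical(unname(sec0$true_log2fc["t001"]), 0)
  expect_identical(unname(sec0$true_log2fc["n001"]), 0)
})

test_that("a null secretome slope leaves targets indistinguishable from non-targets", {
  ps <- replicate(20, {
    s <- sample.int(1e6, 1)
    cfg <- sim_config(seed = s, secretome_slope = 0)
    ids <- c(sprintf("t%03d", 1:250), sprintf("n%03d", 1:250))
    truth <- list(target_ids = ids[1:250],
                  true_mrna_log2fc = setNames(numeric(500), ids))
    reads <- setNames(c(round(rlnorm(250, log(60), 1.8)), rep(0L, 250)), ids)
    sec <- simulate_secretome(truth, reads, cfg)
    shift <- rowMeans(sec$log2_intensities[, sec$groups == "knockdown"]) -
      rowMeans(sec$log2_intensities[, sec$groups == "control"])
    suppressWarnings(ks.test(shift[1:250], shift[251:500])$p.value)
  })
  expect_gt(median(ps), 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(base_composition = c(0.5, 0.5, 0.2, 0)), "sum to 1")
  expect_error(sim_config(conversion_prob = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(spacer_nt = 9), "max_spacer")
  expect_error(sim_config(lfq_samples_per_group = 1), ">= 2")
  cfg <- sim_config(seed = 1, n_transcripts = 5,
                    region_lengths = c(50, 20, 50), tandems_per_target = 2)
  expect_error(generate_transcriptome(cfg), "CDS too short")
  sim <- generate_transcriptome(sim_config(seed = 1, n_transcripts = 5))
  expect_error(simulate_parclip_replicate(sim$transcripts[0, ], sim$truth,
                                          sim_config(seed = 1), 1),
               "empty transcript list")
  expect_error(simulate_secretome(sim$truth, setNames(-1L, "x"),
                                  sim_config(seed = 1)), "nonnegative")
})
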