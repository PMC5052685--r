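# small hand fixtures -------------------------------------------------------

toy_transcript <- function(id = "tx1", u5 = 10, cds = 300, u3 = 90,
                           seed = 1, biotype = "mRNA") {
  set.seed(seed)
  data.frame(id = id, sequence = random_seq(u5 + cds + u3),
             utr5_len = u5, cds_len = cds, utr3_len = u3,
             biotype = biotype, stringsAsFactors = FALSE)
}

mk_reads <- function(tx, start, end, mm = "", replicate = 1L) {
  data.frame(transcript_id = tx, start = as.integer(start),
             end = as.integer(end), mismatches = mm,
             replicate = replicate, stringsAsFactors = FALSE)
}

test_that("conversion profiles accumulate depth and classify mismatches", {
  tr <- toy_transcript()
  substr(tr$sequence, 13, 13) <- "T"
  r <- mk_reads("tx1", 10, 30, "12:T>C")
  p <- profile_conversions(r, tr)
  expect_equal(p$depth[11:30], rep(1L, 20))
  expect_equal(sum(p$depth), 20L)
  expect_equal(p$tc_events[13], 1L)
  expect_equal(sum(p$tc_events), 1L)

  r2 <- mk_reads("tx1", 10, 30, "12:G>A")
  p2 <- profile_conversions(r2, tr)
  expect_equal(sum(p2$tc_events), 0L)
  expect_equal(p2$other_mismatches[13], 1L)

  expect_error(profile_conversions(mk_reads("tx1", 390, 410), tr),
               "outside transcript")
  expect_error(profile_conversions(mk_reads("tx2", 0, 10), tr),
               "different transcript")
})

test_that("profile of 500 simulated reads equals a brute-force recount", {
  cfg <- sim_config(seed = 30, n_transcripts = 6, fraction_targets = 1,
                    reads_per_site = 40, background_read_rate = 10)
  sim <- generate_transcriptome(cfg)
  reads <- simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, 1)
  expect_gt(nrow(reads), 300)
  for (tx in unique(reads$transcript_id)) {
    rr <- reads[reads$transcript_id == tx, , drop = FALSE]
    tr <- sim$transcripts[sim$transcripts$id == tx, , drop = FALSE]
    got <- profile_conversions(rr, tr)
    want <- oracle_profile(rr, tr)
    expect_identical(got$depth, want$depth)
    expect_identical(got$tc_events, want$tc_events)
    expect_identical(got$other_mismatches, want$other_mismatches)
  }
})

test_that("clusters are maximal overlap unions with a read-count floor", {
  r <- mk_reads("tx1", c(0, 15, 100), c(20, 35, 120))
  cl2 <- build_clusters(r, min_reads = 2)
  expect_equal(nrow(cl2), 1)
  expect_equal(c(cl2$start, cl2$end), c(0, 35))
  cl1 <- build_clusters(r, min_reads = 1)
  expect_equal(nrow(cl1), 2)
  expect_equal(cl1$start, c(0, 100))
  expect_equal(cl1$end, c(35, 120))
  expect_equal(nrow(build_clusters(r[0, ], 1)), 0)
  # adjacency without a shared base does not merge (half-open intervals)
  r2 <- mk_reads("tx1", c(0, 20), c(20, 40))
  expect_equal(nrow(build_clusters(r2, 1)), 2)
})

test_that("clusters of 1,000 random reads match the boolean-coverage oracle", {
  set.seed(404)
  reads <- random_reads(1000, c("a", "b", "c"), tx_len = 600)
  for (mr in c(1L, 3L)) {
    got <- build_clusters(reads, mr)
    want <- oracle_clusters(reads, mr)
    expect_identical(got, want)
  }
})

test_that("site calling concentrates on the conversion-dense interval", {
  tr <- toy_transcript(cds = 300)
  # 20 reads tiling [0, 100); conversions only at positions 48..52
  sq <- strsplit(tr$sequence, "")[[1]]
  sq[49:53] <- "T"
  tr$sequence <- paste(sq, collapse = "")
  starts <- rep(seq(0, 60, length.out = 10), 2)
  reads <- mk_reads("tx1", starts, starts + 40)
  conv_pos <- 48:52
  for (i in seq_len(nrow(reads))) {
    p <- conv_pos[conv_pos >= reads$start[i] & conv_pos < reads$end[i]]
    if (length(p)) reads$mismatches[i] <- paste(paste0(p, ":T>C"),
                                                collapse = ";")
  }
  prof <- parclipr:::profile_with_tmask(reads, tr)
  sites <- call_binding_sites(reads, prof, site_params(min_cluster_reads = 5))
  expect_equal(nrow(sites), 1)
  expect_true(sites$start <= 50 && sites$end > 50)
  expect_gte(sites$end - sites$start, site_params()$min_site_len)

  # KDE agrees with an independent dense-grid evaluation at the peak
  dense <- function(g, pos, w, bw) sum(w * dnorm(g, pos, bw)) / sum(w)
  ev <- parclipr:::parse_mismatches(reads$mismatches)
  tcw <- table(ev$pos)
  at50 <- dense(50, as.numeric(names(tcw)), as.numeric(tcw), 3)
  at5 <- dense(5, as.numeric(names(tcw)), as.numeric(tcw), 3)
  expect_gt(at50, at5)

  # zero conversions: no sites, not an error
  reads0 <- reads; reads0$mismatches <- ""
  prof0 <- parclipr:::profile_with_tmask(reads0, tr)
  expect_equal(nrow(call_binding_sites(reads0, prof0, site_params())), 0)
})

test_that("saturated conversion yields one site spanning nearly the cluster", {
  tr <- toy_transcript(seed = 5)
  sq <- strsplit(tr$sequence, "")[[1]]
  sq[seq(1, 120, by = 3)] <- "T"
  tr$sequence <- paste(sq, collapse = "")
  starts <- rep(c(0, 20, 40, 60, 80), each = 4)
  reads <- mk_reads("tx1", starts, starts + 40)
  tpos <- which(sq == "T") - 1L
  for (i in seq_len(nrow(reads))) {
    p <- tpos[tpos >= reads$start[i] & tpos < reads$end[i]]
    reads$mismatches[i] <- paste(paste0(p, ":T>C"), collapse = ";")
  }
  prof <- parclipr:::profile_with_tmask(reads, tr)
  sites <- call_binding_sites(reads, prof, site_params())
  expect_equal(nrow(sites), 1)
  expect_lte(sites$start, 5)
  expect_gte(sites$end, 115)
})

test_that("region annotation picks maximal overlap with CDS-priority ties", {
  tr <- data.frame(id = "tx1", sequence = strrep("A", 300), utr5_len = 0,
                   cds_len = 100, utr3_len = 200, biotype = "mRNA",
                   stringsAsFactors = FALSE)
  s <- data.frame(transcript_id = "tx1",
                  start = c(10, 95, 98), end = c(30, 105, 110),
                  tc_read_count = 5L, stringsAsFactors = FALSE)
  out <- annotate_region(s, tr)
  expect_equal(out$region, c("CDS", "CDS", "3UTR"))
  tr_nc <- tr; tr_nc$biotype <- "ncRNA"
  expect_equal(annotate_region(s, tr_nc)$region, rep("noncoding", 3))
})

test_that("replicate intersection honours half-open overlap semantics", {
  s1 <- data.frame(transcript_id = "tx1", start = 10, end = 30,
                   tc_read_count = 4L, stringsAsFactors = FALSE)
  s2a <- data.frame(transcript_id = "tx1", start = 25, end = 40,
                    tc_read_count = 4L, stringsAsFactors = FALSE)
  s2b <- data.frame(transcript_id = "tx1", start = 30, end = 40,
                    tc_read_count = 4L, stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_replicates(s1, s2a)), 1)
  expect_equal(intersect_replicates(s1, s2a)$replicates_supporting, "1,2")
  expect_equal(nrow(intersect_replicates(s1, s2b)), 0)
  # different transcript never overlaps
  s2c <- s2a; s2c$transcript_id <- "tx2"
  expect_equal(nrow(intersect_replicates(s1, s2c)), 0)
})

test_that("replicate intersection matches the all-pairs oracle on random sites", {
  set.seed(77)
  rand_sites <- function(n) {
    data.frame(transcript_id = sample(c("a", "b", "c", "d"), n, TRUE),
               start = s <- sample(0:400, n, TRUE),
               end = s + sample(5:40, n, TRUE),
               tc_read_count = sample(2:20, n, TRUE),
               stringsAsFactors = FALSE)
  }
  for (i in 1:5) {
    s1 <- rand_sites(150); s2 <- rand_sites(180)
    got <- intersect_replicates(s1, s2)
    want <- oracle_intersect(s1, s2)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$transcript_id, want$transcript_id)
    # empty iff no overlapping pair exists
    expect_identical(nrow(got) == 0, nrow(want) == 0)
  }
})

test_that("target summary applies the min-reads-in-both filter and total ranking", {
  sites <- data.frame(transcript_id = c("txA", "txB"), start = c(50, 50),
                      end = c(70, 70), tc_read_count = 5L,
                      stringsAsFactors = FALSE)
  mk <- function(tx, n_conv, n_plain, rep) {
    rbind(mk_reads(tx, seq(50, by = 0, length.out = n_conv), 70,
                   "55:T>C", rep),
          if (n_plain > 0) mk_reads(tx, rep(50, n_plain), 70, "", rep))
  }
  r1 <- rbind(mk("txA", 5, 2, 1L), mk("txB", 5, 0, 1L))
  r2 <- rbind(mk("txA", 4, 1, 2L), mk("txB", 3, 4, 2L))
  tg <- summarize_targets(list(r1, r2), sites)
  a <- tg[tg$transcript_id == "txA", ]
  b <- tg[tg$transcript_id == "txB", ]
  expect_true(a$passes_min_filter)   # 5 and 4
  expect_false(b$passes_min_filter)  # 5 and 3: retained, flagged
  expect_equal(a$total_tc_reads, 9L)
  expect_equal(b$total_tc_reads, 8L)
  expect_equal(a$rank, 1L)
  expect_equal(b$rank, 2L)
})

test_that("ranking is total, reproducible under shuffling, with lexicographic ties", {
  set.seed(11)
  sites <- data.frame(transcript_id = sprintf("t%02d", 1:8),
                      start = 10, end = 40, tc_read_count = 4L,
                      stringsAsFactors = FALSE)
  reads <- do.call(rbind, lapply(1:8, function(i) {
    n <- c(6, 6, 9, 3, 5, 6, 9, 4)[i]
    mk_reads(sprintf("t%02d", i), rep(12, n), 35, "20:T>C", 1L)
  }))
  reads2 <- reads; reads2$replicate <- 2L
  tg <- summarize_targets(list(reads, reads2), sites)
  shuffled <- reads[sample.int(nrow(reads)), ]
  tg2 <- summarize_targets(list(shuffled, reads2), sites)
  expect_identical(tg, tg2)
  expect_identical(tg$rank, seq_len(nrow(tg)))
  ties <- tg$transcript_id[tg$total_tc_reads == 12]
  expect_identical(ties, sort(ties))
  expect_error(summarize_targets(list(reads), sites,
                                 transcripts = toy_transcript("zzz")),
               "unknown transcript")
})

test_that("metagene profile normalizes per region and localizes midpoints", {
  tr <- data.frame(id = "tx1", sequence = strrep("A", 1000), utr5_len = 100,
                   cds_len = 600, utr3_len = 300, biotype = "mRNA",
                   stringsAsFactors = FALSE)
  s <- data.frame(transcript_id = "tx1", start = 390, end = 410,
                  tc_read_count = 25L, region = "CDS",
                  stringsAsFactors = FALSE)
  mg <- metagene_profile(s, tr, n_bins = 10)
  expect_equal(sum(mg$profile["CDS", ]), 1)
  expect_equal(which(mg$profile["CDS", ] > 0), 6L)  # fraction 0.5
  expect_equal(mg$sites$tier, ">=20")
  expect_true(all(c("5UTR", "3UTR") %in% mg$empty_regions))
})

test_that("uniformly planted sites give a flat CDS metagene profile", {
  ps <- replicate(20, {
    s <- sample.int(1e6, 1)
    cfg <- sim_config(seed = s, n_transcripts = 150)
    sim <- generate_transcriptome(cfg)
    sites <- sim$truth$planted_sites
    sites$tc_read_count <- 10L
    mg <- metagene_profile(annotate_region(sites, sim$transcripts),
                           sim$transcripts, n_bins = 10)
    counts <- mg$profile["CDS", ] * sum(mg$sites$region == "CDS")
    suppressWarnings(chisq.test(counts)$p.value)
  })
  expect_gt(median(ps), 0.01)
})
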