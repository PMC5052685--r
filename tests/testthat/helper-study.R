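with_seed_local <- function(seed, expr) parclipr:::with_seed(seed, expr)

# One full synthetic PAR-CLIP study at default conditions: two replicates,
# site calling, replicate intersection, and cluster sequence extraction.
run_study <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- generate_transcriptome(cfg)
  reads <- lapply(1:2, function(r)
    simulate_parclip_replicate(sim$transcripts, sim$truth, cfg, r))
  per_rep <- lapply(reads, call_sites, transcripts = sim$transcripts)
  replicated <- intersect_replicates(per_rep[[1]], per_rep[[2]])
  list(cfg = cfg, sim = sim, reads = reads, per_rep = per_rep,
       replicated = replicated)
}

# sequences under intervals, with symmetric flank, clipped to transcript
flank_seqs <- function(intervals, transcripts, flank = 20) {
  seqs <- setNames(transcripts$sequence, transcripts$id)
  L <- nchar(seqs[intervals$transcript_id])
  substr(seqs[intervals$transcript_id],
         pmax(intervals$start - flank, 0) + 1,
         pmin(intervals$end + flank, L))
}

# fraction of intervals in `a` overlapped by at least one interval in `b`
overlap_fraction <- function(a, b) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$transcript_id == a$transcript_id[i] &
          b$start < a$end[i] & b$end > a$start[i])
  }, TRUE)
  mean(hit)
}
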