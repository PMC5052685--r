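# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals they check.

oracle_kmer_spectrum <- function(seqs, k, window) {
  seqs <- toupper(chartr("U", "T", seqs))
  seqs <- seqs[nchar(seqs) >= k]
  kmers <- parclipr:::all_kmers(k)
  acc <- setNames(numeric(length(kmers)), kmers)
  n_win <- 0
  for (s in seqs) {
    L <- nchar(s)
    win_starts <- if (L >= window) 1:(L - window + 1) else 1
    for (w0 in win_starts) {
      win <- substr(s, w0, min(w0 + window - 1, L))
      wl <- nchar(win)
      freq <- setNames(numeric(length(kmers)), kmers)
      for (i in 1:(wl - k + 1)) {
        km <- substr(win, i, i + k - 1)
        if (km %in% kmers) freq[km] <- freq[km] + 1
      }
      acc <- acc + freq / (wl - k + 1)
      n_win <- n_win + 1
    }
  }
  out <- acc / n_win
  out / sum(out)
}

oracle_scan_motif <- function(seq, pattern) {
  seq <- toupper(chartr("U", "T", seq))
  pattern <- toupper(chartr("U", "T", pattern))
  sets <- parclipr:::IUPAC_SETS
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  if (length(sc) < length(pc)) return(hits)
  for (i in 1:(length(sc) - length(pc) + 1)) {
    ok <- TRUE
    for (j in seq_along(pc)) {
      if (!(sc[i + j - 1] %in% sets[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# connected components of the pairwise >= 1 nt overlap graph (half-open
# intervals: touching reads do NOT connect), one transcript at a time
oracle_clusters <- function(reads, min_reads) {
  out <- list()
  for (tx in sort(unique(reads$transcript_id))) {
    rr <- reads[reads$transcript_id == tx, , drop = FALSE]
    n <- nrow(rr)
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      nc <- nc + 1L
      queue <- i
      comp[i] <- nc
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]
        nb <- which(is.na(comp) & rr$start < rr$end[j] & rr$end > rr$start[j])
        comp[nb] <- nc
        queue <- c(queue, nb)
      }
    }
    for (cid in seq_len(nc)) {
      m <- comp == cid
      if (sum(m) >= min_reads) {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = tx, start = as.integer(min(rr$start[m])),
          end = as.integer(max(rr$end[m])), n_reads = as.integer(sum(m)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), n_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_profile <- function(reads, transcript) {
  L <- nchar(transcript$sequence)
  depth <- integer(L); tc <- integer(L); other <- integer(L)
  for (i in seq_len(nrow(reads))) {
    for (p in (reads$start[i] + 1):reads$end[i]) depth[p] <- depth[p] + 1L
    mm <- reads$mismatches[i]
    if (nzchar(mm)) {
      for (tok in strsplit(mm, ";")[[1]]) {
        f <- strsplit(tok, "[:>]")[[1]]
        p <- as.integer(f[1]) + 1L
        if (f[2] == "T" && f[3] == "C") tc[p] <- tc[p] + 1L
        else other[p] <- other[p] + 1L
      }
    }
  }
  list(depth = depth, tc_events = tc, other_mismatches = other)
}

# all-pairs overlap check
oracle_intersect <- function(s1, s2) {
  keep <- logical(nrow(s1))
  for (i in seq_len(nrow(s1))) {
    for (j in seq_len(nrow(s2))) {
      if (s1$transcript_id[i] == s2$transcript_id[j] &&
          s1$start[i] < s2$end[j] && s1$end[i] > s2$start[j]) {
        keep[i] <- TRUE
        break
      }
    }
  }
  s1[keep, , drop = FALSE]
}

oracle_dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

random_seq <- function(n, bases = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

random_reads <- function(n, tx_ids, tx_len, max_read = 30) {
  tx <- sample(tx_ids, n, replace = TRUE)
  len <- sample(5:max_read, n, replace = TRUE)
  start <- floor(runif(n) * (tx_len - len))
  data.frame(transcript_id = tx, start = as.integer(start),
             end = as.integer(start + len), mismatches = "",
             replicate = 1L, stringsAsFactors = FALSE)
}
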