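## RNA recognition element discovery by k-mer enrichment.
##
## Binding-site (cluster) sequences are scored for 4-mer content inside
## sliding 20-nt windows and compared against composition-preserving
## shuffles of coding-sequence background; top-ranking k-mers are collapsed
## into a degenerate IUPAC motif, which is then scanned for tandem
## arrangements at spacers 0..max_spacer.

# map an A/C/G/T string to integer codes 0..3 (NA for other characters)
seq_codes <- function(seq) {
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(seq)]
}

# k-mer ids (1-based, lexicographic in A<C<G<T) at every start; NA where
# the k-mer contains a non-ACGT character
kmer_ids <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1) return(integer(0))
  id <- codes[seq_len(n)]
  if (k > 1) {
    for (j in 1:(k - 1)) id <- id * 4L + codes[seq_len(n) + j]
  }
  id + 1L
}

#' All concrete k-mers in lexicographic order
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @keywords internal
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  out
}

#' Composition-preserving sequence shuffles
#'
#' Generates `n_shuffles` independent shuffles of a sequence set. In
#' `mode = "mono"` every sequence is permuted, preserving its
#' mononucleotide multiset exactly. In `mode = "di"` each sequence is
#' rewired along a random Eulerian path of its dinucleotide graph
#' (Altschul-Erickson), preserving its dinucleotide counts exactly.
#'
#' @param seqs Character vector of sequences (U and T equivalent).
#' @param n_shuffles Number of shuffles (>= 1).
#' @param mode "mono" (default) or "di".
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @return Object of class `shuffle_ensemble`: list with `shuffles` (list
#'   of character vectors), `mode`, `n_shuffles`, `seed`.
#' @export
shuffle_sequences <- function(seqs, n_shuffles, mode = c("mono", "di"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (length(seqs) == 0) stop("empty sequence set")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  seqs <- norm_seq(seqs)
  shuffles <- with_seed(child_seed(seed, 7L), {
    if (mode == "mono") {
      lens <- nchar(seqs)
      codes <- utf8ToInt(paste(seqs, collapse = ""))
      seg <- rep.int(seq_along(seqs), lens)
      bounds_end <- cumsum(lens)
      bounds_start <- bounds_end - lens + 1L
      lapply(seq_len(n_shuffles), function(i) {
        perm <- codes[order(seg, runif(length(codes)))]
        full <- intToUtf8(perm)
        substring(full, bounds_start, bounds_end)
      })
    } else {
      lapply(seq_len(n_shuffles), function(i) {
        vapply(seqs, di_shuffle_one, "", USE.NAMES = FALSE)
      })
    }
  })
  structure(list(shuffles = shuffles, mode = mode,
                 n_shuffles = as.integer(n_shuffles), seed = as.integer(seed)),
            class = "shuffle_ensemble")
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence
di_shuffle_one <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  verts <- unique(chars)
  succ <- lapply(setNames(verts, verts),
                 function(v) chars[which(chars[-n] == v) + 1L])
  last <- chars[n]
  nonlast <- setdiff(verts[vapply(succ, length, 1L) > 0], last)
  repeat {
    last_edge <- vapply(nonlast, function(v) {
      s <- succ[[v]]; s[sample.int(length(s), 1)]
    }, "")
    # last edges must form an in-tree toward the terminal vertex
    reach <- last
    repeat {
      add <- nonlast[!(nonlast %in% reach) & last_edge[nonlast] %in% reach]
      if (length(add) == 0) break
      reach <- c(reach, add)
    }
    if (all(nonlast %in% reach)) break
  }
  lists <- lapply(setNames(verts, verts), function(v) {
    s <- succ[[v]]
    if (v %in% nonlast) {
      drop <- match(last_edge[[v]], s)
      s <- s[-drop]
      c(if (length(s)) s[sample.int(length(s))], last_edge[[v]])
    } else {
      if (length(s)) s[sample.int(length(s))] else character()
    }
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Sliding-window k-mer spectrum
#'
#' Slides windows of length `window` (step 1) over each sequence
#' (sequences shorter than the window form a single window), computes
#' per-window k-mer frequencies, and averages them uniformly over all
#' windows of all sequences. The result sums to 1.
#'
#' @param seqs Character vector of sequences.
#' @param k k-mer length (default 4).
#' @param window Window length (default 20); must be >= k.
#' @return Named numeric vector over all `4^k` k-mers, summing to 1.
#' @export
kmer_spectrum <- function(seqs, k = 4L, window = 20L) {
  if (k > window) stop("k must be <= window")
  seqs <- norm_seq(seqs)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k, " skipped")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no sequence of length >= k")
  acc <- numeric(4^k)
  total_windows <- 0
  for (s in seqs) {
    codes <- seq_codes(s)
    L <- length(codes)
    ids <- kmer_ids(codes, k)
    n_kmer <- length(ids)
    if (L >= window) {
      n_win <- L - window + 1L
      i <- seq_len(n_kmer)
      wts <- pmin(i, n_win) - pmax(1L, i + k - window) + 1L
      norm <- window - k + 1L
    } else {
      n_win <- 1L
      wts <- rep(1L, n_kmer)
      norm <- n_kmer
    }
    ok <- !is.na(ids)
    if (any(ok)) {
      contrib <- rowsum(wts[ok] / norm, ids[ok])
      acc[as.integer(rownames(contrib))] <-
        acc[as.integer(rownames(contrib))] + contrib[, 1]
    }
    total_windows <- total_windows + n_win
  }
  out <- acc / total_windows
  tot <- sum(out)
  if (tot > 0) out <- out / tot   # renormalize if ambiguous bases were skipped
  setNames(out, all_kmers(k))
}

# number of sliding windows a sequence set contributes
count_windows <- function(seqs, k, window) {
  L <- nchar(seqs)
  L <- L[L >= k]
  sum(ifelse(L >= window, L - window + 1L, 1L))
}

# spectrum over n windows sampled uniformly from a sequence set
# (fixed window starts may be supplied for reuse across shuffles)
sampled_window_spectrum <- function(seqs, n_windows, k, window,
                                    starts = NULL) {
  codes <- unlist(lapply(seqs, seq_codes), use.names = FALSE)
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  if (is.null(starts)) {
    eligible <- which(lens >= window)
    nw <- lens[eligible] - window + 1L
    pick_seq <- sample(rep.int(eligible, nw), n_windows, replace = TRUE)
    pos <- floor(runif(n_windows) * (lens[pick_seq] - window + 1)) + 1L
    starts <- offs[pick_seq] + pos
  }
  slots <- window - k + 1L
  ids_all <- kmer_ids(codes, k)
  idx <- rep(starts, each = slots) + rep.int(0:(slots - 1L), length(starts))
  ids <- ids_all[idx]
  ids <- ids[!is.na(ids)]
  tab <- tabulate(ids, nbins = 4^k)
  spec <- tab / (length(starts) * slots)
  tot <- sum(spec)
  if (tot > 0) spec <- spec / tot
  list(spec = spec, starts = starts)
}

#' k-mer enrichment against a shuffled background
#'
#' Computes the sliding-window k-mer spectrum of the cluster sequences and
#' compares each k-mer frequency with its empirical distribution over the
#' background ensemble. Each shuffle is evaluated on sampled window runs
#' matched to the observed cluster windows in both number and overlap
#' structure, so shuffle spectra carry the same sampling noise as the
#' observed spectrum and z-scores are on a unit scale under the null.
#'
#' @param cluster_seqs Character vector of binding-site/cluster sequences.
#' @param background A `shuffle_ensemble` built with [shuffle_sequences()]
#'   from background sequences (e.g., coding ORFs); needs >= 2 shuffles.
#' @param k,window k-mer length and sliding-window length.
#' @param seed Seed for background window sampling.
#' @return Data frame sorted by z descending (k-mer lexicographic
#'   tie-break): `kmer`, `observed_freq`, `background_mean`,
#'   `background_sd`, `z_score`, `ratio`, `degenerate_sd` (TRUE where the
#'   background sd was 0 and z is +Inf/0 by convention).
#' @export
kmer_enrichment <- function(cluster_seqs, background, k = 4L, window = 20L,
                            seed = 1L) {
  stopifnot(inherits(background, "shuffle_ensemble"))
  if (background$n_shuffles < 2) stop("background needs >= 2 shuffles")
  obs <- kmer_spectrum(cluster_seqs, k, window)
  n_obs_windows <- count_windows(norm_seq(cluster_seqs), k, window)
  bg <- with_seed(child_seed(seed, 11L), {
    # For every cluster sequence, one anchor is sampled in the background
    # and the same run of consecutive windows is taken, so background
    # spectra reproduce both the window count and the overlap structure of
    # the observed windows. Anchor positions are sampled once and reused
    # across shuffles (each shuffle re-randomizes the content under them);
    # the per-position slot multiplicity then reduces each shuffle to one
    # grouped sum over k-mer ids.
    cl_len <- nchar(norm_seq(cluster_seqs))
    cl_len <- cl_len[cl_len >= k]
    lens <- nchar(background$shuffles[[1]])
    offs <- cumsum(c(0L, lens[-length(lens)]))
    cl_len <- pmin(cl_len, max(lens))   # cap runs at the longest background
    n_win_each <- pmax(cl_len - window + 1L, 1L)
    starts <- unlist(lapply(seq_along(cl_len), function(j) {
      need <- n_win_each[j] + window - 1L
      elig <- which(lens >= need)
      if (length(elig) == 0) stop("no background sequence of window length")
      pick <- elig[sample.int(length(elig), 1L)]
      anchor <- floor(runif(1) * (lens[pick] - need + 1)) + 1L
      offs[pick] + anchor + 0:(n_win_each[j] - 1L)
    }), use.names = FALSE)
    slots <- window - k + 1L
    total <- sum(lens)
    mult <- tabulate(rep(starts, each = slots) +
                       rep.int(0:(slots - 1L), length(starts)),
                     nbins = total - k + 1L)
    nz <- which(mult > 0L)
    m_nz <- mult[nz]
    denom <- as.numeric(length(starts)) * slots
    vapply(background$shuffles, function(ss) {
      codes <- seq_codes(paste(ss, collapse = ""))
      ids <- kmer_ids(codes, k)[nz]
      spec <- numeric(4^k)
      keep <- !is.na(ids)
      agg <- rowsum(m_nz[keep], ids[keep])
      spec[as.integer(rownames(agg))] <- agg[, 1]
      spec <- spec / denom
      tot <- sum(spec)
      if (tot > 0) spec / tot else spec
    }, numeric(4^k))
  })
  mu <- rowMeans(bg)
  sdev <- apply(bg, 1, sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev,
              ifelse(obs > mu, Inf, 0))
  out <- data.frame(kmer = all_kmers(k), observed_freq = as.numeric(obs),
                    background_mean = mu, background_sd = sdev,
                    z_score = z,
                    ratio = ifelse(mu > 0, obs / mu, NA_real_),
                    degenerate_sd = sdev == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z_score, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degenerate IUPAC motif
#'
#' @param pattern IUPAC string (U normalized to T).
#' @return Object of class `degenerate_motif` with `pattern` and `length`.
#' @export
degenerate_motif <- function(pattern) {
  pattern <- norm_seq(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS)))
    stop("invalid IUPAC symbol in '", pattern, "'")
  structure(list(pattern = pattern, length = nchar(pattern)),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("degenerate motif:", x$pattern,
      sprintf("(%d concrete %d-mers)\n", length(expand_motif(x)), x$length))
  invisible(x)
}

#' Expand a degenerate motif into its concrete k-mers
#' @param motif A `degenerate_motif`.
#' @return Character vector of all concrete sequences the motif admits.
#' @export
expand_motif <- function(motif) {
  sets <- IUPAC_SETS[strsplit(motif$pattern, "")[[1]]]
  out <- sets[[1]]
  for (i in seq_along(sets)[-1]) out <- as.vector(t(outer(out, sets[[i]], paste0)))
  out
}

#' Collapse k-mers to the minimal covering IUPAC motif
#'
#' Takes the per-position union of observed bases across the input k-mers
#' and expresses each union as the minimal IUPAC code covering it.
#'
#' @param top_kmers Character vector of equal-length k-mers.
#' @return A [degenerate_motif()].
#' @export
collapse_kmers_to_iupac <- function(top_kmers) {
  if (length(top_kmers) == 0) stop("need at least one k-mer")
  top_kmers <- norm_seq(top_kmers)
  lens <- unique(nchar(top_kmers))
  if (length(lens) != 1) stop("k-mers have mixed lengths")
  mat <- do.call(rbind, strsplit(top_kmers, ""))
  pattern <- paste(apply(mat, 2, function(col) iupac_code_for(col)),
                   collapse = "")
  degenerate_motif(pattern)
}

#' Scan a sequence for motif matches
#'
#' Finds all (overlapping) start positions where every base is admitted by
#' the corresponding IUPAC class of the motif.
#'
#' @param seq A single sequence.
#' @param motif A [degenerate_motif()] (or IUPAC string).
#' @return Integer vector of 0-based match start positions.
#' @export
scan_motif <- function(seq, motif) {
  if (is.character(motif)) motif <- degenerate_motif(motif)
  seq <- norm_seq(seq)
  re <- paste0("(?=", iupac_to_regex(motif$pattern), ")")
  m <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# tandem pair counts per spacer for a set of sequences (vectorized via one
# concatenated scan; matches never span the "X" separators)
count_tandem_spacers <- function(seqs, motif, max_spacer) {
  len <- motif$length
  glued <- paste(seqs, collapse = "X")
  seg_start <- cumsum(c(1L, nchar(seqs[-length(seqs)]) + 1L))
  p <- gregexpr(paste0("(?=", iupac_to_regex(motif$pattern), ")"),
                glued, perl = TRUE)[[1]]
  counts <- integer(max_spacer + 1L)
  if (p[1] != -1) {
    p <- as.integer(p)
    seg <- findInterval(p, seg_start)
    for (s in 0:max_spacer) {
      idx <- match(p + len + s, p)
      ok <- !is.na(idx) & seg[ifelse(is.na(idx), 1L, idx)] == seg
      counts[s + 1L] <- sum(ok)
    }
  }
  # positions where a tandem pair at spacer s could start
  scannable <- vapply(0:max_spacer, function(s) {
    sum(pmax(nchar(seqs) - (2L * len + s) + 1L, 0L))
  }, 0L)
  list(counts = counts, scannable = scannable)
}

#' Tandem-motif spacer enrichment
#'
#' Counts, for each spacer s in `0:max_spacer`, pairs of motif matches in
#' which the second match starts exactly `motif length + s` after the
#' first (the spacer separates the end of the first match from the start
#' of the second). The same counting is applied to every background
#' shuffle; counts are compared as rates per scannable position so cluster
#' and background sets of different total length are comparable.
#'
#' @param cluster_seqs Character vector of cluster sequences.
#' @param motif A [degenerate_motif()] (length >= 2).
#' @param background A `shuffle_ensemble` ([shuffle_sequences()]).
#' @param max_spacer Largest spacer considered (default 8).
#' @return Data frame: `spacer`, `observed_count`, `observed_rate`,
#'   `background_mean`, `background_sd` (rates), `enrichment`, `z_score`.
#' @export
tandem_spacer_enrichment <- function(cluster_seqs, motif, background,
                                     max_spacer = 8L) {
  if (is.character(motif)) motif <- degenerate_motif(motif)
  if (motif$length < 2) stop("motif length must be >= 2")
  if (max_spacer < 0) stop("max_spacer must be >= 0")
  stopifnot(inherits(background, "shuffle_ensemble"))
  cluster_seqs <- norm_seq(cluster_seqs)
  obs <- count_tandem_spacers(cluster_seqs, motif, max_spacer)
  obs_rate <- obs$counts / pmax(obs$scannable, 1L)
  bg_rates <- vapply(background$shuffles, function(ss) {
    b <- count_tandem_spacers(norm_seq(ss), motif, max_spacer)
    b$counts / pmax(b$scannable, 1L)
  }, numeric(max_spacer + 1L))
  bg_rates <- matrix(bg_rates, nrow = max_spacer + 1L)
  mu <- rowMeans(bg_rates)
  sdev <- apply(bg_rates, 1, sd)
  data.frame(spacer = 0:max_spacer,
             observed_count = obs$counts,
             observed_rate = obs_rate,
             background_mean = mu,
             background_sd = sdev,
             enrichment = ifelse(mu > 0, obs_rate / mu, NA_real_),
             z_score = ifelse(sdev > 0, (obs_rate - mu) / sdev,
                              ifelse(obs_rate > mu, Inf, 0)))
}
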