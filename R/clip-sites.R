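## Crosslink binding-site calling from T-to-C conversion density.
##
## The caller follows the classic PAR-CLIP logic: overlapping reads are
## grouped into clusters; within a cluster, a Gaussian kernel density over
## read-weighted conversion events is compared with the density over
## read-weighted non-converted uridine coverage, and each maximal run where
## conversion density exceeds non-conversion density becomes a binding
## site. Sites are then filtered for replicate reproducibility and used to
## rank target transcripts by crosslinked read counts.

#' Site-calling parameters
#'
#' @param min_cluster_reads Minimum overlapping reads for a cluster to be
#'   considered (read-grouping support).
#' @param min_conversion_reads Minimum distinct conversion-carrying reads a
#'   site must have.
#' @param min_site_len Minimum site length (nt); shorter density runs are
#'   symmetrically padded up to this length and clipped to the cluster.
#' @param kde_bandwidth Gaussian kernel bandwidth (nt) for the conversion /
#'   non-conversion densities, evaluated at integer positions.
#' @return A named list of parameters.
#' @export
site_params <- function(min_cluster_reads = 5L, min_conversion_reads = 2L,
                        min_site_len = 8L, kde_bandwidth = 3) {
  stopifnot(min_cluster_reads >= 1, min_conversion_reads >= 1,
            min_site_len >= 1, kde_bandwidth > 0)
  list(min_cluster_reads = as.integer(min_cluster_reads),
       min_conversion_reads = as.integer(min_conversion_reads),
       min_site_len = as.integer(min_site_len),
       kde_bandwidth = kde_bandwidth)
}

#' Per-position conversion profile of one transcript
#'
#' Accumulates read coverage, T-to-C conversion events and other mismatches
#' per transcript position. A read contributes at most one conversion event
#' at each converted position.
#'
#' @param reads Aligned-read table, all rows mapping to `transcript`.
#' @param transcript One-row transcript model (needs `id`, `sequence`).
#' @return List: `transcript_id`, `depth`, `tc_events`, `other_mismatches`
#'   (integer vectors of transcript length, position i = 0-based i-1).
#' @export
profile_conversions <- function(reads, transcript) {
  stopifnot(nrow(transcript) == 1)
  L <- nchar(transcript$sequence)
  if (nrow(reads) > 0) {
    if (!all(reads$transcript_id == transcript$id))
      stop("read mapped to a different transcript than '", transcript$id, "'")
    if (any(reads$start < 0 | reads$end > L)) {
      i <- which(reads$start < 0 | reads$end > L)[1]
      stop("read ", i, " lies outside transcript '", transcript$id, "'")
    }
  }
  depth <- coverage_depth(reads$start, reads$end, L)
  tc <- integer(L); other <- integer(L)
  ev <- parse_mismatches(reads$mismatches)
  if (nrow(ev) > 0) {
    is_tc <- ev$ref == "T" & ev$alt == "C"
    if (any(is_tc)) {
      t1 <- tabulate(ev$pos[is_tc] + 1L, nbins = L)
      tc <- tc + t1
    }
    if (any(!is_tc)) {
      t2 <- tabulate(ev$pos[!is_tc] + 1L, nbins = L)
      other <- other + t2
    }
  }
  list(transcript_id = transcript$id, depth = depth,
       tc_events = tc, other_mismatches = other)
}

#' Group overlapping reads into clusters
#'
#' Computes maximal unions of overlapping reads (>= 1 nt shared base,
#' half-open intervals) per transcript and keeps unions with at least
#' `min_reads` member reads.
#'
#' @param reads Aligned-read table.
#' @param min_reads Minimum member reads per cluster.
#' @return Data frame: `transcript_id`, `start`, `end`, `n_reads`, ordered
#'   by transcript then start.
#' @export
build_clusters <- function(reads, min_reads = 1L) {
  if (nrow(reads) == 0) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), n_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  # offset each transcript into its own disjoint coordinate block so a
  # single IRanges reduce handles all transcripts at once
  tx <- factor(reads$transcript_id)
  span <- max(reads$end) + 1L
  off <- (as.integer(tx) - 1L) * span
  ir <- IRanges::IRanges(start = reads$start + off + 1L,
                         end = reads$end + off)  # 1-based closed for IRanges
  red <- IRanges::reduce(ir, min.gapwidth = 0L)  # adjacency is not overlap
  n_in <- IRanges::countOverlaps(red, ir)
  keep <- n_in >= min_reads
  red <- red[keep]
  blk <- (IRanges::start(red) - 1L) %/% span
  out <- data.frame(transcript_id = levels(tx)[blk + 1L],
                    start = (IRanges::start(red) - 1L) %% span,
                    end = (IRanges::start(red) - 1L) %% span +
                      IRanges::width(red),
                    n_reads = n_in[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaussian KDE of weighted positions, evaluated at integer grid points;
# normalized to unit mass (returns zeros if total weight is 0)
weighted_kde <- function(grid, pos, w, bw) {
  tot <- sum(w)
  if (tot == 0 || length(pos) == 0) return(numeric(length(grid)))
  d <- outer(grid, pos, function(g, p) dnorm(g - p, sd = bw))
  as.numeric(d %*% w) / tot
}

#' Call binding sites within one read cluster
#'
#' Compares the read-weighted Gaussian kernel density of T-to-C conversion
#' events against the density of covered-but-unconverted uridine positions
#' (both normalized to unit mass over the cluster). Each maximal run of
#' integer positions where conversion density strictly exceeds
#' non-conversion density is a candidate site; runs are padded
#' symmetrically to `min_site_len`, clipped to the cluster, merged if
#' padding makes them touch, and kept only if supported by at least
#' `min_conversion_reads` distinct conversion-carrying reads.
#'
#' @param cluster_reads Reads belonging to one cluster (one transcript).
#' @param profile Conversion profile of the transcript
#'   ([profile_conversions()]), or of any span covering the cluster.
#' @param params [site_params()].
#' @return Data frame of sites: `transcript_id`, `start`, `end`,
#'   `tc_read_count`, `read_depth`; zero rows if the cluster has no
#'   conversion events.
#' @export
call_binding_sites <- function(cluster_reads, profile, params = site_params()) {
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), tc_read_count = integer(),
                      read_depth = integer(), stringsAsFactors = FALSE)
  if (nrow(cluster_reads) < params$min_cluster_reads) return(empty)
  ev <- parse_mismatches(cluster_reads$mismatches)
  ev <- ev[ev$ref == "T" & ev$alt == "C", , drop = FALSE]
  if (nrow(ev) == 0) return(empty)

  c_start <- min(cluster_reads$start)
  c_end <- max(cluster_reads$end)
  grid <- seq.int(c_start, c_end - 1L)

  tc_w <- tabulate(ev$pos - c_start + 1L, nbins = length(grid))
  depth <- coverage_depth(cluster_reads$start - c_start,
                          cluster_reads$end - c_start, length(grid))
  # non-conversion weight: covered, unconverted reference-T positions
  t_mask <- attr(profile, "t_mask")
  if (is.null(t_mask)) {
    # fall back: treat positions with any conversion event anywhere as T,
    # plus positions recorded in this cluster's events
    t_mask_grid <- profile$tc_events[grid + 1L] > 0 | tc_w > 0
  } else {
    t_mask_grid <- t_mask[grid + 1L]
  }
  nc_w <- pmax(depth - tc_w, 0L) * t_mask_grid

  d_conv <- weighted_kde(grid, grid[tc_w > 0], tc_w[tc_w > 0],
                         params$kde_bandwidth)
  d_non <- weighted_kde(grid, grid[nc_w > 0], nc_w[nc_w > 0],
                        params$kde_bandwidth)

  above <- d_conv > d_non
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- cbind(starts_i[r$values], ends_i[r$values])

  # pad to min_site_len, clip to cluster (grid indices, 1-based inclusive)
  a <- grid[runs[, 1]]; b <- grid[runs[, 2]] + 1L  # half-open coords
  deficit <- pmax(params$min_site_len - (b - a), 0L)
  a <- pmax(a - deficit %/% 2L, c_start)
  b <- pmin(b + (deficit - deficit %/% 2L), c_end)

  # merge any intervals that padding made overlap
  o <- order(a)
  a <- a[o]; b <- b[o]
  keep_a <- a[1]; keep_b <- b[1]
  if (length(a) > 1) {
    for (i in 2:length(a)) {
      if (a[i] <= keep_b[length(keep_b)]) {
        keep_b[length(keep_b)] <- max(keep_b[length(keep_b)], b[i])
      } else {
        keep_a <- c(keep_a, a[i]); keep_b <- c(keep_b, b[i])
      }
    }
  }

  # support: distinct conversion-carrying reads and depth per interval
  tc_reads <- integer(length(keep_a))
  depth_n <- integer(length(keep_a))
  for (i in seq_along(keep_a)) {
    in_site <- ev$pos >= keep_a[i] & ev$pos < keep_b[i]
    tc_reads[i] <- length(unique(ev$read[in_site]))
    depth_n[i] <- sum(cluster_reads$start < keep_b[i] &
                        cluster_reads$end > keep_a[i])
  }
  ok <- tc_reads >= params$min_conversion_reads
  data.frame(transcript_id = rep(cluster_reads$transcript_id[1], sum(ok)),
             start = keep_a[ok], end = keep_b[ok],
             tc_read_count = tc_reads[ok], read_depth = depth_n[ok],
             stringsAsFactors = FALSE)
}

# Conversion profile with a reference-T mask attached (used by the caller
# so non-conversion density only counts true uridine positions).
profile_with_tmask <- function(reads, transcript) {
  p <- profile_conversions(reads, transcript)
  attr(p, "t_mask") <- strsplit(transcript$sequence, "")[[1]] == "T"
  p
}

#' Call binding sites for a whole replicate
#'
#' Convenience wrapper: groups reads into clusters per transcript, builds
#' conversion profiles, and calls [call_binding_sites()] on every cluster.
#'
#' @param reads Aligned-read table for one replicate.
#' @param transcripts Transcript table.
#' @param params [site_params()].
#' @return Data frame of sites with a `replicate` column.
#' @export
call_sites <- function(reads, transcripts, params = site_params()) {
  validate_reads(reads, transcripts)
  clusters <- build_clusters(reads, params$min_cluster_reads)
  out <- vector("list", nrow(clusters))
  if (nrow(clusters) > 0) {
    reads_split <- split(seq_len(nrow(reads)), reads$transcript_id)
    tx_rows <- setNames(seq_len(nrow(transcripts)), transcripts$id)
    prof_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(clusters))) {
      tx <- clusters$transcript_id[i]
      rr <- reads[reads_split[[tx]], , drop = FALSE]
      in_cl <- rr$start < clusters$end[i] & rr$end > clusters$start[i]
      cl_reads <- rr[in_cl, , drop = FALSE]
      if (!exists(tx, envir = prof_cache)) {
        assign(tx, profile_with_tmask(rr, transcripts[tx_rows[[tx]], , drop = FALSE]),
               envir = prof_cache)
      }
      out[[i]] <- call_binding_sites(cl_reads, get(tx, envir = prof_cache),
                                     params)
    }
  }
  sites <- do.call(rbind, c(out, list(data.frame(
    transcript_id = character(), start = integer(), end = integer(),
    tc_read_count = integer(), read_depth = integer(),
    stringsAsFactors = FALSE))))
  sites$replicate <- rep(if (nrow(reads) > 0) reads$replicate[1] else NA_integer_,
                         nrow(sites))
  rownames(sites) <- NULL
  sites
}

#' Annotate binding sites with transcript regions
#'
#' Assigns each site the region (5UTR / CDS / 3UTR) with maximal overlap;
#' ties are broken by the priority CDS > 3UTR > 5UTR. Sites on non-mRNA
#' biotypes are labelled "noncoding".
#'
#' @param sites Site table (`transcript_id`, `start`, `end`).
#' @param transcripts Transcript table with region lengths and `biotype`.
#' @return `sites` with a `region` column added.
#' @export
annotate_region <- function(sites, transcripts) {
  if (nrow(sites) == 0) { sites$region <- character(); return(sites) }
  idx <- match(sites$transcript_id, transcripts$id)
  if (anyNA(idx)) stop("site on unknown transcript '",
                       sites$transcript_id[which(is.na(idx))[1]], "'")
  u5 <- transcripts$utr5_len[idx]
  cd <- transcripts$cds_len[idx]
  u3 <- transcripts$utr3_len[idx]
  ov <- function(a, b, s, e) pmax(pmin(e, b) - pmax(s, a), 0)
  o5 <- ov(0, u5, sites$start, sites$end)
  oc <- ov(u5, u5 + cd, sites$start, sites$end)
  o3 <- ov(u5 + cd, u5 + cd + u3, sites$start, sites$end)
  if (any(o5 + oc + o3 == 0)) stop("site with zero overlap with its transcript")
  # priority on ties: CDS > 3UTR > 5UTR (column order encodes priority)
  m <- cbind(CDS = oc, `3UTR` = o3, `5UTR` = o5)
  lab <- colnames(m)[max.col(m, ties.method = "first")]
  lab[transcripts$biotype[idx] != "mRNA"] <- "noncoding"
  sites$region <- lab
  sites
}

#' Keep sites reproduced in a second replicate
#'
#' Returns the replicate-1 sites that share at least 1 nt (half-open
#' intervals) with any replicate-2 site on the same transcript, with
#' `replicates_supporting` set to "1,2".
#'
#' @param sites_rep1,sites_rep2 Site tables from two replicates.
#' @return The surviving subset of `sites_rep1`.
#' @export
intersect_replicates <- function(sites_rep1, sites_rep2) {
  if (nrow(sites_rep1) == 0 || nrow(sites_rep2) == 0) {
    out <- sites_rep1[integer(), , drop = FALSE]
    out$replicates_supporting <- character()
    return(out)
  }
  tx_all <- union(sites_rep1$transcript_id, sites_rep2$transcript_id)
  span <- max(sites_rep1$end, sites_rep2$end) + 1L
  off1 <- (match(sites_rep1$transcript_id, tx_all) - 1L) * span
  off2 <- (match(sites_rep2$transcript_id, tx_all) - 1L) * span
  ir1 <- IRanges::IRanges(sites_rep1$start + off1 + 1L,
                          sites_rep1$end + off1)
  ir2 <- IRanges::IRanges(sites_rep2$start + off2 + 1L,
                          sites_rep2$end + off2)
  keep <- IRanges::countOverlaps(ir1, ir2) > 0
  out <- sites_rep1[keep, , drop = FALSE]
  out$replicates_supporting <- rep("1,2", nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank target transcripts by crosslinked reads
#'
#' Counts, per replicate and transcript, the distinct reads that carry at
#' least one T-to-C conversion and (by default) overlap a replicated
#' binding site of that transcript. Targets are ranked by the summed count
#' over replicates (descending; ties broken lexicographically by
#' transcript id) and flagged when every replicate contributes at least
#' `min_reads` crosslinked reads.
#'
#' @param reads_by_replicate List of aligned-read tables, one per
#'   replicate, or a single table with a `replicate` column.
#' @param replicated_sites Replicate-filtered site table
#'   ([intersect_replicates()]).
#' @param min_reads Per-replicate crosslinked-read threshold (default 4).
#' @param mode "sites" counts only conversion reads overlapping replicated
#'   sites (default); "all" counts every conversion read of the transcript.
#' @param transcripts Optional transcript table; when given, reads mapping
#'   to transcripts absent from it raise an error.
#' @return Data frame: `transcript_id`, one `tc_reads_rep<i>` column per
#'   replicate, `total_tc_reads`, `rank`, `passes_min_filter`.
#' @export
summarize_targets <- function(reads_by_replicate, replicated_sites,
                              min_reads = 4L, mode = c("sites", "all"),
                              transcripts = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(reads_by_replicate)) {
    reads_by_replicate <- split(reads_by_replicate,
                                reads_by_replicate$replicate)
  }
  if (!is.null(transcripts)) {
    for (reads in reads_by_replicate) {
      bad <- setdiff(unique(reads$transcript_id), transcripts$id)
      if (length(bad))
        stop("reads map to unknown transcript '", bad[1], "'")
    }
  }
  n_rep <- length(reads_by_replicate)
  tx_ids <- sort(unique(replicated_sites$transcript_id))
  if (mode == "all") {
    tx_ids <- sort(unique(c(tx_ids, unlist(lapply(reads_by_replicate,
                                                  `[[`, "transcript_id")))))
  }
  counts <- matrix(0L, nrow = length(tx_ids), ncol = n_rep,
                   dimnames = list(tx_ids, NULL))
  for (r in seq_len(n_rep)) {
    reads <- reads_by_replicate[[r]]
    if (nrow(reads) == 0) next
    ev <- parse_mismatches(reads$mismatches)
    conv_read <- unique(ev$read[ev$ref == "T" & ev$alt == "C"])
    if (length(conv_read) == 0) next
    cr <- reads[conv_read, , drop = FALSE]
    if (mode == "sites") {
      ok <- logical(nrow(cr))
      ss <- split(seq_len(nrow(replicated_sites)),
                  replicated_sites$transcript_id)
      for (i in seq_len(nrow(cr))) {
        rows <- ss[[cr$transcript_id[i]]]
        if (is.null(rows)) next
        ok[i] <- any(replicated_sites$start[rows] < cr$end[i] &
                       replicated_sites$end[rows] > cr$start[i])
      }
      cr <- cr[ok, , drop = FALSE]
    }
    tb <- table(factor(cr$transcript_id, levels = tx_ids))
    counts[, r] <- counts[, r] + as.integer(tb)
  }
  total <- rowSums(counts)
  ord <- order(-total, tx_ids)
  out <- data.frame(transcript_id = tx_ids[ord], stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) out[[paste0("tc_reads_rep", r)]] <- counts[ord, r]
  out$total_tc_reads <- as.integer(total[ord])
  out$rank <- seq_len(nrow(out))
  out$passes_min_filter <- apply(counts[ord, , drop = FALSE] >= min_reads, 1, all)
  rownames(out) <- NULL
  out
}

#' Metagene profile of binding sites
#'
#' Maps each site midpoint to its fractional position within its region
#' (5UTR, CDS or 3UTR) and histograms those fractions into `n_bins` bins,
#' normalized to sum to 1 per region. Each site is also assigned a
#' read-support tier (crosslinked reads >= 4 and >= 20).
#'
#' @param sites Annotated site table (needs `region`; computed if absent).
#' @param transcripts Transcript table.
#' @param n_bins Number of positional bins (>= 2).
#' @return List: `profile` (region x bin matrix, rows sum to 1 or are
#'   all-zero and flagged in `empty_regions`), `sites` (with `rel_pos` and
#'   `tier` columns), `empty_regions`.
#' @export
metagene_profile <- function(sites, transcripts, n_bins = 20L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  regions <- c("5UTR", "CDS", "3UTR")
  if (!"region" %in% names(sites)) sites <- annotate_region(sites, transcripts)
  prof <- matrix(0, nrow = length(regions), ncol = n_bins,
                 dimnames = list(regions, NULL))
  sites$rel_pos <- rep(NA_real_, nrow(sites))
  sites$tier <- rep(NA_character_, nrow(sites))
  keep <- sites$region %in% regions
  if (any(keep)) {
    idx <- match(sites$transcript_id, transcripts$id)
    u5 <- transcripts$utr5_len[idx]; cd <- transcripts$cds_len[idx]
    u3 <- transcripts$utr3_len[idx]
    r_start <- ifelse(sites$region == "5UTR", 0,
                      ifelse(sites$region == "CDS", u5, u5 + cd))
    r_len <- ifelse(sites$region == "5UTR", u5,
                    ifelse(sites$region == "CDS", cd, u3))
    mid <- (sites$start + sites$end) / 2
    sites$rel_pos <- ifelse(keep, pmin(pmax((mid - r_start) / r_len, 0), 1), NA)
    sites$tier <- ifelse(sites$tc_read_count >= 20, ">=20",
                         ifelse(sites$tc_read_count >= 4, ">=4", "<4"))
    for (rg in regions) {
      v <- sites$rel_pos[keep & sites$region == rg]
      if (length(v) > 0) {
        b <- pmin(floor(v * n_bins) + 1L, n_bins)
        h <- tabulate(b, nbins = n_bins)
        prof[rg, ] <- h / sum(h)
      }
    }
  }
  empty <- regions[rowSums(prof) == 0]
  list(profile = prof, sites = sites, empty_regions = empty)
}
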