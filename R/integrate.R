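## Integration of PAR-CLIP binding with transcriptome and secretome
## regulation: median normalization and SAM-style permutation testing of
## label-free intensities, ECDF stratification of fold changes by
## crosslink rank, and correlation of crosslink reads with secretion
## change.

#' Drop proteins with too many missing intensities
#'
#' @param mat Numeric matrix (proteins x samples), NAs allowed.
#' @param cap Maximum tolerated missing fraction per protein (default 0.5).
#' @return The filtered matrix; the number of dropped proteins is attached
#'   as attribute `n_filtered` and reported via `message()`.
#' @export
filter_missing_proteins <- function(mat, cap = 0.5) {
  frac <- rowMeans(is.na(mat))
  drop <- frac > cap
  if (any(drop)) {
    message(sum(drop), " protein(s) exceeded missing fraction ", cap,
            " and were filtered")
  }
  out <- mat[!drop, , drop = FALSE]
  attr(out, "n_filtered") <- sum(drop)
  out
}

#' Median-normalize an intensity matrix
#'
#' Scales every sample (column) so that all sample medians equal the grand
#' median of the pre-normalization sample medians.
#'
#' @param mat Numeric matrix (proteins x samples); NAs ignored.
#' @return The normalized matrix.
#' @export
median_normalize <- function(mat) {
  meds <- apply(mat, 2, median, na.rm = TRUE)
  if (anyNA(meds)) stop("sample with no observed values: ",
                        colnames(mat)[which(is.na(meds))[1]])
  grand <- median(meds)
  sweep(mat, 2, grand / meds, `*`)
}

# two-group summary statistics under NA-tolerant pooling; X is
# proteins x samples, g a logical vector marking group A columns
two_group_stats <- function(Xz, X2, M, g) {
  g <- as.numeric(g)
  h <- 1 - g
  cA <- as.numeric(M %*% g); cB <- as.numeric(M %*% h)
  sA <- as.numeric(Xz %*% g); sB <- as.numeric(Xz %*% h)
  mA <- sA / cA; mB <- sB / cB
  ssA <- as.numeric(X2 %*% g) - cA * mA^2
  ssB <- as.numeric(X2 %*% h) - cB * mB^2
  df <- cA + cB - 2
  sp2 <- pmax(ssA + ssB, 0) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / cA + 1 / cB))
  list(diff = mA - mB, se = se)
}

#' SAM-style permutation test for two-group differential abundance
#'
#' Computes, for every protein, the moderated statistic
#' `d = (mean_A - mean_B) / (se + s0)` with `se` the pooled two-sample
#' standard error and `s0` a variance fudge factor, estimates the null by
#' permuting group labels, and selects the smallest symmetric cutoff on
#' `|d|` whose estimated FDR (median permuted exceedance count divided by
#' observed exceedance count) is at or below `fdr`. Group A is the second
#' factor level, so with levels (control, knockdown) positive `log2fc`
#' means up in knockdown.
#'
#' @param mat Numeric matrix of log-scale intensities (proteins x
#'   samples); NAs tolerated pairwise.
#' @param groups Factor with two levels assigning samples to groups; both
#'   groups need >= 2 samples.
#' @param s0 Fudge factor added to the standard error (default 0.5).
#' @param n_perm Number of label permutations (default 250; all distinct
#'   assignments are used when fewer exist).
#' @param fdr Target false discovery rate (default 0.01).
#' @param seed Seed for permutation sampling.
#' @return Data frame: `protein`, `d_statistic`, `log2fc`, `significant`,
#'   `threshold_delta`, `fdr_target`, plus the achieved FDR as attribute
#'   `fdr_at_threshold`.
#' @export
sam_permutation_test <- function(mat, groups, s0 = 0.5, n_perm = 250L,
                                 fdr = 0.01, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 2)) stop("both groups need >= 2 samples")
  if (n_perm < 10) stop("n_perm must be >= 10 for a stable FDR estimate")
  n <- ncol(mat)
  if (length(groups) != n) stop("length(groups) must equal ncol(mat)")
  proteins <- rownames(mat)
  if (is.null(proteins)) proteins <- paste0("p", seq_len(nrow(mat)))

  M <- !is.na(mat)
  Xz <- ifelse(M, mat, 0)
  X2 <- Xz^2
  gA <- groups == levels(groups)[2]
  nA <- sum(gA)

  obs <- two_group_stats(Xz, X2, M, gA)
  d_obs <- ifelse(obs$se + s0 > 0, obs$diff / (obs$se + s0), 0)
  d_obs[is.na(d_obs)] <- 0   # constant/degenerate proteins

  # distinct group-A column sets
  n_distinct <- choose(n, nA)
  perm_sets <- with_seed(child_seed(seed, 13L), {
    if (n_distinct <= max(n_perm, 5000)) {
      all_sets <- utils::combn(n, nA)
      if (ncol(all_sets) > n_perm) {
        all_sets[, sample.int(ncol(all_sets), n_perm), drop = FALSE]
      } else all_sets
    } else {
      vapply(seq_len(n_perm), function(i) sample.int(n, nA), integer(nA))
    }
  })
  n_used <- ncol(perm_sets)

  abs_obs_sorted <- sort(abs(d_obs))
  cand <- sort(unique(abs(d_obs)))
  n_prot <- length(d_obs)
  obs_exceed <- n_prot - findInterval(cand - 1e-12, abs_obs_sorted)
  perm_exceed <- matrix(0, nrow = n_used, ncol = length(cand))
  for (j in seq_len(n_used)) {
    g <- seq_len(n) %in% perm_sets[, j]
    st <- two_group_stats(Xz, X2, M, g)
    dp <- ifelse(st$se + s0 > 0, st$diff / (st$se + s0), 0)
    dp[is.na(dp)] <- 0
    sp <- sort(abs(dp))
    perm_exceed[j, ] <- n_prot - findInterval(cand - 1e-12, sp)
  }
  med_exceed <- apply(perm_exceed, 2, median)
  est_fdr <- ifelse(obs_exceed > 0, med_exceed / obs_exceed, 0)
  ok <- which(est_fdr <= fdr)
  if (length(ok) > 0) {
    threshold <- cand[ok[1]]
    achieved <- est_fdr[ok[1]]
  } else {
    threshold <- Inf
    achieved <- NA_real_
  }
  out <- data.frame(protein = proteins,
                    d_statistic = d_obs,
                    log2fc = obs$diff,
                    significant = abs(d_obs) >= threshold,
                    threshold_delta = threshold,
                    fdr_target = fdr,
                    stringsAsFactors = FALSE)
  attr(out, "fdr_at_threshold") <- achieved
  attr(out, "n_permutations") <- n_used
  out
}

#' Stratify genes by crosslink-based target rank
#'
#' Splits expressed genes into "top" (target rank <= `top_n`), "poor"
#' (remaining replicated targets) and "non" (expressed genes never
#' crosslinked in both replicates). Genes below the expression floor are
#' excluded from all strata.
#'
#' @param target_records Ranked target table ([summarize_targets()]).
#' @param fold_changes Data frame with `gene`, `log2fc`, `mean_abundance`.
#' @param top_n Size of the top stratum (default 100).
#' @param expression_floor Minimum abundance (FPKM-like) for a gene to be
#'   considered expressed (default 2).
#' @return `fold_changes` restricted to expressed genes, with a `stratum`
#'   column ("top"/"poor"/"non").
#' @export
stratify_by_crosslink <- function(target_records, fold_changes,
                                  top_n = 100L, expression_floor = 2) {
  if (top_n > nrow(target_records)) {
    warning("top_n (", top_n, ") exceeds the number of targets (",
            nrow(target_records), "); all targets labelled 'top'")
  }
  out <- fold_changes[fold_changes$mean_abundance >= expression_floor, ,
                      drop = FALSE]
  rk <- target_records$rank[match(out$gene, target_records$transcript_id)]
  out$stratum <- ifelse(is.na(rk), "non",
                        ifelse(rk <= top_n, "top", "poor"))
  rownames(out) <- NULL
  out
}

#' Compare fold-change distributions across target strata
#'
#' Builds the ECDF and median of `log2fc` per stratum and runs two-sample
#' Kolmogorov-Smirnov tests of "top" and "poor" against "non".
#'
#' @param stratified Data frame with `log2fc` and `stratum` columns
#'   ([stratify_by_crosslink()]).
#' @return List: `ecdfs` (named list of step functions), `medians` (named
#'   vector), `ks` (data frame: comparison, statistic, p_value,
#'   undefined), `n` (stratum sizes). KS p is NA and flagged when a
#'   stratum has < 3 members.
#' @export
ecdf_compare <- function(stratified) {
  strata <- c("top", "poor", "non")
  vals <- lapply(setNames(strata, strata),
                 function(s) stratified$log2fc[stratified$stratum == s])
  if (any(lengths(vals) == 0)) stop("empty stratum: ",
                                    strata[which(lengths(vals) == 0)[1]])
  ecdfs <- lapply(vals, ecdf)
  medians <- vapply(vals, median, 0)
  ks_row <- function(a, b, label) {
    undef <- length(vals[[a]]) < 3 || length(vals[[b]]) < 3
    if (undef) {
      data.frame(comparison = label, statistic = NA_real_,
                 p_value = NA_real_, undefined = TRUE)
    } else {
      kt <- suppressWarnings(ks.test(vals[[a]], vals[[b]]))
      data.frame(comparison = label, statistic = unname(kt$statistic),
                 p_value = kt$p.value, undefined = FALSE)
    }
  }
  ks <- rbind(ks_row("top", "non", "top_vs_non"),
              ks_row("poor", "non", "poor_vs_non"))
  list(ecdfs = ecdfs, medians = medians, ks = ks, n = lengths(vals))
}

#' Correlate secretion change with crosslink read counts
#'
#' Pearson correlation (with two-sided test) between
#' `log10(1 + crosslink reads)` and secretion log2 fold change.
#'
#' @param log2fc Numeric vector of per-protein secretion log2 fold
#'   changes.
#' @param tc_reads Matching nonnegative crosslinked-read counts.
#' @return List: `r`, `p_value`, `n`.
#' @export
correlate_regulation <- function(log2fc, tc_reads) {
  keep <- complete.cases(log2fc, tc_reads)
  x <- log10(1 + tc_reads[keep])
  y <- log2fc[keep]
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
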