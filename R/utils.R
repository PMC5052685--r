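#' @importFrom stats dnorm ecdf ks.test median quantile rbinom rlnorm rnbinom
#'   rnorm rpois runif sd setNames cor.test complete.cases
#' @importFrom utils read.delim write.table
NULL

# Coordinate convention used throughout the package: 0-based, half-open
# [start, end) intervals in transcript space, sense strand only.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so generators are pure functions of their seed.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a parent seed and a stream label.
# Kept below 2^31 - 1; a simple multiplicative hash is enough here because
# streams are few and never adversarial.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- (as.double(seed) * 48271 + as.double(stream) * 16807 + 1) %% 2147483646
  as.integer(h) + 1L
}

## IUPAC nucleotide classes (DNA alphabet; U is normalized to T on input)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# minimal IUPAC code for a set of concrete bases
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  stop("no IUPAC code for base set: ", paste(bases, collapse = ","))
}

#' Normalize a nucleotide string to upper-case DNA alphabet
#'
#' Upper-cases and replaces U with T, so RNA and DNA inputs are equivalent.
#'
#' @param x Character vector of sequences or motif patterns.
#' @return Character vector in the DNA alphabet.
#' @keywords internal
norm_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

## Mismatch-string encoding: "pos:ref>alt" joined by ";", positions 0-based
## in transcript coordinates. "" means no mismatches.

#' Parse mismatch strings into a long-format table
#'
#' @param mm Character vector of mismatch strings ("pos:ref>alt;...").
#' @return Data frame with columns `read` (index into `mm`), `pos` (0-based
#'   transcript position), `ref`, `alt`.
#' @keywords internal
parse_mismatches <- function(mm) {
  mm[is.na(mm)] <- ""
  n_each <- integer(length(mm))
  nonempty <- nzchar(mm)
  parts <- strsplit(mm[nonempty], ";", fixed = TRUE)
  n_each[nonempty] <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (length(flat) == 0) {
    return(data.frame(read = integer(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  got <- utils::strcapture("^([0-9]+):([A-Za-z])>([A-Za-z])$", flat,
                           proto = data.frame(pos = integer(),
                                              ref = character(),
                                              alt = character()))
  if (anyNA(got$pos)) {
    bad <- flat[which(is.na(got$pos))[1]]
    stop("malformed mismatch token: '", bad, "'")
  }
  data.frame(read = rep.int(seq_along(mm), n_each),
             pos = got$pos, ref = toupper(got$ref), alt = toupper(got$alt),
             stringsAsFactors = FALSE)
}

# Inverse of parse_mismatches: build per-read strings from a long table.
# events must have columns read, pos, ref, alt; n is the number of reads.
format_mismatches <- function(events, n) {
  out <- character(n)
  if (nrow(events) == 0) return(out)
  events <- events[order(events$read, events$pos), , drop = FALSE]
  tok <- paste0(events$pos, ":", events$ref, ">", events$alt)
  agg <- vapply(split(tok, events$read), paste, "", collapse = ";")
  out[as.integer(names(agg))] <- agg
  out
}

# Validate an aligned-read table (transcript_id, start, end, mismatches,
# replicate) against a transcript table. Errors name the offending read.
validate_reads <- function(reads, transcripts) {
  need <- c("transcript_id", "start", "end", "mismatches")
  miss <- setdiff(need, names(reads))
  if (length(miss)) stop("reads table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(reads) == 0) return(invisible(reads))
  if (any(reads$start >= reads$end)) {
    i <- which(reads$start >= reads$end)[1]
    stop("read ", i, " (", reads$transcript_id[i], ") has start >= end")
  }
  len <- setNames(nchar(transcripts$sequence), transcripts$id)
  unknown <- !(reads$transcript_id %in% names(len))
  if (any(unknown)) {
    stop("read ", which(unknown)[1], " maps to unknown transcript '",
         reads$transcript_id[which(unknown)[1]], "'")
  }
  L <- len[reads$transcript_id]
  if (any(reads$start < 0 | reads$end > L)) {
    i <- which(reads$start < 0 | reads$end > L)[1]
    stop("read ", i, " extends beyond transcript '", reads$transcript_id[i], "'")
  }
  ev <- parse_mismatches(reads$mismatches)
  if (nrow(ev)) {
    inside <- ev$pos >= reads$start[ev$read] & ev$pos < reads$end[ev$read]
    if (!all(inside)) {
      i <- ev$read[which(!inside)[1]]
      stop("read ", i, " has a mismatch outside its span")
    }
  }
  invisible(reads)
}

# coverage depth over [0, len) from 0-based half-open read spans
coverage_depth <- function(start, end, len) {
  if (length(start) == 0) return(integer(len))
  add <- tabulate(start + 1L, nbins = len + 1L)
  rem <- tabulate(end + 1L, nbins = len + 1L)
  cumsum(add - rem)[seq_len(len)]
}
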