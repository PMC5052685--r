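## File formats. Transcripts travel as FASTA plus a region table;
## reads as SAM against the transcript FASTA (mismatches in the MD tag) or
## as a simple TSV dialect; sites as BED6/TSV. All tables carry a comment
## header naming the coordinate convention (0-based, half-open).

COORD_HEADER <- "# coordinates: 0-based, half-open [start, end), transcript space, sense strand"

#' Write transcripts as FASTA
#' @param transcripts Transcript table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(setNames(transcripts$sequence, transcripts$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read transcripts from FASTA plus a region table
#' @param fasta_path FASTA of transcript sequences.
#' @param regions_path TSV with `transcript_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`, `biotype`.
#' @return Transcript table as used throughout the package.
#' @export
read_transcripts <- function(fasta_path, regions_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  reg <- read.delim(regions_path, comment.char = "#",
                    stringsAsFactors = FALSE)
  idx <- match(names(x), reg$transcript_id)
  if (anyNA(idx)) stop("transcript missing from region table: ",
                       names(x)[which(is.na(idx))[1]])
  out <- data.frame(id = names(x), sequence = unname(as.character(x)),
                    utr5_len = reg$utr5_len[idx], cds_len = reg$cds_len[idx],
                    utr3_len = reg$utr3_len[idx], biotype = reg$biotype[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

write_tsv_with_header <- function(df, path, comment = COORD_HEADER) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the transcript region table
#' @param transcripts Transcript table.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(transcripts, path) {
  write_tsv_with_header(
    transcripts[, c("id", "utr5_len", "cds_len", "utr3_len", "biotype")] |>
      setNames(c("transcript_id", "utr5_len", "cds_len", "utr3_len", "biotype")),
    path, "# region lengths in nt; transcript = 5'UTR + CDS + 3'UTR")
}

#' Write aligned reads in the TSV dialect
#' @param reads Aligned-read table.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  write_tsv_with_header(reads, path)
}

# apply mismatch records to a reference substring to recover the read seq
read_sequence <- function(ref_seq, start, end, mm) {
  s <- substr(ref_seq, start + 1, end)
  ev <- parse_mismatches(mm)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      off <- ev$pos[i] - start + 1L
      substr(s, off, off) <- ev$alt[i]
    }
  }
  s
}

# MD tag for an all-match CIGAR read with substitutions at given offsets
md_tag <- function(read_len, offsets, refs) {
  if (length(offsets) == 0) return(as.character(read_len))
  o <- order(offsets)
  offsets <- offsets[o]; refs <- refs[o]
  gaps <- diff(c(-1L, offsets)) - 1L
  paste0(paste0(gaps, refs, collapse = ""), read_len - offsets[length(offsets)] - 1L)
}

#' Write aligned reads as SAM against the transcript reference
#'
#' Reads are emitted unmapped-strand-forward with an all-match CIGAR;
#' mismatches are recoverable from the MD and read sequence. The
#' replicate index is stored in the `XR` tag.
#'
#' @param reads Aligned-read table.
#' @param transcripts Transcript table (reference).
#' @param path Output SAM file.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", transcripts$id,
                     nchar(transcripts$sequence)), con)
  if (nrow(reads) > 0) {
    seq_by_id <- setNames(transcripts$sequence, transcripts$id)
    lines <- character(nrow(reads))
    for (i in seq_len(nrow(reads))) {
      st <- reads$start[i]; en <- reads$end[i]
      rl <- en - st
      ev <- parse_mismatches(reads$mismatches[i])
      sq <- read_sequence(seq_by_id[[reads$transcript_id[i]]], st, en,
                          reads$mismatches[i])
      md <- md_tag(rl, ev$pos - st, ev$ref)
      lines[i] <- paste(sprintf("read%06d", i), 0L, reads$transcript_id[i],
                        st + 1L, 255L, paste0(rl, "M"), "*", 0L, 0L, sq, "*",
                        paste0("NM:i:", nrow(ev)), paste0("MD:Z:", md),
                        paste0("XR:i:", reads$replicate[i]), sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

# parse one MD tag plus read sequence into mismatch records
md_to_mismatches <- function(md, seq, start, qname) {
  if (is.na(md)) stop("missing MD tag for record ", qname)
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  off <- 0L
  pos <- integer(); ref <- character(); alt <- character()
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      off <- off + as.integer(t)
    } else if (startsWith(t, "^")) {
      stop("deletion in MD tag unsupported for record ", qname)
    } else {
      pos <- c(pos, start + off)
      ref <- c(ref, t)
      alt <- c(alt, substr(seq, off + 1L, off + 1L))
      off <- off + 1L
    }
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Load aligned reads from SAM or the TSV dialect
#'
#' @param path Input file.
#' @param dialect "sam" (MD tags required for mismatch recovery) or "tsv".
#' @param transcripts Optional transcript table; when given, reads are
#'   validated against it (bounds, mismatch reference bases).
#' @return Aligned-read table (`transcript_id`, `start`, `end`,
#'   `mismatches`, `replicate`).
#' @export
load_alignments <- function(path, dialect = c("tsv", "sam"),
                            transcripts = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    reads <- tryCatch(
      read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = c(mismatches = "character")),
      error = function(e) stop("malformed TSV '", path, "': ",
                               conditionMessage(e)))
    if (nrow(reads) == 0) {
      warning("empty alignment file: ", path)
      reads <- data.frame(transcript_id = character(), start = integer(),
                          end = integer(), mismatches = character(),
                          replicate = integer(), stringsAsFactors = FALSE)
    }
    reads$mismatches[is.na(reads$mismatches)] <- ""
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    res <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "cigar", "seq"),
        tag = c("MD", "XR")))[[1]]
    n <- length(res$qname)
    if (n == 0) {
      warning("empty alignment file: ", path)
      return(data.frame(transcript_id = character(), start = integer(),
                        end = integer(), mismatches = character(),
                        replicate = integer(), stringsAsFactors = FALSE))
    }
    if (any(grepl("[^0-9M]", res$cigar)))
      stop("only all-match (xM) CIGARs are supported")
    rl <- as.integer(sub("M$", "", res$cigar))
    start <- res$pos - 1L
    sq <- as.character(res$seq)
    md <- res$tag$MD
    if (is.null(md)) md <- rep(NA_character_, n)
    mm <- character(n)
    for (i in seq_len(n)) {
      ev <- md_to_mismatches(md[i], sq[i], start[i], res$qname[i])
      mm[i] <- if (nrow(ev) == 0) "" else
        paste(paste0(ev$pos, ":", ev$ref, ">", ev$alt), collapse = ";")
    }
    repl <- res$tag$XR
    if (is.null(repl)) repl <- rep(NA_integer_, n)
    reads <- data.frame(transcript_id = as.character(res$rname),
                        start = start, end = start + rl,
                        mismatches = mm, replicate = repl,
                        stringsAsFactors = FALSE)
  }
  if (!is.null(transcripts)) {
    validate_reads(reads, transcripts)
    ev <- parse_mismatches(reads$mismatches)
    if (nrow(ev) > 0) {
      seqs <- setNames(transcripts$sequence, transcripts$id)
      refs <- substr(seqs[reads$transcript_id[ev$read]], ev$pos + 1, ev$pos + 1)
      bad <- refs != ev$ref
      if (any(bad)) {
        stop("mismatch reference base disagrees with transcript for read ",
             ev$read[which(bad)[1]])
      }
    }
  }
  message(nrow(reads), " reads loaded from ", path)
  reads
}

#' Write binding sites as BED6 (transcript coordinates)
#'
#' Name column carries the region label, score the crosslinked read count.
#'
#' @param sites Annotated site table.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  n <- nrow(sites)
  bed <- data.frame(chrom = sites$transcript_id, start = sites$start,
                    end = sites$end,
                    name = if ("region" %in% names(sites)) sites$region
                           else rep(".", n),
                    score = sites$tc_read_count, strand = rep("+", n))
  con <- file(path, "w")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the ground-truth record as TSV
#' @param truth Ground-truth record from [generate_transcriptome()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  ps <- truth$planted_sites
  ps$is_target <- rep(TRUE, nrow(ps))
  write_tsv_with_header(ps, path)
}
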