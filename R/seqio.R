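# Readers and writers for FASTA, FASTQ (Phred+33), SAM text and BED3.
#
# Internally every coordinate is 0-based half-open; conversion to SAM's
# 1-based convention happens only at serialization. Sequences are held as
# plain uppercase character strings over {A,C,G,T,N}; qualities as integer
# vectors.

#' Read a FASTA file
#'
#' Sequences are uppercased and any IUPAC code outside `{A,C,G,T}` is
#' normalised to `N`. Multi-line records are concatenated. Gzip input is
#' handled transparently.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A list of records, each a list with elements `name` and `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("FASTA format error: no records in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(nm))) stop("FASTA format error: record with empty name")
  seqs <- normalize_nt(as.character(ss))
  unname(Map(function(n, s) list(name = n, seq = s), nm, seqs))
}

# Uppercase and collapse non-ACGT letters to N.
normalize_nt <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Read a FASTQ file
#'
#' Qualities are decoded from Phred+33 to integer scores. A record whose
#' sequence and quality strings differ in length is a format error.
#'
#' @param path Path to a FASTQ file (optionally `.gz`).
#' @return A list of records, each with `name`, `seq` and integer `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(ss) == 0) stop("FASTQ format error: no records in ", path)
  quals <- as.character(S4Vectors::mcols(ss)$qualities)
  seqs <- normalize_nt(as.character(ss))
  nm <- sub("\\s.*$", "", names(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(out)) {
    q <- utf8ToInt(quals[i]) - 33L
    if (nchar(seqs[i]) != length(q))
      stop("FASTQ format error: sequence/quality length mismatch in record ",
           nm[i])
    out[[i]] <- list(name = nm[i], seq = seqs[i], qual = q)
  }
  out
}

#' Write a FASTA file
#'
#' @param records List of records with `name` and `seq`.
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$name), con)
    s <- r$seq
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param records List of records with `name`, `seq` and integer `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    q <- r$qual
    if (length(q) != nchar(r$seq))
      stop("sequence/quality length mismatch for ", r$name)
    if (any(q < 0 | q > 93)) stop("Phred quality out of range [0, 93]")
    writeLines(c(paste0("@", r$name), r$seq, "+",
                 intToUtf8(q + 33L, multiple = FALSE)), con)
  }
  invisible(path)
}

# SAM flag bits.
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L
FLAG_READ1 <- 0x40L
FLAG_READ2 <- 0x80L

#' Write SAM records
#'
#' Emits a `@HD` line, one `@SQ` line per reference sequence, a `@PG` line
#' and then the records, in a fixed field order. Record positions are
#' expected 1-based (SAM convention); unmapped records must carry
#' `rname = "*"`, `pos = 0`, `mapq = 0`, `cigar = "*"`.
#'
#' @param records A data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`.
#' @param ref_info A data.frame with columns `name` and `length`.
#' @param path Output path.
#' @export
write_sam <- function(records, ref_info, path) {
  known <- c(ref_info$name, "*", "=")
  if (nrow(records) && any(!records$rname %in% known))
    stop("SAM record references unknown sequence: ",
         paste(unique(setdiff(records$rname, known)), collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_info$name,
                   as.integer(ref_info$length)),
           "@PG\tID:pinmapr\tPN:pinmapr")
  body <- if (nrow(records)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            records$qname, as.integer(records$flag), records$rname,
            as.integer(records$pos), as.integer(records$mapq), records$cigar,
            records$rnext, as.integer(records$pnext),
            as.integer(records$tlen), records$seq, records$qual)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a CIGAR string into operations
#'
#' @param cigar CIGAR string such as `"100M2D50M"`.
#' @return data.frame with columns `len` and `op`, or zero rows for `"*"`.
#' @export
cigar_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Query length consumed by a CIGAR string
#' @param cigar CIGAR string.
#' @return Number of query bases consumed.
#' @export
cigar_query_length <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

#' Read a BED3 file
#'
#' Intervals are 0-based half-open. An empty or inverted interval
#' (`start >= end`) is an error.
#'
#' @param path Path to a 3-column BED file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric"),
                   col.names = c("chrom", "start", "end"))
  if (any(df$start >= df$end))
    stop("BED format error: interval with start >= end")
  df
}

#' Write a BED3 file
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), sorted within each chromosome.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("BED format error: interval with start >= end")
  lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end))
  writeLines(lines, path)
  invisible(path)
}
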