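# The k-mer hash index.
#
# Plus-strand k-mers are hashed with the MurmurHash3 64-bit finalizer into a
# table of H rows of 5 bytes each (a tally byte plus a 32-bit value). Slots
# occurring exactly once across both strands are pins; slots occurring once
# on the plus strand but whose reverse complement also occurs are
# singletons; slots with 2..t plus-strand occurrences are stored as linked
# lists threaded through nearby empty rows; slots exceeding abundance t on
# either strand are excluded. Hash collisions silently merge position lists
# (verification is delegated to alignment).

INDEX_MAGIC <- "PMAPIDX1"
INDEX_VERSION <- 1L

#' Index parameters
#'
#' @param k Word length in nucleotides (8--31; default 24).
#' @param t Maximum indexed slot abundance per strand (default 32; the
#'   veryfast preset uses 3).
#' @param H Hash table size in rows; must be prime. `NULL` selects the
#'   smallest prime at least 1.6 times the reference length (floored at
#'   65,537).
#' @return A list of validated parameters of class `pinmap_params`.
#' @export
index_params <- function(k = 24L, t = 32L, H = NULL) {
  k <- as.integer(k)
  t <- as.integer(t)
  if (k < 8L || k > 31L) stop("k must be in [8, 31]")
  if (t < 1L) stop("t must be >= 1")
  if (!is.null(H) && !is_prime(H)) stop("H must be prime")
  structure(list(k = k, t = t, H = H), class = "pinmap_params")
}

#' Choose the hash table size
#'
#' The smallest prime at least 1.6 times the reference length, floored at
#' 65,537. A table substantially larger than the reference keeps collision
#' rates low; for a human-scale (~3.1 Gb) reference this rule lands near the
#' recommended 5e9 + 29.
#'
#' @param reference_length Total reference length in bases.
#' @param ratio Table-size to reference-length ratio (default 1.6).
#' @return A prime table size.
#' @export
choose_table_size <- function(reference_length, ratio = 1.6) {
  if (reference_length < 1) stop("reference_length must be >= 1")
  next_prime(max(65537, ceiling(ratio * reference_length)))
}

#' Encode a word as a base-4 integer
#'
#' Letters are base-4 digits A=0, C=1, G=2, T=3 with the 5'-most base most
#' significant. Words containing `N` are not encodable and return `NA`.
#'
#' @param word A nucleotide string of length at most 26 (the exactness limit
#'   of double-precision transport; the compiled index path supports the
#'   full k range internally).
#' @return The integer encoding as a double, or `NA` if not encodable.
#' @export
encode_word <- function(word) encode_word_cpp(word)

#' Reverse-complement an encoded word
#'
#' @param w Encoded word (from [encode_word()]).
#' @param k Word length.
#' @return Encoding of the reverse complement; an involution.
#' @export
revcomp_word <- function(w, k) revcomp_word_cpp(w, k)

#' Hash an encoded word to a table slot
#'
#' `slot = murmur64(w) mod H` where murmur64 is the MurmurHash3 64-bit
#' finalizer (fmix64).
#'
#' @param w Encoded word(s).
#' @param H Table size.
#' @return Slot value(s) in `[0, H)`.
#' @export
hash_slot <- function(w, H) hash_slot_cpp(as.numeric(w), H)

#' Classify a slot from its strand abundances
#'
#' @param plus_count Occurrences of the slot on the plus strand.
#' @param minus_count Occurrences of the slot on the minus strand (i.e. of
#'   plus-strand words whose reverse complement hashes to this slot).
#' @param t Abundance threshold.
#' @return One of `"excluded"`, `"pin"`, `"singleton"`, `"multi"`,
#'   `"absent"`.
#' @export
classify_slot <- function(plus_count, minus_count, t) {
  if (plus_count < 0 || minus_count < 0) stop("counts must be >= 0")
  if (plus_count > t || minus_count > t) return("excluded")
  if (plus_count == 1 && minus_count == 0) return("pin")
  if (plus_count == 1) return("singleton")
  if (plus_count >= 2) return("multi")
  "absent"
}

# status code <-> name used across the C++ boundary
STATUS_NAMES <- c("absent", "pin", "singleton", "multi")
status_name <- function(code) STATUS_NAMES[code + 1L]

#' Build a reference index
#'
#' @param sequences List of records with `name` and `seq` (see
#'   [read_fasta()]).
#' @param params Parameters from [index_params()].
#' @return An object of class `pinmap_index`: parameters, a sequence
#'   catalog with global offsets, the packed genome and the row table.
#' @export
build_index <- function(sequences, params = index_params()) {
  if (!inherits(params, "pinmap_params")) stop("params must be pinmap_params")
  seqs <- vapply(sequences, function(r) r$seq, character(1))
  names <- vapply(sequences, function(r) r$name, character(1))
  lens <- nchar(seqs)
  total <- sum(as.numeric(lens))
  if (total >= 2^32) stop("reference of 4 GB or more is not supported")
  offsets <- cumsum(c(0, lens[-length(lens)]))
  catalog <- data.frame(name = names, offset = as.numeric(offsets),
                        length = as.numeric(lens), stringsAsFactors = FALSE)
  H <- params$H %||% choose_table_size(total)
  if (!is_prime(H)) stop("H must be prime")
  genome <- charToRaw(paste(seqs, collapse = ""))
  built <- build_rows_cpp(genome, params$k, params$t, H,
                          catalog$offset, catalog$length)
  structure(list(params = list(k = params$k, t = params$t, H = H),
                 catalog = catalog, genome = genome, rows = built$rows,
                 stats = built[c("n_pin", "n_singleton", "n_multi",
                                 "n_excluded")]),
            class = "pinmap_index")
}

#' @export
print.pinmap_index <- function(x, ...) {
  cat("pinmap_index: k=", x$params$k, " t=", x$params$t,
      " H=", format(x$params$H, big.mark = ","), "\n", sep = "")
  cat(" reference: ", nrow(x$catalog), " sequence(s), ",
      format(sum(x$catalog$length), big.mark = ","), " bases\n", sep = "")
  cat(" slots: ", x$stats$n_pin, " pins, ", x$stats$n_singleton,
      " singletons, ", x$stats$n_multi, " multi, ", x$stats$n_excluded,
      " excluded\n", sep = "")
  invisible(x)
}

#' Decode one slot of the index
#'
#' Follows 7-bit skip pointers and 32-bit overflow pointers to termination.
#' A slot whose row is empty or used as a list interior is reported absent;
#' excluded slots are not recorded in the table and also decode as absent.
#'
#' @param index A `pinmap_index`.
#' @param slot Slot value in `[0, H)`.
#' @return List with `status` (`"absent"`, `"pin"`, `"singleton"`,
#'   `"multi"`), sorted 0-based global `positions`, and `rows_fetched`.
#' @export
lookup_positions <- function(index, slot) {
  res <- decode_slot_cpp(index$rows, index$params$H, slot)
  list(status = status_name(res$status), positions = sort(res$positions),
       rows_fetched = res$rows_fetched)
}

#' Decode every present slot of the index
#'
#' @param index A `pinmap_index`.
#' @return data.frame with `slot`, `status` and a list-column `positions`.
#' @export
decode_index_slots <- function(index) {
  res <- decode_all_cpp(index$rows, index$params$H)
  data.frame(slot = res$slot, status = status_name(res$status),
             positions = I(lapply(res$positions, sort)),
             stringsAsFactors = FALSE)
}

#' Convert a global coordinate to (sequence, local position)
#'
#' @param index A `pinmap_index`.
#' @param gpos 0-based global coordinates.
#' @return data.frame with `name`, `local` (0-based) and `seq_index`.
#' @export
global_to_local <- function(index, gpos) {
  idx <- findInterval(gpos, index$catalog$offset)
  data.frame(name = index$catalog$name[idx],
             local = gpos - index$catalog$offset[idx],
             seq_index = idx, stringsAsFactors = FALSE)
}

#' Serialize an index to disk
#'
#' Little-endian container: an 8-byte magic, a format version, the
#' parameters, the sequence catalog, the packed genome and exactly `5 * H`
#' bytes of rows.
#'
#' @param index A `pinmap_index`.
#' @param path Output path.
#' @export
save_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(INDEX_VERSION, con, size = 4, endian = "little")
  writeBin(as.integer(c(index$params$k, index$params$t)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(index$params$H), con, size = 8, endian = "little")
  writeBin(nrow(index$catalog), con, size = 4, endian = "little")
  for (i in seq_len(nrow(index$catalog))) {
    nm <- charToRaw(index$catalog$name[i])
    writeBin(length(nm), con, size = 4, endian = "little")
    writeBin(nm, con)
    writeBin(as.numeric(index$catalog$offset[i]), con, size = 8,
             endian = "little")
    writeBin(as.numeric(index$catalog$length[i]), con, size = 8,
             endian = "little")
  }
  writeBin(as.numeric(length(index$genome)), con, size = 8, endian = "little")
  writeBin(index$genome, con)
  writeBin(as.numeric(length(index$rows)), con, size = 8, endian = "little")
  writeBin(index$rows, con)
  invisible(path)
}

#' Load an index from disk
#'
#' @param path Path written by [save_index()].
#' @return A `pinmap_index`.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, INDEX_MAGIC))
    stop("index format error: bad magic '", magic, "'")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, INDEX_VERSION))
    stop("index format error: unsupported version ", version)
  kt <- readBin(con, "integer", 2, size = 4, endian = "little")
  H <- readBin(con, "numeric", 1, size = 8, endian = "little")
  nseq <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nseq) != 1 || is.na(nseq) || nseq < 1)
    stop("index format error: truncated file")
  catalog <- data.frame(name = character(nseq), offset = numeric(nseq),
                        length = numeric(nseq), stringsAsFactors = FALSE)
  for (i in seq_len(nseq)) {
    nl <- readBin(con, "integer", 1, size = 4, endian = "little")
    catalog$name[i] <- rawToChar(readBin(con, "raw", nl))
    catalog$offset[i] <- readBin(con, "numeric", 1, size = 8,
                                 endian = "little")
    catalog$length[i] <- readBin(con, "numeric", 1, size = 8,
                                 endian = "little")
  }
  glen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  genome <- readBin(con, "raw", glen)
  rlen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  rows <- readBin(con, "raw", rlen)
  if (length(genome) != glen || length(rows) != rlen)
    stop("index format error: truncated file")
  if (rlen != 5 * H)
    stop("index format error: row region size does not equal 5*H")
  structure(list(params = list(k = kt[1], t = kt[2], H = H),
                 catalog = catalog, genome = genome, rows = rows,
                 stats = NULL),
            class = "pinmap_index")
}
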