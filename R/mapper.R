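# The three-pass search per read pair.
#
# Pass 1 looks for a brace: a pair of pins, one per mate (or two
# non-overlapping pins in one read), whose reference coordinates are
# consistent with one fragment in FR orientation. A good brace (both reads
# align essentially full length) terminates the search immediately. Pass 2
# seeds from all remaining slots with abundance <= 2, pass 3 from the rest
# up to abundance t. Hash rows are fetched once per scheduled position in
# pass 1 and cached; linked lists are chased lazily in later passes.

#' Query word schedule
#'
#' Word positions are visited at a prime stride so that neighbouring
#' (correlated) words are not queried consecutively. The stride is the
#' smallest prime at least `k + 5`; if it divides the word count `n` the
#' next prime is taken, preserving the visit-each-word-exactly-once
#' guarantee. For `k = 24`, `L = 150` this gives stride 29 over
#' `n = 127` words.
#'
#' @param L Read length.
#' @param k Word length.
#' @return 0-based word positions in visit order (a permutation of
#'   `0:(n-1)`).
#' @export
schedule_positions <- function(L, k) {
  n <- L - k + 1L
  if (n < 1L) stop("read shorter than k")
  p <- next_prime(k + 5L)
  while (n %% p == 0L) p <- next_prime(p + 1L)
  as.integer((p * (seq_len(n) - 1L)) %% n)
}

#' Stride for a given word length
#' @param L Read length.
#' @param k Word length.
#' @return The prime stride used by [schedule_positions()].
#' @export
schedule_stride <- function(L, k) {
  n <- L - k + 1L
  if (n < 1L) stop("read shorter than k")
  p <- next_prime(k + 5L)
  while (n %% p == 0L) p <- next_prime(p + 1L)
  p
}

#' Search parameters
#'
#' @param max_frag Maximum fragment length for a coordinate-compatible pair.
#' @param good_margin A full-length alignment scoring at least
#'   `qlen - good_margin` counts as high-scoring (good brace / early
#'   termination).
#' @param max_alignments Cap on stored alignments per read.
#' @param max_gapped Cap on gapped extensions per read.
#' @param diag_tol Tolerance in bases when deduplicating candidate reference
#'   locations, and for the single-end brace diagonal consistency check.
#' @param pass3 Attempt the high-abundance third pass.
#' @param preset `"default"` or `"veryfast"` (abundance cap 3, x-drop 8,
#'   no third pass, at most 2 gapped extensions).
#' @return A list of class `pinmap_search`.
#' @export
search_params <- function(max_frag = 1000L, good_margin = 10L,
                          max_alignments = 16L, max_gapped = 4L,
                          diag_tol = 16L, pass3 = TRUE,
                          preset = c("default", "veryfast")) {
  preset <- match.arg(preset)
  sp <- list(max_frag = as.numeric(max_frag), good_margin = good_margin,
             max_alignments = max_alignments, max_gapped = max_gapped,
             diag_tol = diag_tol, pass3 = pass3, preset = preset,
             abundance_cap = NA_integer_)
  if (preset == "veryfast") {
    sp$pass3 <- FALSE
    sp$max_gapped <- 2L
    sp$abundance_cap <- 3L
  }
  structure(sp, class = "pinmap_search")
}

# Bounds of the reference sequence containing global position g.
seq_bounds <- function(index, g) {
  i <- findInterval(g, index$catalog$offset)
  lo <- index$catalog$offset[i]
  list(seq_index = i, lo = lo, hi = lo + index$catalog$length[i])
}

# Mutable per-pair search state for one read (one orientation bookkeeping).
new_read_state <- function(seq, index, sp, scoring) {
  L <- nchar(seq)
  sched <- schedule_positions(L, index$params$k)
  ctx <- query_context_cpp(index$rows, index$params$H, seq,
                           index$params$k, sched)
  e <- new.env(parent = emptyenv())
  e$seq <- seq
  e$rcseq <- revcomp(seq)
  e$L <- L
  e$ctx <- ctx
  e$row_fetches <- ctx$row_fetches
  e$tried_plus <- numeric(0)   # attempted ref starts, plus-orientation
  e$tried_minus <- numeric(0)
  e$alignments <- list()       # accepted: score, ref_start, strand, cigar
  e$n_gapped <- 0L
  e$done <- FALSE              # early-termination latch
  e
}

# Implied plus-strand reference start of the (oriented) read for a seed hit.
implied_start <- function(state, qpos, strand, coord, k) {
  if (strand == "+") coord - qpos else coord - (state$L - k - qpos)
}

already_tried <- function(state, strand, rstart, tol) {
  tried <- if (strand == "+") state$tried_plus else state$tried_minus
  length(tried) && any(abs(tried - rstart) <= tol)
}

mark_tried <- function(state, strand, rstart) {
  if (strand == "+") state$tried_plus <- c(state$tried_plus, rstart)
  else state$tried_minus <- c(state$tried_minus, rstart)
}

# Seed-and-extend one candidate location. Returns the accepted alignment or
# NULL. Bookkeeps tried locations, gapped-extension budget and acceptance.
attempt_alignment <- function(state, index, qpos, strand, coord, scoring, sp) {
  k <- index$params$k
  rstart0 <- implied_start(state, qpos, strand, coord, k)
  if (already_tried(state, strand, rstart0, sp$diag_tol)) return(NULL)
  mark_tried(state, strand, rstart0)
  oriented <- if (strand == "+") state$seq else state$rcseq
  oq <- if (strand == "+") qpos else state$L - k - qpos
  b <- seq_bounds(index, coord)
  if (coord + k > b$hi) return(NULL)
  hsp <- xdrop_extend_cpp(oriented, index$genome, oq, coord, k, b$lo, b$hi,
                          scoring$x, scoring$match, scoring$mismatch)
  qlen <- state$L
  hsp_min <- ceiling(qlen * scoring$hsp_min_frac)
  aln <- NULL
  if (hsp$qstart == 0L && hsp$qend == qlen) {
    # HSP covers the whole query: promote, rescoring the M-run honestly
    sc <- score_identity_cpp(oriented, index$genome, hsp$rstart,
                             scoring$match, scoring$mismatch)
    aln <- list(score = sc, ref_start = hsp$rstart, strand = strand,
                cigar = paste0(qlen, "M"))
  } else if (hsp$score >= hsp_min && state$n_gapped < sp$max_gapped) {
    state$n_gapped <- state$n_gapped + 1L
    g <- banded_align_cpp(oriented, index$genome, b$lo, b$hi, hsp$rstart,
                          hsp$qstart, scoring$band, scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend)
    if (isTRUE(g$feasible))
      aln <- list(score = g$score, ref_start = g$ref_start, strand = strand,
                  cigar = g$cigar)
  }
  if (is.null(aln) || aln$score < ceiling(qlen * scoring$hsp_min_frac))
    return(NULL)
  if (length(state$alignments) < sp$max_alignments)
    state$alignments[[length(state$alignments) + 1L]] <- aln
  if (aln$score >= qlen - sp$good_margin) state$done <- TRUE
  aln
}

# Pins of a read in schedule order (plus strand before minus per position).
pin_list <- function(state) {
  ctx <- state$ctx
  out <- list()
  for (j in seq_along(ctx$pos)) {
    if (!is.na(ctx$status_plus[j]) && ctx$status_plus[j] == 1L)
      out[[length(out) + 1L]] <- list(qpos = ctx$pos[j], strand = "+",
                                      coord = ctx$value_plus[j])
    if (!is.na(ctx$status_minus[j]) && ctx$status_minus[j] == 1L)
      out[[length(out) + 1L]] <- list(qpos = ctx$pos[j], strand = "-",
                                      coord = ctx$value_minus[j])
  }
  out
}

#' Candidate braces for a read pair
#'
#' Pins are advanced alternately (next pin in R1, then next pin in R2), and
#' each candidate is screened on coordinates alone: FR orientation, same
#' reference sequence and implied fragment length in `(0, max_frag]`.
#'
#' @param ctx_r1,ctx_r2 Read states from the internal context constructor
#'   (exposed for testing through [map_pair()]'s machinery).
#' @param index A `pinmap_index`.
#' @param max_frag Maximum fragment length.
#' @return List of braces: pin indices, implied starts and fragment length.
#' @keywords internal
find_braces <- function(ctx_r1, ctx_r2, index, max_frag = 1000) {
  pins1 <- pin_list(ctx_r1)
  pins2 <- pin_list(ctx_r2)
  k <- index$params$k
  out <- list()
  for (cand in brace_candidate_order(length(pins1), length(pins2))) {
    p1 <- pins1[[cand[1]]]
    p2 <- pins2[[cand[2]]]
    if (p1$strand == p2$strand) next # FR requires opposite query strands
    a1 <- implied_start(ctx_r1, p1$qpos, p1$strand, p1$coord, k)
    a2 <- implied_start(ctx_r2, p2$qpos, p2$strand, p2$coord, k)
    b1 <- seq_bounds(index, p1$coord)
    b2 <- seq_bounds(index, p2$coord)
    if (b1$seq_index != b2$seq_index) next
    frag <- if (p1$strand == "+") (a2 + ctx_r2$L) - a1 else (a1 + ctx_r1$L) - a2
    if (frag <= 0 || frag > max_frag) next
    out[[length(out) + 1L]] <- list(p1 = p1, p2 = p2, a1 = a1, a2 = a2,
                                    frag = frag)
  }
  out
}

# Alternating-advance candidate order over pin pairs: (1,1), (2,1), (2,2),
# (3,2), (3,3), ... then a tail when one list is exhausted.
brace_candidate_order <- function(n1, n2) {
  out <- list()
  i <- 1L; j <- 1L
  if (n1 >= 1L && n2 >= 1L) out[[1L]] <- c(1L, 1L)
  repeat {
    adv <- FALSE
    if (i < n1 && j <= n2) { i <- i + 1L; out[[length(out) + 1L]] <- c(i, j); adv <- TRUE }
    if (j < n2 && i <= n1) { j <- j + 1L; out[[length(out) + 1L]] <- c(i, j); adv <- TRUE }
    if (!adv) break
  }
  out
}

# Decode a slot's position list with per-pair caching.
slot_positions <- function(index, slot, cache, state) {
  key <- as.character(slot)
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- decode_slot_cpp(index$rows, index$params$H, slot)
  state$row_fetches <- state$row_fetches + res$rows_fetched - 1L # head cached
  cache[[key]] <- res$positions
  res$positions
}

# Seed pass over one read: statuses wanted = subset of context statuses.
# A slot's candidate positions are all attempted before the early-exit check
# so that exact repeat copies surface as ties (MAPQ 0) rather than being
# hidden by early termination.
seed_pass <- function(state, index, scoring, sp, cache, min_ab, max_ab,
                      include_pins = FALSE) {
  ctx <- state$ctx
  for (j in seq_along(ctx$pos)) {
    if (state$done) return(invisible(NULL))
    for (strand in c("+", "-")) {
      st <- if (strand == "+") ctx$status_plus[j] else ctx$status_minus[j]
      if (is.na(st) || st <= 0L) next
      if (st == 1L && !include_pins) next
      slot <- if (strand == "+") ctx$slot_plus[j] else ctx$slot_minus[j]
      pos <- if (st %in% c(1L, 2L)) {
        v <- if (strand == "+") ctx$value_plus[j] else ctx$value_minus[j]
        v
      } else {
        slot_positions(index, slot, cache, state)
      }
      ab <- length(pos)
      if (!is.na(sp$abundance_cap) && ab > sp$abundance_cap) next
      if (ab < min_ab || ab > max_ab) next
      for (coord in pos)
        attempt_alignment(state, index, ctx$pos[j], strand, coord,
                          scoring, sp)
      if (state$done) return(invisible(NULL))
    }
  }
  invisible(NULL)
}

# Best and second-best among stored alignments given the chosen alignment.
second_best <- function(state, chosen) {
  scores <- vapply(state$alignments, function(a) a$score, numeric(1))
  keys <- vapply(state$alignments, function(a)
    paste0(a$strand, ":", a$ref_start), character(1))
  ckey <- paste0(chosen$strand, ":", chosen$ref_start)
  other <- scores[keys != ckey]
  if (!length(other)) return(NA_real_)
  max(other)
}

finalize_read <- function(state, index, chosen, sp) {
  qlen <- state$L
  if (is.null(chosen))
    return(list(mapped = FALSE, qlen = qlen, score = NA_real_,
                second = NA_real_, mapq = 0L))
  S <- second_best(state, chosen)
  if (is.na(S)) S <- chosen$score / 2
  S <- min(S, chosen$score) # pairing may choose a non-top alignment
  loc <- global_to_local(index, chosen$ref_start)
  list(mapped = TRUE, seq_name = loc$name, pos = loc$local,
       strand = chosen$strand, cigar = chosen$cigar, qlen = qlen,
       score = chosen$score, second = S,
       mapq = compute_mapq(chosen$score, S, qlen))
}

# Pick the FR-consistent pair maximizing T1 + T2 within max_frag.
best_pairing <- function(s1, s2, index, sp) {
  best <- NULL
  for (a1 in s1$alignments) for (a2 in s2$alignments) {
    if (a1$strand == a2$strand) next
    b1 <- seq_bounds(index, a1$ref_start)
    b2 <- seq_bounds(index, a2$ref_start)
    if (b1$seq_index != b2$seq_index) next
    frag <- if (a1$strand == "+") (a2$ref_start + s2$L) - a1$ref_start
            else (a1$ref_start + s1$L) - a2$ref_start
    if (frag <= 0 || frag > sp$max_frag) next
    if (is.null(best) || a1$score + a2$score > best$sum)
      best <- list(a1 = a1, a2 = a2, sum = a1$score + a2$score, frag = frag)
  }
  best
}

top_alignment <- function(state) {
  if (!length(state$alignments)) return(NULL)
  scores <- vapply(state$alignments, function(a) a$score, numeric(1))
  state$alignments[[which.max(scores)]]
}

#' Map a read pair
#'
#' Runs the brace pass, then low- and high-abundance seed passes, pairs the
#' per-read alignments and computes MAPQ. Reads shorter than k, or reads
#' whose every indexed word is destroyed, yield unmapped results.
#'
#' @param r1,r2 Read records (`name`, `seq`, optional `qual`).
#' @param index A `pinmap_index`.
#' @param scoring A [scoring_scheme()].
#' @param sp A [search_params()].
#' @return A `pinmap_pair` result: per-mate placement (`r1`, `r2`), pairing
#'   status, template length and search statistics.
#' @export
map_pair <- function(r1, r2, index, scoring = scoring_scheme(),
                     sp = search_params()) {
  k <- index$params$k
  if (nchar(r1$seq) < k || nchar(r2$seq) < k)
    return(unmapped_pair(r1, r2))
  s1 <- new_read_state(r1$seq, index, sp, scoring)
  s2 <- new_read_state(r2$seq, index, sp, scoring)
  cache <- new.env(parent = emptyenv())
  stats <- c(braces_tried = 0, pass2 = 0, pass3 = 0, early = 0)

  braces <- find_braces(s1, s2, index, sp$max_frag)
  good <- FALSE
  for (br in braces) {
    stats["braces_tried"] <- stats["braces_tried"] + 1
    a1 <- attempt_alignment(s1, index, br$p1$qpos, br$p1$strand,
                            br$p1$coord, scoring, sp)
    a2 <- attempt_alignment(s2, index, br$p2$qpos, br$p2$strand,
                            br$p2$coord, scoring, sp)
    ok1 <- !is.null(a1) && a1$score >= s1$L - sp$good_margin
    ok2 <- !is.null(a2) && a2$score >= s2$L - sp$good_margin
    if (ok1 && ok2) { good <- TRUE; stats["early"] <- 1; break }
  }
  if (!good) {
    s1$done <- s2$done <- FALSE
    stats["pass2"] <- 1
    seed_pass(s1, index, scoring, sp, cache, 1L, 2L, include_pins = TRUE)
    seed_pass(s2, index, scoring, sp, cache, 1L, 2L, include_pins = TRUE)
    if (sp$pass3 && (!length(s1$alignments) || !length(s2$alignments) ||
                     !s1$done || !s2$done)) {
      stats["pass3"] <- 1
      seed_pass(s1, index, scoring, sp, cache, 3L, index$params$t)
      seed_pass(s2, index, scoring, sp, cache, 3L, index$params$t)
    }
  }

  pairing <- best_pairing(s1, s2, index, sp)
  if (!is.null(pairing)) {
    c1 <- pairing$a1; c2 <- pairing$a2
    proper <- TRUE
    tlen <- pairing$frag
  } else {
    c1 <- top_alignment(s1)
    c2 <- top_alignment(s2)
    proper <- FALSE
    tlen <- 0
  }
  structure(list(r1 = c(list(name = r1$name, seq = r1$seq,
                             qual = r1$qual %||% NULL),
                        finalize_read(s1, index, c1, sp)),
                 r2 = c(list(name = r2$name, seq = r2$seq,
                             qual = r2$qual %||% NULL),
                        finalize_read(s2, index, c2, sp)),
                 proper = proper, tlen = tlen, paired = TRUE,
                 stats = c(stats, row_fetches_r1 = s1$row_fetches,
                           row_fetches_r2 = s2$row_fetches)),
            class = "pinmap_pair")
}

unmapped_pair <- function(r1, r2) {
  u <- function(r) list(name = r$name, seq = r$seq, qual = r$qual %||% NULL,
                        mapped = FALSE, qlen = nchar(r$seq),
                        score = NA_real_, second = NA_real_, mapq = 0L)
  structure(list(r1 = u(r1), r2 = if (!is.null(r2)) u(r2), proper = FALSE,
                 tlen = 0, paired = !is.null(r2),
                 stats = c(braces_tried = 0, pass2 = 0, pass3 = 0, early = 0,
                           row_fetches_r1 = 0, row_fetches_r2 = 0)),
            class = "pinmap_pair")
}

#' Map a single-end read
#'
#' As [map_pair()], but a brace is a pair of non-overlapping pins within the
#' read, on the same query strand, with consistent implied reference starts
#' (within `diag_tol`).
#'
#' @inheritParams map_pair
#' @param read Read record (`name`, `seq`, optional `qual`).
#' @return A `pinmap_pair` with only `r1` filled and `paired = FALSE`.
#' @export
map_single <- function(read, index, scoring = scoring_scheme(),
                       sp = search_params()) {
  k <- index$params$k
  if (nchar(read$seq) < k) return(unmapped_pair(read, NULL))
  s1 <- new_read_state(read$seq, index, sp, scoring)
  cache <- new.env(parent = emptyenv())
  stats <- c(braces_tried = 0, pass2 = 0, pass3 = 0, early = 0)
  pins <- pin_list(s1)
  good <- FALSE
  if (length(pins) >= 2) {
    for (cidx in 2:length(pins)) {
      for (i in 1:(cidx - 1)) {
        p1 <- pins[[i]]; p2 <- pins[[cidx]]
        if (p1$strand != p2$strand) next
        if (abs(p1$qpos - p2$qpos) < k) next # overlapping pins: not a brace
        a1 <- implied_start(s1, p1$qpos, p1$strand, p1$coord, k)
        a2 <- implied_start(s1, p2$qpos, p2$strand, p2$coord, k)
        if (abs(a1 - a2) > sp$diag_tol) next
        stats["braces_tried"] <- stats["braces_tried"] + 1
        a <- attempt_alignment(s1, index, p1$qpos, p1$strand, p1$coord,
                               scoring, sp)
        if (!is.null(a) && a$score >= s1$L - sp$good_margin) {
          good <- TRUE; stats["early"] <- 1
        }
        if (good) break
      }
      if (good) break
    }
  }
  if (!good) {
    s1$done <- FALSE
    stats["pass2"] <- 1
    seed_pass(s1, index, scoring, sp, cache, 1L, 2L, include_pins = TRUE)
    if (sp$pass3 && !s1$done) {
      stats["pass3"] <- 1
      seed_pass(s1, index, scoring, sp, cache, 3L, index$params$t)
    }
  }
  c1 <- top_alignment(s1)
  structure(list(r1 = c(list(name = read$name, seq = read$seq,
                             qual = read$qual %||% NULL),
                        finalize_read(s1, index, c1, sp)),
                 r2 = NULL, proper = FALSE, tlen = 0, paired = FALSE,
                 stats = c(stats, row_fetches_r1 = s1$row_fetches,
                           row_fetches_r2 = 0)),
            class = "pinmap_pair")
}

# ------------------------------------------------------------ SAM emission

qual_string <- function(rec) {
  if (is.null(rec$qual)) strrep("I", rec$qlen)
  else intToUtf8(rec$qual + 33L, multiple = FALSE)
}

mate_record <- function(rec, mate, flag_self, proper, tlen) {
  flag <- flag_self
  if (!is.null(mate)) {
    flag <- flag + FLAG_PAIRED
    if (proper) flag <- flag + FLAG_PROPER
    if (!mate$mapped) flag <- flag + FLAG_MUNMAPPED
    else if (mate$strand == "-") flag <- flag + FLAG_MREVERSE
  }
  seq <- rec$seq
  qual <- qual_string(rec)
  if (!rec$mapped) {
    flag <- flag + FLAG_UNMAPPED
    return(data.frame(qname = rec$name, flag = flag, rname = "*", pos = 0L,
                      mapq = 0L, cigar = "*", rnext = "*", pnext = 0L,
                      tlen = 0L, seq = seq, qual = qual,
                      stringsAsFactors = FALSE))
  }
  if (rec$strand == "-") {
    flag <- flag + FLAG_REVERSE
    seq <- revcomp(seq)
    qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
  }
  rnext <- "*"; pnext <- 0L
  if (!is.null(mate) && mate$mapped) {
    rnext <- if (identical(mate$seq_name, rec$seq_name)) "=" else mate$seq_name
    pnext <- as.integer(mate$pos + 1L)
  }
  data.frame(qname = rec$name, flag = flag, rname = rec$seq_name,
             pos = as.integer(rec$pos + 1L), mapq = rec$mapq,
             cigar = rec$cigar, rnext = rnext, pnext = pnext,
             tlen = as.integer(tlen), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Convert mapping results to SAM records
#'
#' @param results List of `pinmap_pair` results.
#' @return A data.frame of SAM records suitable for [write_sam()].
#' @export
results_to_sam <- function(results) {
  recs <- list()
  for (res in results) {
    if (res$paired) {
      t1 <- t2 <- 0L
      if (res$proper) {
        left_is_r1 <- res$r1$pos <= res$r2$pos
        t1 <- if (left_is_r1) res$tlen else -res$tlen
        t2 <- -t1
      }
      recs[[length(recs) + 1L]] <-
        mate_record(res$r1, res$r2, FLAG_READ1, res$proper, t1)
      recs[[length(recs) + 1L]] <-
        mate_record(res$r2, res$r1, FLAG_READ2, res$proper, t2)
    } else {
      recs[[length(recs) + 1L]] <- mate_record(res$r1, NULL, 0L, FALSE, 0L)
    }
  }
  do.call(rbind, recs)
}

#' Map reads from records or FASTQ files and write SAM
#'
#' @param r1 List of read records, or a FASTQ path.
#' @param r2 Optional mate records or FASTQ path (paired mode).
#' @param index A `pinmap_index`.
#' @param sam_path Optional output SAM path.
#' @param scoring A [scoring_scheme()].
#' @param sp A [search_params()].
#' @return Invisibly, the list of `pinmap_pair` results.
#' @export
map_reads <- function(r1, r2 = NULL, index, sam_path = NULL,
                      scoring = scoring_scheme(), sp = search_params()) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  results <- if (!is.null(r2)) {
    if (length(r1) != length(r2)) stop("R1/R2 read counts differ")
    lapply(seq_along(r1), function(i)
      map_pair(r1[[i]], r2[[i]], index, scoring, sp))
  } else {
    lapply(r1, function(r) map_single(r, index, scoring, sp))
  }
  if (!is.null(sam_path)) {
    sam <- results_to_sam(results)
    write_sam(sam, data.frame(name = index$catalog$name,
                              length = index$catalog$length), sam_path)
  }
  invisible(results)
}
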