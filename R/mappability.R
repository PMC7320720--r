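# Unmappable-region identification.
#
# Error-free paired reads are simulated from the reference at a target
# depth; a base is mappable iff at least one read with MAPQ >= Q covers it.
# Unmappable regions are maximal runs of unmappable bases of length >= L
# whose every length-L window contains fewer than 10 uncalled bases.
# Consensus across mappers/configurations is the base-level intersection.

#' Mappability scan parameters
#'
#' @param L Read length (default 150).
#' @param Q MAPQ threshold for a covering read to count (default 3; an
#'   error probability of 0.5 or more is presumed unusable downstream).
#' @param depth Target per-base read coverage (default 10).
#' @param fragment Fragment length for the simulated pairs.
#' @param max_uncalled Maximum uncalled (N) bases tolerated per length-L
#'   window of a reported region.
#' @param placement `"tiling"` (deterministic; the default for
#'   reproducibility) or `"random"`.
#' @return A list of class `pinmap_mappability`.
#' @export
mappability_params <- function(L = 150L, Q = 3L, depth = 10L,
                               fragment = 350L, max_uncalled = 10L,
                               placement = c("tiling", "random")) {
  placement <- match.arg(placement)
  if (depth < 1) stop("depth must be >= 1")
  structure(list(L = as.integer(L), Q = as.integer(Q),
                 depth = as.integer(depth), fragment = as.integer(fragment),
                 max_uncalled = as.integer(max_uncalled),
                 placement = placement),
            class = "pinmap_mappability")
}

# Simulate error-free pairs and collect per-read placements with MAPQ.
# Returns a data.frame: chrom, start (0-based), end, mapq per mapped read.
coverage_scan <- function(reference, index, params, scoring, sp, seed) {
  L <- params$L; Fr <- params$fragment
  spacing <- max(1L, floor(2 * L / params$depth))
  placements <- list()
  for (si in seq_along(reference)) {
    rec <- reference[[si]]
    G <- nchar(rec$seq)
    if (G < Fr) next
    starts <- if (params$placement == "tiling")
      seq(0L, G - Fr, by = spacing)
    else with_seed(seed + si, sort(floor(runif(ceiling(G / spacing),
                                               0, G - Fr + 1))))
    for (st in starts) {
      r1 <- list(name = sprintf("m%d_%d", si, st),
                 seq = substr(rec$seq, st + 1, st + L))
      r2 <- list(name = r1$name,
                 seq = revcomp(substr(rec$seq, st + Fr - L + 1, st + Fr)))
      res <- map_pair(r1, r2, index, scoring, sp)
      for (rec_m in list(res$r1, res$r2)) {
        if (!isTRUE(rec_m$mapped)) next
        placements[[length(placements) + 1L]] <-
          data.frame(chrom = rec_m$seq_name, start = rec_m$pos,
                     end = rec_m$pos + rec_m$qlen, mapq = rec_m$mapq,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(placements))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mapq = integer(0)))
  do.call(rbind, placements)
}

# Unmappable intervals for one chromosome given covering placements.
unmappable_one <- function(seq, chrom, cov, params) {
  G <- nchar(seq)
  L <- params$L
  covered <- logical(G)
  keep <- cov[cov$mapq >= params$Q, , drop = FALSE]
  if (nrow(keep)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = keep$start + 1L,
                                           end = pmin(keep$end, G)))
    for (i in seq_along(ir))
      covered[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- TRUE
  }
  runs <- rle(!covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= L)
  if (!length(cand))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  isN <- as.integer(strsplit(seq, "")[[1]] == "N")
  cumN <- c(0L, cumsum(isN))
  ok <- vapply(cand, function(ci) {
    s <- starts[ci]; e <- ends[ci]
    # every length-L window inside [s, e] must hold < max_uncalled Ns
    ws <- s:(e - L + 1)
    maxN <- max(cumN[ws + L] - cumN[ws])
    maxN < params$max_uncalled
  }, logical(1))
  if (!any(ok))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  data.frame(chrom = chrom, start = starts[cand[ok]] - 1,
             end = ends[cand[ok]], stringsAsFactors = FALSE)
}

#' Find unmappable reference regions
#'
#' @param reference List of sequence records the index was built on.
#' @param index A `pinmap_index`.
#' @param params A [mappability_params()].
#' @param scoring,sp Mapper configuration.
#' @param seed Seed for random placement (unused by tiling).
#' @param placements Optional precomputed result of a previous scan (as
#'   returned in the `placements` attribute), allowing several MAPQ
#'   thresholds to be evaluated from one mapping run.
#' @return BED-style data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open), sorted, with the raw `placements` attached as an
#'   attribute.
#' @export
find_unmappable <- function(reference, index, params = mappability_params(),
                            scoring = scoring_scheme(), sp = search_params(),
                            seed = 1L, placements = NULL) {
  if (is.null(placements))
    placements <- coverage_scan(reference, index, params, scoring, sp, seed)
  out <- list()
  for (rec in reference) {
    cov <- placements[placements$chrom == rec$name, , drop = FALSE]
    out[[length(out) + 1L]] <- unmappable_one(rec$seq, rec$name, cov, params)
  }
  bed <- do.call(rbind, out)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  attr(bed, "placements") <- placements
  bed
}

#' Intersect unmappable region sets
#'
#' Base-level intersection across two or more BED-style interval sets;
#' output is sorted and merged.
#'
#' @param region_sets List of data.frames (`chrom`, `start`, `end`).
#' @return data.frame of the consensus intervals.
#' @export
consensus_intersect <- function(region_sets) {
  if (length(region_sets) < 2) stop("need at least two region sets")
  chroms_per_set <- lapply(region_sets, function(b) unique(b$chrom))
  chroms <- Reduce(intersect, chroms_per_set)
  extra <- setdiff(unique(unlist(chroms_per_set)), chroms)
  # a chromosome present in one set but absent from another simply has an
  # empty intersection; a naming mismatch (disjoint name universes) is an
  # error
  if (length(chroms) == 0 && length(extra) > 0 &&
      all(lengths(chroms_per_set) > 0))
    stop("chromosome names do not match across region sets")
  out <- list()
  for (ch in chroms) {
    irs <- lapply(region_sets, function(b) {
      d <- b[b$chrom == ch, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    })
    inter <- Reduce(IRanges::intersect, irs)
    if (length(inter))
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = IRanges::start(inter) - 1,
                   end = IRanges::end(inter), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  bed <- do.call(rbind, out)
  bed[order(bed$chrom, bed$start), , drop = FALSE]
}
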