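# Alignment: scoring, gapless x-drop extension, HSP-constrained banded
# gapped alignment, and MAPQ.

#' Alignment scoring scheme
#'
#' Matches score +1 so the best possible alignment score equals the query
#' length, which the MAPQ formula relies on. Gaps cost
#' `gap_open + g * gap_extend` for length `g`.
#'
#' @param mismatch Mismatch penalty (negative).
#' @param gap_open Gap opening penalty (negative).
#' @param gap_extend Per-base gap extension penalty (negative).
#' @param x X-drop threshold for gapless extension (positive).
#' @param band Band half-width for gapped terminal regions.
#' @param hsp_min_frac An HSP is accepted when its score reaches this
#'   fraction of the query length (rounded up).
#' @return A list of class `pinmap_scoring`.
#' @export
scoring_scheme <- function(mismatch = -2L, gap_open = -4L, gap_extend = -1L,
                           x = 16, band = 16L, hsp_min_frac = 0.5) {
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0)
    stop("penalties must be negative")
  if (x <= 0) stop("x must be positive")
  structure(list(match = 1L, mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x = x, band = as.integer(band),
                 hsp_min_frac = hsp_min_frac),
            class = "pinmap_scoring")
}

#' Gapless x-drop extension of a seed
#'
#' Extends a length-k seed in both directions, stopping a direction when the
#' running score falls more than `x` below its maximum. The seed block is
#' counted as k matches without verification: hash collisions are caught by
#' their mismatching flanks. `x = Inf` yields the exhaustive gapless
#' maximum.
#'
#' @param query Query string (already reverse-complemented for minus-strand
#'   candidates).
#' @param index A `pinmap_index` (source of the packed reference).
#' @param qpos 0-based query position of the seed word.
#' @param rpos 0-based global reference position of the seed word.
#' @param scoring A [scoring_scheme()].
#' @param ref_lo,ref_hi Global bounds of the containing reference sequence
#'   (extension never crosses them).
#' @return List with `qstart`, `qend`, `rstart` (0-based, half-open) and
#'   `score`.
#' @export
xdrop_extend <- function(query, index, qpos, rpos, scoring = scoring_scheme(),
                         ref_lo = 0, ref_hi = length(index$genome)) {
  xdrop_extend_cpp(query, index$genome, qpos, rpos, index$params$k,
                   ref_lo, ref_hi, scoring$x, scoring$match, scoring$mismatch)
}

#' Banded gapped extension of an HSP
#'
#' Semi-global alignment: the entire query must be aligned, the reference is
#' free at both ends. Dynamic-programming cells are restricted to a band
#' around the HSP diagonal, which covers the HSP block and banded terminal
#' regions. With a band spanning the whole matrix this equals full
#' semi-global DP.
#'
#' @param query Query string.
#' @param index A `pinmap_index`.
#' @param hsp List with at least `qstart` and `rstart` (a seed-anchored
#'   gapless segment, see [xdrop_extend()]).
#' @param scoring A [scoring_scheme()].
#' @param band Band half-width; defaults to `scoring$band`.
#' @param ref_lo,ref_hi Containing-sequence bounds.
#' @return List with `score`, `cigar`, `ref_start` (0-based global) or
#'   `feasible = FALSE` when the band cannot reach the query ends.
#' @export
gapped_extend <- function(query, index, hsp, scoring = scoring_scheme(),
                          band = scoring$band, ref_lo = 0,
                          ref_hi = length(index$genome)) {
  res <- banded_align_cpp(query, index$genome, ref_lo, ref_hi,
                          hsp$rstart, hsp$qstart, band, scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend)
  res
}

#' Mapping quality from best and second-best scores
#'
#' `MAPQ = round((T - S) * (T / qlen)^2)` (half up), clamped to `[0, 254]`.
#' When no second alignment was found the caller passes `S = T/2` as a prior
#' estimate of the second-best score (the search may terminate early, so
#' absence of a second alignment is weaker evidence than `S = 0`).
#'
#' @param T_score Score of the best alignment.
#' @param S_score Score of the second-best alignment (`S <= T`).
#' @param qlen Query length (best possible score).
#' @return Integer MAPQ in `[0, 254]`.
#' @export
compute_mapq <- function(T_score, S_score, qlen) {
  if (qlen <= 0) stop("qlen must be positive")
  raw <- (T_score - S_score) * (T_score / qlen)^2
  q <- floor(raw + 0.5) # round half up
  as.integer(pmax(0, pmin(254, q)))
}

#' Error probability implied by a MAPQ value
#'
#' `P_error = 10^(-MAPQ/10)`.
#'
#' @param mapq Non-negative MAPQ value(s).
#' @return Probability the reported location is wrong.
#' @export
mapq_to_perror <- function(mapq) {
  if (any(mapq < 0)) stop("mapq must be >= 0")
  10^(-mapq / 10)
}
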