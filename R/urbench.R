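# Locus-anchored read-simulation benchmark.
#
# A diploid genome is built by applying phased (or randomly assigned)
# variants to the reference; read pairs are simulated anchored on loci so
# that R1 or R2 contains the locus; substitution errors are injected with
# the probability implied by each base's quality score. Mapped output is
# scored per read and per locus, separately for reads drawn from the
# reference and from the variant genome, giving eight metrics, pairwise
# method comparisons (MI/IM/TI) and a MAPQ calibration table.

#' Read variants from a VCF file
#'
#' Phase is taken from the genotype separator (`|` phased, `/` unphased);
#' the carrying haplotype is the first non-reference allele index for
#' phased genotypes.
#'
#' @param path VCF path (plain or gzip).
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `haplotype` (0, 1 or `NA` when unphased), `phased`.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- if ("GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID ||
            ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "GT")[, 1] else
    rep("1|1", nrow(fix))
  phased <- grepl("\\|", gt)
  alleles <- strsplit(gt, "[/|]")
  hap <- vapply(seq_along(alleles), function(i) {
    a <- suppressWarnings(as.integer(alleles[[i]]))
    carrier <- which(!is.na(a) & a > 0)
    if (!length(carrier)) return(NA_integer_)
    if (phased[i]) carrier[1] - 1L else NA_integer_
  }, integer(1))
  data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             haplotype = hap, phased = phased, stringsAsFactors = FALSE)
}

#' Write variants as a minimal VCF
#'
#' @param variants data.frame as returned by [make_variants()] or
#'   [read_vcf_variants()].
#' @param path Output path.
#' @export
write_vcf_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"),
             con)
  gt <- ifelse(is.na(variants$haplotype), "0/1",
               ifelse(variants$haplotype == 0, "1|0", "0|1"))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                     variants$chrom, as.integer(variants$pos), variants$ref,
                     variants$alt, gt), con)
  invisible(path)
}

#' Build a diploid genome from reference and variants
#'
#' Haplotypes are built left to right; unphased variants are assigned to a
#' haplotype by a seeded coin flip. Each haplotype carries a monotone
#' coordinate map back to the reference, recorded through indels as
#' piecewise-linear breakpoints.
#'
#' @param reference List of records (`name`, `seq`) — see [read_fasta()].
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `haplotype`, `phased`.
#' @param seed Seed for unphased-variant assignment.
#' @return A `pinmap_diploid`: per-haplotype sequence records and
#'   coordinate maps.
#' @export
build_diploid <- function(reference, variants, seed = 1L) {
  refmap <- setNames(seq_along(reference),
                     vapply(reference, `[[`, character(1), "name"))
  if (nrow(variants)) {
    bad <- !variants$chrom %in% names(refmap)
    if (any(bad)) stop("variant chrom not in reference: ",
                       paste(unique(variants$chrom[bad]), collapse = ", "))
  }
  hap_assign <- variants$haplotype
  unph <- is.na(hap_assign)
  if (any(unph))
    hap_assign[unph] <- with_seed(seed,
      sample(c(0L, 1L), sum(unph), replace = TRUE))
  haplotypes <- vector("list", 2)
  for (h in 0:1) {
    recs <- vector("list", length(reference))
    for (ci in seq_along(reference)) {
      chrom <- reference[[ci]]$name
      refseq <- reference[[ci]]$seq
      vs <- variants[variants$chrom == chrom & hap_assign == h, , drop = FALSE]
      vs <- vs[order(vs$pos), , drop = FALSE]
      if (nrow(vs) >= 2) {
        # overlap check: each variant's ref span must start after the
        # previous one ends
        ends <- vs$pos + nchar(vs$ref) - 1
        bad <- which(vs$pos[-1] <= ends[-length(ends)])
        if (length(bad))
          stop("overlapping variants on haplotype ", h, " of ", chrom,
               " at positions ",
               paste(vs$pos[bad + 1], collapse = ", "))
      }
      pieces <- character(0)
      # breakpoints: hap coordinate (0-based) -> ref coordinate (0-based)
      bp_hap <- numeric(0); bp_ref <- numeric(0)
      cursor_ref <- 0; cursor_hap <- 0 # 0-based
      bp_hap <- c(bp_hap, 0); bp_ref <- c(bp_ref, 0)
      for (vi in seq_len(nrow(vs))) {
        p0 <- vs$pos[vi] - 1 # 0-based variant start
        refa <- vs$ref[vi]; alta <- vs$alt[vi]
        if (substr(refseq, p0 + 1, p0 + nchar(refa)) != refa)
          stop("variant REF mismatch at ", chrom, ":", vs$pos[vi])
        pieces <- c(pieces, substr(refseq, cursor_ref + 1, p0), alta)
        cursor_hap <- cursor_hap + (p0 - cursor_ref) + nchar(alta)
        cursor_ref <- p0 + nchar(refa)
        bp_hap <- c(bp_hap, cursor_hap); bp_ref <- c(bp_ref, cursor_ref)
      }
      pieces <- c(pieces, substr(refseq, cursor_ref + 1, nchar(refseq)))
      hseq <- paste(pieces, collapse = "")
      recs[[ci]] <- list(name = chrom, seq = hseq,
                         map = list(hap = bp_hap, ref = bp_ref))
    }
    haplotypes[[h + 1]] <- recs
  }
  structure(list(haplotypes = haplotypes, reference = reference,
                 variants = cbind(variants, assigned = hap_assign)),
            class = "pinmap_diploid")
}

#' Map a haplotype coordinate to the reference
#'
#' Positions inside an insertion map to the reference coordinate of the
#' variant's start.
#'
#' @param hap_record One haplotype chromosome from [build_diploid()].
#' @param pos 0-based haplotype coordinates.
#' @return 0-based reference coordinates.
#' @export
hap_to_ref <- function(hap_record, pos) {
  m <- hap_record$map
  if (is.null(m)) return(pos)
  i <- findInterval(pos, m$hap)
  # within segment i (1-based): linear offset from breakpoint, clamped to
  # the segment's reference span so insertions collapse to their start
  ref <- m$ref[i] + (pos - m$hap[i])
  nxt <- c(m$ref[-1], Inf)
  pmin(ref, pmax(m$ref[i], nxt[i] - 1))
}

#' Synthetic quality-string model
#'
#' Per-cycle mean quality Q38 over cycles 1..100 decaying linearly to Q25
#' at cycle `L`, with per-base Gaussian jitter (sd 3) clamped to [2, 41] —
#' emulating position-dependent quality decay of a 2x150 Illumina run.
#'
#' @param n Number of quality strings.
#' @param L Read length.
#' @param seed RNG seed.
#' @return Character vector of `n` Phred+33 quality strings; also usable as
#'   a quality pool for [simulate_pairs()].
#' @export
synthetic_quality_pool <- function(n, L = 150L, seed = 1L) {
  with_seed(seed, {
    cyc <- seq_len(L)
    mu <- ifelse(cyc <= 100, 38, 38 - (cyc - 100) * (38 - 25) / max(L - 100, 1))
    vapply(seq_len(n), function(i) {
      q <- round(rnorm(L, mean = mu, sd = 3))
      q <- pmax(2, pmin(41, q))
      intToUtf8(q + 33L, multiple = FALSE)
    }, character(1))
  })
}

#' Quality pool from a donor FASTQ
#'
#' @param path Donor FASTQ whose quality strings are reused.
#' @param L Required read length (records of other lengths are dropped).
#' @return Character vector of quality strings.
#' @export
donor_quality_pool <- function(path, L = 150L) {
  reads <- read_fastq(path)
  qs <- vapply(reads, function(r) intToUtf8(r$qual + 33L, multiple = FALSE),
               character(1))
  qs <- qs[nchar(qs) == L]
  if (!length(qs)) stop("no donor reads of length ", L)
  qs
}

#' Simulate locus-anchored read pairs
#'
#' For each locus, `pairs_per_locus` FR pairs are drawn with fragment length
#' from a truncated normal model, positioned uniformly among placements
#' where R1 or R2 contains the locus. Which physical end is read 1 is
#' decided by a seeded coin flip per pair.
#'
#' @param source List of sequence records (`name`, `seq`, optional `map`
#'   from [build_diploid()] haplotypes).
#' @param loci data.frame with `seq_index` (into `source`) and `pos`
#'   (0-based locus coordinate in source coordinates).
#' @param pairs_per_locus Pairs per locus (benchmark design: 10).
#' @param L Read length.
#' @param fragment Fragment model: list with `mean`, `sd`, `min`, `max`.
#' @param seed RNG seed.
#' @return List with `pairs` (read records) and `truth` (per-mate true
#'   reference-coordinate placements, 0-based, plus locus bookkeeping).
#' @export
simulate_pairs <- function(source, loci, pairs_per_locus = 10L, L = 150L,
                           fragment = list(mean = 350, sd = 35, min = NA,
                                           max = 1000),
                           seed = 1L) {
  frag_min <- if (is.na(fragment$min %||% NA)) L else fragment$min
  with_seed(seed, {
    pairs <- list(); truth <- list()
    for (li in seq_len(nrow(loci))) {
      si <- loci$seq_index[li]
      rec <- source[[si]]
      G <- nchar(rec$seq)
      locus <- loci$pos[li]
      placed <- 0L
      for (pi in seq_len(pairs_per_locus)) {
        F <- round(rnorm(1, fragment$mean, fragment$sd))
        F <- max(frag_min, min(fragment$max, F, G))
        # fragment starts where R1 (left read) or R2 (right read) covers
        # the locus; each admissible range is at most L wide
        rng <- function(lo, hi) if (hi < lo) integer(0) else seq(lo, hi)
        aset <- rng(max(0, locus - L + 1), min(locus, G - F))
        bset <- rng(max(0, locus - F + 1), min(locus - F + L, G - F))
        starts <- union(aset, bset)
        if (!length(starts)) next
        start <- if (length(starts) == 1) starts else
          starts[sample.int(length(starts), 1)]
        left_seq <- substr(rec$seq, start + 1, start + L)
        right_seq <- revcomp(substr(rec$seq, start + F - L + 1, start + F))
        swap <- sample(c(FALSE, TRUE), 1) # which end is read 1
        placed <- placed + 1L
        id <- sprintf("L%d_P%d", li, pi)
        r1 <- list(name = id, seq = if (swap) right_seq else left_seq)
        r2 <- list(name = id, seq = if (swap) left_seq else right_seq)
        map_pos <- function(p) if (!is.null(rec$map)) hap_to_ref(rec, p) else p
        left_truth <- list(chrom = rec$name, start = map_pos(start),
                           strand = "+")
        right_truth <- list(chrom = rec$name, start = map_pos(start + F - L),
                            strand = "-")
        truth[[length(truth) + 1L]] <- data.frame(
          qname = id, locus = li, mate = c(1L, 2L),
          chrom = rec$name,
          start = if (swap) c(right_truth$start, left_truth$start)
                  else c(left_truth$start, right_truth$start),
          strand = if (swap) c("-", "+") else c("+", "-"),
          frag = F, stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1L]] <- list(r1 = r1, r2 = r2)
      }
      if (placed == 0L)
        warning("locus ", li, " skipped: no valid fragment placement")
    }
    list(pairs = pairs, truth = do.call(rbind, truth))
  })
}

#' Inject quality-driven substitution errors
#'
#' At each base a substitution to a uniformly chosen different base is made
#' with probability `10^(-q/10)`. Indel errors are never introduced.
#'
#' @param read Read record (`name`, `seq`).
#' @param quality_string Phred+33 quality string of the same length.
#' @param seed RNG seed.
#' @return The read with mutated `seq` and integer `qual` attached.
#' @export
inject_errors <- function(read, quality_string, seed = 1L) {
  q <- utf8ToInt(quality_string) - 33L
  s <- strsplit(read$seq, "")[[1]]
  if (length(q) != length(s))
    stop("quality/sequence length mismatch for ", read$name)
  with_seed(seed, {
    p <- 10^(-q / 10)
    hit <- runif(length(s)) < p
    if (any(hit)) {
      bases <- c("A", "C", "G", "T")
      for (i in which(hit)) {
        alt <- setdiff(bases, s[i])
        s[i] <- alt[sample.int(length(alt), 1)]
      }
    }
    read$seq <- paste(s, collapse = "")
    read$qual <- q
    read
  })
}

#' Score mapped reads against simulation truth
#'
#' A read is confident iff `MAPQ >= mapq_threshold`; correct iff mapped to
#' the same reference sequence and strand with start within `tolerance`
#' bases of truth.
#'
#' @param results List of `pinmap_pair` results (or a data.frame of SAM-like
#'   records with `qname`, `mate`, `rname`, `pos0`, `strand`, `mapq`).
#' @param truth Truth table from [simulate_pairs()].
#' @param tolerance Coordinate tolerance in bases (default 10).
#' @param mapq_threshold Confidence threshold (default 10).
#' @return data.frame of per-read verdicts: `correct`, `confident`,
#'   `verdict` in {correct-confident, wrong-confident, not-confident},
#'   reported coordinates and MAPQ.
#' @export
score_mapping <- function(results, truth, tolerance = 10L,
                          mapq_threshold = 10L) {
  rows <- if (is.data.frame(results)) results else {
    do.call(rbind, lapply(results, function(res) {
      one <- function(rec, mate) data.frame(
        qname = rec$name, mate = mate,
        rname = if (rec$mapped) rec$seq_name else NA_character_,
        pos0 = if (rec$mapped) rec$pos else NA_real_,
        strand = if (rec$mapped) rec$strand else NA_character_,
        mapq = rec$mapq, stringsAsFactors = FALSE)
      rbind(one(res$r1, 1L), if (!is.null(res$r2)) one(res$r2, 2L))
    }))
  }
  key <- paste(rows$qname, rows$mate)
  tkey <- paste(truth$qname, truth$mate)
  if (any(!key %in% tkey))
    stop("mapped read not present in truth set: ",
         paste(head(setdiff(key, tkey), 3), collapse = ", "))
  m <- match(key, tkey)
  tr <- truth[m, , drop = FALSE]
  correct <- !is.na(rows$rname) & rows$rname == tr$chrom &
    !is.na(rows$strand) & rows$strand == tr$strand &
    abs(rows$pos0 - tr$start) <= tolerance
  confident <- rows$mapq >= mapq_threshold & !is.na(rows$rname)
  verdict <- ifelse(!confident, "not-confident",
                    ifelse(correct, "correct-confident", "wrong-confident"))
  data.frame(qname = rows$qname, mate = rows$mate, locus = tr$locus,
             rname = rows$rname, pos0 = rows$pos0, strand = rows$strand,
             mapq = rows$mapq, correct = correct, confident = confident,
             verdict = verdict, stringsAsFactors = FALSE)
}

# Majority = strictly more than half of the confident reads of a locus.
locus_call <- function(vd, tolerance) {
  conf <- vd[vd$confident, , drop = FALSE]
  if (nrow(conf) < 3) return("unqualified")
  n <- nrow(conf)
  if (sum(conf$correct) > n / 2) return("correct")
  # cluster incorrect placements by coordinate (within tolerance)
  wrong <- conf[!conf$correct, , drop = FALSE]
  if (nrow(wrong)) {
    wrong <- wrong[order(wrong$rname, wrong$strand, wrong$pos0), , drop = FALSE]
    grp <- cumsum(c(1, (wrong$rname[-1] != wrong$rname[-nrow(wrong)]) |
                      (wrong$strand[-1] != wrong$strand[-nrow(wrong)]) |
                      (diff(wrong$pos0) > tolerance)))
    if (max(table(grp)) > n / 2) return("same-wrong")
  }
  "mixed"
}

#' Compute the eight accuracy metrics
#'
#' Per-read sensitivity `S_r` is the percentage of all reads mapped to the
#' correct coordinate with MAPQ at or above the threshold; per-read error
#' `E_r` the percentage of confident reads mapped incorrectly. Per-locus
#' sensitivity `S_l` is the percentage of loci with at least three
#' confident reads whose majority is correct (denominator: all loci);
#' per-locus error `E_l` the percentage of loci with at least three
#' confident reads in which a majority maps to the same incorrect position
#' (denominator: qualifying loci). With zero confident reads `E_r` is 0;
#' with zero qualifying loci `E_l` is 0.
#'
#' @param verdicts data.frame from [score_mapping()], with a `locus` column.
#' @param origin Label, `"ref"` or `"var"`, attached to metric names.
#' @param n_loci Total locus count for the `S_l` denominator (defaults to
#'   the loci present in `verdicts`).
#' @param tolerance Coordinate-clustering tolerance for systematic errors.
#' @return A named list of class `pinmap_metrics` with `S_r`, `E_r`, `S_l`,
#'   `E_l` (percentages) and the underlying counts.
#' @export
compute_metrics <- function(verdicts, origin = "ref",
                            n_loci = length(unique(verdicts$locus)),
                            tolerance = 10L) {
  n_reads <- nrow(verdicts)
  n_cc <- sum(verdicts$verdict == "correct-confident")
  n_conf <- sum(verdicts$confident)
  n_wc <- sum(verdicts$verdict == "wrong-confident")
  S_r <- if (n_reads) 100 * n_cc / n_reads else 0
  E_r <- if (n_conf) 100 * n_wc / n_conf else 0
  calls <- vapply(split(verdicts, verdicts$locus), locus_call, character(1),
                  tolerance = tolerance)
  n_qual <- sum(calls != "unqualified")
  S_l <- if (n_loci) 100 * sum(calls == "correct") / n_loci else 0
  E_l <- if (n_qual) 100 * sum(calls == "same-wrong") / n_qual else 0
  structure(list(S_r = S_r, E_r = E_r, S_l = S_l, E_l = E_l,
                 origin = origin,
                 counts = list(reads = n_reads, correct_confident = n_cc,
                               confident = n_conf, wrong_confident = n_wc,
                               loci = n_loci, qualifying_loci = n_qual)),
            class = "pinmap_metrics")
}

#' Assemble a full eight-metric report
#'
#' @param ref_metrics,var_metrics `pinmap_metrics` for reads of the
#'   reference and of the variant genome.
#' @return Named numeric vector with the eight metrics.
#' @export
metrics_report <- function(ref_metrics, var_metrics) {
  c(S_r_ref = ref_metrics$S_r, E_r_ref = ref_metrics$E_r,
    S_l_ref = ref_metrics$S_l, E_l_ref = ref_metrics$E_l,
    S_r_var = var_metrics$S_r, E_r_var = var_metrics$E_r,
    S_l_var = var_metrics$S_l, E_l_var = var_metrics$E_l)
}

#' Pairwise method comparison
#'
#' `MI_XY` is the mean of `S_X - S_Y - E_X + E_Y` over the four
#' genome-by-granularity combinations; `IM_XY` counts the metrics (of 8)
#' where X is strictly better (higher sensitivity, lower error); `TI_X`
#' sums MI over the other methods. Notation: `X >>(MI) Y` when all eight
#' are better, `X <<(MI) Y` when all are worse, otherwise `>n` / `<n` with
#' the majority direction.
#'
#' @param reports Named list of eight-metric vectors ([metrics_report()]).
#' @return List with matrices `MI`, `IM`, vector `TI` and a character
#'   matrix `notation`.
#' @export
compare_methods <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports")
  nms <- names(reports)
  need <- c("S_r_ref", "E_r_ref", "S_l_ref", "E_l_ref",
            "S_r_var", "E_r_var", "S_l_var", "E_l_var")
  for (r in reports)
    if (!all(need %in% names(r))) stop("mismatched metric sets")
  n <- length(reports)
  MI <- matrix(0, n, n, dimnames = list(nms, nms))
  IM <- matrix(0L, n, n, dimnames = list(nms, nms))
  notation <- matrix("", n, n, dimnames = list(nms, nms))
  combos <- list(c("S_r_ref", "E_r_ref"), c("S_l_ref", "E_l_ref"),
                 c("S_r_var", "E_r_var"), c("S_l_var", "E_l_var"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    X <- reports[[i]]; Y <- reports[[j]]
    MI[i, j] <- mean(vapply(combos, function(co)
      (X[co[1]] - Y[co[1]]) - (X[co[2]] - Y[co[2]]), numeric(1)))
    better <- sum(X[c("S_r_ref", "S_l_ref", "S_r_var", "S_l_var")] >
                    Y[c("S_r_ref", "S_l_ref", "S_r_var", "S_l_var")]) +
      sum(X[c("E_r_ref", "E_l_ref", "E_r_var", "E_l_var")] <
            Y[c("E_r_ref", "E_l_ref", "E_r_var", "E_l_var")])
    IM[i, j] <- as.integer(better)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    notation[i, j] <- render_comparison(nms[i], nms[j], IM[i, j], IM[j, i],
                                        MI[i, j])
  }
  TI <- rowSums(MI)
  list(MI = MI, IM = IM, TI = TI, notation = notation)
}

#' Render one pairwise comparison in benchmark notation
#'
#' @param x,y Method names.
#' @param im_xy,im_yx Improved-metric counts in both directions.
#' @param mi Mean improvement of `x` over `y`.
#' @return String such as `"BWA >5(2.0) Bowtie2"`.
#' @export
render_comparison <- function(x, y, im_xy, im_yx, mi) {
  sym <- if (im_xy == 8) ">>"
  else if (im_yx == 8) "<<"
  else if (im_xy >= im_yx) paste0(">", im_xy)
  else paste0("<", im_yx)
  sprintf("%s %s(%s) %s", x, sym, format(round(mi, 1), nsmall = 1), y)
}

#' MAPQ calibration table
#'
#' For each reported MAPQ value `q` with at least `min_n` reads, the
#' measured quality is `q_measured = -10*log10(n_error/n)`; with zero
#' errors `q_measured` is `Inf`.
#'
#' @param verdicts data.frame from [score_mapping()] (needs `mapq`,
#'   `correct`, and mapped reads only are counted).
#' @param min_n Minimum reads per reported value (default 50).
#' @return data.frame with `q`, `n`, `n_error`, `f_error`, `q_measured`.
#' @export
calibration_table <- function(verdicts, min_n = 50L) {
  vd <- verdicts[!is.na(verdicts$rname), , drop = FALSE]
  if (!nrow(vd))
    return(data.frame(q = integer(0), n = integer(0), n_error = integer(0),
                      f_error = numeric(0), q_measured = numeric(0)))
  tab <- split(vd, vd$mapq)
  rows <- lapply(tab, function(d) {
    n <- nrow(d); ne <- sum(!d$correct)
    data.frame(q = d$mapq[1], n = n, n_error = ne, f_error = ne / n,
               q_measured = if (ne > 0) -10 * log10(ne / n) else Inf)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n >= min_n, , drop = FALSE]
  out[order(out$q), , drop = FALSE]
}

#' Run the full benchmark on a reference and variant set
#'
#' Convenience pipeline: build the diploid genome, simulate locus-anchored
#' pairs from the reference (random loci) and from the variant genome
#' (variant-position loci), inject quality-driven errors, map everything,
#' and score.
#'
#' @param reference List of sequence records.
#' @param variants Variant data.frame (see [build_diploid()]).
#' @param index A `pinmap_index` built on `reference`.
#' @param n_loci Loci per source genome.
#' @param pairs_per_locus Pairs per locus.
#' @param L Read length.
#' @param quality_pool Character vector of quality strings (length `L`).
#' @param seed RNG seed.
#' @param scoring,sp Mapper configuration.
#' @param tolerance,mapq_threshold Scoring configuration.
#' @return List with the eight-metric `report`, per-origin metrics and
#'   verdicts, and the MAPQ `calibration` table.
#' @export
run_benchmark <- function(reference, variants, index, n_loci = 200L,
                          pairs_per_locus = 10L, L = 150L,
                          quality_pool = synthetic_quality_pool(500L, L),
                          seed = 1L, scoring = scoring_scheme(),
                          sp = search_params(), tolerance = 10L,
                          mapq_threshold = 10L) {
  dip <- build_diploid(reference, variants, seed = seed)
  reflens <- vapply(reference, function(r) nchar(r$seq), numeric(1))
  run_side <- function(source, loci, side_seed, tag) {
    sim <- simulate_pairs(source, loci, pairs_per_locus, L, seed = side_seed)
    sim$truth$qname <- paste0(tag, sim$truth$qname)
    sim$pairs <- lapply(sim$pairs, function(pr) {
      pr$r1$name <- paste0(tag, pr$r1$name)
      pr$r2$name <- paste0(tag, pr$r2$name)
      pr
    })
    reads <- lapply(seq_along(sim$pairs), function(i) {
      pr <- sim$pairs[[i]]
      qs <- quality_pool[((i - 1) %% length(quality_pool)) + 1]
      qs2 <- quality_pool[(i %% length(quality_pool)) + 1]
      list(r1 = inject_errors(pr$r1, qs, seed = side_seed + 7L * i),
           r2 = inject_errors(pr$r2, qs2, seed = side_seed + 7L * i + 3L))
    })
    results <- lapply(reads, function(pr)
      map_pair(pr$r1, pr$r2, index, scoring, sp))
    vd <- score_mapping(results, sim$truth, tolerance, mapq_threshold)
    list(verdicts = vd, n_loci = length(unique(sim$truth$locus)))
  }
  ref_loci <- with_seed(seed + 101L, {
    si <- sample.int(length(reference), n_loci, replace = TRUE,
                     prob = reflens / sum(reflens))
    data.frame(seq_index = si,
               pos = floor(runif(n_loci, 200, reflens[si] - 200)))
  })
  ref_side <- run_side(reference, ref_loci, seed + 11L, "ref_")
  # variant loci: positions of variants, in carrying-haplotype coordinates
  vars <- dip$variants
  keep <- with_seed(seed + 202L,
    sample.int(nrow(vars), min(n_loci, nrow(vars))))
  var_sides <- list()
  for (h in 0:1) {
    vh <- vars[keep, , drop = FALSE]
    vh <- vh[vh$assigned == h, , drop = FALSE]
    if (!nrow(vh)) next
    hap <- dip$haplotypes[[h + 1]]
    hnames <- vapply(hap, `[[`, character(1), "name")
    si <- match(vh$chrom, hnames)
    # locate the variant position in haplotype coordinates
    hpos <- vapply(seq_len(nrow(vh)), function(i) {
      m <- hap[[si[i]]]$map
      j <- findInterval(vh$pos[i] - 1, m$ref)
      (vh$pos[i] - 1) - m$ref[j] + m$hap[j]
    }, numeric(1))
    var_sides[[h + 1]] <- run_side(hap,
      data.frame(seq_index = si, pos = hpos), seed + 23L + h,
      sprintf("var%d_", h))
  }
  var_vd <- do.call(rbind, lapply(Filter(Negate(is.null), var_sides),
                                  `[[`, "verdicts"))
  # re-key loci uniquely across the two haplotype batches
  var_vd$locus <- as.integer(factor(sub("_P[0-9]+$", "", var_vd$qname)))
  ref_m <- compute_metrics(ref_side$verdicts, "ref", ref_side$n_loci,
                           tolerance)
  var_m <- compute_metrics(var_vd, "var", length(unique(var_vd$locus)),
                           tolerance)
  all_vd <- rbind(ref_side$verdicts, var_vd)
  list(report = metrics_report(ref_m, var_m), ref = ref_m, var = var_m,
       verdicts = list(ref = ref_side$verdicts, var = var_vd),
       calibration = calibration_table(all_vd))
}
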