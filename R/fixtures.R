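# Deterministic synthetic-genome fixtures.
#
# An i.i.d. random backbone with planted features — exact repeats, inverted
# repeats, N-runs, over-abundant words — at recorded coordinates, plus a
# clustered variant generator. Every fixture is reproducible byte-for-byte
# from its specification and seed.

#' Specify a synthetic genome
#'
#' @param length Genome length in bases.
#' @param features List of planted features. Each is a list with `type`
#'   (`"repeat"`, `"inverted_repeat"`, `"n_run"`, `"abundant_word"`) and
#'   type-specific fields: `len` (unit length), `copies` (for repeats and
#'   abundant words), optional `at` (explicit 0-based start positions).
#' @param seed RNG seed.
#' @param name Sequence name.
#' @return A list of class `pinmap_fixture_spec`.
#' @export
genome_spec <- function(length, features = list(), seed = 1L,
                        name = "chrS") {
  structure(list(length = as.numeric(length), features = features,
                 seed = as.integer(seed), name = name),
            class = "pinmap_fixture_spec")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with planted features
#'
#' Feature placements are drawn (or taken from `at`) so that features do
#' not overlap; the truth annotation records, per planted feature, its
#' coordinates and the slot status its interior words are expected to
#' take: repeats of c copies give `multi` (abundance c), inverted repeats
#' give `singleton`, words planted more than t times give `excluded`.
#'
#' @param spec A [genome_spec()].
#' @return List with the sequence record (`name`, `seq`) and a `truth`
#'   data.frame of planted features.
#' @export
make_genome <- function(spec) {
  with_seed(spec$seed, {
    G <- spec$length
    seq <- strsplit(random_bases(G), "")[[1]]
    occupied <- IRanges::IRanges()
    truth <- list()
    place <- function(total_len, at = NULL) {
      if (!is.null(at)) return(at)
      for (try in 1:500) {
        st <- floor(runif(1, 0, G - total_len))
        cand <- IRanges::IRanges(start = st + 1, width = total_len)
        if (!length(IRanges::findOverlaps(cand, occupied)@from)) return(st)
      }
      stop("infeasible fixture spec: cannot place feature of length ",
           total_len)
    }
    mark <- function(st, len) {
      occupied <<- c(occupied, IRanges::IRanges(start = st + 1, width = len))
    }
    for (f in spec$features) {
      type <- f$type
      if (type == "repeat" || type == "inverted_repeat") {
        copies <- f$copies %||% 2L
        unit <- random_bases(f$len)
        starts <- if (!is.null(f$at)) f$at else {
          # spread copies at independent non-overlapping positions
          vapply(seq_len(copies), function(i) {
            st <- place(f$len)
            mark(st, f$len)
            st
          }, numeric(1))
        }
        if (!is.null(f$at)) for (st in starts) mark(st, f$len)
        for (ci in seq_along(starts)) {
          s <- if (type == "inverted_repeat" && ci > 1) revcomp(unit) else unit
          substr_assign <- strsplit(s, "")[[1]]
          seq[(starts[ci] + 1):(starts[ci] + f$len)] <- substr_assign
        }
        truth[[length(truth) + 1L]] <- data.frame(
          type = type, start = starts, len = f$len,
          copies = length(starts),
          expected_status = if (type == "inverted_repeat") "singleton"
                            else "multi",
          stringsAsFactors = FALSE)
      } else if (type == "n_run") {
        st <- place(f$len, f$at)
        mark(st, f$len)
        seq[(st + 1):(st + f$len)] <- "N"
        truth[[length(truth) + 1L]] <- data.frame(
          type = type, start = st, len = f$len, copies = 1L,
          expected_status = "absent", stringsAsFactors = FALSE)
      } else if (type == "abundant_word") {
        copies <- f$copies
        word <- random_bases(f$len)
        starts <- vapply(seq_len(copies), function(i) {
          st <- place(f$len)
          mark(st, f$len)
          st
        }, numeric(1))
        for (st in starts)
          seq[(st + 1):(st + f$len)] <- strsplit(word, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          type = type, start = starts, len = f$len, copies = copies,
          expected_status = "excluded", stringsAsFactors = FALSE)
      } else stop("unknown feature type: ", type)
    }
    list(record = list(name = spec$name, seq = paste(seq, collapse = "")),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(type = character(0), start = numeric(0),
                      len = numeric(0), copies = integer(0),
                      expected_status = character(0)))
  })
}

#' Generate clustered variants for a genome
#'
#' Variant positions follow a clustered process — cluster centres from a
#' Poisson process, within-cluster spacing geometric — so that reads
#' carrying several variants occur, as they do in real genomes. With
#' `clustering = FALSE` positions follow a plain geometric-spacing
#' (Poisson) process.
#'
#' @param genome A sequence record (`name`, `seq`).
#' @param density Expected variants per base (at most 0.05).
#' @param snp_indel_ratio Ratio of SNPs to indels, e.g. `9` for 9:1.
#' @param clustering Use the clustered process (default `TRUE`).
#' @param cluster_size Mean variants per cluster.
#' @param cluster_spacing Mean within-cluster spacing in bases.
#' @param phased_fraction Fraction of variants assigned a haplotype.
#' @param seed RNG seed.
#' @return data.frame of variants (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `haplotype`, `phased`).
#' @export
make_variants <- function(genome, density = 0.001, snp_indel_ratio = 9,
                          clustering = TRUE, cluster_size = 4,
                          cluster_spacing = 30, phased_fraction = 0.7,
                          seed = 1L) {
  if (density <= 0 || density > 0.05)
    stop("density must be in (0, 0.05]")
  G <- nchar(genome$seq)
  with_seed(seed, {
    pos <- if (clustering) {
      n_clusters <- rpois(1, density * G / cluster_size)
      centers <- sort(floor(runif(n_clusters, 1, G)))
      unlist(lapply(centers, function(ce) {
        m <- max(1, rpois(1, cluster_size))
        offs <- cumsum(c(0, rgeom(m - 1, 1 / cluster_spacing) + 1))
        ce + offs
      }))
    } else {
      n <- rpois(1, density * G)
      sort(floor(runif(n, 1, G)))
    }
    pos <- sort(unique(pos[pos >= 10 & pos <= G - 10]))
    if (!length(pos))
      return(data.frame(chrom = character(0), pos = numeric(0),
                        ref = character(0), alt = character(0),
                        haplotype = integer(0), phased = logical(0)))
    is_snp <- runif(length(pos)) < snp_indel_ratio / (snp_indel_ratio + 1)
    bases <- c("A", "C", "G", "T")
    ref <- character(length(pos)); alt <- character(length(pos))
    drop <- logical(length(pos))
    prev_end <- 0
    for (i in seq_along(pos)) {
      refbase <- substr(genome$seq, pos[i], pos[i])
      if (refbase == "N" || pos[i] <= prev_end) { drop[i] <- TRUE; next }
      if (is_snp[i]) {
        ref[i] <- refbase
        alt[i] <- sample(setdiff(bases, refbase), 1)
        prev_end <- pos[i]
      } else if (runif(1) < 0.5) { # insertion after this base
        ins_len <- sample(1:6, 1)
        ref[i] <- refbase
        alt[i] <- paste0(refbase, random_bases(ins_len))
        prev_end <- pos[i]
      } else { # deletion of the following bases
        del_len <- sample(1:6, 1)
        if (pos[i] + del_len > G - 5) { drop[i] <- TRUE; next }
        span <- substr(genome$seq, pos[i], pos[i] + del_len)
        if (grepl("N", span)) { drop[i] <- TRUE; next }
        ref[i] <- span
        alt[i] <- refbase
        prev_end <- pos[i] + del_len
      }
    }
    keep <- !drop
    n <- sum(keep)
    phased <- runif(n) < phased_fraction
    hap <- ifelse(phased, sample(c(0L, 1L), n, replace = TRUE), NA_integer_)
    data.frame(chrom = genome$name, pos = pos[keep], ref = ref[keep],
               alt = alt[keep], haplotype = hap, phased = phased,
               stringsAsFactors = FALSE)
  })
}
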