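# Diploid construction, read simulation, error injection, metrics,
# method comparison and MAPQ calibration.

test_that("a diploid genome with no variants is the reference", {
  ref <- ref_record(rand_genome(2000, 61))
  dip <- build_diploid(ref, data.frame(chrom = character(0), pos = numeric(0),
                                       ref = character(0),
                                       alt = character(0),
                                       haplotype = integer(0),
                                       phased = logical(0)))
  for (h in 1:2) {
    expect_identical(dip$haplotypes[[h]][[1]]$seq, ref[[1]]$seq)
    expect_identical(hap_to_ref(dip$haplotypes[[h]][[1]], c(0, 500, 1999)),
                     c(0, 500, 1999))
  }
})

test_that("SNPs and indels edit one haplotype and shift its coordinate map", {
  g <- rand_genome(2000, 62)
  ref <- ref_record(g)
  refbase <- substr(g, 1000, 1000)
  alt <- setdiff(c("A", "C", "G", "T"), refbase)[1]
  vs <- data.frame(chrom = "chr1", pos = 1000, ref = refbase, alt = alt,
                   haplotype = 0L, phased = TRUE)
  dip <- build_diploid(ref, vs)
  h0 <- dip$haplotypes[[1]][[1]]$seq
  h1 <- dip$haplotypes[[2]][[1]]$seq
  expect_identical(h1, g)
  diffs <- which(strsplit(h0, "")[[1]] != strsplit(g, "")[[1]])
  expect_identical(diffs, 1000L)

  # 3 bp deletion on haplotype 1 at 1-based 500 (REF = base + 3 deleted)
  del <- data.frame(chrom = "chr1", pos = 500,
                    ref = substr(g, 500, 503), alt = substr(g, 500, 500),
                    haplotype = 1L, phased = TRUE)
  dip2 <- build_diploid(ref, del)
  hap <- dip2$haplotypes[[2]][[1]]
  expect_identical(nchar(hap$seq), 1997L)
  expect_identical(hap_to_ref(hap, c(0, 498, 499)), c(0, 498, 499))
  expect_identical(hap_to_ref(hap, c(500, 600)), c(503, 603))

  # overlapping variants on one haplotype are rejected
  ov <- data.frame(chrom = "chr1", pos = c(500, 501),
                   ref = c(substr(g, 500, 503), substr(g, 501, 501)),
                   alt = c(substr(g, 500, 500), "A"),
                   haplotype = c(1L, 1L), phased = TRUE)
  expect_error(build_diploid(ref, ov), "overlapping")
  # REF allele must match the reference
  bad <- data.frame(chrom = "chr1", pos = 1000,
                    ref = ifelse(refbase == "A", "C", "A"), alt = "G",
                    haplotype = 0L, phased = TRUE)
  expect_error(build_diploid(ref, bad), "REF mismatch")
})

test_that("simulated pairs anchor each locus inside R1 or R2", {
  g <- rand_genome(20000, 63)
  src <- ref_record(g)
  loci <- data.frame(seq_index = 1, pos = c(3000, 6000, 9000, 12000, 15000))
  sim <- simulate_pairs(src, loci, pairs_per_locus = 10, L = 150, seed = 5)
  expect_length(sim$pairs, 50)
  expect_identical(nrow(sim$truth), 100L)
  for (li in seq_len(nrow(loci))) {
    tr <- sim$truth[sim$truth$locus == li, ]
    for (qn in unique(tr$qname)) {
      mates <- tr[tr$qname == qn, ]
      covers <- (loci$pos[li] >= mates$start) &
        (loci$pos[li] < mates$start + 150)
      expect_true(any(covers))
    }
  }
  # determinism
  sim2 <- simulate_pairs(src, loci, pairs_per_locus = 10, L = 150, seed = 5)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$pairs, sim2$pairs)
})

test_that("abutting-fragment placement puts the locus in exactly one mate", {
  g <- rand_genome(5000, 64)
  src <- ref_record(g)
  sim <- simulate_pairs(src, data.frame(seq_index = 1, pos = 2500),
                        pairs_per_locus = 1, L = 150,
                        fragment = list(mean = 300, sd = 0, min = 300,
                                        max = 300),
                        seed = 9)
  tr <- sim$truth
  expect_identical(nrow(tr), 2L)
  expect_identical(abs(diff(tr$start)), 150) # mates abut
  covers <- (2500 >= tr$start) & (2500 < tr$start + 150)
  expect_identical(sum(covers), 1L)
})

test_that("substitution errors follow the Phred probabilities", {
  n <- 1e5
  read <- list(name = "r", seq = strrep("A", n))
  q40 <- strrep(intToUtf8(40 + 33), n)
  mut <- inject_errors(read, q40, seed = 3)
  nerr <- sum(strsplit(mut$seq, "")[[1]] != "A")
  expect_lt(abs(nerr - n * 1e-4), 3 * sqrt(n * 1e-4))

  q2 <- strrep(intToUtf8(2 + 33), 2000)
  mut2 <- inject_errors(list(name = "r", seq = strrep("A", 2000)), q2,
                        seed = 4)
  rate <- mean(strsplit(mut2$seq, "")[[1]] != "A")
  expect_lt(abs(rate - 10^-0.2), 3 * sqrt(10^-0.2 * (1 - 10^-0.2) / 2000))

  expect_identical(inject_errors(read, q40, seed = 3)$seq, mut$seq)
})

test_that("verdicts combine coordinate tolerance with the MAPQ threshold", {
  truth <- data.frame(qname = c("a", "b", "c"), mate = 1L, locus = 1:3,
                      chrom = "chr1", start = c(100, 200, 300),
                      strand = "+", frag = 350)
  res <- data.frame(qname = c("a", "b", "c"), mate = 1L,
                    rname = "chr1", pos0 = c(100, 205, 311),
                    strand = "+", mapq = c(60L, 5L, 60L))
  vd <- score_mapping(res, truth, tolerance = 10, mapq_threshold = 10)
  expect_identical(vd$verdict,
                   c("correct-confident", "not-confident", "wrong-confident"))
  # unknown read name is an error
  res$qname[1] <- "zz"
  expect_error(score_mapping(res, truth), "not present in truth")
})

test_that("the eight metrics follow their definitions on hand fixtures", {
  mk <- function(qname, locus, verdict, pos0 = 100) {
    conf <- verdict != "not-confident"
    data.frame(qname = qname, mate = 1L, locus = locus, rname = "chr1",
               pos0 = pos0, strand = "+",
               mapq = if (conf) 60L else 5L,
               correct = verdict == "correct-confident",
               confident = conf, verdict = verdict)
  }
  all_good <- do.call(rbind, lapply(1:4, function(l)
    mk(sprintf("L%d_%d", l, 1:5), l, "correct-confident")))
  m <- compute_metrics(all_good, "ref")
  expect_identical(c(m$S_r, m$E_r, m$S_l, m$E_l), c(100, 0, 100, 0))

  # 4 loci x 5 reads; locus 4: exactly 3 confident reads, all clustered at
  # the same wrong coordinate -> systematic per-locus error of 25%
  vd <- rbind(
    do.call(rbind, lapply(1:3, function(l)
      mk(sprintf("L%d_%d", l, 1:5), l, "correct-confident"))),
    mk("L4_1", 4, "wrong-confident", 5000),
    mk("L4_2", 4, "wrong-confident", 5003),
    mk("L4_3", 4, "wrong-confident", 5006),
    mk("L4_4", 4, "not-confident"),
    mk("L4_5", 4, "not-confident"))
  m2 <- compute_metrics(vd, "ref")
  expect_identical(m2$S_l, 75)
  expect_identical(m2$E_l, 25)
  expect_identical(m2$S_r, 100 * 15 / 20)
  expect_identical(m2$E_r, 100 * 3 / 18)

  # a locus with only 2 confident reads is excluded from both S_l's
  # numerator and E_l's denominator
  vd3 <- rbind(
    do.call(rbind, lapply(1:3, function(l)
      mk(sprintf("L%d_%d", l, 1:5), l, "correct-confident"))),
    mk("L4_1", 4, "wrong-confident", 5000),
    mk("L4_2", 4, "wrong-confident", 5001),
    mk("L4_3", 4, "not-confident"),
    mk("L4_4", 4, "not-confident"),
    mk("L4_5", 4, "not-confident"))
  m3 <- compute_metrics(vd3, "ref")
  expect_identical(m3$S_l, 75)
  expect_identical(m3$E_l, 0)
  expect_identical(m3$counts$qualifying_loci, 3L)
})

test_that("majority-correct and majority-same-wrong exclude each other", {
  set.seed(71)
  verdict_pool <- c("correct-confident", "wrong-confident", "not-confident")
  for (rep in 1:60) {
    n <- sample(3:9, 1)
    v <- sample(verdict_pool, n, replace = TRUE)
    pos <- ifelse(v == "wrong-confident",
                  sample(c(5000, 5001, 8000), n, replace = TRUE), 100)
    vd <- data.frame(qname = paste0("r", 1:n), mate = 1L, locus = 1L,
                     rname = "chr1", pos0 = pos, strand = "+",
                     mapq = ifelse(v == "not-confident", 2L, 60L),
                     correct = v == "correct-confident",
                     confident = v != "not-confident", verdict = v)
    conf <- vd[vd$confident, ]
    if (nrow(conf) < 3) next
    # independent re-derivation of the two locus predicates
    maj_correct <- sum(conf$correct) > nrow(conf) / 2
    wrongs <- conf$pos0[!conf$correct]
    maj_same_wrong <- FALSE
    if (length(wrongs)) {
      cl <- table(cut(wrongs, breaks = c(-Inf, 6000, Inf)))
      maj_same_wrong <- max(vapply(unique(wrongs), function(w)
        sum(abs(wrongs - w) <= 10), numeric(1))) > nrow(conf) / 2
    }
    expect_false(maj_correct && maj_same_wrong)
    call <- pinmapr:::locus_call(vd, tolerance = 10)
    if (maj_correct) expect_identical(call, "correct")
    if (maj_same_wrong) expect_identical(call, "same-wrong")
  }
})

test_that("pairwise comparison reproduces MI, IM, TI and the notation", {
  X <- c(S_r_ref = 95, E_r_ref = 1, S_l_ref = 96, E_l_ref = 0.5,
         S_r_var = 90, E_r_var = 2, S_l_var = 91, E_l_var = 1)
  expect_identical(compare_methods(list(A = X, B = X))$MI[1, 2], 0)
  expect_identical(compare_methods(list(A = X, B = X))$IM[1, 2], 0L)

  # hand-built pair with IM = 5 and MI = 2.0
  Y <- c(S_r_ref = 92, E_r_ref = 2, S_l_ref = 95, E_l_ref = 0.4,
         S_r_var = 87, E_r_var = 3, S_l_var = 91.5, E_l_var = 0.6)
  cmp <- compare_methods(list(BWA = X, Bowtie2 = Y))
  mi_hand <- mean(c((95 - 92) - (1 - 2), (96 - 95) - (0.5 - 0.4),
                    (90 - 87) - (2 - 3), (91 - 91.5) - (1 - 0.6)))
  expect_identical(mi_hand, 2)
  expect_identical(cmp$MI["BWA", "Bowtie2"], mi_hand)
  expect_identical(cmp$MI["BWA", "Bowtie2"], -cmp$MI["Bowtie2", "BWA"])
  expect_identical(cmp$IM["BWA", "Bowtie2"], 5L)
  expect_identical(cmp$notation["BWA", "Bowtie2"], "BWA >5(2.0) Bowtie2")
  expect_identical(cmp$TI[["BWA"]], cmp$MI["BWA", "Bowtie2"])

  # all-eight-better renders as >>
  Z <- c(S_r_ref = 80, E_r_ref = 5, S_l_ref = 81, E_l_ref = 4,
         S_r_var = 70, E_r_var = 8, S_l_var = 72, E_l_var = 6)
  cmp2 <- compare_methods(list(X = X, Z = Z))
  expect_identical(cmp2$IM["X", "Z"], 8L)
  expect_match(cmp2$notation["X", "Z"], "^X >>\\(")
  expect_match(cmp2$notation["Z", "X"], "^Z <<\\(")
  expect_error(compare_methods(list(A = X)), "at least two")
  expect_error(compare_methods(list(A = X, B = c(S_r_ref = 1))),
               "mismatched")
})

test_that("calibration recovers measured quality from error counts", {
  mkv <- function(q, n, nerr) {
    data.frame(qname = paste0("q", q, "_", seq_len(n)), mate = 1L,
               locus = 1L, rname = "chr1", pos0 = 100, strand = "+",
               mapq = q, correct = c(rep(FALSE, nerr), rep(TRUE, n - nerr)),
               confident = TRUE,
               verdict = "x")
  }
  vd <- rbind(mkv(10L, 1000, 100), mkv(20L, 1000, 10), mkv(30L, 1000, 1),
              mkv(40L, 200, 0), mkv(50L, 10, 1))
  tab <- calibration_table(vd, min_n = 50)
  expect_identical(tab$q, c(10L, 20L, 30L, 40L)) # q=50 under min_n
  expect_equal(tab$q_measured[1:3], c(10, 20, 30))
  expect_identical(tab$q_measured[4], Inf)
  expect_identical(tab$n_error, c(100L, 10L, 1L, 0L))
})

test_that("the full pipeline recovers reference reads at high accuracy", {
  # unique backbone with planted duplications; locus-anchored pairs with
  # quality-driven errors, mapped and scored end to end
  g <- rand_genome(1000000, 73)
  g <- plant_duplication(g, len = 2000, at1 = 100000, at2 = 600000, seed = 74)
  g <- plant_duplication(g, len = 800, at1 = 300000, at2 = 800000, seed = 75)
  ref <- ref_record(g)
  idx <- build_index(ref, index_params(k = 24, t = 32))
  n_loci <- 200
  loci <- with_seed_t(76, data.frame(
    seq_index = 1, pos = sort(floor(runif(n_loci, 500, 999500)))))
  sim <- simulate_pairs(ref, loci, pairs_per_locus = 10, L = 150, seed = 77)
  pool <- synthetic_quality_pool(200, 150, seed = 78)
  results <- lapply(seq_along(sim$pairs), function(i) {
    pr <- sim$pairs[[i]]
    r1 <- inject_errors(pr$r1, pool[(i %% 200) + 1], seed = 1000 + i)
    r2 <- inject_errors(pr$r2, pool[((i + 7) %% 200) + 1], seed = 5000 + i)
    map_pair(r1, r2, idx)
  })
  vd <- score_mapping(results, sim$truth, tolerance = 10,
                      mapq_threshold = 10)
  m <- compute_metrics(vd, "ref", n_loci = n_loci)
  expect_gt(m$S_r, 95)
  expect_lt(m$E_r, 1)
})
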