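# Word scheduling, brace search and the full three-pass mapper.

test_that("the word schedule is a prime-stride permutation", {
  expect_identical(schedule_stride(150, 24), 29)
  sched <- schedule_positions(150, 24)
  expect_length(sched, 127)
  expect_identical(sched[1:3], c(0L, 29L, 58L))
  expect_identical(sort(sched), 0:126)
  # k+5 prime dividing n forces the next prime
  expect_identical(schedule_positions(10, 4), c(0L, 4L, 1L, 5L, 2L, 6L, 3L))
  expect_error(schedule_positions(3, 4), "shorter than k")
})

test_that("brace search pairs pins under FR and fragment constraints", {
  g <- rand_genome(30000, 51)
  idx <- build_test_index(g)
  sp <- search_params()
  sc <- scoring_scheme()
  pr <- make_pair(g, 12000)
  s1 <- pinmapr:::new_read_state(pr$r1$seq, idx, sp, sc)
  s2 <- pinmapr:::new_read_state(pr$r2$seq, idx, sp, sc)
  braces <- pinmapr:::find_braces(s1, s2, idx, 1000)
  expect_gt(length(braces), 0)
  expect_identical(braces[[1]]$a1, 12000)
  expect_identical(braces[[1]]$frag, 350)

  # mates drawn over 10 kb apart: rejected on coordinates alone
  far1 <- list(name = "f", seq = substr(g, 2001, 2150))
  far2 <- list(name = "f",
               seq = pinmapr:::revcomp(substr(g, 25001, 25150)))
  sf1 <- pinmapr:::new_read_state(far1$seq, idx, sp, sc)
  sf2 <- pinmapr:::new_read_state(far2$seq, idx, sp, sc)
  expect_length(pinmapr:::find_braces(sf1, sf2, idx, 1000), 0)

  # no pins in R2 (all Ns): no braces
  nn <- list(name = "n", seq = strrep("N", 150))
  sn <- pinmapr:::new_read_state(nn$seq, idx, sp, sc)
  expect_length(pinmapr:::find_braces(s1, sn, idx, 1000), 0)
})

test_that("error-free unique pairs map to truth as proper pairs", {
  g <- rand_genome(30000, 51)
  idx <- build_test_index(g)
  for (st in c(500, 7000, 21000)) {
    pr <- make_pair(g, st)
    res <- map_pair(pr$r1, pr$r2, idx)
    expect_true(res$r1$mapped)
    expect_true(res$r2$mapped)
    expect_identical(res$r1$pos, st)
    expect_identical(res$r2$pos, st + 200)
    expect_identical(res$r1$strand, "+")
    expect_identical(res$r2$strand, "-")
    expect_true(res$proper)
    expect_identical(res$tlen, 350)
    expect_gte(res$r1$mapq, 10L)
    expect_gte(res$r2$mapq, 10L)
  }
})

test_that("pairs inside an exact long repeat are ambiguous with MAPQ 0", {
  g <- rand_genome(30000, 52)
  g <- plant_duplication(g, len = 1200, at1 = 5000, at2 = 20000)
  idx <- build_test_index(g)
  # fragment wholly inside the repeat unit
  pr <- make_pair(g, 5300, frag = 400)
  res <- map_pair(pr$r1, pr$r2, idx)
  expect_true(res$r1$mapped)
  expect_true(res$r2$mapped)
  expect_identical(res$r1$second, res$r1$score)
  expect_identical(res$r2$second, res$r2$score)
  expect_identical(res$r1$mapq, 0L)
  expect_identical(res$r2$mapq, 0L)
})

test_that("reads with every scheduled word destroyed go unmapped", {
  g <- rand_genome(30000, 53)
  idx <- build_test_index(g)
  read <- substr(g, 10001, 10150)
  # substitute one base every 20 positions: every 24-mer contains one
  rv <- strsplit(read, "")[[1]]
  for (i in seq(5, 150, by = 15))
    rv[i] <- setdiff(c("A", "C", "G", "T"), rv[i])[1]
  broken <- paste(rv, collapse = "")
  res <- map_single(list(name = "b", seq = broken), idx)
  expect_false(res$r1$mapped)
  expect_identical(res$r1$mapq, 0L)
})

test_that("single-end mapping braces within one read and handles short reads", {
  g <- rand_genome(30000, 54)
  idx <- build_test_index(g)
  res <- map_single(list(name = "s", seq = substr(g, 4001, 4150)), idx)
  expect_true(res$r1$mapped)
  expect_identical(res$r1$pos, 4000)
  expect_identical(res$r1$score, 150)
  expect_identical(res$r1$cigar, "150M")

  short <- map_single(list(name = "t", seq = "ACGTACGT"), idx)
  expect_false(short$r1$mapped)
})

test_that("early termination matches exhaustive search on pin-only reads", {
  g <- rand_genome(20000, 55)
  idx <- build_test_index(g, H_factor = 100)
  sp_exhaustive <- search_params(good_margin = -1000) # never terminate early
  for (st in c(1000, 9000, 15000)) {
    pr <- make_pair(g, st)
    fast <- map_pair(pr$r1, pr$r2, idx)
    slow <- map_pair(pr$r1, pr$r2, idx, sp = sp_exhaustive)
    expect_identical(fast$r1$pos, slow$r1$pos)
    expect_identical(fast$r2$pos, slow$r2$pos)
    expect_identical(fast$r1$strand, slow$r1$strand)
  }
})

test_that("braced reads touch each hash row at most once per position", {
  g <- rand_genome(20000, 56)
  idx <- build_test_index(g)
  pr <- make_pair(g, 8000)
  res <- map_pair(pr$r1, pr$r2, idx)
  expect_identical(res$stats[["early"]], 1)
  n_sched <- length(schedule_positions(150, 24))
  expect_lte(res$stats[["row_fetches_r1"]], 2 * n_sched)
  expect_lte(res$stats[["row_fetches_r2"]], 2 * n_sched)
})

test_that("identical inputs produce byte-identical SAM", {
  g <- rand_genome(15000, 57)
  idx <- build_test_index(g)
  reads1 <- lapply(c(1000, 4000, 9000), function(st)
    make_pair(g, st, name = paste0("p", st)))
  p1 <- withr::local_tempfile(fileext = ".sam")
  p2 <- withr::local_tempfile(fileext = ".sam")
  map_reads(lapply(reads1, `[[`, "r1"), lapply(reads1, `[[`, "r2"),
            idx, sam_path = p1)
  map_reads(lapply(reads1, `[[`, "r1"), lapply(reads1, `[[`, "r2"),
            idx, sam_path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(tools::md5sum(p1)[[1]], tools::md5sum(p2)[[1]])
})

test_that("emitted MAPQ always equals the formula on (T, S, |Q|)", {
  g <- rand_genome(20000, 58)
  g <- plant_duplication(g, len = 800, at1 = 3000, at2 = 15000)
  idx <- build_test_index(g)
  starts <- c(500, 3100, 6000, 12000, 15100)
  for (st in starts) {
    pr <- make_pair(g, st, frag = 400)
    res <- map_pair(pr$r1, pr$r2, idx)
    for (rec in list(res$r1, res$r2)) {
      if (!rec$mapped) next
      expect_identical(rec$mapq,
                       compute_mapq(rec$score, rec$second, rec$qlen))
    }
  }
})

test_that("the veryfast preset caps abundance and skips the third pass", {
  g <- rand_genome(15000, 59)
  idx3 <- build_index(ref_record(g),
                      index_params(k = 24, t = 3,
                                   H = pinmapr:::next_prime(300000)))
  pr <- make_pair(g, 6000)
  res <- map_pair(pr$r1, pr$r2, idx3, scoring_scheme(x = 8),
                  search_params(preset = "veryfast"))
  expect_true(res$r1$mapped)
  expect_identical(res$r1$pos, 6000)
  expect_identical(res$stats[["pass3"]], 0)
})
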