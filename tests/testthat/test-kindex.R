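# Word encoding, hashing, slot classification, row codec and serialization.

test_that("word encoding treats bases as base-4 digits, 5' most significant", {
  expect_identical(encode_word(strrep("A", 24)), 0)
  expect_identical(encode_word(strrep("T", 24)), 4^24 - 1)
  expect_identical(encode_word("ACGT"), 27)
  expect_true(is.na(encode_word("ACNT")))
})

test_that("encoded reverse complement is an involution", {
  expect_identical(revcomp_word(encode_word("ACGT"), 4), encode_word("ACGT"))
  expect_identical(revcomp_word(encode_word("AAAA"), 4), encode_word("TTTT"))
  set.seed(11)
  for (w in floor(runif(25, 0, 4^12))) {
    expect_identical(revcomp_word(revcomp_word(w, 12), 12), w)
  }
})

test_that("the hash matches an independent 64-bit finalizer implementation", {
  vals <- c(0, 1, 2, 27, 4^24 - 1, floor(runif(20, 0, 2^50)))
  expect_identical(vapply(vals, pinmapr:::fmix64_hex_cpp, character(1)),
                   limbs_to_hex(fmix64_oracle_limbs(limbs_from_num(vals))))
  H <- 65537
  expect_identical(hash_slot(vals, H), oracle_slots(vals, H))
})

test_that("slot values are uniform and deterministic", {
  set.seed(2)
  words <- floor(runif(1e4, 0, 4^24))
  H <- 1009
  slots <- hash_slot(words, H)
  expect_identical(slots, hash_slot(words, H))
  cs <- suppressWarnings(chisq.test(tabulate(slots + 1, nbins = H)))
  expect_gt(cs$p.value, 0.01)
})

test_that("table size is the smallest admissible prime", {
  expect_identical(choose_table_size(1000), 65537)
  H <- choose_table_size(200000)
  expect_true(pinmapr:::is_prime(H))
  expect_gte(H, 1.6 * 200000)
  # human-scale sanity: the rule lands near 5e9 for a ~3.1 Gb genome
  Hbig <- choose_table_size(3.1e9)
  expect_true(pinmapr:::is_prime(Hbig))
  expect_gt(Hbig, 4.9e9)
  expect_lt(Hbig, 5.1e9)
})

test_that("slot classification follows the strand-abundance rules", {
  expect_identical(classify_slot(1, 0, 32), "pin")
  expect_identical(classify_slot(1, 3, 32), "singleton")
  expect_identical(classify_slot(1, 33, 32), "excluded")
  expect_identical(classify_slot(33, 0, 32), "excluded")
  expect_identical(classify_slot(2, 0, 32), "multi")
  expect_identical(classify_slot(0, 2, 32), "absent")
})

test_that("small genomes decode exactly to the brute-force census", {
  g <- rand_genome(200, 3)
  idx <- build_test_index(g, k = 24)
  cen <- oracle_census(g, 24, idx$params$H, 32)
  expect_index_matches_census(idx, cen)

  # exact duplicate of a 100-mer: interior words are multi with 2 positions
  dup <- paste0(substr(g, 1, 100), substr(g, 1, 100))
  idx2 <- build_test_index(dup, k = 24)
  cen2 <- oracle_census(dup, 24, idx2$params$H, 32)
  expect_index_matches_census(idx2, cen2)
  expect_true(any(cen2$status == "multi"))
  mpos <- cen2$positions[vapply(cen2$positions, length, 1L) == 2]
  expect_gt(length(mpos), 50)

  # a word and its reverse complement elsewhere: singleton, not pin
  w <- substr(g, 10, 33)
  ginv <- paste0(g, "NN", pinmapr:::revcomp(w))
  idx3 <- build_test_index(ginv, k = 24)
  cen3 <- oracle_census(ginv, 24, idx3$params$H, 32)
  expect_index_matches_census(idx3, cen3)
  sl <- hash_slot(encode_word(w), idx3$params$H)
  expect_identical(lookup_positions(idx3, sl)$status, "singleton")
})

test_that("linked lists recover positions through 7-bit-skip overflows", {
  # census-level: a multi slot whose 126 following rows are all occupied,
  # forcing the head's skip pointer to overflow into the 32-bit value
  H <- 1009
  slots <- c(100, 101:226)
  pos <- c(list(seq(0, 29) * 50), as.list(1000 + seq_len(126)))
  rows <- pinmapr:::encode_rows_cpp(as.numeric(slots), pos,
                                    rep(0L, length(slots)), H)
  expect_identical(rows[100 * 5 + 1], as.raw(0xFD)) # overflow head
  dec <- pinmapr:::decode_slot_cpp(rows, H, 100)
  expect_identical(dec$status, 3L)
  expect_identical(sort(dec$positions), seq(0, 29) * 50)
  # the neighbouring singleton-coded slots survive untouched
  for (s in 101:226) {
    d <- pinmapr:::decode_slot_cpp(rows, H, s)
    expect_identical(d$status, 1L)
  }
})

test_that("an index round-trips through its on-disk container", {
  g <- rand_genome(5000, 9)
  idx <- build_test_index(g, k = 16)
  p <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, p)
  idx2 <- load_index(p)
  expect_identical(idx2$rows, idx$rows)
  expect_identical(idx2$genome, idx$genome)
  expect_identical(idx2$params, idx$params)
  expect_identical(length(idx$rows), 5L * as.integer(idx$params$H))

  # bad magic
  raw <- readBin(p, "raw", file.size(p))
  raw[1] <- as.raw(0x58)
  writeBin(raw, p)
  expect_error(load_index(p), "bad magic")

  # truncation
  save_index(idx, p)
  raw <- readBin(p, "raw", file.size(p))
  writeBin(raw[1:(length(raw) - 100)], p)
  expect_error(load_index(p))
})

test_that("row tampering is detected when a decode touches it", {
  H <- 1009
  rows <- pinmapr:::encode_rows_cpp(c(50), list(c(10, 20, 30)), 0L, H)
  dec <- pinmapr:::decode_slot_cpp(rows, H, 50)
  expect_identical(sort(dec$positions), c(10, 20, 30))
  # blank an interior list row: the chain now hits an empty row
  tal <- rows[50 * 5 + 1]
  skip <- as.integer(tal) - 0x80
  rows[(50 + skip) * 5 + 1] <- as.raw(0x00)
  expect_error(pinmapr:::decode_slot_cpp(rows, H, 50), "corruption")
})

test_that("pin density approaches one on random genomes with ample tables", {
  g <- rand_genome(10000, 13)
  idx <- build_test_index(g, k = 24, H_factor = 400)
  dec <- decode_index_slots(idx)
  frac_pin <- mean(dec$status == "pin")
  expect_gte(frac_pin, 0.99)
})
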