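# Independent oracles, implemented with no reference to the package's
# compiled kernels: a pure-R 64-bit MurmurHash3 finalizer built on 16-bit
# limb arithmetic, a brute-force both-strand k-mer census, exhaustive
# gapless extension, and full (unbanded) affine semi-global DP.

# ---- 64-bit arithmetic on 16-bit limbs (n x 4 matrices, limb 1 = lowest)

limbs_from_num <- function(x) {
  # exact for x < 2^53
  l0 <- x %% 65536; x <- (x - l0) / 65536
  l1 <- x %% 65536; x <- (x - l1) / 65536
  l2 <- x %% 65536; x <- (x - l2) / 65536
  l3 <- x %% 65536
  cbind(l0, l1, l2, l3, deparse.level = 0)
}

limbs_from_hex <- function(h) {
  stopifnot(nchar(h) == 16)
  rev(vapply(seq(1, 16, 4), function(i)
    strtoi(substr(h, i, i + 3), 16L), numeric(1)))
}

limbs_xor <- function(a, b) {
  m <- a
  for (j in 1:4) m[, j] <- bitwXor(as.integer(a[, j]), as.integer(b[, j]))
  m
}

# x >> 33: keep bits 33..63 = floor((l2 + l3*2^16) / 2)
limbs_shr33 <- function(a) {
  hi <- a[, 3] + a[, 4] * 65536
  v <- floor(hi / 2)
  cbind(v %% 65536, floor(v / 65536), 0 * v, 0 * v, deparse.level = 0)
}

# (x * c) mod 2^64 with c a 4-limb constant
limbs_mul <- function(a, cl) {
  n <- nrow(a)
  acc <- matrix(0, n, 4)
  for (i in 1:4) for (j in 1:4) {
    k <- i + j - 1
    if (k <= 4) acc[, k] <- acc[, k] + a[, i] * cl[j]
  }
  for (k in 1:3) {
    carry <- floor(acc[, k] / 65536)
    acc[, k] <- acc[, k] %% 65536
    acc[, k + 1] <- acc[, k + 1] + carry
  }
  acc[, 4] <- acc[, 4] %% 65536
  acc
}

MM_C1 <- limbs_from_hex("ff51afd7ed558ccd")
MM_C2 <- limbs_from_hex("c4ceb9fe1a85ec53")

# Murmur finalizer on limb matrices
fmix64_oracle_limbs <- function(a) {
  a <- limbs_xor(a, limbs_shr33(a))
  a <- limbs_mul(a, MM_C1)
  a <- limbs_xor(a, limbs_shr33(a))
  a <- limbs_mul(a, MM_C2)
  limbs_xor(a, limbs_shr33(a))
}

limbs_to_hex <- function(a) {
  apply(a, 1, function(r)
    paste(sprintf("%04x", rev(as.integer(r))), collapse = ""))
}

limbs_mod <- function(a, H) {
  r <- rep(0, nrow(a))
  for (j in 4:1) r <- (r * 65536 + a[, j]) %% H
  r
}

# slot = fmix64(word encoding) mod H, vectorised over encodings < 2^53
oracle_slots <- function(enc, H) {
  limbs_mod(fmix64_oracle_limbs(limbs_from_num(enc)), H)
}

# ---- brute-force k-mer census over both strands

oracle_encode <- function(words) {
  k <- nchar(words[1])
  digits <- matrix(match(unlist(strsplit(words, "")),
                         c("A", "C", "G", "T")) - 1,
                   ncol = k, byrow = TRUE)
  as.numeric(digits %*% (4^((k - 1):0)))
}

oracle_revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

# Census of one or more sequences: per-slot plus-strand positions (global,
# 0-based) and minus-strand counts, then classification under t.
oracle_census <- function(seqs, k, H, t) {
  all_slot <- numeric(0); all_pos <- numeric(0); all_minus <- numeric(0)
  offset <- 0
  for (s in seqs) {
    L <- nchar(s)
    if (L >= k) {
      starts <- 1:(L - k + 1)
      words <- substring(s, starts, starts + k - 1)
      keep <- !grepl("N", words, fixed = TRUE)
      if (any(keep)) {
        enc_p <- oracle_encode(words[keep])
        enc_m <- oracle_encode(oracle_revcomp_str(words[keep]))
        all_slot <- c(all_slot, oracle_slots(enc_p, H))
        all_minus <- c(all_minus, oracle_slots(enc_m, H))
        all_pos <- c(all_pos, offset + starts[keep] - 1)
      }
    }
    offset <- offset + L
  }
  plus_pos <- lapply(split(all_pos, all_slot), sort)
  minus_tab <- table(all_minus)
  slots <- names(plus_pos)
  minus <- as.numeric(minus_tab[slots])
  minus[is.na(minus)] <- 0
  plus_n <- vapply(plus_pos, length, integer(1))
  status <- vapply(seq_along(slots), function(i)
    classify_slot(plus_n[i], minus[i], t), character(1))
  ord <- order(as.numeric(slots))
  list(slot = as.numeric(slots)[ord],
       positions = unname(plus_pos[ord]),
       minus = minus[ord],
       status = status[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compare an index against the oracle census in one aggregate comparison.
expect_index_matches_census <- function(index, cen) {
  decoded <- decode_index_slots(index)
  ord <- order(decoded$slot)
  present <- cen$status %in% c("pin", "singleton", "multi")
  expect_identical(decoded$slot[ord], cen$slot[present])
  expect_identical(decoded$status[ord], cen$status[present])
  expect_identical(lapply(decoded$positions[ord], as.numeric),
                   lapply(cen$positions[present], as.numeric))
  # excluded and absent slots must decode as absent with no positions
  not_present <- cen$slot[!present]
  if (length(not_present)) {
    checks <- vapply(not_present, function(s) {
      lk <- lookup_positions(index, s)
      lk$status == "absent" && length(lk$positions) == 0
    }, logical(1))
    expect_true(all(checks))
  }
}

# ---- exhaustive gapless extension (x-drop with x = infinity)

oracle_gapless_max <- function(query, genome, qpos, rpos, k, lo, hi,
                               match = 1, mismatch = -2) {
  qv <- strsplit(query, "")[[1]]
  gl <- max(0, min(qpos, rpos - lo))
  gr <- max(0, min(nchar(query) - qpos - k, hi - rpos - k))
  col_score <- function(qi, ri) {
    gb <- rawToChar(genome[ri + 1])
    if (qv[qi + 1] %in% c("A", "C", "G", "T") && qv[qi + 1] == gb)
      match else mismatch
  }
  best_left <- 0
  if (gl > 0) {
    run <- cumsum(vapply(1:gl, function(i)
      col_score(qpos - i, rpos - i), numeric(1)))
    best_left <- max(0, run)
  }
  best_right <- 0
  if (gr > 0) {
    run <- cumsum(vapply(1:gr, function(i)
      col_score(qpos + k + i - 1, rpos + k + i - 1), numeric(1)))
    best_right <- max(0, run)
  }
  k * match + best_left + best_right
}

# ---- full affine semi-global DP (query global, reference local)

oracle_semiglobal <- function(query, ref, match = 1, mismatch = -2,
                              gap_open = -4, gap_extend = -1) {
  m <- nchar(query); n <- nchar(ref)
  qv <- strsplit(query, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1)
  I <- matrix(NEG, m + 1, n + 1) # consumes query
  D <- matrix(NEG, m + 1, n + 1) # consumes reference
  M[1, ] <- 0
  go <- gap_open + gap_extend
  for (i in 2:(m + 1)) {
    for (j in 1:(n + 1)) {
      if (j > 1) {
        sub <- if (qv[i - 1] %in% c("A", "C", "G", "T") &&
                   qv[i - 1] == rv[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + sub
        D[i, j] <- max(max(M[i, j - 1], I[i, j - 1], D[i, j - 1]) + go,
                       D[i, j - 1] + gap_extend)
      }
      I[i, j] <- max(max(M[i - 1, j], I[i - 1, j], D[i - 1, j]) + go,
                     I[i - 1, j] + gap_extend)
    }
  }
  max(M[m + 1, ], I[m + 1, ])
}

# Score implied by a CIGAR at a given reference start (consistency check).
score_from_cigar <- function(query, genome, ref_start, cigar,
                             match = 1, mismatch = -2, gap_open = -4,
                             gap_extend = -1) {
  ops <- cigar_ops(cigar)
  qi <- 0; ri <- ref_start; sc <- 0
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]; op <- ops$op[r]
    if (op == "M") {
      for (z in seq_len(len)) {
        qb <- substr(query, qi + z, qi + z)
        gb <- rawToChar(genome[ri + z])
        sc <- sc + if (qb %in% c("A", "C", "G", "T") && qb == gb)
          match else mismatch
      }
      qi <- qi + len; ri <- ri + len
    } else if (op == "I") {
      sc <- sc + gap_open + len * gap_extend
      qi <- qi + len
    } else if (op == "D") {
      sc <- sc + gap_open + len * gap_extend
      ri <- ri + len
    } else stop("unexpected op ", op)
  }
  list(score = sc, query_consumed = as.integer(qi))
}
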