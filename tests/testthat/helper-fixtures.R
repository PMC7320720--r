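# Shared fixture builders for the test suite. Everything is generated
# in code from fixed seeds; no data files.

rand_genome <- function(n, seed) {
  with_seed_t(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = ""))
}

with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

ref_record <- function(seq, name = "chr1") list(list(name = name, seq = seq))

# Extract an error-free FR pair with fragment `frag` starting at `st`
# (0-based) from genome string g.
make_pair <- function(g, st, L = 150, frag = 350, name = "p") {
  list(r1 = list(name = name, seq = substr(g, st + 1, st + L)),
       r2 = list(name = name,
                 seq = pinmapr:::revcomp(substr(g, st + frag - L + 1,
                                                st + frag))))
}

# A genome with an exact duplication: unit of length `len` copied at
# `at1` and `at2` (0-based). Returns the sequence string.
plant_duplication <- function(g, len, at1, at2, seed = 7) {
  unit <- with_seed_t(seed, paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""))
  substr(g, at1 + 1, at1 + len) <- unit
  substr(g, at2 + 1, at2 + len) <- unit
  g
}

# Small index over a random genome with an H large enough to keep hash
# collisions negligible at test scale.
build_test_index <- function(seq, k = 24, t = 32, H_factor = 20,
                             name = "chr1") {
  H <- pinmapr:::next_prime(max(65537, H_factor * nchar(seq)))
  build_index(ref_record(seq, name), index_params(k = k, t = t, H = H))
}
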