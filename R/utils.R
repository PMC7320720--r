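# Shared internal helpers.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic primality by trial division (sufficient for table sizes).
is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

next_prime <- function(n) {
  n <- ceiling(n)
  while (!is_prime(n)) n <- n + 1
  n
}

# Reverse complement of a nucleotide string (N maps to N).
revcomp <- function(s) revcomp_seq_cpp(s)

`%||%` <- function(a, b) if (is.null(a)) b else a
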