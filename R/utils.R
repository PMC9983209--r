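# Internal helpers: seeded evaluation and k-mer hashing.
#
# Hashing uses two independent modular rolling hashes with ~26-bit prime
# moduli, combined into a single double below 2^52 so the value is exact in
# IEEE doubles. This gives a deterministic, seedable stand-in for a 64-bit
# k-mer hash without integer-overflow issues in base R.

.P1 <- 67108859   # largest prime below 2^26
.P2 <- 67108837

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.hash_base <- function(seed, p) {
  b <- (1103515245 * ((as.numeric(seed) %% 1e6) + 1) + 12345) %% (p - 512)
  131 + (b %% (p - 1024))
}

# Rolling polynomial hashes of all k-windows of an integer code vector.
# codes may contain NA (invalid letters); windows touching NA are dropped by
# the caller via the returned mask.
.rolling_hash <- function(codes, k, b, p) {
  n <- length(codes)
  m <- n - k + 1L
  pow <- numeric(k)
  pow[1] <- 1
  if (k > 1) for (j in 2:k) pow[j] <- (pow[j - 1] * b) %% p
  cc <- codes
  cc[is.na(cc)] <- 0
  acc <- numeric(m)
  for (j in seq_len(k)) {
    acc <- (acc + cc[j:(m + j - 1L)] * pow[j]) %% p
  }
  acc
}

.dna_codes <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  function(seq) lut[as.integer(charToRaw(seq)) + 1L]
})

# Canonical k-mer hashes of one nucleotide sequence. Canonical means the
# smaller of the hash of the k-mer and of its reverse complement, so a k-mer
# and its reverse complement always collapse to one value. Windows containing
# N (or any non-ACGT letter) are dropped. Returns a numeric vector, one entry
# per valid window, in sequence order.
kmer_hashes_dna <- function(seq, k, hash_seed = 42L) {
  codes <- .dna_codes(seq)
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  bad <- is.na(codes)
  cb <- cumsum(bad)
  win_bad <- (c(cb[k:n]) - c(0, cb[seq_len(m - 1L)])) > 0
  b1 <- .hash_base(hash_seed, .P1)
  b2 <- .hash_base(hash_seed + 7L, .P2)
  h1 <- .rolling_hash(codes, k, b1, .P1)
  h2 <- .rolling_hash(codes, k, b2, .P2)
  fwd <- h1 * 67108864 + h2
  rc_codes <- rev(3L - codes)
  r1 <- .rolling_hash(rc_codes, k, b1, .P1)
  r2 <- .rolling_hash(rc_codes, k, b2, .P2)
  rc <- (r1 * 67108864 + r2)[m:1L]
  out <- pmin(fwd, rc)
  out[!win_bad]
}

# Plain (non-canonical) k-mer hashes of a protein/byte string.
kmer_hashes_aa <- function(seq, k, hash_seed = 42L) {
  codes <- as.integer(charToRaw(seq))
  n <- length(codes)
  if (n < k) return(numeric(0))
  b1 <- .hash_base(hash_seed + 13L, .P1)
  b2 <- .hash_base(hash_seed + 29L, .P2)
  h1 <- .rolling_hash(codes, k, b1, .P1)
  h2 <- .rolling_hash(codes, k, b2, .P2)
  h1 * 67108864 + h2
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
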