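# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings) wherever they are used to verify them.

# Affine-gap Smith-Waterman in plain R with the same scoring scheme as the
# package kernel (match 2, mismatch -3, N/X mismatch -1, gap open 5, gap
# extend 2; opening a gap costs open + extend). Instead of a traceback,
# match/column/consumed counts are propagated through the DP along one
# deterministic optimal path, so identity and coverage fall out directly.
# The optimal *score* is unique; identity may differ between co-optimal
# paths, so tests compare identity exactly only on gap-free constructions.
# Small sequences only (plain R loops).
sw_oracle <- function(a, b, match = 2, mismatch = -3, fuzzy = -1,
                      gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  mk <- function(init) matrix(init, n + 1, m + 1)
  # per state: score, matches, columns, consumed a, consumed b
  S <- list(M = mk(0), X = mk(NEG), Y = mk(NEG))
  Mt <- list(M = mk(0L), X = mk(0L), Y = mk(0L))
  Cl <- list(M = mk(0L), X = mk(0L), Y = mk(0L))
  Ca <- list(M = mk(0L), X = mk(0L), Y = mk(0L))
  Cb <- list(M = mk(0L), X = mk(0L), Y = mk(0L))
  best <- list(score = 0, identity = 0, coverage_a = 0, coverage_b = 0)
  for (i in 1:n) {
    for (j in 1:m) {
      fz <- A[i] %in% c("N", "X") || B[j] %in% c("N", "X")
      s <- if (fz) fuzzy else if (A[i] == B[j]) match else mismatch
      is_match <- !fz && A[i] == B[j]
      # state M: diagonal from best of M/X/Y (ties: M, X, Y), or fresh start
      prev <- c(S$M[i, j], S$X[i, j], S$Y[i, j])
      k <- which.max(prev)
      val <- s + prev[k]
      key <- c("M", "X", "Y")[k]
      if (val <= 0) {
        # local alignment restarts; counts reset with the score
        S$M[i + 1, j + 1] <- 0
        Mt$M[i + 1, j + 1] <- 0L; Cl$M[i + 1, j + 1] <- 0L
        Ca$M[i + 1, j + 1] <- 0L; Cb$M[i + 1, j + 1] <- 0L
      } else {
        S$M[i + 1, j + 1] <- val
        Mt$M[i + 1, j + 1] <- Mt[[key]][i, j] + as.integer(is_match)
        Cl$M[i + 1, j + 1] <- Cl[[key]][i, j] + 1L
        Ca$M[i + 1, j + 1] <- Ca[[key]][i, j] + 1L
        Cb$M[i + 1, j + 1] <- Cb[[key]][i, j] + 1L
      }
      # state X: gap in b (consumes a): open from M or extend X
      op <- S$M[i, j + 1] - gap_open - gap_ext
      ex <- S$X[i, j + 1] - gap_ext
      if (op >= ex) {
        S$X[i + 1, j + 1] <- op
        Mt$X[i + 1, j + 1] <- Mt$M[i, j + 1]; Cl$X[i + 1, j + 1] <- Cl$M[i, j + 1] + 1L
        Ca$X[i + 1, j + 1] <- Ca$M[i, j + 1] + 1L; Cb$X[i + 1, j + 1] <- Cb$M[i, j + 1]
      } else {
        S$X[i + 1, j + 1] <- ex
        Mt$X[i + 1, j + 1] <- Mt$X[i, j + 1]; Cl$X[i + 1, j + 1] <- Cl$X[i, j + 1] + 1L
        Ca$X[i + 1, j + 1] <- Ca$X[i, j + 1] + 1L; Cb$X[i + 1, j + 1] <- Cb$X[i, j + 1]
      }
      # state Y: gap in a (consumes b)
      op <- S$M[i + 1, j] - gap_open - gap_ext
      ex <- S$Y[i + 1, j] - gap_ext
      if (op >= ex) {
        S$Y[i + 1, j + 1] <- op
        Mt$Y[i + 1, j + 1] <- Mt$M[i + 1, j]; Cl$Y[i + 1, j + 1] <- Cl$M[i + 1, j] + 1L
        Ca$Y[i + 1, j + 1] <- Ca$M[i + 1, j]; Cb$Y[i + 1, j + 1] <- Cb$M[i + 1, j] + 1L
      } else {
        S$Y[i + 1, j + 1] <- ex
        Mt$Y[i + 1, j + 1] <- Mt$Y[i + 1, j]; Cl$Y[i + 1, j + 1] <- Cl$Y[i + 1, j] + 1L
        Ca$Y[i + 1, j + 1] <- Ca$Y[i + 1, j]; Cb$Y[i + 1, j + 1] <- Cb$Y[i + 1, j] + 1L
      }
      if (S$M[i + 1, j + 1] > best$score) {
        best <- list(score = S$M[i + 1, j + 1],
                     identity = Mt$M[i + 1, j + 1] / Cl$M[i + 1, j + 1],
                     coverage_a = Ca$M[i + 1, j + 1] / n,
                     coverage_b = Cb$M[i + 1, j + 1] / m)
      }
    }
  }
  best
}

# Exact Jaccard over canonical k-mer string sets (canonical = the pair
# {kmer, revcomp(kmer)} counted once).
rc_oracle <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

kmer_set_oracle <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- vapply(km, rc_oracle, character(1), USE.NAMES = FALSE)
    out <- c(out, pmin(km, rc))
  }
  unique(out)
}

jaccard_oracle <- function(seqs_a, seqs_b, k) {
  A <- kmer_set_oracle(seqs_a, k)
  B <- kmer_set_oracle(seqs_b, k)
  length(intersect(A, B)) / length(union(A, B))
}

# N50 by literal definition scan.
n50_oracle <- function(lengths) {
  sl <- sort(lengths, decreasing = TRUE)
  half <- sum(sl) / 2
  acc <- 0
  for (l in sl) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Welch t from the textbook formula.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# OLS by the normal equations.
ols_oracle <- function(x, y, through_origin = FALSE) {
  if (through_origin) {
    list(slope = sum(x * y) / sum(x^2), intercept = 0)
  } else {
    sl <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
      (sum(x^2) - length(x) * mean(x)^2)
    list(slope = sl, intercept = mean(y) - sl * mean(x))
  }
}

# Six-frame ORF scan from first principles (own codon table walk).
orf_oracle <- function(contig, min_aa, require_start = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  rc <- rc_oracle(contig)
  n <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 1) next
      aa <- character(ncod)
      for (ci in seq_len(ncod)) {
        cod <- substr(s, frame + 3 * ci - 2, frame + 3 * ci)
        aa[ci] <- if (cod %in% names(gc)) gc[[cod]] else "X"
      }
      run_start <- 1L
      for (ci in seq_len(ncod + 1L)) {
        if (ci <= ncod && aa[ci] != "*") next
        seg <- run_start:(ci - 1L)
        run_start <- ci + 1L
        if (length(seg) == 0 || seg[1] > seg[length(seg)]) next
        from <- seg[1]
        if (require_start) {
          ms <- seg[aa[seg] == "M"]
          if (length(ms) == 0) next
          from <- ms[1]
        }
        to <- seg[length(seg)]
        if (to - from + 1L < min_aa) next
        nt_from <- frame + (from - 1L) * 3L
        nt_to <- frame + to * 3L
        if (strand == "+") span <- c(nt_from, nt_to)
        else span <- c(n - nt_to, n - nt_from)
        out[[length(out) + 1L]] <- data.frame(
          frame = frame, strand = strand, start = span[1], end = span[2],
          protein = paste(aa[from:to], collapse = ""))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      protein = character(0)))
  do.call(rbind, out)
}

# Trimmomatic-style trim span oracle: exhaustive window scan.
trim_oracle <- function(q, window, thr, leading, trailing) {
  a <- 1L
  while (a <= length(q) && q[a] < leading) a <- a + 1L
  b <- length(q)
  while (b >= a && q[b] < trailing) b <- b - 1L
  if (a > b) return(integer(0))
  end <- b
  for (i in a:(b - window + 1L)) {
    if (i + window - 1L > b) break
    if (mean(q[i:(i + window - 1L)]) < thr) { end <- i - 1L; break }
  }
  while (end >= a && q[end] < thr) end <- end - 1L
  if (end < a) return(integer(0))
  c(a, end)
}

random_dna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = "")
  if (is.null(seed)) f() else eukbench:::with_seed(seed, f())
}
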