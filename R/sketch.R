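#' Bottom-s MinHash sketch of a sequence set
#'
#' Canonical k-mers (a k-mer and its reverse complement collapse to one
#' value) are hashed with a seeded deterministic hash and the `sketch_size`
#' smallest distinct hash values are retained, sourmash-style.
#'
#' @param records a [seq_records] object (or character vector of sequences).
#' @param k k-mer size (>= 11, default 31).
#' @param sketch_size number of minimum hashes retained (default 1000).
#' @param hash_seed integer hash seed; sketches are only comparable at equal
#'   `k` and `hash_seed`.
#' @param id optional source id stored in the sketch.
#' @return a `kmer_sketch`: list(k, sketch_size, hash_seed, hashes, id).
#' @export
kmer_sketch <- function(records, k = 31L, sketch_size = 1000L, hash_seed = 42L,
                        id = NULL) {
  if (k < 11) .stopf("kmer_sketch: k must be >= 11")
  seqs <- if (inherits(records, "seq_records")) records$seq else as.character(records)
  h <- unlist(lapply(seqs, kmer_hashes_dna, k = k, hash_seed = hash_seed),
              use.names = FALSE)
  h <- unique(h)
  if (length(h) == 0) .stopf("kmer_sketch: no valid k-mer of size %d", k)
  h <- sort(h)
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 hash_seed = as.integer(hash_seed),
                 hashes = h[seq_len(min(length(h), sketch_size))],
                 id = id),
            class = "kmer_sketch")
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("kmer_sketch%s: k=%d, %d/%d hashes\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$k, length(x$hashes), x$sketch_size))
  invisible(x)
}

.check_comparable <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k) .stopf("sketches have different k (%d vs %d)", a$k, b$k)
  if (a$hash_seed != b$hash_seed) .stopf("sketches have different hash seeds")
}

#' MinHash Jaccard estimate between two sketches
#'
#' Bottom-s estimate of |A n B| / |A u B|: the s smallest hashes of the
#' union are taken and the fraction also present in both sketches reported.
#'
#' @param a,b [kmer_sketch] objects with equal `k` and `hash_seed`.
#' @return estimate in \[0, 1\].
#' @export
sketch_jaccard <- function(a, b) {
  .check_comparable(a, b)
  s <- min(a$sketch_size, b$sketch_size, length(a$hashes) + length(b$hashes))
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(length(u), s))]
  sum(u %in% a$hashes & u %in% b$hashes) / length(u)
}

#' ANI estimate from sketch Jaccard (Mash distance transform)
#'
#' `ANI = 100 * (1 + (1/k) * ln(2j / (1 + j)))`, floored at 0. A Jaccard of
#' 0 returns 0 with attribute `below_detection = TRUE`.
#'
#' @param a,b [kmer_sketch] objects.
#' @return ANI percentage in \[0, 100\].
#' @export
ani_estimate <- function(a, b) {
  j <- sketch_jaccard(a, b)
  if (j == 0) return(structure(0, below_detection = TRUE))
  max(0, 100 * (1 + (1 / a$k) * log(2 * j / (1 + j))))
}

#' All-pairs similarity matrix over sketches
#'
#' @param sketches named list of [kmer_sketch] objects (names are member ids).
#' @param kind `"jaccard"` (values in \[0,1\], diagonal 1) or `"ani"`
#'   (percent, diagonal 100).
#' @return symmetric matrix with attribute `kind`.
#' @export
similarity_matrix <- function(sketches, kind = c("jaccard", "ani")) {
  kind <- match.arg(kind)
  n <- length(sketches)
  ids <- names(sketches)
  if (is.null(ids)) .stopf("similarity_matrix: sketches must be named")
  m <- matrix(if (kind == "ani") 100 else 1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- if (kind == "ani") ani_estimate(sketches[[i]], sketches[[j]])
           else sketch_jaccard(sketches[[i]], sketches[[j]])
      m[i, j] <- m[j, i] <- as.numeric(v)
    }
  }
  attr(m, "kind") <- kind
  m
}

#' Highly-related partner pairs from an ANI matrix
#'
#' All unordered pairs of distinct members with ANI at or above the
#' threshold (default 80%), each reported once.
#'
#' @param ani_matrix symmetric ANI matrix (percent), e.g. from
#'   [similarity_matrix()] with `kind = "ani"`.
#' @param threshold ANI percentage cutoff (default 80).
#' @return data frame with columns a, b, ani.
#' @export
partner_pairs <- function(ani_matrix, threshold = 80) {
  ids <- rownames(ani_matrix)
  out <- data.frame(a = character(0), b = character(0), ani = numeric(0))
  n <- nrow(ani_matrix)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ani_matrix[i, j] >= threshold)
        out <- rbind(out, data.frame(a = ids[i], b = ids[j],
                                     ani = ani_matrix[i, j]))
    }
  }
  rownames(out) <- NULL
  out
}
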