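#' Fragment length model
#'
#' Normal fragment lengths (default mean 180 bp, sd 40 bp), truncated by
#' clamping to `[read_length, contig_length]` at draw time.
#'
#' @param mean mean fragment length in bp (>= read length).
#' @param sd standard deviation in bp (>= 0).
#' @return a `fragment_model` list.
#' @export
fragment_model <- function(mean = 180, sd = 40) {
  if (sd < 0) .stopf("fragment_model: sd must be >= 0")
  structure(list(mean = mean, sd = sd), class = "fragment_model")
}

#' Per-cycle quality profile
#'
#' Phred scores for cycles `1..read_length`; the substitution probability at
#' cycle c is `10^(-Q_c/10)`. A score of 60 (the ceiling) is treated as
#' error-free. The default profile decays linearly from Q38 at cycle 1 to
#' Q25 at the last cycle, a generic short-read Illumina shape.
#'
#' @param read_length number of cycles (default 75).
#' @param q_start,q_end Phred scores at the first and last cycle (in
#'   \[2, 60\]).
#' @return integer vector of class `quality_profile`.
#' @export
quality_profile <- function(read_length = 75L, q_start = 38, q_end = 25) {
  if (q_start < 2 || q_start > 60 || q_end < 2 || q_end > 60)
    .stopf("quality_profile: Phred scores must be in [2, 60]")
  q <- as.integer(round(seq(q_start, q_end, length.out = read_length)))
  structure(q, class = "quality_profile")
}

#' Draw truncated fragment lengths
#'
#' Rounded draws from the fragment model, clamped to
#' `[read_length, contig_length]`.
#'
#' @param n number of fragments.
#' @param contig_length upper clamp in bp.
#' @param model a [fragment_model()].
#' @param read_length lower clamp in bp (default 75).
#' @param seed optional integer seed.
#' @return integer vector of lengths.
#' @export
simulate_fragment_lengths <- function(n, contig_length, model = fragment_model(),
                                      read_length = 75L, seed = NULL) {
  if (model$mean < read_length) .stopf("fragment mean below read length")
  with_seed(seed, {
    len <- round(rnorm(n, model$mean, model$sd))
    as.integer(pmin(pmax(len, read_length), contig_length))
  })
}

#' Simulate error-bearing paired-end reads from a designer set
#'
#' For each pair: a source contig is drawn proportional to
#' `weight * (length - read_length + 1)`; a fragment length is drawn from
#' the fragment model (clamped to `[read_length, contig_length]`) and its
#' start uniformly; R1 is the 5' end of the fragment on the forward strand
#' and R2 the reverse complement of its 3' end. Substitution errors are
#' injected per cycle with probability `10^(-Q/10)` (Q >= 60 means none),
#' always to a different base. Read names encode the source contig, 0-based
#' fragment start and fragment length; the same provenance is returned as a
#' truth table. Deterministic per seed.
#'
#' @param records designer contigs ([seq_records]) or a `designer_set`.
#' @param weights positive per-contig expression weights; defaults to the
#'   designer manifest weights, or uniform.
#' @param n_pairs number of read pairs (default 1e6).
#' @param read_length read length in bp (default 75).
#' @param fragment a [fragment_model()].
#' @param quality a [quality_profile()] of length `read_length`.
#' @param seed integer seed.
#' @return list with `r1`, `r2` ([seq_records] with qualities) and `truth`
#'   (data frame: read_id, contig_id, start, frag_len, strand of R1 = "+").
#' @export
simulate_reads <- function(records, weights = NULL, n_pairs = 1e6,
                           read_length = 75L, fragment = fragment_model(),
                           quality = quality_profile(read_length), seed = 1) {
  if (inherits(records, "designer_set")) {
    if (is.null(weights))
      weights <- setNames(records$manifest$weight, records$manifest$contig_id)
    records <- records$records
  }
  if (is.null(weights)) weights <- setNames(rep(1, nrow(records)), records$id)
  w <- as.numeric(weights[records$id])
  if (any(is.na(w) | w <= 0)) .stopf("simulate_reads: every contig needs a positive weight")
  len <- nchar(records$seq)
  short <- len < read_length
  if (any(short))
    .stopf("contig '%s' (%d bp) is shorter than the read length %d",
           records$id[short][1], len[short][1], read_length)
  if (length(quality) != read_length)
    .stopf("quality profile length %d != read length %d", length(quality), read_length)
  perr <- ifelse(quality >= 60, 0, 10^(-as.numeric(quality) / 10))
  qstr <- rawToChar(as.raw(as.integer(quality) + 33L))

  with_seed(seed, {
    eff <- w * (len - read_length + 1)
    src <- sample.int(nrow(records), n_pairs, replace = TRUE, prob = eff / sum(eff))
    flen <- as.integer(pmin(pmax(round(rnorm(n_pairs, fragment$mean, fragment$sd)),
                                 read_length), len[src]))
    start0 <- floor(runif(n_pairs) * (len[src] - flen + 1))   # 0-based
    ctg <- records$seq[src]
    r1 <- substr(ctg, start0 + 1, start0 + read_length)
    r2 <- reverse_complement(substr(ctg, start0 + flen - read_length + 1,
                                    start0 + flen))
    r1 <- .inject_errors(r1, perr)
    r2 <- .inject_errors(r2, perr)
    rid <- sprintf("r%06d_%s_%d_%d", seq_len(n_pairs), records$id[src], start0, flen)
    truth <- data.frame(read_id = rid, contig_id = records$id[src],
                        start = as.integer(start0), frag_len = flen,
                        strand = "+", stringsAsFactors = FALSE)
    qlist <- rep(list(as.integer(quality)), n_pairs)
    list(r1 = seq_records(paste0(rid, "/1"), r1, qual = qlist),
         r2 = seq_records(paste0(rid, "/2"), r2, qual = qlist),
         truth = truth)
  })
}

# substitute bases per cycle with probability perr[c], always to a different base
.inject_errors <- function(reads, perr) {
  n <- length(reads)
  for (c in seq_along(perr)) {
    if (perr[c] == 0) next
    hit <- which(runif(n) < perr[c])
    if (length(hit) == 0) next
    cur <- substr(reads[hit], c, c)
    ci <- match(cur, .BASES)
    off <- sample.int(3L, length(hit), replace = TRUE)
    repl <- .BASES[((ci - 1L + off) %% 4L) + 1L]
    repl[is.na(ci)] <- "N"
    substr(reads[hit], c, c) <- repl
  }
  reads
}

#' Sliding-window quality trimming of read pairs
#'
#' Trimmomatic-style semantics, in order: LEADING (clip leading bases with
#' quality below the threshold), TRAILING (same from the 3' end),
#' SLIDINGWINDOW (cut the read at the start of the first full window whose
#' mean quality falls below the threshold), MINLEN (drop reads shorter than
#' the minimum). When one mate of a pair is dropped, the survivor is routed
#' to the unpaired output. Defaults mirror
#' `LEADING:2 TRAILING:2 SLIDINGWINDOW:4:2 MINLEN:50`.
#'
#' @param r1,r2 paired [seq_records] with qualities, equal record counts.
#' @param window sliding window width (default 4).
#' @param mean_quality window mean-quality threshold (default 2).
#' @param leading,trailing per-base clip thresholds (default 2).
#' @param min_len minimum surviving read length (default 50).
#' @return list with `r1`, `r2` (surviving pairs), `unpaired` (single
#'   survivors) and `log` (data frame: id, mate, action).
#' @export
trim_reads <- function(r1, r2, window = 4L, mean_quality = 2, leading = 2,
                       trailing = 2, min_len = 50L) {
  if (nrow(r1) != nrow(r2))
    .stopf("mate files differ in record count (%d vs %d)", nrow(r1), nrow(r2))
  t1 <- .trim_set(r1, window, mean_quality, leading, trailing, min_len)
  t2 <- .trim_set(r2, window, mean_quality, leading, trailing, min_len)
  both <- t1$keep & t2$keep
  only1 <- t1$keep & !t2$keep
  only2 <- t2$keep & !t1$keep
  log_entry <- function(ids, mate, action) {
    data.frame(id = ids, mate = rep(mate, length(ids)),
               action = rep(action, length(ids)), stringsAsFactors = FALSE)
  }
  log <- rbind(
    log_entry(r1$id[!t1$keep], 1L, "dropped"),
    log_entry(r2$id[!t2$keep], 2L, "dropped"),
    log_entry(r1$id[only1], 1L, "unpaired"),
    log_entry(r2$id[only2], 2L, "unpaired"))
  list(r1 = records_subset(t1$records, which(both)),
       r2 = records_subset(t2$records, which(both)),
       unpaired = records_bind(records_subset(t1$records, which(only1)),
                               records_subset(t2$records, which(only2))),
       log = log)
}

# Returns the kept [start, end] span (1-based, on the original read) or
# integer(0) when nothing survives. The sliding-window step also strips
# trailing bases below the window threshold from the kept region, as
# Trimmomatic's window trimmer does; this makes trimming idempotent.
.trim_one_qual <- function(q, window, mean_quality, leading, trailing) {
  n <- length(q)
  a <- 1L
  while (a <= n && q[a] < leading) a <- a + 1L
  b <- n
  while (b >= a && q[b] < trailing) b <- b - 1L
  if (a > b) return(integer(0))
  qq <- q[a:b]
  m <- length(qq)
  end <- b
  if (m >= window) {
    cs <- c(0, cumsum(qq))
    wmean <- (cs[(window + 1):(m + 1)] - cs[1:(m - window + 1)]) / window
    cut <- which(wmean < mean_quality)
    if (length(cut) > 0) end <- a + cut[1] - 2L
  }
  while (end >= a && q[end] < mean_quality) end <- end - 1L
  if (end < a) return(integer(0))
  c(a, end)
}

.trim_set <- function(recs, window, mean_quality, leading, trailing, min_len) {
  n <- nrow(recs)
  keep <- logical(n)
  seqs <- recs$seq
  quals <- recs$qual
  for (i in seq_len(n)) {
    q <- quals[[i]]
    if (is.null(q)) .stopf("record '%s' has no qualities; cannot trim", recs$id[i])
    span <- .trim_one_qual(q, window, mean_quality, leading, trailing)
    if (length(span) == 2L && (span[2] - span[1] + 1L) >= min_len) {
      keep[i] <- TRUE
      if (span[1] != 1L || span[2] != length(q)) {
        seqs[i] <- substr(seqs[i], span[1], span[2])
        quals[[i]] <- q[span[1]:span[2]]
      }
    }
  }
  out <- seq_records(recs$id, seqs, recs$desc, quals)
  list(records = out, keep = keep)
}
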