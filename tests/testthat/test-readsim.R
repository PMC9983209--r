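make_small_designer <- function(n = 20, len = 400, seed = 31) {
  eukbench:::with_seed(seed, {
    seq_records(sprintf("ctg%03d", 1:n),
                vapply(rep(len, n), function(l)
                  paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
                  character(1)))
  })
}

test_that("simulated reads have the configured length and deterministic output", {
  recs <- make_small_designer()
  rs <- simulate_reads(recs, n_pairs = 2000, seed = 1)
  expect_equal(nrow(rs$r1), 2000)
  expect_equal(nrow(rs$r2), 2000)
  expect_true(all(nchar(rs$r1$seq) == 75))
  expect_true(all(nchar(rs$r2$seq) == 75))
  rs2 <- simulate_reads(recs, n_pairs = 2000, seed = 1)
  expect_identical(rs$r1$seq, rs2$r1$seq)
  expect_identical(rs$truth, rs2$truth)
  # read names encode contig, start and fragment length
  expect_match(rs$r1$id[1], "^r000001_ctg[0-9]+_[0-9]+_[0-9]+/1$")
  expect_error(simulate_reads(seq_records("short", random_dna(50)), n_pairs = 10),
               "shorter than the read length")
})

test_that("error-free mode yields exact substrings in the right orientation", {
  recs <- make_small_designer()
  rs <- simulate_reads(recs, n_pairs = 400,
                       quality = quality_profile(75, 60, 60), seed = 2)
  ctg <- setNames(recs$seq, recs$id)
  src <- ctg[rs$truth$contig_id]
  r1_sub <- substr(src, rs$truth$start + 1, rs$truth$start + 75)
  expect_identical(unname(r1_sub), rs$r1$seq)
  r2_sub <- substr(src, rs$truth$start + rs$truth$frag_len - 74,
                   rs$truth$start + rs$truth$frag_len)
  expect_identical(reverse_complement(r2_sub), rs$r2$seq)
})

test_that("injected error rate tracks the quality profile", {
  recs <- make_small_designer(n = 5, len = 2000)
  qp <- quality_profile(75, 20, 20)       # p = 0.01 per cycle
  rs <- simulate_reads(recs, n_pairs = 5000, quality = qp, seed = 3)
  ctg <- setNames(recs$seq, recs$id)
  src <- substr(ctg[rs$truth$contig_id], rs$truth$start + 1, rs$truth$start + 75)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), rs$r1$seq, unname(src)))
  rate <- mism / (5000 * 75)
  se3 <- 3 * sqrt(0.01 * 0.99 / (5000 * 75))
  expect_lt(abs(rate - 0.01), se3)
})

test_that("fragment lengths realize the 180 +/- 40 model", {
  fl <- simulate_fragment_lengths(1e5, 5000, seed = 1)
  expect_lt(abs(mean(fl) - 180), 3 * 40 / sqrt(1e5))
  expect_lt(abs(sd(fl) - 40), 3 * 40 / sqrt(2 * 1e5))
  expect_true(all(fl >= 75 & fl <= 5000))
})

test_that("per-contig read counts follow manifest weights", {
  n <- 100
  recs <- make_small_designer(n = n, len = 500, seed = 5)
  w <- eukbench:::with_seed(6, setNames(runif(n, 0.2, 5), recs$id))
  rs <- simulate_reads(recs, weights = w, n_pairs = 1e5, seed = 7)
  counts <- table(factor(rs$truth$contig_id, levels = recs$id))
  expect_gt(cor(as.numeric(counts), as.numeric(w)), 0.99)
})

test_that("quality trimming follows Trimmomatic-style semantics", {
  mk <- function(qs) seq_records(paste0("r", seq_along(qs)),
                                 vapply(lengths(qs), function(l) strrep("A", l),
                                        character(1)),
                                 qual = qs)
  # 60 bases all Q40: unchanged
  r <- mk(list(rep(40L, 60)))
  out <- trim_reads(r, r)
  expect_equal(out$r1$seq, strrep("A", 60))
  # 40 bases all Q40: below MINLEN, dropped
  r <- mk(list(rep(40L, 40)))
  out <- trim_reads(r, mk(list(rep(40L, 60))))
  expect_equal(nrow(out$r1), 0)
  expect_equal(nrow(out$unpaired), 1)    # surviving mate routed to unpaired
  expect_true(any(out$log$action == "dropped"))
  # Q40 prefix then Q0 tail: truncated at the first failing window
  q <- c(rep(40L, 60), rep(0L, 15))
  out <- trim_reads(mk(list(q)), mk(list(rep(40L, 75))))
  span <- trim_oracle(q, 4, 2, 2, 2)
  expect_equal(nchar(out$r1$seq[1]), span[2] - span[1] + 1)
  expect_error(trim_reads(mk(list(rep(40L, 60))), mk(rep(list(rep(40L, 60)), 2))),
               "differ in record count")
})

test_that("trimming agrees with the exhaustive window-scan oracle and is idempotent", {
  set.seed(8)
  quals <- lapply(1:40, function(i) {
    n <- sample(55:75, 1)
    pmin(pmax(as.integer(round(rnorm(n, 25, 14))), 0L), 40L)
  })
  recs <- seq_records(sprintf("r%02d", 1:40),
                      vapply(lengths(quals), function(l)
                        paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
                        character(1)),
                      qual = quals)
  out <- trim_reads(recs, recs, min_len = 30)
  for (i in seq_along(quals)) {
    span <- trim_oracle(quals[[i]], 4, 2, 2, 2)
    keep <- length(span) == 2 && span[2] - span[1] + 1 >= 30
    id <- sprintf("r%02d", i)
    if (keep) {
      j <- match(id, out$r1$id)
      expect_false(is.na(j))
      expect_equal(out$r1$qual[[j]], quals[[i]][span[1]:span[2]])
    } else {
      expect_false(id %in% out$r1$id)
    }
  }
  again <- trim_reads(out$r1, out$r2, min_len = 30)
  expect_identical(again$r1$seq, out$r1$seq)
  expect_identical(again$r2$qual, out$r2$qual)
  expect_equal(nrow(again$unpaired), 0)
})

test_that("error-free simulated reads all pseudomap back to their contigs", {
  fx <- fixture_designer()
  rs <- simulate_reads(fx$designer, n_pairs = 500,
                       quality = quality_profile(75, 60, 60), seed = 9)
  pm <- pseudomap(records_bind(rs$r1, rs$r2), fx$designer$records)
  expect_equal(pm$percent_mapped, 100)
})
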