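test_that("the alignment kernel matches the DP oracle", {
  set.seed(41)
  # identical sequences
  s <- random_dna(100)
  al <- local_align_identity(s, s)
  expect_equal(al$identity, 1.0)
  expect_equal(al$coverage_a, 1.0)
  expect_equal(al$coverage_b, 1.0)
  # one interior mismatch: full-length alignment at 99%
  t <- s
  substr(t, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1]
  expect_equal(local_align_identity(s, t)$identity, 0.99)
  expect_equal(sw_oracle(s, t)$identity, 0.99)
  # reverse-complement detection
  alrc <- local_align_identity(s, reverse_complement(s))
  expect_equal(alrc$identity, 1.0)
  expect_equal(alrc$strand, "-")
  # random mutated/indel pairs: score and identity equal the oracle
  for (i in 1:6) {
    a <- random_dna(150)
    b <- mutate_sequence(a, 0.06, 0.02)
    o <- sw_oracle(a, b)
    al <- local_align_identity(a, b, clustering_params(strand_aware = FALSE))
    expect_equal(al$identity, o$identity, tolerance = 1e-12)
    expect_equal(al$coverage_a, o$coverage_a, tolerance = 1e-12)
  }
  # symmetry of identity under argument swap
  a <- random_dna(120); b <- mutate_sequence(a, 0.05)
  expect_equal(local_align_identity(a, b)$identity,
               local_align_identity(b, a)$identity)
  expect_error(local_align_identity("", "ACGT"), "empty")
})

test_that("greedy clustering groups duplicates and separates 97% pairs at 0.98", {
  set.seed(42)
  s <- random_dna(300)
  dup <- seq_records(c("a", "b"), c(s, s))
  cs <- greedy_cluster(dup, clustering_params(min_identity = 1, min_coverage = 1))
  expect_length(cs$clusters, 1)
  # a pair at ~97% identity stays separate at the 98% threshold
  t97 <- s
  pos <- sample(20:280, 9)  # 9 interior substitutions = 97% identity
  for (p in pos) substr(t97, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(t97, p, p))[1]
  expect_equal(sw_oracle(s, t97)$identity, 0.97)
  cs <- greedy_cluster(seq_records(c("a", "b"), c(s, t97)),
                       clustering_params(min_identity = 0.98))
  expect_length(cs$clusters, 2)
  # at ~99% they merge
  t99 <- s
  for (p in sample(300, 3)) substr(t99, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                         substr(t99, p, p))[1]
  cs <- greedy_cluster(seq_records(c("a", "b"), c(s, t99)),
                       clustering_params(min_identity = 0.98))
  expect_length(cs$clusters, 1)
})

test_that("every clustered member meets both thresholds against its representative", {
  set.seed(43)
  bases <- vapply(1:60, function(i)
    random_dna(sample(100:160, 1)), character(1))
  extra <- vapply(sample(bases, 40, replace = TRUE), function(s)
    mutate_sequence(s, sample(c(0.005, 0.01, 0.05), 1)), character(1))
  recs <- seq_records(sprintf("s%03d", 1:100), c(bases, extra))
  params <- clustering_params(min_identity = 0.98, min_coverage = 0.8)
  cs <- greedy_cluster(recs, params)
  tab <- clusters_table(cs)
  seqs <- setNames(recs$seq, recs$id)
  shorter_cov <- function(o, x, y) {
    if (nchar(x) <= nchar(y)) o$coverage_a else o$coverage_b
  }
  for (r in seq_len(nrow(tab))) {
    if (tab$member[r] == tab$representative[r]) next
    o <- sw_oracle(seqs[[tab$member[r]]], seqs[[tab$representative[r]]])
    expect_gte(o$identity, 0.98)
    expect_gte(shorter_cov(o, seqs[[tab$member[r]]], seqs[[tab$representative[r]]]),
               0.8 - 1e-9)
  }
  # no two retained representatives are mutually above both thresholds
  # (brute-force spot check over a random subset of representative pairs)
  reps <- vapply(cs$clusters, `[[`, character(1), "representative")
  pairs <- t(combn(length(reps), 2))
  pairs <- pairs[sample(nrow(pairs), min(60, nrow(pairs))), , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    x <- seqs[[reps[pairs[r, 1]]]]; y <- seqs[[reps[pairs[r, 2]]]]
    o <- sw_oracle(x, y)
    expect_false(o$identity >= 0.98 && shorter_cov(o, x, y) >= 0.8)
  }
  # clustering is invariant to input record order
  perm <- eukbench:::with_seed(5, sample(nrow(recs)))
  cs2 <- greedy_cluster(records_subset(recs, perm), params)
  sig <- function(x) sort(vapply(x$clusters, function(cl)
    paste(sort(cl$members$id), collapse = ","), character(1)))
  expect_equal(sig(cs2), sig(cs))
})

test_that("assembly merging rewrites ids and keeps provenance recoverable", {
  set.seed(44)
  a1 <- seq_records(sprintf("c%d", 1:10), replicate(10, random_dna(120)))
  a2 <- seq_records(sprintf("c%d", 1:15), replicate(15, random_dna(120)))
  agm <- merge_assemblies(list(rnaspades = a1, megahit = a2), "S1")
  expect_equal(nrow(agm$records), 25)
  expect_true(all(grepl("^S1_(rnaspades|megahit)_c[0-9]+$", agm$records$id)))
  expect_equal(agm$provenance$original_id,
               c(a1$id, a2$id))
  # empty assembly contributes nothing
  agm2 <- merge_assemblies(list(rnaspades = a1,
                                empty = seq_records(character(0), character(0))),
                           "S2")
  expect_equal(nrow(agm2$records), 10)
})

test_that("containment dedup removes exact substrings only, idempotently", {
  set.seed(45)
  s <- random_dna(400)
  recs <- seq_records(c("full", "sub", "other"),
                      c(s, substr(s, 100, 250), random_dna(300)))
  dd <- dedup_identical(recs)
  expect_setequal(dd$records$id, c("full", "other"))
  # all-unique input is unchanged (verified by brute-force containment scan)
  uniq <- seq_records(sprintf("u%d", 1:12), replicate(12, random_dna(200)))
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    o <- sw_oracle(uniq$seq[i], uniq$seq[j])
    expect_false(o$identity == 1 && min(o$coverage_a, o$coverage_b) == 1)
  }
  dd2 <- dedup_identical(uniq)
  expect_equal(dd2$records$id, uniq$id[order(-nchar(uniq$seq), uniq$id)])
  dd3 <- dedup_identical(dd$records)
  expect_identical(dd3$records$seq, dd$records$seq)
})

test_that("CAG/MAD clustering collapses near-duplicates at the 98% level", {
  set.seed(46)
  base <- replicate(20, random_dna(300))
  near <- vapply(base[1:8], function(s) {
    t <- s
    for (p in sample(300, 3)) substr(t, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                         substr(t, p, p))[1]
    t
  }, character(1))         # ~99% identical twins
  far <- vapply(base[9:12], function(s) mutate_sequence(s, 0.05), character(1))
  recs <- seq_records(sprintf("k%02d", 1:32), c(base, near, far))
  cag <- build_cag(recs)
  expect_equal(nrow(cag$records), 24)    # 20 base + 4 far survivors
  expect_lte(nrow(cag$records), nrow(recs))
  # MAD: two identical CAGs collapse to one
  cag_b <- cag$records
  cag_b$id <- paste0("b_", cag_b$id)
  mad <- build_mad(list(cag$records, cag_b))
  expect_equal(nrow(mad$records), nrow(cag$records))
  # single CAG re-clusters to itself
  mad1 <- build_mad(list(cag$records))
  expect_setequal(mad1$records$id, cag$records$id)
})
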