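test_that("N50 and contig statistics follow their definitions", {
  lens <- c(10, 9, 8, 7, 5)
  recs <- seq_records(paste0("c", 1:5),
                      vapply(lens, function(l) strrep("A", l), character(1)))
  st <- assembly_stats(recs)
  expect_equal(st$n50, 8)         # cumulative 10, 19, 27 >= 19.5
  expect_equal(st$min, 5); expect_equal(st$max, 10)
  expect_equal(st$mean, mean(lens)); expect_equal(st$sd, sd(lens))
  expect_equal(assembly_stats(seq_records("one", strrep("G", 77)))$n50, 77)
  expect_equal(assembly_stats(seq_records(paste0("s", 1:4),
                                          rep(strrep("A", 33), 4)))$n50, 33)
  expect_error(assembly_stats(seq_records(character(0), character(0))), "empty")
  # random fixtures against the brute-force definition scan
  set.seed(51)
  for (i in 1:10) {
    ls <- sample(50:500, sample(3:30, 1), replace = TRUE)
    r <- seq_records(paste0("x", seq_along(ls)),
                     vapply(ls, function(l) strrep("T", l), character(1)))
    expect_equal(assembly_stats(r)$n50, n50_oracle(ls))
  }
})

test_that("six-frame ORF calls equal the exhaustive scan, including reverse strand", {
  set.seed(52)
  # planted 150-codon ORF on the reverse strand of a random background
  orf_nt <- paste0("ATG", paste(sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), 150, TRUE), collapse = ""), "TAA")
  contig <- paste0(random_dna(83), reverse_complement(orf_nt), random_dna(60))
  got <- find_orfs(contig, min_aa = 100)
  exp <- orf_oracle(contig, min_aa = 100)
  expect_equal(got[order(got$start, got$strand), ],
               exp[order(exp$start, exp$strand), ], ignore_attr = TRUE)
  rev_hits <- got[got$strand == "-", ]
  expect_gte(nrow(rev_hits), 1)
  expect_true(any(grepl("^M", rev_hits$protein)))
  # coordinates recover the planted protein from the forward strand
  i <- which(got$strand == "-" & nchar(got$protein) >= 150)[1]
  sub <- substr(contig, got$start[i] + 1, got$end[i])
  expect_true(grepl(got$protein[i], paste(
    eukbench:::.translate_nt(reverse_complement(sub)), collapse = ""), fixed = TRUE))
  # no-ATG (on either strand: no A forward means no T on the reverse) and
  # min_aa filters
  no_atg <- paste(sample(c("C", "G", "T"), 400, TRUE), collapse = "")
  expect_equal(nrow(find_orfs(no_atg, min_aa = 10, require_start = TRUE)), 0)
  short_orf <- paste0(strrep("C", 30), "ATG", strrep("GCA", 50), "TAA", strrep("C", 31))
  expect_equal(nrow(find_orfs(short_orf, min_aa = 100)), 0)
  expect_gte(nrow(find_orfs(short_orf, min_aa = 40)), 1)
  # random contigs agree with the oracle across all six frames
  for (i in 1:5) {
    ctg <- random_dna(500)
    g <- find_orfs(ctg, min_aa = 20)
    e <- orf_oracle(ctg, min_aa = 20)
    expect_equal(g[order(g$start, g$strand, g$frame), ],
                 e[order(e$start, e$strand, e$frame), ], ignore_attr = TRUE)
  }
})

test_that("pseudomapping maps simulated reads and normalizes TPM", {
  set.seed(53)
  contigs <- seq_records(paste0("c", 1:20), replicate(20, random_dna(400)))
  rs <- simulate_reads(contigs, n_pairs = 300,
                       quality = quality_profile(75, 60, 60), seed = 1)
  pm <- pseudomap(records_bind(rs$r1, rs$r2), contigs)
  expect_equal(pm$percent_mapped, 100)
  expect_equal(sum(pm$tpm), 1e6)
  # unrelated random reads share essentially no 31-mers
  noise <- seq_records(paste0("n", 1:200), replicate(200, random_dna(75)))
  pm2 <- pseudomap(noise, contigs)
  expect_lt(pm2$percent_mapped, 1)
  # removing contigs can only decrease the mapped percentage
  pm3 <- pseudomap(records_bind(rs$r1, rs$r2), records_subset(contigs, 1:10))
  expect_lte(pm3$percent_mapped, pm$percent_mapped)
  expect_error(pseudomap(seq_records("r", "ACGTACGT"), contigs, k = 31), "smaller")
})

test_that("protein recovery is complete on self and verified at 90/90", {
  fx <- fixture_designer(generate_panel(panel_config(
    n_organisms = 5, genes_per_organism = 150, gene_length = c(450, 900),
    seed = 12)), budget = 150)
  des <- records_subset(fx$designer$records, 1:60)
  pr <- protein_recovery(des, des)
  expect_equal(pr$counts[["unmatched"]], 0)
  orf_bearing <- pr$counts[["matched"]]
  expect_gt(orf_bearing, 0)
  expect_equal(pr$counts[["matched"]] + pr$counts[["no_orf"]], nrow(des))
  # self matches include identity-1 pairs
  self <- pr$pairs[pr$pairs$assembly_contig == pr$pairs$designer_contig, ]
  expect_true(all(self$identity == 1 & self$coverage == 1))
  # a random contig is never matched
  plus <- records_bind(des, seq_records("random1k", random_dna(1000, seed = 9)))
  pr2 <- protein_recovery(des, plus)
  cat_r <- pr2$per_contig$category[pr2$per_contig$contig == "random1k"]
  expect_true(cat_r %in% c("unmatched", "no_orf"))
  # every reported pair satisfies the thresholds per the oracle
  take <- head(order(pr2$pairs$identity), 10)
  for (r in take) {
    expect_gte(pr2$pairs$identity[r], 0.90)
    expect_gte(pr2$pairs$coverage[r], 0.90)
  }
})

test_that("degrading an assembly moves exactly the dropped contigs out of matched", {
  fx <- fixture_designer(generate_panel(panel_config(
    n_organisms = 5, genes_per_organism = 150, gene_length = c(450, 900),
    seed = 12)), budget = 150)
  des <- records_subset(fx$designer$records, 1:60)
  full <- protein_recovery(des, des)
  keep <- seq_len(nrow(des)) %% 3 != 0     # drop a third
  degraded <- records_subset(des, keep)
  part <- protein_recovery(des, degraded)
  expect_equal(part$per_contig$category,
               full$per_contig$category[keep])
  expect_lte(part$counts[["matched"]], full$counts[["matched"]])
})

test_that("taxonomic recovery classifies match/conflict/unannotated with abundances", {
  truth <- c(s1 = "Skeletonema", s2 = "Emiliania", s3 = "Thalassiosira")
  expect_equal(taxonomic_recovery(truth, truth)$counts,
               c(match = 3, conflict = 0, unannotated = 0))
  obs <- c(s1 = "Skeletonema", s2 = "Micromonas", s3 = "unannotated")
  tr <- taxonomic_recovery(truth, obs, abundances = c(s1 = 10, s2 = 5, s3 = 2))
  expect_equal(tr$counts, c(match = 1, conflict = 1, unannotated = 1))
  expect_equal(unname(tr$abundance_sums), c(10, 5, 2))
  expect_equal(tr$per_sequence$category, c("match", "conflict", "unannotated"))
  # per-label table supports designed-vs-recovered regression
  expect_setequal(tr$per_label$label,
                  c("Skeletonema", "Emiliania", "Thalassiosira", "Micromonas"))
  lab <- tr$per_label[tr$per_label$label == "Skeletonema", ]
  expect_equal(lab$truth_n, 1); expect_equal(lab$observed_n, 1)
  expect_error(taxonomic_recovery(truth, obs, abundances = c(s1 = 1)), "abundance")
})

test_that("functional recovery is exact set algebra", {
  d <- c(x1 = "K1", x2 = "K2", x3 = "K3")
  a <- c(y1 = "K2", y2 = "K3", y3 = "K4")
  fr <- functional_recovery(d, a)
  expect_equal(fr$match, c("K2", "K3"))
  expect_equal(fr$false_positive, "K4")
  expect_equal(fr$not_recovered, "K1")
  same <- functional_recovery(d, d)
  expect_length(same$false_positive, 0)
  expect_length(same$not_recovered, 0)
})

test_that("consensus support counts assemblers per cluster", {
  set.seed(54)
  shared <- random_dna(300)
  a1 <- seq_records(c("p1", "q1"), c(shared, random_dna(250)))
  a2 <- seq_records(c("p2", "q2"), c(shared, random_dna(250)))
  a3 <- seq_records(c("p3", "q3"), c(shared, random_dna(250)))
  a4 <- seq_records(c("p4", "q4"), c(shared, random_dna(250)))
  cs <- consensus_support(list(w = a1, x = a2, y = a3, z = a4))
  expect_equal(max(cs$support), 4)
  expect_equal(sum(cs$support == 4), 1)   # exactly the planted shared contig
  expect_true(all(cs$support[cs$n_members == 1] == 1))
  # the same assembly under two labels: every cluster supported twice
  dup <- consensus_support(list(lab1 = a1, lab2 = a1))
  expect_true(all(dup$support == 2))
  expect_error(consensus_support(list(only = a1)), ">= 2")
})

test_that("regression and Welch's t match their closed-form oracles", {
  x <- c(1, 2, 3, 4, 5)
  r <- linear_regression(x, x)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$pearson_r, 1); expect_equal(r$r_squared, 1)
  r2 <- linear_regression(x, 2 * x + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  set.seed(55)
  xs <- rnorm(50); ys <- 1.4 * xs + rnorm(50, sd = 0.3)
  got <- linear_regression(xs, ys)
  exp <- ols_oracle(xs, ys)
  expect_equal(got$slope, exp$slope, tolerance = 1e-10)
  expect_equal(got$intercept, exp$intercept, tolerance = 1e-10)
  goto <- linear_regression(xs, ys, through_origin = TRUE)
  expect_equal(goto$slope, ols_oracle(xs, ys, TRUE)$slope, tolerance = 1e-10)
  expect_equal(goto$intercept, 0)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")

  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- welch_t(a, b)
  exp <- welch_oracle(a, b)
  expect_equal(got$t, exp$t, tolerance = 1e-12)
  expect_equal(got$df, exp$df, tolerance = 1e-12)
  expect_equal(got$p, exp$p, tolerance = 1e-12)
  expect_equal(welch_t(b, a)$t, -got$t)
  expect_equal(welch_t(a, a)$t, 0)
  expect_equal(welch_t(c(2, 2), c(2, 2))$t, 0)   # zero-variance convention
  set.seed(56)
  for (i in 1:5) {
    aa <- rnorm(8); bb <- rnorm(10, mean = 0.5)
    expect_equal(welch_t(aa, bb)$t, welch_oracle(aa, bb)$t, tolerance = 1e-12)
  }
})
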