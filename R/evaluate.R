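#' Contig summary statistics
#'
#' Minimum, maximum, mean and standard deviation of contig length, N50 and
#' per-sequence GC fractions. N50 follows the QUAST definition: the minimum
#' length among the set of longest contigs that together constitute half
#' the total assembly length (sort descending, take the length where the
#' cumulative sum first reaches total/2).
#'
#' @param records a [seq_records] object with at least one record.
#' @return an `assembly_stats` list: n, min, max, mean, sd, n50, gc.
#' @export
assembly_stats <- function(records) {
  if (nrow(records) == 0) .stopf("assembly_stats: empty assembly")
  len <- nchar(records$seq)
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
  structure(list(n = length(len), min = min(len), max = max(len),
                 mean = mean(len), sd = if (length(len) > 1) sd(len) else 0,
                 n50 = n50, gc = gc_fraction(records$seq)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly_stats: %d contigs, length %d-%d (mean %.1f, sd %.1f), N50 %d\n",
              x$n, x$min, x$max, x$mean, x$sd, x$n50))
  cat(sprintf("  mean GC fraction: %.3f\n", mean(x$gc)))
  invisible(x)
}

#' k-mer pseudo-mapping of reads to contigs
#'
#' A light-weight read-representation proxy: a read is assigned to the
#' contig sharing the largest number of its canonical k-mers, provided that
#' share covers at least `min_kmer_frac` of the read's k-mers. Reports the
#' percentage of reads mapped, per-contig counts, and TPM
#' (count / length-in-kb, normalized to sum 1e6 over contigs with reads).
#'
#' @param reads a [seq_records] of reads (e.g. R1 and R2 bound together);
#'   every read must be longer than `k`.
#' @param contigs a [seq_records] of contigs.
#' @param k k-mer size (default 31).
#' @param min_kmer_frac minimum shared fraction of the read's k-mers.
#' @return list with `percent_mapped`, `counts` (named, all contigs) and
#'   `tpm` (named, sums to 1e6 when any read maps).
#' @export
pseudomap <- function(reads, contigs, k = 31L, min_kmer_frac = 0.7) {
  if (nrow(reads) == 0) .stopf("pseudomap: no reads")
  if (any(nchar(reads$seq) <= k))
    .stopf("pseudomap: k = %d must be smaller than every read length", k)
  ckl <- lapply(contigs$seq, kmer_hashes_dna, k = k)
  cdt <- data.table::data.table(
    hash = unlist(ckl, use.names = FALSE),
    contig = rep(seq_len(nrow(contigs)), vapply(ckl, length, integer(1))))
  cdt <- unique(cdt)
  rkl <- lapply(reads$seq, function(s) unique(kmer_hashes_dna(s, k = k)))
  nk <- vapply(rkl, length, integer(1))
  rdt <- data.table::data.table(
    hash = unlist(rkl, use.names = FALSE),
    read = rep(seq_len(nrow(reads)), nk))
  hits <- cdt[rdt, on = "hash", nomatch = NULL, allow.cartesian = TRUE]
  counts <- numeric(nrow(contigs))
  mapped <- 0L
  if (nrow(hits) > 0) {
    shared <- hits[, .N, by = .(read, contig)]
    data.table::setorder(shared, read, -N, contig)
    best <- shared[!duplicated(read)]
    best <- best[N >= min_kmer_frac * nk[read]]
    mapped <- nrow(best)
    if (mapped > 0) {
      tab <- best[, .N, by = contig]
      counts[tab$contig] <- tab$N
    }
  }
  names(counts) <- contigs$id
  tpm <- setNames(numeric(nrow(contigs)), contigs$id)
  pos <- counts > 0
  if (any(pos)) {
    rate <- counts[pos] / (nchar(contigs$seq[pos]) / 1000)
    tpm[pos] <- rate / sum(rate) * 1e6
  }
  list(percent_mapped = 100 * mapped / nrow(reads), counts = counts, tpm = tpm)
}

#' Protein-space recovery of designer content
#'
#' Translates designer and assembly contigs with the six-frame ORF finder,
#' then classifies each assembly contig: `matched` when at least one of its
#' ORF proteins aligns to a designer protein at `min_identity` or better
#' covering at least `min_target_coverage` of the designer protein (the
#' target, mmseqs2 cov-mode 1 style); `unmatched` when it has ORFs but no
#' such alignment; `no_orf` otherwise. All matched designer ids are
#' recorded per contig.
#'
#' @param designer designer [seq_records] (or a `designer_set`).
#' @param assembly assembly [seq_records] to evaluate.
#' @param min_identity minimum protein alignment identity (default 0.90).
#' @param min_target_coverage minimum designer-protein coverage (default 0.90).
#' @param min_aa minimum ORF length in amino acids (default 100).
#' @param prefilter_k shared amino-acid k-mer prefilter size (default 6).
#' @return a `recovery_report`: list with `per_contig` (data frame: contig,
#'   category, matched_designer), `counts` (matched/unmatched/no_orf) and
#'   `pairs` (data frame of verified ORF-protein matches with identity and
#'   coverage).
#' @export
protein_recovery <- function(designer, assembly, min_identity = 0.90,
                             min_target_coverage = 0.90, min_aa = 100L,
                             prefilter_k = 6L) {
  if (inherits(designer, "designer_set")) designer <- designer$records
  d_orfs <- .contig_orfs(designer, min_aa)
  a_orfs <- .contig_orfs(assembly, min_aa)
  params <- clustering_params(min_identity = min_identity,
                              min_coverage = min_target_coverage,
                              coverage_mode = "target_sequence",
                              alphabet = "protein")
  # prefilter: assembly ORF x designer protein pairs sharing an aa k-mer
  ddt <- .aa_kmer_table(d_orfs$protein, prefilter_k)
  adt <- .aa_kmer_table(a_orfs$protein, prefilter_k)
  cand <- unique(ddt[adt, on = "hash", nomatch = NULL,
                     allow.cartesian = TRUE][, .(d = seq_i, a = i.seq_i)])
  data.table::setorder(cand, a, d)
  pairs <- list()
  matched_by <- vector("list", nrow(assembly))
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      ai <- cand$a[r]; di <- cand$d[r]
      al <- local_align_identity(a_orfs$protein[ai], d_orfs$protein[di], params)
      if (al$identity >= min_identity && al$coverage_b >= min_target_coverage) {
        ci <- a_orfs$contig_idx[ai]
        matched_by[[ci]] <- union(matched_by[[ci]], d_orfs$contig[di])
        pairs[[length(pairs) + 1L]] <- data.frame(
          assembly_contig = a_orfs$contig[ai], designer_contig = d_orfs$contig[di],
          identity = al$identity, coverage = al$coverage_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  has_orf <- tabulate(a_orfs$contig_idx, nbins = nrow(assembly)) > 0
  n_match <- lengths(matched_by) > 0
  category <- ifelse(n_match, "matched", ifelse(has_orf, "unmatched", "no_orf"))
  per_contig <- data.frame(
    contig = assembly$id, category = category,
    matched_designer = vapply(matched_by, function(x)
      paste(sort(x), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  structure(list(
    per_contig = per_contig,
    counts = c(matched = sum(category == "matched"),
               unmatched = sum(category == "unmatched"),
               no_orf = sum(category == "no_orf")),
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(assembly_contig = character(0), designer_contig = character(0),
                 identity = numeric(0), coverage = numeric(0))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("recovery_report: %d contigs - matched %d (%.1f%%), unmatched %d, no ORF %d\n",
              n, x$counts["matched"], 100 * x$counts["matched"] / max(n, 1),
              x$counts["unmatched"], x$counts["no_orf"]))
  invisible(x)
}

.contig_orfs <- function(records, min_aa) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    o <- find_orfs(records$seq[i], min_aa = min_aa)
    if (nrow(o) == 0) return(NULL)
    data.frame(contig = records$id[i], contig_idx = i, protein = o$protein,
               stringsAsFactors = FALSE)
  })
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0)
    return(data.frame(contig = character(0), contig_idx = integer(0),
                      protein = character(0)))
  do.call(rbind, res)
}

.aa_kmer_table <- function(proteins, k) {
  kl <- lapply(proteins, kmer_hashes_aa, k = k)
  unique(data.table::data.table(
    hash = unlist(kl, use.names = FALSE),
    seq_i = rep(seq_along(proteins), vapply(kl, length, integer(1)))))
}

.as_label_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    lab <- setNames(as.character(x[[2]]), as.character(x[[1]]))
    ab <- if (ncol(x) >= 3) setNames(as.numeric(x[[3]]), as.character(x[[1]])) else NULL
  } else {
    lab <- x
    ab <- NULL
  }
  if (anyDuplicated(names(lab))) .stopf("label table has duplicate ids")
  list(labels = lab, abundance = ab)
}

#' Taxonomic recovery classification
#'
#' Classifies each observed sequence against the truth labels: `match`
#' (same label), `conflict` (both annotated, different labels - or
#' annotated where the truth is unannotated), `unannotated` (observed label
#' is `"unannotated"`, regardless of truth). Reports raw counts,
#' abundance-weighted sums, and a per-label table suitable for regression
#' of recovered against designed annotation abundance.
#'
#' @param truth,observed label tables: named character vectors (id ->
#'   label) or data frames with columns id, label. The token
#'   `"unannotated"` marks an explicit non-annotation.
#' @param abundances optional named numeric (id -> abundance); defaults
#'   to 1 per sequence. Observed ids must all have an abundance.
#' @return list with `per_sequence` (id, truth, observed, category),
#'   `counts`, `abundance_sums`, and `per_label` (label, truth_n,
#'   observed_n, truth_abundance, observed_abundance).
#' @export
taxonomic_recovery <- function(truth, observed, abundances = NULL) {
  tr <- .as_label_table(truth)$labels
  obs <- .as_label_table(observed)$labels
  ids <- names(obs)
  if (is.null(abundances)) abundances <- setNames(rep(1, length(ids)), ids)
  noab <- setdiff(ids, names(abundances))
  if (length(noab) > 0) .stopf("no abundance for observed id '%s'", noab[1])
  tlab <- ifelse(ids %in% names(tr), tr[ids], "unannotated")
  category <- ifelse(obs == "unannotated", "unannotated",
                     ifelse(tlab != "unannotated" & obs == tlab, "match", "conflict"))
  ab <- abundances[ids]
  counts <- c(match = sum(category == "match"),
              conflict = sum(category == "conflict"),
              unannotated = sum(category == "unannotated"))
  sums <- c(match = sum(ab[category == "match"]),
            conflict = sum(ab[category == "conflict"]),
            unannotated = sum(ab[category == "unannotated"]))
  labs <- sort(unique(c(tlab[tlab != "unannotated"], obs[obs != "unannotated"])))
  per_label <- data.frame(
    label = labs,
    truth_n = vapply(labs, function(l) sum(tlab == l), numeric(1)),
    observed_n = vapply(labs, function(l) sum(obs == l), numeric(1)),
    truth_abundance = vapply(labs, function(l) sum(ab[tlab == l]), numeric(1)),
    observed_abundance = vapply(labs, function(l) sum(ab[obs == l]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_sequence = data.frame(id = ids, truth = tlab, observed = unname(obs),
                                 category = category, stringsAsFactors = FALSE),
       counts = counts, abundance_sums = sums, per_label = per_label)
}

#' Functional recovery of annotation tokens
#'
#' Set comparison of function tokens (KO-like) between the designer and an
#' assembly: `match` (both), `false_positive` (assembly only),
#' `not_recovered` (designer only), with per-set abundance totals when
#' abundances are present (3rd column of the label tables).
#'
#' @param designer_labels,assembly_labels label tables (named vector or
#'   data frame id, label\[, abundance\]); the `"unannotated"` token is
#'   ignored.
#' @return list with `match`, `false_positive`, `not_recovered` (sorted
#'   token sets) and `abundance` (named totals per set).
#' @export
functional_recovery <- function(designer_labels, assembly_labels) {
  d <- .as_label_table(designer_labels)
  a <- .as_label_table(assembly_labels)
  dtok <- setdiff(unique(d$labels), "unannotated")
  atok <- setdiff(unique(a$labels), "unannotated")
  match_set <- sort(intersect(dtok, atok))
  fp <- sort(setdiff(atok, dtok))
  nr <- sort(setdiff(dtok, atok))
  tok_ab <- function(tab, toks) {
    if (is.null(tab$abundance)) return(length(toks))
    sum(tab$abundance[tab$labels %in% toks])
  }
  list(match = match_set, false_positive = fp, not_recovered = nr,
       abundance = c(match = tok_ab(a, match_set),
                     false_positive = tok_ab(a, fp),
                     not_recovered = tok_ab(d, nr)))
}

#' Multi-assembler consensus support
#'
#' Clusters the union of labeled assemblies and annotates each cluster with
#' the set of assembler labels present, giving the consensus support (how
#' many assemblers recovered the sequence) and member length distribution.
#'
#' @param assemblies named list of [seq_records] (names = assembler labels;
#'   at least 2).
#' @param params a [clustering_params()] for the union clustering.
#' @return data frame: representative, support, labels (";"-joined),
#'   n_members, min_len, mean_len, max_len.
#' @export
consensus_support <- function(assemblies, params = clustering_params()) {
  if (length(assemblies) < 2) .stopf("consensus_support: need >= 2 assemblies")
  merged <- merge_assemblies(assemblies, group = "cs")
  cs <- greedy_cluster(merged$records, params)
  lab_of <- setNames(merged$provenance$assembler, merged$provenance$new_id)
  len_of <- setNames(nchar(merged$records$seq), merged$records$id)
  do.call(rbind, lapply(cs$clusters, function(cl) {
    labs <- sort(unique(lab_of[cl$members$id]))
    lens <- len_of[cl$members$id]
    data.frame(representative = cl$representative,
               support = length(labs), labels = paste(labs, collapse = ";"),
               n_members = nrow(cl$members),
               min_len = min(lens), mean_len = mean(lens), max_len = max(lens),
               stringsAsFactors = FALSE)
  }))
}

#' Ordinary least squares with optional zero intercept
#'
#' Standard OLS of y on x; with `through_origin` the intercept is forced to
#' 0 and the slope is `sum(xy)/sum(x^2)`. `pearson_r` is always the Pearson
#' correlation of x and y; `r_squared` is the fit's R^2 (uncentered for the
#' through-origin fit, as base R reports it).
#'
#' @param x,y numeric vectors (>= 3 points; x not constant).
#' @param through_origin force a zero intercept (default FALSE).
#' @return list(slope, intercept, pearson_r, r_squared).
#' @export
linear_regression <- function(x, y, through_origin = FALSE) {
  if (length(x) < 3 || length(x) != length(y))
    .stopf("linear_regression: need >= 3 paired points")
  if (sd(x) == 0) .stopf("linear_regression: x is constant")
  fit <- if (through_origin) lm(y ~ 0 + x) else lm(y ~ x)
  cf <- coef(fit)
  r2 <- if (through_origin) {
    1 - sum(residuals(fit)^2) / sum(y^2)   # uncentered, as base R reports it
  } else {
    cor(x, y)^2
  }
  list(slope = unname(cf["x"]),
       intercept = if (through_origin) 0 else unname(cf["(Intercept)"]),
       pearson_r = cor(x, y),
       r_squared = r2)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. When both samples have zero variance and equal
#' means, t = 0 and p = 1 by convention.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @return list(t, df, p).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) .stopf("welch_t: each sample needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
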