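#' Greedy identity/coverage clustering
#'
#' LINCLUST-style greedy incremental clustering: sequences are sorted by
#' length descending (ties by id), and each sequence joins the first
#' existing representative it meets both thresholds against; otherwise it
#' founds a new cluster. Candidate representatives must share at least one
#' canonical prefilter k-mer with the query; candidates are then verified by
#' the Smith-Waterman kernel, so every recorded (member, representative)
#' pair satisfies the thresholds. Representatives are therefore always the
#' longest member of their cluster.
#'
#' @param records a [seq_records] object.
#' @param params a [clustering_params()].
#' @param prefilter_k k-mer size of the shared-k-mer prefilter (default 15).
#' @return a `cluster_set`: list with `clusters` (list of
#'   `list(representative, members)` where `members` is a data frame with
#'   columns id, identity, coverage) and `params`.
#' @export
greedy_cluster <- function(records, params = clustering_params(), prefilter_k = 15L) {
  if (nrow(records) == 0) .stopf("greedy_cluster: no records")
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  n <- length(ids)
  hash_fun <- if (params$alphabet == "nucleotide") kmer_hashes_dna else kmer_hashes_aa

  rep_of <- integer(n)        # index (into sorted order) of each seq's representative
  ident <- numeric(n); cover <- numeric(n)
  kindex <- new.env(parent = emptyenv())   # k-mer hash (as char) -> rep indices
  reps <- integer(0)

  for (i in seq_len(n)) {
    kh <- unique(hash_fun(seqs[i], prefilter_k))
    keys <- sprintf("%.0f", kh)
    cand <- integer(0)
    for (key in keys) {
      v <- kindex[[key]]
      if (!is.null(v)) cand <- c(cand, v)
    }
    cand <- sort(unique(cand))
    assigned <- FALSE
    for (r in cand) {
      al <- local_align_identity(seqs[i], seqs[r], params)
      cov <- switch(params$coverage_mode,
                    shorter_sequence = if (nchar(seqs[i]) <= nchar(seqs[r]))
                      al$coverage_a else al$coverage_b,
                    target_sequence = al$coverage_b)
      if (al$identity >= params$min_identity && cov >= params$min_coverage) {
        rep_of[i] <- r; ident[i] <- al$identity; cover[i] <- cov
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_of[i] <- i; ident[i] <- 1; cover[i] <- 1
      reps <- c(reps, i)
      for (key in keys) kindex[[key]] <- c(kindex[[key]], i)
    }
  }

  clusters <- lapply(reps, function(r) {
    mem <- which(rep_of == r)
    list(representative = ids[r],
         members = data.frame(id = ids[mem], identity = ident[mem],
                              coverage = cover[mem], stringsAsFactors = FALSE))
  })
  structure(list(clusters = clusters, params = params), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("cluster_set: %d clusters over %d sequences (largest %d)\n",
              length(sizes), sum(sizes), if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Flatten a cluster set to a member table
#'
#' @param x a `cluster_set`.
#' @return data frame with columns member, representative, identity, coverage.
#' @export
clusters_table <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(member = cl$members$id, representative = cl$representative,
               identity = cl$members$identity, coverage = cl$members$coverage,
               stringsAsFactors = FALSE)
  }))
}

cluster_representatives <- function(records, cs) {
  reps <- vapply(cs$clusters, `[[`, character(1), "representative")
  records_subset(records, match(reps, records$id))
}

#' Merge assemblies into an assembly-group merge (AGM)
#'
#' Concatenates per-assembler FASTAs for one assembly group, rewriting ids
#' to `<group>_<assembler>_<original id>` so provenance stays recoverable.
#'
#' @param assemblies named list of [seq_records] (names are assembler labels).
#' @param group assembly-group id (no whitespace).
#' @return list with `records` (the AGM) and `provenance` (data frame:
#'   new_id, group, assembler, original_id).
#' @export
merge_assemblies <- function(assemblies, group) {
  if (length(assemblies) == 0) .stopf("merge_assemblies: no assemblies")
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    .stopf("merge_assemblies: assemblies must be a named list (assembler labels)")
  prov <- do.call(rbind, lapply(names(assemblies), function(lab) {
    a <- assemblies[[lab]]
    if (nrow(a) == 0) return(NULL)
    data.frame(new_id = paste(group, lab, a$id, sep = "_"),
               group = group, assembler = lab, original_id = a$id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(prov)) prov <- data.frame(new_id = character(0), group = character(0),
                                        assembler = character(0),
                                        original_id = character(0))
  if (anyDuplicated(prov$new_id))
    .stopf("merge_assemblies: id collision after rewrite: %s",
           prov$new_id[duplicated(prov$new_id)][1])
  seqs <- unlist(lapply(assemblies, `[[`, "seq"), use.names = FALSE)
  recs <- if (nrow(prov) > 0) seq_records(prov$new_id, seqs)
          else seq_records(character(0), character(0))
  list(records = recs, provenance = prov)
}

#' Remove contigs fully contained in longer ones (100% identity)
#'
#' First-round deduplication: greedy clustering at 100% identity with full
#' shorter-sequence coverage in a local alignment, keeping representatives.
#'
#' @param records the AGM [seq_records].
#' @return list with `records` (deduplicated) and `clusters` (the
#'   `cluster_set` recording what was removed against what).
#' @export
dedup_identical <- function(records) {
  params <- clustering_params(min_identity = 1.0, min_coverage = 1.0,
                              coverage_mode = "shorter_sequence")
  cs <- greedy_cluster(records, params)
  list(records = cluster_representatives(records, cs), clusters = cs)
}

#' Cluster an assembly group at the 98% level (CAG)
#'
#' Second-round clustering of a deduplicated AGM: greedy clustering at 98%
#' identity (shorter-sequence coverage 0.8), keeping representatives.
#'
#' @param records deduplicated AGM [seq_records].
#' @param min_identity identity threshold (default 0.98).
#' @param min_coverage shorter-sequence coverage threshold (default 0.8).
#' @return list with `records` (the CAG) and `clusters`.
#' @export
build_cag <- function(records, min_identity = 0.98, min_coverage = 0.8) {
  params <- clustering_params(min_identity = min_identity,
                              min_coverage = min_coverage,
                              coverage_mode = "shorter_sequence")
  cs <- greedy_cluster(records, params)
  list(records = cluster_representatives(records, cs), clusters = cs)
}

#' Merge CAGs across samples and cluster (MAD)
#'
#' Concatenates the per-sample CAGs (the sample-wide merge, SWAM) and
#' reclusters at the 98% level, yielding the final cross-sample assembly.
#'
#' @param cags list of [seq_records] (one per sample/assembly group). Ids
#'   must be globally unique across CAGs.
#' @param min_identity,min_coverage thresholds as in [build_cag()].
#' @return list with `records` (the MAD) and `clusters`.
#' @export
build_mad <- function(cags, min_identity = 0.98, min_coverage = 0.8) {
  if (length(cags) == 0) .stopf("build_mad: no CAGs")
  swam <- do.call(records_bind, cags)
  build_cag(swam, min_identity, min_coverage)
}
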