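#' Orthogroup tables
#'
#' An orthogroup table maps orthogroup ids to the gene ids each organism
#' contributes, in the dialect of an OrthoFinder `Orthogroups.tsv` file:
#' header `Orthogroup<TAB>org1<TAB>org2...`, cells comma-space separated gene
#' lists, empty cell meaning the organism is absent from the group.
#'
#' @param groups named list: orthogroup id -> named list (organism -> gene
#'   id character vector).
#' @param roster character vector of organism ids covering all columns.
#' @return an `orthogroup_table` object.
#' @export
orthogroup_table <- function(groups, roster = NULL) {
  if (is.null(roster))
    roster <- unique(unlist(lapply(groups, names), use.names = FALSE))
  all_genes <- unlist(groups, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup) > 0)
    .stopf("gene '%s' appears in more than one orthogroup", dup[1])
  missing_org <- setdiff(unique(unlist(lapply(groups, names), use.names = FALSE)), roster)
  if (length(missing_org) > 0)
    .stopf("organism '%s' not in roster", missing_org[1])
  structure(list(groups = groups, roster = roster), class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(unlist(g, use.names = FALSE)), integer(1))
  cat(sprintf("orthogroup_table: %d groups over %d organisms (%d genes)\n",
              length(x$groups), length(x$roster), sum(sizes)))
  invisible(x)
}

#' Read an Orthogroups.tsv-dialect table
#'
#' @param path TSV path with header `Orthogroup` followed by organism ids.
#' @return an [orthogroup_table()].
#' @export
load_orthogroups <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0) .stopf("%s: empty orthogroup file (no header)", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "Orthogroup")
    .stopf("%s: line 1: expected header 'Orthogroup<TAB>org1...'", path)
  roster <- header[-1]
  groups <- list()
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(cells) <- length(header)   # pad trailing empties
    cells[is.na(cells)] <- ""
    gid <- cells[1]
    row <- list()
    for (j in seq_along(roster)) {
      cell <- cells[j + 1]
      if (!nzchar(cell)) next
      row[[roster[j]]] <- strsplit(cell, ", ", fixed = TRUE)[[1]]
    }
    groups[[gid]] <- row
  }
  orthogroup_table(groups, roster)
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' @param table an [orthogroup_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(table, path) {
  stopifnot(inherits(table, "orthogroup_table"))
  roster <- table$roster
  lines <- c(paste(c("Orthogroup", roster), collapse = "\t"))
  for (g in names(table$groups)) {
    cells <- vapply(roster, function(o) {
      ids <- table$groups[[g]][[o]]
      if (is.null(ids)) "" else paste(ids, collapse = ", ")
    }, character(1))
    lines <- c(lines, paste(c(g, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Infer approximate orthogroups from sequences
#'
#' Single-linkage closure over pairwise local alignments: two genes join the
#' same group when their alignment passes both the identity and the
#' (shorter-sequence) coverage threshold. Candidate pairs are prefiltered by
#' a shared canonical k-mer, then verified by the alignment kernel. The
#' partition is deterministic: genes are processed in lexicographic id
#' order and groups are numbered by their smallest member id.
#'
#' @param transcripts named list (organism id -> [seq_records]).
#' @param min_identity minimum alignment identity in (0, 1].
#' @param min_coverage minimum shorter-sequence coverage in (0, 1].
#' @param prefilter_k k-mer size for the candidate prefilter.
#' @return an [orthogroup_table()] with group ids `IOG...`.
#' @export
infer_orthogroups <- function(transcripts, min_identity = 0.8,
                              min_coverage = 0.5, prefilter_k = 15L) {
  if (length(transcripts) == 0) .stopf("infer_orthogroups: no organisms supplied")
  orgs <- names(transcripts)
  gene_org <- unlist(lapply(orgs, function(o) rep(o, nrow(transcripts[[o]]))),
                     use.names = FALSE)
  gene_id <- unlist(lapply(transcripts, `[[`, "id"), use.names = FALSE)
  gene_seq <- unlist(lapply(transcripts, `[[`, "seq"), use.names = FALSE)
  if (length(gene_id) == 0) .stopf("infer_orthogroups: no genes supplied")
  ord <- order(gene_id)
  gene_org <- gene_org[ord]; gene_id <- gene_id[ord]; gene_seq <- gene_seq[ord]
  n <- length(gene_id)

  # candidate pairs sharing >= 1 canonical prefilter k-mer
  kl <- lapply(gene_seq, kmer_hashes_dna, k = prefilter_k)
  dt <- data.table::data.table(
    hash = unlist(kl, use.names = FALSE),
    gene = rep(seq_len(n), vapply(kl, length, integer(1))))
  dt <- unique(dt)
  pairs <- dt[dt, on = "hash", allow.cartesian = TRUE][gene < i.gene,
              .(a = gene, b = i.gene)]
  pairs <- unique(pairs)
  data.table::setorder(pairs, a, b)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  params <- clustering_params(min_identity = min_identity,
                              min_coverage = min_coverage,
                              coverage_mode = "shorter_sequence")
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$a[r]; j <- pairs$b[r]
      if (find(i) == find(j)) next
      al <- local_align_identity(gene_seq[i], gene_seq[j], params)
      cov <- if (nchar(gene_seq[i]) <= nchar(gene_seq[j])) al$coverage_a else al$coverage_b
      if (al$identity >= min_identity && cov >= min_coverage)
        parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  # stable group ids: order components by smallest member id
  comp <- comp[order(vapply(comp, function(ix) gene_id[ix[1]], character(1)))]
  groups <- list()
  for (ci in seq_along(comp)) {
    ix <- comp[[ci]]
    row <- split(gene_id[ix], gene_org[ix])
    groups[[sprintf("IOG%05d", ci)]] <- row[unique(gene_org[ix])]
  }
  orthogroup_table(groups, roster = orgs)
}

#' Single-copy orthogroups over a roster
#'
#' Groups contributing exactly one gene for every roster member - none
#' missing, none duplicated. Membership is evaluated against the supplied
#' roster (e.g. the organisms of the current community), ignoring organisms
#' outside it.
#'
#' @param table an [orthogroup_table()].
#' @param roster character vector of organism ids (subset of the table's).
#' @return character vector of orthogroup ids.
#' @export
single_copy_groups <- function(table, roster = table$roster) {
  stopifnot(inherits(table, "orthogroup_table"))
  extra <- setdiff(roster, table$roster)
  if (length(extra) > 0) .stopf("roster organism '%s' not in table", extra[1])
  keep <- vapply(table$groups, function(g) {
    all(vapply(roster, function(o) length(g[[o]]) == 1L, logical(1)))
  }, logical(1))
  names(table$groups)[keep]
}
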