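#' Build a community specification from a template
#'
#' Six community archetypes of increasing/contrasting complexity:
#' \describe{
#'   \item{1}{dominated by a single organism (richness 4, 0.85/0.05/0.05/0.05).}
#'   \item{2}{two strains of one species make up the majority (richness 5;
#'     the designated strain pair holds the two largest proportions,
#'     0.40/0.35; the rest split the remainder evenly).}
#'   \item{3}{many exclusive genes, skewed membership (richness 8, geometric
#'     decay with ratio 0.7).}
#'   \item{4}{high diversity with related groups (richness 10, near-even,
#'     geometric ratio 0.95; partner pairs placed adjacent at the front).}
#'   \item{5}{several mutually related organisms, even (richness 7).}
#'   \item{6}{highest species diversity, even (richness 12).}
#' }
#' Proportions may be overridden; they are defaults, not fitted values.
#'
#' @param template_id integer 1-6.
#' @param members candidate organism ids (at least the template's richness).
#' @param partner_pairs list of length-2 character vectors of designated
#'   highly-related pairs (e.g. from [partner_pairs()] rows or a panel's
#'   `strain_pairs`). Required for template 2.
#' @param proportions optional override (length = richness, sums to 1).
#' @param budget total designer contig budget (default 5000).
#' @param seed integer seed carried into contig selection.
#' @return a `community_spec`: list(template, members, proportions,
#'   partner_pairs, budget, seed).
#' @export
make_template <- function(template_id, members, partner_pairs = list(),
                          proportions = NULL, budget = 5000, seed = 1) {
  template_id <- as.integer(template_id)
  if (!template_id %in% 1:6) .stopf("template_id must be in 1..6")
  rich <- c(4L, 5L, 8L, 10L, 7L, 12L)[template_id]
  if (length(members) < rich)
    .stopf("template %d needs %d members, got %d", template_id, rich, length(members))
  if (is.data.frame(partner_pairs))
    partner_pairs <- lapply(seq_len(nrow(partner_pairs)),
                            function(i) c(partner_pairs$a[i], partner_pairs$b[i]))
  # order members so designated pairs sit adjacent at the front where the
  # template calls for it
  if (template_id %in% c(2L, 4L, 5L)) {
    avail <- lapply(partner_pairs, function(pr) if (all(pr %in% members)) pr else NULL)
    avail <- Filter(Negate(is.null), avail)
    if (template_id == 2L && length(avail) == 0)
      .stopf("template 2 requires a designated partner pair among the members")
    front <- unique(unlist(avail, use.names = FALSE))
    members <- c(front, setdiff(members, front))
  }
  members <- members[seq_len(rich)]
  if (is.null(proportions)) {
    proportions <- switch(template_id,
      c(0.85, 0.05, 0.05, 0.05),
      c(0.40, 0.35, rep(0.25 / 3, 3)),
      { q <- 0.7 ^ (0:7); q / sum(q) },
      { q <- 0.95 ^ (0:9); q / sum(q) },
      rep(1 / 7, 7),
      rep(1 / 12, 12))
  }
  p <- community_proportions(members, proportions)
  keep <- lapply(partner_pairs, function(pr) if (all(pr %in% members)) pr else NULL)
  structure(list(template = template_id, members = members, proportions = p,
                 partner_pairs = Filter(Negate(is.null), keep),
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("community_spec: template %d, richness %d, budget %d\n",
              x$template, length(x$members), x$budget))
  cat("  proportions:", paste(sprintf("%s=%.3f", x$members,
                                      as.numeric(x$proportions)), collapse = " "), "\n")
  if (length(x$partner_pairs) > 0)
    cat("  partner pairs:",
        paste(vapply(x$partner_pairs, paste, character(1), collapse = "~"),
              collapse = ", "), "\n")
  invisible(x)
}

# round-half-up, avoiding R's round-to-even at .5
.round_half_up <- function(x) floor(x + 0.5)

# largest-remainder split of q into fractions fr (sums to q exactly);
# ties go to the earlier (larger-fraction) category.
.lr_split <- function(q, fr) {
  raw <- q * fr
  base <- floor(raw)
  rem <- q - sum(base)
  if (rem > 0) {
    frac <- raw - base
    give <- order(-frac, seq_along(fr))[seq_len(rem)]
    base[give] <- base[give] + 1L
  }
  as.integer(base)
}

#' Select contigs for a designer metatranscriptome
#'
#' Applies the ortholog-aware selection rules to a community specification:
#' \enumerate{
#'   \item 10% of the single-copy orthogroups over the community roster are
#'     chosen at random and every member's gene from each chosen group is
#'     force-included.
#'   \item Each organism's remaining quota,
#'     `round(proportion * (budget - forced))`, is filled 75% from shared
#'     orthogroups (groups containing at least one other community member)
#'     and 25% from exclusive groups when the organism has a designated
#'     highly-related partner in the community - and 75% exclusive / 25%
#'     shared when it does not. Quota splits use largest-remainder rounding.
#' }
#' No gene is selected twice; expression weights are uniform within an
#' organism (proportion / contig count). The output is deterministic for a
#' fixed seed.
#'
#' @param spec a [make_template()] community spec.
#' @param panel a `reference_panel` (or a named list of [seq_records] in
#'   `transcripts` plus an orthogroup table via `orthogroups`).
#' @param orthogroups an [orthogroup_table()]; defaults to the panel's truth
#'   table.
#' @param seed integer seed (defaults to the spec's).
#' @return a `designer_set`: list with `records` (the designer FASTA
#'   records) and `manifest` (data frame: contig_id, organism, gene_id,
#'   orthogroup, category, weight).
#' @export
select_contigs <- function(spec, panel, orthogroups = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(orthogroups)) {
    stopifnot(inherits(panel, "reference_panel"))
    orthogroups <- orthogroup_table(panel$orthogroups,
                                    roster = panel$organisms$org_id)
  }
  roster <- spec$members
  missing <- setdiff(roster, names(panel$transcripts))
  if (length(missing) > 0) .stopf("community member '%s' not in panel", missing[1])
  with_seed(seed, .select_contigs_impl(spec, panel, orthogroups))
}

.select_contigs_impl <- function(spec, panel, ogt) {
  roster <- spec$members
  p <- spec$proportions
  # gene -> orthogroup map restricted to roster organisms
  acc_g <- list(); acc_og <- list(); acc_org <- list()
  og_members <- list()   # og -> roster organisms present
  for (g in names(ogt$groups)) {
    row <- ogt$groups[[g]]
    orgs_in <- intersect(names(row), roster)
    if (length(orgs_in) == 0) next
    og_members[[g]] <- orgs_in
    ids <- unlist(row[orgs_in], use.names = FALSE)
    acc_g[[g]] <- ids
    acc_og[[g]] <- rep(g, length(ids))
    acc_org[[g]] <- rep(orgs_in, vapply(row[orgs_in], length, integer(1)))
  }
  all_ids <- unlist(acc_g, use.names = FALSE)
  gene_og <- setNames(unlist(acc_og, use.names = FALSE), all_ids)
  gene_org <- setNames(unlist(acc_org, use.names = FALSE), all_ids)

  scg <- single_copy_groups(ogt, roster)
  n_force_groups <- .round_half_up(0.10 * length(scg))
  forced_groups <- sort(sample(scg, n_force_groups))
  forced_genes <- unlist(lapply(forced_groups, function(g) {
    unlist(ogt$groups[[g]][roster], use.names = FALSE)
  }), use.names = FALSE)
  n_forced <- length(forced_genes)
  if (n_forced >= spec$budget)
    .stopf("budget %d too small: %d contigs are force-included", spec$budget, n_forced)

  partnered <- roster %in% unlist(spec$partner_pairs, use.names = FALSE)
  names(partnered) <- roster

  rows <- list(data.frame(
    contig_id = forced_genes, organism = gene_org[forced_genes],
    gene_id = forced_genes, orthogroup = gene_og[forced_genes],
    category = "single_copy_forced", weight = NA_real_,
    stringsAsFactors = FALSE))

  for (o in roster) {
    quota <- .round_half_up(as.numeric(p[o]) * (spec$budget - n_forced))
    if (quota == 0) next
    own <- names(gene_org)[gene_org == o]
    own <- setdiff(own, forced_genes)
    og_sizes <- setNames(vapply(og_members, length, integer(1)), names(og_members))
    multi <- unname(og_sizes[gene_og[own]] > 1L)
    pool_shared <- sort(own[multi])
    pool_excl <- sort(own[!multi])
    split <- .lr_split(quota, c(0.75, 0.25))
    if (partnered[o]) {
      n_shared <- split[1]; n_excl <- split[2]
    } else {
      n_excl <- split[1]; n_shared <- split[2]
    }
    if (n_shared > length(pool_shared))
      .stopf("organism %s: shared-orthogroup pool exhausted (need %d, have %d)",
             o, n_shared, length(pool_shared))
    if (n_excl > length(pool_excl))
      .stopf("organism %s: exclusive-orthogroup pool exhausted (need %d, have %d)",
             o, n_excl, length(pool_excl))
    take_shared <- sort(sample(pool_shared, n_shared))
    take_excl <- sort(sample(pool_excl, n_excl))
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = c(take_shared, take_excl),
      organism = o,
      gene_id = c(take_shared, take_excl),
      orthogroup = gene_og[c(take_shared, take_excl)],
      category = rep(c("shared_og", "exclusive_og"), c(n_shared, n_excl)),
      weight = NA_real_, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  cnt <- table(manifest$organism)
  manifest$weight <- as.numeric(p[manifest$organism]) /
    as.numeric(cnt[manifest$organism])

  seq_by_id <- unlist(lapply(panel$transcripts[roster], function(tr)
    setNames(tr$seq, tr$id)), use.names = TRUE)
  names(seq_by_id) <- sub("^[^.]*\\.", "", names(seq_by_id))
  recs <- seq_records(manifest$contig_id, seq_by_id[manifest$contig_id])
  structure(list(records = recs, manifest = manifest), class = "designer_set")
}

#' @export
print.designer_set <- function(x, ...) {
  cat(sprintf("designer_set: %d contigs from %d organisms\n",
              nrow(x$manifest), length(unique(x$manifest$organism))))
  print(table(x$manifest$category))
  invisible(x)
}

#' Diversity report for a community specification
#'
#' Sketches each member's transcriptome, then reports the Shannon index,
#' richness and abundance-weighted composite score of the community.
#'
#' @param spec a [make_template()] spec.
#' @param panel a `reference_panel`.
#' @param k,sketch_size MinHash parameters (see [kmer_sketch()]).
#' @return list(shannon, richness, composite).
#' @export
designer_diversity <- function(spec, panel, k = 31L, sketch_size = 1000L) {
  stopifnot(inherits(spec, "community_spec"))
  sk <- lapply(spec$members, function(o)
    kmer_sketch(panel$transcripts[[o]], k = k, sketch_size = sketch_size, id = o))
  names(sk) <- spec$members
  m <- similarity_matrix(sk, kind = "jaccard")
  list(shannon = shannon_index(spec$proportions),
       richness = richness(spec$proportions),
       composite = composite_score(m, spec$proportions))
}
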