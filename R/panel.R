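#' Mutate a nucleotide sequence at controlled rates
#'
#' Each position is substituted independently with probability `sub_rate`,
#' uniformly to one of the three alternative bases. Insertions and deletions
#' each occur at rate `indel_rate / 2` per position (a deletion removes the
#' base; an insertion adds one random base after it). Used to create
#' controlled divergence between orthologs and strain pairs.
#'
#' @param seq a single nucleotide sequence (non-empty).
#' @param sub_rate substitution rate in \[0, 1\].
#' @param indel_rate indel rate in \[0, 1); default 0.
#' @param seed optional integer seed for deterministic output.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = NULL) {
  if (!nzchar(seq)) .stopf("mutate_sequence: empty sequence")
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate >= 1)
    .stopf("mutate_sequence: rates out of range")
  with_seed(seed, .mutate_one(seq, sub_rate, indel_rate))
}

.BASES <- c("A", "C", "G", "T")

.mutate_one <- function(seq, sub_rate, indel_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit) > 0) {
      # uniform over the 3 alternatives: offset current base by 1..3 in ACGT
      cur <- match(ch[hit], .BASES)
      off <- sample.int(3L, length(hit), replace = TRUE)
      repl <- .BASES[((cur - 1L + off) %% 4L) + 1L]
      repl[is.na(cur)] <- .BASES[sample.int(4L, sum(is.na(cur)), replace = TRUE)]
      ch[hit] <- repl
    }
  }
  if (indel_rate > 0) {
    u <- runif(n)
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    if (any(ins)) {
      add <- .BASES[sample.int(4L, sum(ins), replace = TRUE)]
      ch[ins] <- paste0(ch[ins], add)
    }
    ch <- ch[!del]
  }
  paste(ch, collapse = "")
}

#' Configuration for a synthetic reference panel
#'
#' Describes an MMETSP-like panel of organism transcriptomes with controlled
#' gene-family sharing, divergence and strain structure. Gene families follow
#' a star topology: one ancestral sequence per family, each member mutated
#' independently from it, so pairwise identity is controllable. Strain-pair
#' second members are derived from their partner's genes at
#' `strain_pair_sub_rate` and share `strain_shared_fraction` of its families.
#'
#' @param n_organisms number of organisms (>= 1).
#' @param genes_per_organism transcripts per organism.
#' @param gene_length length-2 vector, uniform gene length bounds in bp.
#' @param fraction_shared_families fraction of each organism's non-single-copy
#'   genes placed in families shared with other organisms.
#' @param within_family_sub_rate per-member substitution rate from the family
#'   ancestor (pairwise member divergence is about twice this).
#' @param strain_pair_sub_rate substitution rate between designated strain
#'   partners.
#' @param fraction_single_copy fraction of genes in single-copy families
#'   (exactly one gene in every organism).
#' @param n_strain_pairs number of designated strain pairs (organisms 1&2,
#'   3&4, ...).
#' @param strain_shared_fraction fraction of the first strain's families also
#'   carried by its partner.
#' @param seed integer seed; the panel is byte-identical for a fixed config.
#' @return a `panel_config` list.
#' @export
panel_config <- function(n_organisms = 6, genes_per_organism = 120,
                         gene_length = c(300, 3000),
                         fraction_shared_families = 0.3,
                         within_family_sub_rate = 0.05,
                         strain_pair_sub_rate = 0.02,
                         fraction_single_copy = 0.1,
                         n_strain_pairs = 1,
                         strain_shared_fraction = 0.8,
                         seed = 1) {
  stopifnot(n_organisms >= 1, genes_per_organism >= 1,
            length(gene_length) == 2, gene_length[1] >= 30,
            gene_length[2] >= gene_length[1])
  rates <- c(fraction_shared_families, within_family_sub_rate,
             strain_pair_sub_rate, fraction_single_copy, strain_shared_fraction)
  if (any(rates < 0 | rates > 1)) .stopf("panel_config: rates must be in [0, 1]")
  if (2 * n_strain_pairs > n_organisms)
    .stopf("panel_config: %d strain pairs need %d organisms, have %d",
           n_strain_pairs, 2 * n_strain_pairs, n_organisms)
  structure(list(n_organisms = as.integer(n_organisms),
                 genes_per_organism = as.integer(genes_per_organism),
                 gene_length = as.integer(gene_length),
                 fraction_shared_families = fraction_shared_families,
                 within_family_sub_rate = within_family_sub_rate,
                 strain_pair_sub_rate = strain_pair_sub_rate,
                 fraction_single_copy = fraction_single_copy,
                 n_strain_pairs = as.integer(n_strain_pairs),
                 strain_shared_fraction = strain_shared_fraction,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# Random ORF-bearing coding sequence: ATG + non-stop codons + stop, so that
# frame 0 carries a clean open reading frame for downstream ORF tests.
.STOPS <- c("TAA", "TAG", "TGA")
.CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .STOPS)
})

.random_cds <- function(len) {
  nc <- max(4L, as.integer(len %/% 3L))
  paste0("ATG",
         paste(sample(.CODONS, nc - 2L, replace = TRUE), collapse = ""),
         sample(.STOPS, 1L))
}

#' Generate a synthetic reference panel
#'
#' Realizes the gene families described by a [panel_config()]: single-copy
#' families span every organism; shared families span random organism
#' subsets; exclusive families belong to one organism. Strain-pair partners
#' are derived from each other at the strain substitution rate. Output is
#' deterministic for a fixed config (including seed).
#'
#' @param config a [panel_config()].
#' @return A `reference_panel`: list with `organisms` (data frame: org_id,
#'   genus, species, strain), `transcripts` (named list of [seq_records] per
#'   organism), `orthogroups` (named list: orthogroup -> organism -> gene
#'   ids), `strain_pairs` (list of length-2 character vectors),
#'   `function_labels` (named character: orthogroup -> KO-like token).
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, .generate_panel_impl(config))
}

.generate_panel_impl <- function(cf) {
  n <- cf$n_organisms
  G <- cf$genes_per_organism
  orgs <- sprintf("org%02d", seq_len(n))
  strain_pairs <- list()
  genus <- sprintf("Genus%s", LETTERS[((seq_len(n) - 1L) %% 26L) + 1L])
  species <- sprintf("species%02d", seq_len(n))
  strain <- sprintf("st%02d", seq_len(n))
  if (cf$n_strain_pairs > 0) {
    for (p in seq_len(cf$n_strain_pairs)) {
      a <- 2L * p - 1L; b <- 2L * p
      genus[b] <- genus[a]; species[b] <- species[a]
      strain[a] <- "stA"; strain[b] <- "stB"
      strain_pairs[[p]] <- c(orgs[a], orgs[b])
    }
  }
  derived <- rep(NA_integer_, n)   # derived[b] = a when b is the second strain
  for (p in strain_pairs) derived[match(p[2], orgs)] <- match(p[1], orgs)
  indep <- which(is.na(derived))

  S <- max(1L, round(cf$fraction_single_copy * G))
  if (S > G) .stopf("generate_panel: single-copy families exceed genes_per_organism")
  rest <- G - S
  n_shared <- round(cf$fraction_shared_families * rest)
  n_excl <- rest - n_shared

  # flat preallocated gene store
  tot <- n * G
  g_org <- integer(tot); g_seq <- character(tot); g_og <- character(tot)
  g_num <- integer(tot)                 # per-organism running gene number
  cnt <- integer(n)                     # genes so far per organism
  ptr <- 0L
  og_counter <- 0L
  new_og_id <- function() {
    og_counter <<- og_counter + 1L
    sprintf("OG%05d", og_counter)
  }
  rand_len <- function() sample(cf$gene_length[1]:cf$gene_length[2], 1L)
  add_gene <- function(i_org, seqv, og_id) {
    ptr <<- ptr + 1L
    cnt[i_org] <<- cnt[i_org] + 1L
    g_org[ptr] <<- i_org
    g_seq[ptr] <<- seqv
    g_og[ptr] <<- og_id
    g_num[ptr] <<- cnt[i_org]
  }

  # 1. single-copy families: one gene in every organism.
  for (f in seq_len(S)) {
    anc <- .random_cds(rand_len())
    ogid <- new_og_id()
    seqs <- rep(NA_character_, n)
    for (i in indep) seqs[i] <- .mutate_one(anc, cf$within_family_sub_rate, 0)
    for (i in seq_len(n)) {
      if (is.na(derived[i])) next
      seqs[i] <- .mutate_one(seqs[derived[i]], cf$strain_pair_sub_rate, 0)
    }
    for (i in seq_len(n)) add_gene(i, seqs[i], ogid)
  }

  # 2. shared families among independent organisms (round-robin quota fill).
  quota <- integer(n)
  quota[indep] <- n_shared
  while (sum(quota > 0) >= 2) {
    avail <- which(quota > 0)
    m <- sample(2:min(length(avail), 4L), 1L)
    pick <- avail[order(-quota[avail], avail)][seq_len(m)]
    anc <- .random_cds(rand_len())
    ogid <- new_og_id()
    for (i in pick) {
      add_gene(i, .mutate_one(anc, cf$within_family_sub_rate, 0), ogid)
      quota[i] <- quota[i] - 1L
    }
  }
  # a lone remainder becomes exclusive genes below
  extra_excl <- quota

  # 3. exclusive families (one gene each).
  for (i in indep) {
    for (f in seq_len(n_excl + extra_excl[i])) {
      add_gene(i, .random_cds(rand_len()), new_og_id())
    }
  }

  # 4. derived strain members: carry strain_shared_fraction of the partner's
  #    non-single-copy families (mutated at the strain rate), fill the rest
  #    with exclusive families.
  for (i in seq_len(n)) {
    a <- derived[i]
    if (is.na(a)) next
    src_idx <- which(g_org[seq_len(ptr)] == a)
    nonsc <- src_idx[g_num[src_idx] > S]   # skip the single-copy genes
    n_share <- round(cf$strain_shared_fraction * length(nonsc))
    take <- sort(sample(nonsc, n_share))
    for (j in take) {
      add_gene(i, .mutate_one(g_seq[j], cf$strain_pair_sub_rate, 0), g_og[j])
    }
    while (cnt[i] < G) add_gene(i, .random_cds(rand_len()), new_og_id())
  }

  g_id <- sprintf("%s_g%04d", orgs[g_org], g_num)
  transcripts <- lapply(seq_len(n), function(i) {
    idx <- which(g_org == i)
    idx <- idx[order(g_num[idx])]
    seq_records(g_id[idx], g_seq[idx])
  })
  names(transcripts) <- orgs
  # orthogroup id -> organism -> gene ids (creation order via zero-padded ids)
  by_og <- split(seq_len(tot), g_og)
  og <- lapply(by_og, function(idx) {
    o <- split(g_id[idx], orgs[g_org[idx]])
    o[unique(orgs[g_org[idx]])]
  })
  labels <- setNames(sprintf("K%05d", seq_along(og)), names(og))
  structure(list(
    organisms = data.frame(org_id = orgs, genus = genus, species = species,
                           strain = strain, stringsAsFactors = FALSE),
    transcripts = transcripts,
    orthogroups = og,
    strain_pairs = strain_pairs,
    function_labels = labels,
    config = cf
  ), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d organisms, %d genes, %d orthogroups, %d strain pair(s)\n",
              nrow(x$organisms),
              sum(vapply(x$transcripts, nrow, integer(1))),
              length(x$orthogroups), length(x$strain_pairs)))
  invisible(x)
}

#' Write a panel's FASTAs and ground-truth tables
#'
#' Emits one FASTA per organism, an orthogroup table in the
#' `Orthogroups.tsv` dialect (re-loadable with [load_orthogroups()]), a
#' taxonomy TSV and a function-label TSV.
#'
#' @param panel a `reference_panel`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
emit_truth_tables <- function(panel, out_dir) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .stopf("cannot create directory: %s", out_dir)
  }
  paths <- character(0)
  for (o in names(panel$transcripts)) {
    p <- file.path(out_dir, paste0(o, ".fasta"))
    write_seqs(panel$transcripts[[o]], p, "fasta")
    paths[o] <- p
  }
  ogt <- orthogroup_table(panel$orthogroups, roster = panel$organisms$org_id)
  paths["orthogroups"] <- file.path(out_dir, "orthogroups.tsv")
  write_orthogroups(ogt, paths["orthogroups"])
  paths["taxonomy"] <- file.path(out_dir, "taxonomy.tsv")
  write.table(panel$organisms, paths["taxonomy"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths["function_labels"] <- file.path(out_dir, "function_labels.tsv")
  write.table(data.frame(orthogroup = names(panel$function_labels),
                         label = unname(panel$function_labels)),
              paths["function_labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
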