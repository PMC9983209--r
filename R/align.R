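#' Clustering / alignment parameters
#'
#' @param min_identity minimum alignment identity in (0, 1]. Identity is
#'   matches / alignment columns, gap columns included (mmseqs2-like).
#' @param min_coverage minimum aligned-span coverage in (0, 1].
#' @param coverage_mode which sequence the coverage threshold applies to:
#'   `"shorter_sequence"` or `"target_sequence"` (the cluster representative
#'   / designer protein, as in mmseqs2 cov-mode 1).
#' @param strand_aware for nucleotides, align both orientations and keep the
#'   better one.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return a `clustering_params` list.
#' @export
clustering_params <- function(min_identity = 0.98, min_coverage = 0.8,
                              coverage_mode = c("shorter_sequence", "target_sequence"),
                              strand_aware = TRUE,
                              alphabet = c("nucleotide", "protein")) {
  coverage_mode <- match.arg(coverage_mode)
  alphabet <- match.arg(alphabet)
  if (min_identity <= 0 || min_identity > 1 || min_coverage <= 0 || min_coverage > 1)
    .stopf("clustering thresholds must be in (0, 1]")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 coverage_mode = coverage_mode, strand_aware = strand_aware,
                 alphabet = alphabet),
            class = "clustering_params")
}

.nuc_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c("A", "C", "G", "T", "N")
      mm <- matrix(-3, 5, 5, dimnames = list(letters, letters))
      diag(mm) <- 2
      mm["N", ] <- -1; mm[, "N"] <- -1
      m <<- mm
    }
    m
  }
})

.aa_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
      mm <- matrix(-2, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 2
      mm["X", ] <- -1; mm[, "X"] <- -1
      m <<- mm
    }
    m
  }
})

.align_once <- function(a, b, submat) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = submat,
                                gapOpening = 5, gapExtension = 2)
}

#' Local alignment identity and coverage
#'
#' Smith-Waterman local alignment (via Biostrings) returning identity =
#' matches / alignment columns (gap columns count) and the aligned-span
#' coverage of each input. For nucleotides with `strand_aware`, the better
#' of the forward and reverse-complement orientations is used.
#'
#' @param a,b sequences (character scalars).
#' @param params a [clustering_params()]; only `alphabet` and `strand_aware`
#'   are used here.
#' @return list with `identity`, `coverage_a`, `coverage_b`, `strand`
#'   (`"+"` or `"-"`).
#' @export
local_align_identity <- function(a, b, params = clustering_params()) {
  if (!nzchar(a) || !nzchar(b)) .stopf("local_align_identity: empty sequence")
  if (params$alphabet == "nucleotide") {
    .check_nucleotide(c(a, b), "local_align_identity input")
    submat <- .nuc_submat()
  } else {
    submat <- .aa_submat()
  }
  aln <- .align_once(a, b, submat)
  strand <- "+"
  if (params$alphabet == "nucleotide" && params$strand_aware) {
    aln_rc <- .align_once(a, reverse_complement(b), submat)
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc
      strand <- "-"
    }
  }
  cols <- Biostrings::nchar(aln)   # alignment length incl. gap columns
  if (cols == 0)
    return(list(identity = 0, coverage_a = 0, coverage_b = 0, strand = "+"))
  ident <- Biostrings::nmatch(aln) / cols
  span_a <- Biostrings::width(Biostrings::pattern(aln))
  span_b <- Biostrings::width(Biostrings::subject(aln))
  list(identity = ident,
       coverage_a = span_a / nchar(a),
       coverage_b = span_b / nchar(b),
       strand = strand)
}
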