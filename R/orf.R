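#' Six-frame ORF finding
#'
#' Scans all six reading frames with the standard genetic code. Within each
#' stop-free stretch, the ORF runs from the first start codon (or the
#' stretch's beginning when `require_start = FALSE`) to the stop codon or
#' the open end of the frame. Returned coordinates are 0-based half-open on
#' the forward strand and span the protein's codons (stop codon excluded).
#'
#' @param contig a nucleotide sequence (character scalar).
#' @param min_aa minimum protein length in amino acids (default 100).
#' @param require_start require a leading methionine (default TRUE).
#' @return data frame with columns frame (0-2), strand (+/-), start, end,
#'   protein; zero rows when no ORF qualifies.
#' @export
find_orfs <- function(contig, min_aa = 100L, require_start = TRUE) {
  .check_nucleotide(contig, "find_orfs input")
  n <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else reverse_complement(contig)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 1) next
      sub <- substr(s, frame + 1, frame + 3 * ncod)
      prot <- .translate_nt(sub)
      for (orf in .orf_spans(prot, min_aa, require_start)) {
        # codon span [orf[1], orf[2]] (1-based aa) on strand s
        nt_from <- frame + (orf[1] - 1L) * 3L        # 0-based on s
        nt_to <- frame + orf[2] * 3L                 # 0-based half-open on s
        if (strand == "+") {
          start <- nt_from; end <- nt_to
        } else {
          start <- n - nt_to; end <- n - nt_from
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = frame, strand = strand, start = start, end = end,
          protein = substr(prot, orf[1], orf[2]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# vectorized standard-code translation; codons with N (or any non-ACGT) -> X
.translate_nt <- local({
  code <- NULL
  function(nt) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    n <- nchar(nt)
    starts <- seq.int(1L, n, by = 3L)
    aa <- code[substring(nt, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

# aa spans [from, to] of qualifying ORFs within a translated frame
.orf_spans <- function(prot, min_aa, require_start) {
  segs <- list()
  stops <- c(0L, which(strsplit(prot, "", fixed = TRUE)[[1]] == "*"),
             nchar(prot) + 1L)
  stops <- unique(stops)
  res <- list()
  for (i in seq_len(length(stops) - 1L)) {
    from <- stops[i] + 1L
    to <- stops[i + 1L] - 1L
    if (to < from) next
    if (require_start) {
      seg <- substr(prot, from, to)
      m <- regexpr("M", seg, fixed = TRUE)
      if (m < 0) next
      from <- from + as.integer(m) - 1L
    }
    if (to - from + 1L >= min_aa) res[[length(res) + 1L]] <- c(from, to)
  }
  res
}
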