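#' Construct a set of sequence records
#'
#' The elementary container used throughout the package: an ordered set of
#' named sequences, optionally with per-base Phred quality scores (as read
#' from FASTQ). Stored as a data frame with columns `id`, `desc`, `seq` and a
#' list column `qual` (integer Phred vectors, or `NULL` entries when absent).
#'
#' @param id character vector of unique identifiers (no whitespace).
#' @param seq character vector of sequences (uppercase).
#' @param desc character vector of free-text descriptions (default empty).
#' @param qual optional list of integer Phred vectors (0-60), one per record,
#'   each the same length as its sequence; or `NULL` for none.
#' @return An object of class `seq_records` (a data frame).
#' @export
seq_records <- function(id, seq, desc = "", qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) .stopf("id and seq lengths differ")
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id)))
    .stopf("sequence ids must be non-empty and contain no whitespace")
  if (anyDuplicated(id))
    .stopf("duplicate sequence id: %s", id[duplicated(id)][1])
  desc <- rep_len(as.character(desc), length(id))
  df <- data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != length(id)) .stopf("qual must have one entry per record")
    for (i in seq_along(qual)) {
      q <- qual[[i]]
      if (is.null(q)) next
      if (length(q) != nchar(seq[i]))
        .stopf("record '%s': quality length %d != sequence length %d",
               id[i], length(q), nchar(seq[i]))
      if (any(q < 0 | q > 60)) .stopf("record '%s': Phred scores must be in [0, 60]", id[i])
    }
    df$qual <- I(qual)
  } else {
    df$qual <- I(vector("list", length(id)))
  }
  class(df) <- c("seq_records", "data.frame")
  df
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d record(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    len <- nchar(x$seq)
    cat(sprintf("  lengths: min %d, median %d, max %d\n",
                min(len), as.integer(stats::median(len)), max(len)))
    hq <- sum(!vapply(x$qual, is.null, logical(1)))
    cat(sprintf("  with qualities: %d\n", hq))
  }
  invisible(x)
}

n_records <- function(x) nrow(x)

#' Subset sequence records by position or logical mask
#'
#' @param x a [seq_records] object.
#' @param i row index.
#' @return a [seq_records] object.
#' @export
records_subset <- function(x, i) {
  y <- x[i, , drop = FALSE]
  rownames(y) <- NULL
  class(y) <- c("seq_records", "data.frame")
  y
}

#' Concatenate sequence record sets
#'
#' @param ... [seq_records] objects; ids must stay unique.
#' @return a [seq_records] object.
#' @export
records_bind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) return(seq_records(character(0), character(0)))
  seq_records(
    id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
    seq = unlist(lapply(parts, `[[`, "seq"), use.names = FALSE),
    desc = unlist(lapply(parts, `[[`, "desc"), use.names = FALSE),
    qual = do.call(c, lapply(parts, `[[`, "qual"))
  )
}

.check_nucleotide <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seq)
  if (any(bad))
    .stopf("%s contains non-nucleotide characters: %s", what,
           substr(gsub("[ACGTN]", "", seq[bad][1]), 1, 10))
  invisible(TRUE)
}
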