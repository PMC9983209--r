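#' Read sequences from FASTA or FASTQ
#'
#' FASTA is parsed with Biostrings (line wrapping collapsed); the text up to
#' the first whitespace in a header is the record id, the remainder its
#' description. FASTQ is parsed as strict 4-line records with Phred+33
#' qualities. Sequences are uppercased on read. Files compressed with gzip
#' are handled transparently.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; default guesses from the extension.
#' @return A [seq_records] object in file order.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (format == "fasta") {
    first <- readLines(path, n = 1L)
    if (length(first) > 0 && !startsWith(first, ">"))
      .stopf("%s: line 1: expected FASTA header starting with '>'", path)
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(ss) == 0) return(seq_records(character(0), character(0)))
    nm <- names(ss)
    id <- sub("\\s.*$", "", nm)
    desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
    return(seq_records(id = id, seq = toupper(as.character(ss)), desc = desc))
  }
  .read_fastq(path)
}

.read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) return(seq_records(character(0), character(0)))
  if (n %% 4 != 0)
    .stopf("%s: line %d: truncated FASTQ record (file has %d lines, not a multiple of 4)",
           path, n, n)
  hi <- seq(1L, n, by = 4L)
  heads <- lines[hi]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad) > 0)
    .stopf("%s: line %d: expected FASTQ header starting with '@'", path, hi[bad[1]])
  plus <- lines[hi + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0)
    .stopf("%s: line %d: expected '+' separator line", path, hi[bad[1]] + 2L)
  seqs <- toupper(lines[hi + 1L])
  quals <- lines[hi + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0)
    .stopf("%s: line %d: quality length differs from sequence length",
           path, hi[bad[1]] + 3L)
  nm <- substring(heads, 2L)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  qual <- lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
  seq_records(id = id, seq = seqs, desc = desc, qual = qual)
}

#' Write sequences to FASTA or FASTQ
#'
#' Output is deterministic byte-for-byte for fixed inputs. FASTQ records are
#' always 4 lines with Phred+33 qualities; writing a record without
#' qualities as FASTQ is an error.
#'
#' @param records a [seq_records] object.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @param wrap FASTA line width (default 80); `NULL` or `Inf` for no wrapping.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(records, path, format = c("fasta", "fastq"), wrap = 80) {
  format <- match.arg(format)
  hdr <- ifelse(nzchar(records$desc), paste(records$id, records$desc), records$id)
  if (format == "fasta") {
    if (is.null(wrap) || !is.finite(wrap)) {
      body <- records$seq
      out <- rbind(paste0(">", hdr), body)
      writeLines(as.vector(out), path)
    } else {
      if (wrap < 1) .stopf("wrap must be >= 1")
      con <- file(path, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(records))) {
        writeLines(paste0(">", hdr[i]), con)
        s <- records$seq[i]
        n <- nchar(s)
        starts <- seq(1L, max(n, 1L), by = as.integer(wrap))
        writeLines(substring(s, starts, pmin(starts + wrap - 1L, n)), con)
      }
    }
  } else {
    noq <- vapply(records$qual, is.null, logical(1))
    if (any(noq))
      .stopf("record '%s' has no qualities; cannot write FASTQ", records$id[noq][1])
    qstr <- vapply(records$qual, function(q) rawToChar(as.raw(q + 33L)), character(1))
    out <- rbind(paste0("@", hdr), records$seq, "+", qstr)
    writeLines(as.vector(out), path)
  }
  invisible(path)
}

#' Per-sequence GC fraction
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from the
#' denominator. Errors on empty or all-N sequences.
#'
#' @param seq character vector of nucleotide sequences.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  .check_nucleotide(seq, "gc_fraction input")
  vapply(seq, function(s) {
    if (!nzchar(s)) .stopf("gc_fraction: empty sequence")
    b <- charToRaw(s)
    gc <- sum(b == charToRaw("G") | b == charToRaw("C"))
    at <- sum(b == charToRaw("A") | b == charToRaw("T"))
    if (gc + at == 0) .stopf("gc_fraction: sequence has no A/C/G/T bases")
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' Standard complement, reversed; N maps to N. Errors on non-nucleotide
#' characters.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector.
#' @export
reverse_complement <- function(seq) {
  .check_nucleotide(seq, "reverse_complement input")
  vapply(chartr("ACGTN", "TGCAN", seq), function(s) {
    rawToChar(rev(charToRaw(s)))
  }, character(1), USE.NAMES = FALSE)
}
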