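# Plain-text sequence and table IO.
#
# The FASTQ layer is deliberately strict: every record is validated and
# malformations are reported with the 1-based record index, and a
# read -> write -> read round trip is the identity on (id, seq, qual),
# including duplicate identifiers (which the deduplication stage relies on).

#' Read a 4-line FASTQ file
#'
#' @param path path to an uncompressed 4-line FASTQ file.
#' @return data.frame with columns `id` (header up to first whitespace,
#'   without the leading `@`), `seq` (uppercased) and `qual` (Phred+33
#'   string), one row per record, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): truncated record at end of file ",
         "(line count ", length(lines), " not a multiple of 4)")
  n <- length(lines) %/% 4L
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": separator line does not start with '+'")
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": quality length differs from sequence length")
  id <- sub("\\s.*$", "", substring(hd, 2L))
  bad <- which(!nzchar(id))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": empty identifier")
  data.frame(id = id, seq = toupper(sq), qual = ql, stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns (as returned by
#'   [read_fastq()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) if (nzchar(q)) utf8ToInt(q) - 33L else integer(0))
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; duplicate ids and empty sequences are errors.
#'
#' @param path FASTA path.
#' @return named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA id: ", ids[!nzchar(seqs)][1])
  stats::setNames(seqs, ids)
}

#' Write records as a tab-separated table with header
#'
#' Refuses to write if any requested column is missing or any value
#' contains a tab or newline (delimiter safety) -- the check runs before
#' anything is written.
#'
#' @param records data.frame.
#' @param path output path.
#' @param columns columns to write, in order (default: all).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, columns = names(records)) {
  missing_cols <- setdiff(columns, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- records[, columns, drop = FALSE]
  for (cl in columns) {
    v <- out[[cl]]
    if (is.character(v) || is.factor(v)) {
      if (any(grepl("[\t\n\r]", as.character(v))))
        stop("column '", cl, "' contains a tab or newline; refusing to write")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
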