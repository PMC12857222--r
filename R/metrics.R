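# Repertoire metrics: translation, productivity, length classes, sample
# summaries, simplified germline gene assignment and clonotype collapsing.

#' Translate an in-frame nucleotide region
#'
#' Standard genetic code; stop codons become `*`; any codon containing an
#' ambiguous base ('N') becomes `X`.  `X` is never treated as a stop, so
#' ambiguity cannot create or mask stop codons.
#'
#' @param nt nucleotide string with length divisible by 3.
#' @return amino-acid string.
#' @export
translate_region <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L)
    stop("region length (", n, ") is not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Is an amino-acid junction productive (stop-free)?
#'
#' @param aa amino-acid string (vectorised).
#' @return logical; `TRUE` iff no `*` present.
#' @export
is_productive <- function(aa) {
  !grepl("*", aa, fixed = TRUE)
}

#' CDR3 length-class thresholds
#'
#' Bovine convention: short <= 10 aa, ultralong >= 40 aa, medium between.
#' Lengths count both anchors (C104 through W118 inclusive).
#'
#' @param short_max largest short length (default 10).
#' @param ultralong_min smallest ultralong length (default 40).
#' @return list with the two fields.
#' @export
class_thresholds <- function(short_max = 10L, ultralong_min = 40L) {
  stopifnot(short_max < ultralong_min)
  list(short_max = as.integer(short_max),
       ultralong_min = as.integer(ultralong_min))
}

#' Classify CDR3 lengths into short / medium / ultralong
#'
#' @param length_aa integer vector of junction lengths (aa, anchors
#'   included).
#' @param thresholds a [class_thresholds()] list.
#' @return character vector over \{"short", "medium", "ultralong"\}.
#' @export
classify_length <- function(length_aa, thresholds = class_thresholds()) {
  stopifnot(all(length_aa >= 1, na.rm = TRUE))
  ifelse(length_aa <= thresholds$short_max, "short",
         ifelse(length_aa >= thresholds$ultralong_min, "ultralong", "medium"))
}

#' Summarise one sample's extraction records
#'
#' Computes counts and percentages under both denominators used in the
#' field: all sequences with an identified CDR3 (`*_total`) and the
#' stop-codon-free subset (`*_productive`).  Zero denominators yield `NA`
#' percentages (absence of data, not 0%).
#'
#' @param records extraction-record data.frame from [run_rslb()].
#' @param thresholds a [class_thresholds()] list.
#' @param sample_id,isotype labels carried into the summary.
#' @return object of class `repertoire_summary` (a list).
#' @export
summarize_sample <- function(records, thresholds = class_thresholds(),
                             sample_id = NA_character_,
                             isotype = NA_character_) {
  ex <- records[records$outcome == "extracted", , drop = FALSE]
  n_total <- nrow(ex)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  cls <- if (n_total) classify_length(ex$length_aa, thresholds) else character(0)
  prod <- if (n_total) is_productive(ex$junction_aa) else logical(0)
  n_productive <- sum(prod)
  n_ul_total <- sum(cls == "ultralong")
  n_ul_prod <- sum(cls == "ultralong" & prod)
  cls_p <- cls[prod]
  structure(
    list(
      sample_id = sample_id,
      isotype = isotype,
      n_cdr3_total = n_total,
      n_productive = n_productive,
      n_ultralong_total = n_ul_total,
      n_ultralong_productive = n_ul_prod,
      pct_ultralong_total = pct(n_ul_total, n_total),
      pct_ultralong_productive = pct(n_ul_prod, n_productive),
      pct_short = pct(sum(cls_p == "short"), n_productive),
      pct_medium = pct(sum(cls_p == "medium"), n_productive),
      pct_ultralong = pct(sum(cls_p == "ultralong"), n_productive)
    ),
    class = "repertoire_summary"
  )
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf("Repertoire summary [%s, %s]\n", x$sample_id, x$isotype))
  cat(sprintf("  CDR3s: %d total, %d productive\n",
              x$n_cdr3_total, x$n_productive))
  cat(sprintf("  ultralong: %.2f%% of total, %.2f%% of productive\n",
              x$pct_ultralong_total, x$pct_ultralong_productive))
  cat(sprintf("  productive classes: short %.2f%% / medium %.2f%% / ultralong %.2f%%\n",
              x$pct_short, x$pct_medium, x$pct_ultralong))
  invisible(x)
}

#' @export
as.data.frame.repertoire_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

# longest exact common substring length between two strings (DP, one row)
longest_common_substring <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (!length(av) || !length(bv)) return(0L)
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    eq <- av[i] == bv
    cur <- integer(length(bv))
    cur[eq] <- c(0L, prev[-length(prev)])[eq] + 1L
    b2 <- max(cur, 0L)
    if (b2 > best) best <- b2
    prev <- cur
  }
  as.integer(best)
}

# best sliding-window identity of the shorter string within the longer;
# returns NA when the overlap would be below min_overlap
best_window_identity <- function(a, b, min_overlap) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(b) < min_overlap) return(NA_real_)
  mm <- motif_mismatches(a, b)
  1 - min(mm) / nchar(b)
}

#' Simplified germline V/D/J assignment for one extracted read
#'
#' A deliberately simple stand-in for full repertoire annotation tools: V
#' is the germline with the highest best-window Hamming identity against
#' the region upstream of the junction, J likewise downstream, and D the
#' germline sharing the longest exact substring with the junction interior
#' (anchor codons removed).  Designed to be exact on the toy database at
#' zero sequencing error; use [import_gene_calls()] to substitute real
#' annotation output.
#'
#' @param junction_nt extracted junction (C104..W118 codons inclusive).
#' @param seq oriented read sequence the junction came from.
#' @param db a [germline_db()].
#' @param min_v_identity,min_j_identity identity thresholds below which the
#'   call is `NA` (unassigned).
#' @param min_overlap smallest overlap (nt) for a V/J identity to count.
#' @param min_d_match smallest exact D substring accepted (default 5 nt).
#' @return one-row data.frame: `v_name`, `d_name`, `j_name`, `v_identity`,
#'   `j_identity`, `d_match_len`.
#' @export
assign_genes <- function(junction_nt, seq, db,
                         min_v_identity = 0.7, min_j_identity = 0.7,
                         min_overlap = 30L, min_d_match = 5L) {
  jpos <- regexpr(junction_nt, seq, fixed = TRUE)
  if (jpos < 0)
    stop("junction not found in oriented sequence")
  jstart <- as.integer(jpos)
  jend <- jstart + nchar(junction_nt) - 1L
  # include the anchor codons in the flanks: the Cys codon's head overlaps
  # the V tail and the Trp codon opens the J, so trimming them would leave
  # no window that fits the full germline segment
  upstream <- substr(seq, 1L, min(jstart + 2L, nchar(seq)))
  downstream <- substr(seq, max(jend - 2L, 1L), nchar(seq))

  best_of <- function(region, genes, min_ident) {
    ids <- vapply(genes, best_window_identity, numeric(1),
                  a = region, min_overlap = min_overlap)
    if (all(is.na(ids)) || max(ids, na.rm = TRUE) < min_ident)
      return(list(name = NA_character_, identity = NA_real_))
    best <- max(ids, na.rm = TRUE)
    nm <- sort(names(ids)[!is.na(ids) & ids == best])[1]  # lexicographic tie
    list(name = nm, identity = best)
  }
  v <- best_of(upstream, db$v_genes, min_v_identity)
  j <- best_of(downstream, db$j_genes, min_j_identity)

  interior <- substr(junction_nt, 4L, nchar(junction_nt) - 3L)
  d_name <- NA_character_
  d_len <- 0L
  for (nm in sort(names(db$d_genes))) {
    l <- longest_common_substring(interior, db$d_genes[[nm]])
    if (l > d_len) { d_len <- l; d_name <- nm }  # strict > keeps lexicographic tie
  }
  if (d_len < min_d_match) { d_name <- NA_character_; d_len <- 0L }

  data.frame(v_name = v$name, d_name = d_name, j_name = j$name,
             v_identity = v$identity, j_identity = j$identity,
             d_match_len = d_len, stringsAsFactors = FALSE)
}

#' Import external gene-call tables
#'
#' Joins an external annotation TSV (e.g. from a full V(D)J annotation
#' service) onto extraction records by sequence id.  Allele suffixes in
#' the calls are preserved.
#'
#' @param records extraction-record data.frame.
#' @param path TSV with columns `sequence_id`, `v_call`, `d_call`,
#'   `j_call`.
#' @return `records` with `v_name`, `d_name`, `j_name` columns added.
#' @export
import_gene_calls <- function(records, path) {
  calls <- read_table_tsv(path)
  need <- c("sequence_id", "v_call", "d_call", "j_call")
  if (!all(need %in% names(calls)))
    stop("gene-call table must have columns: ", paste(need, collapse = ", "))
  idx <- match(records$read_id, calls$sequence_id)
  records$v_name <- calls$v_call[idx]
  records$d_name <- calls$d_call[idx]
  records$j_name <- calls$j_call[idx]
  records
}

#' Collapse annotated records into clonotypes
#'
#' A clonotype is a unique (V, D, J, junction amino-acid) combination whose
#' junction is in-frame (no stop), starts with cysteine and ends with
#' tryptophan or phenylalanine.  Records failing these requirements are
#' excluded; unassigned genes are keyed as "unassigned".
#'
#' @param records data.frame with `junction_aa`, `v_name`, `d_name`,
#'   `j_name` columns.
#' @return data.frame `v_name`, `d_name`, `j_name`, `junction_aa`,
#'   `abundance`, sorted by decreasing abundance then key.
#' @export
collapse_clonotypes <- function(records) {
  aa <- records$junction_aa
  ok <- !is.na(aa) & nzchar(aa) &
    is_productive(aa) &
    substr(aa, 1L, 1L) == "C" &
    substr(aa, nchar(aa), nchar(aa)) %in% c("W", "F")
  r <- records[ok, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(v_name = character(0), d_name = character(0),
                      j_name = character(0), junction_aa = character(0),
                      abundance = integer(0), stringsAsFactors = FALSE))
  }
  fill <- function(x) ifelse(is.na(x) | !nzchar(x), "unassigned", x)
  key <- data.frame(v_name = fill(r$v_name), d_name = fill(r$d_name),
                    j_name = fill(r$j_name), junction_aa = r$junction_aa,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(abundance = rep(1L, nrow(key))), key, sum)
  agg <- agg[order(-agg$abundance, agg$v_name, agg$d_name, agg$j_name,
                   agg$junction_aa), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Gene usage percentages from a clonotype table
#'
#' Reports, for every named gene, its percent among clonotypes (each key
#' counted once) and among reads (abundance-weighted).  "unassigned" keys
#' stay in the denominators but are not reported as genes, so percentages
#' sum to at most 100 within a segment.
#'
#' @param clonotypes table from [collapse_clonotypes()].
#' @return data.frame `segment`, `gene`, `pct_clonotypes`, `pct_reads`.
#' @export
gene_usage <- function(clonotypes) {
  n_clone <- nrow(clonotypes)
  n_reads <- sum(clonotypes$abundance)
  one_segment <- function(col, segment) {
    g <- clonotypes[[col]]
    keep <- g != "unassigned"
    if (!any(keep)) {
      return(data.frame(segment = character(0), gene = character(0),
                        pct_clonotypes = numeric(0), pct_reads = numeric(0)))
    }
    cl <- tapply(rep(1L, sum(keep)), g[keep], sum)
    rd <- tapply(clonotypes$abundance[keep], g[keep], sum)
    data.frame(segment = segment, gene = names(cl),
               pct_clonotypes = 100 * as.vector(cl) / n_clone,
               pct_reads = 100 * as.vector(rd) / n_reads,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_segment("v_name", "V"), one_segment("d_name", "D"),
               one_segment("j_name", "J"))
  rownames(out) <- NULL
  out
}
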