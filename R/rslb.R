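# Stepwise literature-based filtering and motif-anchored CDR3 extraction.
#
# Cascade order (first failing gate assigns the read's outcome):
#   length window -> quality gate -> primer orientation -> isotype motif
#   -> duplicate removal -> pre/post-motif junction extraction.
# Outcome counters always sum to the number of input reads.

RSLB_OUTCOMES <- c("fail_length", "fail_quality", "no_primer",
                   "no_isotype_motif", "duplicate", "no_cdr3",
                   "frame_error", "anchor_error", "extracted")

#' Length-window gate
#'
#' @param seq nucleotide sequence(s).
#' @param window a [length_window()] (bounds inclusive).
#' @return logical vector: inside the window?
#' @export
filter_length <- function(seq, window) {
  n <- nchar(seq)
  n >= window$min_len & n <= window$max_len
}

#' Quality gate
#'
#' A read fails when the fraction of bases with Phred score below
#' `qualified_phred` exceeds (strictly) `max_unqualified_fraction`.
#'
#' @param qual Phred+33 quality string(s).
#' @param gate a [quality_gate()].
#' @return logical vector: pass?
#' @export
filter_quality <- function(qual, gate = quality_gate()) {
  vapply(phred_scores(qual), function(q) {
    if (!length(q)) return(TRUE)
    mean(q < gate$qualified_phred) <= gate$max_unqualified_fraction
  }, logical(1))
}

#' Orient a read by primer search
#'
#' Four pieces of evidence are checked in priority order: the forward
#' primer on the given strand (keep as-is), the isotype's reverse primer
#' on the given strand (reverse-complement the read, reversing its
#' qualities), the reverse-complement of the reverse primer (the
#' amplicon's 3' primer site; keep as-is), and the reverse-complement of
#' the forward primer (flip).  The forward-primer branch has priority when
#' several match.  Checking both primer sites makes the decision symmetric
#' under global reverse-complementation: a genuine amplicon whose forward
#' primer was destroyed by sequencing noise is still orientable by its 3'
#' reverse-primer site, on either strand.
#'
#' @param seq,qual read sequence and Phred+33 quality string.
#' @param primers a [primer_set()].
#' @param isotype which reverse primer to use.
#' @return list with `seq`, `qual`, `orientation` ("as-is"/"flipped") and
#'   `outcome` ("ok" or "no_primer"; sequence unchanged on failure).
#' @export
orient_read <- function(seq, qual, primers = primer_set(), isotype = "IgM") {
  rp <- primers$reverse_by_isotype[[isotype]]
  if (is.null(rp)) stop("no reverse primer configured for isotype ", isotype)
  mm <- primers$max_mismatch
  hit <- function(motif) !is.null(find_motif(seq, motif, mm))
  flip <- function() {
    list(seq = revcomp(seq),
         qual = paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]),
                      collapse = ""),
         orientation = "flipped", outcome = "ok")
  }
  if (hit(primers$forward))
    return(list(seq = seq, qual = qual, orientation = "as-is",
                outcome = "ok"))
  if (hit(rp)) return(flip())
  if (hit(revcomp(rp)))
    return(list(seq = seq, qual = qual, orientation = "as-is",
                outcome = "ok"))
  if (hit(revcomp(primers$forward))) return(flip())
  list(seq = seq, qual = qual, orientation = "as-is", outcome = "no_primer")
}

#' Isotype-determining motif screen
#'
#' @param seq oriented nucleotide sequence.
#' @param motifs a [motif_library()].
#' @param isotype isotype whose motifs to screen for.
#' @return `TRUE` iff any configured motif for the isotype matches within
#'   the library's mismatch budget (Hamming semantics as [find_motif()]).
#' @export
has_isotype_motif <- function(seq, motifs = motif_library(), isotype = "IgM") {
  ms <- motifs$isotype_motifs[[isotype]]
  if (is.null(ms) || !length(ms)) return(FALSE)
  for (m in ms) {
    if (!is.null(find_motif(seq, m, motifs$isotype_max_mismatch))) return(TRUE)
  }
  FALSE
}

#' Flag duplicate read identifiers
#'
#' First occurrence kept; later occurrences flagged.  Idempotent on the
#' kept subset.
#'
#' @param ids character vector of read identifiers in processing order.
#' @return logical vector: is this occurrence a duplicate of an earlier one?
#' @export
dedupe_flags <- function(ids) {
  duplicated(ids)
}

#' Extract the CDR3 junction between pre- and post-CDR3 motifs
#'
#' All pre- and post-motif hits within their per-motif mismatch budgets
#' are enumerated; among pairs with the post motif strictly downstream of
#' the pre motif, the pair minimising total mismatches wins (ties: leftmost
#' pre motif, then shortest span).  The junction is stitched as the last
#' `c104_carry` nt of the pre-motif match, the nucleotides strictly between
#' the matches, and the first `w118_lead` nt of the post-motif match; it
#' must be a whole number of codons (`frame_error` otherwise) translating
#' to C...W (`anchor_error` otherwise).
#'
#' @param seq oriented nucleotide sequence.
#' @param motifs a [motif_library()].
#' @return list: `outcome` ("extracted", "no_cdr3", "frame_error",
#'   "anchor_error"), and when extracted `junction_nt`, `junction_aa`,
#'   `length_aa` (C104..W118 inclusive), `pre_motif_used`,
#'   `post_motif_used`.
#' @export
extract_cdr3 <- function(seq, motifs = motif_library()) {
  fail <- function(outcome) list(outcome = outcome,
                                 junction_nt = NA_character_,
                                 junction_aa = NA_character_,
                                 length_aa = NA_integer_,
                                 pre_motif_used = NA_character_,
                                 post_motif_used = NA_character_)
  pre_hits <- do.call(rbind, lapply(seq_len(nrow(motifs$pre_cdr3)), function(i) {
    h <- find_motif_all(seq, motifs$pre_cdr3$motif[i],
                        motifs$pre_cdr3$allowed_mismatch[i])
    if (!nrow(h)) return(NULL)
    h$motif_i <- i
    h
  }))
  if (is.null(pre_hits) || !nrow(pre_hits)) return(fail("no_cdr3"))
  post_hits <- do.call(rbind, lapply(seq_len(nrow(motifs$post_cdr3)), function(i) {
    h <- find_motif_all(seq, motifs$post_cdr3$motif[i],
                        motifs$post_cdr3$allowed_mismatch[i])
    if (!nrow(h)) return(NULL)
    h$motif_i <- i
    h
  }))
  if (is.null(post_hits) || !nrow(post_hits)) return(fail("no_cdr3"))

  pre_len <- nchar(motifs$pre_cdr3$motif)[pre_hits$motif_i]
  pre_end <- pre_hits$pos + pre_len - 1L
  best <- NULL
  for (a in seq_len(nrow(pre_hits))) {
    downstream <- which(post_hits$pos > pre_end[a])
    for (b in downstream) {
      cand <- c(total_mm = pre_hits$mismatches[a] + post_hits$mismatches[b],
                pre_pos = pre_hits$pos[a],
                span = post_hits$pos[b] - pre_end[a] - 1L,
                a = a, b = b)
      if (is.null(best) ||
          cand["total_mm"] < best["total_mm"] ||
          (cand["total_mm"] == best["total_mm"] &&
           (cand["pre_pos"] < best["pre_pos"] ||
            (cand["pre_pos"] == best["pre_pos"] &&
             cand["span"] < best["span"])))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(fail("no_cdr3"))

  a <- best[["a"]]; b <- best[["b"]]
  carry <- motifs$pre_cdr3$c104_carry[pre_hits$motif_i[a]]
  lead <- motifs$post_cdr3$w118_lead[post_hits$motif_i[b]]
  j_start <- pre_end[a] - carry + 1L
  j_end <- post_hits$pos[b] + lead - 1L
  junction_nt <- substr(seq, j_start, j_end)
  if (nchar(junction_nt) %% 3L != 0L) return(fail("frame_error"))
  if (nchar(junction_nt) == 0L) return(fail("anchor_error"))
  junction_aa <- translate_region(junction_nt)
  n_aa <- nchar(junction_aa)
  if (substr(junction_aa, 1L, 1L) != "C" ||
      substr(junction_aa, n_aa, n_aa) != "W") {
    return(fail("anchor_error"))
  }
  list(outcome = "extracted",
       junction_nt = junction_nt,
       junction_aa = junction_aa,
       length_aa = n_aa,
       pre_motif_used = motifs$pre_cdr3$motif[pre_hits$motif_i[a]],
       post_motif_used = motifs$post_cdr3$motif[post_hits$motif_i[b]])
}

#' Assemble the full cascade configuration
#'
#' @param isotype "IgM" or "IgG".
#' @param window length window (defaults to the isotype's standard window).
#' @param gate quality gate.
#' @param primers primer set.
#' @param motifs motif library.
#' @param imgt_length also report the anchor-exclusive (IMGT-style) CDR3
#'   length, `length_aa - 2`, in an extra column.
#' @return object of class `rslb_config`.
#' @export
rslb_config <- function(isotype = c("IgM", "IgG"),
                        window = NULL,
                        gate = quality_gate(),
                        primers = primer_set(),
                        motifs = motif_library(),
                        imgt_length = FALSE) {
  isotype <- match.arg(isotype)
  if (is.null(window)) window <- length_window(isotype)
  if (is.null(primers$reverse_by_isotype[[isotype]]))
    stop("primer set lacks a reverse primer for ", isotype)
  if (is.null(motifs$isotype_motifs[[isotype]]))
    stop("motif library lacks isotype motifs for ", isotype)
  structure(
    list(isotype = isotype, window = window, gate = gate,
         primers = primers, motifs = motifs, imgt_length = imgt_length),
    class = "rslb_config"
  )
}

#' Run the full filtering and extraction cascade over a set of reads
#'
#' @param reads data.frame with `id`, `seq`, `qual` (from [read_fastq()] or
#'   [simulate_sample()]).
#' @param config an [rslb_config()].
#' @return list with `records` (one row per input read: `read_id`,
#'   `isotype`, `orientation`, `outcome`, `junction_nt`, `junction_aa`,
#'   `length_aa`, `pre_motif_used`, `post_motif_used`) and `counts`
#'   (named integer vector over all outcome categories plus
#'   `total_input`).
#' @export
run_rslb <- function(reads, config) {
  if (!inherits(config, "rslb_config")) stop("config must be an rslb_config")
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  outcome <- character(n)
  orientation <- rep("as-is", n)
  junction_nt <- rep(NA_character_, n)
  junction_aa <- rep(NA_character_, n)
  length_aa <- rep(NA_integer_, n)
  pre_used <- rep(NA_character_, n)
  post_used <- rep(NA_character_, n)

  pass_len <- filter_length(reads$seq, config$window)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    if (!pass_len[i]) { outcome[i] <- "fail_length"; next }
    if (!filter_quality(reads$qual[i], config$gate)) {
      outcome[i] <- "fail_quality"; next
    }
    o <- orient_read(reads$seq[i], reads$qual[i], config$primers,
                     config$isotype)
    if (o$outcome == "no_primer") { outcome[i] <- "no_primer"; next }
    orientation[i] <- o$orientation
    if (!has_isotype_motif(o$seq, config$motifs, config$isotype)) {
      outcome[i] <- "no_isotype_motif"; next
    }
    id <- reads$id[i]
    if (!is.null(seen[[id]])) { outcome[i] <- "duplicate"; next }
    seen[[id]] <- TRUE
    ex <- extract_cdr3(o$seq, config$motifs)
    outcome[i] <- ex$outcome
    junction_nt[i] <- ex$junction_nt
    junction_aa[i] <- ex$junction_aa
    length_aa[i] <- ex$length_aa
    pre_used[i] <- ex$pre_motif_used
    post_used[i] <- ex$post_motif_used
  }

  records <- data.frame(
    read_id = reads$id, isotype = rep(config$isotype, n),
    orientation = orientation, outcome = outcome,
    junction_nt = junction_nt, junction_aa = junction_aa,
    length_aa = length_aa, pre_motif_used = pre_used,
    post_motif_used = post_used, stringsAsFactors = FALSE
  )
  if (isTRUE(config$imgt_length)) {
    records$imgt_cdr3_length_aa <- records$length_aa - 2L
  }
  counts <- vapply(RSLB_OUTCOMES, function(o) sum(outcome == o), integer(1))
  counts <- c(counts, total_input = n)
  list(records = records, counts = counts)
}
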