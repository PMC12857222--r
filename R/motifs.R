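# Mismatch-tolerant motif search and the default primer/motif configuration.
#
# All motif matching in the pipeline is substitution-only (Hamming distance
# over every ungapped alignment window); 'N' in either string always counts
# as a mismatch, so ambiguity can never silently create a hit.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over the \{A,C,G,T,N\} alphabet (lowercase
#' accepted).  Implemented with `chartr` rather than an XStringSet round
#' trip because the simulator and orientation step call it per read.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x),
         function(s) if (nzchar(s)) intToUtf8(rev(utf8ToInt(s))) else s,
         character(1), USE.NAMES = FALSE)
}

#' Per-window Hamming mismatch counts of a motif against a sequence
#'
#' Slides `motif` over every ungapped alignment window of `seq` and counts
#' mismatching positions.  'N' in either string counts as a mismatch.
#'
#' @param seq nucleotide sequence (single string).
#' @param motif nucleotide motif (single string, no shorter than 1 nt).
#' @return integer vector of length `nchar(seq) - nchar(motif) + 1` (empty
#'   when the motif is longer than the sequence); element `i` is the number
#'   of mismatches when the motif starts at position `i`.
#' @export
motif_mismatches <- function(seq, motif) {
  s <- utf8ToInt(seq)
  p <- utf8ToInt(motif)
  L <- length(s)
  m <- length(p)
  if (m == 0L) stop("motif must be non-empty")
  if (m > L) return(integer(0))
  nw <- L - m + 1L
  mm <- integer(nw)
  n_int <- utf8ToInt("N")
  for (j in seq_len(m)) {
    sj <- s[j:(j + nw - 1L)]
    mm <- mm + (sj != p[j] | sj == n_int | p[j] == n_int)
  }
  mm
}

#' Best motif hit within a mismatch budget
#'
#' Scans every alignment window (no indels) and returns the hit with the
#' fewest mismatches, leftmost on ties, or `NULL` if every window exceeds
#' `max_mm`.  A motif longer than the sequence yields `NULL`, not an error.
#'
#' @param seq nucleotide sequence.
#' @param motif nucleotide motif.
#' @param max_mm maximum number of mismatching positions tolerated.
#' @return `NULL`, or a list with `pos` (1-based start) and `mismatches`.
#' @export
find_motif <- function(seq, motif, max_mm = 0L) {
  mm <- motif_mismatches(seq, motif)
  ok <- which(mm <= max_mm)
  if (!length(ok)) return(NULL)
  best <- ok[which.min(mm[ok])]
  list(pos = best, mismatches = mm[best])
}

#' All motif hits within a mismatch budget
#'
#' @inheritParams find_motif
#' @return data.frame with columns `pos` and `mismatches`, one row per
#'   window at or under the budget (possibly zero rows).
#' @export
find_motif_all <- function(seq, motif, max_mm = 0L) {
  mm <- motif_mismatches(seq, motif)
  ok <- which(mm <= max_mm)
  data.frame(pos = ok, mismatches = mm[ok])
}

#' Amplification primer set
#'
#' The single forward primer amplifies both isotypes; the reverse primer is
#' isotype specific.  Primer search tolerates up to `max_mismatch`
#' substitutions (default 4).
#'
#' @param forward forward primer (5'->3').
#' @param reverse_by_isotype named character vector of reverse primers,
#'   names are isotypes.
#' @param max_mismatch mismatch budget for primer search.
#' @return object of class `primer_set`.
#' @export
primer_set <- function(forward = "AGATGAACCCACTGTGGACC",
                       reverse_by_isotype = c(
                         IgM = "TGTTTGGGGCTGAAGTCC",
                         IgG = "GCTGTGGTGGAGGCTGAG"
                       ),
                       max_mismatch = 4L) {
  stopifnot(nzchar(forward), all(nzchar(reverse_by_isotype)),
            !is.null(names(reverse_by_isotype)), max_mismatch >= 0)
  structure(
    list(
      forward = toupper(forward),
      reverse_by_isotype = toupper(reverse_by_isotype),
      max_mismatch = as.integer(max_mismatch)
    ),
    class = "primer_set"
  )
}

#' Motif library for isotype screening and CDR3 anchoring
#'
#' Pre-CDR3 motifs end inside the conserved Cys-104 codon: `c104_carry`
#' gives how many nucleotides of that codon the motif's 3' tail already
#' covers (the default motif ends ...TAC-TACTG, carrying "TG" of TGT/TGC,
#' so `c104_carry = 2`).  Post-CDR3 motifs begin at the Trp-118 codon:
#' `w118_lead` gives how many nucleotides of the TGG codon open the motif
#' (the default TGGGGCCAA leads with the full codon, `w118_lead = 3`).
#' Extraction stitches the junction back together from these overlaps.
#'
#' @param isotype_motifs named list (isotype -> character vector of
#'   isotype-determining motifs).
#' @param isotype_max_mismatch mismatch budget for isotype motif screening.
#' @param pre_cdr3 data.frame with columns `motif`, `c104_carry`,
#'   `allowed_mismatch`.
#' @param post_cdr3 data.frame with columns `motif`, `w118_lead`,
#'   `allowed_mismatch`.
#' @return object of class `motif_library`.
#' @export
motif_library <- function(isotype_motifs = list(
                            IgM = "ACTTGGACGACGTGCCCGGCCCTA",
                            IgG = "GAACAGAGTGTAAGTGGGTATCGT"
                          ),
                          isotype_max_mismatch = 2L,
                          pre_cdr3 = data.frame(
                            motif = "GAGGACACGGCCACATACTACTG",
                            c104_carry = 2L,
                            allowed_mismatch = 1L
                          ),
                          post_cdr3 = data.frame(
                            motif = "TGGGGCCAA",
                            w118_lead = 3L,
                            allowed_mismatch = 1L
                          )) {
  stopifnot(
    is.list(isotype_motifs),
    all(c("motif", "c104_carry", "allowed_mismatch") %in% names(pre_cdr3)),
    all(c("motif", "w118_lead", "allowed_mismatch") %in% names(post_cdr3)),
    all(pre_cdr3$c104_carry %in% 0:2),
    all(post_cdr3$w118_lead %in% 0:3)
  )
  pre_cdr3$motif <- toupper(pre_cdr3$motif)
  post_cdr3$motif <- toupper(post_cdr3$motif)
  structure(
    list(
      isotype_motifs = lapply(isotype_motifs, toupper),
      isotype_max_mismatch = as.integer(isotype_max_mismatch),
      pre_cdr3 = pre_cdr3,
      post_cdr3 = post_cdr3
    ),
    class = "motif_library"
  )
}

#' Isotype-specific read length window (nt, both bounds inclusive)
#'
#' Defaults follow the read-cleaning settings used for each amplicon type:
#' IgM 700-1200 nt, IgG 200-800 nt.
#'
#' @param isotype "IgM" or "IgG" (any isotype named in a custom window set).
#' @param min_len,max_len optional overrides.
#' @return list with `isotype`, `min_len`, `max_len`.
#' @export
length_window <- function(isotype = c("IgM", "IgG"),
                          min_len = NULL, max_len = NULL) {
  isotype <- match.arg(isotype)
  defaults <- list(IgM = c(700L, 1200L), IgG = c(200L, 800L))
  w <- defaults[[isotype]]
  if (!is.null(min_len)) w[1] <- as.integer(min_len)
  if (!is.null(max_len)) w[2] <- as.integer(max_len)
  if (w[1] > w[2]) stop("min_len must be <= max_len")
  list(isotype = isotype, min_len = w[1], max_len = w[2])
}

#' Read quality gate (fastp-style default settings)
#'
#' A read fails when more than `max_unqualified_fraction` of its bases have
#' Phred quality below `qualified_phred`.
#'
#' @param qualified_phred Phred threshold below which a base is
#'   "unqualified" (default 15).
#' @param max_unqualified_fraction largest tolerated unqualified fraction
#'   (default 0.40; the boundary itself passes).
#' @return list with the two fields.
#' @export
quality_gate <- function(qualified_phred = 15L,
                         max_unqualified_fraction = 0.40) {
  stopifnot(qualified_phred >= 0,
            max_unqualified_fraction >= 0, max_unqualified_fraction <= 1)
  list(
    qualified_phred = as.integer(qualified_phred),
    max_unqualified_fraction = max_unqualified_fraction
  )
}
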