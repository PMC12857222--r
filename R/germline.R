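# Built-in toy germline reference.
#
# The sequences below are fabricated stand-ins (NOT IMGT downloads) whose
# names echo the bovine segments most associated with ultralong CDR3s
# (IGHV1-7, IGHD8-2, IGHJ2-4).  They were generated once under constraint
# checks so that simple identity-based gene assignment is unambiguous at
# zero sequencing error:
#   * >= 20% pairwise divergence within a segment class,
#   * pairwise D-gene longest common substring <= 7 nt,
#   * no spurious primer / pre-CDR3 / post-CDR3 / isotype-motif occurrence
#     (within the allowed mismatches) on either strand,
#   * every V ends with the default pre-CDR3 motif, every J starts with the
#     default post-CDR3 motif.
# The IGHD8-2 stand-in is long (160 nt) because ultralong junctions need a
# long D contribution, mirroring the real gene's exceptional length.

.TOY_V <- c(
  `IGHV1-7`  = "ATGGATTTACGAAAAAGGAGGAGATTTTCCCGGGCTCGGAGTACGGCATCCAGGGTAGGTCGTTATGGTGGACATACAGGCTCTCTAGGCAACCATGCAATCACAGACACGGCGCGTGATAGACGAGTAACGTAGTTATAACCAACGGTCGCCCAGGGGTTTTAAATGGTAGCTTCTGAGATGGCTGCGATTTGTCCGAAGTCCGTAGGGAAAAGTGCTCAATTAAAGCATTTAGCACCGCAGTACCCTTTTACTCGACTGAGGACACGGCCACATACTACTG",
  `IGHV1-10` = "TCTTGCGTTATATTCGAATTATGTGGCAAGTGACGTAATCGTTGAGGTCAAGCATGAACATATTTTTGTCCAATTAACCGAACCATGGCTCGCACGATCTTATGTTAATTCCGAACCAGGGGATTGTTTGTATTGTCTGAGGCTGTAGCAGACGTGATCATCACCCCTGTCTTCCGACGTTAATGCTGGGAGGTTAGCACATAGCTACTCAGAATGTACCTGAAGTACGAATAGAGTGTGTCCCGGGTCATCTACAACGAGAGGACACGGCCACATACTACTG",
  `IGHV1-14` = "ACCTTCTGTTTTCGTTGCCCAGAGACTGGGTTCCCCGGTGCCTTTTCTCGGTGGGAATCGCACAATAACGCAGCACTGTCCCGCGATATGACAAGACGGGAATTTACAACCTAATGACATGCAAAGATCACGGGCTGTGACAAACAAACAGCCGCTCAGGAGGTGGTAGGCGGTATCTAATGAACAAGCGATCTAGGACTGTCTCTTAGCCTATTCCGCTTGCACCCCCAGTCTCGGACGTTTCACCGCTTTTGGTGATAGAGGACACGGCCACATACTACTG",
  `IGHV1-17` = "TATAGTGTCAATGCTGGTCTCGTTGAAGGGCCGACAGGGGACAATACCTAGTATGACATATAGAATAGCACCTAATGTACGCTTATGTTGAAAGGTCACTCTAGACTTTCGTAAGCGTTTCCTGGTGCATTGTATTCTATGGGATAGAGGGCAAATTGATTATTTACTAGTAGACACACACGCATCGCGTAGTATTATAAGGATGAGAAGCCATGCTGAAGTTACTAGAGTATATGTGCGTAAGACCGGCCCACGACTTAGAGGACACGGCCACATACTACTG"
)

.TOY_D <- c(
  `IGHD8-2` = "GTCTACCGTATTCAAATGTCCGGGTCCCCCTTGATAAAAGGATTCCTGGGTGGCTCAACGTCCACCATGTCCCACACGGGCAGTCGGCCGTCCAACAGTACTTTTGCGTCTTATGGATAATGCCGAGCACCACTTGTTCAAAGTTACGAAAAAATTGTGT",
  `IGHD1-1` = "CTACCTGGCGTTGAGCACACCGATTTGACA",
  `IGHD5-3` = "CGGTGTATTCCCTCGCCGAAACCTAGATCGGTCCGC",
  `IGHD7-4` = "ACGACGATACCGTCCTGTGCAAAAGAACGGTAAGCATAGCTG"
)

.TOY_J <- c(
  `IGHJ2-4` = "TGGGGCCAAGTTAGATATCACGTACAGAACAGGTGCATCAGTCCGGTG",
  `IGHJ1-6` = "TGGGGCCAAGGATTGAAAGCGGCCGTAGTCACGTAGGTAACAGCCGCT"
)

.TOY_CONST <- c(
  IgM = "ACTTGGACGACGTGCCCGGCCCTA",
  IgG = "GAACAGAGTGTAAGTGGGTATCGT"
)

#' Toy germline V/D/J reference database
#'
#' Returns the built-in synthetic germline database (see source comments
#' for the construction constraints), or wraps user-supplied segment maps
#' after validation.
#'
#' @param v_genes,d_genes,j_genes named character vectors (name -> nt
#'   sequence).
#' @param constant_motifs named character vector (isotype -> nt motif
#'   placed downstream of the J segment).
#' @return object of class `germline_db` with fields `v_genes`, `d_genes`,
#'   `j_genes`, `constant_motifs`.
#' @export
germline_db <- function(v_genes = .TOY_V, d_genes = .TOY_D,
                        j_genes = .TOY_J, constant_motifs = .TOY_CONST) {
  check_seg <- function(x, what) {
    if (!length(x) || is.null(names(x)) || anyDuplicated(names(x)))
      stop("germline ", what, " must be a non-empty uniquely named vector")
    x <- toupper(x)
    if (any(grepl("[^ACGT]", x)))
      stop("germline ", what, " sequences must be over {A,C,G,T}")
    x
  }
  db <- structure(
    list(
      v_genes = check_seg(v_genes, "V"),
      d_genes = check_seg(d_genes, "D"),
      j_genes = check_seg(j_genes, "J"),
      constant_motifs = check_seg(constant_motifs, "constant-motif")
    ),
    class = "germline_db"
  )
  db
}

#' Write a germline database to FASTA files
#'
#' One record per segment, ids are the gene names.  V, D and J go into a
#' single FASTA; constant motifs are written with `const_` id prefixes.
#'
#' @param db a `germline_db`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(db, path) {
  seqs <- c(db$v_genes, db$d_genes, db$j_genes,
            stats::setNames(db$constant_motifs,
                            paste0("const_", names(db$constant_motifs))))
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a germline database from a FASTA file
#'
#' Record ids starting with IGHV/IGHD/IGHJ are sorted into the three
#' segment classes; ids prefixed `const_` become constant motifs.
#'
#' @param path FASTA file written by [write_germline_fasta()] or following
#'   the same id convention.
#' @return a `germline_db`.
#' @export
read_germline_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  pick <- function(prefix) seqs[startsWith(ids, prefix)]
  const <- pick("const_")
  names(const) <- sub("^const_", "", names(const))
  germline_db(
    v_genes = pick("IGHV"), d_genes = pick("IGHD"),
    j_genes = pick("IGHJ"), constant_motifs = const
  )
}
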