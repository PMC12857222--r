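# Shared fixture builders (everything is generated in code; no data files).

PRE_MOTIF <- "GAGGACACGGCCACATACTACTG"
POST_MOTIF <- "TGGGGCCAA"
FWD_PRIMER <- "AGATGAACCCACTGTGGACC"

# a minimal sequence carrying the default pre/post anchor pair around `span`
worked_seq <- function(span, left = "CCCCACCC", right = "GGGTGGGA") {
  paste0(left, PRE_MOTIF, span, POST_MOTIF, right)
}

# clean (error-free, unduplicated, unflipped-optional) simulated sample
clean_sim <- function(n, isotype = "IgM", seed = 1, ...) {
  simulate_sample(sim_config(
    n_reads = n, isotype = isotype, seed = seed,
    sub_rate = 0, ins_rate = 0, del_rate = 0, dup_rate = 0, ...
  ))
}

# independent brute-force oracle for the sliding Hamming motif scan
bf_find_motif <- function(seq, motif, max_mm) {
  L <- nchar(seq); m <- nchar(motif)
  if (m > L) return(NULL)
  best <- NULL
  for (pos in seq_len(L - m + 1)) {
    w <- strsplit(substr(seq, pos, pos + m - 1), "")[[1]]
    p <- strsplit(motif, "")[[1]]
    mm <- sum(w != p | w == "N" | p == "N")
    if (mm <= max_mm && (is.null(best) || mm < best$mismatches)) {
      best <- list(pos = pos, mismatches = mm)
    }
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute k distinct positions of a string with different bases
mutate_positions <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}
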