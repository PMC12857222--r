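test_that("length windows are inclusive at both bounds", {
  wm <- length_window("IgM")
  expect_true(filter_length(strrep("A", 700), wm))
  expect_false(filter_length(strrep("A", 699), wm))
  expect_true(filter_length(strrep("A", 1200), wm))
  expect_false(filter_length(strrep("A", 1201), wm))
  wg <- length_window("IgG")
  expect_true(filter_length(strrep("A", 800), wg))
  expect_false(filter_length(strrep("A", 801), wg))
})

test_that("quality gate fails only above the unqualified fraction", {
  gate <- quality_gate()
  expect_true(filter_quality(strrep("5", 100), gate))   # all Q20
  expect_false(filter_quality(strrep("+", 100), gate))  # all Q10
  # exactly 40 of 100 bases below Q15: 0.40 is not > 0.40 -> pass
  boundary <- paste0(strrep("+", 40), strrep("5", 60))
  expect_true(filter_quality(boundary, gate))
  over <- paste0(strrep("+", 41), strrep("5", 59))
  expect_false(filter_quality(over, gate))
})

test_that("find_motif reports the best hit within the mismatch budget", {
  primer <- FWD_PRIMER
  set.seed(21)
  seq <- paste0(random_dna(37), primer, random_dna(43))
  expect_equal(find_motif(seq, primer, 4), list(pos = 38L, mismatches = 0L))
  mut4 <- paste0(random_dna(30), mutate_positions(primer, c(2, 7, 11, 19)),
                 random_dna(30))
  hit <- find_motif(mut4, primer, 4)
  expect_equal(hit$mismatches, 4L)
  mut5 <- paste0(random_dna(30), mutate_positions(primer, c(2, 7, 11, 15, 19)),
                 random_dna(30))
  expect_null(find_motif(mut5, primer, 4))
  expect_null(find_motif("ACGT", primer, 4))  # motif longer than sequence
  # leftmost window wins a mismatch tie
  expect_equal(find_motif("AAAAGGAAAA", "AAAA", 0)$pos, 1L)
})

test_that("find_motif agrees with a brute-force Hamming scan", {
  set.seed(99)
  for (i in 1:200) {
    L <- sample(10:200, 1)
    m <- sample(4:12, 1)
    seq <- random_dna(L, alphabet = c("A", "C", "G", "T", "N"))
    motif <- random_dna(m, alphabet = c("A", "C", "G", "T", "N"))
    mm <- sample(0:3, 1)
    expect_identical(find_motif(seq, motif, mm), bf_find_motif(seq, motif, mm))
  }
})

test_that("orientation recovers flipped reads and flags primerless ones", {
  sim <- clean_sim(10, seed = 6, flip_rate = 0)
  primers <- primer_set()
  s <- sim$reads$seq[1]
  q <- sim$reads$qual[1]
  o1 <- orient_read(s, q, primers, "IgM")
  expect_identical(o1$orientation, "as-is")
  o2 <- orient_read(revcomp(s), q, primers, "IgM")
  expect_identical(o2$orientation, "flipped")
  expect_identical(o2$seq, s)  # reverse complement is an involution
  o3 <- orient_read(random_dna(200), strrep("I", 200), primers, "IgM")
  expect_identical(o3$outcome, "no_primer")
})

test_that("isotype motif screen separates isotypes and rejects empty lists", {
  sim <- clean_sim(5, seed = 7, flip_rate = 0)
  motifs <- motif_library()
  expect_true(has_isotype_motif(sim$reads$seq[1], motifs, "IgM"))
  expect_false(has_isotype_motif(sim$reads$seq[1], motifs, "IgG"))
  empty <- motif_library(isotype_motifs = list(IgM = character(0)))
  expect_false(has_isotype_motif(sim$reads$seq[1], empty, "IgM"))
})

test_that("duplicate flagging keeps first occurrences and is idempotent", {
  expect_identical(dedupe_flags(c("a", "b", "a")), c(FALSE, FALSE, TRUE))
  expect_identical(dedupe_flags(c("a", "b", "c")), rep(FALSE, 3))
  kept <- c("a", "b", "a")[!dedupe_flags(c("a", "b", "a"))]
  expect_identical(dedupe_flags(kept), rep(FALSE, 2))
})

test_that("the worked junction example extracts as CAKW with length 4", {
  ex <- extract_cdr3(worked_seq("TGCTAAG"))
  expect_identical(ex$outcome, "extracted")
  expect_identical(ex$junction_nt, "TGTGCTAAGTGG")
  expect_identical(ex$junction_aa, "CAKW")
  expect_identical(ex$length_aa, 4L)
  expect_identical(ex$pre_motif_used, PRE_MOTIF)
  expect_identical(ex$post_motif_used, POST_MOTIF)

  # shortening the span by one nucleotide breaks the reading frame
  expect_identical(extract_cdr3(worked_seq("TGCTAA"))$outcome, "frame_error")
  # mutating the motif-carried anchor nucleotide breaks the Cys anchor:
  # the pre motif still matches with 1 mismatch but translation starts Y
  pre_mut <- sub("TACTG", "TACTA", PRE_MOTIF)
  seq_anchor <- paste0("CCCCACCC", pre_mut, "TGCTAAG", POST_MOTIF, "GGG")
  expect_identical(extract_cdr3(seq_anchor)$outcome, "anchor_error")
  # no motif pair at all
  expect_identical(extract_cdr3(random_dna(120))$outcome, "no_cdr3")
})

test_that("extraction prefers the pair with fewest total mismatches", {
  # a decoy post motif with one mismatch sits closer to the pre motif than
  # the exact one; minimising total mismatches must skip the decoy
  decoy <- sub("TGGGGCCAA", "TGGGGCGAA", POST_MOTIF)
  seq <- paste0("CACC", PRE_MOTIF, "TGC", decoy, "TAAG", POST_MOTIF, "GG")
  ex <- extract_cdr3(seq)
  expect_identical(ex$outcome, "extracted")
  expect_identical(ex$post_motif_used, POST_MOTIF)
  expect_identical(substr(ex$junction_aa, 1, 1), "C")
})

test_that("the cascade conserves reads and recovers clean samples", {
  empty <- run_rslb(data.frame(id = character(0), seq = character(0),
                               qual = character(0)), rslb_config("IgM"))
  expect_true(all(empty$counts == 0))

  sim <- clean_sim(150, seed = 10)
  out <- run_rslb(sim$reads, rslb_config("IgM"))
  expect_equal(unname(out$counts[["extracted"]]), 150)
  expect_identical(out$records$junction_aa, sim$truth$true_junction_aa)

  noisy <- simulate_sample(sim_config(n_reads = 200, dup_rate = 0.2,
                                      low_quality_rate = 0.05, seed = 11))
  outn <- run_rslb(noisy$reads, rslb_config("IgM"))
  expect_equal(sum(outn$counts[names(outn$counts) != "total_input"]),
               unname(outn$counts[["total_input"]]))
  expect_equal(unname(outn$counts[["total_input"]]), 200)
  expect_gt(outn$counts[["duplicate"]], 0)
  expect_gt(outn$counts[["fail_quality"]], 0)
})

test_that("reverse-complementing every input leaves junction multisets unchanged", {
  sim <- simulate_sample(sim_config(n_reads = 80, dup_rate = 0, seed = 12))
  out1 <- run_rslb(sim$reads, rslb_config("IgM"))
  flipped <- sim$reads
  flipped$seq <- revcomp(flipped$seq)
  flipped$qual <- vapply(flipped$qual, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  out2 <- run_rslb(flipped, rslb_config("IgM"))
  j1 <- sort(out1$records$junction_aa[out1$records$outcome == "extracted"])
  j2 <- sort(out2$records$junction_aa[out2$records$outcome == "extracted"])
  expect_identical(j1, j2)
})

test_that("raising the primer mismatch budget never loses oriented reads", {
  sim <- simulate_sample(sim_config(n_reads = 120, seed = 13))
  oriented <- function(max_mm) {
    cfg <- rslb_config("IgM", primers = primer_set(max_mismatch = max_mm))
    out <- run_rslb(sim$reads, cfg)
    sum(!out$records$outcome %in% c("no_primer", "fail_length",
                                    "fail_quality"))
  }
  counts <- vapply(0:6, oriented, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
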