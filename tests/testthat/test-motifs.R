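# motif_screen: IUPAC scanning, enrichment statistics, k-mer ranking

test_that("IUPAC scanning reports all (overlapping) matches", {
  expect_equal(scan_motif("TGCATGCATG", "TGCATG"), c(1L, 5L))
  expect_equal(scan_motif("AG", "RK"), 1L)          # R~{A,G}, K~{G,T}
  expect_length(scan_motif("AG", "RY"), 0)          # Y is C/T, never G
  expect_equal(scan_motif("ACGT", "ACGU"), 1L)      # U treated as T
  expect_error(scan_motif("ACGT", "AXGT"), "IUPAC")
  # no match shorter than the pattern
  expect_length(scan_motif("ACG", "ACGT"), 0)
})

test_that("circular scanning finds junction-spanning matches exactly once", {
  # "ACGT" split as GT...AC across the junction
  s <- paste0("GTTTTTTTAC")
  expect_length(scan_motif(s, "ACGT", circular = FALSE), 0)
  hits <- scan_motif(s, "ACGT", circular = TRUE)
  expect_equal(hits, 9L)
  expect_gt(hits, nchar(s) - 3L)
})

test_that("scanner agrees with a brute-force matcher on random sequences", {
  pats <- c("TGCATG", "RYKM", "ANNT", "GGWCC")
  seqs <- withr::with_seed(21L, vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  }, ""))
  for (p in pats) {
    for (s in seqs) {
      expect_identical(scan_motif(s, p, circular = FALSE),
                       oracle_iupac_positions(s, p, circular = FALSE))
      expect_identical(scan_motif(s, p, circular = TRUE),
                       oracle_iupac_positions(s, p, circular = TRUE))
    }
  }
  # linear scan equals the circular scan minus junction-zone starts
  for (s in seqs) {
    circ <- scan_motif(s, "TGCATG", circular = TRUE)
    lin <- scan_motif(s, "TGCATG", circular = FALSE)
    expect_identical(lin, circ[circ <= nchar(s) - 5L])
  }
})

test_that("enrichment: equal sets give fold 1; planted density is recovered", {
  motifs <- tibble::tibble(motif_id = "m1", rbp_name = "X", pattern = "TGCATG")
  seqs <- tibble::tibble(circ_id = c("a", "b"), seq_type = "w",
                         sequence = c("AATGCATGAA", "TGCATGTGCATG"),
                         length = c(10L, 12L), circular = FALSE)
  e <- motif_enrichment(seqs, seqs, motifs)
  expect_equal(e$fold, 1)
  expect_equal(e$fg_count, 3L)

  # absent motif: counts 0, undefined fold, p = 1
  none <- motif_enrichment(seqs, seqs,
                           tibble::tibble(motif_id = "m2", rbp_name = "Y",
                                          pattern = "CCCCCC"))
  expect_equal(none$fg_count, 0L)
  expect_true(is.na(none$fold))
  expect_equal(none$p, 1)

  # batch splitting never changes total counts
  sets <- simulate_motif_sets(seed = 2L, n_fg = 20, n_bg = 20, len = 300,
                              fg_per_seq = 3L, bg_per_seq = 1L)
  whole <- motif_enrichment(sets$fg, sets$bg, motifs)
  half <- motif_enrichment(sets$fg[1:10, ], sets$bg, motifs)
  half2 <- motif_enrichment(sets$fg[11:20, ], sets$bg, motifs)
  expect_equal(whole$fg_count, half$fg_count + half2$fg_count)
})

test_that("the Fisher p equals a brute-force hypergeometric tail on small tables", {
  motifs <- tibble::tibble(motif_id = "m1", rbp_name = "X", pattern = "ACGT")
  fg <- tibble::tibble(circ_id = "f", seq_type = "w", sequence = "ACGTACGTAAAA",
                       length = 12L, circular = FALSE)
  bg <- tibble::tibble(circ_id = "b", seq_type = "w", sequence = "ACGTAAAAAAAA",
                       length = 12L, circular = FALSE)
  e <- motif_enrichment(fg, bg, motifs)
  # 2x2: fg 2/9 positions, bg 1/9 positions; two-sided Fisher by minimum
  # likelihood, reproduced from the hypergeometric pmf
  m <- matrix(c(2, 7, 1, 8), 2)
  k <- sum(m[1, ]); n1 <- sum(m[, 1]); n2 <- sum(m[, 2])
  probs <- stats::dhyper(0:min(k, n1), n1, n2, k)
  pref <- sum(probs[probs <= stats::dhyper(m[1, 1], n1, n2, k) * (1 + 1e-7)])
  expect_equal(e$p, pref, tolerance = 1e-10)
})

test_that("a motif planted at higher foreground density ranks first", {
  sets <- simulate_motif_sets(seed = 5L, n_fg = 60, n_bg = 60, len = 600,
                              motif = "TGCATG", fg_per_seq = 5L, bg_per_seq = 1L)
  motifs <- tibble::tibble(
    motif_id = c("m1", "m2", "m3"),
    rbp_name = c("planted", "decoy1", "decoy2"),
    pattern = c("TGCATG", "ACWGTA", "CYGGAR"))
  e <- motif_enrichment(sets$fg, sets$bg, motifs)
  expect_equal(e$rbp_name[1], "planted")
  expect_equal(e$fold[1], 5, tolerance = 0.15)
})

test_that("k-mer over-representation surfaces a planted hexamer", {
  sets <- simulate_motif_sets(seed = 6L, n_fg = 30, n_bg = 30, len = 400,
                              motif = "TGCATG", fg_per_seq = 6L, bg_per_seq = 1L)
  tab <- kmer_overrepresentation(sets$fg, sets$bg, k = 6L)
  expect_equal(tab$kmer[1], "TGCATG")
  expect_gt(tab$fold[1], 3)

  # identical sets: nothing significant after BH
  same <- kmer_overrepresentation(sets$bg, sets$bg, k = 6L)
  expect_true(all(same$padj >= 0.999))

  # k = 1 degenerate case: division by an absent background base is flagged
  fg1 <- tibble::tibble(circ_id = "f", seq_type = "w", sequence = "AAAA",
                        length = 4L, circular = FALSE)
  bg1 <- tibble::tibble(circ_id = "b", seq_type = "w", sequence = "CCCC",
                        length = 4L, circular = FALSE)
  t1 <- kmer_overrepresentation(fg1, bg1, k = 1L)
  expect_true(is.na(t1$fold[t1$kmer == "A"]))
  expect_equal(t1$fg_count[t1$kmer == "A"], 4L)
})

test_that("scan_motifs tabulates per-sequence matches for a motif table", {
  seqs <- tibble::tibble(circ_id = c("c1", "c2"), seq_type = "internal",
                         sequence = c("TGCATGCATG", "AAAAAAAA"),
                         length = c(10L, 8L), circular = c(TRUE, TRUE))
  motifs <- tibble::tibble(motif_id = c("m1", "m2"), rbp_name = c("X", "Y"),
                           pattern = c("TGCATG", "TTTT"))
  hits <- scan_motifs(seqs, motifs)
  expect_equal(hits$pos[hits$circ_id == "c1" & hits$motif_id == "m1"],
               c(1L, 5L))
  expect_equal(nrow(hits[hits$motif_id == "m2", ]), 0)
})
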