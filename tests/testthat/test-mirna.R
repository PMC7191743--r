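# mirna_sites: seed scoring, junction-aware scanning, expression filtering

test_that("seed/window pairing scores canonical and wobble pairs", {
  # perfect antiparallel duplex
  expect_equal(score_window("AGCUUAU", "ATAAGCT"), c(wc = 7L, wobble = 0L))
  # seed G pairing a T instead of C: one G:U wobble
  # seed pos 2 (G) pairs window pos 6; change that C to T
  expect_equal(score_window("AGCUUAU", "ATAAGTT"), c(wc = 6L, wobble = 1L))
  # seed U over G: the other wobble direction
  expect_equal(score_window("UUUUUUU", "GAAAAAA"), c(wc = 6L, wobble = 1L))
  # N in the target is a mismatch
  expect_equal(score_window("AGCUUAU", "ATAAGCN"), c(wc = 6L, wobble = 0L))
})

test_that("vectorised scoring agrees with the brute-force pairing oracle", {
  seeds <- c("AGCUUAU", "GGGUUUC", "ACACACA")
  wins <- withr::with_seed(41L, vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
  }, ""))
  for (seed in seeds) {
    got <- score_windows(seed, wins)
    ref <- t(vapply(wins, function(w) oracle_pair(seed, w), c(wc = 0L, wobble = 0L)))
    expect_equal(got$wc, unname(ref[, "wc"]))
    expect_equal(got$wobble, unname(ref[, "wobble"]))
  }
})

test_that("find_sites detects planted sites, including across the junction", {
  mirna <- tibble::tibble(mirna_id = "mir-x",
                          mature_seq = "AAGCUUAUGGGGGGGGGGGGGG",
                          seed = "AGCUUAU")
  site <- revcomp(chartr("U", "T", mirna$seed))   # perfect 7-nt target
  backbone <- strrep("C", 30)
  s1 <- paste0(substr(backbone, 1, 10), site, substr(backbone, 18, 30))
  circ <- tibble::tibble(circ_id = "c1", seq_type = "internal", sequence = s1,
                         length = nchar(s1), circular = TRUE)
  hits <- find_sites(circ, mirna)
  expect_equal(hits$pos, 11L)
  expect_equal(hits$wc, 7L)
  expect_false(hits$spans_junction)

  # split 3 + 4 across the junction: circular finds it, linear does not
  s2 <- paste0(substr(site, 4, 7), backbone, substr(site, 1, 3))
  circ2 <- tibble::tibble(circ_id = "c2", seq_type = "internal", sequence = s2,
                          length = nchar(s2), circular = TRUE)
  h2 <- find_sites(circ2, mirna)
  expect_equal(h2$pos, nchar(s2) - 2L)
  expect_true(h2$spans_junction)
  lin <- find_sites(circ2 |> dplyr::mutate(circular = FALSE), mirna)
  expect_equal(nrow(lin), 0)
})

test_that("site lists match a rotation-and-deduplicate brute force scanner", {
  seqlen <- 600L
  s <- withr::with_seed(17L, paste(sample(c("A", "C", "G", "T"), seqlen, TRUE),
                                   collapse = ""))
  mirnas <- withr::with_seed(18L, tibble::tibble(
    mirna_id = paste0("m", 1:8),
    mature_seq = vapply(1:8, function(i) {
      paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    }, ""))) |>
    dplyr::mutate(seed = substr(.data$mature_seq, 2, 8))
  circ <- tibble::tibble(circ_id = "c", seq_type = "internal", sequence = s,
                         length = seqlen, circular = TRUE)
  got <- find_sites(circ, mirnas, min_total = 6, min_wc = 5, max_wobble = 1)

  # oracle: scan every rotation linearly, keep sites starting at phase 1..len
  ref <- list()
  for (m in seq_len(nrow(mirnas))) {
    for (rot in 0:(seqlen - 1)) {
      r <- paste0(substr(s, rot + 1, seqlen), substr(s, 1, rot))
      w <- substr(r, 1, 7)
      sc <- oracle_pair(mirnas$seed[m], w)
      if (sc["wc"] + sc["wobble"] >= 6 && sc["wc"] >= 5 && sc["wobble"] <= 1) {
        ref[[length(ref) + 1]] <- tibble::tibble(
          mirna_id = mirnas$mirna_id[m], pos = rot + 1L,
          wc = sc[["wc"]], wobble = sc[["wobble"]])
      }
    }
  }
  ref <- dplyr::bind_rows(ref) |> dplyr::arrange(.data$mirna_id, .data$pos)
  got2 <- got |> dplyr::select(dplyr::all_of(c("mirna_id", "pos", "wc", "wobble"))) |>
    dplyr::arrange(.data$mirna_id, .data$pos)
  expect_equal(as.data.frame(got2), as.data.frame(ref))
})

test_that("rotating a circular sequence preserves the multiset of site scores", {
  s <- withr::with_seed(19L, paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                   collapse = ""))
  mirnas <- withr::with_seed(20L, tibble::tibble(
    mirna_id = paste0("m", 1:3),
    mature_seq = vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    }, ""))) |>
    dplyr::mutate(seed = substr(.data$mature_seq, 2, 8))
  base_sites <- find_sites(
    tibble::tibble(circ_id = "c", seq_type = "internal", sequence = s,
                   length = 400L, circular = TRUE), mirnas)
  base_key <- sort(paste(base_sites$mirna_id, base_sites$wc, base_sites$wobble))
  for (rot in withr::with_seed(22L, sample(399L, 8L))) {
    r <- paste0(substr(s, rot + 1, 400), substr(s, 1, rot))
    rs <- find_sites(
      tibble::tibble(circ_id = "c", seq_type = "internal", sequence = r,
                     length = 400L, circular = TRUE), mirnas)
    expect_identical(sort(paste(rs$mirna_id, rs$wc, rs$wobble)), base_key)
  }
})

test_that("tightening any stringency threshold never adds sites", {
  s <- withr::with_seed(23L, paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                   collapse = ""))
  mirnas <- withr::with_seed(24L, tibble::tibble(
    mirna_id = "m1",
    mature_seq = paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""))) |>
    dplyr::mutate(seed = substr(.data$mature_seq, 2, 8))
  circ <- tibble::tibble(circ_id = "c", seq_type = "internal", sequence = s,
                         length = 500L, circular = TRUE)
  loose <- find_sites(circ, mirnas, 5, 4, 2)
  key <- function(x) paste(x$mirna_id, x$pos)
  expect_true(all(key(find_sites(circ, mirnas, 6, 4, 2)) %in% key(loose)))
  expect_true(all(key(find_sites(circ, mirnas, 5, 5, 2)) %in% key(loose)))
  expect_true(all(key(find_sites(circ, mirnas, 5, 4, 1)) %in% key(loose)))
})

test_that("miRNA loading derives seeds and expression filtering applies the mean rule", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">mir-a", "UAGCUUAUCAGACUGAUGUUGA",
               ">mir-b", "ACGU",                     # too short: dropped
               ">mir-c stuff", "AAGGCCUUAAGGCCUUAAGG"), f)
  expect_warning(m <- read_mirna_fasta(f), "shorter")
  expect_equal(m$mirna_id, c("mir-a", "mir-c"))
  expect_equal(m$seed[1], "AGCUUAU")
  expect_equal(nchar(m$seed), c(7L, 7L))

  expr <- tibble::tibble(mirna_id = c("mir-a", "mir-c"),
                         s1 = c(10, 9), s2 = c(10, 10), s3 = c(10, 10),
                         s4 = c(10, 10))
  kept <- filter_mirnas(m, expr, min_mean = 10)
  expect_equal(kept$mirna_id, "mir-a")          # 9.75 < 10 drops mir-c

  expect_warning(filter_mirnas(m, expr[1, ], min_mean = 1), "absent")
})

test_that("sequences shorter than the seed yield an empty result with a warning", {
  mirnas <- tibble::tibble(mirna_id = "m", mature_seq = "UAGCUUAUCAGACUGAUGUUGA",
                           seed = "AGCUUAU")
  tiny <- tibble::tibble(circ_id = "c", seq_type = "internal", sequence = "ACGT",
                         length = 4L, circular = TRUE)
  expect_warning(out <- find_sites(tiny, mirnas), "shorter")
  expect_equal(nrow(out), 0)
})
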