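# sequence_extraction: internal, across-junction and flanking sequences

test_that("single-exon extraction honours strand (revcomp identity)", {
  g <- Biostrings::DNAStringSet(c(chr1 = "TTTTAACCGGTTTT"))
  model <- gene_model(tibble::tibble(
    gene_id = c("gp", "gm"), transcript_id = c("gp.t", "gm.t"),
    chrom = "chr1", strand = c("+", "-"), start = 5L, end = 10L))
  plus <- extract_internal(annotate_circs(bsj_row("gp", "+", "chr1", 5, 10), model), g)
  minus <- extract_internal(annotate_circs(bsj_row("gm", "-", "chr1", 10, 5), model), g)
  expect_equal(plus$sequence, "AACCGG")
  expect_equal(minus$sequence, "CCGGTT")
  expect_true(plus$circular)
  expect_equal(plus$length, 6L)
})

test_that("multi-exon internal sequences equal a naive slicing oracle on both strands", {
  fx <- the_fixture()
  model <- load_gtf(file.path(fx$dir, fx$manifest$paths$gtf))
  genome <- load_genome(file.path(fx$dir, fx$manifest$paths$genome))
  chrom_str <- as.character(genome)

  circs <- dplyr::bind_rows(
    fx$manifest$truth$circs,
    generate_random_bsjs(model, 40, exclude = fx$manifest$truth$circs$circ_id,
                         seed = 99L))
  ann <- annotate_circs(circs, model)
  got <- extract_internal(ann, genome)

  naive_rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  for (k in seq_len(nrow(ann))) {
    ex <- ann$exons[[k]]
    pieces <- vapply(seq_len(nrow(ex)), function(i) {
      substr(chrom_str[[ann$chrom[k]]], ex$start[i], ex$end[i])
    }, "")
    want <- if (ann$strand[k] == "+") paste(pieces, collapse = "")
            else paste(vapply(pieces, naive_rc, ""), collapse = "")
    expect_identical(got$sequence[k], want)
    expect_equal(got$length[k], ann$len_exonic[k])
  }
})

test_that("across-junction sequences read tail-then-head of the circle", {
  internal <- tibble::tibble(circ_id = c("a", "b"), seq_type = "internal",
                             sequence = c("AAAACCCC", "ACG"),
                             length = c(8L, 3L), circular = TRUE)
  x <- extract_across_bsj(internal, w = 2L)
  expect_equal(x$sequence[1], "CCAA")
  # shorter than w: both sides truncate to the full sequence
  x5 <- extract_across_bsj(internal, w = 5L)
  expect_equal(x5$sequence[2], "ACGACG")
  # property: across-bsj is a substring of the doubled internal sequence
  # centred on the junction
  fx <- the_fixture()
  model <- load_gtf(file.path(fx$dir, fx$manifest$paths$gtf))
  genome <- load_genome(file.path(fx$dir, fx$manifest$paths$genome))
  ann <- annotate_circs(fx$manifest$truth$circs, model)
  int <- extract_internal(ann, genome)
  ab <- extract_across_bsj(int, w = 11L)
  for (k in seq_len(nrow(ab))) {
    doubled <- paste0(int$sequence[k], int$sequence[k])
    len <- int$length[k]
    kk <- min(11L, len)
    expect_identical(ab$sequence[k], substr(doubled, len - kk + 1L, len + kk))
  }
})

test_that("windows join intron and exon segments at the junction with clipping", {
  # plus strand: 300-nt introns around a 100-nt exon triplet
  exons <- tibble::tibble(
    gene_id = "g", transcript_id = "g.t", chrom = "chr1", strand = "+",
    start = c(401L, 801L, 1201L), end = c(500L, 900L, 1300L))
  model <- gene_model(exons)
  chars <- withr::with_seed(3L, sample(c("A", "C", "G", "T"), 2000, TRUE))
  g <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chr1"))
  gs <- as.character(g)[[1]]

  ann <- annotate_circs(bsj_row("g", "+", "chr1", 801, 900), model)
  w <- extract_flanks(ann, g, "window", intron_nt = 200L, exon_nt = 10L)
  up <- w[w$seq_type == "window_up", ]
  dn <- w[w$seq_type == "window_down", ]
  expect_equal(up$length, 210L)
  expect_identical(up$sequence, paste0(substr(gs, 601, 800), substr(gs, 801, 810)))
  expect_identical(dn$sequence, paste0(substr(gs, 891, 900), substr(gs, 901, 1100)))

  # clipping at a short intron: 150 + 10 = 160 nt and a warning
  exons2 <- exons
  exons2$end[1] <- 650L   # first intron shrinks to 150 nt
  ann2 <- annotate_circs(bsj_row("g", "+", "chr1", 801, 900), gene_model(exons2))
  expect_warning(w2 <- extract_flanks(ann2, g, "window", 200L, 10L), "clipped")
  expect_equal(w2$length[w2$seq_type == "window_up"], 160L)

  # bse mode returns the full back-spliced exons
  b <- extract_flanks(ann, g, "bse")
  expect_identical(b$sequence[b$seq_type == "bse_up"], substr(gs, 801, 900))

  # introns mode returns the full flanking introns
  ii <- extract_flanks(ann, g, "introns")
  expect_identical(ii$sequence[ii$seq_type == "flank_intron_up"],
                   substr(gs, 501, 800))

  # a first-exon circ has no upstream intron: side omitted with a warning
  ann3 <- annotate_circs(bsj_row("g", "+", "chr1", 401, 900), model)
  expect_warning(w3 <- extract_flanks(ann3, g, "window"), "omitted")
  expect_equal(w3$seq_type, "window_down")
})

test_that("minus-strand windows equal the revcomp of the mirrored plus computation", {
  # same coordinates, opposite strands
  mkm <- function(strand) gene_model(tibble::tibble(
    gene_id = "g", transcript_id = "g.t", chrom = "chr1", strand = strand,
    start = c(401L, 801L, 1201L), end = c(500L, 900L, 1300L)))
  chars <- withr::with_seed(5L, sample(c("A", "C", "G", "T"), 2000, TRUE))
  g <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chr1"))

  annp <- annotate_circs(bsj_row("g", "+", "chr1", 801, 900), mkm("+"))
  annm <- annotate_circs(bsj_row("g", "-", "chr1", 900, 801), mkm("-"))
  wp <- extract_flanks(annp, g, "window", 200L, 10L)
  wm <- extract_flanks(annm, g, "window", 200L, 10L)
  # the minus-strand up-window covers the genomic region of the plus
  # down-window, read on the other strand
  expect_identical(wm$sequence[wm$seq_type == "window_up"],
                   revcomp(wp$sequence[wp$seq_type == "window_down"]))
  expect_identical(wm$sequence[wm$seq_type == "window_down"],
                   revcomp(wp$sequence[wp$seq_type == "window_up"]))
})

test_that("FASTA round trip preserves sequences, and the RNA flag converts T to U", {
  fx <- the_fixture()
  model <- load_gtf(file.path(fx$dir, fx$manifest$paths$gtf))
  genome <- load_genome(file.path(fx$dir, fx$manifest$paths$genome))
  int <- extract_internal(annotate_circs(fx$manifest$truth$circs, model), genome)
  f <- tempfile(fileext = ".fa")
  write_seq_fasta(int, f)
  back <- read_seq_fasta(f)
  expect_equal(back$sequence, int$sequence)
  expect_equal(back$circ_id, int$circ_id)
  expect_true(all(back$circular))

  write_seq_fasta(int[1, ], f, rna = TRUE)
  raw <- Biostrings::readBStringSet(f)
  expect_false(grepl("T", as.character(raw[[1]])))
  expect_equal(chartr("U", "T", as.character(raw[[1]])), int$sequence[1])
})
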