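# region_annotation: SNP/repeat assignment to flanks, inverted repeat pairs

region_model <- function(strand = "+") {
  gene_model(tibble::tibble(
    gene_id = "g", transcript_id = "g.t", chrom = "chr1", strand = strand,
    start = c(1001L, 2001L, 3001L), end = c(1200L, 2200L, 3200L)))
}

region_ann <- function(strand = "+") {
  if (strand == "+") annotate_circs(bsj_row("g", "+", "chr1", 2001, 2200),
                                    region_model("+"))
  else annotate_circs(bsj_row("g", "-", "chr1", 2200, 2001), region_model("-"))
}

feat <- function(kind, chrom, start, end, strand, name, family) {
  tibble::tibble(kind = kind, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, name = name,
                 family = family)
}

test_that("boundary-inclusive overlap assigns features to the right flank", {
  ann <- region_ann()
  # introns: up = [1201, 2000], down = [2201, 3000]
  features <- dplyr::bind_rows(
    feat("snp", "chr1", 1201, 1201, "na", "rs_first_base", "trait"),
    feat("snp", "chr1", 1200, 1200, "na", "rs_outside", "trait"),
    feat("snp", "chr1", 2500, 2500, "na", "rs_mid_down", "trait"),
    feat("repeat", "chr1", 1900, 2050, "+", "AluOverlap", "Alu"))
  fl <- annotate_flanks(ann, features, region = "introns")
  expect_setequal(fl$name[fl$side == "up"], c("rs_first_base", "AluOverlap"))
  expect_equal(fl$name[fl$side == "down"], "rs_mid_down")
  expect_false("rs_outside" %in% fl$name)
})

test_that("flank assignment equals a brute-force all-pairs overlap scan", {
  fx <- the_fixture()
  model <- load_gtf(file.path(fx$dir, fx$manifest$paths$gtf))
  ann <- annotate_circs(fx$manifest$truth$circs, model)
  features <- withr::with_seed(33L, {
    n <- 120
    chrom <- sample(c("chrA", "chrB"), n, TRUE)
    start <- sample(30000L, n, TRUE)
    len <- sample(c(0L, 5L, 60L, 300L), n, TRUE)
    feat(sample(c("snp", "repeat"), n, TRUE), chrom, start, start + len,
         sample(c("+", "-", "na"), n, TRUE), paste0("f", seq_len(n)), "fam")
  })
  features$end[features$kind == "snp"] <- features$start[features$kind == "snp"]
  fl <- annotate_flanks(ann, features, region = "introns")

  # quadratic oracle over (circ, side, feature)
  ref <- list()
  for (k in seq_len(nrow(ann))) {
    for (side in c("up", "down")) {
      lo <- if (side == "up") ann$intron_up_start[k] else ann$intron_down_start[k]
      hi <- if (side == "up") ann$intron_up_end[k] else ann$intron_down_end[k]
      if (is.na(lo)) next
      for (f in seq_len(nrow(features))) {
        if (features$chrom[f] == ann$chrom[k] &&
            features$start[f] <= hi && features$end[f] >= lo) {
          ref[[length(ref) + 1]] <- tibble::tibble(
            circ_id = ann$circ_id[k], side = side, name = features$name[f])
        }
      }
    }
  }
  ref <- dplyr::bind_rows(ref) |> dplyr::distinct() |>
    dplyr::arrange(.data$circ_id, .data$side, .data$name)
  got <- fl |> dplyr::select(dplyr::all_of(c("circ_id", "side", "name"))) |>
    dplyr::distinct() |> dplyr::arrange(.data$circ_id, .data$side, .data$name)
  expect_equal(as.data.frame(got), as.data.frame(ref))
})

test_that("growing the window never removes annotated features", {
  fx <- the_fixture()
  model <- load_gtf(file.path(fx$dir, fx$manifest$paths$gtf))
  ann <- annotate_circs(fx$manifest$truth$circs, model)
  features <- read_rmsk_tsv(file.path(fx$dir, fx$manifest$paths$rmsk))
  small <- annotate_flanks(ann, features, "window", intron_nt = 50L, exon_nt = 5L)
  big <- annotate_flanks(ann, features, "window", intron_nt = 400L, exon_nt = 20L)
  key <- function(x) paste(x$circ_id, x$side, x$name, x$start)
  expect_true(all(key(small) %in% key(big)))
})

test_that("complementary pairs require the family predicate and opposite strands", {
  fl <- dplyr::bind_rows(
    tibble::tibble(circ_id = "c1", side = "up", kind = "repeat", name = "AluSx",
                   family = "Alu", start = 1L, end = 60L, strand = "+"),
    tibble::tibble(circ_id = "c1", side = "down", kind = "repeat", name = "AluJb",
                   family = "Alu", start = 500L, end = 560L, strand = "-"),
    tibble::tibble(circ_id = "c2", side = "up", kind = "repeat", name = "AluSx",
                   family = "Alu", start = 1L, end = 60L, strand = "+"),
    tibble::tibble(circ_id = "c2", side = "down", kind = "repeat", name = "AluSx",
                   family = "Alu", start = 500L, end = 560L, strand = "+"),
    tibble::tibble(circ_id = "c3", side = "up", kind = "repeat", name = "L1MA4",
                   family = "L1", start = 1L, end = 60L, strand = "+"),
    tibble::tibble(circ_id = "c3", side = "down", kind = "repeat", name = "L1PA2",
                   family = "L1", start = 500L, end = 560L, strand = "-"))
  cp <- complementary_pairs(fl)
  expect_equal(cp$pairs$circ_id, "c1")
  expect_equal(cp$summary$has_complementary_pair[cp$summary$circ_id == "c1"], TRUE)
  expect_equal(cp$summary$has_complementary_pair[cp$summary$circ_id == "c2"], FALSE)
  # family predicate is pluggable: L1 pair counts under an L1 predicate
  cp2 <- complementary_pairs(fl, function(name, family) family == "L1")
  expect_equal(cp2$pairs$circ_id, "c3")
})

test_that("overlap assignment is symmetric under strand mirroring", {
  annp <- region_ann("+")
  annm <- region_ann("-")
  features <- feat("snp", "chr1", c(1500, 2600), c(1500, 2600), "na",
                   c("rsA", "rsB"), "t")
  flp <- annotate_flanks(annp, features, "introns")
  flm <- annotate_flanks(annm, features, "introns")
  # the same genomic SNPs land in the same genomic introns; sides swap
  expect_setequal(flp$name, flm$name)
  expect_equal(flp$side[flp$name == "rsA"], "up")
  expect_equal(flm$side[flm$name == "rsA"], "down")
})

test_that("GWAS and rmsk readers apply conventions and trait filters", {
  fx <- the_fixture()
  g_all <- read_gwas_tsv(file.path(fx$dir, fx$manifest$paths$gwas))
  g_cv <- read_gwas_tsv(file.path(fx$dir, fx$manifest$paths$gwas),
                        traits = "cardiac|vascular")
  expect_gt(nrow(g_all), nrow(g_cv))
  expect_false("rs999999" %in% g_cv$name)
  expect_true(all(g_cv$start == g_cv$end))
  expect_true(all(startsWith(g_all$chrom, "chr")))

  r <- read_rmsk_tsv(file.path(fx$dir, fx$manifest$paths$rmsk))
  raw <- readr::read_tsv(file.path(fx$dir, fx$manifest$paths$rmsk),
                         show_col_types = FALSE)
  expect_equal(r$start, raw$genoStart + 1L)   # 0-based converted on load
  expect_equal(r$end, raw$genoEnd)
})

test_that("per-circ summary counts SNPs and repeats and flags pairs", {
  fl <- dplyr::bind_rows(
    tibble::tibble(circ_id = "c1", side = "up", kind = "snp", name = "rs1",
                   family = "t", start = 5L, end = 5L, strand = "na"),
    tibble::tibble(circ_id = "c1", side = "up", kind = "repeat", name = "AluY",
                   family = "Alu", start = 10L, end = 70L, strand = "+"),
    tibble::tibble(circ_id = "c1", side = "down", kind = "repeat", name = "AluY",
                   family = "Alu", start = 900L, end = 960L, strand = "-"))
  s <- summarize_flanks(fl)
  expect_equal(s$n_snps, 1L)
  expect_equal(s$n_repeats, 2L)
  expect_true(s$has_complementary_pair)
})
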