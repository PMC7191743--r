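# deterministic synthetic mini-dataset: genome, GTF, tool outputs in all six
# dialects, motif/miRNA/SNP/repeat/chain files, and a ground-truth manifest

#' Specification of a synthetic fixture
#'
#' Defaults give a ~60 kb genome over two chromosomes with 12 single-transcript
#' genes, 20 true circRNAs reported by all six tools, per-tool decoy junctions
#' with counts too low to survive the prevalence filter, two antisense decoys,
#' 3 + 3 samples with NB junction counts (dispersion 0.2) and four planted
#' two-fold-change (log2) effects of magnitude 2, one planted internal and one
#' junction-spanning miRNA seed site, a hexamer RBP motif enriched near the
#' true junctions, GWAS SNPs and Alu repeats planted in flanking introns
#' (inverted pairs in half the eligible circs), and identity / shift /
#' inversion / partial chain files with inverses.
#'
#' @param seed integer seed; the whole fixture is a pure function of the
#'   parameters and this seed.
#' @param ... overrides for the defaults listed above (see source for keys).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, ...) {
  spec <- list(
    seed = as.integer(seed),
    chroms = c("chrA", "chrB"),
    n_genes = 12L,
    exons_per_gene = c(4L, 8L),
    exon_len = c(120L, 300L),
    intron_len = c(250L, 600L),
    intergenic = c(300L, 800L),
    n_circs = 20L,
    n_antisense = 2L,
    n_decoys_per_tool = 2L,
    conditions = c("control", "disease"),
    n_per_condition = 3L,
    count_mean = c(30, 150),
    dispersion = 0.2,
    n_de = 4L,
    de_lfc = 2,
    tools = c("mapsplice2", "nclscan", "circmarker", "circexplorer2",
              "knife", "uroborus"),
    motif = "TGCATG",
    motif_rbp = "RBM24",
    repeat_pair_frac = 0.5
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(spec))
  if (length(unknown) > 0) abort(sprintf("unknown fixture_spec field(s): %s",
                                         paste(unknown, collapse = ", ")))
  spec[names(user)] <- user
  structure(spec, class = "fixture_spec")
}

.runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# map internal positions (transcription order, 1..len_exonic) of a circ to
# genomic coordinates, given its internal exons (genomic coords, transcription
# order) and strand
.internal_to_genomic <- function(exons, strand) {
  unlist(lapply(seq_len(nrow(exons)), function(k) {
    if (strand == "+") exons$start[k]:exons$end[k] else exons$end[k]:exons$start[k]
  }))
}

# write a transcript-oriented string into a genome character-vector list
.plant_tx_string <- function(seqs, chrom, gpos, strand, string) {
  chars <- strsplit(string, "")[[1]]
  if (strand == "-") chars <- .COMPLEMENT[chars]
  seqs[[chrom]][gpos] <- chars
  seqs
}

# generator-side intron intervals of a circ (same adjacency rule the
# annotation stage uses, recomputed from the generator's own exon table)
.gen_introns <- function(tx_exons, i, j) {
  up <- if (i > 1) .gap_between(tx_exons[i - 1, ], tx_exons[i, ]) else NULL
  dn <- if (j < nrow(tx_exons)) .gap_between(tx_exons[j, ], tx_exons[j + 1, ]) else NULL
  list(up = up, down = dn)
}

#' Build the synthetic fixture
#'
#' Writes every input file the pipeline consumes plus `manifest.json` holding
#' the planted ground truth, and returns the manifest invisibly. Byte-identical
#' for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
build_fixture <- function(spec = fixture_spec(), outdir) {
  if (!inherits(spec, "fixture_spec")) abort("spec must be a fixture_spec")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, .build_fixture_impl(spec, outdir))
}

.build_fixture_impl <- function(spec, outdir) {
  p <- function(...) file.path(outdir, ...)

  ## gene structures ---------------------------------------------------------
  genes <- list()
  cursor <- setNames(rep(1L, length(spec$chroms)), spec$chroms)
  for (g in seq_len(spec$n_genes)) {
    chrom <- spec$chroms[(g - 1L) %% length(spec$chroms) + 1L]
    strand <- sample(c("+", "-"), 1)
    ne <- .runif_int(1, spec$exons_per_gene)
    elens <- .runif_int(ne, spec$exon_len)
    ilens <- if (ne > 1) .runif_int(ne - 1, spec$intron_len) else integer()
    start <- cursor[chrom] + .runif_int(1, spec$intergenic)
    starts <- integer(ne); ends <- integer(ne)
    pos <- start
    for (k in seq_len(ne)) {
      starts[k] <- pos
      ends[k] <- pos + elens[k] - 1L
      pos <- ends[k] + 1L + if (k < ne) ilens[k] else 0L
    }
    cursor[chrom] <- ends[ne]
    gid <- sprintf("gene%02d", g)
    genes[[g]] <- tibble(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = chrom, strand = strand, start = starts, end = ends)
  }
  exon_tbl <- bind_rows(genes)
  chrom_len <- vapply(spec$chroms, function(cc) {
    max(exon_tbl$end[exon_tbl$chrom == cc]) + 500L
  }, 1L)

  ## genome ------------------------------------------------------------------
  seqs <- lapply(spec$chroms, function(cc) {
    sample(c("A", "C", "G", "T"), chrom_len[cc], replace = TRUE)
  })
  names(seqs) <- spec$chroms

  model <- gene_model(exon_tbl)
  ex_by_tx <- split(model$exons, model$exons$transcript_id)

  ## true circRNAs -----------------------------------------------------------
  tx_meta <- model$exons |> distinct(.data$transcript_id, .data$gene_id,
                                     .data$chrom, .data$strand)
  pick_circ <- function(min_exons = 1L) {
    repeat {
      m <- tx_meta[sample.int(nrow(tx_meta), 1), ]
      e <- ex_by_tx[[m$transcript_id]] |> arrange(.data$exon_index)
      if (nrow(e) < min_exons) next
      i <- sample.int(nrow(e) - min_exons + 1L, 1)
      j <- i + min_exons - 1L + sample.int(nrow(e) - (i + min_exons - 1L) + 1L, 1) - 1L
      su <- .t_start(m$strand, e$start[i], e$end[i])
      ed <- .t_end(m$strand, e$start[j], e$end[j])
      return(tibble(gene = m$gene_id, strand = m$strand, chrom = m$chrom,
                    startUpBSE = su, endDownBSE = ed,
                    transcript_id = m$transcript_id, i = i, j = j))
    }
  }
  circs <- list()
  seen <- character()
  # first two circs host the planted miRNA sites: multi-exon, then any;
  # they come from different genes so the planted bases cannot collide
  want_min_exons <- c(2L, 1L, rep(1L, spec$n_circs - 2L))
  while (length(circs) < spec$n_circs) {
    cand <- pick_circ(want_min_exons[length(circs) + 1L])
    if (length(circs) == 1L && cand$gene == circs[[1]]$gene) next
    id <- make_circ_id(cand$gene, cand$strand, cand$chrom,
                       cand$startUpBSE, cand$endDownBSE)
    if (id %in% seen) next
    seen <- c(seen, id)
    circs[[length(circs) + 1L]] <- cand |> mutate(circ_id = id)
  }
  truth <- bind_rows(circs)

  ## decoys and antisense ----------------------------------------------------
  decoys <- list()
  for (tool in spec$tools) {
    got <- 0L
    while (got < spec$n_decoys_per_tool) {
      cand <- pick_circ()
      id <- make_circ_id(cand$gene, cand$strand, cand$chrom,
                         cand$startUpBSE, cand$endDownBSE)
      if (id %in% seen) next
      seen <- c(seen, id)
      got <- got + 1L
      decoys[[length(decoys) + 1L]] <- cand |> mutate(circ_id = id, tool = tool)
    }
  }
  decoys <- bind_rows(decoys)

  anti <- list()
  got <- 0L
  while (got < spec$n_antisense) {
    cand <- pick_circ()
    flipped <- if (cand$strand == "+") "-" else "+"
    su <- cand$endDownBSE; ed <- cand$startUpBSE   # transcription order flips
    id <- make_circ_id(cand$gene, flipped, cand$chrom, su, ed)
    if (id %in% seen) next
    seen <- c(seen, id)
    got <- got + 1L
    anti[[got]] <- tibble(gene = cand$gene, strand = flipped, chrom = cand$chrom,
                          startUpBSE = su, endDownBSE = ed, circ_id = id)
  }
  anti <- bind_rows(anti)

  ## counts ------------------------------------------------------------------
  samples <- paste0(rep(c("C", "D"), each = spec$n_per_condition),
                    seq_len(spec$n_per_condition))
  design <- tibble(sample = samples,
                   condition = rep(spec$conditions, each = spec$n_per_condition))
  n_c <- spec$n_circs
  mu <- exp(runif(n_c, log(spec$count_mean[1]), log(spec$count_mean[2])))
  de_idx <- if (spec$n_de > 0) sample.int(n_c, spec$n_de) else integer()
  lfc <- rep(0, n_c)
  if (spec$n_de > 0) {
    lfc[de_idx] <- rep_len(c(spec$de_lfc, -spec$de_lfc), spec$n_de)
  }
  counts <- matrix(0L, n_c, length(samples), dimnames = list(truth$circ_id, samples))
  for (ci in seq_len(n_c)) {
    for (si in seq_along(samples)) {
      m <- if (design$condition[si] == spec$conditions[2]) mu[ci] * 2^lfc[ci] else mu[ci]
      counts[ci, si] <- rnbinom(1, mu = m, size = 1 / spec$dispersion)
    }
  }
  decoy_counts <- matrix(sample(0:2, nrow(decoys) * length(samples), replace = TRUE),
                         nrow(decoys), length(samples),
                         dimnames = list(decoys$circ_id, samples))
  anti_counts <- matrix(sample(0:3, nrow(anti) * length(samples), replace = TRUE),
                        nrow(anti), length(samples),
                        dimnames = list(anti$circ_id, samples))
  anti_tools <- spec$tools[1:2]

  ## plant miRNA sites -------------------------------------------------------
  mirna_len <- 22L
  mirnas <- tibble(
    mirna_id = c("mir-fix-1", "mir-fix-2", "mir-low"),
    mature_seq = vapply(1:3, function(i) {
      chartr("T", "U", .rand_dna(mirna_len))
    }, ""))
  site_of <- function(mature) revcomp(chartr("U", "T", str_sub(mature, 2, 8)))

  circ_exons <- function(row) {
    e <- ex_by_tx[[row$transcript_id]] |> arrange(.data$exon_index)
    e[row$i:row$j, c("start", "end")]
  }
  # internal site for mir-fix-1 in circ 1
  c1 <- truth[1, ]
  g1 <- .internal_to_genomic(circ_exons(c1), c1$strand)
  site1_pos <- 10L
  seqs <- .plant_tx_string(seqs, c1$chrom, g1[site1_pos:(site1_pos + 6L)],
                           c1$strand, site_of(mirnas$mature_seq[1]))
  # junction-spanning site for mir-fix-2 in circ 2: last 3 nt + first 4 nt
  c2 <- truth[2, ]
  g2 <- .internal_to_genomic(circ_exons(c2), c2$strand)
  len2 <- length(g2)
  site2_pos <- len2 - 2L
  jpos <- c(g2[(len2 - 2L):len2], g2[1:4])
  seqs <- .plant_tx_string(seqs, c2$chrom, jpos, c2$strand,
                           site_of(mirnas$mature_seq[2]))
  planted_sites <- tibble(
    circ_id = c(c1$circ_id, c2$circ_id),
    mirna_id = c("mir-fix-1", "mir-fix-2"),
    pos = c(site1_pos, site2_pos),
    spans_junction = c(FALSE, TRUE))

  mirna_expr <- tibble(
    mirna_id = mirnas$mirna_id,
    C1 = c(40, 25, 3), C2 = c(35, 30, 5), C3 = c(50, 20, 2), C4 = c(45, 25, 4))

  ## plant RBP motif occurrences near true junctions -------------------------
  motif_plants <- 0L
  for (ci in seq_len(n_c)) {
    row <- truth[ci, ]
    tx_exons <- ex_by_tx[[row$transcript_id]] |> arrange(.data$exon_index)
    intr <- .gen_introns(tx_exons, row$i, row$j)
    for (side in c("up", "down")) {
      iv <- intr[[side]]
      if (is.null(iv)) next
      # two copies inside the 200-nt intron segment adjacent to the junction
      near_low <- (row$strand == "+") == (side == "up")
      width <- min(200L, iv[2] - iv[1] + 1L)
      base <- if (near_low) iv[2] - width + 1L else iv[1]
      offs <- c(20L, 90L)
      for (o in offs) {
        gpos <- (base + o):(base + o + nchar(spec$motif) - 1L)
        if (max(gpos) > iv[2] || min(gpos) < iv[1]) next
        if (row$strand == "-") gpos <- rev(gpos)   # transcript orientation
        seqs <- .plant_tx_string(seqs, row$chrom, gpos, row$strand, spec$motif)
        motif_plants <- motif_plants + 1L
      }
    }
  }
  motif_db <- tibble(
    motif_id = c("M001", "M002", "M003"),
    rbp_name = c(spec$motif_rbp, "DECOY1", "DECOY2"),
    pattern = c(spec$motif, "ACGTAC", "GGGAGG"))

  ## plant SNPs and repeats in flanking introns ------------------------------
  introns_of <- function(ci) {
    row <- truth[ci, ]
    tx_exons <- ex_by_tx[[row$transcript_id]] |> arrange(.data$exon_index)
    .gen_introns(tx_exons, row$i, row$j)
  }
  both_introns <- vapply(seq_len(n_c), function(ci) {
    iv <- introns_of(ci); !is.null(iv$up) && !is.null(iv$down)
  }, TRUE)
  eligible <- which(both_introns)
  # one designated circ per gene to keep planted repeats attributable
  eligible <- eligible[!duplicated(truth$gene[eligible])]
  n_inv <- ceiling(length(eligible) * spec$repeat_pair_frac)
  inv_set <- eligible[seq_len(n_inv)]
  same_set <- setdiff(eligible, inv_set)

  rmsk_rows <- list()
  add_repeat <- function(chrom, start, end, strand, name) {
    rmsk_rows[[length(rmsk_rows) + 1L]] <<- tibble(
      genoName = chrom, genoStart = start - 1L, genoEnd = end,
      strand = strand, repName = name, repClass = "SINE",
      repFamily = if (startsWith(name, "Alu")) "Alu" else "L1")
  }
  place_in <- function(iv, w = 60L) {
    w <- min(w, iv[2] - iv[1] + 1L)
    s <- iv[1] + max(0L, floor((iv[2] - iv[1] + 1L - w) / 2))
    c(s, s + w - 1L)
  }
  for (ci in inv_set) {
    row <- truth[ci, ]; iv <- introns_of(ci)
    ru <- place_in(iv$up); rd <- place_in(iv$down)
    add_repeat(row$chrom, ru[1], ru[2], "+", "AluSx")
    add_repeat(row$chrom, rd[1], rd[2], "-", "AluJb")
  }
  for (ci in same_set) {
    row <- truth[ci, ]; iv <- introns_of(ci)
    ru <- place_in(iv$up); rd <- place_in(iv$down)
    add_repeat(row$chrom, ru[1], ru[2], "+", "AluY")
    add_repeat(row$chrom, rd[1], rd[2], "+", "AluSq")
  }
  # non-Alu decoy repeat
  add_repeat(truth$chrom[1], 5L, 40L, "+", "L1MA4")
  rmsk <- bind_rows(rmsk_rows)

  # generator-side expectation: circs with >=1 inverted Alu pair across their
  # own flanking introns (brute force over planted repeats)
  has_pair <- vapply(seq_len(n_c), function(ci) {
    iv <- introns_of(ci)
    if (is.null(iv$up) || is.null(iv$down)) return(FALSE)
    inside <- function(interval) {
      rmsk$genoName == truth$chrom[ci] & startsWith(rmsk$repName, "Alu") &
        rmsk$genoStart + 1L <= interval[2] & rmsk$genoEnd >= interval[1]
    }
    up <- rmsk[inside(iv$up), ]; dn <- rmsk[inside(iv$down), ]
    any(outer(up$strand, dn$strand, "!="))
  }, TRUE)

  ## GWAS SNPs ---------------------------------------------------------------
  gwas_rows <- list()
  snp_truth <- list()
  snp_id <- 0L
  for (ci in head(eligible, 4)) {
    row <- truth[ci, ]; iv <- introns_of(ci)
    spots <- list(up = iv$up[1],                       # first intron base
                  down = iv$up[1] - 1L,                # just outside (exonic)
                  mid = iv$down[1] + (iv$down[2] - iv$down[1]) %/% 2L)
    traits <- c("Cardiac hypertrophy", "Cardiac hypertrophy", "Vascular stiffness")
    inside <- c(TRUE, FALSE, TRUE)
    side <- c("up", NA, "down")
    for (k in 1:3) {
      snp_id <- snp_id + 1L
      rs <- sprintf("rs%06d", snp_id)
      gwas_rows[[snp_id]] <- tibble(
        CHR_ID = sub("^chr", "", row$chrom), CHR_POS = spots[[k]],
        SNPS = rs, `DISEASE/TRAIT` = traits[k])
      if (inside[k]) {
        snp_truth[[length(snp_truth) + 1L]] <- tibble(
          circ_id = row$circ_id, side = side[k], name = rs)
      }
    }
  }
  # off-trait SNP inside an intron: must be excluded by the trait filter
  row <- truth[eligible[1], ]; iv <- introns_of(eligible[1])
  gwas_rows[[length(gwas_rows) + 1L]] <- tibble(
    CHR_ID = sub("^chr", "", row$chrom), CHR_POS = iv$up[1] + 5L,
    SNPS = "rs999999", `DISEASE/TRAIT` = "Standing height")
  gwas <- bind_rows(gwas_rows)
  snp_truth <- bind_rows(snp_truth)

  ## write genome + GTF ------------------------------------------------------
  genome_path <- p("genome.fa")
  fa <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(fa) <- names(seqs)
  Biostrings::writeXStringSet(fa, genome_path, width = 70L)

  gtf_path <- p("genes.gtf")
  gtf_lines <- unlist(lapply(split(exon_tbl, exon_tbl$gene_id), function(g) {
    attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";',
                       g$gene_id[1], g$transcript_id[1])
    c(sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
              g$chrom[1], min(g$start), max(g$end), g$strand[1], g$gene_id[1]),
      sprintf("%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom[1], min(g$start), max(g$end), g$strand[1], attr_tx),
      sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$start, g$end, g$strand, attr_tx))
  }), use.names = FALSE)
  writeLines(gtf_lines, gtf_path)

  ## write per-tool prediction files -----------------------------------------
  dialects <- default_dialects()[spec$tools]
  tool_files <- list()
  for (tool in spec$tools) {
    for (si in seq_along(samples)) {
      rec <- truth |>
        select(all_of(c("circ_id", "gene", "strand", "chrom",
                        "startUpBSE", "endDownBSE"))) |>
        mutate(count = counts[, si])
      dc <- decoys |> filter(.data$tool == !!tool)
      if (nrow(dc) > 0) {
        rec <- bind_rows(rec, dc |>
          select(all_of(c("circ_id", "gene", "strand", "chrom",
                          "startUpBSE", "endDownBSE"))) |>
          mutate(count = decoy_counts[dc$circ_id, si]))
      }
      if (tool %in% anti_tools && nrow(anti) > 0) {
        rec <- bind_rows(rec, anti |>
          select(all_of(c("circ_id", "gene", "strand", "chrom",
                          "startUpBSE", "endDownBSE"))) |>
          mutate(count = anti_counts[, si]))
      }
      fname <- sprintf("%s_%s.txt", tool, samples[si])
      write_dialect_file(rec, dialects[[tool]], p(fname))
      tool_files[[tool]] <- c(tool_files[[tool]], setNames(fname, samples[si]))
    }
  }

  ## auxiliary tables --------------------------------------------------------
  readr::write_tsv(design, p("design.tsv"))
  readr::write_tsv(motif_db, p("motifs.tsv"))
  readr::write_tsv(gwas, p("gwas.tsv"))
  readr::write_tsv(rmsk, p("rmsk.tsv"))
  readr::write_tsv(mirna_expr, p("mirna_expression.tsv"))
  mi <- Biostrings::BStringSet(mirnas$mature_seq)
  names(mi) <- mirnas$mirna_id
  Biostrings::writeXStringSet(mi, p("mirna.fa"))

  ## chain files -------------------------------------------------------------
  chain_paths <- write_fixture_chains(spec$chroms, chrom_len, outdir)

  ## config ------------------------------------------------------------------
  config <- list(
    genome = "genome.fa", gtf = "genes.gtf", design = "design.tsv",
    tools = lapply(setNames(spec$tools, spec$tools), function(tool) {
      list(dialect = tool,
           files = as.list(setNames(sprintf("%s_%s.txt", tool, samples), samples)))
    }),
    motif_db = "motifs.tsv", mirna_fasta = "mirna.fa",
    mirna_expression = "mirna_expression.tsv",
    gwas = "gwas.tsv", rmsk = "rmsk.tsv",
    chain = basename(chain_paths[["shift"]]),
    traits = "cardiac|vascular",
    seed = spec$seed
  )
  yaml::write_yaml(config, p("config.yml"))

  ## manifest ----------------------------------------------------------------
  merged_truth <- bind_rows(
    truth |> mutate(n_tools = length(spec$tools),
                    total = as.integer(rowSums(counts)) * length(spec$tools)),
    decoys |> mutate(n_tools = 1L,
                     total = as.integer(rowSums(decoy_counts))[match(.data$circ_id, rownames(decoy_counts))]),
    anti |> mutate(n_tools = length(anti_tools),
                   total = as.integer(rowSums(anti_counts)) * length(anti_tools))
  ) |> select(all_of(c("circ_id", "gene", "strand", "chrom", "startUpBSE",
                       "endDownBSE", "n_tools", "total")))

  manifest <- list(
    spec = unclass(spec),
    samples = samples,
    design = design,
    # paths are relative to the fixture directory so rebuilding the same spec
    # anywhere yields byte-identical files
    paths = c(list(genome = "genome.fa", gtf = "genes.gtf", config = "config.yml",
                   design = "design.tsv", motif_db = "motifs.tsv",
                   gwas = "gwas.tsv", rmsk = "rmsk.tsv",
                   mirna_fasta = "mirna.fa",
                   mirna_expression = "mirna_expression.tsv"),
              as.list(vapply(chain_paths, basename, ""))),
    tool_files = tool_files,
    truth = list(
      circs = truth |> select(-"transcript_id", -"i", -"j"),
      counts = as_tibble(counts, rownames = "circ_id"),
      de = tibble(circ_id = truth$circ_id, log2FC = lfc)[lfc != 0, ],
      antisense = anti$circ_id,
      decoys = decoys |> select(all_of(c("tool", "circ_id"))),
      merged = merged_truth,
      mirna_sites = planted_sites,
      repeat_pair_circs = truth$circ_id[has_pair],
      repeat_pair_fraction = mean(has_pair),
      snps = snp_truth,
      motif = spec$motif,
      motif_plants = motif_plants
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write canonical records in a tool dialect (fixture support)
#'
#' Inverse of [parse_tool_output()] for the built-in dialects: converts
#' canonical 1-based inclusive transcription-order coordinates back to the
#' dialect's base and end convention and lays the fields out per its
#' column_map, padding unmapped columns with `"."`.
#'
#' @param records tibble with circ_id, gene, strand, chrom, startUpBSE,
#'   endDownBSE, count.
#' @param dialect a [tool_dialect()] with integer or (if `header`) character
#'   column references.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dialect_file <- function(records, dialect, path) {
  lo <- pmin(records$startUpBSE, records$endDownBSE)
  hi <- pmax(records$startUpBSE, records$endDownBSE)
  start_raw <- lo - (dialect$coordinate_base == 0L)
  end_raw <- hi - (dialect$coordinate_base == 0L) +
    (dialect$end_convention == "half_open")
  vals <- list(chrom = records$chrom, strand = records$strand,
               start = start_raw, end = end_raw,
               count = records$count, gene = records$gene)

  cm <- dialect$column_map
  if (dialect$header) {
    nm <- vapply(cm, as.character, "")
    df <- as.data.frame(vals[names(cm)])
    names(df) <- nm
    delim <- dialect$delim %||% "\t"
    readr::write_delim(df, path, delim = delim)
  } else {
    idx <- vapply(cm, as.integer, 1L)
    ncol <- max(idx)
    m <- matrix(".", nrow(records), ncol)
    for (k in names(cm)) m[, idx[[k]]] <- as.character(vals[[k]])
    delim <- if (is.null(dialect$delim)) " " else dialect$delim
    writeLines(apply(m, 1, paste, collapse = delim), path)
  }
  invisible(path)
}

#' Write the fixture's chain files
#'
#' Four plans per genome: identity (every position maps to itself), shift
#' (renamed chromosomes, +1000 offset), inversion (query strand `-`), and
#' partial (two aligned blocks with target and query gaps). Inverse chains are
#' written for shift and inversion so round-trip lifting is testable.
#'
#' @param chroms chromosome names.
#' @param chrom_len named lengths.
#' @param outdir output directory.
#' @return named character vector of file paths.
#' @export
write_fixture_chains <- function(chroms, chrom_len, outdir) {
  mk <- function(score, tName, tSize, tStart, tEnd, qName, qSize, qStrand,
                 qStart, qEnd, id, blocks) {
    tibble(score = score, tName = tName, tSize = as.integer(tSize),
           tStrand = "+", tStart = as.integer(tStart), tEnd = as.integer(tEnd),
           qName = qName, qSize = as.integer(qSize), qStrand = qStrand,
           qStart = as.integer(qStart), qEnd = as.integer(qEnd),
           chain_id = id, blocks = list(blocks))
  }
  one_block <- function(n) tibble(size = as.integer(n), dt = NA_integer_, dq = NA_integer_)

  paths <- c()
  ident <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    mk(1000, cc, n, 0, n, cc, n, "+", 0, n, paste0("id_", cc), one_block(n))
  }))
  paths["identity"] <- file.path(outdir, "identity.chain")
  write_chain(ident, paths["identity"])

  off <- 1000L
  shift <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    mk(900, cc, n, 0, n, paste0("m", cc), n + 2L * off, "+", off, off + n,
       paste0("sh_", cc), one_block(n))
  }))
  paths["shift"] <- file.path(outdir, "shift.chain")
  write_chain(shift, paths["shift"])
  shift_inv <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    mk(900, paste0("m", cc), n + 2L * off, off, off + n, cc, n, "+", 0, n,
       paste0("shi_", cc), one_block(n))
  }))
  paths["shift_inverse"] <- file.path(outdir, "shift_inverse.chain")
  write_chain(shift_inv, paths["shift_inverse"])

  invs <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    mk(800, cc, n, 0, n, paste0("i", cc), n, "-", 0, n,
       paste0("inv_", cc), one_block(n))
  }))
  paths["inversion"] <- file.path(outdir, "inversion.chain")
  write_chain(invs, paths["inversion"])
  invs_inv <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    mk(800, paste0("i", cc), n, 0, n, cc, n, "-", 0, n,
       paste0("invi_", cc), one_block(n))
  }))
  paths["inversion_inverse"] <- file.path(outdir, "inversion_inverse.chain")
  write_chain(invs_inv, paths["inversion_inverse"])

  partial <- bind_rows(lapply(chroms, function(cc) {
    n <- chrom_len[cc]
    b1 <- as.integer(floor(n * 0.3)); gap_t <- 200L; gap_q <- 50L
    b2 <- as.integer(n - b1 - gap_t - 1000L)
    blocks <- tibble(size = c(b1, b2),
                     dt = c(gap_t, NA_integer_), dq = c(gap_q, NA_integer_))
    qspan <- b1 + gap_q + b2
    mk(700, cc, n, 0, b1 + gap_t + b2, paste0("p", cc), qspan + 500L, "+",
       100, 100 + qspan, paste0("part_", cc), blocks)
  }))
  paths["partial"] <- file.path(outdir, "partial.chain")
  write_chain(partial, paths["partial"])
  paths
}

#' Generate a random chain with gapped blocks (test support)
#'
#' Builds one alignment chain whose block structure is drawn at random:
#' alternating aligned blocks and target/query gaps across a `tsize`-base
#' target chromosome. Invariants hold by construction.
#'
#' @param seed RNG seed.
#' @param tname,qname chromosome names.
#' @param tsize target chromosome size.
#' @param qstrand `"+"` or `"-"`.
#' @param n_blocks number of aligned blocks.
#' @return a one-row chain tibble (same shape as [parse_chain()]).
#' @export
random_chain <- function(seed, tname = "chrT", qname = "chrQ", tsize = 10000L,
                         qstrand = "+", n_blocks = 8L) {
  with_seed(seed, {
    sizes <- .runif_int(n_blocks, c(50L, 800L))
    dts <- .runif_int(n_blocks - 1L, c(0L, 300L))
    dqs <- .runif_int(n_blocks - 1L, c(0L, 300L))
    tstart <- .runif_int(1, c(0L, 200L))
    tspan <- sum(sizes) + sum(dts)
    if (tstart + tspan > tsize) tsize <- as.integer(tstart + tspan + 100L)
    qstart <- .runif_int(1, c(0L, 200L))
    qspan <- sum(sizes) + sum(dqs)
    qsize <- as.integer(qstart + qspan + .runif_int(1, c(50L, 500L)))
    tibble(score = 1000, tName = tname, tSize = as.integer(tsize), tStrand = "+",
           tStart = tstart, tEnd = as.integer(tstart + tspan),
           qName = qname, qSize = qsize, qStrand = qstrand,
           qStart = qstart, qEnd = as.integer(qstart + qspan),
           chain_id = paste0("rnd", seed),
           blocks = list(tibble(size = sizes,
                                dt = c(dts, NA_integer_), dq = c(dqs, NA_integer_))))
  })
}

#' Simulate NB count matrices with planted fold changes (test support)
#'
#' @param n_circs rows.
#' @param design experiment design tibble (two conditions).
#' @param mu mean count (scalar or per-row) in the first condition.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param de tibble(row, log2FC) of planted effects applied to the second
#'   condition (empty for a null matrix).
#' @param seed RNG seed.
#' @return count matrix tibble (circ_id + samples) with the design attached.
#' @export
simulate_nb_counts <- function(n_circs, design, mu = 100, dispersion = 0.2,
                               de = tibble(row = integer(), log2FC = numeric()),
                               seed = 1L) {
  with_seed(seed, {
    conds <- unique(design$condition)
    mu <- rep_len(mu, n_circs)
    lfc <- rep(0, n_circs)
    if (nrow(de) > 0) lfc[de$row] <- de$log2FC
    m <- sapply(seq_len(nrow(design)), function(si) {
      mm <- if (design$condition[si] == conds[2]) mu * 2^lfc else mu
      rnbinom(n_circs, mu = mm, size = 1 / dispersion)
    })
    colnames(m) <- design$sample
    out <- bind_cols(tibble(circ_id = sprintf("circ%05d", seq_len(n_circs))),
                     as_tibble(m))
    attr(out, "design") <- design
    out
  })
}

#' Simulate foreground/background sequence sets with a planted motif
#'
#' Random sequences in which all chance occurrences of `motif` are removed and
#' exactly `fg_per_seq` (resp. `bg_per_seq`) copies are written at fixed
#' non-overlapping offsets, giving a foreground/background density ratio of
#' `fg_per_seq / bg_per_seq`.
#'
#' @param seed RNG seed.
#' @param n_fg,n_bg number of sequences per set.
#' @param len sequence length.
#' @param motif the planted pattern (plain ACGT).
#' @param fg_per_seq,bg_per_seq planted copies per sequence.
#' @return list(fg = tibble, bg = tibble) of linear sequence tibbles.
#' @export
simulate_motif_sets <- function(seed = 1L, n_fg = 150L, n_bg = 150L, len = 1000L,
                                motif = "TGCATG", fg_per_seq = 8L, bg_per_seq = 2L) {
  plen <- nchar(motif)
  with_seed(seed, {
    make_set <- function(n, copies, tag) {
      seqs <- character(n)
      for (i in seq_len(n)) {
        chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        s <- paste(chars, collapse = "")
        # erase chance occurrences (mutate the middle base), bounded loop
        for (pass in 1:20) {
          hits <- scan_motif(s, motif)
          if (length(hits) == 0) break
          for (h in hits) {
            mid <- h + plen %/% 2L
            cur <- str_sub(s, mid, mid)
            str_sub(s, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
        offs <- floor(seq(1L, len - plen + 1L, length.out = copies + 2L))
        offs <- offs[2:(copies + 1L)]
        for (o in offs) str_sub(s, o, o + plen - 1L) <- motif
        seqs[i] <- s
      }
      tibble(circ_id = sprintf("%s%04d", tag, seq_len(n)), seq_type = "window_up",
             sequence = seqs, length = len, circular = FALSE)
    }
    list(fg = make_set(n_fg, fg_per_seq, "fg"), bg = make_set(n_bg, bg_per_seq, "bg"))
  })
}
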