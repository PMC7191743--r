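# annotation of GWAS SNPs and repeats in BSJ-flanking regions; inverted
# repeat-pair detection in the flanking introns

#' Read a GWAS-catalog-style SNP table
#'
#' Expects the catalog export columns CHR_ID, CHR_POS, SNPS and DISEASE/TRAIT
#' (extra columns ignored). An optional trait regex keeps only associations
#' whose trait field matches (e.g. `"cardiac|vascular"`).
#'
#' @param path TSV path.
#' @param traits optional regex applied (case-insensitively) to DISEASE/TRAIT.
#' @param chrom_prefix prefix prepended to CHR_ID (default `"chr"`, set to
#'   `""` for unprefixed assemblies).
#' @return feature tibble: kind ("snp"), chrom, start, end, strand ("na"),
#'   name, family (the trait string).
#' @export
read_gwas_tsv <- function(path, traits = NULL, chrom_prefix = "chr") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("CHR_ID", "CHR_POS", "SNPS", "DISEASE/TRAIT"), "GWAS table")
  out <- tibble(
    kind = "snp",
    chrom = paste0(chrom_prefix, df$CHR_ID),
    start = as.integer(df$CHR_POS), end = as.integer(df$CHR_POS),
    strand = "na", name = df$SNPS, family = df[["DISEASE/TRAIT"]]
  )
  if (!is.null(traits)) {
    out <- out |> filter(str_detect(tolower(.data$family), tolower(traits)))
  }
  out
}

#' Read a RepeatMasker (UCSC rmsk) repeat table
#'
#' Expects genoName, genoStart (0-based), genoEnd, strand, repName, repClass,
#' repFamily; coordinates are converted to 1-based inclusive on load.
#'
#' @param path TSV path.
#' @return feature tibble: kind ("repeat"), chrom, start, end, strand, name
#'   (repName), family (repFamily).
#' @export
read_rmsk_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("genoName", "genoStart", "genoEnd", "strand", "repName",
                      "repClass", "repFamily"), "rmsk table")
  tibble(kind = "repeat", chrom = df$genoName,
         start = as.integer(df$genoStart) + 1L, end = as.integer(df$genoEnd),
         strand = df$strand, name = df$repName, family = df$repFamily)
}

# genomic flank intervals per circ and side for a region definition
.flank_intervals <- function(annotated, region = "introns",
                             intron_nt = 200L, exon_nt = 10L) {
  ann <- annotated[annotated$matched, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    ex <- r$exons[[1]]
    for (side in c("up", "down")) {
      istart <- if (side == "up") r$intron_up_start else r$intron_down_start
      iend <- if (side == "up") r$intron_up_end else r$intron_down_end
      if (is.na(istart)) next
      if (region == "introns") {
        lo <- istart; hi <- iend
      } else {
        # window: intron_nt of intron nearest the BSJ plus exon_nt of the BSE
        bse <- if (side == "up") ex[1, ] else ex[nrow(ex), ]
        junction_at_low_end <- (r$strand == "+") == (side == "up")
        if (junction_at_low_end) {
          lo <- max(istart, iend - intron_nt + 1L)
          hi <- min(bse$end, bse$start + exon_nt - 1L)
        } else {
          hi <- min(iend, istart + intron_nt - 1L)
          lo <- max(bse$start, bse$end - exon_nt + 1L)
        }
      }
      rows[[length(rows) + 1]] <- tibble(circ_id = r$circ_id, side = side,
                                         chrom = r$chrom, start = lo, end = hi)
    }
  }
  if (length(rows) == 0) {
    return(tibble(circ_id = character(), side = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  list_rbind(rows)
}

#' Annotate features in BSJ-flanking regions
#'
#' Assigns every feature whose interval overlaps a flank interval by at least
#' one base (inclusive boundaries) to that circ/side. Flanks are either the
#' full flanking introns or the biogenesis window around each junction side
#' (`intron_nt` intronic + `exon_nt` exonic nt, both anchored at the BSJ).
#'
#' @param annotated output of [annotate_circs()].
#' @param features feature tibble ([read_gwas_tsv()], [read_rmsk_tsv()], or
#'   both bound together).
#' @param region `"introns"` or `"window"`.
#' @param intron_nt,exon_nt window composition when `region = "window"`.
#' @return tibble circ_id, side, kind, name, family, start, end, strand.
#' @export
annotate_flanks <- function(annotated, features, region = c("introns", "window"),
                            intron_nt = 200L, exon_nt = 10L) {
  region <- match.arg(region)
  check_columns(features, c("kind", "chrom", "start", "end", "strand", "name", "family"),
                "features")
  fl <- .flank_intervals(annotated, region, intron_nt, exon_nt)
  if (nrow(fl) == 0 || nrow(features) == 0) {
    return(tibble(circ_id = character(), side = character(), kind = character(),
                  name = character(), family = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  q <- GenomicRanges::GRanges(fl$chrom, IRanges::IRanges(fl$start, fl$end))
  s <- GenomicRanges::GRanges(features$chrom, IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tibble(circ_id = fl$circ_id[qi], side = fl$side[qi],
         kind = features$kind[si], name = features$name[si],
         family = features$family[si], start = features$start[si],
         end = features$end[si], strand = features$strand[si]) |>
    distinct() |>
    arrange(.data$circ_id, .data$side, .data$start)
}

#' Complementary (inverted) repeat pairs across the two flanking introns
#'
#' For each circ, pairs every repeat in the upstream flank with every repeat in
#' the downstream flank where both satisfy the family predicate and the two
#' copies lie on opposite strands — the configuration whose base pairing is a
#' known driver of back-splicing. A circ "contains complementary repeats" iff
#' it has at least one such pair.
#'
#' @param flank_features output of [annotate_flanks()] (repeat rows are used).
#' @param family_predicate function(name, family) -> logical; default: repeat
#'   name starts with "Alu".
#' @return list with `pairs` (circ_id, name_up, strand_up, name_down,
#'   strand_down) and `summary` (circ_id, n_pairs, has_complementary_pair).
#' @export
complementary_pairs <- function(flank_features,
                                family_predicate = function(name, family) {
                                  startsWith(name, "Alu")
                                }) {
  reps <- flank_features |>
    filter(.data$kind == "repeat",
           family_predicate(.data$name, .data$family),
           .data$strand %in% c("+", "-"))
  pair_rows <- list()
  for (id in unique(reps$circ_id)) {
    up <- reps |> filter(.data$circ_id == id, .data$side == "up")
    dn <- reps |> filter(.data$circ_id == id, .data$side == "down")
    if (nrow(up) == 0 || nrow(dn) == 0) next
    grid <- tidyr::expand_grid(u = seq_len(nrow(up)), d = seq_len(nrow(dn)))
    grid <- grid |> filter(up$strand[.data$u] != dn$strand[.data$d])
    if (nrow(grid) == 0) next
    pair_rows[[length(pair_rows) + 1]] <- tibble(
      circ_id = id,
      name_up = up$name[grid$u], strand_up = up$strand[grid$u],
      name_down = dn$name[grid$d], strand_down = dn$strand[grid$d])
  }
  pairs <- if (length(pair_rows) == 0) {
    tibble(circ_id = character(), name_up = character(), strand_up = character(),
           name_down = character(), strand_down = character())
  } else list_rbind(pair_rows)
  summary <- flank_features |>
    distinct(.data$circ_id) |>
    left_join(pairs |> count(.data$circ_id, name = "n_pairs"), by = "circ_id") |>
    mutate(n_pairs = ifelse(is.na(.data$n_pairs), 0L, .data$n_pairs),
           has_complementary_pair = .data$n_pairs > 0)
  list(pairs = pairs, summary = summary)
}

#' Per-circ summary of flank annotation
#'
#' @param flank_features output of [annotate_flanks()].
#' @param pairs output of [complementary_pairs()].
#' @return tibble circ_id, n_snps, n_repeats, has_complementary_pair.
#' @export
summarize_flanks <- function(flank_features, pairs = complementary_pairs(flank_features)) {
  base <- flank_features |>
    group_by(.data$circ_id) |>
    summarise(n_snps = sum(.data$kind == "snp"),
              n_repeats = sum(.data$kind == "repeat"), .groups = "drop")
  base |>
    left_join(pairs$summary |> select(all_of(c("circ_id", "has_complementary_pair"))),
              by = "circ_id") |>
    mutate(has_complementary_pair = ifelse(is.na(.data$has_complementary_pair),
                                           FALSE, .data$has_complementary_pair))
}
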