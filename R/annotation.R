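# gene-model loading and exon-level annotation of back-splice junctions

#' Build a gene model from an exon table
#'
#' Used by [load_gtf()] and by the fixture generator. Exons are indexed in
#' transcription order (index 1 = 5'-most exon, i.e. descending genomic
#' coordinate on `-` transcripts).
#'
#' @param exons tibble with columns gene_id, transcript_id, chrom, strand,
#'   start, end (1-based inclusive genomic).
#' @return object of class `gene_model`: a list with tibbles `genes`
#'   (gene_id, chrom, strand) and `exons` (input columns plus `exon_index`).
#' @export
gene_model <- function(exons) {
  check_columns(exons, c("gene_id", "transcript_id", "chrom", "strand", "start", "end"),
                "exon table")
  exons <- exons |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    group_by(.data$transcript_id) |>
    mutate(exon_index = if (first(.data$strand) == "+") rank(.data$start)
           else rank(-.data$start)) |>
    mutate(exon_index = as.integer(.data$exon_index)) |>
    arrange(.data$exon_index, .by_group = TRUE) |>
    ungroup()

  overlap_bad <- exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start[-1] <= head(.data$end, -1)), .groups = "drop") |>
    filter(.data$bad)
  if (nrow(overlap_bad) > 0) {
    abort(sprintf("overlapping exons within transcript(s): %s",
                  paste(overlap_bad$transcript_id, collapse = ", ")))
  }

  genes <- exons |> distinct(.data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(genes$gene_id)) {
    warn("gene(s) with inconsistent chrom/strand across exons; first occurrence kept")
    genes <- genes |> distinct(.data$gene_id, .keep_all = TRUE)
  }
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' Load a gene model from a GTF file
#'
#' Exon features are grouped per transcript and sorted into transcription
#' order. Transcript features without any exon are dropped with a warning.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes
#'   (Ensembl/GENCODE style).
#' @return a `gene_model` (see [gene_model()]).
#' @export
load_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(meta))) {
    abort(sprintf("%s: GTF lacks gene_id/transcript_id attributes", path))
  }
  ex <- meta[meta$type == "exon", , drop = FALSE]
  tx_declared <- unique(meta$transcript_id[meta$type == "transcript"])
  tx_declared <- tx_declared[!is.na(tx_declared)]
  orphans <- setdiff(tx_declared, unique(ex$transcript_id))
  if (length(orphans) > 0) {
    warn(sprintf("dropped %d transcript(s) with zero exons: %s",
                 length(orphans), paste(orphans, collapse = ", ")))
  }
  if (nrow(ex) == 0) abort(sprintf("%s: no exon features", path))
  gene_model(tibble(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = ex$start, end = ex$end
  ))
}

# transcribed start/end of exons given strand
.t_start <- function(strand, start, end) if (strand == "+") start else end
.t_end <- function(strand, start, end) if (strand == "+") end else start

# genomic gap between two exons of one transcript: c(start, end) or NULL
.gap_between <- function(e1, e2) {
  lo <- min(e1$end, e2$end) + 1L
  hi <- max(e1$start, e2$start) - 1L
  if (hi < lo) return(NULL)
  c(lo, hi)
}

#' Annotate BSJ records with exon composition and flanking introns
#'
#' For each junction, finds a transcript in which `startUpBSE` coincides with
#' the transcribed start of some exon i and `endDownBSE` with the transcribed
#' end of some exon j >= i (exact boundary match by default; `tolerance` allows
#' a +/- k nt slack). Internal exons are i..j; the flanking introns are the
#' introns adjacent to exon i and exon j in the chosen transcript. When several
#' transcripts qualify, the one with the most exons wins, ties broken by
#' longest genomic span, then lexicographic transcript id. Records that match
#' no transcript are returned with `matched = FALSE` and the nearest exon
#' boundary distance; sequence-based stages exclude them.
#'
#' @param bsj BSJ tibble (antisense records should be excluded beforehand).
#' @param model a `gene_model`.
#' @param tolerance maximum boundary mismatch in nt (default 0, exact).
#' @return tibble with one row per input record: circ_id, gene, strand, chrom,
#'   startUpBSE, endDownBSE, matched, transcript_used, n_exons, len_exonic,
#'   intron_up_start/end, intron_down_start/end, len_intron_up, len_intron_down,
#'   nearest_dist, and a list-column `exons` (internal exons, genomic
#'   coordinates, transcription order).
#' @export
annotate_circs <- function(bsj, model, tolerance = 0L) {
  check_columns(bsj, BSJ_KEY, "bsj")
  ex_by_tx <- split(model$exons, model$exons$transcript_id)
  tx_gene <- model$exons |> distinct(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand)

  annotate_one <- function(circ_id, gene, strand, chrom, startUpBSE, endDownBSE) {
    cands <- tx_gene |>
      filter(.data$chrom == !!chrom, .data$strand == !!strand)
    if (gene != ".") cands <- cands |> filter(.data$gene_id == gene)

    best <- NULL
    nearest <- Inf   # smallest tolerance that would match some transcript
    for (tx in cands$transcript_id) {
      e <- ex_by_tx[[tx]] |> arrange(.data$exon_index)
      ts <- vapply(seq_len(nrow(e)), function(k) .t_start(strand, e$start[k], e$end[k]), 1L)
      te <- vapply(seq_len(nrow(e)), function(k) .t_end(strand, e$start[k], e$end[k]), 1L)
      nearest <- min(nearest,
                     max(min(abs(ts - startUpBSE)), min(abs(te - endDownBSE))))
      i <- which(abs(ts - startUpBSE) <= tolerance)
      j <- which(abs(te - endDownBSE) <= tolerance)
      if (length(i) == 0 || length(j) == 0) next
      i <- min(i)
      j <- j[j >= i]
      if (length(j) == 0) next
      j <- max(j)
      span <- max(e$end) - min(e$start) + 1L
      cand <- list(tx = tx, e = e, i = i, j = j, n_tx_exons = nrow(e), span = span)
      if (is.null(best) ||
          cand$n_tx_exons > best$n_tx_exons ||
          (cand$n_tx_exons == best$n_tx_exons && cand$span > best$span) ||
          (cand$n_tx_exons == best$n_tx_exons && cand$span == best$span && cand$tx < best$tx)) {
        best <- cand
      }
    }

    base <- tibble(circ_id = circ_id, gene = gene, strand = strand, chrom = chrom,
                   startUpBSE = startUpBSE, endDownBSE = endDownBSE)
    if (is.null(best)) {
      return(base |> mutate(
        matched = FALSE, transcript_used = NA_character_, n_exons = NA_integer_,
        len_exonic = NA_integer_,
        intron_up_start = NA_integer_, intron_up_end = NA_integer_,
        intron_down_start = NA_integer_, intron_down_end = NA_integer_,
        len_intron_up = NA_integer_, len_intron_down = NA_integer_,
        nearest_dist = if (is.finite(nearest)) as.integer(nearest) else NA_integer_,
        exons = list(tibble(start = integer(), end = integer()))
      ))
    }

    e <- best$e
    internal <- e[best$i:best$j, c("start", "end")]
    gap_up <- if (best$i > 1) .gap_between(e[best$i - 1, ], e[best$i, ]) else NULL
    gap_dn <- if (best$j < nrow(e)) .gap_between(e[best$j, ], e[best$j + 1, ]) else NULL
    base |> mutate(
      matched = TRUE, transcript_used = best$tx,
      n_exons = best$j - best$i + 1L,
      len_exonic = as.integer(sum(internal$end - internal$start + 1L)),
      intron_up_start = if (is.null(gap_up)) NA_integer_ else gap_up[1],
      intron_up_end = if (is.null(gap_up)) NA_integer_ else gap_up[2],
      intron_down_start = if (is.null(gap_dn)) NA_integer_ else gap_dn[1],
      intron_down_end = if (is.null(gap_dn)) NA_integer_ else gap_dn[2],
      len_intron_up = if (is.null(gap_up)) NA_integer_ else gap_up[2] - gap_up[1] + 1L,
      len_intron_down = if (is.null(gap_dn)) NA_integer_ else gap_dn[2] - gap_dn[1] + 1L,
      nearest_dist = 0L,
      exons = list(as_tibble(internal))
    )
  }

  bsj |>
    select(all_of(BSJ_KEY)) |>
    pmap(annotate_one) |>
    list_rbind()
}

#' Number of distinct circRNAs per host gene
#'
#' @param annotated output of [annotate_circs()] (or any BSJ tibble with a
#'   `gene` column).
#' @return tibble gene, n_circs, sorted by decreasing count.
#' @export
circs_per_gene <- function(annotated) {
  check_columns(annotated, "gene", "annotated circs")
  annotated |>
    count(.data$gene, name = "n_circs") |>
    arrange(desc(.data$n_circs), .data$gene)
}

#' Write the annotation table
#'
#' @param annotated output of [annotate_circs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotated, path) {
  readr::write_tsv(annotated |> select(-"exons"), path)
  invisible(path)
}
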