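# background set of random back-spliced exon pairs drawn from the annotation

#' Generate random back-splice junctions from a gene model
#'
#' Draws a transcript uniformly, then an exon pair i <= j uniformly from its
#' exons, and forms the junction from exon i's transcribed start to exon j's
#' transcribed end — so every generated record matches annotated exon
#' boundaries exactly and is a valid input to every downstream stage.
#' Members of `exclude` (observed circRNAs) and duplicates are rejected and
#' redrawn. Deterministic given `seed`.
#'
#' @param model a `gene_model`.
#' @param n number of records to generate.
#' @param exclude character vector of circ_ids never to emit.
#' @param seed integer RNG seed.
#' @return BSJ tibble (circ_id, gene, strand, chrom, startUpBSE, endDownBSE,
#'   n_tools = 0, source = "random").
#' @export
generate_random_bsjs <- function(model, n, exclude = character(), seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  ex_sorted <- model$exons |> arrange(.data$transcript_id, .data$exon_index)
  ex_by_tx <- split(ex_sorted, ex_sorted$transcript_id)
  tx_ids <- names(ex_by_tx)
  tx_meta <- model$exons |> distinct(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand)
  meta_by_tx <- split(tx_meta, tx_meta$transcript_id)

  with_seed(seed, {
    seen <- character()
    rows <- vector("list", n)
    got <- 0L
    attempts <- 0L
    max_attempts <- n * 1000L
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf("could not generate %d distinct random BSJs in %d attempts; annotation too small",
                      n, max_attempts))
      }
      tx <- tx_ids[sample.int(length(tx_ids), 1)]
      e <- ex_by_tx[[tx]]
      ne <- nrow(e)
      # uniform over the ne*(ne+1)/2 ordered pairs i <= j
      pk <- sample.int(ne * (ne + 1L) / 2L, 1L)
      i <- 1L
      while (pk > ne - i + 1L) { pk <- pk - (ne - i + 1L); i <- i + 1L }
      j <- i + pk - 1L
      m <- meta_by_tx[[tx]]
      su <- .t_start(m$strand, e$start[i], e$end[i])
      ed <- .t_end(m$strand, e$start[j], e$end[j])
      id <- make_circ_id(m$gene_id, m$strand, m$chrom, su, ed)
      if (id %in% exclude || id %in% seen) next
      seen <- c(seen, id)
      got <- got + 1L
      rows[[got]] <- tibble(circ_id = id, gene = m$gene_id, strand = m$strand,
                            chrom = m$chrom, startUpBSE = su, endDownBSE = ed)
    }
    bind_rows(rows) |> mutate(n_tools = 0L, source = "random")
  })
}
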