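# retrieval of circular-topology sequences from the genome FASTA
#
# All sequences are returned 5'->3' in transcript orientation (minus-strand
# records are reverse-complemented), as DNA (T, not U); an RNA conversion is
# offered at FASTA export only.

#' Load a genome FASTA
#'
#' Soft-masked (lowercase) bases are uppercased; masking is not preserved.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet] (names truncated at whitespace).
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

# slice [start, end] (1-based inclusive) of a chromosome, plus strand
.slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) abort(sprintf("chromosome '%s' not in genome", chrom))
  if (start < 1 || end > length(genome[[chrom]])) {
    abort(sprintf("interval %s:%d-%d exceeds contig bounds", chrom, start, end))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

# slice in transcript orientation (revcomp on '-')
.slice_tx <- function(genome, chrom, start, end, strand) {
  s <- .slice(genome, chrom, start, end)
  if (strand == "-") revcomp(s) else s
}

.seq_row <- function(circ_id, seq_type, sequence, circular = FALSE) {
  tibble(circ_id = circ_id, seq_type = seq_type, sequence = sequence,
         length = nchar(sequence), circular = circular)
}

#' Extract internal circRNA sequences
#'
#' Concatenates the internal exon sequences in transcription order; the result
#' reads 5'->3' around the circle and is flagged circular.
#'
#' @param annotated output of [annotate_circs()]; unmatched records are skipped
#'   with a warning.
#' @param genome a genome from [load_genome()].
#' @return sequence tibble: circ_id, seq_type ("internal"), sequence, length,
#'   circular.
#' @export
extract_internal <- function(annotated, genome) {
  ok <- annotated$matched
  if (any(!ok)) {
    warn(sprintf("%d unmatched record(s) skipped in sequence extraction", sum(!ok)))
  }
  ann <- annotated[ok, , drop = FALSE]
  rows <- pmap(
    list(ann$circ_id, ann$chrom, ann$strand, ann$exons),
    function(id, chrom, strand, exons) {
      parts <- vapply(seq_len(nrow(exons)), function(k) {
        .slice_tx(genome, chrom, exons$start[k], exons$end[k], strand)
      }, "")
      .seq_row(id, "internal", paste(parts, collapse = ""), circular = TRUE)
    })
  list_rbind(rows)
}

#' Extract the sequence reading through the back-splice junction
#'
#' The last `w` nt of the internal sequence joined to its first `w` nt — the
#' junction as seen on the circle. When the circle is shorter than `w`, each
#' side is truncated to the full sequence.
#'
#' @param internal sequence tibble from [extract_internal()].
#' @param w nucleotides per side (default 11).
#' @return sequence tibble with seq_type "across_bsj" (linear).
#' @export
extract_across_bsj <- function(internal, w = 11L) {
  stopifnot(all(internal$seq_type == "internal"))
  rows <- pmap(list(internal$circ_id, internal$sequence), function(id, s) {
    len <- nchar(s)
    k <- min(w, len)
    .seq_row(id, "across_bsj",
             paste0(str_sub(s, len - k + 1, len), str_sub(s, 1, k)))
  })
  list_rbind(rows)
}

#' Extract sequences flanking the back-splice junction
#'
#' Three region definitions:
#' * `introns`: the full flanking introns (`flank_intron_up`/`_down`);
#' * `window`: per junction side, `intron_nt` nt of the intron adjacent to the
#'   BSJ joined to `exon_nt` nt of the back-spliced exon adjacent to the BSJ
#'   (`window_up` = intron tail + exon head, `window_down` = exon tail +
#'   intron head), clipped at feature boundaries with a warning;
#' * `bse`: the full upstream and downstream back-spliced exons.
#'
#' A side whose flanking intron does not exist (first/last exon) is omitted
#' with a warning in `introns`/`window` mode.
#'
#' @param annotated output of [annotate_circs()].
#' @param genome genome from [load_genome()].
#' @param mode one of `"introns"`, `"window"`, `"bse"`.
#' @param intron_nt,exon_nt window composition (defaults 200 and 10 nt).
#' @return sequence tibble (one row per circ and side; all linear, 5'->3' in
#'   transcript orientation).
#' @export
extract_flanks <- function(annotated, genome, mode = c("introns", "window", "bse"),
                           intron_nt = 200L, exon_nt = 10L) {
  mode <- match.arg(mode)
  ann <- annotated[annotated$matched, , drop = FALSE]
  clipped <- 0L
  missing_side <- 0L

  # transcript-oriented sub-slice helpers: head = first n transcribed bases
  tx_head <- function(chrom, start, end, strand, n) {
    n <- min(n, end - start + 1L)
    if (strand == "+") .slice_tx(genome, chrom, start, start + n - 1L, strand)
    else .slice_tx(genome, chrom, end - n + 1L, end, strand)
  }
  tx_tail <- function(chrom, start, end, strand, n) {
    n <- min(n, end - start + 1L)
    if (strand == "+") .slice_tx(genome, chrom, end - n + 1L, end, strand)
    else .slice_tx(genome, chrom, start, start + n - 1L, strand)
  }

  rows <- list()
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    ex <- r$exons[[1]]
    up_exon <- ex[1, ]                       # upstream back-spliced exon
    dn_exon <- ex[nrow(ex), ]                # downstream back-spliced exon
    has_up <- !is.na(r$intron_up_start)
    has_dn <- !is.na(r$intron_down_start)

    if (mode == "bse") {
      rows <- c(rows, list(
        .seq_row(r$circ_id, "bse_up",
                 .slice_tx(genome, r$chrom, up_exon$start, up_exon$end, r$strand)),
        .seq_row(r$circ_id, "bse_down",
                 .slice_tx(genome, r$chrom, dn_exon$start, dn_exon$end, r$strand))
      ))
      next
    }
    if (mode == "introns") {
      if (has_up) {
        rows <- c(rows, list(.seq_row(r$circ_id, "flank_intron_up",
          .slice_tx(genome, r$chrom, r$intron_up_start, r$intron_up_end, r$strand))))
      } else missing_side <- missing_side + 1L
      if (has_dn) {
        rows <- c(rows, list(.seq_row(r$circ_id, "flank_intron_down",
          .slice_tx(genome, r$chrom, r$intron_down_start, r$intron_down_end, r$strand))))
      } else missing_side <- missing_side + 1L
      next
    }
    # mode == "window": both segments anchored at the BSJ
    if (has_up) {
      ilen <- r$intron_up_end - r$intron_up_start + 1L
      if (ilen < intron_nt) clipped <- clipped + 1L
      intron_part <- tx_tail(r$chrom, r$intron_up_start, r$intron_up_end, r$strand, intron_nt)
      exon_part <- tx_head(r$chrom, up_exon$start, up_exon$end, r$strand, exon_nt)
      rows <- c(rows, list(.seq_row(r$circ_id, "window_up",
                                    paste0(intron_part, exon_part))))
    } else missing_side <- missing_side + 1L
    if (has_dn) {
      ilen <- r$intron_down_end - r$intron_down_start + 1L
      if (ilen < intron_nt) clipped <- clipped + 1L
      exon_part <- tx_tail(r$chrom, dn_exon$start, dn_exon$end, r$strand, exon_nt)
      intron_part <- tx_head(r$chrom, r$intron_down_start, r$intron_down_end, r$strand, intron_nt)
      rows <- c(rows, list(.seq_row(r$circ_id, "window_down",
                                    paste0(exon_part, intron_part))))
    } else missing_side <- missing_side + 1L
  }
  if (clipped > 0) warn(sprintf("%d window(s) clipped at a short flanking intron", clipped))
  if (missing_side > 0) {
    warn(sprintf("%d flank side(s) omitted (no flanking intron)", missing_side))
  }
  list_rbind(rows)
}

#' Write / read sequence tibbles as FASTA
#'
#' Headers are `<circ_id>|<seq_type>|<length>`. `rna = TRUE` converts T to U
#' for display; sequences are kept as DNA internally.
#'
#' @param seqs sequence tibble.
#' @param path FASTA path.
#' @param rna write as RNA alphabet?
#' @return `write_seq_fasta()` returns `path` invisibly; `read_seq_fasta()` a
#'   sequence tibble (circular flag restored from seq_type).
#' @export
write_seq_fasta <- function(seqs, path, rna = FALSE) {
  s <- seqs$sequence
  if (rna) s <- chartr("T", "U", s)
  x <- Biostrings::BStringSet(s)
  names(x) <- paste(seqs$circ_id, seqs$seq_type, seqs$length, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_seq_fasta
#' @export
read_seq_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- str_split(names(x), "\\|")
  n <- length(parts)
  tibble(
    circ_id = vapply(parts, function(p) paste(head(p, -2), collapse = "|"), ""),
    seq_type = vapply(parts, function(p) p[length(p) - 1], ""),
    sequence = unname(chartr("U", "T", as.character(x))),
    length = vapply(parts, function(p) as.integer(p[length(p)]), 1L),
    circular = vapply(parts, function(p) p[length(p) - 1] == "internal", TRUE)
  )
}
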