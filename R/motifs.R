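# IUPAC motif scanning and foreground/background enrichment

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Scan one sequence for an IUPAC motif
#'
#' Reports every 1-based start position where the degenerate pattern matches;
#' overlapping matches are all reported. For circular sequences the scan
#' extends over the sequence plus its first `nchar(pattern) - 1` nt, so a
#' match spanning the back-splice junction is found exactly once; start
#' positions still range over 1..length.
#'
#' @param sequence DNA string (A/C/G/T/N; upper case).
#' @param pattern IUPAC pattern (U accepted, treated as T).
#' @param circular does `sequence` close on itself?
#' @return integer vector of match start positions.
#' @export
#' @examples
#' scan_motif("TGCATGCATG", "TGCATG")   # overlapping matches at 1 and 5
scan_motif <- function(sequence, pattern, circular = FALSE) {
  pat <- toupper(pattern)
  pchars <- strsplit(pat, "")[[1]]
  bad <- setdiff(pchars, names(IUPAC_SETS))
  if (length(bad) > 0) abort(sprintf("invalid IUPAC character(s): %s", paste(bad, collapse = "")))
  plen <- length(pchars)
  len <- nchar(sequence)
  ext <- if (circular && len >= 1) paste0(sequence, str_sub(sequence, 1, plen - 1)) else sequence
  npos <- if (circular) len else len - plen + 1L
  if (npos < 1) return(integer())
  schars <- strsplit(ext, "")[[1]]
  ok <- rep(TRUE, npos)
  for (k in seq_len(plen)) {
    ok <- ok & schars[seq_len(npos) + k - 1L] %in% IUPAC_SETS[[pchars[k]]]
  }
  which(ok)
}

#' Read a motif table (ATtRACT-style TSV)
#'
#' Accepts either canonical columns (motif_id, rbp_name, pattern) or the
#' ATtRACT export columns (Gene_name, Motif). U is normalized to T; patterns
#' shorter than `min_len` are dropped with a warning.
#'
#' @param path TSV path.
#' @param min_len minimum pattern length (default 4).
#' @return tibble motif_id, rbp_name, pattern.
#' @export
read_motif_db <- function(path, min_len = 4L) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("Gene_name", "Motif") %in% names(df))) {
    df <- tibble(motif_id = paste0("m", seq_len(nrow(df))),
                 rbp_name = df$Gene_name, pattern = df$Motif)
  }
  check_columns(df, c("motif_id", "rbp_name", "pattern"), "motif table")
  df <- df |> mutate(pattern = chartr("U", "T", toupper(.data$pattern)))
  short <- nchar(df$pattern) < min_len
  if (any(short)) {
    warn(sprintf("dropped %d motif(s) shorter than %d nt", sum(short), min_len))
    df <- df[!short, , drop = FALSE]
  }
  df |> select(all_of(c("motif_id", "rbp_name", "pattern")))
}

# scanned start positions for a pattern length (vectorised over sequences)
.n_positions <- function(len, plen, circular) {
  ifelse(circular, pmax(len, 0L), pmax(len - plen + 1L, 0L))
}

#' Scan a sequence set for a motif table
#'
#' @param seqs sequence tibble (circ_id, seq_type, sequence, circular).
#' @param motifs motif tibble from [read_motif_db()].
#' @return tibble circ_id, seq_type, motif_id, rbp_name, pos (one row per
#'   match).
#' @export
scan_motifs <- function(seqs, motifs) {
  rows <- list()
  for (m in seq_len(nrow(motifs))) {
    for (i in seq_len(nrow(seqs))) {
      pos <- scan_motif(seqs$sequence[i], motifs$pattern[m], seqs$circular[i])
      if (length(pos) > 0) {
        rows[[length(rows) + 1]] <- tibble(
          circ_id = seqs$circ_id[i], seq_type = seqs$seq_type[i],
          motif_id = motifs$motif_id[m], rbp_name = motifs$rbp_name[m], pos = pos)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(circ_id = character(), seq_type = character(),
                  motif_id = character(), rbp_name = character(), pos = integer()))
  }
  list_rbind(rows)
}

#' Motif enrichment of a foreground vs a background sequence set
#'
#' Per motif, match counts are summed over each set and converted to rates per
#' kilobase of scanned start positions; `fold = fg_rate / bg_rate`
#' (`fold_undefined` flags a zero background rate). Significance is a Fisher
#' exact test on the 2x2 table of match vs non-match scan positions in the two
#' sets, BH-adjusted across motifs.
#'
#' @param fg,bg sequence tibbles (non-empty).
#' @param motifs motif tibble.
#' @return tibble of class `motif_enrichment`: motif_id, rbp_name, fg_count,
#'   fg_rate, bg_count, bg_rate, fold, fold_undefined, p, padj; sorted by p.
#' @export
motif_enrichment <- function(fg, bg, motifs) {
  if (nrow(fg) == 0 || nrow(bg) == 0) abort("foreground and background must be non-empty")
  one <- function(m) {
    plen <- nchar(motifs$pattern[m])
    fg_pos <- sum(.n_positions(nchar(fg$sequence), plen, fg$circular))
    bg_pos <- sum(.n_positions(nchar(bg$sequence), plen, bg$circular))
    if (bg_pos == 0) abort("zero total background length")
    fg_count <- sum(vapply(seq_len(nrow(fg)), function(i)
      length(scan_motif(fg$sequence[i], motifs$pattern[m], fg$circular[i])), 1L))
    bg_count <- sum(vapply(seq_len(nrow(bg)), function(i)
      length(scan_motif(bg$sequence[i], motifs$pattern[m], bg$circular[i])), 1L))
    fg_rate <- 1000 * fg_count / fg_pos
    bg_rate <- 1000 * bg_count / bg_pos
    p <- if (fg_count + bg_count == 0) 1 else
      fisher.test(matrix(c(fg_count, fg_pos - fg_count,
                           bg_count, bg_pos - bg_count), nrow = 2))$p.value
    tibble(motif_id = motifs$motif_id[m], rbp_name = motifs$rbp_name[m],
           fg_count = fg_count, fg_rate = fg_rate,
           bg_count = bg_count, bg_rate = bg_rate,
           fold = if (bg_rate > 0) fg_rate / bg_rate else NA_real_,
           fold_undefined = bg_rate == 0 & fg_rate > 0,
           p = p)
  }
  res <- list_rbind(map(seq_len(nrow(motifs)), one)) |>
    mutate(padj = p.adjust(.data$p, method = "BH")) |>
    arrange(.data$p, .data$motif_id)
  class(res) <- c("motif_enrichment", class(res))
  res
}

#' Plot motif enrichment folds
#'
#' @param object a `motif_enrichment` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$rbp_name, .data$fold),
                                   y = .data$fold, fill = .data$padj <= 0.05)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment (fg rate / bg rate)",
                  fill = "padj <= 0.05") +
    ggplot2::theme_minimal()
}

#' k-mer over-representation between two sequence sets
#'
#' Counts every overlapping k-mer in the foreground and background (with
#' circular extension where flagged), then ranks k-mers by Fisher exact p on
#' counts vs scanned positions, ties broken by descending fold then
#' lexicographically. A light-weight stand-in for de novo motif discovery.
#'
#' @param fg,bg sequence tibbles.
#' @param k k-mer length (default 6).
#' @param top return at most this many rows (default all observed k-mers).
#' @return tibble kmer, fg_count, bg_count, fg_rate, bg_rate, fold, p, padj.
#' @export
kmer_overrepresentation <- function(fg, bg, k = 6L, top = Inf) {
  count_set <- function(seqs) {
    ext <- ifelse(seqs$circular & nchar(seqs$sequence) >= 1,
                  paste0(seqs$sequence, str_sub(seqs$sequence, 1, k - 1)),
                  seqs$sequence)
    npos <- sum(.n_positions(nchar(seqs$sequence), k, seqs$circular))
    keep <- nchar(ext) >= k
    counts <- if (any(keep)) {
      colSums(Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(ext[keep]), width = k))
    } else setNames(integer(0), character(0))
    list(counts = counts, npos = npos)
  }
  f <- count_set(fg); b <- count_set(bg)
  kmers <- sort(union(names(f$counts)[f$counts > 0], names(b$counts)[b$counts > 0]))
  if (length(kmers) == 0) return(tibble(kmer = character()))
  fgc <- unname(ifelse(kmers %in% names(f$counts), f$counts[kmers], 0L))
  bgc <- unname(ifelse(kmers %in% names(b$counts), b$counts[kmers], 0L))
  p <- vapply(seq_along(kmers), function(i) {
    fisher.test(matrix(c(fgc[i], f$npos - fgc[i], bgc[i], b$npos - bgc[i]),
                       nrow = 2))$p.value
  }, 1.0)
  fg_rate <- 1000 * fgc / f$npos
  bg_rate <- 1000 * bgc / b$npos
  res <- tibble(kmer = kmers, fg_count = as.integer(fgc), bg_count = as.integer(bgc),
                fg_rate = fg_rate, bg_rate = bg_rate,
                fold = ifelse(bg_rate > 0, fg_rate / bg_rate, NA_real_),
                p = p) |>
    mutate(padj = p.adjust(.data$p, method = "BH")) |>
    arrange(.data$p, desc(.data$fold), .data$kmer)
  head(res, top)
}
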