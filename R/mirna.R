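# junction-aware miRNA seed-site scanning with G:U wobble scoring
#
# The seed is mature-miRNA positions 2-8 (7 nt, the standard definition,
# configurable). A candidate 7-nt target window is paired antiparallel with
# the seed: the window is read 3'->5' against the seed 5'->3'. Canonical
# Watson-Crick pairs are (seed, target) in {(A,T),(U,A),(G,C),(C,G)}; G:U
# wobbles are {(G,T),(U,G)}; anything else (including N) is a mismatch.

#' Read mature miRNA sequences and derive seeds
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet; stored
#'   as RNA).
#' @param seed_offset 1-based position of the first seed base (default 2).
#' @param seed_len seed length (default 7).
#' @return tibble mirna_id, mature_seq, seed; miRNAs shorter than
#'   `seed_offset + seed_len - 1` nt are dropped with a warning.
#' @export
read_mirna_fasta <- function(path, seed_offset = 2L, seed_len = 7L) {
  x <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(x)))
  ids <- sub("\\s.*$", "", names(x))
  need <- seed_offset + seed_len - 1L
  short <- nchar(seqs) < need
  if (any(short)) {
    warn(sprintf("dropped %d miRNA(s) shorter than %d nt", sum(short), need))
  }
  tibble(mirna_id = ids[!short], mature_seq = seqs[!short],
         seed = str_sub(seqs[!short], seed_offset, seed_offset + seed_len - 1L))
}

# seed (RNA, 5'->3') vs reversed target window: logical pair tables
.SEED_WC <- c(A = "T", U = "A", G = "C", C = "G")
.SEED_WOBBLE <- c(G = "T", U = "G")

#' Score one seed against one target window
#'
#' @param seed 7-nt RNA seed, 5'->3'.
#' @param window 7-nt DNA target window, 5'->3'.
#' @return named integer vector `c(wc = ..., wobble = ...)`.
#' @export
#' @examples
#' score_window("AGCUUAU", "ATAAGCT")  # perfect duplex: wc 7, wobble 0
score_window <- function(seed, window) {
  s <- score_windows(seed, window)
  c(wc = unname(s$wc), wobble = unname(s$wobble))
}

#' Score one seed against many target windows (vectorised)
#'
#' @param seed 7-nt (or `seed_len`-nt) RNA seed, 5'->3'.
#' @param windows character vector of equal-length DNA windows, 5'->3'.
#' @return tibble window, wc, wobble, total.
#' @export
score_windows <- function(seed, windows) {
  L <- nchar(seed)
  if (any(nchar(windows) != L)) abort("windows must match the seed length")
  schars <- strsplit(toupper(chartr("T", "U", seed)), "")[[1]]
  wm <- do.call(rbind, strsplit(toupper(windows), ""))
  wc <- integer(length(windows))
  wob <- integer(length(windows))
  for (i in seq_len(L)) {
    tb <- wm[, L - i + 1L]          # antiparallel: seed pos i pairs window pos L-i+1
    sc <- schars[i]
    wc <- wc + unname((!is.na(.SEED_WC[sc])) & tb == .SEED_WC[sc])
    wob <- wob + unname((!is.na(.SEED_WOBBLE[sc])) & tb == .SEED_WOBBLE[sc])
  }
  tibble(window = windows, wc = as.integer(unname(wc)),
         wobble = as.integer(unname(wob))) |>
    mutate(total = .data$wc + .data$wobble)
}

# vectorised scan of one seed along an (extended) sequence; returns wc/wobble
# per start position 1..npos
.scan_seed <- function(seed, sequence, npos) {
  L <- nchar(seed)
  schars <- strsplit(toupper(chartr("T", "U", seed)), "")[[1]]
  tchars <- strsplit(sequence, "")[[1]]
  wc <- integer(npos)
  wob <- integer(npos)
  idx <- seq_len(npos)
  for (i in seq_len(L)) {
    tb <- tchars[idx + (L - i)]     # window position L-i+1 pairs seed position i
    sc <- schars[i]
    if (!is.na(.SEED_WC[sc])) wc <- wc + (tb == .SEED_WC[sc])
    if (!is.na(.SEED_WOBBLE[sc])) wob <- wob + (tb == .SEED_WOBBLE[sc])
  }
  list(wc = wc, wobble = wob)
}

#' Find miRNA seed sites on circular internal sequences
#'
#' Scans every start position 1..length over the sequence extended with its
#' first `seed_len - 1` nt, so sites spanning the back-splice junction are
#' found; `spans_junction` marks starts in the extension zone. A site is
#' accepted iff `total >= min_total`, `wc >= min_wc` and
#' `wobble <= max_wobble` (defaults 6 / 5 / 1: at least six matched positions
#' of which at least five canonical and at most one G:U).
#'
#' @param seqs sequence tibble of internal (circular) sequences.
#' @param mirnas tibble from [read_mirna_fasta()].
#' @param min_total,min_wc,max_wobble acceptance thresholds.
#' @return tibble circ_id, mirna_id, pos, wc, wobble, total, spans_junction.
#' @export
find_sites <- function(seqs, mirnas, min_total = 6L, min_wc = 5L, max_wobble = 1L) {
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[i]
    len <- nchar(s)
    for (m in seq_len(nrow(mirnas))) {
      L <- nchar(mirnas$seed[m])
      if (len < L) {
        warn(sprintf("sequence %s shorter than the seed; skipped", seqs$circ_id[i]))
        next
      }
      if (isTRUE(seqs$circular[i])) {
        ext <- paste0(s, str_sub(s, 1, L - 1L))
        npos <- len
      } else {
        ext <- s
        npos <- len - L + 1L
      }
      sc <- .scan_seed(mirnas$seed[m], ext, npos)
      total <- sc$wc + sc$wobble
      hit <- which(total >= min_total & sc$wc >= min_wc & sc$wobble <= max_wobble)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- tibble(
          circ_id = seqs$circ_id[i], mirna_id = mirnas$mirna_id[m],
          pos = hit, wc = sc$wc[hit], wobble = sc$wobble[hit], total = total[hit],
          spans_junction = isTRUE(seqs$circular[i]) & hit > len - (L - 1L))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(circ_id = character(), mirna_id = character(), pos = integer(),
                  wc = integer(), wobble = integer(), total = integer(),
                  spans_junction = logical()))
  }
  list_rbind(out)
}

#' Filter miRNAs on mean expression
#'
#' @param mirnas tibble from [read_mirna_fasta()].
#' @param expression tibble with column `mirna_id` plus one numeric column per
#'   sample (or a `mean_reads` column).
#' @param samples sample columns to average over; default all numeric columns.
#' @param min_mean minimum mean read count (default 10).
#' @return the surviving rows of `mirnas`; miRNAs absent from the table are
#'   excluded with a warning.
#' @export
filter_mirnas <- function(mirnas, expression, samples = NULL, min_mean = 10) {
  check_columns(expression, "mirna_id", "expression table")
  if (is.null(samples)) {
    samples <- names(expression)[vapply(expression, is.numeric, TRUE)]
  }
  if (length(samples) == 0) abort("expression table has no numeric sample columns")
  absent <- setdiff(mirnas$mirna_id, expression$mirna_id)
  if (length(absent) > 0) {
    warn(sprintf("%d miRNA(s) absent from the expression table were excluded",
                 length(absent)))
  }
  means <- expression |>
    mutate(mean_expr = rowMeans(across(all_of(samples)))) |>
    select(all_of(c("mirna_id", "mean_expr")))
  mirnas |>
    inner_join(means, by = "mirna_id") |>
    filter(.data$mean_expr >= min_mean) |>
    select(-"mean_expr")
}
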