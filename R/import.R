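# import and harmonization of per-tool BSJ prediction tables

# columns that identify a junction in every canonical table
BSJ_KEY <- c("circ_id", "gene", "strand", "chrom", "startUpBSE", "endDownBSE")

#' Count columns of a merged BSJ table
#'
#' Merged tables carry one read-count column per (tool, sample) pair, named
#' `<tool>.<sample>`. Everything that is not a fixed identity/flag column is a
#' count column.
#'
#' @param bsj a merged BSJ tibble.
#' @return character vector of count column names.
#' @export
count_columns <- function(bsj) {
  fixed <- c(BSJ_KEY, "n_tools", "antisense", "unannotated", "source")
  setdiff(names(bsj), fixed)
}

#' Parse one detection-tool output table into canonical BSJ records
#'
#' Reads a prediction table in the layout declared by `dialect` and returns one
#' row per reported junction with coordinates normalized to 1-based, inclusive,
#' transcription order: `startUpBSE` is the first transcribed base of the
#' upstream back-spliced exon and `endDownBSE` the last transcribed base of the
#' downstream one, so `startUpBSE <= endDownBSE` on `+` and the reverse on `-`.
#' Rows with zero reads are retained; filtering is a separate stage.
#'
#' @param path path to the tool's output table.
#' @param dialect a [tool_dialect()].
#' @param sample sample identifier the file belongs to.
#' @return tibble with columns circ_id, gene, strand, chrom, startUpBSE,
#'   endDownBSE, tool, sample, count (one row per junction).
#' @export
parse_tool_output <- function(path, dialect, sample) {
  if (!inherits(dialect, "tool_dialect")) abort("dialect must be a tool_dialect object")
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  header <- NULL
  if (dialect$header) {
    if (length(lines) == 0) abort(sprintf("%s: empty file but dialect expects a header", path))
    header <- split_fields(lines[1], dialect$delim)
    lines <- lines[-1]
    offset <- 1L
  }
  if (length(lines) == 0) {
    return(tibble(circ_id = character(), gene = character(), strand = character(),
                  chrom = character(), startUpBSE = integer(), endDownBSE = integer(),
                  tool = character(), sample = character(), count = integer()))
  }

  fields <- lapply(lines, split_fields, delim = dialect$delim)
  col_of <- function(key) {
    ref <- dialect$column_map[[key]]
    if (is.null(ref)) return(NULL)
    if (is.character(ref)) {
      idx <- match(ref, header)
      if (is.na(idx)) abort(sprintf("%s: header has no column '%s'", path, ref))
      return(idx)
    }
    as.integer(ref)
  }
  idx <- lapply(c(chrom = "chrom", strand = "strand", start = "start",
                  end = "end", count = "count", gene = "gene"), col_of)

  grab <- function(row, i, key, lineno) {
    if (i > length(row)) {
      abort(sprintf("%s line %d: too few fields (need column %d for %s)",
                    path, lineno, i, key))
    }
    row[[i]]
  }
  n <- length(fields)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    lineno <- r + offset
    row <- fields[[r]]
    chrom <- grab(row, idx$chrom, "chrom", lineno)
    strand <- grab(row, idx$strand, "strand", lineno)
    start_raw <- suppressWarnings(as.numeric(grab(row, idx$start, "start", lineno)))
    end_raw <- suppressWarnings(as.numeric(grab(row, idx$end, "end", lineno)))
    count <- suppressWarnings(as.numeric(grab(row, idx$count, "count", lineno)))
    if (!strand %in% c("+", "-")) {
      abort(sprintf("%s line %d: unknown strand symbol '%s'", path, lineno, strand))
    }
    if (anyNA(c(start_raw, end_raw, count)) ||
        start_raw != round(start_raw) || end_raw != round(end_raw) ||
        count != round(count) || count < 0) {
      abort(sprintf("%s line %d: malformed row (coordinates and count must be non-negative integers)",
                    path, lineno))
    }
    gene <- if (is.null(idx$gene)) NA_character_ else grab(row, idx$gene, "gene", lineno)
    out[[r]] <- list(chrom = chrom, strand = strand,
                     start = start_raw, end = end_raw, count = count, gene = gene)
  }
  df <- bind_rows(lapply(out, as_tibble))

  if (is.null(idx$gene)) {
    warn(sprintf("%s: dialect '%s' has no gene column; gene set to '.'",
                 path, dialect$tool_name))
    df$gene <- "."
  }

  # normalize conventions to 1-based inclusive genomic, then transcription order
  start1 <- as.integer(df$start + (dialect$coordinate_base == 0L))
  end1 <- as.integer(df$end + (dialect$coordinate_base == 0L) -
                       (dialect$end_convention == "half_open"))
  lo <- pmin(start1, end1)
  hi <- pmax(start1, end1)
  startUpBSE <- ifelse(df$strand == "+", lo, hi)
  endDownBSE <- ifelse(df$strand == "+", hi, lo)

  tibble(
    circ_id = make_circ_id(df$gene, df$strand, df$chrom, startUpBSE, endDownBSE),
    gene = df$gene, strand = df$strand, chrom = df$chrom,
    startUpBSE = as.integer(startUpBSE), endDownBSE = as.integer(endDownBSE),
    tool = dialect$tool_name, sample = sample, count = as.integer(df$count)
  )
}

split_fields <- function(line, delim) {
  if (is.null(delim)) {
    strsplit(trimws(line), "[ \t]+")[[1]]
  } else {
    strsplit(line, delim, fixed = TRUE)[[1]]
  }
}

#' Merge per-tool, per-sample BSJ records into one canonical table
#'
#' One output row per unique (gene, strand, chrom, startUpBSE, endDownBSE);
#' read counts become one column per (tool, sample) pair named
#' `<tool>.<sample>` with missing cells set to 0. `n_tools` counts the distinct
#' tools that reported the junction (in any sample, at any count). Records
#' identical in coordinates but attributed to different genes are kept as
#' distinct records with a warning.
#'
#' @param parsed a tibble as returned by [parse_tool_output()] (rows from any
#'   number of calls bound together), or a list of such tibbles.
#' @return merged tibble sorted by (chrom, lowest coordinate), with columns
#'   circ_id, gene, strand, chrom, startUpBSE, endDownBSE, n_tools and one
#'   count column per (tool, sample).
#' @export
merge_predictions <- function(parsed) {
  if (is.list(parsed) && !is.data.frame(parsed)) parsed <- bind_rows(parsed)
  check_columns(parsed, c(BSJ_KEY, "tool", "sample", "count"), "parsed predictions")

  dup_gene <- parsed |>
    distinct(.data$strand, .data$chrom, .data$startUpBSE, .data$endDownBSE, .data$gene) |>
    count(.data$strand, .data$chrom, .data$startUpBSE, .data$endDownBSE) |>
    filter(.data$n > 1)
  if (nrow(dup_gene) > 0) {
    warn(sprintf(
      "%d junction coordinate(s) carry conflicting gene symbols; kept as distinct records",
      nrow(dup_gene)))
  }

  meta <- parsed |>
    group_by(across(all_of(BSJ_KEY))) |>
    summarise(n_tools = n_distinct(.data$tool), .groups = "drop")

  wide <- parsed |>
    mutate(key = paste(.data$tool, .data$sample, sep = ".")) |>
    group_by(across(all_of(BSJ_KEY)), .data$key) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    pivot_wider(names_from = "key", values_from = "count",
                values_fill = 0L, names_sort = TRUE)

  meta |>
    left_join(wide, by = BSJ_KEY) |>
    arrange(.data$chrom, pmin(.data$startUpBSE, .data$endDownBSE), .data$circ_id)
}

#' Flag antisense circRNAs against a gene model
#'
#' A junction is antisense when its reported strand differs from the annotated
#' strand of its gene while both BSJ coordinates still fall on annotated exon
#' boundaries of that gene — a signature of a prediction assigned to the wrong
#' strand (or to an unannotated antisense transcript). Downstream stages drop
#' antisense records by default. Records whose gene is absent from the model,
#' or whose strand differs without exon-boundary support, are flagged
#' `unannotated` instead.
#'
#' @param bsj merged BSJ tibble.
#' @param model a gene model from [load_gtf()].
#' @return `bsj` with logical columns `antisense` and `unannotated` added.
#' @export
flag_antisense <- function(bsj, model) {
  check_columns(bsj, BSJ_KEY, "bsj")
  genes <- model$genes
  exons <- model$exons

  boundary_sets <- exons |>
    pivot_longer(c("start", "end"), values_to = "pos") |>
    distinct(.data$gene_id, .data$pos)

  gene_strand <- setNames(genes$strand, genes$gene_id)
  ann_strand <- unname(gene_strand[bsj$gene])
  known <- !is.na(ann_strand)

  on_boundaries <- function(g, a, b) {
    pos <- boundary_sets$pos[boundary_sets$gene_id == g]
    a %in% pos && b %in% pos
  }
  differs <- known & bsj$strand != ann_strand
  anti <- rep(FALSE, nrow(bsj))
  unann <- !known
  ix <- which(differs)
  for (i in ix) {
    if (on_boundaries(bsj$gene[i], bsj$startUpBSE[i], bsj$endDownBSE[i])) {
      anti[i] <- TRUE
    } else {
      unann[i] <- TRUE
    }
  }
  bsj |> mutate(antisense = anti, unannotated = unann)
}

#' Read an experiment design table
#'
#' @param path TSV with header columns `sample` and `condition`.
#' @return tibble with columns sample, condition.
#' @export
read_experiment_design <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("sample", "condition"), "experiment design")
  if (anyDuplicated(df$sample)) abort("experiment design: duplicated sample ids")
  df |> mutate(sample = as.character(.data$sample), condition = as.character(.data$condition))
}

#' Write / read the canonical merged BSJ table
#'
#' Plain TSV, lossless round trip (column order and integer types preserved).
#'
#' @param bsj merged BSJ tibble.
#' @param path output path.
#' @return `write_bsj_tsv()` returns `path` invisibly; `read_bsj_tsv()` the tibble.
#' @export
write_bsj_tsv <- function(bsj, path) {
  readr::write_tsv(bsj, path)
  invisible(path)
}

#' @rdname write_bsj_tsv
#' @export
read_bsj_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          circ_id = "c", gene = "c", strand = "c", chrom = "c",
                          startUpBSE = "i", endDownBSE = "i",
                          .default = readr::col_guess()))
  for (cc in count_columns(df)) df[[cc]] <- as.integer(df[[cc]])
  if ("n_tools" %in% names(df)) df$n_tools <- as.integer(df$n_tools)
  df
}
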