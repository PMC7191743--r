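# read-count prevalence filter (false-positive removal)

#' Collapse per-(tool, sample) counts to a per-sample count matrix
#'
#' The detection tools report overlapping evidence for the same junction, so
#' the default aggregation is the per-sample maximum across tools — conservative
#' against counting the same BSJ-spanning reads twice. `sum` and single-tool
#' modes are available.
#'
#' @param bsj merged BSJ tibble (see [merge_predictions()]).
#' @param design experiment design tibble (sample, condition).
#' @param mode `"max"` (default), `"sum"`, or `"tool:<name>"`.
#' @return tibble with columns circ_id and one integer count column per sample
#'   in `design$sample` order; attribute `"design"` carries the design.
#' @export
collapse_counts <- function(bsj, design, mode = "max") {
  check_columns(design, c("sample", "condition"), "design")
  cc <- count_columns(bsj)
  if (length(cc) == 0) abort("bsj has no count columns")
  long <- bsj |>
    select(all_of(c("circ_id", cc))) |>
    pivot_longer(all_of(cc), names_to = "key", values_to = "count") |>
    tidyr::separate_wider_delim("key", ".", names = c("tool", "sample"),
                                too_many = "merge")

  if (startsWith(mode, "tool:")) {
    want <- sub("^tool:", "", mode)
    if (!want %in% unique(long$tool)) abort(sprintf("unknown tool '%s' in mode", want))
    long <- long |> filter(.data$tool == want)
    agg <- long |> group_by(.data$circ_id, .data$sample) |>
      summarise(count = sum(.data$count), .groups = "drop")
  } else if (mode == "sum") {
    agg <- long |> group_by(.data$circ_id, .data$sample) |>
      summarise(count = sum(.data$count), .groups = "drop")
  } else if (mode == "max") {
    agg <- long |> group_by(.data$circ_id, .data$sample) |>
      summarise(count = max(.data$count), .groups = "drop")
  } else {
    abort(sprintf("unknown mode '%s'", mode))
  }

  missing_samples <- setdiff(design$sample, unique(agg$sample))
  if (length(missing_samples) > 0) {
    abort(sprintf("no counts for design sample(s): %s",
                  paste(missing_samples, collapse = ", ")))
  }
  mat <- agg |>
    filter(.data$sample %in% design$sample) |>
    pivot_wider(names_from = "sample", values_from = "count", values_fill = 0L) |>
    select(all_of(c("circ_id", design$sample)))
  # preserve input row order
  mat <- mat[match(unique(bsj$circ_id), mat$circ_id), , drop = FALSE]
  attr(mat, "design") <- design
  mat
}

#' Filter circRNAs on read-count prevalence
#'
#' A junction survives iff in at least one condition at least `min_samples`
#' samples have a count of at least `min_count`. Defaults mirror a stringent
#' heart-tissue analysis: count >= 5 in at least 3 samples of one condition.
#' Row order is preserved.
#'
#' @param mat count matrix tibble from [collapse_counts()] (circ_id + one
#'   column per sample).
#' @param design experiment design tibble; defaults to the matrix's
#'   `"design"` attribute.
#' @param min_count minimum per-sample read count (>= 0).
#' @param min_samples minimum number of qualifying samples within a condition.
#' @return the surviving rows of `mat` (design attribute preserved).
#' @export
filter_circs <- function(mat, design = attr(mat, "design"),
                         min_count = 5L, min_samples = 3L) {
  if (is.null(design)) abort("no design given and none attached to the matrix")
  if (min_count < 0) abort("min_count must be >= 0")
  if (min_samples < 1) abort("min_samples must be >= 1")
  check_columns(mat, c("circ_id", design$sample), "count matrix")

  cond_samples <- split(design$sample, design$condition)
  if (all(vapply(cond_samples, length, 1L) < min_samples)) {
    abort("min_samples exceeds every condition's sample count: filter unsatisfiable")
  }
  keep <- rep(FALSE, nrow(mat))
  for (ss in cond_samples) {
    if (length(ss) < min_samples) next
    sub <- as.matrix(mat[, ss, drop = FALSE])
    keep <- keep | rowSums(sub >= min_count) >= min_samples
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "design") <- design
  out
}
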