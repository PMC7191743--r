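# table-driven adapters for the output formats of the supported detection tools

#' Describe the table layout of a circRNA detection tool
#'
#' A dialect tells [parse_tool_output()] where to find each canonical field in
#' a tool's prediction table and which coordinate conventions the tool uses.
#' Built-in best-effort dialects for the six supported tools are returned by
#' [default_dialects()]; the published formats drift between tool versions, so
#' all layouts can be overridden here.
#'
#' @param tool_name one of `"mapsplice2"`, `"nclscan"`, `"circmarker"`,
#'   `"circexplorer2"`, `"knife"`, `"uroborus"`, `"generic"`, or any other
#'   label for a user-defined layout.
#' @param column_map named list mapping the canonical fields `chrom`, `strand`,
#'   `start`, `end`, `count` and (optionally) `gene` to column indices
#'   (integers) or column names (characters, requires `header = TRUE`).
#' @param coordinate_base 0 or 1: base of the `start` column.
#' @param end_convention `"inclusive"` (the `end` column is the last base) or
#'   `"half_open"` (one past the last base).
#' @param delim field delimiter; `NULL` means any run of whitespace.
#' @param header does the file carry a header line?
#' @return an object of class `tool_dialect`.
#' @export
#' @examples
#' tool_dialect("generic",
#'   column_map = list(chrom = 1, strand = 2, start = 3, end = 4, gene = 5, count = 6))
tool_dialect <- function(tool_name,
                         column_map,
                         coordinate_base = 1L,
                         end_convention = c("inclusive", "half_open"),
                         delim = "\t",
                         header = FALSE) {
  end_convention <- match.arg(end_convention)
  required <- c("chrom", "strand", "start", "end", "count")
  missing <- setdiff(required, names(column_map))
  if (length(missing) > 0) {
    abort(sprintf("column_map for dialect '%s' must cover: %s",
                  tool_name, paste(missing, collapse = ", ")))
  }
  if (!coordinate_base %in% c(0L, 1L)) abort("coordinate_base must be 0 or 1")
  structure(
    list(tool_name = tool_name, column_map = column_map,
         coordinate_base = as.integer(coordinate_base),
         end_convention = end_convention, delim = delim, header = header),
    class = "tool_dialect"
  )
}

#' Built-in dialects for the six supported detection tools
#'
#' Column layouts are best-effort defaults chosen to exercise every
#' normalization path (0/1 base, inclusive/half-open ends, header or not,
#' tab or whitespace delimited); override with [tool_dialect()] when a tool
#' version uses a different layout.
#'
#' @return named list of `tool_dialect` objects (includes `"generic"`).
#' @export
default_dialects <- function() {
  list(
    generic = tool_dialect(
      "generic",
      list(chrom = 1, strand = 2, start = 3, end = 4, gene = 5, count = 6)
    ),
    mapsplice2 = tool_dialect(
      "mapsplice2",
      list(chrom = 1, start = 2, end = 3, strand = 4, count = 5, gene = 6)
    ),
    nclscan = tool_dialect(
      "nclscan",
      list(gene = 1, chrom = 2, start = 3, strand = 4, end = 6, count = 8)
    ),
    circmarker = tool_dialect(
      "circmarker",
      list(chrom = 1, start = 2, end = 3, strand = 4, gene = 5, count = 6),
      delim = NULL
    ),
    circexplorer2 = tool_dialect(
      "circexplorer2",
      list(chrom = 1, start = 2, end = 3, gene = 4, count = 5, strand = 6),
      coordinate_base = 0L, end_convention = "half_open"
    ),
    knife = tool_dialect(
      "knife",
      list(chrom = "chrom", gene = "gene", strand = "strand",
           start = "start", end = "end", count = "reads"),
      header = TRUE
    ),
    uroborus = tool_dialect(
      "uroborus",
      list(chrom = 1, start = 2, end = 3, strand = 4, count = 5, gene = 7),
      coordinate_base = 0L, end_convention = "half_open"
    )
  )
}
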