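# shared helpers: reverse complement, circ_id construction, seeded RNG scope

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. Accepts A/C/G/T/N (any case), returns upper case.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AACCGG")
revcomp <- function(x) {
  up <- toupper(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

#' Canonical circRNA identifier
#'
#' `gene|strand|chrom|startUpBSE|endDownBSE`, a pure function of its inputs.
#'
#' @param gene,strand,chrom,startUpBSE,endDownBSE vectors of equal length.
#' @return character vector of identifiers.
#' @export
make_circ_id <- function(gene, strand, chrom, startUpBSE, endDownBSE) {
  paste(gene, strand, chrom, startUpBSE, endDownBSE, sep = "|")
}

# run code with a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# assert a data frame has the given columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# empty canonical BSJ tibble (see parse_tool_output for column semantics)
empty_bsj <- function() {
  tibble(
    circ_id = character(), gene = character(), strand = character(),
    chrom = character(), startUpBSE = integer(), endDownBSE = integer()
  )
}
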