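# small constructed inputs shared across test files

# two-gene model: geneP (+, chr1, 5 exons), geneM (-, chr1, 4 exons)
toy_exons <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = "geneP", transcript_id = "geneP.t1", chrom = "chr1", strand = "+",
      start = c(101L, 501L, 901L, 1301L, 1701L),
      end = c(200L, 620L, 1010L, 1400L, 1820L)),
    tibble::tibble(
      gene_id = "geneM", transcript_id = "geneM.t1", chrom = "chr1", strand = "-",
      start = c(2101L, 2501L, 2901L, 3301L),
      end = c(2220L, 2600L, 3020L, 3400L)))
}

toy_model <- function() gene_model(toy_exons())

# deterministic 4-kb chr1 sequence
toy_genome <- function(len = 4000L, seed = 11L) {
  chars <- withr::with_seed(seed, sample(c("A", "C", "G", "T"), len, replace = TRUE))
  g <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g) <- "chr1"
  g
}

# canonical BSJ row builder
bsj_row <- function(gene, strand, chrom, su, ed) {
  tibble::tibble(
    circ_id = make_circ_id(gene, strand, chrom, su, ed),
    gene = gene, strand = strand, chrom = chrom,
    startUpBSE = as.integer(su), endDownBSE = as.integer(ed))
}

# cache the default synthetic fixture for the whole test session
the_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$manifest)) {
      cache$dir <- file.path(tempdir(), "circkit-fixture")
      unlink(cache$dir, recursive = TRUE)
      cache$manifest <- build_fixture(fixture_spec(seed = 7L), cache$dir)
    }
    list(dir = cache$dir, manifest = cache$manifest)
  }
})

# parse + merge the whole fixture (all six dialects, all samples)
merge_fixture <- function(fx) {
  dial <- default_dialects()
  parsed <- list()
  for (tool in names(fx$manifest$tool_files)) {
    for (s in names(fx$manifest$tool_files[[tool]])) {
      parsed[[length(parsed) + 1]] <- parse_tool_output(
        file.path(fx$dir, fx$manifest$tool_files[[tool]][[s]]), dial[[tool]], s)
    }
  }
  list(parsed = dplyr::bind_rows(parsed), merged = merge_predictions(parsed))
}

# brute-force IUPAC matcher (independent of scan_motif)
oracle_iupac_positions <- function(sequence, pattern, circular = FALSE) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  pc <- strsplit(pattern, "")[[1]]
  len <- nchar(sequence)
  ext <- if (circular) paste0(sequence, substr(sequence, 1, length(pc) - 1)) else sequence
  npos <- if (circular) len else len - length(pc) + 1L
  hits <- integer()
  for (p in seq_len(max(npos, 0L))) {
    ok <- TRUE
    for (k in seq_along(pc)) {
      if (!substr(ext, p + k - 1L, p + k - 1L) %in% sets[[pc[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# brute-force antiparallel seed pairing (independent of score_window)
oracle_pair <- function(seed, window) {
  s <- strsplit(chartr("T", "U", toupper(seed)), "")[[1]]
  w <- rev(strsplit(toupper(window), "")[[1]])
  wc <- 0L; wob <- 0L
  for (i in seq_along(s)) {
    pair <- paste0(s[i], w[i])
    if (pair %in% c("AT", "UA", "GC", "CG")) wc <- wc + 1L
    else if (pair %in% c("GT", "UG")) wob <- wob + 1L
  }
  c(wc = wc, wobble = wob)
}

# expand a chain tibble row into a per-base map of the target (0-based keys)
oracle_chain_map <- function(ch) {
  b <- ch$blocks[[1]]
  t0 <- ch$tStart; q0 <- ch$qStart
  tpos <- integer(0); qpos <- integer(0)
  for (r in seq_len(nrow(b))) {
    tpos <- c(tpos, t0:(t0 + b$size[r] - 1L))
    qpos <- c(qpos, q0:(q0 + b$size[r] - 1L))
    if (is.na(b$dt[r])) break
    t0 <- t0 + b$size[r] + b$dt[r]
    q0 <- q0 + b$size[r] + b$dq[r]
  }
  if (ch$qStrand == "-") qpos <- ch$qSize - qpos - 1L
  tibble::tibble(t = tpos, q = qpos)
}
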