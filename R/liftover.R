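# UCSC chain parsing and point lifting of BSJ coordinates across assemblies

#' Parse a UCSC chain file
#'
#' Chains describe gapped alignments between a target (source) and query
#' (destination) assembly; coordinates are 0-based half-open, with query
#' coordinates given on `qStrand`. Block-sum invariants
#' (`sum(size) + sum(dt) == tEnd - tStart`, same for q/dq) are verified on
#' load and violations are a hard error naming the chain id.
#'
#' @param path `.chain` file, plain or gzip.
#' @return tibble with one row per chain: score, tName, tSize, tStrand,
#'   tStart, tEnd, qName, qSize, qStrand, qStart, qEnd, chain_id and a
#'   list-column `blocks` (size, dt, dq; dt/dq are NA on the last block).
#' @export
parse_chain <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)

  starts <- grep("^chain\\b", lines)
  if (length(starts) == 0) abort(sprintf("%s: no chain records", path))
  ends <- c(starts[-1] - 1L, length(lines))

  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[k]]), "[ \t]+")[[1]]
    if (length(hdr) < 13) abort(sprintf("%s: malformed chain header at line %d", path, starts[k]))
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[nzchar(trimws(body))]
    bl <- lapply(strsplit(trimws(body), "[ \t]+"), as.numeric)
    sizes <- vapply(bl, `[`, 0, 1)
    dts <- vapply(bl, function(x) if (length(x) >= 2) x[2] else NA_real_, 0)
    dqs <- vapply(bl, function(x) if (length(x) >= 3) x[3] else NA_real_, 0)
    if (any(sizes <= 0)) abort(sprintf("%s: non-positive block size in chain %s", path, hdr[13]))

    ch <- tibble(
      score = as.numeric(hdr[2]),
      tName = hdr[3], tSize = as.integer(hdr[4]), tStrand = hdr[5],
      tStart = as.integer(hdr[6]), tEnd = as.integer(hdr[7]),
      qName = hdr[8], qSize = as.integer(hdr[9]), qStrand = hdr[10],
      qStart = as.integer(hdr[11]), qEnd = as.integer(hdr[12]),
      chain_id = hdr[13],
      blocks = list(tibble(size = as.integer(sizes), dt = as.integer(dts),
                           dq = as.integer(dqs)))
    )
    tspan <- sum(sizes) + sum(dts, na.rm = TRUE)
    qspan <- sum(sizes) + sum(dqs, na.rm = TRUE)
    if (tspan != ch$tEnd - ch$tStart || qspan != ch$qEnd - ch$qStart) {
      abort(sprintf("%s: block sums do not match span in chain %s", path, ch$chain_id))
    }
    out[[k]] <- ch
  }
  bind_rows(out)
}

#' Serialize chains back to UCSC chain format
#'
#' Inverse of [parse_chain()]: `parse_chain(write_chain(x, f))` is identical
#' to `x`.
#'
#' @param chains chain tibble from [parse_chain()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  fmt_one <- function(i) {
    ch <- chains[i, ]
    b <- ch$blocks[[1]]
    hdr <- sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %s",
                   format(ch$score, scientific = FALSE, trim = TRUE),
                   ch$tName, ch$tSize, ch$tStrand, ch$tStart, ch$tEnd,
                   ch$qName, ch$qSize, ch$qStrand, ch$qStart, ch$qEnd, ch$chain_id)
    body <- ifelse(is.na(b$dt), sprintf("%d", b$size),
                   sprintf("%d\t%d\t%d", b$size, b$dt, b$dq))
    c(hdr, body, "")
  }
  writeLines(unlist(lapply(seq_len(nrow(chains)), fmt_one)), path)
  invisible(path)
}

#' Lift single genomic positions through a chain set
#'
#' Chains covering the position are tried in descending score order; the
#' position maps when it falls inside an aligned block (positions inside
#' dt/dq gaps are unmapped, a value rather than an error). On `-`-strand
#' query chains the destination coordinate is reflected onto the plus strand
#' and `flip` is TRUE.
#'
#' @param chains chain tibble from [parse_chain()].
#' @param chrom,pos equal-length vectors; `pos` 1-based.
#' @return tibble with columns chrom, pos, mapped, dest_chrom, dest_pos
#'   (1-based), flip.
#' @export
lift_points <- function(chains, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  res <- tibble(chrom = chrom, pos = as.integer(pos), mapped = FALSE,
                dest_chrom = NA_character_, dest_pos = NA_integer_, flip = NA)

  for (i in seq_len(n)) {
    p0 <- pos[i] - 1L
    cand <- chains |> filter(.data$tName == chrom[i], .data$tStart <= p0, p0 < .data$tEnd) |>
      arrange(desc(.data$score))
    for (k in seq_len(nrow(cand))) {
      ch <- cand[k, ]
      b <- ch$blocks[[1]]
      t0 <- ch$tStart; q0 <- ch$qStart
      hit <- FALSE
      for (r in seq_len(nrow(b))) {
        if (p0 < t0) break                       # inside a dt gap
        if (p0 < t0 + b$size[r]) {
          o <- p0 - t0
          q <- q0 + o
          if (ch$qStrand == "-") {
            res$dest_pos[i] <- ch$qSize - q      # 1-based plus-strand coordinate
            res$flip[i] <- TRUE
          } else {
            res$dest_pos[i] <- q + 1L
            res$flip[i] <- FALSE
          }
          res$dest_chrom[i] <- ch$qName
          res$mapped[i] <- TRUE
          hit <- TRUE
          break
        }
        if (is.na(b$dt[r])) break
        t0 <- t0 + b$size[r] + b$dt[r]
        q0 <- q0 + b$size[r] + b$dq[r]
      }
      if (hit) break
    }
  }
  res
}

#' Lift BSJ records to another assembly
#'
#' Both junction coordinates are lifted independently; the record lifts when
#' both map, to the same destination chromosome, with the same mapping
#' orientation. Destination coordinates are re-canonicalized to transcription
#' order on the destination strand.
#'
#' @param bsj BSJ tibble.
#' @param chains chain tibble from [parse_chain()].
#' @return tibble circ_id, lifted, dest_chrom, dest_strand, dest_startUpBSE,
#'   dest_endDownBSE, failure_reason (`NA` | unmapped | split |
#'   strand_conflict).
#' @export
lift_bsj <- function(bsj, chains) {
  check_columns(bsj, BSJ_KEY, "bsj")
  up <- lift_points(chains, bsj$chrom, bsj$startUpBSE)
  dn <- lift_points(chains, bsj$chrom, bsj$endDownBSE)

  out <- tibble(circ_id = bsj$circ_id, lifted = FALSE,
                dest_chrom = NA_character_, dest_strand = NA_character_,
                dest_startUpBSE = NA_integer_, dest_endDownBSE = NA_integer_,
                failure_reason = NA_character_)
  for (i in seq_len(nrow(bsj))) {
    if (!up$mapped[i] || !dn$mapped[i]) {
      out$failure_reason[i] <- "unmapped"
    } else if (up$dest_chrom[i] != dn$dest_chrom[i]) {
      out$failure_reason[i] <- "split"
    } else if (up$flip[i] != dn$flip[i]) {
      out$failure_reason[i] <- "strand_conflict"
    } else {
      strand <- if (up$flip[i]) setdiff(c("+", "-"), bsj$strand[i]) else bsj$strand[i]
      a <- up$dest_pos[i]; b <- dn$dest_pos[i]
      out$lifted[i] <- TRUE
      out$dest_chrom[i] <- up$dest_chrom[i]
      out$dest_strand[i] <- strand
      out$dest_startUpBSE[i] <- if (strand == "+") min(a, b) else max(a, b)
      out$dest_endDownBSE[i] <- if (strand == "+") max(a, b) else min(a, b)
    }
  }
  out
}
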