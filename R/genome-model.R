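# Draft genome model: gap (N-run) discovery and flank extraction.
# All coordinates are 0-based half-open; a gap occupies [b1, b2) on its
# scaffold and d = b2 - b1 is taken as the gap-length estimate.

#' Read a draft genome FASTA
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than N are kept as
#' literal characters (they are not treated as gaps).
#'
#' @param path FASTA file of scaffolds.
#' @return named character vector of scaffold sequences.
#' @export
read_draft <- function(path) {
  draft <- read_fasta(path)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", draft)
  if (any(bad))
    stop("non-IUPAC characters in scaffold(s): ",
         paste(names(draft)[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(draft)))
    stop("duplicate scaffold ids in draft", call. = FALSE)
  draft
}

#' Find gaps (maximal N-runs) in a draft genome
#'
#' A gap is a maximal run of N characters. Gap ids are deterministic:
#' scaffolds in input order, gaps left to right within a scaffold.
#'
#' @param draft named character vector of scaffold sequences (see
#'   [read_draft()]).
#' @param min_gap_len minimum N-run length to report (default 1; evaluation
#'   reports conventionally use 100).
#' @return `data.table` with columns `gap_id`, `scaffold`, `b1`, `b2`, `d`
#'   (0-based half-open; `d = b2 - b1`).
#' @export
find_gaps <- function(draft, min_gap_len = 1L) {
  stopifnot(length(draft) > 0L)
  if (is.null(names(draft)) || any(!nzchar(names(draft))))
    stop("draft scaffolds must be named", call. = FALSE)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", draft)
  if (any(bad))
    stop("non-IUPAC characters in scaffold(s): ",
         paste(names(draft)[bad], collapse = ", "), call. = FALSE)
  res <- lapply(seq_along(draft), function(i) {
    m <- gregexpr("N+", draft[[i]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_gap_len
    if (!any(keep)) return(NULL)
    data.table(scaffold = names(draft)[i],
               b1 = as.integer(m[keep]) - 1L,
               b2 = as.integer(m[keep]) - 1L + len[keep])
  })
  gaps <- rbindlist(res)
  if (nrow(gaps) == 0L)
    return(data.table(gap_id = character(), scaffold = character(),
                      b1 = integer(), b2 = integer(), d = integer()))
  gaps[, d := b2 - b1]
  gaps[, gap_id := sprintf("gap_%04d", seq_len(.N))]
  setcolorder(gaps, c("gap_id", "scaffold", "b1", "b2", "d"))
  gaps[]
}

#' Extract flanking sequences for each gap
#'
#' The left flank is the up-to-`flank_len` bases immediately left of `b1`,
#' truncated at the scaffold start. When two gaps lie closer than
#' `flank_len`, the whole inter-gap segment is used as the (shared) flank,
#' so flanks never contain N. Gaps with an empty flank on either side are
#' flagged `NO_FLANK` and excluded from closure.
#'
#' @param gaps gap table from [find_gaps()].
#' @param draft named character vector of scaffolds.
#' @param flank_len maximum flank length in bases (default 300).
#' @return the gap table with added columns `left_flank`, `right_flank`,
#'   `no_flank` (logical).
#' @export
extract_flanks <- function(gaps, draft, flank_len = 300L) {
  gaps <- copy(gaps)
  if (nrow(gaps) == 0L) {
    gaps[, `:=`(left_flank = character(), right_flank = character(),
                no_flank = logical())]
    return(gaps[])
  }
  # N-runs of any length bound flanks, not only gaps passing min_gap_len
  allN <- find_gaps(draft, min_gap_len = 1L)
  gaps[, row_ := .I]
  lf <- character(nrow(gaps)); rf <- character(nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    sc <- gaps$scaffold[i]; g1 <- gaps$b1[i]; g2 <- gaps$b2[i]
    seq_sc <- draft[[sc]]
    slen <- nchar(seq_sc)
    other <- allN[scaffold == sc & !(b1 == g1 & b2 == g2)]
    prev_end <- max(0L, other[b2 <= g1, b2])
    next_start <- min(slen, other[b1 >= g2, b1])
    lstart <- max(g1 - flank_len, prev_end)
    rend <- min(g2 + flank_len, next_start)
    lf[i] <- if (lstart < g1) substr(seq_sc, lstart + 1L, g1) else ""
    rf[i] <- if (rend > g2) substr(seq_sc, g2 + 1L, rend) else ""
  }
  gaps[, `:=`(left_flank = lf, right_flank = rf)]
  gaps[, no_flank := !nzchar(left_flank) | !nzchar(right_flank)]
  gaps[, row_ := NULL]
  gaps[]
}

#' Write a gap table as TSV (or BED)
#'
#' @param gaps gap table from [find_gaps()].
#' @param path output path.
#' @param format "tsv" (gap_id, scaffold, b1, b2, length) or "bed".
#' @return `path`, invisibly.
#' @export
write_gap_table <- function(gaps, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- gaps[, .(gap_id, scaffold, b1, b2, length = d)]
    fwrite(out, path, sep = "\t")
  } else {
    out <- gaps[, .(scaffold, b1, b2, gap_id)]
    fwrite(out, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}
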