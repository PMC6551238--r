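# SAM/BAM ingest. Records are loaded into a flat data.table, one row per
# primary record (secondary and supplementary records are dropped), with
# 0-based positions and pre-parsed soft-clip structure. Mates are joined by
# (qname, mate_index) downstream.

#' Read alignments from a SAM or BAM file
#'
#' Loads all primary records (including unmapped reads) into a
#' `data.table`. SAM files are converted with [Rsamtools::asBam()] first.
#' Duplicate records for the same (name, mate) are collapsed to the first.
#'
#' @param path SAM or BAM file. BAM need not be indexed.
#' @param library_id label recorded in the `library` column.
#' @return `data.table` with one row per read record: `name`, `mate_index`
#'   (1 or 2), `mapped`, `scaffold` (NA if unmapped), `pos` (0-based
#'   leftmost, NA if unmapped), `end` (0-based exclusive end of the aligned
#'   span), `mapq`, `reverse`, `cigar`, `clip_left`, `clip_right` (soft-clip
#'   lengths), `seq` (read bases as sequenced, i.e. reverse-complemented
#'   back to original orientation for reverse-strand alignments), `qual`,
#'   `library`.
#' @export
read_alignments <- function(path, library_id = "lib1") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  p <- Rsamtools::ScanBamParam(what = what)
  x <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(x$qname) == 0L) return(empty_alignments())
  flag <- x$flag
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  dt <- data.table(
    name = x$qname,
    mate_index = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    mapped = bitwAnd(flag, 4L) == 0L,
    scaffold = as.character(x$rname),
    pos = as.integer(x$pos) - 1L,
    mapq = as.integer(x$mapq),
    reverse = bitwAnd(flag, 16L) > 0L,
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual)
  )[!secondary]
  dt[mapped == FALSE, `:=`(scaffold = NA_character_, pos = NA_integer_,
                           cigar = NA_character_, mapq = NA_integer_)]
  # restore as-sequenced orientation
  rev_idx <- which(dt$reverse & nzchar(dt$seq) & dt$seq != "*")
  if (length(rev_idx)) {
    dt[rev_idx, seq := revcomp(seq)]
    dt[rev_idx, qual := vapply(qual, function(q)
      paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1))]
  }
  cl <- parse_cigar_clips(dt$cigar)
  dt[, `:=`(clip_left = cl$left, clip_right = cl$right,
            end = pos + cl$ref_span)]
  dt <- dt[!duplicated(paste(name, mate_index))]
  dt[, library := library_id]
  setcolorder(dt, c("name", "mate_index", "mapped", "scaffold", "pos", "end",
                    "mapq", "reverse", "cigar", "clip_left", "clip_right",
                    "seq", "qual", "library"))
  dt[]
}

empty_alignments <- function() {
  data.table(name = character(), mate_index = integer(), mapped = logical(),
             scaffold = character(), pos = integer(), end = integer(),
             mapq = integer(), reverse = logical(), cigar = character(),
             clip_left = integer(), clip_right = integer(), seq = character(),
             qual = character(), library = character())
}

# Soft-clip lengths at each end and reference span, from CIGAR strings.
parse_cigar_clips <- function(cigar) {
  n <- length(cigar)
  out <- list(left = integer(n), right = integer(n), ref_span = integer(n))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    cig <- cigar[ok]
    ops <- GenomicAlignments::explodeCigarOps(cig)
    lens <- GenomicAlignments::explodeCigarOpLengths(cig)
    left <- vapply(seq_along(ops), function(i) {
      o <- ops[[i]]
      if (length(o) && o[1] == "S") lens[[i]][1] else if (length(o) > 1 &&
        o[1] == "H" && o[2] == "S") lens[[i]][2] else 0L
    }, integer(1))
    right <- vapply(seq_along(ops), function(i) {
      o <- ops[[i]]; k <- length(o)
      if (k && o[k] == "S") lens[[i]][k] else if (k > 1 && o[k] == "H" &&
        o[k - 1] == "S") lens[[i]][k - 1] else 0L
    }, integer(1))
    out$left[ok] <- left
    out$right[ok] <- right
    out$ref_span[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  }
  out
}

#' Read several libraries' alignments and stack them
#'
#' @param paths character vector of SAM/BAM paths.
#' @param library_ids labels, one per path.
#' @return stacked alignments `data.table`.
#' @export
read_alignment_set <- function(paths, library_ids = names(paths)) {
  if (is.null(library_ids)) library_ids <- paste0("lib", seq_along(paths))
  rbindlist(Map(read_alignments, paths, library_ids))
}

#' Read a library statistics table
#'
#' A TSV with columns `library_id`, `m` (insert-size mean), `v` (insert-size
#' SD), `l` (read length), `kind` (PE or MP), and optionally `fq1`, `fq2`,
#' `bam`.
#'
#' @param path TSV path.
#' @return `data.table` of library statistics.
#' @export
read_library_stats <- function(path) {
  st <- fread(path)
  need <- c("library_id", "m", "v", "l", "kind")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("library stats missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(all(st$m > 0), all(st$v >= 0), all(st$l > 0))
  st
}
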