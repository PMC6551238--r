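# Stage-2 local assembly: greedy prefix-suffix merging of per-gap contigs.
# The longest qualifying overlap is merged first; contained sequences are
# absorbed without extension; high-quality orphan reads can join as
# mini-contigs. Fully deterministic, with documented tie-breaks.

#' Contig-merging configuration
#'
#' @param min_overlap minimum qualifying suffix/prefix overlap (bases).
#' @param max_mismatch_rate maximum mismatch fraction inside an overlap.
#' @param use_hq_reads include unassembled high-quality reads as
#'   mini-contigs.
#' @return list of class `merge_config`.
#' @export
merge_config <- function(min_overlap = 20L, max_mismatch_rate = 0.02,
                         use_hq_reads = TRUE) {
  stopifnot(min_overlap >= 10L, max_mismatch_rate >= 0,
            max_mismatch_rate < 0.5)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 use_hq_reads = use_hq_reads), class = "merge_config")
}

# Longest suffix(a)/prefix(b) overlap for fixed orientation; raw byte
# vectors in, list(length, mismatches) or NULL out. Candidate lengths are
# prefiltered with a base-composition bound (mismatches >= half the L1
# distance between the suffix and prefix compositions), which is exact:
# no qualifying overlap can be excluded by it.
best_overlap_1 <- function(ra, rb, min_overlap, max_mismatch_rate) {
  la <- length(ra); lb <- length(rb)
  max_len <- min(la, lb)
  if (max_len < min_overlap) return(NULL)
  bases <- as.raw(c(65L, 67L, 71L, 84L))   # A C G T
  bound <- numeric(max_len)
  for (b in bases) {
    ca <- cumsum(rev(ra) == b)[seq_len(max_len)]
    cb <- cumsum(rb == b)[seq_len(max_len)]
    bound <- bound + abs(ca - cb)
  }
  bound <- bound / 2
  lens <- max_len:min_overlap
  lens <- lens[bound[lens] <= max_mismatch_rate * lens]
  for (len in lens) {
    mm <- sum(ra[(la - len + 1L):la] != rb[seq_len(len)])
    if (mm <= max_mismatch_rate * len)
      return(list(length = len, mismatches = mm))
  }
  NULL
}

#' Best suffix/prefix overlap between two sequences
#'
#' Searches for the longest overlap between the suffix of `a` and the prefix
#' of `b`, considering `b` in both orientations, with mismatch fraction at
#' most `cfg$max_mismatch_rate` and length at least `cfg$min_overlap`.
#'
#' @param a,b DNA sequences (character scalars).
#' @param cfg a [merge_config()].
#' @return `NULL` if no qualifying overlap, else a list with `length`,
#'   `mismatches`, `orientation` (`"forward"` or `"reverse"`, orientation of
#'   `b`).
#' @export
overlap <- function(a, b, cfg = merge_config()) {
  if (nchar(a) < cfg$min_overlap || nchar(b) < cfg$min_overlap) return(NULL)
  ra <- charToRaw(a)
  fwd <- best_overlap_1(ra, charToRaw(b), cfg$min_overlap,
                        cfg$max_mismatch_rate)
  rev <- best_overlap_1(ra, charToRaw(revcomp(b)), cfg$min_overlap,
                        cfg$max_mismatch_rate)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (is.null(rev) || (!is.null(fwd) && fwd$length >= rev$length))
    c(fwd, orientation = "forward")
  else c(rev, orientation = "reverse")
}

# Is `b` (either orientation) contained in `a` with at most
# rate * nchar(b) mismatches (no indels)? Returns list(offset, orientation)
# of the first match or NULL.
find_containment <- function(a, b, max_mismatch_rate) {
  if (nchar(b) > nchar(a)) return(NULL)
  max_mm <- floor(max_mismatch_rate * nchar(b))
  subj <- Biostrings::DNAString(a)
  m <- Biostrings::matchPattern(b, subj, max.mismatch = max_mm)
  if (length(m) > 0L)
    return(list(offset = IRanges::start(m)[1L] - 1L,
                orientation = "forward"))
  m <- Biostrings::matchPattern(revcomp(b), subj, max.mismatch = max_mm)
  if (length(m) > 0L)
    return(list(offset = IRanges::start(m)[1L] - 1L,
                orientation = "reverse"))
  NULL
}

new_item <- function(id, seq) {
  list(seq = seq, score = 0L,
       constituents = data.table(contig_id = id, offset = 0L,
                                 orientation = "forward",
                                 width = nchar(seq)))
}

# remap constituents for a reverse-complemented container of length len
flip_cons <- function(cons, len) {
  cons <- copy(cons)
  cons[, `:=`(offset = len - (offset + width),
              orientation = ifelse(orientation == "forward", "reverse",
                                   "forward"))]
  cons
}

#' Greedy merging of a gap's contigs and high-quality orphan reads
#'
#' Repeatedly merges the pair with the largest qualifying suffix/prefix
#' overlap (ties: more constituents first, then lexicographically smaller
#' merged sequence) until none qualifies. Sequences fully contained in
#' another (within the mismatch rate, either orientation) are absorbed
#' without extension. Inside an overlap, bases are taken from the longer of
#' the two sequences (ties: the one appearing earlier in the input).
#'
#' @param contigs `data.table` with `contig_id`, `seq` (or a named character
#'   vector).
#' @param hq_reads optional character vector (or recruitment table) of
#'   high-quality reads; those not contained in any contig join the merge as
#'   mini-contigs.
#' @param cfg a [merge_config()].
#' @return `data.table` with `merged_id`, `seq`, `score` (total overlap
#'   bases) and a `constituents` list-column of
#'   (`contig_id`, `offset`, `orientation`).
#' @export
merge_all <- function(contigs, hq_reads = NULL, cfg = merge_config()) {
  if (is.character(contigs))
    contigs <- data.table(contig_id = names(contigs) %||%
                            paste0("c", seq_along(contigs)), seq = contigs)
  items <- lapply(seq_len(nrow(contigs)),
                  function(i) new_item(contigs$contig_id[i], contigs$seq[i]))
  if (!is.null(hq_reads) && cfg$use_hq_reads) {
    if (is.data.frame(hq_reads)) {
      ids <- paste0("hq|", hq_reads$name, "/", hq_reads$mate_index)
      seqs <- hq_reads$seq
    } else {
      ids <- names(hq_reads) %||% paste0("hq", seq_along(hq_reads))
      seqs <- hq_reads
    }
    # a read counts as alignable to the contigs (and is excluded) when it
    # is contained in one or shares an end-overlap of at least half its
    # length with one, as an aligner-based filter would decide
    half_cfg <- function(s) merge_config(
      min_overlap = max(10L, nchar(s) %/% 2L),
      max_mismatch_rate = cfg$max_mismatch_rate)
    keep <- vapply(seqs, function(s) {
      hc <- half_cfg(s)
      !any(vapply(contigs$seq, function(cs) {
        !is.null(find_containment(cs, s, cfg$max_mismatch_rate)) ||
          !is.null(overlap(cs, s, hc)) || !is.null(overlap(s, cs, hc))
      }, logical(1)))
    }, logical(1))
    for (i in which(keep & nchar(seqs) >= cfg$min_overlap))
      items[[length(items) + 1L]] <- new_item(ids[i], seqs[i])
  }
  if (length(items) <= 1L) return(items_to_dt(items))

  absorb_contained <- function(items) {
    repeat {
      n <- length(items)
      done <- TRUE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j) next
          # absorb the shorter into the longer; on equal length absorb the
          # later item (covers a contig and its own reverse complement)
          li <- nchar(items[[i]]$seq); lj <- nchar(items[[j]]$seq)
          if (lj > li || (lj == li && j < i)) next
          hit <- find_containment(items[[i]]$seq, items[[j]]$seq,
                                  cfg$max_mismatch_rate)
          if (is.null(hit)) next
          cons <- if (hit$orientation == "reverse")
            flip_cons(items[[j]]$constituents, nchar(items[[j]]$seq))
          else copy(items[[j]]$constituents)
          cons[, offset := offset + hit$offset]
          items[[i]]$constituents <- rbind(items[[i]]$constituents, cons)
          items[[i]]$score <- items[[i]]$score + items[[j]]$score +
            nchar(items[[j]]$seq)
          items <- items[-j]
          done <- FALSE
          break
        }
        if (!done) break
      }
      if (done) return(items)
    }
  }

  items <- absorb_contained(items)
  # overlap cache keyed by the two sequences; merges only invalidate pairs
  # that involve the new item
  memo <- new.env(parent = emptyenv())
  cached_overlap <- function(a, b) {
    key <- paste0(a, "\r", b)
    if (!is.null(v <- memo[[key]])) return(if (identical(v, FALSE)) NULL else v)
    v <- overlap(a, b, cfg)
    memo[[key]] <- if (is.null(v)) FALSE else v
    v
  }
  repeat {
    if (length(items) <= 1L) break
    n <- length(items)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        a_seq <- items[[i]]$seq; b_seq <- items[[j]]$seq
        # two configurations per ordered pair: a+b and rc(a)+b; together
        # with the orientation search on b and the (j,i) pass this covers
        # all four relative orientations of the join
        for (aflip in c(FALSE, TRUE)) {
          a_use <- if (aflip) revcomp(a_seq) else a_seq
          ov <- cached_overlap(a_use, b_seq)
          if (is.null(ov)) next
          cand <- list(i = i, j = j, ov = ov, aflip = aflip,
                       ncons = nrow(items[[i]]$constituents) +
                         nrow(items[[j]]$constituents),
                       merged = merged_seq(a_use, b_seq, ov))
          if (is.null(best) ||
              cand$ov$length > best$ov$length ||
              (cand$ov$length == best$ov$length &&
                 cand$ncons > best$ncons) ||
              (cand$ov$length == best$ov$length &&
                 cand$ncons == best$ncons && cand$merged < best$merged))
            best <- cand
        }
      }
    }
    if (is.null(best)) break
    a <- items[[best$i]]; b <- items[[best$j]]
    acons <- if (best$aflip) flip_cons(a$constituents, nchar(a$seq))
             else copy(a$constituents)
    bcons <- if (best$ov$orientation == "reverse")
      flip_cons(b$constituents, nchar(b$seq)) else copy(b$constituents)
    bcons[, offset := offset + nchar(a$seq) - best$ov$length]
    merged <- list(seq = best$merged,
                   score = a$score + b$score + best$ov$length,
                   constituents = rbind(acons, bcons))
    items <- items[-sort(c(best$i, best$j))]
    items[[length(items) + 1L]] <- merged
    items <- absorb_contained(items)
  }
  items_to_dt(items)
}

# overlap-region bases come from the longer sequence
merged_seq <- function(a, b, ov) {
  bseq <- if (ov$orientation == "reverse") revcomp(b) else b
  if (nchar(b) > nchar(a)) {
    paste0(substr(a, 1L, nchar(a) - ov$length), bseq)
  } else {
    paste0(a, substr(bseq, ov$length + 1L, nchar(bseq)))
  }
}

items_to_dt <- function(items) {
  if (length(items) == 0L)
    return(data.table(merged_id = character(), seq = character(),
                      score = integer(), constituents = list()))
  dt <- data.table(
    merged_id = sprintf("m%d", seq_along(items)),
    seq = vapply(items, `[[`, character(1), "seq"),
    score = vapply(items, function(x) as.integer(x$score), integer(1)),
    constituents = lapply(items, `[[`, "constituents"))
  setorder(dt, -score, seq)
  dt[, merged_id := sprintf("m%d", seq_len(.N))]
  dt[]
}
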