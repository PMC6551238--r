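# Recruitment of gap-associated reads from draft-genome alignments.
#
# Four classes are collected per gap:
#   type i   - unmapped mates of reads anchored within m+3v+l of a breakpoint
#   type ii  - repeat-associated reads: mapq-0 mates of reads inside the
#              recruitment window [b1-m-3v-l, b2+m+3v+l], plus mapq-0 reads
#              within [p-d/2, p+d/2] of each such mate at position p
#   type iii - reads soft-clipped within clip_slack of a breakpoint
#   type iv  - doubly-unmapped pairs, assigned later by aligning them to the
#              stage-1 contigs (see recruit_unmapped())
#
# A read may be recruited by several gaps; it is then used for all of them.

# Append mate columns (m_mapped, m_scaffold, m_pos, m_mapq) by self-join on
# (name, other mate index).
annotate_mates <- function(aln) {
  if ("m_mapped" %in% names(aln)) return(aln)
  mate <- aln[, .(name, mate_index = 3L - mate_index, m_mapped = mapped,
                  m_scaffold = scaffold, m_pos = pos, m_mapq = mapq)]
  out <- merge(aln, mate, by = c("name", "mate_index"), all.x = TRUE,
               sort = FALSE)
  out[is.na(m_mapped), m_mapped := FALSE]
  out
}

#' Classify a read pair's concordance against its library geometry
#'
#' A pair is DISCORDANT when both mates map to one scaffold but the observed
#' insert size falls outside \eqn{[m - 3v, m + 3v]} or the orientation is not
#' forward-reverse (innie); CROSS_SCAFFOLD when the mates map to different
#' scaffolds.
#'
#' @param pair a two-row alignment `data.table` (both mates of one pair).
#' @param stats a list or one-row data.frame with `m` (insert mean) and `v`
#'   (insert SD).
#' @return one of `"CONCORDANT"`, `"DISCORDANT"`, `"CROSS_SCAFFOLD"`,
#'   `"HALF_MAPPED"`, `"BOTH_UNMAPPED"`.
#' @export
concordance <- function(pair, stats) {
  stopifnot(nrow(pair) == 2L)
  n_mapped <- sum(pair$mapped)
  if (n_mapped == 0L) return("BOTH_UNMAPPED")
  if (n_mapped == 1L) return("HALF_MAPPED")
  if (pair$scaffold[1] != pair$scaffold[2]) return("CROSS_SCAFFOLD")
  left <- which.min(pair$pos); right <- 3L - left
  insert <- max(pair$end) - min(pair$pos)
  proper <- !pair$reverse[left] && pair$reverse[right]
  lo <- stats$m - 3 * stats$v; hi <- stats$m + 3 * stats$v
  if (proper && insert >= lo && insert <= hi) "CONCORDANT" else "DISCORDANT"
}

#' Collect type-i reads: unmapped mates of breakpoint-anchored reads
#'
#' Anchors are mapped reads whose leftmost position lies within
#' \eqn{m + 3v + l} of a breakpoint, on the gap-facing side, with an unmapped
#' mate. All anchors are considered regardless of mapping quality; mates of
#' mapq-60 anchors are additionally tagged high quality (`hq`), and mates of
#' anchors above `min_anchor_mapq` are tagged `confident`.
#'
#' @param aln alignment `data.table` (see [read_alignments()]).
#' @param gap one-row gap record with `gap_id`, `scaffold`, `b1`, `b2`.
#' @param stats library stats with `m`, `v`, `l`.
#' @param min_anchor_mapq anchor mapq above which the mate is `confident`.
#' @param require_orientation only accept anchors oriented into the gap
#'   (forward-strand left of `b1`, reverse-strand right of `b2`).
#' @return recruited-read `data.table` (`name`, `mate_index`, `seq`, `qual`,
#'   `library`, `type`, `hq`, `confident`, `gap_id`).
#' @export
collect_type_i <- function(aln, gap, stats, min_anchor_mapq = 30L,
                           require_orientation = TRUE) {
  aln <- annotate_mates(aln)
  W <- stats$m + 3 * stats$v + stats$l
  anchors <- aln[mapped & !m_mapped & scaffold == gap$scaffold]
  if (nrow(anchors) == 0L) return(empty_recruits())
  left_ok <- anchors$pos >= gap$b1 - W & anchors$pos < gap$b1 &
    (!require_orientation | !anchors$reverse)
  right_ok <- anchors$pos >= gap$b2 & anchors$pos < gap$b2 + W &
    (!require_orientation | anchors$reverse)
  anchors <- anchors[left_ok | right_ok]
  if (nrow(anchors) == 0L) return(empty_recruits())
  mates <- merge(
    anchors[, .(name, mate_index = 3L - mate_index, anchor_mapq = mapq)],
    aln[, .(name, mate_index, seq, qual, library)],
    by = c("name", "mate_index"), sort = FALSE)
  mates[, .(name, mate_index, seq, qual, library, type = "i",
            hq = anchor_mapq == 60L,
            confident = anchor_mapq > min_anchor_mapq,
            gap_id = gap$gap_id)]
}

#' Collect type-ii reads: repeat-associated discordant and mapq-0 reads
#'
#' Two rules: (a) every read B with mapq 0 whose mate lies inside the
#' recruitment window \eqn{[b1 - m - 3v - l, b2 + m + 3v + l]} while B itself
#' lies outside it; (b) for each such B aligned at position p, every mapq-0
#' read within \eqn{[p - d/2, p + d/2]} on B's scaffold, where d is the gap
#' length. These reads likely originate inside a repeat-associated gap but
#' were placed on another copy of the repeat.
#'
#' @inheritParams collect_type_i
#' @return recruited-read `data.table`.
#' @export
collect_type_ii <- function(aln, gap, stats) {
  aln <- annotate_mates(aln)
  W <- stats$m + 3 * stats$v + stats$l
  lo <- gap$b1 - W; hi <- gap$b2 + W
  inside <- function(sc, p) !is.na(p) & sc == gap$scaffold & p >= lo & p <= hi
  # (a) mapq-0 reads whose mate is inside the window, B itself outside it
  b <- aln[mapped & mapq == 0L & m_mapped & inside(m_scaffold, m_pos) &
             !inside(scaffold, pos)]
  # (b) mapq-0 neighbourhoods around each recruited B
  nb <- list()
  if (nrow(b)) {
    half <- gap$d / 2
    mq0 <- aln[mapped & mapq == 0L]
    nb <- lapply(seq_len(nrow(b)), function(i) {
      mq0[scaffold == b$scaffold[i] & pos >= b$pos[i] - half &
            pos <= b$pos[i] + half]
    })
  }
  out <- rbindlist(c(list(b), nb), fill = TRUE)
  if (nrow(out) == 0L) return(empty_recruits())
  out <- out[!duplicated(paste(name, mate_index))]
  out[, .(name, mate_index, seq, qual, library, type = "ii", hq = FALSE,
          confident = FALSE, gap_id = gap$gap_id)]
}

#' Collect type-iii reads: reads soft-clipped at the gap breakpoints
#'
#' Recruits reads whose soft-clip boundary lies within `clip_slack` of a
#' breakpoint with the clipped portion (length at least `min_clip`) pointing
#' into the gap: right-clipped reads ending near `b1`, left-clipped reads
#' starting near `b2`.
#'
#' @inheritParams collect_type_i
#' @param clip_slack allowed distance (bp) between clip position and
#'   breakpoint (default 20).
#' @param min_clip minimum clipped-portion length (default 10).
#' @return recruited-read `data.table`; `hq` marks mapq-60 records.
#' @export
collect_type_iii <- function(aln, gap, clip_slack = 20L, min_clip = 10L) {
  cand <- aln[mapped & scaffold == gap$scaffold]
  if (nrow(cand) == 0L) return(empty_recruits())
  left_bp <- cand$clip_right >= min_clip & abs(cand$end - gap$b1) <= clip_slack
  right_bp <- cand$clip_left >= min_clip & abs(cand$pos - gap$b2) <= clip_slack
  out <- cand[left_bp | right_bp]
  if (nrow(out) == 0L) return(empty_recruits())
  out <- out[!duplicated(paste(name, mate_index))]
  out[, .(name, mate_index, seq, qual, library, type = "iii",
          hq = mapq == 60L, confident = mapq >= 30L, gap_id = gap$gap_id)]
}

#' Collect the doubly-unmapped read pool
#'
#' Pairs with both mates unmapped cannot be assigned to a gap from the
#' draft alignment; they are pooled here and assigned by
#' [recruit_unmapped()] after stage-1 contigs exist.
#'
#' @param aln alignment `data.table`.
#' @return `data.table` of records belonging to doubly-unmapped pairs.
#' @export
collect_unmapped_pool <- function(aln) {
  aln <- annotate_mates(aln)
  aln[!mapped & !m_mapped,
      .(name, mate_index, seq, qual, library)]
}

empty_recruits <- function() {
  data.table(name = character(), mate_index = integer(), seq = character(),
             qual = character(), library = character(), type = character(),
             hq = logical(), confident = logical(), gap_id = character())
}

#' Build per-gap recruited read sets (types i-iii)
#'
#' Runs the three alignment-based collectors for every gap and library and
#' stacks the results. Type-iv membership is added later by
#' [recruit_unmapped()].
#'
#' @param aln alignment `data.table` covering all libraries (the `library`
#'   column must match `lib_stats$library_id`).
#' @param gaps gap table with flanks (see [extract_flanks()]).
#' @param lib_stats library statistics table (see [read_library_stats()]).
#' @param min_anchor_mapq,clip_slack,min_clip,require_orientation collector
#'   parameters.
#' @param collect_type2 set `FALSE` to disable repeat-associated (type-ii)
#'   recruitment, e.g. for ablation experiments.
#' @return recruitment `data.table` over all gaps, one row per
#'   (gap, read, type).
#' @export
build_gap_read_sets <- function(aln, gaps, lib_stats, min_anchor_mapq = 30L,
                                clip_slack = 20L, min_clip = 10L,
                                require_orientation = TRUE,
                                collect_type2 = TRUE) {
  aln <- annotate_mates(aln)
  res <- list()
  for (g in seq_len(nrow(gaps))) {
    gap <- gaps[g]
    if (isTRUE(gap$no_flank)) next
    for (li in seq_len(nrow(lib_stats))) {
      stats <- lib_stats[li]
      sub <- aln[library == stats$library_id]
      res[[length(res) + 1L]] <-
        collect_type_i(sub, gap, stats, min_anchor_mapq, require_orientation)
      if (collect_type2)
        res[[length(res) + 1L]] <- collect_type_ii(sub, gap, stats)
    }
    res[[length(res) + 1L]] <-
      collect_type_iii(aln, gap, clip_slack, min_clip)
  }
  out <- rbindlist(res)
  if (nrow(out) == 0L) return(empty_recruits())
  # a read keeps one row per (gap, type); hq/confident flags are OR-ed
  out[, .(seq = seq[1], qual = qual[1], library = library[1],
          hq = any(hq), confident = any(confident)),
      by = .(gap_id, type, name, mate_index)]
}
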