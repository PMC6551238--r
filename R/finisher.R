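# Gap finishing: anchor merged candidates with the gap flanks, call
# FULL / EXTENDED / UNFILLED, and patch the scaffolds.
#
# A candidate is FULL when the left flank overlaps one side of it and the
# right flank the other side, both in the same orientation; the sequence
# between the two flank hits is the gap sequence. Among several FULL
# candidates the longest wins. Otherwise the candidate (or one per side)
# covering the gap the most provides EXTENDED sequence.

# Align one flank against a candidate (fixed orientation). Returns NULL or
# list(start, end, prox_clip, identity, span) in 1-based candidate coords.
align_flank <- function(flank, candidate, side, end_slack, min_identity,
                        min_span) {
  if (nchar(flank) < min_span || nchar(candidate) < min_span) return(NULL)
  # cheap screen: a qualifying hit implies the flank's gap-proximal 60 bp
  # nearly always contain an exact 20-mer of the candidate
  n <- nchar(flank)
  if (n >= 60L) {
    hit <- FALSE
    for (o in c(0L, 20L, 40L)) {
      s <- if (side == "left") substr(flank, n - o - 19L, n - o)
           else substr(flank, 1L + o, 20L + o)
      if (grepl(s, candidate, fixed = TRUE)) { hit <- TRUE; break }
    }
    if (!hit) return(NULL)
  }
  pa <- Biostrings::pairwiseAlignment(flank, candidate, type = "overlap")
  pr <- methods::slot(Biostrings::pattern(pa), "range")
  sr <- methods::slot(Biostrings::subject(pa), "range")
  span <- IRanges::width(pr)
  if (span < min_span) return(NULL)
  ident <- Biostrings::pid(pa) / 100
  if (ident < min_identity) return(NULL)
  # proximal end of the flank is the gap-facing one
  if (side == "left") {
    prox_clip <- nchar(flank) - IRanges::end(pr)
    distal_clip <- min(IRanges::start(pr) - 1L, IRanges::start(sr) - 1L)
  } else {
    prox_clip <- IRanges::start(pr) - 1L
    distal_clip <- min(nchar(flank) - IRanges::end(pr),
                       nchar(candidate) - IRanges::end(sr))
  }
  if (prox_clip > end_slack || distal_clip > end_slack) return(NULL)
  list(start = IRanges::start(sr), end = IRanges::end(sr),
       prox_clip = prox_clip, identity = ident, span = span)
}

#' Anchor the two gap flanks on a candidate sequence
#'
#' Reports, per orientation of the candidate, the best qualifying
#' semi-global hit of each flank: identity at least `min_identity` over at
#' least `min_span` bases, the flank's gap-proximal end within `end_slack`
#' of an interior candidate position, and its distal end either fully
#' aligned or running off the candidate end.
#'
#' @param candidate candidate gap sequence (character scalar).
#' @param left_flank,right_flank flank sequences from [extract_flanks()].
#' @param end_slack allowed soft-clip at flank ends (default 15).
#' @param min_identity,min_span qualifying-alignment thresholds.
#' @return nested list: `$forward` / `$reverse`, each with `$left`, `$right`
#'   hits (or NULL).
#' @export
anchor_flanks <- function(candidate, left_flank, right_flank,
                          end_slack = 15L, min_identity = 0.95,
                          min_span = 30L) {
  out <- list()
  for (ori in c("forward", "reverse")) {
    cand <- if (ori == "reverse") revcomp(candidate) else candidate
    out[[ori]] <- list(
      left = align_flank(left_flank, cand, "left", end_slack, min_identity,
                         min_span),
      right = align_flank(right_flank, cand, "right", end_slack,
                          min_identity, min_span))
  }
  out
}

#' Choose a gap's closure from its merged candidates
#'
#' FULL closures require both flanks anchored in the same orientation with
#' the left hit ending before the right hit starts; among FULL candidates
#' the longest is chosen. Otherwise coverage of the gap is maximised:
#' extension length is capped at the gap length `d` and extensions below
#' `min_extension` are discarded; one candidate per side may contribute when
#' no single candidate covers both.
#'
#' @param candidates merged-candidate table from [merge_all()] (needs `seq`,
#'   `merged_id`).
#' @param left_flank,right_flank flank sequences.
#' @param d gap length estimate (N-run length).
#' @param gap_id gap label for the result.
#' @param end_slack,min_identity,min_span anchoring thresholds.
#' @param min_extension extensions below this are treated as noise
#'   (default 10).
#' @return one-row `data.table`: `gap_id`, `status` (FULL / EXTENDED /
#'   UNFILLED), `gap_sequence`, `left_seq`, `right_seq`, `left_extension`,
#'   `right_extension`, `chosen_contig`, `orientation`.
#' @export
choose_closure <- function(candidates, left_flank, right_flank, d,
                           gap_id = "gap", end_slack = 15L,
                           min_identity = 0.95, min_span = 30L,
                           min_extension = 10L) {
  empty <- data.table(gap_id = gap_id, status = "UNFILLED",
                      gap_sequence = NA_character_, left_seq = NA_character_,
                      right_seq = NA_character_, left_extension = 0L,
                      right_extension = 0L, chosen_contig = NA_character_,
                      orientation = NA_character_)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  full <- list(); ext_left <- list(); ext_right <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates$seq[i]
    anch <- anchor_flanks(cand, left_flank, right_flank, end_slack,
                          min_identity, min_span)
    for (ori in c("forward", "reverse")) {
      cseq <- if (ori == "reverse") revcomp(cand) else cand
      L <- anch[[ori]]$left; R <- anch[[ori]]$right
      if (!is.null(L) && !is.null(R)) {
        if (R$start > L$end) {
          gseq <- if (R$start - 1L >= L$end + 1L)
            substr(cseq, L$end + 1L, R$start - 1L) else ""
          full[[length(full) + 1L]] <- data.table(
            idx = i, ori = ori, len = nchar(cand), gap_sequence = gseq)
        }
        # flanks both on one end: contradictory geometry, candidate dropped
        next
      }
      if (!is.null(L)) {
        e <- nchar(cseq) - L$end
        if (e >= min_extension)
          ext_left[[length(ext_left) + 1L]] <- data.table(
            idx = i, ori = ori,
            ext = min(e, d), seq = substr(cseq, L$end + 1L, nchar(cseq)))
      }
      if (!is.null(R)) {
        e <- R$start - 1L
        if (e >= min_extension)
          ext_right[[length(ext_right) + 1L]] <- data.table(
            idx = i, ori = ori,
            ext = min(e, d), seq = substr(cseq, 1L, R$start - 1L))
      }
    }
  }
  full <- rbindlist(full)
  if (nrow(full) > 0L) {
    setorder(full, -len, idx, ori)
    best <- full[1L]
    return(data.table(gap_id = gap_id, status = "FULL",
                      gap_sequence = best$gap_sequence,
                      left_seq = NA_character_, right_seq = NA_character_,
                      left_extension = 0L, right_extension = 0L,
                      chosen_contig = candidates$merged_id[best$idx],
                      orientation = best$ori))
  }
  ext_left <- rbindlist(ext_left); ext_right <- rbindlist(ext_right)
  bl <- if (nrow(ext_left)) ext_left[order(-ext, idx)][1L] else NULL
  br <- if (nrow(ext_right)) ext_right[order(-ext, idx)][1L] else NULL
  # prefer a single candidate covering both sides if one exists
  if (nrow(ext_left) && nrow(ext_right)) {
    both <- merge(ext_left, ext_right, by = c("idx", "ori"),
                  suffixes = c("_l", "_r"))
    if (nrow(both)) {
      both[, cover := pmin(ext_l + ext_r, d)]
      bb <- both[order(-cover, idx)][1L]
      single_best <- max(if (is.null(bl)) 0L else bl$ext,
                         if (is.null(br)) 0L else br$ext)
      if (bb$cover >= single_best) {
        extL <- bb$ext_l; extR <- bb$ext_r
        if (extL + extR >= d) {
          # the two extensions meet or overlap: cap at the gap length
          extR <- max(d - extL, 0L)
        }
        return(data.table(gap_id = gap_id, status = "EXTENDED",
                          gap_sequence = NA_character_,
                          left_seq = substr(bb$seq_l, 1L, extL),
                          right_seq = substr(bb$seq_r,
                                             nchar(bb$seq_r) - extR + 1L,
                                             nchar(bb$seq_r)),
                          left_extension = extL, right_extension = extR,
                          chosen_contig = candidates$merged_id[bb$idx],
                          orientation = bb$ori))
      }
    }
  }
  if (is.null(bl) && is.null(br)) return(empty)
  extL <- if (is.null(bl)) 0L else bl$ext
  extR <- if (is.null(br)) 0L else br$ext
  if (extL + extR >= d) extR <- max(d - extL, 0L)
  chosen <- if (!is.null(bl) && (is.null(br) || bl$ext >= br$ext))
    candidates$merged_id[bl$idx] else candidates$merged_id[br$idx]
  data.table(gap_id = gap_id, status = "EXTENDED",
             gap_sequence = NA_character_,
             left_seq = if (is.null(bl)) NA_character_ else
               substr(bl$seq, 1L, extL),
             right_seq = if (is.null(br)) NA_character_ else
               substr(br$seq, nchar(br$seq) - extR + 1L, nchar(br$seq)),
             left_extension = extL, right_extension = extR,
             chosen_contig = chosen,
             orientation = if (!is.null(bl)) bl$ori else br$ori)
}

#' Patch closed gaps into the draft scaffolds
#'
#' FULL gaps have their N-run replaced by the closed sequence; EXTENDED gaps
#' keep a residual N-run of length `max(d - covered, 1)` between the
#' extensions; everything else is untouched.
#'
#' @param draft named character vector of scaffolds.
#' @param gaps gap table (with `b1`, `b2`).
#' @param results closure results table (stacked [choose_closure()] rows).
#' @return named character vector of patched scaffolds, in input order.
#' @export
patch_scaffolds <- function(draft, gaps, results) {
  out <- draft
  tab <- merge(gaps, results, by = "gap_id")
  setorder(tab, scaffold, -b1)      # right-to-left keeps coordinates valid
  for (i in seq_len(nrow(tab))) {
    r <- tab[i]
    if (!r$status %in% c("FULL", "EXTENDED")) next
    sc <- out[[r$scaffold]]
    repl <- if (r$status == "FULL") {
      r$gap_sequence
    } else {
      resid <- max(r$d - r$left_extension - r$right_extension, 1L)
      paste0(ifelse(is.na(r$left_seq), "", r$left_seq),
             strrep("N", resid),
             ifelse(is.na(r$right_seq), "", r$right_seq))
    }
    out[[r$scaffold]] <- paste0(substr(sc, 1L, r$b1), repl,
                                substr(sc, r$b2 + 1L, nchar(sc)))
  }
  out
}
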