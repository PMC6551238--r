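# Assessment of closures, two ways:
#  * reference-based: align the gap flanks to a trusted reference; when both
#    flanks map uniquely (mapq 60), nearly fully (soft-clip <= 15 bp), in
#    the same orientation on one sequence, the spanned reference interval is
#    the "true" gap sequence and closures are scored against it;
#  * reference-free: rebuild each closure as flank + gap sequence + flank,
#    align the reads back, and require unclipped joint-spanning reads plus
#    near-complete >= 10x coverage.

#' Extract "true" gap sequences from a reference genome
#'
#' @param gaps gap table with flanks (see [extract_flanks()]).
#' @param reference named character vector of reference sequences.
#' @param flank_aln optional alignment `data.table` (see
#'   [read_alignments()]) of the flanks to the reference, with read names
#'   `<gap_id>|L` and `<gap_id>|R`; computed with BWA-MEM when `NULL`.
#' @param end_slack maximum soft-clip per flank alignment (default 15).
#' @return `data.table`: `gap_id`, `usable`, `reason`, `true_seq`,
#'   `ref_scaffold`, `left_map_pos`, `right_map_pos`, `orientation`.
#' @export
extract_truth <- function(gaps, reference, flank_aln = NULL,
                          end_slack = 15L) {
  if (is.null(flank_aln)) {
    wd <- tempfile("truth"); dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE), add = TRUE)
    ref_fa <- file.path(wd, "ref.fa")
    write_fasta(reference, ref_fa)
    fl <- gaps[no_flank == FALSE]
    seqs <- c(setNames(fl$left_flank, paste0(fl$gap_id, "|L")),
              setNames(fl$right_flank, paste0(fl$gap_id, "|R")))
    fq <- file.path(wd, "flanks.fastq")
    writeLines(as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+",
                               vapply(nchar(seqs), strrep, character(1),
                                      x = "I"))), fq)
    bam <- file.path(wd, "flanks.bam")
    bwa_mem(ref_fa, fq, NULL, bam, sort = "none")
    flank_aln <- read_alignments(bam)
  }
  res <- lapply(gaps$gap_id, function(gid) {
    rec <- function(usable, reason, true_seq = NA_character_,
                    sc = NA_character_, lp = NA_integer_, rp = NA_integer_,
                    ori = NA_character_)
      data.table(gap_id = gid, usable = usable, reason = reason,
                 true_seq = true_seq, ref_scaffold = sc, left_map_pos = lp,
                 right_map_pos = rp, orientation = ori)
    L <- flank_aln[name == paste0(gid, "|L")]
    R <- flank_aln[name == paste0(gid, "|R")]
    if (nrow(L) != 1L || nrow(R) != 1L)
      return(rec(FALSE, "MISSING_OR_SPLIT"))
    if (!L$mapped || !R$mapped) return(rec(FALSE, "UNMAPPED"))
    if (L$mapq != 60L || R$mapq != 60L) return(rec(FALSE, "NOT_UNIQUE"))
    if (max(L$clip_left, L$clip_right, R$clip_left, R$clip_right) >
          end_slack)
      return(rec(FALSE, "CLIPPED"))
    if (L$reverse != R$reverse) return(rec(FALSE, "ORIENTATION"))
    if (L$scaffold != R$scaffold) return(rec(FALSE, "SPLIT_REFERENCE"))
    refseq <- reference[[L$scaffold]]
    if (!L$reverse) {
      if (L$end > R$pos) return(rec(FALSE, "ORDER"))
      ts <- substr(refseq, L$end + 1L, R$pos)
      ori <- "forward"
    } else {
      # mirrored layout on the reference
      if (R$end > L$pos) return(rec(FALSE, "ORDER"))
      ts <- revcomp(substr(refseq, R$end + 1L, L$pos))
      ori <- "reverse"
    }
    rec(TRUE, "OK", ts, L$scaffold, L$pos, R$pos, ori)
  })
  rbindlist(res)
}

#' Score a closed (or extended) sequence against the true gap sequence
#'
#' CORRECT when the sequence aligns to the truth with at most `end_slack`
#' soft-clip on each of its ends and identity at least `min_identity`
#' (either orientation); NOT_ASSESSABLE when the truth is unusable.
#'
#' @param closed_seq the closed gap sequence (for EXTENDED closures, score
#'   each extension separately and combine).
#' @param true_seq the "true" gap sequence, or `NA`.
#' @param usable whether the truth record is usable.
#' @param end_slack allowed clip per end (default 15).
#' @param min_identity identity threshold over the aligned span.
#' @return `"CORRECT"`, `"INCORRECT"`, or `"NOT_ASSESSABLE"`.
#' @export
score_closure <- function(closed_seq, true_seq, usable = TRUE,
                          end_slack = 15L, min_identity = 0.95) {
  if (!isTRUE(usable) || is.na(true_seq) || !nzchar(true_seq))
    return("NOT_ASSESSABLE")
  if (is.na(closed_seq) || !nzchar(closed_seq)) return("INCORRECT")
  ok <- function(qry, sbj) {
    pa <- Biostrings::pairwiseAlignment(qry, sbj, type = "overlap")
    pr <- methods::slot(Biostrings::pattern(pa), "range")
    if (IRanges::width(pr) < 1L) return(FALSE)
    # soft-clip allowance applies to the ends of the closed sequence
    clip_l <- IRanges::start(pr) - 1L
    clip_r <- nchar(qry) - IRanges::end(pr)
    clip_l <= end_slack && clip_r <= end_slack &&
      Biostrings::pid(pa) / 100 >= min_identity
  }
  if (ok(closed_seq, true_seq) || ok(revcomp(closed_seq), true_seq))
    "CORRECT" else "INCORRECT"
}

#' Score a table of closures against truth records
#'
#' FULL closures are scored on their gap sequence; EXTENDED closures on each
#' extension (both present extensions must be CORRECT).
#'
#' @param results closure results table (see [choose_closure()]).
#' @param truth truth table from [extract_truth()].
#' @param end_slack,min_identity see [score_closure()].
#' @return `results` with an added `score` column.
#' @export
score_closures <- function(results, truth, end_slack = 15L,
                           min_identity = 0.95) {
  out <- merge(results, truth[, .(gap_id, usable, true_seq)], by = "gap_id",
               all.x = TRUE, sort = FALSE)
  out[, score := vapply(seq_len(.N), function(i) {
    r <- out[i]
    if (r$status == "FULL")
      return(score_closure(r$gap_sequence, r$true_seq, r$usable, end_slack,
                           min_identity))
    if (r$status == "EXTENDED") {
      parts <- c(if (!is.na(r$left_seq) && nzchar(r$left_seq)) r$left_seq,
                 if (!is.na(r$right_seq) && nzchar(r$right_seq)) r$right_seq)
      if (length(parts) == 0L) return("NOT_ASSESSABLE")
      sc <- vapply(parts, score_closure, character(1),
                   true_seq = r$true_seq, usable = r$usable,
                   end_slack = end_slack, min_identity = min_identity)
      if (any(sc == "NOT_ASSESSABLE")) return("NOT_ASSESSABLE")
      return(if (all(sc == "CORRECT")) "CORRECT" else "INCORRECT")
    }
    "NOT_ASSESSABLE"
  }, character(1))]
  out
}

# construct = left150 + closure + right150; EXTENDED keeps a residual N-run
build_validation_constructs <- function(results, gaps, flank_len = 150L) {
  tab <- merge(gaps, results, by = "gap_id")
  tab <- tab[status %in% c("FULL", "EXTENDED")]
  if (nrow(tab) == 0L) return(list(seqs = character(0), info = NULL))
  seqs <- character(nrow(tab)); info <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i]
    lf <- substr(r$left_flank, max(1L, nchar(r$left_flank) - flank_len + 1L),
                 nchar(r$left_flank))
    rf <- substr(r$right_flank, 1L, flank_len)
    mid <- if (r$status == "FULL") r$gap_sequence else
      paste0(ifelse(is.na(r$left_seq), "", r$left_seq),
             strrep("N", max(r$d - r$left_extension - r$right_extension, 1L)),
             ifelse(is.na(r$right_seq), "", r$right_seq))
    seqs[i] <- paste0(lf, mid, rf)
    info[[i]] <- data.table(gap_id = r$gap_id, construct_len = nchar(seqs[i]),
                            joint_left = nchar(lf),
                            joint_right = nchar(lf) + nchar(mid))
  }
  names(seqs) <- tab$gap_id
  list(seqs = seqs, info = rbindlist(info))
}

#' Reference-free validation of closures by read-back alignment
#'
#' Each closure is rebuilt as `flank + gap sequence + flank` (default 150 bp
#' flanks), all reads are aligned back with BWA-MEM, and the closure is
#' validated when at least `min_joint_reads` reads span each flank/closure
#' joint without clipping inside a 20 bp window around it, and at least
#' `min_frac` of the construct's non-N bases have coverage at least
#' `min_cov`.
#'
#' @param results closure results table.
#' @param gaps gap table with flanks.
#' @param fastq_pairs `data.table` with columns `fq1`, `fq2` (one row per
#'   library).
#' @param flank_len flank length in the construct (default 150).
#' @param min_joint_reads required joint-spanning reads per joint
#'   (default 10).
#' @param min_cov,min_frac coverage thresholds (default 10x over 95%).
#' @param joint_margin required unclipped margin on each side of a joint.
#' @return `data.table`: `gap_id`, `joint_left_reads`, `joint_right_reads`,
#'   `frac_ge_cov`, `validated`.
#' @export
validate_by_reads <- function(results, gaps, fastq_pairs, flank_len = 150L,
                              min_joint_reads = 10L, min_cov = 10L,
                              min_frac = 0.95, joint_margin = 20L) {
  bc <- build_validation_constructs(results, gaps, flank_len)
  base <- data.table(gap_id = results$gap_id, joint_left_reads = 0L,
                     joint_right_reads = 0L, frac_ge_cov = 0,
                     validated = FALSE)
  if (length(bc$seqs) == 0L) return(base)
  wd <- tempfile("validate"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  fa <- file.path(wd, "constructs.fa")
  write_fasta(bc$seqs, fa)
  alns <- list()
  for (i in seq_len(nrow(fastq_pairs))) {
    bam <- file.path(wd, sprintf("lib%d.bam", i))
    bwa_mem(fa, fastq_pairs$fq1[i], fastq_pairs$fq2[i], bam, sort = "none")
    alns[[i]] <- read_alignments(bam, sprintf("lib%d", i))
  }
  aln <- rbindlist(alns)[mapped == TRUE]
  for (i in seq_len(nrow(bc$info))) {
    inf <- bc$info[i]
    sub <- aln[scaffold == inf$gap_id]
    cs <- bc$seqs[[inf$gap_id]]
    if (inf$construct_len < 1L || nrow(sub) == 0L) next
    spans <- function(j) sum(sub$pos <= j - joint_margin &
                               sub$end >= j + joint_margin)
    jl <- spans(inf$joint_left); jr <- spans(inf$joint_right)
    cov <- IRanges::coverage(IRanges::IRanges(sub$pos + 1L, sub$end),
                             width = inf$construct_len)
    covv <- as.integer(cov)
    non_n <- which(strsplit(cs, "")[[1]] != "N")
    frac <- if (length(non_n)) mean(covv[non_n] >= min_cov) else 0
    base[gap_id == inf$gap_id,
         `:=`(joint_left_reads = jl, joint_right_reads = jr,
              frac_ge_cov = frac,
              validated = jl >= min_joint_reads & jr >= min_joint_reads &
                frac >= min_frac)]
  }
  base
}
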