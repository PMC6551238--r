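# Pipeline orchestration: align -> collect -> assemble (pass 1) -> finish
# (pass 1) -> recruit doubly-unmapped pairs -> assemble (pass 2) -> merge ->
# finish (final) -> patch. Each gap is processed independently; a failure
# on one gap marks it ERROR without aborting the run.

#' Default pipeline parameters
#'
#' @param flank_len flank length for anchoring (default 300).
#' @param min_gap_len minimum N-run length treated as a gap.
#' @param min_anchor_mapq,clip_slack,min_clip recruitment parameters.
#' @param end_slack,min_identity,min_span,min_extension finishing
#'   parameters.
#' @param assembly an [assembly_config()].
#' @param merge a [merge_config()].
#' @param collect_type2 recruit repeat-associated (type-ii) reads.
#' @return list of parameters.
#' @export
pipeline_params <- function(flank_len = 300L, min_gap_len = 1L,
                            min_anchor_mapq = 30L, clip_slack = 20L,
                            min_clip = 10L, end_slack = 15L,
                            min_identity = 0.95, min_span = 30L,
                            min_extension = 10L,
                            assembly = assembly_config(),
                            merge = merge_config(), collect_type2 = TRUE) {
  list(flank_len = flank_len, min_gap_len = min_gap_len,
       min_anchor_mapq = min_anchor_mapq, clip_slack = clip_slack,
       min_clip = min_clip, end_slack = end_slack,
       min_identity = min_identity, min_span = min_span,
       min_extension = min_extension, assembly = assembly, merge = merge,
       collect_type2 = collect_type2)
}

# unique read sequences recruited for one gap, restricted to given types
gap_read_seqs <- function(recruits, gid, types) {
  r <- recruits[gap_id == gid & type %in% types]
  if (nrow(r) == 0L) return(character(0))
  unique(r, by = c("name", "mate_index"))$seq
}

finish_one <- function(merged, gap, params) {
  choose_closure(merged, gap$left_flank, gap$right_flank, gap$d,
                 gap_id = gap$gap_id, end_slack = params$end_slack,
                 min_identity = params$min_identity,
                 min_span = params$min_span,
                 min_extension = params$min_extension)
}

#' Close the gaps of a draft genome
#'
#' Runs the full gap-closing pipeline. Reads are aligned to the draft with
#' BWA-MEM unless pre-aligned BAMs are given in `libraries$bam`.
#'
#' @param draft_fa draft genome FASTA path.
#' @param libraries `data.table` describing the libraries: `library_id`,
#'   `m`, `v`, `l`, `kind`, and `fq1`/`fq2` (FASTQ pair) or `bam`
#'   (pre-aligned, coordinate-sorted).
#' @param workdir working directory for intermediate files (default a
#'   tempdir).
#' @param params a [pipeline_params()] list.
#' @return list with `gaps`, `results` (per-gap closure table), `scaffolds`
#'   (patched draft), `recruits` (recruitment table), `contigs`, `paths`.
#' @export
close_gaps <- function(draft_fa, libraries, workdir = tempfile("gapfill"),
                       params = pipeline_params()) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  draft <- read_draft(draft_fa)
  gaps <- find_gaps(draft, params$min_gap_len)
  gaps <- extract_flanks(gaps, draft, params$flank_len)
  lib_stats <- as.data.table(libraries)

  # 1. genome-wide alignment (or ingest of provided BAMs)
  alns <- list()
  for (i in seq_len(nrow(lib_stats))) {
    lib <- lib_stats[i]
    bam <- if ("bam" %in% names(lib) && !is.na(lib$bam) && nzchar(lib$bam)) {
      lib$bam
    } else {
      out <- file.path(workdir, paste0(lib$library_id, ".bam"))
      bwa_mem(draft_fa, lib$fq1, lib$fq2, out)
      out
    }
    alns[[i]] <- read_alignments(bam, lib$library_id)
  }
  aln <- annotate_mates(rbindlist(alns))

  # 2. recruit types i-iii per gap
  recruits <- build_gap_read_sets(
    aln, gaps, lib_stats, min_anchor_mapq = params$min_anchor_mapq,
    clip_slack = params$clip_slack, min_clip = params$min_clip,
    collect_type2 = params$collect_type2)

  closable <- gaps[no_flank == FALSE]
  results1 <- list(); contigs1 <- list(); errors <- character(0)
  for (g in seq_len(nrow(closable))) {
    gap <- closable[g]
    res <- tryCatch({
      reads <- gap_read_seqs(recruits, gap$gap_id, c("i", "ii", "iii"))
      ctg <- assemble_gap(reads, params$assembly, gap$gap_id)
      contigs1[[gap$gap_id]] <- ctg
      merged <- if (nrow(ctg)) merge_all(ctg[, .(contig_id, seq)],
                                         cfg = params$merge) else NULL
      finish_one(merged, gap, params)
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", gap$gap_id, conditionMessage(e)))
      data.table(gap_id = gap$gap_id, status = "ERROR",
                 gap_sequence = NA_character_, left_seq = NA_character_,
                 right_seq = NA_character_, left_extension = 0L,
                 right_extension = 0L, chosen_contig = NA_character_,
                 orientation = NA_character_)
    })
    results1[[gap$gap_id]] <- res
  }
  results1 <- rbindlist(results1)
  contigs1 <- rbindlist(contigs1)

  # 3. assign doubly-unmapped pairs to still-open gaps via pass-1 contigs
  full1 <- results1[status == "FULL", gap_id]
  open_ids <- setdiff(closable$gap_id, full1)
  pool <- collect_unmapped_pool(aln)
  recruits_iv <- recruit_unmapped(pool, contigs1, open_ids)
  recruits <- rbindlist(list(recruits, recruits_iv), use.names = TRUE)

  # 4. pass 2 on open gaps: reassemble with type-iv, merge with HQ orphans
  results2 <- list()
  for (g in seq_len(nrow(closable))) {
    gap <- closable[g]
    if (gap$gap_id %in% full1) {
      results2[[gap$gap_id]] <- results1[gap_id == gap$gap_id]
      next
    }
    res <- tryCatch({
      reads <- gap_read_seqs(recruits, gap$gap_id,
                             c("i", "ii", "iii", "iv"))
      ctg2 <- assemble_gap(reads, params$assembly,
                           paste0(gap$gap_id, ".p2"))
      ctg <- rbindlist(list(contigs1[gap_id == gap$gap_id], ctg2))
      ctg <- ctg[!duplicated(seq)]
      hq <- recruits[gap_id == gap$gap_id & hq == TRUE]
      hq <- unique(hq, by = c("name", "mate_index"))
      merged <- if (nrow(ctg))
        merge_all(ctg[, .(contig_id, seq)],
                  hq_reads = if (nrow(hq)) hq else NULL,
                  cfg = params$merge)
      else if (nrow(hq))
        merge_all(data.table(contig_id = character(), seq = character()),
                  hq_reads = hq, cfg = params$merge)
      else NULL
      finish_one(merged, gap, params)
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", gap$gap_id, conditionMessage(e)))
      data.table(gap_id = gap$gap_id, status = "ERROR",
                 gap_sequence = NA_character_, left_seq = NA_character_,
                 right_seq = NA_character_, left_extension = 0L,
                 right_extension = 0L, chosen_contig = NA_character_,
                 orientation = NA_character_)
    })
    results2[[gap$gap_id]] <- res
  }
  results <- rbindlist(results2)
  if (nrow(gaps[no_flank == TRUE])) {
    results <- rbindlist(list(results, data.table(
      gap_id = gaps[no_flank == TRUE, gap_id], status = "NO_FLANK",
      gap_sequence = NA_character_, left_seq = NA_character_,
      right_seq = NA_character_, left_extension = 0L, right_extension = 0L,
      chosen_contig = NA_character_, orientation = NA_character_)))
  }
  setkey(results, gap_id)
  results <- results[gaps$gap_id]   # deterministic gap order

  scaffolds <- patch_scaffolds(draft, gaps, results)
  out_fa <- file.path(workdir, "filled.fa")
  out_tsv <- file.path(workdir, "results.tsv")
  write_fasta(scaffolds, out_fa)
  fwrite(results[, .(gap_id, status, left_extension, right_extension,
                     chosen_contig, orientation)], out_tsv, sep = "\t")
  list(gaps = gaps, results = results, scaffolds = scaffolds,
       recruits = recruits, contigs = contigs1, errors = errors,
       paths = list(filled = out_fa, results = out_tsv, workdir = workdir))
}

#' Run the pipeline from a configuration list
#'
#' Thin wrapper over [close_gaps()] accepting the layout written by
#' [simulate_fixture()] (a draft FASTA plus a `libs.tsv`).
#'
#' @param draft_fa draft FASTA path.
#' @param libs_tsv library stats TSV with `fq1`/`fq2` or `bam` columns.
#' @param workdir working directory.
#' @param ... overrides passed to [pipeline_params()].
#' @return see [close_gaps()].
#' @export
run_pipeline <- function(draft_fa, libs_tsv, workdir = tempfile("gapfill"),
                         ...) {
  libraries <- read_library_stats(libs_tsv)
  close_gaps(draft_fa, libraries, workdir, params = pipeline_params(...))
}
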