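# Shared test fixtures: random sequences, tiling reads, toy SAM writing,
# and a lazily-built (then cached) default synthetic pipeline run used by
# the acceptance tests.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# error-free reads of length l tiling src at the given step, covering the
# final position
tile_reads <- function(src, l = 100L, step = 3L) {
  L <- nchar(src)
  starts <- unique(c(seq(1L, L - l + 1L, by = step), L - l + 1L))
  substring(src, starts, starts + l - 1L)
}

# Write a toy SAM file. `dt` columns: qname, flag, rname ("*" if unmapped),
# pos1 (1-based; 0 if unmapped), mapq, cigar, seq. RNEXT/PNEXT left "*"/0:
# the package joins mates by name, not by these fields.
write_toy_sam <- function(dt, path, sq = c(s1 = 100000L, s2 = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  qual <- vapply(nchar(dt$seq), strrep, character(1), x = "I")
  qual[dt$seq == "*"] <- "*"
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  dt$qname, dt$flag, dt$rname, dt$pos1, dt$mapq, dt$cigar,
                  dt$seq, qual)
  # SAM requires coordinate sort for asBam
  ord <- order(match(dt$rname, c(names(sq), "*")), dt$pos1)
  writeLines(c(hdr, body[ord]), path)
  path
}

# one-row gap table with flanks, as extract_flanks() would produce
make_gap_row <- function(gap_id = "g1", scaffold = "s1", b1, b2,
                         left_flank = strrep("A", 300),
                         right_flank = strrep("C", 300)) {
  data.table::data.table(gap_id = gap_id, scaffold = scaffold, b1 = b1,
                         b2 = b2, d = b2 - b1, left_flank = left_flank,
                         right_flank = right_flank, no_flank = FALSE)
}

# ---- cached default-fixture pipeline runs (expensive; built on demand) ----

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    set.seed(1)
    .fixture_cache$fx <- gapfillr::simulate_fixture(
      gapfillr::sim_config(seed = 1L),
      file.path(tempdir(), "gapfillr-default-fixture"))
  }
  .fixture_cache$fx
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    fx <- default_fixture()
    .fixture_cache$run <- gapfillr::run_pipeline(
      fx$paths$draft, fx$paths$libs,
      file.path(tempdir(), "gapfillr-default-run"))
  }
  .fixture_cache$run
}

ablated_run <- function() {
  if (is.null(.fixture_cache$ablated)) {
    fx <- default_fixture()
    .fixture_cache$ablated <- gapfillr::run_pipeline(
      fx$paths$draft, fx$paths$libs,
      file.path(tempdir(), "gapfillr-ablated-run"), collect_type2 = FALSE)
  }
  .fixture_cache$ablated
}

# score a closure table against the simulator's truth table: FULL closures
# on their gap sequence, EXTENDED closures on both extensions
score_against_planted <- function(results, truth_tab) {
  res <- merge(results, truth_tab[, list(gap_id, true_seq, in_repeat)],
               by = "gap_id")
  res$score <- mapply(function(st, gs, ts, ls, rs) {
    if (st == "FULL") return(gapfillr::score_closure(gs, ts))
    if (st == "EXTENDED") {
      parts <- c(if (!is.na(ls) && nzchar(ls)) ls,
                 if (!is.na(rs) && nzchar(rs)) rs)
      if (length(parts) == 0L) return("NOT_ASSESSABLE")
      sc <- vapply(parts, gapfillr::score_closure, "", true_seq = ts)
      return(if (all(sc == "CORRECT")) "CORRECT" else "INCORRECT")
    }
    "NOT_ASSESSABLE"
  }, res$status, res$gap_sequence, res$true_seq, res$left_seq,
  res$right_seq)
  res
}

# crafted flank-to-reference alignment records for one gap; defaults are
# the usable case: both flanks mapq 60, unclipped, forward, left first
mk_flank_aln <- function(gap_id = "g1", mapq = c(60L, 60L),
                         reverse = c(FALSE, FALSE),
                         scaffold = c("ref", "ref"),
                         pos = c(1000L, 1700L), clip = c(0L, 0L),
                         width = 300L) {
  data.table::data.table(
    name = paste0(gap_id, c("|L", "|R")), mate_index = 1L, mapped = TRUE,
    scaffold = scaffold, pos = pos, end = pos + width - clip,
    mapq = mapq, reverse = reverse, cigar = "300M",
    clip_left = 0L, clip_right = clip, seq = "", qual = "",
    library = "flanks")
}

default_scored <- function() {
  if (is.null(.fixture_cache$scored)) {
    fx <- default_fixture()
    run <- default_run()
    truth <- gapfillr::extract_truth(run$gaps, fx$genome$reference)
    .fixture_cache$scored <- gapfillr::score_closures(run$results, truth)
  }
  .fixture_cache$scored
}

# ---- crafted 12-pair SAM exercising every recruitment window exactly -----
# gap on s1 at [10000, 10500); library m=300 v=30 l=100 so the type-i
# window is 490 and the type-ii region is [9510, 10990]; d/2 = 250.
toy_window_sam <- function(path) {
  A <- strrep("A", 100); G <- strrep("G", 100)
  rec <- function(qname, flag, rname, pos1, mapq, cigar, seq)
    data.table::data.table(qname = qname, flag = flag, rname = rname,
                           pos1 = pos1, mapq = mapq, cigar = cigar,
                           seq = seq)
  dt <- rbind(
    # p01: anchor fwd mapq60 at 9520 (480 <= 490), mate unmapped -> type i, hq
    rec("p01", 65L, "s1", 9521L, 60L, "100M", A),
    rec("p01", 133L, "*", 0L, 0L, "*", G),
    # p02: anchor at 9400 (600 > 490) -> mate not recruited
    rec("p02", 65L, "s1", 9401L, 40L, "100M", A),
    rec("p02", 133L, "*", 0L, 0L, "*", G),
    # p03: low-mapq anchor (20) still recruits its mate, not hq/confident
    rec("p03", 65L, "s1", 9601L, 20L, "100M", A),
    rec("p03", 133L, "*", 0L, 0L, "*", G),
    # p04: reverse anchor right of b2 at 10600 (100 <= 490) -> type i, hq
    rec("p04", 81L, "s1", 10601L, 60L, "100M", A),
    rec("p04", 133L, "*", 0L, 0L, "*", G),
    # p05: forward-strand anchor right of b2: wrong orientation, skipped
    rec("p05", 65L, "s1", 10601L, 60L, "100M", A),
    rec("p05", 133L, "*", 0L, 0L, "*", G),
    # p06: mate A inside [9510,10990], read B mapq0 at 50000 -> B type ii
    rec("p06", 65L, "s1", 9601L, 60L, "100M", A),
    rec("p06", 129L, "s1", 50001L, 0L, "100M", A),
    # p07: mapq0 read at 50200, inside [49750, 50250] around B -> type ii
    rec("p07", 65L, "s1", 50201L, 0L, "100M", A),
    rec("p07", 129L, "s1", 52001L, 60L, "100M", A),
    # p08: mapq0 read at 50400, outside the d/2 neighbourhood -> skipped
    rec("p08", 65L, "s1", 50401L, 0L, "100M", A),
    rec("p08", 129L, "s1", 52001L, 60L, "100M", A),
    # p09: mate inside window but read B mapq 15 -> not type ii
    rec("p09", 65L, "s1", 9601L, 60L, "100M", A),
    rec("p09", 129L, "s1", 60001L, 15L, "100M", A),
    # p10: right-clipped exactly at b1 (end 10000) -> type iii, hq
    rec("p10", 65L, "s1", 9931L, 60L, "70M30S", A),
    rec("p10", 145L, "s1", 9701L, 60L, "100M", A),
    # p11: clip boundary at 9965, 35 bp from b1 (> 20 slack) -> skipped
    rec("p11", 65L, "s1", 9896L, 60L, "70M30S", A),
    rec("p11", 145L, "s1", 9701L, 60L, "100M", A),
    # p12: both mates unmapped -> unmapped pool
    rec("p12", 77L, "*", 0L, 0L, "*", G),
    rec("p12", 141L, "*", 0L, 0L, "*", G))
  write_toy_sam(dt, path)
}

toy_window_gap <- function() make_gap_row("g1", "s1", 10000L, 10500L)
toy_window_stats <- function() list(library_id = "lib1", m = 300, v = 30,
                                    l = 100, kind = "PE")

write_fastq_pair_test <- function(reads, prefix) {
  gapfillr:::write_fastq_pair(reads$name, reads$seq1, reads$seq2, prefix)
}
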