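# The fixture generator: genomes with planted repeats, gapped drafts,
# paired reads. Scaled-down configurations keep the unit suite fast; the
# default configuration is exercised by the acceptance suite.

small_cfg <- function(seed = 11L, ...) {
  sim_config(genome_len = 20000L, n_repeat_families = 2L,
             copies_per_family = 3L, n_gaps = 4L, seed = seed,
             libraries = list(list(library_id = "pe", m = 300, v = 30,
                                   l = 100, coverage = 20,
                                   error_rate = 0.005, kind = "PE")), ...)
}

test_that("simulate_genome is deterministic and honours divergence", {
  g1 <- simulate_genome(small_cfg())
  g2 <- simulate_genome(small_cfg())
  expect_identical(g1$reference, g2$reference)
  expect_identical(g1$repeats, g2$repeats)

  g0 <- simulate_genome(small_cfg(divergence = 0))
  seqs <- substring(g0$reference[[1]], g0$repeats$start + 1L,
                    g0$repeats$end)
  for (f in unique(g0$repeats$family))
    expect_equal(length(unique(seqs[g0$repeats$family == f])), 1L)
})

test_that("a repeat-free genome has no duplicated 31-mers", {
  cfg <- small_cfg(); cfg$n_repeat_families <- 0L
  g <- simulate_genome(cfg)
  k31 <- kmerize(g$reference[[1]], 31L)
  expect_true(all(k31$count == 1L))
})

test_that("make_draft round-trips: truth re-inserted reproduces reference", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  dr <- make_draft(g, cfg)
  rebuilt <- dr$draft[[1]]
  for (i in rev(seq_len(nrow(dr$truth)))) {
    tr <- dr$truth[i]
    rebuilt <- paste0(substr(rebuilt, 1, tr$start), tr$true_seq,
                      substr(rebuilt, tr$end + 1, nchar(rebuilt)))
  }
  expect_identical(rebuilt, g$reference[[1]])
  # gap ids match find_gaps on the draft
  found <- find_gaps(dr$draft)
  expect_equal(found$gap_id, dr$truth$gap_id)
  expect_equal(found$b1, dr$truth$start)
  expect_equal(found$b2, dr$truth$end)
})

test_that("zero gaps leave the draft equal to the reference", {
  cfg <- small_cfg(); cfg$n_gaps <- 0L
  g <- simulate_genome(cfg)
  dr <- make_draft(g, cfg)
  expect_identical(dr$draft[[1]], g$reference[[1]])
})

test_that("repeat-fraction gaps intersect repeat copies", {
  cfg <- sim_config(genome_len = 20000L, n_repeat_families = 2L,
                    copies_per_family = 3L, seed = 11L,
                    frac_repeat_gaps = 1, n_gaps = 2L,
                    libraries = list(list(library_id = "pe", m = 300,
                                          v = 30, l = 100, coverage = 20,
                                          error_rate = 0.005, kind = "PE")))
  g <- simulate_genome(cfg)
  dr <- make_draft(g, cfg)
  for (i in seq_len(nrow(dr$truth))) {
    tr <- dr$truth[i]
    expect_true(any(pmin(g$repeats$end, tr$end) -
                      pmax(g$repeats$start, tr$start) > 0))
  }
})

test_that("read simulation: insert model, coverage and concordance", {
  set.seed(12)
  ref <- c(chr = rand_seq(50000))
  lib <- list(library_id = "pe", m = 300, v = 30, l = 100, coverage = 30,
              error_rate = 0, kind = "PE")
  reads <- simulate_reads(ref, lib, seed = 12L)
  # coverage within 10% of nominal
  depth <- nrow(reads) * 2 * lib$l / nchar(ref[[1]])
  expect_lt(abs(depth - 30) / 30, 0.1)

  # v = 0: every fragment has length exactly m (mate 2 ends at start+m)
  lib0 <- list(library_id = "pe", m = 300, v = 0, l = 100, coverage = 2,
               error_rate = 0, kind = "PE")
  r0 <- simulate_reads(ref, lib0, seed = 13L)
  for (i in sample(nrow(r0), 20)) {
    p1 <- regexpr(r0$seq1[i], ref[[1]], fixed = TRUE)
    p2 <- regexpr(revcomp(r0$seq2[i]), ref[[1]], fixed = TRUE)
    expect_equal(as.integer(p2) + lib0$l - 1L - as.integer(p1) + 1L, 300L)
  }

  # re-aligning error-free pairs gives CONCORDANT for > 99%
  wd <- tempfile(); dir.create(wd)
  fa <- file.path(wd, "ref.fa"); write_fasta(ref, fa)
  fq <- write_fastq_pair_test(reads, file.path(wd, "pe"))
  bam <- file.path(wd, "pe.bam")
  bwa_mem(fa, fq[1], fq[2], bam)
  aln <- read_alignments(bam, "pe")
  st <- list(m = 300, v = 30)
  status <- vapply(split(seq_len(nrow(aln)), aln$name), function(ix) {
    if (length(ix) != 2L) return(NA_character_)
    concordance(aln[ix], st)
  }, character(1))
  expect_gt(mean(status == "CONCORDANT", na.rm = TRUE), 0.99)
})

test_that("simulate_fixture writes a complete, consistent bundle", {
  fx <- simulate_fixture(small_cfg(), tempfile("fxsmall"))
  expect_true(all(file.exists(unlist(fx$paths))))
  expect_true(all(file.exists(fx$libraries$fq1, fx$libraries$fq2)))
  draft <- read_draft(fx$paths$draft)
  expect_equal(nrow(find_gaps(draft)), nrow(fx$truth))
  st <- read_library_stats(fx$paths$libs)
  expect_equal(st$library_id, "pe")
})
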