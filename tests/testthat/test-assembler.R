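# k-mer counting and the de Bruijn micro-assembler.

test_that("kmerize canonicalizes by reverse complement", {
  # "ACGTA": 3-mers ACG, CGT, GTA; CGT's rc is ACG, so {ACG:2, GTA:1}
  k <- kmerize("ACGTA", 3L)
  expect_equal(k[order(kmer)],
               data.table::data.table(kmer = c("ACG", "GTA"),
                                      count = c(2L, 1L)),
               ignore_attr = TRUE)
  expect_equal(nrow(kmerize(character(0), 3L)), 0L)
  expect_warning(k2 <- kmerize("ACG", 31L), "no reads")
  expect_equal(nrow(k2), 0L)
  # non-ACGT k-mers are dropped
  expect_equal(nrow(kmerize("ACNGT", 3L)), 0L)
  # min_count filter
  expect_equal(kmerize("ACGTA", 3L, min_count = 2L)$kmer, "ACG")
})

test_that("error-free tiling reads assemble to the source sequence", {
  set.seed(101)
  for (rep in 1:5) {
    src <- rand_seq(500)
    reads <- tile_reads(src)
    ctg <- assemble_gap(reads, assembly_config(min_kmer_count = 1L), "g")
    expect_equal(nrow(ctg), 3L)   # one contig per k
    expect_true(all(ctg$seq == src | ctg$seq == revcomp(src)))
    # every constituent k-mer of the contig is in the filtered k-mer set
    k <- ctg$k_used[1]
    ktab <- kmerize(reads, k, 1L)
    ckmers <- substring(ctg$seq[1], 1:(nchar(ctg$seq[1]) - k + 1),
                        k:nchar(ctg$seq[1]))
    rc <- revcomp(ckmers)
    expect_true(all(ifelse(ckmers <= rc, ckmers, rc) %in% ktab$kmer))
  }
})

test_that("reads from two disjoint sources yield non-chimeric contigs", {
  set.seed(102)
  src1 <- rand_seq(500); src2 <- rand_seq(500)
  reads <- c(tile_reads(src1), tile_reads(src2))
  ctg <- assemble_gap(reads, assembly_config(min_kmer_count = 1L,
                                             k_values = 31L), "g")
  expect_gte(nrow(ctg), 2L)
  expect_true(all(ctg$seq %in% c(src1, src2, revcomp(src1), revcomp(src2))))
})

test_that("no reads give an empty contig list", {
  expect_equal(nrow(assemble_gap(character(0), assembly_config(), "g")), 0L)
})

test_that("low-count error k-mers are filtered at depth", {
  set.seed(103)
  src <- rand_seq(500)
  reads <- rep(tile_reads(src, step = 2L), 2L)   # every k-mer seen >= 2x
  # one singleton read with an error in the middle
  bad <- paste0(substr(src, 200, 249), "A", substr(src, 251, 299))
  ctg <- assemble_gap(c(reads, bad), assembly_config(), "g")
  expect_equal(nrow(ctg), 3L)
  expect_true(all(ctg$seq == src | ctg$seq == revcomp(src)))
})

test_that("recruit_unmapped assigns doubly-unmapped pairs by contig hit", {
  set.seed(104)
  srcA <- rand_seq(400); srcB <- rand_seq(400)
  contigs <- data.table::data.table(
    contig_id = c("cA", "cB"), gap_id = c("gA", "gB"),
    seq = c(srcA, srcB))
  pool <- data.table::data.table(
    name = c("u1", "u1", "u2", "u2"), mate_index = c(1L, 2L, 1L, 2L),
    seq = c(substr(srcA, 50, 149),            # exact substring of gA contig
            revcomp(substr(srcA, 200, 299)),  # mate, reverse strand
            rand_seq(100), rand_seq(100)),    # matches nothing
    qual = strrep("I", 100), library = "lib1")
  out <- recruit_unmapped(pool, contigs, c("gA", "gB"), use_bwa = FALSE)
  expect_setequal(out[gap_id == "gA", name], "u1")
  expect_equal(nrow(out[gap_id == "gA"]), 2L)  # read and its mate
  expect_equal(nrow(out[gap_id == "gB"]), 0L)
  expect_true(all(out$type == "iv"))

  # a read matching contigs of two gaps joins both
  contigs2 <- rbind(contigs,
                    data.table::data.table(contig_id = "cA2", gap_id = "gC",
                                           seq = srcA))
  out2 <- recruit_unmapped(pool, contigs2, c("gA", "gB", "gC"),
                           use_bwa = FALSE)
  expect_setequal(out2[name == "u1", unique(gap_id)], c("gA", "gC"))

  # fully-closed gaps receive nothing
  out3 <- recruit_unmapped(pool, contigs, "gB", use_bwa = FALSE)
  expect_equal(nrow(out3), 0L)
})

test_that("adding true reads never shrinks the assembly (property)", {
  set.seed(105)
  src <- rand_seq(600)
  half <- tile_reads(substr(src, 1, 350))
  more <- tile_reads(src)
  cfg <- assembly_config(min_kmer_count = 1L, k_values = 31L)
  base <- assemble_gap(half, cfg, "g")
  grown <- assemble_gap(c(half, more), cfg, "g")
  expect_gte(sum(nchar(grown$seq)), sum(nchar(base$seq)))
})
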