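# Read-pair concordance and the four recruitment rules.

mk_pair <- function(mapped = c(TRUE, TRUE), scaffold = c("s1", "s1"),
                    pos = c(1000L, 1250L), end = pos + 100L,
                    reverse = c(FALSE, TRUE)) {
  data.table::data.table(name = "r", mate_index = 1:2, mapped = mapped,
                         scaffold = scaffold, pos = pos, end = end,
                         mapq = 60L, reverse = reverse)
}

test_that("concordance follows the [m-3v, m+3v] insert window", {
  st <- list(m = 300, v = 30)
  # observed insert 350 in [210, 390], proper orientation
  expect_equal(concordance(mk_pair(pos = c(1000L, 1250L)), st), "CONCORDANT")
  # observed insert 2000
  expect_equal(concordance(mk_pair(pos = c(1000L, 2900L)), st), "DISCORDANT")
  # wrong orientation at a proper distance
  expect_equal(concordance(mk_pair(reverse = c(TRUE, FALSE)), st),
               "DISCORDANT")
  expect_equal(concordance(mk_pair(scaffold = c("s1", "s7")), st),
               "CROSS_SCAFFOLD")
  expect_equal(concordance(mk_pair(mapped = c(TRUE, FALSE)), st),
               "HALF_MAPPED")
  expect_equal(concordance(mk_pair(mapped = c(FALSE, FALSE)), st),
               "BOTH_UNMAPPED")
})

test_that("recruitment windows match hand-computed decisions on the toy SAM", {
  sam <- toy_window_sam(tempfile(fileext = ".sam"))
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 24L)
  gap <- toy_window_gap()
  st <- toy_window_stats()

  t1 <- collect_type_i(aln, gap, st)
  expect_setequal(t1$name, c("p01", "p03", "p04"))
  expect_true(t1[name == "p01", hq])
  expect_true(t1[name == "p04", hq])
  expect_false(t1[name == "p03", hq])
  expect_false(t1[name == "p03", confident])
  # recruited reads are the unmapped mates (all seq G in the fixture)
  expect_true(all(grepl("^G+$", t1$seq)))

  # without the orientation filter the wrong-facing anchor also recruits
  t1b <- collect_type_i(aln, gap, st, require_orientation = FALSE)
  expect_setequal(t1b$name, c("p01", "p03", "p04", "p05"))

  t2 <- collect_type_ii(aln, gap, st)
  expect_setequal(t2$name, c("p06", "p07"))
  expect_equal(t2[name == "p06", mate_index], 2L)  # read B, not read A
  expect_equal(t2[name == "p07", mate_index], 1L)  # the mapq0 neighbour

  t3 <- collect_type_iii(aln, gap)
  expect_equal(t3$name, "p10")
  expect_true(t3$hq)
  # a wider slack admits the 35 bp-away clip
  expect_setequal(collect_type_iii(aln, gap, clip_slack = 40L)$name,
                  c("p10", "p11"))

  pool <- collect_unmapped_pool(aln)
  expect_setequal(pool$name, "p12")
  expect_equal(nrow(pool), 2L)
})

test_that("type-ii mate positions always lie inside the recruitment window", {
  sam <- toy_window_sam(tempfile(fileext = ".sam"))
  aln <- gapfillr:::annotate_mates(read_alignments(sam))
  gap <- toy_window_gap(); st <- toy_window_stats()
  t2 <- collect_type_ii(aln, gap, st)
  W <- st$m + 3 * st$v + st$l
  for (nm in t2[mate_index == 2L, name]) {
    mate_pos <- aln[name == nm & mate_index == 1L, pos]
    expect_true(mate_pos >= gap$b1 - W && mate_pos <= gap$b2 + W)
  }
})

test_that("a read satisfying two gaps' windows joins both read sets", {
  sam <- toy_window_sam(tempfile(fileext = ".sam"))
  aln <- read_alignments(sam)
  gaps <- rbind(toy_window_gap(),
                make_gap_row("g2", "s1", 9990L, 10490L))
  st <- data.table::as.data.table(toy_window_stats())
  rec <- build_gap_read_sets(aln, gaps, st)
  shared <- rec[name == "p01" & type == "i"]
  expect_setequal(shared$gap_id, c("g1", "g2"))
})

test_that("duplicate records collapse and empty input yields empty output", {
  sam <- tempfile(fileext = ".sam")
  A <- strrep("A", 50)
  dt <- data.table::data.table(
    qname = c("d1", "d1", "d1"), flag = c(65L, 65L, 129L),
    rname = "s1", pos1 = c(101L, 101L, 401L), mapq = 60L, cigar = "50M",
    seq = A)
  write_toy_sam(dt, sam)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 2L)
  expect_equal(nrow(collect_unmapped_pool(gapfillr:::empty_alignments())), 0L)
})
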