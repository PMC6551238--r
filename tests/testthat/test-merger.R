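# Prefix-suffix overlap detection and greedy contig merging.

# brute-force longest qualifying suffix/prefix overlap, one orientation
bf_overlap <- function(a, b, min_overlap, rate) {
  best <- NULL
  for (len in seq(min(nchar(a), nchar(b)), min_overlap)) {
    sa <- substr(a, nchar(a) - len + 1, nchar(a))
    sb <- substr(b, 1, len)
    mm <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
    if (mm <= rate * len) { best <- list(length = len, mismatches = mm); break }
  }
  best
}

test_that("overlap finds the longest qualifying suffix/prefix match", {
  cfg <- merge_config(min_overlap = 10L, max_mismatch_rate = 0)
  set.seed(201)
  src <- rand_seq(300)
  a <- substr(src, 1, 180); b <- substr(src, 141, 300)
  ov <- overlap(a, b, cfg)
  expect_equal(ov$length, 40L)
  expect_equal(ov$mismatches, 0L)
  expect_equal(ov$orientation, "forward")

  # orientation search finds the overlap on the rc strand
  ovr <- overlap(a, revcomp(b), cfg)
  expect_equal(ovr$length, 40L)
  expect_equal(ovr$orientation, "reverse")

  # disjoint random 200-mers: no qualifying overlap
  expect_null(overlap(rand_seq(200), rand_seq(200), cfg))

  # mismatch tolerance admits a 1-error overlap
  b_err <- paste0("T", substr(b, 2, 160))
  b_err <- sub("^T", ifelse(substr(b, 1, 1) == "T", "A", "T"), b_err)
  expect_null(overlap(a, b_err, cfg))
  ov2 <- overlap(a, b_err, merge_config(min_overlap = 10L,
                                        max_mismatch_rate = 0.05))
  expect_equal(ov2$length, 40L)
  expect_equal(ov2$mismatches, 1L)
})

test_that("overlap agrees with a brute-force oracle on random fragments", {
  set.seed(202)
  cfg <- merge_config(min_overlap = 15L, max_mismatch_rate = 0.02)
  for (rep in 1:20) {
    src <- rand_seq(400)
    cut1 <- sample(100:250, 1); cut2 <- sample(30:90, 1)
    a <- substr(src, 1, cut1 + cut2)
    b <- substr(src, cut1, 400)
    ov <- overlap(a, b, cfg)
    bf <- bf_overlap(a, b, cfg$min_overlap, cfg$max_mismatch_rate)
    expect_equal(ov$length, bf$length)
    expect_equal(ov$mismatches, bf$mismatches)
  }
})

test_that("three tiling contigs merge to the source sequence", {
  set.seed(203)
  src <- rand_seq(600)
  frags <- c(substr(src, 1, 250), substr(src, 201, 450),
             substr(src, 401, 600))
  m <- merge_all(data.table::data.table(contig_id = c("a", "b", "c"),
                                        seq = frags))
  expect_equal(nrow(m), 1L)
  expect_true(m$seq %in% c(src, revcomp(src)))
  expect_setequal(m$constituents[[1]]$contig_id, c("a", "b", "c"))
})

test_that("a contig and its reverse complement collapse to one", {
  set.seed(204)
  a <- rand_seq(200)
  m <- merge_all(data.table::data.table(contig_id = c("f", "r"),
                                        seq = c(a, revcomp(a))))
  expect_equal(nrow(m), 1L)
})

test_that("inputs with no qualifying overlaps pass through unchanged", {
  set.seed(205)
  frags <- replicate(4, rand_seq(150))
  m <- merge_all(data.table::data.table(contig_id = paste0("c", 1:4),
                                        seq = frags))
  expect_equal(nrow(m), 4L)
  expect_setequal(m$seq, frags)
})

test_that("every input contig ends up in exactly one merged contig", {
  set.seed(206)
  for (rep in 1:10) {
    src <- rand_seq(800)
    n <- sample(3:6, 1)
    starts <- sort(sample(1:500, n))
    frags <- substring(src, starts, pmin(starts + sample(200:300, n,
                                                         TRUE), 800))
    ids <- paste0("c", seq_len(n))
    m <- merge_all(data.table::data.table(contig_id = ids, seq = frags))
    seen <- unlist(lapply(m$constituents, `[[`, "contig_id"))
    expect_setequal(seen, ids)
    expect_equal(length(seen), n)   # exactly once
  }
})

test_that("merging is idempotent", {
  set.seed(207)
  src <- rand_seq(500)
  frags <- c(substr(src, 1, 220), substr(src, 180, 380),
             substr(src, 350, 500), rand_seq(120))
  m1 <- merge_all(data.table::data.table(contig_id = paste0("c", 1:4),
                                         seq = frags))
  m2 <- merge_all(m1[, .(contig_id = merged_id, seq)])
  expect_setequal(m2$seq, m1$seq)
})

test_that("mismatches in an overlap resolve to the longer constituent", {
  set.seed(208)
  src <- rand_seq(300)
  long <- substr(src, 1, 250)
  short_true <- substr(src, 211, 300)
  # corrupt one base of the short fragment inside the overlap region
  ch <- strsplit(short_true, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  short <- paste(ch, collapse = "")
  m <- merge_all(data.table::data.table(contig_id = c("long", "short"),
                                        seq = c(long, short)),
                 cfg = merge_config(min_overlap = 20L,
                                    max_mismatch_rate = 0.05))
  expect_equal(nrow(m), 1L)
  # the disputed base comes from the longer fragment, i.e. the source
  expect_true(m$seq %in% c(src, revcomp(src)))
})
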