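# Flank anchoring, closure calling, scaffold patching.

setup_candidate <- function(seed = 301, insert_len = 400) {
  set.seed(seed)
  list(lf = rand_seq(300), rf = rand_seq(300), ins = rand_seq(insert_len))
}

test_that("anchor_flanks reports FULL geometry for exact constructs", {
  x <- setup_candidate()
  cand <- paste0(x$lf, x$ins, x$rf)
  a <- anchor_flanks(cand, x$lf, x$rf)
  expect_false(is.null(a$forward$left))
  expect_false(is.null(a$forward$right))
  expect_equal(a$forward$left$end, 300L)
  expect_equal(a$forward$right$start, 701L)
  # reverse-complemented candidate anchors in reverse orientation
  ar <- anchor_flanks(revcomp(cand), x$lf, x$rf)
  expect_false(is.null(ar$reverse$left))
  expect_false(is.null(ar$reverse$right))
  expect_true(is.null(ar$forward$left) || is.null(ar$forward$right))
})

test_that("choose_closure implements FULL / EXTENDED / UNFILLED logic", {
  x <- setup_candidate()
  cand_full <- paste0(x$lf, x$ins, x$rf)
  cands <- data.table::data.table(
    merged_id = c("m1", "m2", "m3", "m4"),
    seq = c(cand_full, revcomp(cand_full),
            paste0(x$lf, substr(x$ins, 1, 120)), rand_seq(500)))
  r1 <- choose_closure(cands[1], x$lf, x$rf, 400L, "g")
  expect_equal(r1$status, "FULL")
  expect_equal(r1$gap_sequence, x$ins)
  expect_equal(r1$orientation, "forward")
  r2 <- choose_closure(cands[2], x$lf, x$rf, 400L, "g")
  expect_equal(r2$status, "FULL")
  expect_equal(r2$orientation, "reverse")
  expect_equal(r2$gap_sequence, x$ins)
  r3 <- choose_closure(cands[3], x$lf, x$rf, 400L, "g")
  expect_equal(r3$status, "EXTENDED")
  expect_equal(r3$left_extension, 120L)
  expect_equal(r3$left_seq, substr(x$ins, 1, 120))
  expect_equal(r3$right_extension, 0L)
  r4 <- choose_closure(cands[4], x$lf, x$rf, 400L, "g")
  expect_equal(r4$status, "UNFILLED")
  expect_equal(choose_closure(NULL, x$lf, x$rf, 400L, "g")$status,
               "UNFILLED")
})

test_that("among several FULL candidates the longest is chosen", {
  x <- setup_candidate(insert_len = 500)
  short_ins <- substr(x$ins, 1, 350)
  # a shorter full candidate built from a (pretend) alternative closure
  cands <- data.table::data.table(
    merged_id = c("small", "big"),
    seq = c(paste0(x$lf, short_ins, x$rf), paste0(x$lf, x$ins, x$rf)))
  r <- choose_closure(cands, x$lf, x$rf, 500L, "g")
  expect_equal(r$status, "FULL")
  expect_equal(r$chosen_contig, "big")
  expect_equal(r$gap_sequence, x$ins)
})

test_that("gap coverage picks the candidate extending the most", {
  x <- setup_candidate(insert_len = 500)
  # (120 + 0) vs (60 + 80): the combined 140 wins
  c_left <- paste0(x$lf, substr(x$ins, 1, 120))
  c_right <- paste0(substr(x$ins, 421, 500), x$rf)
  cands <- data.table::data.table(merged_id = c("a", "b"),
                                  seq = c(c_left, c_right))
  r <- choose_closure(cands, x$lf, x$rf, 500L, "g")
  expect_equal(r$status, "EXTENDED")
  expect_equal(r$left_extension + r$right_extension, 200L)
  expect_equal(r$left_seq, substr(x$ins, 1, 120))
  expect_equal(r$right_seq, substr(x$ins, 421, 500))
})

test_that("patch_scaffolds rewrites gaps and round-trips through find_gaps", {
  set.seed(302)
  lf <- rand_seq(300); rf <- rand_seq(300); ins <- rand_seq(480)
  pre <- rand_seq(200); post <- rand_seq(200)
  draft <- c(sc = paste0(pre, lf, strrep("N", 500), rf, post))
  gaps <- extract_flanks(find_gaps(draft), draft)
  # FULL closure 480 bp into a 500 bp gap: scaffold shrinks by 20
  res_full <- data.table::data.table(
    gap_id = gaps$gap_id, status = "FULL", gap_sequence = ins,
    left_seq = NA_character_, right_seq = NA_character_,
    left_extension = 0L, right_extension = 0L,
    chosen_contig = "m1", orientation = "forward")
  patched <- patch_scaffolds(draft, gaps, res_full)
  expect_equal(nchar(patched[["sc"]]), nchar(draft[["sc"]]) - 20L)
  expect_equal(patched[["sc"]], paste0(pre, lf, ins, rf, post))
  expect_equal(nrow(find_gaps(patched)), 0L)

  # EXTENDED by 120 bp on the left: N-run shrinks to 380
  res_ext <- data.table::data.table(
    gap_id = gaps$gap_id, status = "EXTENDED", gap_sequence = NA_character_,
    left_seq = substr(ins, 1, 120), right_seq = NA_character_,
    left_extension = 120L, right_extension = 0L,
    chosen_contig = "m1", orientation = "forward")
  patched2 <- patch_scaffolds(draft, gaps, res_ext)
  g2 <- find_gaps(patched2)
  expect_equal(g2$d, 380L)

  # UNFILLED: byte-identical scaffold
  res_un <- data.table::data.table(
    gap_id = gaps$gap_id, status = "UNFILLED", gap_sequence = NA_character_,
    left_seq = NA_character_, right_seq = NA_character_,
    left_extension = 0L, right_extension = 0L,
    chosen_contig = NA_character_, orientation = NA_character_)
  expect_identical(patch_scaffolds(draft, gaps, res_un), draft)
})
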