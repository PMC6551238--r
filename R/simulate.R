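# Synthetic fixtures: a genome with dispersed low-divergence repeat
# families, a draft in which selected intervals (biased toward repeat
# copies) are replaced by N-runs, and paired reads with configurable insert
# geometry. Everything is deterministic per seed so pipeline truth-recovery
# is testable end to end.

#' Simulation configuration
#'
#' Defaults describe the standard desk-scale fixture: a 100 kb genome with
#' ten dispersed repeat families of six copies each (600 bp, 0.5%
#' divergence -- low enough that 100 bp reads multi-map across the intact
#' copies, as in young SINE/LINE subfamilies), 20 gaps of 200-800 bp half
#' of which fall inside repeat copies (at most one gapped copy per family,
#' so every family keeps several intact copies to attract the gap copy's
#' reads), a 40x paired-end library (insert 300 +/- 30, 100 bp reads) and
#' a 10x mate-pair library (3000 +/- 300), both with 0.5% substitution
#' error.
#'
#' @param genome_len genome length (bases).
#' @param n_repeat_families,copies_per_family,repeat_len,divergence repeat
#'   model: family count, copies per family, copy length, per-base
#'   substitution rate between a copy and the family consensus.
#' @param n_gaps,gap_len_range,frac_repeat_gaps gap model: number, length
#'   range, fraction of gaps planted inside repeat copies.
#' @param min_gap_spacing minimum distance between planted gaps (default
#'   twice the 300 bp flank length).
#' @param libraries list of library descriptions, each a list with
#'   `library_id`, `m`, `v`, `l`, `coverage`, `error_rate`, `kind`.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 100000L, n_repeat_families = 10L,
                       copies_per_family = 6L, repeat_len = 600L,
                       divergence = 0.005, n_gaps = 20L,
                       gap_len_range = c(200L, 800L),
                       frac_repeat_gaps = 0.5, min_gap_spacing = 600L,
                       libraries = NULL, seed = 1L) {
  if (is.null(libraries))
    libraries <- list(
      list(library_id = "pe300", m = 300, v = 30, l = 100, coverage = 40,
           error_rate = 0.005, kind = "PE"),
      list(library_id = "mp3000", m = 3000, v = 300, l = 100, coverage = 10,
           error_rate = 0.005, kind = "MP"))
  stopifnot(divergence >= 0, divergence <= 1, frac_repeat_gaps >= 0,
            frac_repeat_gaps <= 1)
  structure(list(genome_len = as.integer(genome_len),
                 n_repeat_families = as.integer(n_repeat_families),
                 copies_per_family = as.integer(copies_per_family),
                 repeat_len = as.integer(repeat_len),
                 divergence = divergence, n_gaps = as.integer(n_gaps),
                 gap_len_range = as.integer(gap_len_range),
                 frac_repeat_gaps = frac_repeat_gaps,
                 min_gap_spacing = as.integer(min_gap_spacing),
                 libraries = libraries, seed = as.integer(seed)),
            class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted repeat families
#'
#' Background sequence is i.i.d. uniform over ACGT; each repeat copy is the
#' family consensus with independent per-base substitutions at
#' `cfg$divergence`, written over the background at non-overlapping
#' positions.
#'
#' @param cfg a [sim_config()].
#' @return list with `reference` (named character, one scaffold
#'   `scaffold_1`) and `repeats` (`data.table`: `family`, `copy`, `start`,
#'   `end`, 0-based half-open).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ref <- rand_dna(cfg$genome_len)
  placed <- data.table(family = integer(), copy = integer(),
                       start = integer(), end = integer())
  margin <- 2000L
  copy_spacing <- 300L    # copies need not be far apart, gaps do
  for (f in seq_len(cfg$n_repeat_families)) {
    consensus <- rand_dna(cfg$repeat_len)
    for (cp in seq_len(cfg$copies_per_family)) {
      for (try in 1:2000) {
        s <- sample.int(cfg$genome_len - cfg$repeat_len - 2L * margin,
                        1L) + margin
        e <- s + cfg$repeat_len
        if (nrow(placed) == 0L ||
            all(pmax(placed$start, s) - pmin(placed$end, e) >
                  copy_spacing)) break
        if (try == 2000L) stop("could not place repeat copies")
      }
      copy_seq <- mutate_seq(consensus, cfg$divergence)
      ref <- paste0(substr(ref, 1L, s), copy_seq,
                    substr(ref, e + 1L, nchar(ref)))
      placed <- rbind(placed, data.table(family = f, copy = cp, start = s,
                                         end = e))
    }
  }
  setorder(placed, start)
  list(reference = c(scaffold_1 = ref), repeats = placed)
}

#' Replace intervals of the reference by N-runs to make a gapped draft
#'
#' `cfg$frac_repeat_gaps` of the gaps are planted inside repeat copies (one
#' gap per copy at most), the rest in repeat-free background. Gaps are
#' non-overlapping and at least `cfg$min_gap_spacing` apart so each keeps
#' full-length flanks. The N-run length equals the removed length, so the
#' gap-length estimate matches the truth.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg a [sim_config()].
#' @return list with `draft` (named character), `truth` (`data.table`:
#'   `gap_id`, `start`, `end`, `true_seq`, `in_repeat`); gap ids match
#'   [find_gaps()] on the draft.
#' @export
make_draft <- function(genome, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  ref <- genome$reference[[1]]
  glen <- nchar(ref)
  n_rep <- round(cfg$n_gaps * cfg$frac_repeat_gaps)
  n_rep <- min(n_rep, nrow(genome$repeats))
  intervals <- data.table(start = integer(), end = integer(),
                          in_repeat = logical())
  ok_placement <- function(s, e) {
    s > 400L && e < glen - 400L &&
      (nrow(intervals) == 0L ||
         all(pmax(intervals$start, s) - pmin(intervals$end, e) >
               cfg$min_gap_spacing))
  }
  if (n_rep > 0L) {
    # at most one gapped copy per family, so every family keeps intact
    # copies for the gap copy's reads to multi-map to
    copies <- genome$repeats[sample.int(nrow(genome$repeats))]
    placed <- 0L; used_families <- integer(0)
    for (i in seq_len(nrow(copies))) {
      if (placed == n_rep) break
      if (copies$family[i] %in% used_families) next
      len <- sample(cfg$gap_len_range[1]:cfg$gap_len_range[2], 1L)
      # start inside the copy so the gap intersects it substantially
      lo <- copies$start[i]; hi <- max(lo, copies$end[i] - 50L)
      s <- sample(lo:hi, 1L); e <- s + len
      if (!ok_placement(s, e)) next
      # the gap must not bite into a second copy
      others <- genome$repeats[!(start == copies$start[i] &
                                   end == copies$end[i])]
      if (nrow(others) &&
          any(pmin(others$end, e) - pmax(others$start, s) > 0)) next
      intervals <- rbind(intervals,
                         data.table(start = s, end = e, in_repeat = TRUE))
      placed <- placed + 1L
      used_families <- c(used_families, copies$family[i])
    }
  }
  while (nrow(intervals) < cfg$n_gaps) {
    len <- sample(cfg$gap_len_range[1]:cfg$gap_len_range[2], 1L)
    s <- sample.int(glen - len - 800L, 1L) + 400L
    e <- s + len
    # background gaps avoid repeats entirely
    if (nrow(genome$repeats) &&
        any(pmin(genome$repeats$end, e) - pmax(genome$repeats$start, s) > 0))
      next
    if (!ok_placement(s, e)) next
    intervals <- rbind(intervals,
                       data.table(start = s, end = e, in_repeat = FALSE))
  }
  setorder(intervals, start)
  draft <- ref
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    draft <- paste0(substr(draft, 1L, s), strrep("N", e - s),
                    substr(draft, e + 1L, nchar(draft)))
  }
  truth <- if (nrow(intervals) == 0L) {
    data.table(gap_id = character(), start = integer(), end = integer(),
               true_seq = character(), in_repeat = logical())
  } else {
    intervals[, .(gap_id = sprintf("gap_%04d", .I), start, end,
                  true_seq = substring(ref, start + 1L, end), in_repeat)]
  }
  list(draft = c(scaffold_1 = draft), truth = truth)
}

#' Simulate one paired-read library from a reference
#'
#' Fragment lengths are Normal(m, v) truncated below at 2l (and above at the
#' reference length); mates of length l are taken from the fragment ends in
#' forward-reverse (innie) orientation for both PE and MP libraries;
#' per-base substitution errors at `error_rate`.
#'
#' @param reference named character vector (first sequence is used).
#' @param lib library description (see [sim_config()] `libraries`).
#' @param seed integer seed.
#' @return `data.table` with `name`, `seq1`, `seq2`.
#' @export
simulate_reads <- function(reference, lib, seed = 1L) {
  set.seed(seed)
  ref <- reference[[1]]
  glen <- nchar(ref)
  l <- lib$l
  n_pairs <- ceiling(lib$coverage * glen / (2 * l))
  ins <- pmax(2L * l, pmin(glen, round(rnorm(n_pairs, lib$m, lib$v))))
  start <- vapply(ins, function(d) sample.int(glen - d + 1L, 1L),
                  integer(1))
  r1 <- substring(ref, start, start + l - 1L)
  r2 <- revcomp(substring(ref, start + ins - l, start + ins - 1L))
  if (lib$error_rate > 0) {
    add_err <- function(reads) {
      n_err <- stats::rbinom(length(reads), l, lib$error_rate)
      idx <- which(n_err > 0L)
      for (i in idx) {
        ch <- strsplit(reads[i], "")[[1]]
        at <- sample.int(l, n_err[i])
        for (p in at)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        reads[i] <- paste(ch, collapse = "")
      }
      reads
    }
    r1 <- add_err(r1); r2 <- add_err(r2)
  }
  data.table(name = sprintf("%s_%06d", lib$library_id, seq_len(n_pairs)),
             seq1 = r1, seq2 = r2)
}

#' Generate a complete fixture on disk
#'
#' Writes `reference.fa`, `draft.fa`, `truth.tsv`, `repeats.bed`,
#' per-library FASTQ pairs and `libs.tsv` under `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `cfg`, file `paths`, and the in-memory `genome`,
#'   `draft`, `truth` objects.
#' @export
simulate_fixture <- function(cfg = sim_config(), out_dir = tempfile("fix")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(cfg)
  dr <- make_draft(genome, cfg)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    draft = file.path(out_dir, "draft.fa"),
    truth = file.path(out_dir, "truth.tsv"),
    repeats = file.path(out_dir, "repeats.bed"),
    libs = file.path(out_dir, "libs.tsv"))
  write_fasta(genome$reference, paths$reference)
  write_fasta(dr$draft, paths$draft)
  fwrite(dr$truth, paths$truth, sep = "\t")
  fwrite(genome$repeats[, .(scaffold = "scaffold_1", start, end,
                            name = paste0("fam", family, ".", copy))],
         paths$repeats, sep = "\t", col.names = FALSE)
  libs <- list()
  for (i in seq_along(cfg$libraries)) {
    lib <- cfg$libraries[[i]]
    reads <- simulate_reads(genome$reference, lib, seed = cfg$seed + 10L + i)
    pre <- file.path(out_dir, lib$library_id)
    fq <- write_fastq_pair(reads$name, reads$seq1, reads$seq2, pre)
    libs[[i]] <- data.table(library_id = lib$library_id, m = lib$m,
                            v = lib$v, l = lib$l, kind = lib$kind,
                            fq1 = fq[1], fq2 = fq[2])
  }
  fwrite(rbindlist(libs), paths$libs, sep = "\t")
  list(cfg = cfg, paths = paths, genome = genome, draft = dr$draft,
       truth = dr$truth, libraries = rbindlist(libs))
}
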