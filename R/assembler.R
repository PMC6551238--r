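# Stage-1 local assembly: a small canonical-k-mer de Bruijn assembler.
# Each gap's recruited reads are k-merized, low-count k-mers are dropped,
# short dead-end paths (tips) are clipped, simple bubbles popped, and
# maximal unbranched paths reported as contigs. Deterministic: the graph is
# traversed in sorted k-mer order and carries no randomness.

#' Default local-assembly configuration
#'
#' @param k_values odd k-mer sizes; each is assembled independently and the
#'   contigs pooled.
#' @param min_kmer_count k-mers seen fewer times are dropped (reduced to 1
#'   automatically for gaps with fewer than 50 reads).
#' @param min_contig_len shortest contig reported.
#' @param tip_len dead-end paths shorter than this (bases) are clipped;
#'   `NULL` means 2k.
#' @param bubble_identity two parallel paths with identity above this are
#'   collapsed to the better-covered one.
#' @return a list of class `assembly_config`.
#' @export
assembly_config <- function(k_values = c(31L, 41L, 51L), min_kmer_count = 2L,
                            min_contig_len = 100L, tip_len = NULL,
                            bubble_identity = 0.9) {
  stopifnot(all(k_values %% 2L == 1L), min_kmer_count >= 1L,
            min_contig_len >= max(k_values))
  structure(list(k_values = as.integer(k_values),
                 min_kmer_count = as.integer(min_kmer_count),
                 min_contig_len = as.integer(min_contig_len),
                 tip_len = tip_len, bubble_identity = bubble_identity),
            class = "assembly_config")
}

#' Count canonical k-mers in a read set
#'
#' Each k-mer is represented by the lexicographically smaller of itself and
#' its reverse complement. k-mers containing non-ACGT characters are
#' dropped, as are counts below `min_count`.
#'
#' @param reads character vector of read sequences.
#' @param k odd k-mer size.
#' @param min_count minimum retained count.
#' @return `data.table` with columns `kmer`, `count`.
#' @export
kmerize <- function(reads, k, min_count = 1L) {
  stopifnot(k %% 2L == 1L)
  had_reads <- length(reads) > 0L
  reads <- toupper(reads[nchar(reads) >= k])
  if (length(reads) == 0L) {
    if (had_reads) warning("no reads of length >= k; empty k-mer set")
    return(data.table(kmer = character(), count = integer()))
  }
  # vectorised extraction, grouped by read length
  kmers <- unlist(lapply(split(reads, nchar(reads)), function(grp) {
    L <- nchar(grp[1]); n_pos <- L - k + 1L
    substring(rep(grp, each = n_pos), rep.int(seq_len(n_pos), length(grp)),
              rep.int(seq_len(n_pos) + k - 1L, length(grp)))
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(data.table(kmer = character(), count = integer()))
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- data.table(kmer = canon)[, .(count = .N), by = kmer]
  tab <- tab[count >= min_count]
  setkey(tab, kmer)
  tab[]
}

# Both-strand unitig construction. Returns data.table(seq, cov,
# start_node, end_node) with one row per unitig orientation; callers
# deduplicate by canonical sequence. Node bookkeeping uses integer ids and
# vectorised successor arrays so the walk is a tight index loop.
build_unitigs <- function(ktab, k) {
  if (nrow(ktab) == 0L)
    return(data.table(seq = character(), cov = numeric(),
                      start_node = character(), end_node = character()))
  fwd <- ktab$kmer
  rev <- revcomp(fwd)
  edges <- data.table(kmer = c(fwd, rev), count = rep(ktab$count, 2L))
  edges <- unique(edges, by = "kmer")     # palindromes appear once
  setorder(edges, kmer)
  from_s <- substr(edges$kmer, 1L, k - 1L)
  to_s <- substr(edges$kmer, 2L, k)
  nodes <- unique(c(from_s, to_s))
  from_id <- match(from_s, nodes); to_id <- match(to_s, nodes)
  n_nodes <- length(nodes); n_edges <- nrow(edges)
  outdeg <- tabulate(from_id, n_nodes); indeg <- tabulate(to_id, n_nodes)
  simple <- outdeg == 1L & indeg == 1L
  # unique outgoing edge per out-degree-1 node
  node2edge <- rep(NA_integer_, n_nodes)
  o1 <- which(outdeg == 1L)
  node2edge[o1] <- match(o1, from_id)
  succ <- ifelse(simple[to_id], node2edge[to_id], NA_integer_)
  last_char <- substr(edges$kmer, k, k)
  used <- rep(FALSE, n_edges)
  res <- list()
  walk <- function(i) {
    path <- integer(0)
    repeat {
      path <- c(path, i)
      used[i] <<- TRUE
      j <- succ[i]
      if (is.na(j) || used[j]) break
      i <- j
    }
    path
  }
  for (i in which(!simple[from_id])) {
    if (!used[i]) res[[length(res) + 1L]] <- walk(i)
  }
  for (i in seq_len(n_edges)) {          # remaining edges: simple cycles
    if (!used[i]) res[[length(res) + 1L]] <- walk(i)
  }
  rbindlist(lapply(res, function(path) {
    data.table(seq = paste0(nodes[from_id[path[1L]]],
                            paste(last_char[path], collapse = "")),
               cov = mean(edges$count[path]),
               start_node = nodes[from_id[path[1L]]],
               end_node = nodes[to_id[path[length(path)]]])
  }))
}

canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Clip short dead-end unitigs and pop simple bubbles, returning a reduced
# canonical k-mer table. One round per call.
simplify_graph <- function(ktab, k, tip_len, bubble_identity) {
  uni <- build_unitigs(ktab, k)
  if (nrow(uni) == 0L) return(ktab)
  uni[, canon := canonical_seq(seq)]
  # recompute degrees over the full both-strand edge set
  fwd <- ktab$kmer; rev <- revcomp(fwd)
  edges <- unique(data.table(kmer = c(fwd, rev)), by = "kmer")
  edges[, `:=`(from = substr(kmer, 1L, k - 1L), to = substr(kmer, 2L, k))]
  outdeg <- edges[, .N, by = from]; setkey(outdeg, from)
  indeg <- edges[, .N, by = to]; setkey(indeg, to)
  deg <- function(tab, key) { v <- tab[J(key), N]; v[is.na(v)] <- 0L; v }
  uni[, `:=`(len = nchar(seq),
             dead_start = deg(indeg, start_node) == 0L,
             dead_end = deg(outdeg, end_node) == 0L)]
  drop_canon <- character(0)
  # tips: short unitig with one free end and one attached end
  tips <- uni[len < tip_len & xor(dead_start, dead_end), canon]
  drop_canon <- c(drop_canon, tips)
  # simple bubbles: two unitigs sharing both endpoints, similar sequence
  bub <- uni[!canon %in% drop_canon & !dead_start & !dead_end]
  if (nrow(bub) > 1L) {
    bub <- bub[, .(n = .N, canons = list(canon), covs = list(cov),
                   seqs = list(seq)), by = .(start_node, end_node)]
    for (j in which(bub$n >= 2L)) {
      seqs <- bub$seqs[[j]]; covs <- bub$covs[[j]]; cns <- bub$canons[[j]]
      keep <- which.max(covs)
      for (q in seq_along(seqs)) {
        if (q == keep) next
        if (abs(nchar(seqs[q]) - nchar(seqs[keep])) > 0.1 * nchar(seqs[keep]))
          next
        pa <- Biostrings::pairwiseAlignment(seqs[q], seqs[keep],
                                            type = "global")
        pid <- Biostrings::pid(pa) / 100
        if (pid >= bubble_identity) drop_canon <- c(drop_canon, cns[q])
      }
    }
  }
  if (length(drop_canon) == 0L) return(ktab)
  bad_kmers <- unlist(lapply(unique(drop_canon), function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }))
  bad_canon <- unique(canonical_seq(bad_kmers))
  ktab[!kmer %in% bad_canon]
}

#' Assemble a gap's recruited reads into contigs
#'
#' Runs the de Bruijn assembler once per k in `cfg$k_values` and pools the
#' resulting contigs (each tagged with the k that produced it).
#'
#' @param reads character vector of recruited read sequences.
#' @param cfg an [assembly_config()].
#' @param gap_id label for contig ids.
#' @return `data.table` with columns `contig_id`, `gap_id`, `seq`, `k_used`,
#'   `cov` (mean k-mer coverage). Empty when nothing assembles.
#' @export
assemble_gap <- function(reads, cfg = assembly_config(), gap_id = "gap") {
  out <- list()
  min_count <- if (length(reads) < 50L) 1L else cfg$min_kmer_count
  for (k in cfg$k_values) {
    if (all(nchar(reads) < k)) next
    ktab <- suppressWarnings(kmerize(reads, k, min_count))
    if (nrow(ktab) == 0L) next
    tip_len <- cfg$tip_len %||% (2L * k)
    for (round in 1:2) {
      n0 <- nrow(ktab)
      ktab <- simplify_graph(ktab, k, tip_len, cfg$bubble_identity)
      if (nrow(ktab) == n0) break
    }
    uni <- build_unitigs(ktab, k)
    if (nrow(uni) == 0L) next
    uni[, canon := canonical_seq(seq)]
    uni <- unique(uni, by = "canon")
    uni <- uni[nchar(seq) >= cfg$min_contig_len]
    if (nrow(uni) == 0L) next
    setorder(uni, -cov, canon)
    out[[length(out) + 1L]] <- data.table(
      contig_id = sprintf("%s.k%d.c%d", gap_id, k, seq_len(nrow(uni))),
      gap_id = gap_id, seq = uni$canon, k_used = k, cov = uni$cov)
  }
  if (length(out) == 0L)
    return(data.table(contig_id = character(), gap_id = character(),
                      seq = character(), k_used = integer(), cov = numeric()))
  rbindlist(out)
}

#' Assign doubly-unmapped pairs to gaps via their stage-1 contigs
#'
#' Aligns the doubly-unmapped read pool to the contigs of gaps that are not
#' yet fully closed. An exact-substring fast path (both strands) is tried
#' first; remaining reads are aligned with BWA-MEM when available. A read
#' aligning to a contig of an open gap with identity at least `min_identity`
#' over at least `min_frac` of its length joins that gap's type-iv set,
#' together with its mate; a read may join several gaps.
#'
#' @param unmapped_pool pool from [collect_unmapped_pool()].
#' @param contigs contig table (from [assemble_gap()], stacked over gaps).
#' @param open_gap_ids gaps still eligible (not FULL after pass 1).
#' @param min_identity,min_frac alignment acceptance thresholds.
#' @param use_bwa align error-carrying reads with bwa mem (default when
#'   available).
#' @return recruitment `data.table` with `type = "iv"` rows.
#' @export
recruit_unmapped <- function(unmapped_pool, contigs, open_gap_ids,
                             min_identity = 0.9, min_frac = 0.8,
                             use_bwa = tool_available("bwa")) {
  contigs <- contigs[gap_id %in% open_gap_ids]
  if (nrow(contigs) == 0L || nrow(unmapped_pool) == 0L)
    return(empty_recruits())
  pool <- copy(unmapped_pool)
  pool[, rid := paste0(name, "/", mate_index)]
  hits <- list()
  # exact-substring fast path, grouped by read length so PDict applies
  csub <- Biostrings::DNAStringSet(contigs$seq)
  matched <- rep(FALSE, nrow(pool))
  for (L in unique(nchar(pool$seq))) {
    idx <- which(nchar(pool$seq) == L & !grepl("[^ACGT]", pool$seq))
    if (!length(idx)) next
    rs <- Biostrings::DNAStringSet(pool$seq[idx])
    for (strand_seq in list(rs, Biostrings::reverseComplement(rs))) {
      pd <- Biostrings::PDict(strand_seq)
      cnt <- Biostrings::vcountPDict(pd, csub)   # reads x contigs
      hit <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(hit)) {
        hits[[length(hits) + 1L]] <- data.table(
          rid = pool$rid[idx[hit[, 1L]]],
          gap_id = contigs$gap_id[hit[, 2L]])
        matched[idx[unique(hit[, 1L])]] <- TRUE
      }
    }
  }
  rest <- pool[!matched]
  if (nrow(rest) > 0L && use_bwa) {
    wd <- tempfile("recruit"); dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE), add = TRUE)
    ctg_fa <- file.path(wd, "contigs.fa")
    write_fasta(setNames(contigs$seq, contigs$contig_id), ctg_fa)
    fq <- file.path(wd, "pool.fastq")
    writeLines(as.vector(rbind(paste0("@", rest$rid), rest$seq, "+",
                               rest$qual)), fq)
    bam <- file.path(wd, "pool.bam")
    bwa_mem(ctg_fa, fq, NULL, bam, sort = "none")
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "cigar"), tag = "NM")
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    if (length(x$qname)) {
      hdt <- data.table(rid = x$qname, flag = x$flag,
                        contig_id = as.character(x$rname),
                        cigar = x$cigar, nm = x$tag$NM)
      hdt <- hdt[bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
                   bitwAnd(flag, 2048L) == 0L]
      if (nrow(hdt)) {
        cl <- parse_cigar_clips(hdt$cigar)
        rlen <- nchar(rest$seq)[match(hdt$rid, rest$rid)]
        span <- rlen - cl$left - cl$right
        ident <- 1 - hdt$nm / pmax(span, 1L)
        keep <- !is.na(span) & !is.na(ident) & span >= min_frac * rlen &
          ident >= min_identity
        if (any(keep)) {
          hdt <- hdt[keep]
          hdt[, gap_id := contigs$gap_id[match(contig_id, contigs$contig_id)]]
          hits[[length(hits) + 1L]] <- hdt[, .(rid, gap_id)]
        }
      }
    }
  }
  if (length(hits) == 0L) return(empty_recruits())
  hits <- unique(rbindlist(hits))
  # a hit recruits the read and its mate
  hit_reads <- merge(hits, pool, by = "rid", allow.cartesian = TRUE)
  mates <- hit_reads[, .(gap_id, name, mate_index = 3L - mate_index)]
  mate_reads <- merge(mates, pool, by = c("name", "mate_index"))
  out <- rbindlist(list(
    hit_reads[, .(gap_id, name, mate_index, seq, qual, library)],
    mate_reads[, .(gap_id, name, mate_index, seq, qual, library)]))
  out <- unique(out, by = c("gap_id", "name", "mate_index"))
  out[, `:=`(type = "iv", hq = FALSE, confident = FALSE)]
  setcolorder(out, c("name", "mate_index", "seq", "qual", "library", "type",
                     "hq", "confident", "gap_id"))
  out[]
}
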