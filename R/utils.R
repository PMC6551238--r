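#' @import data.table
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

# Internal coordinate convention: 0-based half-open everywhere; SAM positions
# are converted from 1-based at I/O boundaries.

#' Reverse complement of character DNA sequences
#'
#' Vectorised IUPAC-aware reverse complement on plain character vectors
#' (uppercase input). Implemented with `chartr` plus `stringi` reversal,
#' which is far faster than round-tripping millions of k-mers through
#' `DNAStringSet`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  stringi::stri_reverse(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count mismatches between two equal-length sequences
#' @noRd
count_mismatches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector (uppercased)
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write paired reads to a pair of FASTQ files
#' @noRd
write_fastq_pair <- function(names, seq1, seq2, prefix, qual_char = "I") {
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  fq <- function(nm, s, path) {
    q <- vapply(nchar(s), function(n) strrep(qual_char, n), character(1))
    writeLines(as.vector(rbind(paste0("@", nm), s, "+", q)), path)
  }
  fq(names, seq1, f1); fq(names, seq2, f2)
  c(f1, f2)
}

# ---- external tool wrappers (bwa / samtools) --------------------------------

tool_available <- function(tool) nzchar(Sys.which(tool))

require_tool <- function(tool) {
  if (!tool_available(tool))
    stop(sprintf("required external tool '%s' not found on PATH", tool),
         call. = FALSE)
}

#' Align paired FASTQ files to a FASTA reference with BWA-MEM
#'
#' Indexes `ref_fasta` if needed and runs single-threaded `bwa mem`, piping
#' through `samtools sort` to a coordinate-sorted BAM. Used for the
#' genome-wide alignment step, for recruiting doubly-unmapped pairs against
#' local contigs, and for read-back validation.
#'
#' @param ref_fasta reference FASTA path.
#' @param fq1,fq2 paired FASTQ paths (`fq2` may be `NULL` for unpaired input).
#' @param out_bam output BAM path.
#' @param sort either "coord" or "none".
#' @return `out_bam`, invisibly.
#' @export
bwa_mem <- function(ref_fasta, fq1, fq2 = NULL, out_bam, sort = "coord") {
  require_tool("bwa"); require_tool("samtools")
  if (!file.exists(paste0(ref_fasta, ".bwt")))
    system2("bwa", c("index", shQuote(ref_fasta)), stdout = FALSE, stderr = FALSE)
  args <- c("mem", "-t", "1", shQuote(ref_fasta), shQuote(fq1))
  if (!is.null(fq2)) args <- c(args, shQuote(fq2))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2("bwa", args, stdout = sam, stderr = FALSE)
  if (status != 0) stop("bwa mem failed", call. = FALSE)
  if (identical(sort, "coord")) {
    system2("samtools", c("sort", "-o", shQuote(out_bam), shQuote(sam)),
            stdout = FALSE, stderr = FALSE)
    system2("samtools", c("index", shQuote(out_bam)), stdout = FALSE, stderr = FALSE)
  } else {
    system2("samtools", c("view", "-b", "-o", shQuote(out_bam), shQuote(sam)),
            stdout = FALSE, stderr = FALSE)
  }
  invisible(out_bam)
}
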