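Package: gapfillr
Title: Sensitive Gap Closing for Draft Genomes with Paired-End and Mate-Pair Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closes N-run gaps in draft genome scaffolds by recruiting four
    classes of gap-associated short reads: anchored unmapped mates,
    repeat-associated discordant and multi-mapped (mapping quality zero)
    reads, reads soft-clipped at gap breakpoints, and doubly-unmapped pairs
    recruited against locally assembled contigs. Recruitment is followed by
    a two-stage local assembly, per-gap de Bruijn contig assembly and greedy
    prefix-suffix contig merging. Merged candidates are anchored with the
    gap flanks to call FULL, EXTENDED or UNFILLED closures, and closures
    can be benchmarked against a reference genome or validated
    reference-free by read-back alignment. Includes a synthetic fixture
    generator (repeat-bearing genomes, gapped drafts, paired reads with
    configurable insert-size distributions) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    data.table,
    methods,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
SystemRequirements: bwa, samtools
RoxygenNote: 7.3.3
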