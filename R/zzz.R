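utils::globalVariables(c(
  ".", ".I", ".N", "b1", "b2", "gap_id", "scaffold", "d", "row_",
  "left_flank", "right_flank", "no_flank", "name", "mate_index", "mapped",
  "pos", "end", "mapq", "reverse", "cigar", "clip_left", "clip_right",
  "seq", "qual", "library", "m_mapped", "m_scaffold", "m_pos", "m_mapq",
  "anchor_mapq", "type", "hq", "confident", "kmer", "count", "from", "to",
  "N", "canon", "cov", "len", "dead_start", "dead_end", "start_node",
  "end_node", "contig_id", "rid", "flag", "nm", "k_used", "merged_id",
  "constituents", "offset", "orientation", "score", "status", "gap_sequence",
  "left_seq", "right_seq", "left_extension", "right_extension",
  "chosen_contig", "idx", "ori", "ext", "ext_l", "ext_r", "cover",
  "usable", "true_seq", "in_repeat", "family", "copy", "construct_len",
  "joint_left", "joint_right", "validated", "joint_left_reads",
  "joint_right_reads", "frac_ge_cov", "J", "width", "seq_l", "seq_r"))
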