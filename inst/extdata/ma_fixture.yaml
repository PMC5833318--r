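# Marginal totals of the published MA experiment (47 lines, ~3,025
# generations, 5.19-Mb circular genome). Splits not fixed here are filled
# deterministically by build_paper_fixture()'s documented rules.
n_lines: 47
generations_per_line: 3025
genome_size: 5190000
terminus_position: 2500000
bps:
  total: 779
  transitions: 558
  at_ward: 533
indels:
  total: 106
  deletions: 73
  insertions: 33
  short_deletions: 47
  short_insertions: 25
  deletion_nt_total: 14061
  insertion_nt_total: 80
  large_deletion:
    size: 12581
    line: 47
clusters:
  window: 50
  clustered_bps: 21
  clustered_indels: 16
  triple_line: 29
  lines_with_clusters: 16
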