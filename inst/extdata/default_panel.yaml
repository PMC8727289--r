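# Default four-region AML BA-seq panel.
# CpG counts, anchor cg-identifiers, aberration directions and SNP positions
# define the panel; the CpG coordinates themselves are SYNTHETIC placeholders
# spaced around each anchor (replace with primer-table coordinates for use on
# real alignments). Positions are 1-based, (+) strand, C of each CpG.
regions:
- region_id: cg15289427
  anchor_cpg: cg15289427
  chrom: chr6
  cpg_positions: [24891502, 24891515, 24891523, 24891536, 24891548, 24891561,
                  24891570, 24891584, 24891597, 24891608, 24891621, 24891633,
                  24891646, 24891659]
  target_index: 8
  direction: hyper_in_aml
- region_id: cg22797031
  anchor_cpg: cg22797031
  chrom: chr12
  cpg_positions: [104356010, 104356022, 104356035, 104356047, 104356058,
                  104356071, 104356083, 104356096, 104356104, 104356117]
  target_index: 6
  direction: hyper_in_aml
- region_id: cg27630153
  anchor_cpg: cg27630153
  chrom: chr16
  cpg_positions: [88844920, 88844933, 88844941, 88844956, 88844962, 88844975,
                  88844983, 88845004, 88845011, 88845027, 88845040, 88845052,
                  88845069, 88845081, 88845095]
  target_index: 8
  direction: hypo_in_aml
  snp_positions: [88844998]
- region_id: cg19586199
  anchor_cpg: cg19586199
  chrom: chr19
  cpg_positions: [14225120, 14225131, 14225144, 14225156, 14225165, 14225180,
                  14225192, 14225203, 14225215]
  target_index: 5
  direction: hypo_in_aml
  snp_positions: [14225172]
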