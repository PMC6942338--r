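.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "..density..", "probeset_id", "snp_id", "direction", "repetitive",
  "pconvert", "recommendation", "genome_match", "n_scaffold_hits_v05",
  "n_perfect_alleles", "flanking_rank", "transcript_id",
  "transcript_confidence", "allele_a", "allele_b", "flanking_variants",
  "infinium_success", "target_snp_prob", "n_detect_programs", "level", "id",
  "hit_category", "mean_hits", "confidence_score", "n_snps", "combined_rank",
  "within_rank", "final_rank", "plate_id", "dqc", "sample_cr", "pass_sample",
  "pass_fraction", "plate_cr", "pass_plate", "pass", "category", "call_rate",
  "nAA", "nAB", "nBB", "nNC", "successful", "population", "population_id",
  "maf", "hwe_p", "cr", "het_obs", "het_exp", "pic", "n_called", "qseqid",
  "pident", "snp", "allele", "n_hits", "pid_best", "pid_second", "n_gt90",
  "pid_pair_category", "hit_bin", "sample_id", "tree_id", "N", "true_logit",
  "success", "call", "confidence"))
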