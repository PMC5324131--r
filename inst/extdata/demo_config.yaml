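seed: 42
n_chromosomes: 2
chromosome_length: 400000.0
n_coding_genes: 16
n_lncrnas: 80
class_proportions:
  intergenic: 0.516
  intragenic: 0.415
  antisense: 0.069
n_replicates_per_genotype: 3
de_fraction: 0.1
planted_log2fc: 2.0
nb_dispersion: 0.1
mean_expression_fpkm: 20.0
library_size: 9.0e+07
n_mirnas: 5
n_planted_target_sites: 6
n_planted_etm_sites: 3
single_genotype_fraction: 0.05
n_housekeeping_decoys: 2
n_precursor_decoys: 2
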