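# lncorange

Discovery and characterization of flowering-related long non-coding RNAs
(lncRNAs) in trifoliate orange (*Poncirus trifoliata*), as a tested,
reusable R pipeline.

Precocious trifoliate orange (MT) is an early-flowering mutant whose
juvenile phase is 1–2 years instead of the wild type's (WT) 6–8.
Comparing the two genotypes' transcriptomes at the phase-transition stage
is a route to lncRNAs involved in the flowering switch. `lncorange`
implements the downstream analysis of such a study, starting from
assembled transcripts:

* **Identification cascade** — sequential filters turn assembled
  transcripts into lncRNA candidates: a similarity screen against known
  coding transcripts (local alignment, identity > 90% and coverage
  > 80%), spliced length > 200 nt, longest six-frame ORF < 100 aa,
  a known-protein screen, a coding-potential filter (injected external
  scores, or a built-in surrogate `w1·(ORF_aa/100 − 1) + w2·hexamer
  log-odds`, discard when > 0), presence in both genotypes (FPKM ≥ 1 in
  ≥ 1 replicate of each), and housekeeping-ncRNA / miRNA-precursor
  screens.
* **Positional classification** — antisense (exon–exon overlap, opposite
  strand) > intragenic (wholly inside a coding locus) > intergenic (no
  overlap), plus 10-Mb density profiles and length/exon histograms.
* **Differential expression** — FPKM = count·10⁹/(library·length);
  FC = FPKM(WT)/FPKM(MT) with pseudocount 0.1; two-sample t-test on
  log2(FPKM + 0.1); lncRNAs significant at |log2FC| ≥ 1 & p < 0.05,
  coding genes at |log2FC| ≥ 4 & BH q ≤ 0.05. `log2FC ≤ −1` means
  up-regulated in the mutant.
* **miRNA interactions** — penalty-scored cleavage-target sites on both
  strands (mismatch 1, G:U 0.5, indel 2, positions 2–13 doubled, cutoff
  4), and endogenous target mimics (eTMs) detected by four explicit
  rules: a single 3-nt bulge opposite miRNA positions 9–12, perfect
  seed pairing at positions 2–8, and at most three mismatch/G:U edits
  elsewhere. An RA-PCR helper computes the 3′/5′ cleavage-consistency
  ratio.
* **Synthetic data with planted truth** — a miniature genome, coding
  genes with genuine ≥ 100-codon ORFs, lncRNAs planted at the
  51.6/41.5/6.9% intergenic/intragenic/antisense split, 3-replicate
  negative-binomial counts (dispersion 0.1, ~9×10⁷ fragments/library)
  with planted |log2FC| = 2 effects, and planted miRNA target/eTM
  sites — so the whole pipeline is exercised end to end against known
  ground truth.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods, `autoplot()` and `plot_*()` figures.

## A worked example

```r
library(lncorange)

cfg <- sim_config(seed = 1, n_chromosomes = 2, chromosome_length = 4e5,
                  n_coding_genes = 16, n_lncrnas = 80, n_mirnas = 5,
                  n_planted_target_sites = 6, n_planted_etm_sites = 3)
run <- run_lncrna_study(cfg)
run$cascade
```

```
             stage n_in n_out
 coding_similarity  104    88
            length   88    88
               orf   88    88
     known_protein   88    88
  coding_potential   88    88
    both_genotypes   88    83
      housekeeping   83    81
   mirna_precursor   81    79
```

104 assembled transcripts (16 coding + 80 lncRNAs + 8 decoys) enter the
funnel; the 16 coding transcripts fall at the similarity screen, the
single-genotype decoys at `both_genotypes`, and the housekeeping/
precursor decoys at their screens, leaving 79 candidates.

```r
glance(run)
#>  n_lncrnas n_intergenic n_intragenic n_antisense n_de n_up_in_mt n_down_in_mt ...
#>         79           41           32           6    9          6            3

validate_against_truth(run)
#>                metric numerator denominator value   ci_lo ci_hi
#>    lncrna_sensitivity        79          80 0.988 0.93231 1.000
#>    lncrna_specificity        24          24 1.000 0.85753 1.000
#>        class_recovery        79          79 1.000 0.95438 1.000
#>        de_sensitivity         8           8 1.000 0.63058 1.000
#>                de_fdr         1           9 0.111 0.00281 0.482
#>  target_site_recovery         6           6 1.000 0.54074 1.000
#>     etm_site_recovery         3           3 1.000 0.29240 1.000
```

Reading this: 79 of 80 planted lncRNAs survive the cascade (one fell to
the both-genotype filter by expression chance), every planted positional
class and miRNA site is recovered exactly, 8 of the 8 planted expression
effects that survived filtering are called with one false positive among
nine calls. `autoplot(run$cascade)` draws the funnel,
`autoplot(run$de_lncrna)` the volcano, and
`run_lncrna_study(cfg, outdir = "demo")` writes every artifact (FASTA,
GTF, TSV tables, JSON summary) plus an md5 manifest; reruns are
byte-identical.

The methods vignette (`vignettes/lncorange-methods.Rmd`) documents the
model choices, boundary semantics, and what passing on synthetic data
does and does not demonstrate.

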