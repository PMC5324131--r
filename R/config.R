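#' Simulation configuration
#'
#' Builds the configuration object that drives the synthetic-data generator.
#' Defaults encode the study design the pipeline assumes: two genotypes (an
#' early-flowering mutant, MT, and its wild type, WT) with three biological
#' replicates each, a class split of 51.6% intergenic / 41.5% intragenic /
#' 6.9% antisense lncRNAs, lncRNA lengths concentrated in 200-1,000 nt with
#' 1-2 exons, and negative-binomial fragment counts.
#'
#' @param seed Integer seed governing every random stage (sub-seeds are
#'   derived deterministically per stage).
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in nt.
#' @param n_coding_genes Number of protein-coding genes to plant.
#' @param n_lncrnas Number of true lncRNAs to plant.
#' @param class_proportions Named or unnamed numeric triple (intergenic,
#'   intragenic, antisense); must sum to 1.
#' @param n_replicates_per_genotype Biological replicates per genotype.
#' @param de_fraction Fraction of lncRNAs carrying a planted expression
#'   effect between MT and WT.
#' @param planted_log2fc Magnitude of the planted effect, on the
#'   log2(FPKM WT / FPKM MT) scale; signs are assigned at random.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2). Must be > 0.
#' @param mean_expression_fpkm Median of the log-normal baseline FPKM
#'   distribution across transcripts.
#' @param library_size Mean sequencing depth (mapped fragments) per
#'   library; the study design this emulates sequenced ~90 million reads
#'   per library. Per-sample sizes vary +/-5% around this mean.
#' @param n_mirnas Number of mature miRNAs (19-24 nt) to generate.
#' @param n_planted_target_sites Number of perfect cleavage-target sites to
#'   plant across lncRNAs.
#' @param n_planted_etm_sites Number of rule-compliant endogenous
#'   target-mimic (eTM) sites to plant.
#' @param single_genotype_fraction Fraction (relative to `n_lncrnas`) of
#'   decoy transcripts expressed in only one genotype, planted to exercise
#'   the both-genotype filter.
#' @param n_housekeeping_decoys,n_precursor_decoys Decoy transcripts copied
#'   (with light mutation) from the housekeeping-ncRNA / miRNA-precursor
#'   exclusion sets, planted to exercise those screens.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 1, n_coding_genes = 5, n_lncrnas = 20)
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 5e5,
                       n_coding_genes = 40L,
                       n_lncrnas = 200L,
                       class_proportions = c(intergenic = 0.516,
                                             intragenic = 0.415,
                                             antisense = 0.069),
                       n_replicates_per_genotype = 3L,
                       de_fraction = 0.1,
                       planted_log2fc = 2,
                       nb_dispersion = 0.1,
                       mean_expression_fpkm = 20,
                       library_size = 9e7,
                       n_mirnas = 10L,
                       n_planted_target_sites = 10L,
                       n_planted_etm_sites = 5L,
                       single_genotype_fraction = 0.05,
                       n_housekeeping_decoys = 2L,
                       n_precursor_decoys = 2L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_lncrnas = as.integer(n_lncrnas),
    class_proportions = class_proportions,
    n_replicates_per_genotype = as.integer(n_replicates_per_genotype),
    de_fraction = de_fraction,
    planted_log2fc = planted_log2fc,
    nb_dispersion = nb_dispersion,
    mean_expression_fpkm = mean_expression_fpkm,
    library_size = library_size,
    n_mirnas = as.integer(n_mirnas),
    n_planted_target_sites = as.integer(n_planted_target_sites),
    n_planted_etm_sites = as.integer(n_planted_etm_sites),
    single_genotype_fraction = single_genotype_fraction,
    n_housekeeping_decoys = as.integer(n_housekeeping_decoys),
    n_precursor_decoys = as.integer(n_precursor_decoys)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (length(p) != 3 || any(p < 0)) {
    abort("`class_proportions` must be three non-negative fractions.")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1 (tolerance 1e-9).")
  }
  if (is.null(names(p))) {
    names(cfg$class_proportions) <- c("intergenic", "intragenic", "antisense")
  }
  counts <- c(cfg$n_chromosomes, cfg$n_coding_genes, cfg$n_lncrnas,
              cfg$n_mirnas, cfg$n_planted_target_sites,
              cfg$n_planted_etm_sites, cfg$n_housekeeping_decoys,
              cfg$n_precursor_decoys)
  if (any(counts < 0)) abort("all counts must be >= 0.")
  if (cfg$n_chromosomes < 1) abort("need at least one chromosome.")
  if (cfg$n_replicates_per_genotype < 2) {
    abort("`n_replicates_per_genotype` must be >= 2.")
  }
  check_scalar_number(cfg$chromosome_length, "chromosome_length",
                      positive = TRUE)
  check_scalar_number(cfg$nb_dispersion, "nb_dispersion", positive = TRUE)
  check_scalar_number(cfg$mean_expression_fpkm, "mean_expression_fpkm",
                      positive = TRUE)
  check_scalar_number(cfg$library_size, "library_size", positive = TRUE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    abort("`de_fraction` must lie in [0, 1].")
  }
  if (cfg$single_genotype_fraction < 0 || cfg$single_genotype_fraction > 1) {
    abort("`single_genotype_fraction` must lie in [0, 1].")
  }
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' @param path Path to a YAML file whose keys are `sim_config()` arguments.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$class_proportions)) {
    vals$class_proportions <- unlist(vals$class_proportions)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals$class_proportions <- as.list(vals$class_proportions)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d chromosome(s) x %s nt\n", x$seed,
              x$n_chromosomes, format(x$chromosome_length, big.mark = ",")))
  cat(sprintf("  %d coding genes, %d lncRNAs (%.1f/%.1f/%.1f%% ig/in/as)\n",
              x$n_coding_genes, x$n_lncrnas,
              100 * x$class_proportions[[1]], 100 * x$class_proportions[[2]],
              100 * x$class_proportions[[3]]))
  cat(sprintf("  %d reps/genotype, DE fraction %.2f at |log2FC| = %g, NB dispersion %g\n",
              x$n_replicates_per_genotype, x$de_fraction,
              x$planted_log2fc, x$nb_dispersion))
  cat(sprintf("  %d miRNAs, %d target + %d eTM planted sites\n",
              x$n_mirnas, x$n_planted_target_sites, x$n_planted_etm_sites))
  invisible(x)
}
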