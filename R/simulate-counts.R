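#' Simulate negative-binomial fragment counts for MT and WT replicates
#'
#' Each transcript gets a baseline WT expression level drawn from a
#' log-normal distribution (median `mean_expression_fpkm`, sdlog 1); the MT
#' level is `FPKM_WT * 2^(-true_log2fc)` so that positive `true_log2fc`
#' (defined as log2(WT/MT)) means lower expression in the mutant. Counts
#' are drawn per replicate as NB(mu, size = 1/dispersion) with
#' `mu = FPKM * length * library_size / 1e9`, i.e. mean proportional to
#' transcript length and library depth. Transcripts flagged as
#' single-genotype decoys get zero expression in the other genotype.
#'
#' @param transcripts Tibble with `transcript_id` and `sequence` (or a
#'   `length` column).
#' @param truth Tibble with `transcript_id`, `true_log2fc` (0 for non-DE;
#'   NA allowed only with `present_genotype` set) and optionally
#'   `present_genotype` (`"MT"`/`"WT"`/NA).
#' @param config A [sim_config()]; `nb_dispersion` must be > 0.
#' @return A `lnc_counts` list: `counts` (long tibble: `transcript_id`,
#'   `sample`, `genotype`, `replicate`, `fragment_count`), `samples`
#'   (`sample`, `genotype`, `replicate`, `library_size`), `lengths`
#'   (`transcript_id`, `length`) and `truth_expr` (per-transcript means).
#' @export
simulate_counts <- function(transcripts, truth, config) {
  config <- validate_sim_config(config)
  if (config$nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  set.seed(stage_seed(config$seed, "counts"))
  n <- nrow(transcripts)
  lengths <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    length = if ("length" %in% names(transcripts)) transcripts$length
             else nchar(transcripts$sequence)
  )
  truth <- truth[match(transcripts$transcript_id, truth$transcript_id), ]
  tau <- truth$true_log2fc
  present <- truth$present_genotype %||% rep(NA_character_, n)
  tau[is.na(tau)] <- 0

  base_wt <- rlnorm(n, meanlog = log(config$mean_expression_fpkm), sdlog = 1)
  fpkm_wt <- base_wt
  fpkm_mt <- base_wt * 2^(-tau)
  fpkm_wt[!is.na(present) & present == "MT"] <- 0
  fpkm_mt[!is.na(present) & present == "WT"] <- 0

  reps <- config$n_replicates_per_genotype
  samples <- tibble::tibble(
    sample = c(sprintf("MT_%d", seq_len(reps)), sprintf("WT_%d", seq_len(reps))),
    genotype = rep(c("MT", "WT"), each = reps),
    replicate = rep(seq_len(reps), 2),
    library_size = round(config$library_size * runif(2 * reps, 0.95, 1.05))
  )
  size <- 1 / config$nb_dispersion
  counts <- purrr::pmap(samples, function(sample, genotype, replicate,
                                          library_size) {
    fpkm <- if (genotype == "MT") fpkm_mt else fpkm_wt
    mu <- fpkm * lengths$length * library_size / 1e9
    tibble::tibble(
      transcript_id = lengths$transcript_id,
      sample = sample, genotype = genotype, replicate = replicate,
      fragment_count = rnbinom(n, mu = mu, size = size)
    )
  }) |> purrr::list_rbind()

  structure(
    list(
      counts = counts, samples = samples, lengths = lengths,
      truth_expr = tibble::tibble(
        transcript_id = lengths$transcript_id,
        baseline_fpkm_wt = fpkm_wt, baseline_fpkm_mt = fpkm_mt,
        true_log2fc = truth$true_log2fc
      )
    ),
    class = "lnc_counts"
  )
}

#' @export
print.lnc_counts <- function(x, ...) {
  cat(sprintf("<lnc_counts> %d transcripts x %d samples\n",
              nrow(x$lengths), nrow(x$samples)))
  invisible(x)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_genome()], [plant_lncrnas()],
#' [plant_mirna_sites()] and [simulate_counts()] under the single seed in
#' `config`. The result carries complete ground truth: coding status and
#' positional class per transcript, planted expression effects, and planted
#' miRNA site coordinates.
#'
#' @param config A [sim_config()].
#' @return A `lnc_sim` with `counts` attached.
#' @examples
#' sim <- simulate_lncrna_study(sim_config(seed = 1, n_coding_genes = 5,
#'                                         n_lncrnas = 20, n_mirnas = 3,
#'                                         n_planted_target_sites = 2,
#'                                         n_planted_etm_sites = 1))
#' @export
simulate_lncrna_study <- function(config = sim_config()) {
  genome <- generate_genome(config)
  sim <- plant_lncrnas(genome, config)
  sim <- plant_mirna_sites(sim, config)
  sim$counts <- simulate_counts(sim$transcripts, sim$truth, config)
  sim
}
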