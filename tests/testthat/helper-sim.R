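# Shared miniature study configurations. The demo run uses the bundled
# demo config and is computed once per test session, then reused.

demo_config <- function() {
  read_sim_config(system.file("extdata", "demo_config.yaml",
                              package = "lncorange"))
}

.demo_cache <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.demo_cache$run)) {
    .demo_cache$run <- run_lncrna_study(demo_config())
  }
  .demo_cache$run
}

demo_sim <- function() demo_run()$sim

# Flat transcript/truth tables for expression-only experiments.
flat_expression_sim <- function(n, seed, de_fraction = 0,
                                planted_log2fc = 2) {
  set.seed(seed)
  tx <- tibble::tibble(
    transcript_id = sprintf("T%05d", seq_len(n)),
    length = sample(201:2000, n, replace = TRUE)
  )
  tau <- rep(0, n)
  if (de_fraction > 0) {
    idx <- sample(n, round(de_fraction * n))
    tau[idx] <- sample(c(-1, 1), length(idx), TRUE) * planted_log2fc
  }
  truth <- tibble::tibble(transcript_id = tx$transcript_id,
                          true_log2fc = tau,
                          present_genotype = NA_character_)
  list(transcripts = tx, truth = truth)
}
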