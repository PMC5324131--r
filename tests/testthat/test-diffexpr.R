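test_that("FPKM follows the count * 1e9 / (library * length) formula", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  # doubling count and library size together leaves FPKM unchanged
  expect_equal(compute_fpkm(100, 1000, 1e6), compute_fpkm(200, 1000, 2e6))
  expect_error(compute_fpkm(1, 0, 1e6), "length")
  expect_error(compute_fpkm(1, 100, 0), "library")
})

test_that("the expression prefilter applies FPKM and coverage bounds strictly", {
  fpkm <- tibble::tibble(
    transcript_id = rep(c("a", "b", "c"), each = 2),
    sample = rep(c("MT_1", "WT_1"), 3),
    genotype = rep(c("MT", "WT"), 3),
    fpkm = c(0.9, 0.7, 5, 5, 1.0, 0.2)
  )
  cov <- tibble::tibble(transcript_id = c("a", "b", "c"),
                        coverage_fraction = c(1, 0.49, 0.5))
  out <- expression_prefilter(fpkm, cov)
  expect_false(out$keep[out$transcript_id == "a"])  # max FPKM 0.9 < 1
  expect_false(out$keep[out$transcript_id == "b"])  # coverage 0.49 < 0.5
  expect_true(out$keep[out$transcript_id == "c"])   # both at boundary
})

test_that("the two-sample test behaves at its boundaries and matches closed forms", {
  # identical replicate vectors -> guarded p = 1
  expect_equal(de_test(c(3, 3, 3), c(3, 3, 3)), 1)
  # clear separation -> small p
  expect_lt(de_test(c(100, 110, 90), c(1, 1.2, 0.9)), 0.01)
  # Welch variant equals the closed-form Welch computation
  set.seed(81)
  for (i in 1:20) {
    wt <- rlnorm(3, 3, 0.4); mt <- rlnorm(3, 2, 0.6)
    expect_equal(de_test(wt, mt, var_equal = FALSE),
                 oracle_welch_p(log2(wt + 0.1), log2(mt + 0.1)))
  }
  expect_error(de_test(1, c(1, 2)), "replicates")
})

test_that("BH step-up matches p.adjust on random vectors and the worked example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(82)
  for (i in 1:300) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls follow the WT/MT fold-change convention", {
  res <- tibble::tibble(
    transcript_id = c("up", "weak", "down", "coding_na"),
    log2fc = c(-2, -0.8, 1.5, -5),
    p_value = c(0.01, 0.001, 0.02, 0.2)
  )
  out <- call_de(res, mode = "lncrna")
  # FPKM_WT = 2 vs FPKM_MT = 8 gives log2fc ~ -2: up-regulated in MT
  expect_equal(as.character(out$call[1]), "up_in_MT")
  # |log2fc| = 0.8 below threshold despite tiny p
  expect_equal(as.character(out$call[2]), "not_significant")
  expect_equal(as.character(out$call[3]), "down_in_MT")
  # coding mode needs q-values
  expect_error(call_de(res, mode = "coding"), "q_value")
  res$q_value <- c(0.01, 0.001, 0.02, 0.04)
  outc <- call_de(res, mode = "coding")
  # coding threshold is |log2fc| >= 4
  expect_equal(as.character(outc$call), c("not_significant",
                                          "not_significant",
                                          "not_significant", "up_in_MT"))
})

test_that("calls are monotone in p at fixed fold change", {
  base <- tibble::tibble(transcript_id = "t", log2fc = -1.5, p_value = 0.04)
  stopifnot(call_de(base, "lncrna")$call == "up_in_MT")
  for (p in c(0.03, 0.01, 1e-5)) {
    expect_equal(as.character(call_de(dplyr::mutate(base, p_value = p),
                                      "lncrna")$call), "up_in_MT")
  }
})

test_that("the 0.1 pseudocount gives FC = 1 for 0 vs 0", {
  samples <- tibble::tibble(sample = c("MT_1", "MT_2", "WT_1", "WT_2"),
                            genotype = c("MT", "MT", "WT", "WT"),
                            replicate = c(1, 2, 1, 2),
                            library_size = rep(1e6, 4))
  cnt <- structure(list(
    counts = tibble::tibble(transcript_id = "z", sample = samples$sample,
                            genotype = samples$genotype,
                            replicate = samples$replicate,
                            fragment_count = 0L),
    samples = samples,
    lengths = tibble::tibble(transcript_id = "z", length = 1000L)
  ), class = "lnc_counts")
  de <- diff_expr(cnt, mode = "lncrna")
  expect_equal(de$fc, 1)
  expect_equal(de$log2fc, 0)
  expect_equal(as.character(de$call), "filtered")
})

test_that("diff_expr recovers planted effects with controlled error", {
  sim <- flat_expression_sim(1500, seed = 83, de_fraction = 0.1)
  cnt <- simulate_counts(sim$transcripts, sim$truth, sim_config(seed = 84))
  de <- diff_expr(cnt, mode = "lncrna")
  j <- dplyr::left_join(tidy(de), sim$truth, by = "transcript_id")
  called <- j$call %in% c("up_in_MT", "down_in_MT")
  truly <- j$true_log2fc != 0
  expect_gte(mean(called[truly]), 0.8)
  expect_lte(sum(called & !truly) / max(1, sum(called)), 0.1)
  # directions match the planted sign (log2fc is WT/MT)
  dir_ok <- j$call[truly & called] ==
    ifelse(j$true_log2fc[truly & called] < 0, "up_in_MT", "down_in_MT")
  expect_true(all(dir_ok))
})
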