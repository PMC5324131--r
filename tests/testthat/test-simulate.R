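test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 1.5e5,
                    n_coding_genes = 6, n_lncrnas = 15, n_mirnas = 3,
                    n_planted_target_sites = 2, n_planted_etm_sites = 1)
  s1 <- simulate_lncrna_study(cfg)
  s2 <- simulate_lncrna_study(cfg)
  expect_identical(s1$genome$chromosomes, s2$genome$chromosomes)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts$counts, s2$counts$counts)

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_fasta(s1$genome$chromosomes, file.path(tempdir(), "g1.fa"))
  write_fasta(s2$genome$chromosomes, file.path(tempdir(), "g2.fa"))
  expect_identical(unname(tools::md5sum(file.path(tempdir(), "g1.fa"))),
                   unname(tools::md5sum(file.path(tempdir(), "g2.fa"))))
})

test_that("coding genes carry genuine long ORFs and lncRNAs never do", {
  sim <- demo_sim()
  genes <- sim$genes
  expect_true(all(vapply(genes$sequence,
                         function(s) scan_orfs(s)$longest_orf_aa >= 100,
                         logical(1))))
  lnc <- sim$transcripts$sequence[
    sim$truth$category[match(sim$transcripts$transcript_id,
                             sim$truth$transcript_id)] == "lncrna"]
  expect_true(all(vapply(lnc,
                         function(s) scan_orfs(s)$longest_orf_aa < 100,
                         logical(1))))
})

test_that("transcript sequences equal their spliced genomic sequence", {
  sim <- demo_sim()
  ok <- vapply(seq_len(nrow(sim$transcripts)), function(i) {
    tx <- sim$transcripts[i, ]
    spliced <- lncorange:::spliced_sequence(
      sim$genome$chromosomes[[tx$chrom]], tx$exons[[1]], tx$strand
    )
    identical(spliced, tx$sequence)
  }, logical(1))
  expect_true(all(ok))
})

test_that("planted class counts follow the requested proportions", {
  sim <- demo_sim()
  lnc <- sim$truth[sim$truth$category == "lncrna", ]
  frac <- table(lnc$positional_class) / nrow(lnc)
  props <- demo_config()$class_proportions
  expect_lt(abs(frac[["intergenic"]] - props[["intergenic"]]), 0.03)
  expect_lt(abs(frac[["intragenic"]] - props[["intragenic"]]), 0.03)
  expect_lt(abs(frac[["antisense"]] - props[["antisense"]]), 0.03)
})

test_that("lncRNA structure matches the emulated study: short, few exons", {
  sim <- demo_sim()
  idx <- match(sim$truth$transcript_id[sim$truth$category == "lncrna"],
               sim$transcripts$transcript_id)
  lens <- nchar(sim$transcripts$sequence[idx])
  nex <- vapply(sim$transcripts$exons[idx], nrow, integer(1))
  expect_true(all(lens > 200))
  expect_gte(mean(lens <= 1000), 0.90)
  expect_gte(mean(nex <= 2), 0.95)
})

test_that("negative-binomial counts have the right moments and null ratio", {
  n <- 600
  set.seed(61)
  tx <- tibble::tibble(transcript_id = sprintf("T%04d", 1:n),
                       length = rep(1000L, n))
  truth <- tibble::tibble(transcript_id = tx$transcript_id,
                          true_log2fc = 0, present_genotype = NA_character_)
  cfg <- sim_config(seed = 9, nb_dispersion = 0.1,
                    n_replicates_per_genotype = 3)
  cnt <- simulate_counts(tx, truth, cfg)
  wide <- tidyr::pivot_wider(cnt$counts, id_cols = "transcript_id",
                             names_from = "sample",
                             values_from = "fragment_count")
  mat <- as.matrix(wide[, -1])
  # variance ~ mean + dispersion * mean^2 across transcripts: regress the
  # excess variance on mean^2; the slope should recover the dispersion
  mu <- rowMeans(mat)
  v <- apply(mat, 1, var)
  disp_hat <- mean((v - mu) / mu^2)
  expect_lt(abs(disp_hat - 0.1), 0.03)
  # null construction: mean MT/WT count ratio ~ 1
  fpkm <- fpkm_table(cnt)
  ratio <- fpkm |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(r = mean(fpkm[genotype == "MT"]) /
                       mean(fpkm[genotype == "WT"]))
  expect_lt(abs(mean(log2(ratio$r))), 0.05)
})

test_that("a planted log2 fold change is recovered on the FPKM scale", {
  n <- 400
  tx <- tibble::tibble(transcript_id = sprintf("T%04d", 1:n),
                       length = rep(800L, n))
  # planted_log2fc = -2 by the WT/MT convention: higher in MT
  truth <- tibble::tibble(transcript_id = tx$transcript_id,
                          true_log2fc = -2, present_genotype = NA_character_)
  cnt <- simulate_counts(tx, truth, sim_config(seed = 10))
  fpkm <- fpkm_table(cnt)
  lfc <- fpkm |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(lfc = log2(mean(fpkm[genotype == "WT"]) /
                                  mean(fpkm[genotype == "MT"])))
  expect_lt(abs(mean(lfc$lfc) - (-2)), 0.05)
})

test_that("the dispersion -> 0 limit approaches Poisson", {
  n <- 400
  tx <- tibble::tibble(transcript_id = sprintf("T%04d", 1:n),
                       length = rep(1000L, n))
  truth <- tibble::tibble(transcript_id = tx$transcript_id,
                          true_log2fc = 0, present_genotype = NA_character_)
  cnt <- simulate_counts(tx, truth, sim_config(seed = 12,
                                               nb_dispersion = 1e-8))
  # normalize out per-sample depth so only the count noise remains
  depth <- cnt$samples$library_size / mean(cnt$samples$library_size)
  wide <- tidyr::pivot_wider(cnt$counts, id_cols = "transcript_id",
                             names_from = "sample",
                             values_from = "fragment_count")
  mat <- sweep(as.matrix(wide[, -1]), 2,
               depth[match(colnames(wide)[-1], cnt$samples$sample)], "/")
  vmr <- apply(mat, 1, var) / rowMeans(mat)
  expect_lt(abs(mean(vmr) - 1), 0.15)
})

test_that("degenerate configurations behave as specified", {
  # zero genes: genome still emitted, empty annotation
  g0 <- generate_genome(sim_config(seed = 2, n_coding_genes = 0,
                                   n_chromosomes = 1,
                                   chromosome_length = 5e4))
  expect_equal(nrow(g0$genes), 0)
  expect_equal(nchar(g0$chromosomes[[1]]), 5e4)

  # zero lncRNAs: valid truth object, no planted transcripts
  cfg0 <- sim_config(seed = 2, n_coding_genes = 3, n_lncrnas = 0,
                     n_chromosomes = 1, chromosome_length = 1e5,
                     n_mirnas = 0, n_planted_target_sites = 0,
                     n_planted_etm_sites = 0,
                     single_genotype_fraction = 0,
                     n_housekeeping_decoys = 0, n_precursor_decoys = 0)
  s0 <- plant_lncrnas(generate_genome(cfg0), cfg0)
  expect_equal(sum(s0$truth$category == "lncrna"), 0)
  expect_true(all(s0$truth$category == "coding"))

  # infeasible packing raises the dedicated error
  expect_error(
    generate_genome(sim_config(seed = 3, n_chromosomes = 1,
                               chromosome_length = 2e4,
                               n_coding_genes = 10)),
    class = "lncorange_packing_error"
  )

  # invalid proportions / dispersion are rejected
  expect_error(sim_config(class_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("single-genotype decoys are expressed in exactly one genotype", {
  sim <- demo_sim()
  dec <- sim$truth[sim$truth$category == "decoy_single_genotype", ]
  expect_gt(nrow(dec), 0)
  fpkm <- fpkm_table(sim$counts)
  for (i in seq_len(nrow(dec))) {
    f <- fpkm[fpkm$transcript_id == dec$transcript_id[i], ]
    on <- dec$present_genotype[i]
    off <- setdiff(c("MT", "WT"), on)
    expect_true(all(f$fpkm[f$genotype == off] == 0))
    expect_true(any(f$fpkm[f$genotype == on] > 0))
  }
})
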