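simple_gene <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
    chrom = chrom, strand = strand,
    start = min(exon_starts), end = max(exon_ends),
    exons = list(lncorange:::exon_tbl(exon_starts, exon_ends))
  )
}

simple_lnc <- function(id, chrom, strand, start, end) {
  tibble::tibble(
    transcript_id = id, chrom = chrom, strand = strand,
    start = start, end = end,
    exons = list(lncorange:::exon_tbl(start, end))
  )
}

test_that("the three class definitions and their precedence hold", {
  genes <- simple_gene("G1", "chr1", "+", c(1000, 3000), c(1999, 3999))
  # no overlap with the gene span -> intergenic
  out <- classify_position(simple_lnc("L1", "chr1", "+", 6000, 6500), genes)
  expect_equal(out$positional_class, "intergenic")
  # wholly inside the intron, same strand -> intragenic
  out <- classify_position(simple_lnc("L2", "chr1", "+", 2100, 2700), genes)
  expect_equal(out$positional_class, "intragenic")
  # exon overlap on the opposite strand -> antisense (beats intragenic)
  out <- classify_position(simple_lnc("L3", "chr1", "-", 1500, 2300), genes)
  expect_equal(out$positional_class, "antisense")
  # nearest gene is reported
  expect_equal(out$nearest_gene_id, "G1")
  # unknown chromosome errors when a namespace is given
  expect_error(
    classify_position(simple_lnc("L4", "chrX", "+", 1, 300), genes,
                      chromosomes = "chr1"),
    "unknown chromosome"
  )
})

test_that("classification equals the naive all-pairs oracle on random placements", {
  set.seed(71)
  genes <- purrr::list_rbind(purrr::map(1:12, function(g) {
    s <- sample(1e3:8e4, 1)
    n_ex <- sample(1:3, 1)
    starts <- s + cumsum(c(0, rep(600, n_ex - 1)))
    simple_gene(paste0("G", g), sample(c("chr1", "chr2"), 1),
                sample(c("+", "-"), 1), starts, starts + 299)
  }))
  lnc <- purrr::list_rbind(purrr::map(1:500, function(i) {
    s <- sample(1e3:9e4, 1)
    simple_lnc(paste0("L", i), sample(c("chr1", "chr2"), 1),
               sample(c("+", "-"), 1), s, s + sample(200:1500, 1))
  }))
  impl <- classify_position(lnc, genes)
  expect_equal(impl$positional_class, oracle_classify(lnc, genes))
})

test_that("classification recovers every planted class", {
  run <- demo_run()
  truth <- run$sim$truth
  cls <- dplyr::inner_join(
    run$classes,
    dplyr::select(truth, transcript_id, true_class = positional_class),
    by = "transcript_id"
  ) |> dplyr::filter(!is.na(true_class))
  expect_gt(nrow(cls), 0)
  expect_equal(cls$positional_class, cls$true_class)
})

test_that("classification is strand-flip covariant", {
  set.seed(72)
  genes <- purrr::list_rbind(purrr::map(1:6, function(g) {
    s <- sample(1e3:4e4, 1)
    simple_gene(paste0("G", g), "chr1", sample(c("+", "-"), 1),
                c(s, s + 900), c(s + 399, s + 1299))
  }))
  lnc <- purrr::list_rbind(purrr::map(1:150, function(i) {
    s <- sample(1e3:45e3, 1)
    simple_lnc(paste0("L", i), "chr1", sample(c("+", "-"), 1),
               s, s + sample(200:1200, 1))
  }))
  flip <- function(tbl) dplyr::mutate(tbl, strand = ifelse(strand == "+",
                                                           "-", "+"))
  a <- classify_position(lnc, genes)
  b <- classify_position(flip(lnc), flip(genes))
  expect_equal(a$positional_class, b$positional_class)
})

test_that("density profile bins by start with a short last bin", {
  feats <- tibble::tibble(chrom = "chr1", start = c(1, 5e6, 1.5e7))
  prof <- density_profile(feats, c(chr1 = 2e7), bin_size = 1e7)
  expect_equal(prof$n, c(2L, 1L))
  expect_equal(prof$bin_end, c(1e7, 2e7))
  # conservation: bin counts sum to the feature count
  set.seed(73)
  feats2 <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                           start = sample(1:9e6, 300))
  prof2 <- density_profile(feats2, c(chr1 = 9e6, chr2 = 9e6),
                           bin_size = 1e6)
  expect_equal(sum(prof2$n), 300L)
  # empty input: all-zero profile
  prof0 <- density_profile(feats2[0, ], c(chr1 = 9e6), bin_size = 1e6)
  expect_true(all(prof0$n == 0))
  # out-of-range start errors
  expect_error(density_profile(tibble::tibble(chrom = "chr1", start = 3e7),
                               c(chr1 = 2e7)), "outside")
})

test_that("structure summary uses the standard bins and normalizes", {
  one <- tibble::tibble(length = 250L, n_exons = 1L)
  cod <- tibble::tibble(length = c(1500L, 800L), n_exons = c(11L, 3L))
  out <- structure_summary(one, cod)
  lnc_len <- out[out$set == "lncRNA" & out$metric == "length_nt", ]
  expect_equal(lnc_len$fraction[lnc_len$bin == "200-400"], 1)
  cod_ex <- out[out$set == "coding" & out$metric == "n_exons", ]
  expect_equal(cod_ex$fraction[cod_ex$bin == ">=10"], 0.5)
  sums <- out |>
    dplyr::group_by(set, metric) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("the simulated survivors are mostly 200-1,000 nt", {
  run <- demo_run()
  surv <- run$cascade$survivors
  ss <- structure_summary(surv, run$sim$genes)
  short <- ss |>
    dplyr::filter(set == "lncRNA", metric == "length_nt", bin != ">1000") |>
    dplyr::summarise(f = sum(fraction))
  expect_gte(short$f, 0.9)
})
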