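perfect_site <- function(mir) revcomp(chartr("Uu", "Tt", mir))

test_that("target penalties follow the declared cost table", {
  mir <- "UGACAGAAGAGAGUGAGCACA"  # 21 nt
  site <- perfect_site(mir)
  expect_equal(score_target_site(mir, site), 0)

  # single G:U at miRNA position 15 (outside the 2-13 core) -> 0.5
  # miRNA pos 15 pairs the site base at position L - 15 + 1 = 7
  m15 <- substring(mir, 15, 15)
  gu <- c(A = NA, C = NA, G = "T", U = "G")[[m15]]
  site_gu <- site
  substr(site_gu, 7, 7) <- gu
  expect_equal(score_target_site(mir, site_gu), 0.5)

  # single mismatch at miRNA position 10 (core) -> 1.0 * 2 = 2.0
  m10 <- substring(mir, 10, 10)
  wc <- c(A = "T", C = "G", G = "C", U = "A")[[m10]]
  wobble <- c(A = NA, C = NA, G = "T", U = "G")[[m10]]
  mm <- setdiff(c("A", "C", "G", "T"), c(wc, wobble))[1]
  site_mm <- site
  substr(site_mm, 12, 12) <- mm  # site position L - 10 + 1 = 12
  expect_equal(score_target_site(mir, site_mm), 2.0)

  expect_error(score_target_site(mir, "ACGT"), "within one")
  expect_error(score_target_site("UGAXCA", site), "only")
})

test_that("single-site penalties equal the exhaustive R oracle, indels included", {
  set.seed(91)
  for (i in 1:150) {
    L <- sample(19:24, 1)
    mir <- random_rna_str(L)
    site <- random_rna_str(L + sample(-1:1, 1))
    expect_equal(score_target_site(mir, site),
                 oracle_target_penalty(mir, site),
                 info = paste("case", i))
  }
})

test_that("window scanning equals the exhaustive window oracle", {
  set.seed(92)
  for (i in 1:6) {
    tseq <- random_rna_str(500)
    mir <- random_rna_str(21)
    # plant one near-perfect site so the hit set is non-trivial
    s <- sample(400, 1)
    site <- chartr("Tt", "Uu", perfect_site(mir))
    substr(tseq, s, s + nchar(site) - 1) <- site
    impl <- find_target_sites(
      tibble::tibble(mirna_id = "m", sequence = mir),
      tibble::tibble(transcript_id = "t", sequence = tseq),
      strands = "sense"
    )
    oracle <- oracle_scan_targets(tseq, mir)
    # every implementation hit appears in the oracle with the same penalty
    expect_true(all(paste(impl$start, impl$penalty) %in%
                      paste(oracle$start, oracle$penalty)))
    # the planted site is recovered at exact coordinates
    expect_true(any(impl$start == s & impl$penalty == 0))
    # greedy selection keeps non-overlapping windows only
    if (nrow(impl) > 1) {
      o <- order(impl$start)
      expect_true(all(impl$start[o][-1] > impl$end[o][-nrow(impl)]))
    }
  }
})

test_that("sense hits mirror to antisense hits on the reverse complement", {
  set.seed(93)
  tseq <- random_rna_str(400)
  mir <- random_rna_str(21)
  s <- 100
  site <- chartr("Tt", "Uu", perfect_site(mir))
  substr(tseq, s, s + 20) <- site
  mirnas <- tibble::tibble(mirna_id = "m", sequence = mir)
  fwd <- find_target_sites(mirnas,
                           tibble::tibble(transcript_id = "t",
                                          sequence = tseq))
  rc <- chartr("Tt", "Uu", revcomp(chartr("Uu", "Tt", tseq)))
  rev <- find_target_sites(mirnas,
                           tibble::tibble(transcript_id = "t",
                                          sequence = rc))
  sense_fwd <- fwd[fwd$strand == "sense", ]
  anti_rev <- rev[rev$strand == "antisense", ]
  n <- nchar(tseq)
  expect_equal(sort(n - sense_fwd$end + 1), sort(anti_rev$start))
  expect_equal(sort(sense_fwd$penalty), sort(anti_rev$penalty))
})

test_that("the four eTM boundary behaviours hold exactly", {
  set.seed(94)
  # fixed 21-nt miRNA with four G/U bases among positions 13-21 (needed
  # for the rule-4 case below)
  mir <- "UGACAGAAGAGAGUGAGCACA"
  tx <- function(site) tibble::tibble(transcript_id = "t",
                                      sequence = site)
  mirnas <- tibble::tibble(mirna_id = "m", sequence = mir)

  # (1) perfect complement + 3-nt bulge at junction 10/11, no edits
  built <- lncorange:::make_etm_site(mir, junction = 10, n_edits = 0)
  hits <- detect_target_mimics(mirnas, tx(built$site))
  expect_true(any(hits$start == 1 & hits$junction == 10 &
                    hits$n_edits == 0))

  # (2) the same site with a mismatch at miRNA position 5 -> rule 3 fails
  m5 <- substring(mir, 5, 5)
  wc <- c(A = "U", C = "G", G = "C", U = "A")[[m5]]
  gu <- c(A = NA, C = NA, G = "U", U = "G")[[m5]]
  bad <- setdiff(c("A", "C", "G", "U"), c(wc, gu))[1]
  site2 <- built$site
  # miRNA position 5 pairs site position (L+3) - 5 + 1 = 20
  substr(site2, 20, 20) <- bad
  hits2 <- detect_target_mimics(mirnas, tx(site2))
  expect_false(any(hits2$junction == 10 & hits2$start == 1))

  # (3) a 2-nt insertion instead of 3 -> rule 2 fails (no valid window)
  r <- rev(strsplit(chartr("Tt", "Uu", built$site), "")[[1]])
  site3 <- paste(rev(r[-11]), collapse = "")  # drop one bulge base
  expect_equal(nrow(detect_target_mimics(mirnas, tx(site3))), 0)

  # (4) 3-nt bulge plus 4 G:U pairs at miRNA positions 13-21 -> rule 4
  site4 <- lncorange:::make_etm_site(mir, junction = 10, n_edits = 0)$site
  r4 <- rev(strsplit(site4, "")[[1]])
  gu_of <- c(G = "U", U = "G")
  flipped <- 0
  for (i in 13:21) {
    m <- substring(mir, i, i)
    if (m %in% c("G", "U") && flipped < 4) {
      r4[i + 3] <- gu_of[[m]]
      flipped <- flipped + 1
    }
  }
  stopifnot(flipped == 4)
  site4 <- paste(rev(r4), collapse = "")
  hits4 <- detect_target_mimics(mirnas, tx(site4))
  expect_false(any(hits4$junction == 10 & hits4$start == 1))
  # with the default budget raised the same site is accepted
  hits4b <- detect_target_mimics(mirnas, tx(site4), max_edits = 4)
  expect_true(any(hits4b$junction == 10 & hits4b$start == 1))
})

test_that("eTM detection equals the exhaustive enumeration oracle", {
  set.seed(95)
  for (i in 1:40) {
    L <- sample(19:22, 1)
    mir <- random_rna_str(L)
    tseq <- if (i %% 2 == 0) {
      # embed a constructed site (random junction/edits, possibly over
      # budget) in a random transcript
      built <- lncorange:::make_etm_site(mir, sample(9:11, 1),
                                         n_edits = sample(0:3, 1))
      paste0(random_rna_str(20), built$site, random_rna_str(20))
    } else {
      random_rna_str(sample(60:200, 1))
    }
    impl <- detect_target_mimics(
      tibble::tibble(mirna_id = "m", sequence = mir),
      tibble::tibble(transcript_id = "t", sequence = tseq)
    )
    orc <- oracle_etm(tseq, mir)
    expect_equal(nrow(impl), nrow(orc), info = paste("case", i))
    expect_equal(paste(impl$start, impl$junction, impl$n_edits),
                 paste(orc$start, orc$junction, orc$n_edits),
                 info = paste("case", i))
  }
})

test_that("planted sites are recovered exactly and duplexes render", {
  sim <- demo_sim()
  ts <- sim$truth_sites
  hosts <- sim$transcripts[match(unique(ts$transcript_id),
                                 sim$transcripts$transcript_id), ]
  hits <- predict_mirna_interactions(sim$mirnas, hosts, mode = "both")
  key <- paste(hits$mirna_id, hits$transcript_id, hits$start, hits$end,
               hits$kind)
  planted <- paste(ts$mirna_id, ts$transcript_id, ts$start, ts$end, ts$kind)
  expect_true(all(planted %in% key))
  # eTM bulge coordinates match the planted truth
  etm <- ts[ts$kind == "etm", ]
  for (i in seq_len(nrow(etm))) {
    h <- hits[hits$kind == "etm" &
                hits$transcript_id == etm$transcript_id[i] &
                hits$start == etm$start[i], ]
    expect_true(etm$junction[i] %in% h$junction)
    expect_true(etm$bulge_start[i] %in% h$bulge_start)
  }
  # duplex rendering produces three equal-width rows
  mir <- sim$mirnas$sequence[match(etm$mirna_id[1], sim$mirnas$mirna_id)]
  tx <- sim$transcripts$sequence[match(etm$transcript_id[1],
                                       sim$transcripts$transcript_id)]
  site <- substring(tx, etm$start[1], etm$end[1])
  out <- render_duplex(mir, site, junction = etm$junction[1])
  expect_length(out, 3)
  expect_equal(length(unique(nchar(out))), 1)
})

test_that("RA-PCR ratios flag cleavage-consistent transcripts", {
  # 3' region 6.5x the 5'/middle regions: cleavage-consistent
  expect_true(ra_pcr_ratio(1, 1, 6.5)$cleavage_consistent)
  expect_equal(ra_pcr_ratio(1, 1, 6.5)$ratio, 6.5)
  # flat profile: the negative-control behaviour
  flat <- ra_pcr_ratio(1, 1, 1)
  expect_false(flat$cleavage_consistent)
  expect_equal(flat$ratio, 1)
  # the denominator is the larger of 5' and middle
  expect_equal(ra_pcr_ratio(2, 1, 6)$ratio, 3)
  expect_error(ra_pcr_ratio(0, 1, 1), "> 0")
})
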