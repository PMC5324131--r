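#' Run the whole study end to end on synthetic data
#'
#' Chains simulation, the identification cascade, positional
#' classification, differential expression (lncRNA survivors and coding
#' transcripts) and miRNA interaction prediction under one seed, and
#' optionally writes every artifact plus an md5 manifest to a directory.
#' Rerunning with the same configuration reproduces the artifacts
#' byte-identically. No ground-truth information flows into the analysis
#' stages: the coding side of the differential-expression comparison is
#' taken from transcripts flagged by the coding-similarity screen, and
#' lncRNA calls use only cascade survivors.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @param cascade Optional [cascade_params()] override.
#' @param bin_size Density-profile bin width in nt (default 10 Mb, so
#'   miniature chromosomes fall in one bin each).
#' @return A `lnc_run` list: `sim`, `cascade`, `classes`, `density`,
#'   `structure`, `de_lncrna`, `de_coding`, `hits`, `config`.
#' @export
run_lncrna_study <- function(config = sim_config(), outdir = NULL,
                             cascade = cascade_params(), bin_size = 1e7) {
  sim <- simulate_lncrna_study(config)
  casc <- run_cascade(sim$transcripts, sim$counts, sim$exclusion_sets,
                      params = cascade, hexamer_model = sim$hexamer_model)
  survivors <- casc$survivors
  classes <- classify_position(survivors, sim$genes,
                               chromosomes = names(sim$genome$chromosomes))
  survivors <- left_join(survivors, classes, by = "transcript_id")

  chrom_lens <- nchar(sim$genome$chromosomes)
  feats <- bind_rows(
    tibble::tibble(chrom = survivors$chrom, start = survivors$start,
                   group = "lncRNA"),
    tibble::tibble(chrom = sim$genes$chrom, start = sim$genes$start,
                   group = "coding")
  )
  density <- density_profile(feats, chrom_lens, bin_size)
  structure_tbl <- if (nrow(survivors) > 0 && nrow(sim$genes) > 0) {
    structure_summary(survivors, sim$genes)
  } else {
    NULL
  }

  coding_ids <- casc$detail$transcript_id[
    casc$detail$reason == "failed_coding_similarity"]
  de_lnc <- diff_expr(sim$counts, mode = "lncrna",
                      ids = survivors$transcript_id)
  de_cod <- if (length(coding_ids) > 0) {
    diff_expr(sim$counts, mode = "coding", ids = coding_ids)
  } else {
    NULL
  }
  hits <- predict_mirna_interactions(sim$mirnas, survivors, mode = "both")

  run <- structure(
    list(sim = sim, cascade = casc, classes = classes, density = density,
         structure = structure_tbl, de_lncrna = de_lnc, de_coding = de_cod,
         hits = hits, config = config),
    class = "lnc_run"
  )
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' Summary of a pipeline run
#'
#' One row of headline counts: funnel input/output, class counts, DE calls
#' by direction, genotype-specific survivors (zero FPKM throughout one
#' genotype), and miRNA interaction counts by kind and strand.
#'
#' @param x A `lnc_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lnc_run <- function(x, ...) {
  cls <- table(factor(x$classes$positional_class,
                      levels = c("intergenic", "intragenic", "antisense")))
  de <- table(x$de_lncrna$call)
  fpkm <- fpkm_table(x$sim$counts) |>
    filter(.data$transcript_id %in% x$classes$transcript_id) |>
    group_by(.data$transcript_id) |>
    summarise(mt = max(.data$fpkm[.data$genotype == "MT"]),
              wt = max(.data$fpkm[.data$genotype == "WT"]),
              .groups = "drop")
  targets <- filter(x$hits, .data$kind == "cleavage_target")
  etms <- filter(x$hits, .data$kind == "etm")
  tibble::tibble(
    n_transcripts = nrow(x$sim$transcripts),
    n_lncrnas = nrow(x$classes),
    n_intergenic = as.integer(cls[["intergenic"]]),
    n_intragenic = as.integer(cls[["intragenic"]]),
    n_antisense = as.integer(cls[["antisense"]]),
    n_de = as.integer(de[["up_in_MT"]] + de[["down_in_MT"]]),
    n_up_in_mt = as.integer(de[["up_in_MT"]]),
    n_down_in_mt = as.integer(de[["down_in_MT"]]),
    n_mt_specific = sum(fpkm$wt == 0 & fpkm$mt > 0),
    n_wt_specific = sum(fpkm$mt == 0 & fpkm$wt > 0),
    n_target_interactions = nrow(targets),
    n_target_sense = sum(targets$strand == "sense"),
    n_target_antisense = sum(targets$strand == "antisense"),
    n_etm_duplexes = nrow(etms),
    n_etm_lncrnas = dplyr::n_distinct(etms$transcript_id)
  )
}

#' @export
print.lnc_run <- function(x, ...) {
  cat("<lnc_run>\n")
  print(as.data.frame(glance(x)), row.names = FALSE)
  invisible(x)
}

#' Write every artifact of a run to a directory
#'
#' Writes the genome and annotation, transcript models and sequences,
#' counts, miRNAs, truth tables, cascade outputs, classification, DE
#' tables, interaction hits, a JSON summary and an md5 `manifest.tsv`.
#' All writers are deterministic (no timestamps), so identical runs give
#' identical files.
#'
#' @param run A `lnc_run`.
#' @param outdir Target directory.
#' @return Invisibly, the manifest tibble.
#' @export
write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- run$sim
  write_fasta(sim$genome$chromosomes, file.path(outdir, "genome.fa"))
  write_transcripts_gtf(sim$genes, file.path(outdir, "annotation.gtf"))
  write_fasta(setNames(sim$transcripts$sequence,
                       sim$transcripts$transcript_id),
              file.path(outdir, "transcripts.fa"))
  write_transcripts_gtf(sim$transcripts, file.path(outdir, "transcripts.gtf"))
  write_counts_tsv(sim$counts, outdir)
  write_fasta(setNames(as_dna(sim$mirnas$sequence), sim$mirnas$mirna_id),
              file.path(outdir, "mirnas.fa"))
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  readr::write_tsv(sim$truth_sites, file.path(outdir, "truth_sites.tsv"))

  surv <- run$cascade$survivors
  write_fasta(setNames(surv$sequence, surv$transcript_id),
              file.path(outdir, "lncrnas.fa"))
  write_transcripts_gtf(surv, file.path(outdir, "lncrnas.gtf"))
  readr::write_tsv(run$cascade$report, file.path(outdir, "filter_report.tsv"))
  readr::write_tsv(run$cascade$detail, file.path(outdir, "filter_detail.tsv"))
  readr::write_tsv(run$classes, file.path(outdir, "classes.tsv"))
  readr::write_tsv(run$density, file.path(outdir, "density.tsv"))
  if (!is.null(run$structure)) {
    readr::write_tsv(run$structure, file.path(outdir, "structure.tsv"))
  }
  readr::write_tsv(run$de_lncrna, file.path(outdir, "de_lncrna.tsv"))
  if (!is.null(run$de_coding)) {
    readr::write_tsv(run$de_coding, file.path(outdir, "de_coding.tsv"))
  }
  readr::write_tsv(run$hits, file.path(outdir, "mirna_hits.tsv"))
  jsonlite::write_json(as.list(glance(run)), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Compare a run against its planted truth
#'
#' Compares every planted label with the pipeline's calls: coding/noncoding
#' recovery of the cascade, positional-class recovery, the DE confusion
#' (sensitivity and realized FDR at the lncRNA thresholds), and exact
#' planted-site recovery for cleavage targets and eTMs. Rates carry exact
#' binomial 95% confidence intervals.
#'
#' @param run A `lnc_run`.
#' @param truth A `SyntheticTruth`-style tibble; defaults to the run's own.
#' @return Tibble `(metric, numerator, denominator, value, ci_lo, ci_hi)`.
#' @export
validate_against_truth <- function(run, truth = run$sim$truth) {
  if (is.null(truth) || nrow(truth) == 0) {
    abort("`truth` is empty.")
  }
  if (!all(truth$transcript_id %in% run$sim$transcripts$transcript_id)) {
    abort("truth/report transcript ids do not match.")
  }
  surv_ids <- run$cascade$survivors$transcript_id
  is_lnc <- truth$category == "lncrna"
  called_lnc <- truth$transcript_id %in% surv_ids

  rows <- list(
    rate_row("lncrna_sensitivity", sum(is_lnc & called_lnc), sum(is_lnc)),
    rate_row("lncrna_specificity", sum(!is_lnc & !called_lnc), sum(!is_lnc))
  )

  cls <- left_join(run$classes,
                   select(truth, "transcript_id", "positional_class"),
                   by = "transcript_id",
                   suffix = c("_called", "_true")) |>
    filter(!is.na(.data$positional_class_true))
  rows <- c(rows, list(rate_row(
    "class_recovery",
    sum(cls$positional_class_called == cls$positional_class_true),
    nrow(cls)
  )))

  de <- left_join(run$de_lncrna,
                  select(truth, "transcript_id", "true_log2fc"),
                  by = "transcript_id") |>
    filter(!is.na(.data$true_log2fc))
  truly_de <- de$true_log2fc != 0
  called_de <- de$call %in% c("up_in_MT", "down_in_MT")
  rows <- c(rows, list(
    rate_row("de_sensitivity", sum(truly_de & called_de), sum(truly_de)),
    rate_row("de_fdr", sum(!truly_de & called_de), sum(called_de))
  ))

  ts <- run$sim$truth_sites
  if (!is.null(ts) && nrow(ts) > 0) {
    hit_key <- with(run$hits, paste(mirna_id, transcript_id, start, end,
                                    kind, sep = "/"))
    planted_key <- with(ts, paste(mirna_id, transcript_id, start, end,
                                  ifelse(kind == "etm", "etm",
                                         "cleavage_target"), sep = "/"))
    rec <- planted_key %in% hit_key
    rows <- c(rows, list(
      rate_row("target_site_recovery", sum(rec[ts$kind == "cleavage_target"]),
               sum(ts$kind == "cleavage_target")),
      rate_row("etm_site_recovery", sum(rec[ts$kind == "etm"]),
               sum(ts$kind == "etm"))
    ))
  }
  purrr::list_rbind(rows)
}

rate_row <- function(metric, k, n) {
  if (n > 0) {
    ci <- stats::binom.test(k, n)$conf.int
    tibble::tibble(metric = metric, numerator = k, denominator = n,
                   value = k / n, ci_lo = ci[1], ci_hi = ci[2])
  } else {
    tibble::tibble(metric = metric, numerator = 0L, denominator = 0L,
                   value = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  }
}
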