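#' Fragments per kilobase of transcript per million fragments
#'
#' `FPKM = count * 1e9 / (library_size * transcript_length)`.
#'
#' @param count Fragment count(s), non-negative.
#' @param transcript_length Transcript length(s) in nt, > 0.
#' @param library_size Total mapped fragments in the sample, > 0.
#' @return Numeric FPKM vector.
#' @examples
#' compute_fpkm(100, 1000, 1e6)  # 100
#' @export
compute_fpkm <- function(count, transcript_length, library_size) {
  if (any(transcript_length <= 0)) abort("`transcript_length` must be > 0.")
  if (any(library_size <= 0)) abort("`library_size` must be > 0.")
  count * 1e9 / (library_size * transcript_length)
}

#' Per-sample FPKM table from a count set
#'
#' @param counts A `lnc_counts` object (see [simulate_counts()]) or a list
#'   with `counts` (long tibble: `transcript_id`, `sample`, `genotype`,
#'   `replicate`, `fragment_count`), `samples` (`sample`, `genotype`,
#'   `replicate`, `library_size`) and `lengths` (`transcript_id`, `length`).
#' @return Long tibble with an `fpkm` column added.
#' @export
fpkm_table <- function(counts) {
  counts$counts |>
    left_join(select(counts$samples, "sample", "library_size"), by = "sample") |>
    left_join(counts$lengths, by = "transcript_id") |>
    mutate(fpkm = compute_fpkm(.data$fragment_count, .data$length,
                               .data$library_size)) |>
    select(-"library_size", -"length")
}

#' Expression prefilter
#'
#' Drops transcripts whose FPKM never reaches 1 in any sample, or whose
#' read-mapping coverage is below half the transcript length. Coverage is
#' supplied as an input column (computing it from reads is upstream of this
#' package); when absent it defaults to 1.
#'
#' @param fpkm Long tibble from [fpkm_table()].
#' @param coverage Optional tibble `(transcript_id, coverage_fraction)`.
#' @return Tibble `(transcript_id, max_fpkm, coverage_fraction, keep)`.
#' @export
expression_prefilter <- function(fpkm, coverage = NULL) {
  out <- fpkm |>
    group_by(.data$transcript_id) |>
    summarise(max_fpkm = max(.data$fpkm), .groups = "drop")
  if (is.null(coverage)) {
    out$coverage_fraction <- 1
  } else {
    out <- left_join(out, coverage, by = "transcript_id")
    out$coverage_fraction[is.na(out$coverage_fraction)] <- 1
  }
  out$keep <- out$max_fpkm >= 1 & out$coverage_fraction >= 0.5
  out
}

#' Two-sample t-test on log-FPKM between genotypes
#'
#' Two-sided t-test on `log2(FPKM + 0.1)`. The default is the pooled
#' (equal-variance) test: with three replicates per genotype the
#' Welch-Satterthwaite correction is markedly conservative (its random
#' degrees of freedom reject well below nominal even for normal data),
#' while the pooled test holds its nominal size under the symmetric null
#' this pipeline assumes. Set `var_equal = FALSE` for Welch's test. When
#' both groups are essentially constant the p-value is guarded to 1 for
#' equal means and 0 otherwise (the degenerate limit).
#'
#' @param fpkm_wt,fpkm_mt Numeric replicate vectors (length >= 2 each).
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @return A single p-value in \[0, 1\].
#' @export
de_test <- function(fpkm_wt, fpkm_mt, var_equal = TRUE) {
  if (length(fpkm_wt) < 2 || length(fpkm_mt) < 2) {
    abort("need >= 2 replicates per genotype.")
  }
  x <- log2(fpkm_wt + 0.1)
  y <- log2(fpkm_mt + 0.1)
  if (sd(x) < 1e-12 && sd(y) < 1e-12) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) ( p_(j) * m / j )`, capped at 1, mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Significance calls from fold changes and p-values
#'
#' Fold change follows the convention `FC = FPKM(WT) / FPKM(MT)`, so
#' `log2fc <= -threshold` means higher expression in the mutant
#' (`up_in_MT`) and `log2fc >= +threshold` means `down_in_MT`.
#' lncRNA mode: significant iff `|log2fc| >= 1` and `p < 0.05`.
#' Coding mode: significant iff `|log2fc| >= 4` and `q <= 0.05`
#' (BH-adjusted).
#'
#' @param results Tibble with `log2fc`, `p_value` (and `q_value` in coding
#'   mode) columns; a logical `keep` column, if present, marks transcripts
#'   that survived the prefilter (others are called `filtered`).
#' @param mode `"lncrna"` or `"coding"`.
#' @param lfc_threshold,alpha Overrides for the mode defaults.
#' @return `results` with a `call` factor added: `up_in_MT`, `down_in_MT`,
#'   `not_significant`, `filtered`.
#' @export
call_de <- function(results, mode = c("lncrna", "coding"),
                    lfc_threshold = NULL, alpha = NULL) {
  mode <- match.arg(mode)
  lfc <- lfc_threshold %||% if (mode == "lncrna") 1 else 4
  a <- alpha %||% 0.05
  if (mode == "coding") {
    if (!"q_value" %in% names(results)) {
      abort("coding mode requires a `q_value` column.")
    }
    sig_p <- results$q_value <= a
  } else {
    sig_p <- results$p_value < a
  }
  sig <- sig_p & abs(results$log2fc) >= lfc
  call <- ifelse(!sig, "not_significant",
                 ifelse(results$log2fc <= -lfc, "up_in_MT", "down_in_MT"))
  if ("keep" %in% names(results)) call[!results$keep] <- "filtered"
  results$call <- factor(call, levels = c("up_in_MT", "down_in_MT",
                                          "not_significant", "filtered"))
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential expression between MT and WT
#'
#' End-to-end FPKM differential expression: per-sample FPKM, the
#' expression prefilter, mean FPKM per genotype, fold change
#' `FC = (mean FPKM WT + eps) / (mean FPKM MT + eps)` with pseudocount
#' `eps = 0.1` (so 0-vs-0 gives FC = 1 exactly), a Welch test on
#' `log2(FPKM + 0.1)` replicate values, BH adjustment, and significance
#' calls via [call_de()].
#'
#' @inheritParams fpkm_table
#' @inheritParams call_de
#' @param ids Optional transcript ids to restrict to (e.g. cascade
#'   survivors for lncRNA mode, coding gene ids for coding mode).
#' @param coverage Optional coverage tibble, see [expression_prefilter()].
#' @param pseudocount Fold-change pseudocount (default 0.1).
#' @param test A function `(fpkm_wt, fpkm_mt) -> p value`; defaults to
#'   [de_test()] (pluggable, e.g. for rank or moderated tests).
#' @return A `lnc_de` tibble: `transcript_id`, `mean_fpkm_wt`,
#'   `mean_fpkm_mt`, `fc`, `log2fc`, `p_value`, `q_value`, `call`.
#' @export
diff_expr <- function(counts, mode = c("lncrna", "coding"), ids = NULL,
                      coverage = NULL, lfc_threshold = NULL, alpha = NULL,
                      pseudocount = 0.1, test = de_test) {
  mode <- match.arg(mode)
  fpkm <- fpkm_table(counts)
  if (!is.null(ids)) fpkm <- filter(fpkm, .data$transcript_id %in% ids)
  pre <- expression_prefilter(fpkm, coverage)

  stats_tbl <- fpkm |>
    group_by(.data$transcript_id) |>
    summarise(
      mean_fpkm_wt = mean(.data$fpkm[.data$genotype == "WT"]),
      mean_fpkm_mt = mean(.data$fpkm[.data$genotype == "MT"]),
      p_value = test(.data$fpkm[.data$genotype == "WT"],
                     .data$fpkm[.data$genotype == "MT"]),
      .groups = "drop"
    ) |>
    mutate(
      fc = (.data$mean_fpkm_wt + pseudocount) /
        (.data$mean_fpkm_mt + pseudocount),
      log2fc = log2(.data$fc)
    ) |>
    left_join(select(pre, "transcript_id", "keep"), by = "transcript_id")
  # BH over the transcripts that enter testing (prefilter survivors)
  stats_tbl$q_value <- NA_real_
  stats_tbl$q_value[stats_tbl$keep] <- bh_fdr(stats_tbl$p_value[stats_tbl$keep])
  out <- call_de(stats_tbl, mode = mode, lfc_threshold = lfc_threshold,
                 alpha = alpha) |>
    select("transcript_id", "mean_fpkm_wt", "mean_fpkm_mt", "fc", "log2fc",
           "p_value", "q_value", "keep", "call")
  class(out) <- c("lnc_de", class(out))
  attr(out, "mode") <- mode
  attr(out, "pseudocount") <- pseudocount
  out
}
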