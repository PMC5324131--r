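#' Classify lncRNAs by position relative to coding genes
#'
#' Assigns each lncRNA exactly one positional class, with precedence
#' antisense > intragenic > intergenic:
#' * **antisense** — any lncRNA exon overlaps any coding exon on the
#'   opposite strand (checked first; the definition is exon-specific);
#' * **intragenic** — the lncRNA's genomic span lies entirely within a
#'   coding gene's span (either strand, span = min start to max end over
#'   the gene's transcripts);
#' * **intergenic** — no overlap with any coding locus.
#'
#' Two undefined-by-definition cases are resolved explicitly and flagged:
#' same-strand exonic overlap with a coding exon, and partial (not
#' contained) overlap with a gene span, are both classified intragenic
#' with `flag = TRUE`.
#'
#' @param lncrnas Tibble with `transcript_id`, `chrom`, `strand`, `start`,
#'   `end` and an `exons` list-column.
#' @param annotation Coding-gene tibble of the same shape (plus `gene_id`),
#'   e.g. the `genes` element of a simulation.
#' @param chromosomes Optional character vector naming the shared
#'   chromosome namespace; lncRNAs on chromosomes outside it raise an
#'   error. Defaults to the union of the two inputs' chromosomes.
#' @return Tibble `(transcript_id, positional_class, nearest_gene_id,
#'   flag)`.
#' @export
classify_position <- function(lncrnas, annotation, chromosomes = NULL) {
  if (nrow(lncrnas) == 0) {
    return(tibble::tibble(transcript_id = character(),
                          positional_class = character(),
                          nearest_gene_id = character(), flag = logical()))
  }
  if (!is.null(chromosomes)) {
    bad <- setdiff(unique(c(lncrnas$chrom, annotation$chrom)), chromosomes)
    if (length(bad)) {
      abort(sprintf("unknown chromosome(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }

  lnc_exons <- unnest_exons(lncrnas)
  lnc_gr <- GenomicRanges::GRanges(
    lnc_exons$chrom,
    IRanges::IRanges(lnc_exons$start, lnc_exons$end),
    strand = lnc_exons$strand
  )
  span_gr <- GenomicRanges::GRanges(
    lncrnas$chrom, IRanges::IRanges(lncrnas$start, lncrnas$end)
  )

  n <- nrow(lncrnas)
  cls <- rep("intergenic", n)
  flag <- rep(FALSE, n)
  nearest_gene <- rep(NA_character_, n)

  if (nrow(annotation) > 0) {
    gene_exons <- unnest_exons(annotation)
    gene_exon_gr <- GenomicRanges::GRanges(
      gene_exons$chrom,
      IRanges::IRanges(gene_exons$start, gene_exons$end),
      strand = gene_exons$strand
    )
    gene_span <- annotation |>
      group_by(.data$gene_id, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    gene_span_gr <- GenomicRanges::GRanges(
      gene_span$chrom, IRanges::IRanges(gene_span$start, gene_span$end)
    )

    # exon-exon overlaps, split by relative strand
    ov <- GenomicRanges::findOverlaps(lnc_gr, gene_exon_gr,
                                      ignore.strand = TRUE)
    li <- lnc_exons$row[S4Vectors::queryHits(ov)]
    opposite <- lnc_exons$strand[S4Vectors::queryHits(ov)] !=
      gene_exons$strand[S4Vectors::subjectHits(ov)]
    antisense_rows <- unique(li[opposite])
    same_strand_rows <- unique(li[!opposite])

    # span containment / any-span overlap
    within_ov <- GenomicRanges::findOverlaps(span_gr, gene_span_gr,
                                             type = "within",
                                             ignore.strand = TRUE)
    any_ov <- GenomicRanges::findOverlaps(span_gr, gene_span_gr,
                                          ignore.strand = TRUE)
    within_rows <- unique(S4Vectors::queryHits(within_ov))
    touched_rows <- unique(S4Vectors::queryHits(any_ov))

    cls[touched_rows] <- "intragenic"
    flag[setdiff(touched_rows, within_rows)] <- TRUE
    flag[intersect(same_strand_rows, setdiff(seq_len(n), antisense_rows))] <- TRUE
    cls[antisense_rows] <- "antisense"
    flag[antisense_rows] <- FALSE

    near <- GenomicRanges::nearest(span_gr, gene_span_gr)
    ok <- !is.na(near)
    nearest_gene[ok] <- gene_span$gene_id[near[ok]]
  }

  tibble::tibble(
    transcript_id = lncrnas$transcript_id,
    positional_class = cls,
    nearest_gene_id = nearest_gene,
    flag = flag
  )
}

unnest_exons <- function(tbl) {
  tbl |>
    mutate(row = dplyr::row_number()) |>
    select("row", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
}

#' Feature density in fixed genomic bins
#'
#' Counts features (lncRNAs, coding genes, ...) in physical bins of
#' `bin_size` nt per chromosome. Each feature is counted once, in the bin
#' containing its start coordinate; the last bin may be short.
#'
#' @param features Tibble with `chrom` and `start` (a `group` column, if
#'   present, is tabulated separately).
#' @param chromosome_lengths Named numeric vector of chromosome lengths.
#' @param bin_size Bin width in nt (default 10 Mb).
#' @return Tibble `(chrom, bin_start, bin_end, [group,] n)` covering every
#'   bin of every chromosome.
#' @export
density_profile <- function(features, chromosome_lengths, bin_size = 1e7) {
  check_scalar_number(bin_size, "bin_size", positive = TRUE)
  bins <- purrr::imap(as.list(chromosome_lengths), function(len, cn) {
    starts <- seq(1, len, by = bin_size)
    tibble::tibble(chrom = cn, bin_start = starts,
                   bin_end = pmin(starts + bin_size - 1, len))
  }) |> purrr::list_rbind()
  groups <- if ("group" %in% names(features)) unique(features$group) else NULL
  if (!is.null(groups)) {
    bins <- tidyr::crossing(bins, group = groups)
  }
  if (nrow(features) > 0) {
    bad <- !(features$chrom %in% names(chromosome_lengths)) |
      features$start < 1 |
      features$start > chromosome_lengths[features$chrom]
    if (any(bad)) abort("feature start outside its chromosome.")
    feat <- features |>
      mutate(bin_start = floor((.data$start - 1) / bin_size) * bin_size + 1)
    by_cols <- c("chrom", "bin_start", if (!is.null(groups)) "group")
    tallied <- feat |> count(dplyr::pick(dplyr::all_of(by_cols)))
    bins <- bins |>
      left_join(tallied, by = by_cols) |>
      mutate(n = dplyr::coalesce(.data$n, 0L))
  } else {
    bins$n <- 0L
  }
  bins
}

#' Length and exon-count histograms of lncRNAs vs coding transcripts
#'
#' Bins follow the conventional summary scheme: lengths 200-400, 400-600,
#' 600-800, 800-1,000, >1,000 nt; exon counts 1, 2, ..., 9, >=10.
#' Fractions sum to 1 within each set and metric.
#'
#' @param lncrnas,coding_transcripts Tibbles with `sequence` (or `length`)
#'   and an `exons` list-column (or `n_exons`).
#' @return Tibble `(set, metric, bin, n, fraction)`.
#' @export
structure_summary <- function(lncrnas, coding_transcripts) {
  one_set <- function(tbl, label) {
    if (nrow(tbl) == 0) abort("`structure_summary` needs non-empty sets.")
    len <- if ("length" %in% names(tbl)) tbl$length else nchar(tbl$sequence)
    nex <- if ("n_exons" %in% names(tbl)) tbl$n_exons
           else purrr::map_int(tbl$exons, nrow)
    len_bin <- cut(len, c(-Inf, 400, 600, 800, 1000, Inf),
                   labels = c("200-400", "400-600", "600-800", "800-1000",
                              ">1000"))
    ex_bin <- factor(ifelse(nex >= 10, ">=10", as.character(nex)),
                     levels = c(as.character(1:9), ">=10"))
    bind_rows(
      tibble::tibble(set = label, metric = "length_nt",
                     bin = factor(len_bin)) |> count(.data$set, .data$metric, .data$bin,
                                                     .drop = FALSE),
      tibble::tibble(set = label, metric = "n_exons",
                     bin = ex_bin) |> count(.data$set, .data$metric, .data$bin,
                                            .drop = FALSE)
    ) |>
      group_by(.data$set, .data$metric) |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup() |>
      mutate(bin = as.character(.data$bin))
  }
  bind_rows(one_set(lncrnas, "lncRNA"),
            one_set(coding_transcripts, "coding"))
}
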