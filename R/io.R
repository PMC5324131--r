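# Readers/writers for the standard interchange formats. FASTA goes through
# Biostrings, GTF through rtracklayer, tables through readr.

#' Read and write FASTA sequence sets
#'
#' @param x Named character vector of DNA sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_dna(x)), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

#' Write transcript models as GTF
#'
#' Emits one `transcript` and per-exon `exon` features, 1-based closed
#' coordinates (the GTF standard).
#'
#' @param transcripts Tibble with `transcript_id`, `chrom`, `strand`,
#'   `exons` (list-column) and optionally `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  if (nrow(transcripts) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gene_id <- if ("gene_id" %in% names(transcripts)) transcripts$gene_id
             else transcripts$transcript_id
  ex <- transcripts |>
    mutate(gene_id = gene_id) |>
    select("transcript_id", "gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
  tx <- transcripts |>
    mutate(gene_id = gene_id, start = .data$start, end = .data$end)
  gr <- c(
    GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
      type = "transcript", gene_id = tx$gene_id,
      transcript_id = tx$transcript_id
    ),
    GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
      type = "exon", gene_id = ex$gene_id, transcript_id = ex$transcript_id
    )
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF (+ optional FASTA of spliced sequences)
#'
#' @param gtf_path GTF with `exon` features carrying `transcript_id`.
#' @param fasta_path Optional FASTA of spliced transcript sequences named
#'   by transcript id.
#' @return Tibble `transcript_id`, `chrom`, `strand`, `start`, `end`,
#'   `exons` (list-column) and, when FASTA is given, `sequence`.
#' @export
read_transcripts_gtf <- function(gtf_path, fasta_path = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  tbl <- tibble::tibble(
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex)
  ) |>
    group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(exons = list(exon_tbl(.data$start, .data$end)),
              .groups = "drop") |>
    mutate(start = purrr::map_int(.data$exons, ~ .x$start[1]),
           end = purrr::map_int(.data$exons, ~ .x$end[nrow(.x)]))
  if (!is.null(fasta_path)) {
    seqs <- read_fasta(fasta_path)
    tbl$sequence <- unname(seqs[tbl$transcript_id])
  }
  tbl
}

#' Write a long count table as TSV
#'
#' @param counts A `lnc_counts` object.
#' @param dir Output directory; writes `counts.tsv`, `samples.tsv`,
#'   `transcript_lengths.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_tsv <- function(counts, dir) {
  readr::write_tsv(counts$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(counts$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(counts$lengths, file.path(dir, "transcript_lengths.tsv"))
  invisible(dir)
}

#' Read a count set written by [write_counts_tsv()]
#'
#' @param dir Directory containing the three TSVs.
#' @return A `lnc_counts` list.
#' @export
read_counts_tsv <- function(dir) {
  structure(
    list(
      counts = readr::read_tsv(file.path(dir, "counts.tsv"),
                               show_col_types = FALSE),
      samples = readr::read_tsv(file.path(dir, "samples.tsv"),
                                show_col_types = FALSE),
      lengths = readr::read_tsv(file.path(dir, "transcript_lengths.tsv"),
                                show_col_types = FALSE)
    ),
    class = "lnc_counts"
  )
}
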