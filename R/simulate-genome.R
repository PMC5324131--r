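#' Generate a miniature genome with a coding-gene annotation
#'
#' Chromosomes are uniform-random DNA of the configured length. Each coding
#' gene gets 1-12 exons and an mRNA consisting of a short 5' UTR, a genuine
#' ORF of at least 100 codons (ATG, sense codons, stop), and a 3' UTR; the
#' mRNA is split across the exons and written into the chromosome (reverse
#' complemented for minus-strand genes), so the spliced genomic sequence of
#' every gene equals its mRNA. Genes are packed left to right with
#' intergenic gaps wide enough to host planted lncRNAs; if they do not fit
#' an explicit packing error is raised.
#'
#' @param config A [sim_config()].
#' @return A `lnc_genome` list: `chromosomes` (named character vector),
#'   `genes` (tibble: `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `exons` list-column, `sequence`), `config`.
#' @export
generate_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"))
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chroms <- setNames(
    vapply(chrom_names, function(x) random_dna(config$chromosome_length),
           character(1)),
    chrom_names
  )

  genes <- empty_gene_tbl()
  if (config$n_coding_genes > 0) {
    per_chrom <- table(factor(
      rep(chrom_names, length.out = config$n_coding_genes),
      levels = chrom_names
    ))
    gene_idx <- 0L
    rows <- list()
    for (cn in chrom_names) {
      cursor <- sample(2000:6000, 1)
      for (g in seq_len(per_chrom[[cn]])) {
        gene_idx <- gene_idx + 1L
        model <- random_gene_model()
        span <- sum(nchar(model$chunks)) + sum(model$introns)
        if (cursor + span > config$chromosome_length - 2000) {
          abort(
            sprintf("infeasible packing: gene %d does not fit on %s.",
                    gene_idx, cn),
            class = "lncorange_packing_error"
          )
        }
        placed <- place_gene(chroms[[cn]], cursor, model)
        chroms[[cn]] <- placed$chrom_seq
        rows[[gene_idx]] <- tibble::tibble(
          gene_id = sprintf("GENE%04d", gene_idx),
          transcript_id = sprintf("GENE%04d.1", gene_idx),
          chrom = cn,
          strand = model$strand,
          start = placed$exons$start[1],
          end = placed$exons$end[nrow(placed$exons)],
          exons = list(placed$exons),
          sequence = model$mrna
        )
        cursor <- placed$exons$end[nrow(placed$exons)] +
          sample(3000:9000, 1)
      }
    }
    genes <- purrr::list_rbind(rows)
  }

  structure(
    list(chromosomes = chroms, genes = genes, config = config),
    class = "lnc_genome"
  )
}

empty_gene_tbl <- function() {
  tibble::tibble(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    exons = list(), sequence = character()
  )
}

# mRNA (UTR5 + ORF >= 100 codons + UTR3), split into exon chunks with
# intron lengths; strand chosen at random.
random_gene_model <- function() {
  n_codons <- sample(100:400, 1)
  utr5 <- random_dna(sample(20:80, 1))
  utr3 <- random_dna(sample(40:150, 1))
  cds <- paste0(
    "ATG",
    paste(sample(SENSE_CODONS, n_codons - 1, replace = TRUE), collapse = ""),
    sample(STOP_CODONS, 1)
  )
  mrna <- paste0(utr5, cds, utr3)
  n_exons <- sample(1:12, 1,
                    prob = c(0.24, 0.2, 0.15, 0.11, 0.08, 0.06, 0.05,
                             0.04, 0.03, 0.02, 0.01, 0.01))
  n_exons <- min(n_exons, max(1L, nchar(mrna) %/% 60L))
  chunks <- split_sequence(mrna, n_exons, min_chunk = 30L)
  introns <- if (n_exons > 1) sample(300:2500, n_exons - 1, replace = TRUE)
             else integer()
  list(mrna = mrna, chunks = chunks, introns = introns,
       strand = sample(c("+", "-"), 1))
}

# Split a sequence into n contiguous chunks, each >= min_chunk nt.
split_sequence <- function(seq, n, min_chunk = 30L) {
  len <- nchar(seq)
  if (n == 1) return(seq)
  slack <- len - n * min_chunk
  cuts <- sort(sample(0:slack, n - 1, replace = TRUE))
  sizes <- diff(c(0, cuts + min_chunk * seq_len(n - 1), len))
  substring(seq, cumsum(c(1, head(sizes, -1))),
            cumsum(sizes))
}

# Write a gene's exon chunks into the chromosome starting at `cursor`.
# For minus-strand genes the genomic exon in ascending order j carries the
# reverse complement of mRNA chunk (n - j + 1), so splicing (descending
# order, reverse complemented) reconstructs the mRNA.
place_gene <- function(chrom_seq, cursor, model) {
  n_exons <- length(model$chunks)
  widths <- nchar(model$chunks)
  genomic_chunks <- if (model$strand == "+") model$chunks
                    else rev(revcomp(model$chunks))
  genomic_widths <- nchar(genomic_chunks)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- cursor
  for (j in seq_len(n_exons)) {
    starts[j] <- pos
    ends[j] <- pos + genomic_widths[j] - 1L
    chrom_seq <- write_genome(chrom_seq, pos, genomic_chunks[j])
    pos <- ends[j] + 1L
    if (j < n_exons) pos <- pos + model$introns[j]
  }
  list(chrom_seq = chrom_seq, exons = exon_tbl(starts, ends))
}

#' @export
print.lnc_genome <- function(x, ...) {
  cat(sprintf("<lnc_genome> %d chromosome(s), %d coding gene(s)\n",
              length(x$chromosomes), nrow(x$genes)))
  invisible(x)
}
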