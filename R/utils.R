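# Shared sequence helpers. All sequences are plain uppercase character
# strings; DNA in genomic/transcript context, RNA inside the duplex logic.

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

# DNA -> RNA (and tolerate already-RNA input)
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Derive a per-stage RNG seed from the single global seed so each
# simulation stage has an independent, reproducible stream.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genome = 101L, lncrna = 211L, mirna = 307L, counts = 401L,
    decoy = 503L, screen = 601L
  )
  k <- offsets[[stage]]
  as.integer((as.double(seed) %% 1048576) * 1009 + k)
}

# Spliced transcript sequence from a chromosome string and an exon table
# (1-based closed genomic coordinates, exons sorted ascending).
spliced_sequence <- function(chrom_seq, exons, strand) {
  pieces <- substring(chrom_seq, exons$start, exons$end)
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

# Overwrite a genomic interval with new content (same length).
write_genome <- function(chrom_seq, start, content) {
  stopifnot(nchar(content) >= 1)
  substr(chrom_seq, start, start + nchar(content) - 1L) <- content
  chrom_seq
}

exon_tbl <- function(start, end) tibble::tibble(start = start, end = end)

transcript_length <- function(exons) {
  sum(exons$end - exons$start + 1L)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
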