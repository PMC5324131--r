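#' Six-frame open-reading-frame scan
#'
#' Finds the longest ORF over all six reading frames (three frames on each
#' strand). An ORF is an ATG followed by in-frame sense codons up to an
#' in-frame stop; its amino-acid length includes the initial Met and
#' excludes the stop. ORFs running off the end of the sequence without a
#' stop are ignored, and any codon containing an N breaks an ORF (N codons
#' are treated as non-coding).
#'
#' The lncRNA criterion downstream is that the longest ORF be *smaller*
#' than 100 amino acids, scanned on both strands.
#'
#' @param sequence A single DNA string over A/C/G/T/N (U tolerated).
#' @return A one-row tibble with `longest_orf_aa` and `orf_strand`
#'   (`"+"`/`"-"`; `"+"` when both strands tie, including the no-ORF case).
#' @examples
#' scan_orfs("CCCATGAAATAACCC")   # 2-aa ORF: Met-Lys
#' @export
scan_orfs <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  seq <- as_dna(sequence)
  if (grepl("[^ACGTN]", seq)) {
    abort("`sequence` may contain only A/C/G/T/N (or U).")
  }
  fwd <- longest_orf_one_strand(seq)
  rev <- longest_orf_one_strand(revcomp(seq))
  tibble::tibble(
    longest_orf_aa = max(fwd, rev),
    orf_strand = if (rev > fwd) "-" else "+"
  )
}

# Longest ORF (in codons, stop excluded) over the 3 frames of one strand.
longest_orf_one_strand <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 2) next
    starts <- frame + seq_len(n_codons) * 3L - 2L
    codons <- substring(seq, starts, starts + 2L)
    best <- max(best, longest_orf_codons(codons))
  }
  best
}

# Single left-to-right pass: track the earliest ATG since the last
# barrier (stop codon or N-containing codon); close it at each stop.
longest_orf_codons <- function(codons) {
  is_stop <- codons %in% STOP_CODONS
  has_n <- grepl("N", codons, fixed = TRUE)
  is_start <- codons == "ATG"
  best <- 0L
  cur_atg <- NA_integer_
  for (i in seq_along(codons)) {
    if (has_n[i]) {
      cur_atg <- NA_integer_
    } else if (is_stop[i]) {
      if (!is.na(cur_atg)) best <- max(best, i - cur_atg)
      cur_atg <- NA_integer_
    } else if (is.na(cur_atg) && is_start[i]) {
      cur_atg <- i
    }
  }
  best
}

#' ORF length filter for lncRNA candidates
#'
#' @param longest_orf_aa Longest six-frame ORF length(s), in amino acids.
#' @param max_aa Candidates pass while strictly below this bound
#'   (default 100).
#' @return Logical vector: `TRUE` when the transcript passes.
#' @export
orf_filter <- function(longest_orf_aa, max_aa = 100) {
  longest_orf_aa < max_aa
}
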