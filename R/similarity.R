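#' Similarity screen against an exclusion set
#'
#' Screens query transcripts against a FASTA-style exclusion set (known
#' coding transcripts, housekeeping ncRNAs, or miRNA precursors). Candidate
#' pairs are seeded by shared k-mers and then aligned locally
#' (Smith-Waterman via [Biostrings::pairwiseAlignment()]) with match +1,
#' mismatch -2, gap open -5, gap extend -2. A query is *matched* (and hence
#' excluded downstream) when its best alignment reaches both thresholds:
#' identity strictly greater than `min_identity` over the aligned columns
#' and query coverage strictly greater than `min_coverage`.
#'
#' Defaults follow the coding-gene screen (identity > 90%, coverage > 80%);
#' the housekeeping and miRNA-precursor screens use coverage > 50%.
#'
#' @param queries Named character vector of query sequences, or a tibble
#'   with `transcript_id` and `sequence`.
#' @param exclusion_set Named character vector of exclusion sequences
#'   (must be non-empty).
#' @param min_identity,min_coverage Strict lower thresholds on identity and
#'   query coverage.
#' @param seed_k Word size of the k-mer seeding prefilter; pairs sharing no
#'   `seed_k`-mer are not aligned.
#' @return Tibble: `transcript_id`, `matched`, `best_entry`, `identity`,
#'   `coverage` (NA identity/coverage when nothing was aligned).
#' @export
similarity_screen <- function(queries, exclusion_set,
                              min_identity = 0.9, min_coverage = 0.8,
                              seed_k = 11L) {
  if (is.data.frame(queries)) {
    queries <- setNames(queries$sequence, queries$transcript_id)
  }
  if (length(exclusion_set) == 0) {
    abort("`exclusion_set` must be non-empty.", class = "lncorange_config_error")
  }
  if (is.null(names(exclusion_set))) {
    names(exclusion_set) <- paste0("excl_", seq_along(exclusion_set))
  }
  queries <- as_dna(queries)
  exclusion_set <- as_dna(exclusion_set)
  subj_kmers <- lapply(exclusion_set, seq_kmers, k = seed_k)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE
  )
  res <- purrr::imap(queries, function(q, qid) {
    qk <- seq_kmers(q, seed_k)
    cand <- names(exclusion_set)[vapply(subj_kmers, function(sk) {
      any(qk %in% sk)
    }, logical(1))]
    best <- list(matched = FALSE, best_entry = NA_character_,
                 identity = NA_real_, coverage = NA_real_)
    for (sid in cand) {
      m <- align_local(q, exclusion_set[[sid]], submat)
      score_now <- if (is.na(best$identity)) -Inf else {
        min(best$identity / min_identity, best$coverage / min_coverage)
      }
      score_new <- min(m$identity / min_identity, m$coverage / min_coverage)
      if (score_new > score_now) {
        best$best_entry <- sid
        best$identity <- m$identity
        best$coverage <- m$coverage
      }
      if (m$identity > min_identity && m$coverage > min_coverage) {
        best$matched <- TRUE
      }
    }
    tibble::tibble(transcript_id = qid, matched = best$matched,
                   best_entry = best$best_entry,
                   identity = best$identity, coverage = best$coverage)
  })
  purrr::list_rbind(res)
}

seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, 1:(n - k + 1), k:n))
}

# One local alignment; identity over aligned columns (gaps included),
# coverage = aligned query span / query length.
align_local <- function(query, subject, submat) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
  )
  aln_len <- Biostrings::nchar(pa)
  qr <- pa@pattern@range
  list(
    identity = if (aln_len > 0) Biostrings::nmatch(pa) / aln_len else 0,
    coverage = IRanges::width(qr) / nchar(query)
  )
}
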