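#' Train the surrogate coding-potential model
#'
#' The pipeline's built-in stand-in for external coding-potential tools is a
#' two-term score: an ORF-length term and a hexamer log-odds term. The
#' hexamer component is trained here from the coding transcripts of the
#' annotation: hexamer frequencies (with add-one smoothing) are contrasted
#' against a background in which each hexamer's probability is the product
#' of the mononucleotide frequencies of the same training set. The
#' background is thus analytic and the model fully deterministic.
#'
#' @param coding_seqs Character vector of coding transcript (mRNA or CDS)
#'   sequences.
#' @return A `hexamer_model` list with `log_odds` (named, 4096 hexamers).
#' @export
train_hexamer_model <- function(coding_seqs) {
  coding_seqs <- coding_seqs[nchar(coding_seqs) >= 6]
  if (length(coding_seqs) == 0) {
    abort("need at least one coding sequence of length >= 6.")
  }
  dss <- Biostrings::DNAStringSet(as_dna(coding_seqs))
  hex <- colSums(Biostrings::oligonucleotideFrequency(dss, width = 6))
  p_cod <- (hex + 1) / sum(hex + 1)
  base <- colSums(Biostrings::alphabetFrequency(dss)[, DNA_BASES, drop = FALSE])
  p_base <- (base + 1) / sum(base + 1)
  hex_chars <- strsplit(names(p_cod), "", fixed = TRUE)
  p_bg <- vapply(hex_chars, function(ch) prod(p_base[ch]), numeric(1))
  structure(list(log_odds = log(p_cod) - log(p_bg)), class = "hexamer_model")
}

#' Hexamer log-odds score of a sequence
#'
#' Mean log-odds (coding vs mononucleotide background) over all overlapping
#' hexamers. Positive values indicate coding-like hexamer composition.
#'
#' @param sequence Character vector of DNA sequences.
#' @param model A `hexamer_model` from [train_hexamer_model()].
#' @return Numeric vector of scores (0 for sequences shorter than 6 nt).
#' @export
hexamer_score <- function(sequence, model) {
  stopifnot(inherits(model, "hexamer_model"))
  dss <- Biostrings::DNAStringSet(as_dna(sequence))
  freq <- Biostrings::oligonucleotideFrequency(dss, width = 6)
  tot <- rowSums(freq)
  score <- as.numeric(freq %*% model$log_odds)
  ifelse(tot > 0, score / tot, 0)
}

#' Surrogate coding-potential score
#'
#' `w1 * (longest_orf_aa / 100 - 1) + w2 * hexamer_score`. Transcripts with
#' score > 0 are treated as coding, mirroring the "score > 0 discards"
#' convention of external coding-potential calculators. The surrogate is a
#' declared scheme of this package, not a reimplementation of any external
#' tool.
#'
#' @param longest_orf_aa Longest six-frame ORF length(s) in amino acids.
#' @param hex_score Hexamer log-odds score(s) from [hexamer_score()].
#' @param w1,w2 Term weights (defaults 1 and 1).
#' @return Numeric score vector.
#' @export
surrogate_coding_score <- function(longest_orf_aa, hex_score, w1 = 1, w2 = 1) {
  w1 * (longest_orf_aa / 100 - 1) + w2 * hex_score
}

#' Coding-evidence table for a set of transcripts
#'
#' @param transcripts Tibble with `transcript_id` and `sequence` columns.
#' @param model Optional `hexamer_model`; when supplied the surrogate score
#'   is computed, otherwise only ORF evidence is returned.
#' @return Tibble: `transcript_id`, `longest_orf_aa`, `orf_strand`,
#'   `hexamer_score`, `surrogate_coding_score`.
#' @export
coding_evidence <- function(transcripts, model = NULL) {
  orf <- purrr::map(transcripts$sequence, scan_orfs) |> purrr::list_rbind()
  out <- tibble::tibble(
    transcript_id = transcripts$transcript_id,
    longest_orf_aa = orf$longest_orf_aa,
    orf_strand = orf$orf_strand
  )
  if (!is.null(model)) {
    out$hexamer_score <- hexamer_score(transcripts$sequence, model)
    out$surrogate_coding_score <-
      surrogate_coding_score(out$longest_orf_aa, out$hexamer_score)
  }
  out
}

#' Coding-potential filter
#'
#' Discards transcripts whose coding-potential score is strictly positive.
#' If externally computed scores are injected (e.g. from CPC/PLEK/CNCI-like
#' tools), a transcript is discarded when *any* injected score exceeds 0;
#' otherwise the built-in surrogate score decides.
#'
#' @param evidence Tibble from [coding_evidence()] (must carry
#'   `surrogate_coding_score` unless scores are injected for every
#'   transcript).
#' @param injected_scores Optional tibble `(transcript_id, tool, score)`.
#' @param threshold Scores strictly above this are discarded (default 0).
#' @return Tibble `(transcript_id, pass, decisive_score)`.
#' @export
coding_potential_filter <- function(evidence, injected_scores = NULL,
                                    threshold = 0) {
  if (!is.null(injected_scores)) {
    inj <- injected_scores |>
      group_by(.data$transcript_id) |>
      summarise(decisive_score = max(.data$score), .groups = "drop")
  } else {
    inj <- tibble::tibble(transcript_id = character(),
                          decisive_score = numeric())
  }
  out <- evidence |>
    select("transcript_id",
           surrogate = dplyr::any_of("surrogate_coding_score")) |>
    left_join(inj, by = "transcript_id")
  has_inj <- !is.na(out$decisive_score)
  if (!all(has_inj) && is.null(out$surrogate)) {
    abort("no surrogate score available and injected scores do not cover all transcripts.")
  }
  if (is.null(out$surrogate)) out$surrogate <- NA_real_
  out$decisive_score <- ifelse(has_inj, out$decisive_score, out$surrogate)
  tibble::tibble(
    transcript_id = out$transcript_id,
    pass = out$decisive_score <= threshold,
    decisive_score = out$decisive_score
  )
}
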