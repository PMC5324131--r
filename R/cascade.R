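#' Transcript length filter
#'
#' lncRNA candidates must be longer than 200 nt (strict inequality; a
#' 200-nt transcript fails).
#'
#' @param length Spliced transcript length(s) in nt.
#' @param min_nt Strict lower bound (default 200).
#' @return Logical vector, `TRUE` = pass.
#' @export
length_filter <- function(length, min_nt = 200) {
  length > min_nt
}

#' Presence-in-both-genotypes filter
#'
#' The candidate must "appear" in both MT and WT, operationalized as
#' FPKM >= `min_fpkm` in at least one replicate of *each* genotype. Guards
#' against transcripts that reflect genotype-specific artifacts (e.g.
#' genomic DNA contamination of one library).
#'
#' @param transcript_ids Ids to test.
#' @param counts A `lnc_counts`-style object (see [fpkm_table()]).
#' @param min_fpkm Presence threshold (default 1; boundary inclusive).
#' @return Tibble `(transcript_id, pass)`.
#' @export
both_genotype_filter <- function(transcript_ids, counts, min_fpkm = 1) {
  fpkm <- fpkm_table(counts)
  missing <- setdiff(transcript_ids, fpkm$transcript_id)
  if (length(missing) > 0) {
    abort(sprintf("transcripts absent from the expression matrix: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  fpkm |>
    filter(.data$transcript_id %in% transcript_ids) |>
    group_by(.data$transcript_id) |>
    summarise(
      pass = any(.data$fpkm[.data$genotype == "MT"] >= min_fpkm) &&
        any(.data$fpkm[.data$genotype == "WT"] >= min_fpkm),
      .groups = "drop"
    ) |>
    (\(d) d[match(transcript_ids, d$transcript_id), ])()
}

#' Cascade parameters
#'
#' Thresholds and switches for [run_cascade()]. Boundary semantics follow
#' the strict readings: length > 200 nt, ORF < 100 aa, coding-potential
#' score > 0 discards, FPKM >= 1 counts as present.
#'
#' @param min_length,max_orf_aa,min_fpkm_present Core thresholds.
#' @param coding_identity,coding_coverage Similarity thresholds for the
#'   coding-gene and known-protein screens (strict >).
#' @param ncrna_identity,ncrna_coverage Similarity thresholds for the
#'   housekeeping and miRNA-precursor screens (strict >).
#' @param score_threshold Coding-potential discard bound (strict >).
#' @param seed_k k-mer word size for similarity seeding.
#' @param enabled Character vector of stages to run (default all, in the
#'   pipeline's fixed order).
#' @return A `cascade_params` list.
#' @export
cascade_params <- function(min_length = 200, max_orf_aa = 100,
                           min_fpkm_present = 1,
                           coding_identity = 0.9, coding_coverage = 0.8,
                           ncrna_identity = 0.9, ncrna_coverage = 0.5,
                           score_threshold = 0, seed_k = 11L,
                           enabled = CASCADE_STAGES) {
  structure(
    list(min_length = min_length, max_orf_aa = max_orf_aa,
         min_fpkm_present = min_fpkm_present,
         coding_identity = coding_identity,
         coding_coverage = coding_coverage,
         ncrna_identity = ncrna_identity, ncrna_coverage = ncrna_coverage,
         score_threshold = score_threshold, seed_k = as.integer(seed_k),
         enabled = enabled),
    class = "cascade_params"
  )
}

CASCADE_STAGES <- c("coding_similarity", "length", "orf", "known_protein",
                    "coding_potential", "both_genotypes", "housekeeping",
                    "mirna_precursor")

#' Run the lncRNA identification cascade
#'
#' Applies the sequential filters that turn assembled transcripts into
#' putative lncRNAs, in this fixed order: (1) similarity screen against
#' known coding transcripts; (2) length > 200 nt; (3) longest six-frame
#' ORF < 100 aa; (4) similarity screen against known proteins' transcripts
#' (domain-bearing set) or injected domain hits; (5) coding-potential
#' filter (injected scores or the built-in surrogate); (6) presence in
#' both genotypes; (7) housekeeping-ncRNA screen; (8) miRNA-precursor
#' screen. Each stage only sees the survivors of the previous one, so the
#' funnel is monotone by construction.
#'
#' @param transcripts Tibble with `transcript_id` and `sequence` (other
#'   columns are carried through to the survivors).
#' @param counts Expression set (see [fpkm_table()]); required while the
#'   `both_genotypes` stage is enabled.
#' @param exclusion_sets Named list of named character vectors: `coding`
#'   (required for stage 1), optional `protein` (defaults to `coding`),
#'   `housekeeping`, `mirna_precursor`. Screens whose set is absent are
#'   recorded as pass-through.
#' @param params A [cascade_params()].
#' @param hexamer_model Optional pre-trained [train_hexamer_model()];
#'   trained from `exclusion_sets$coding` when absent.
#' @param injected_scores Optional tibble `(transcript_id, tool, score)` of
#'   externally computed coding-potential scores (CPC/PLEK/CNCI-style; any
#'   score > 0 discards).
#' @param injected_domain_hits Optional tibble `(transcript_id, evalue)`;
#'   transcripts with `evalue < 0.001` are discarded at the known-protein
#'   stage in addition to the similarity screen.
#' @return A `lnc_cascade` list: `survivors` (tibble of surviving
#'   transcripts), `report` (stage, n_in, n_out), `detail` (per transcript:
#'   pass/fail with the first failing stage as reason code), `params`.
#' @export
run_cascade <- function(transcripts, counts = NULL, exclusion_sets = list(),
                        params = cascade_params(), hexamer_model = NULL,
                        injected_scores = NULL,
                        injected_domain_hits = NULL) {
  stopifnot(is.data.frame(transcripts))
  ids_all <- transcripts$transcript_id
  if (anyDuplicated(ids_all)) abort("duplicated transcript ids.")
  if (is.null(hexamer_model) && length(exclusion_sets$coding) > 0) {
    hexamer_model <- train_hexamer_model(exclusion_sets$coding)
  }
  alive <- transcripts
  report <- list()
  fail_tbl <- tibble::tibble(transcript_id = character(), stage = character())

  apply_stage <- function(stage, pass) {
    n_in <- nrow(alive)
    failed <- alive$transcript_id[!pass]
    if (length(failed) > 0) {
      fail_tbl <<- bind_rows(fail_tbl, tibble::tibble(
        transcript_id = failed, stage = stage
      ))
    }
    alive <<- alive[pass, , drop = FALSE]
    report[[stage]] <<- tibble::tibble(stage = stage, n_in = n_in,
                                       n_out = nrow(alive))
  }

  for (stage in params$enabled) {
    if (nrow(alive) == 0) {
      apply_stage(stage, logical(0))
      next
    }
    pass <- switch(stage,
      coding_similarity = {
        if (length(exclusion_sets$coding) == 0) rep(TRUE, nrow(alive))
        else !similarity_screen(alive, exclusion_sets$coding,
                                params$coding_identity,
                                params$coding_coverage,
                                params$seed_k)$matched
      },
      length = length_filter(nchar(alive$sequence), params$min_length),
      orf = {
        aa <- vapply(alive$sequence,
                     function(s) scan_orfs(s)$longest_orf_aa, numeric(1))
        orf_filter(aa, params$max_orf_aa)
      },
      known_protein = {
        set <- exclusion_sets$protein %||% exclusion_sets$coding
        p <- if (length(set) == 0) rep(TRUE, nrow(alive))
             else !similarity_screen(alive, set, params$coding_identity,
                                     params$coding_coverage,
                                     params$seed_k)$matched
        if (!is.null(injected_domain_hits)) {
          hit <- alive$transcript_id %in%
            injected_domain_hits$transcript_id[
              injected_domain_hits$evalue < 0.001]
          p <- p & !hit
        }
        p
      },
      coding_potential = {
        ev <- coding_evidence(alive, hexamer_model)
        coding_potential_filter(ev, injected_scores,
                                params$score_threshold)$pass
      },
      both_genotypes = {
        if (is.null(counts)) abort("`counts` required for the both_genotypes stage.")
        both_genotype_filter(alive$transcript_id, counts,
                             params$min_fpkm_present)$pass
      },
      housekeeping = {
        if (length(exclusion_sets$housekeeping) == 0) rep(TRUE, nrow(alive))
        else !similarity_screen(alive, exclusion_sets$housekeeping,
                                params$ncrna_identity,
                                params$ncrna_coverage,
                                params$seed_k)$matched
      },
      mirna_precursor = {
        if (length(exclusion_sets$mirna_precursor) == 0) rep(TRUE, nrow(alive))
        else !similarity_screen(alive, exclusion_sets$mirna_precursor,
                                params$ncrna_identity,
                                params$ncrna_coverage,
                                params$seed_k)$matched
      },
      abort(sprintf("unknown cascade stage `%s`.", stage))
    )
    apply_stage(stage, pass)
  }

  detail <- tibble::tibble(transcript_id = ids_all) |>
    left_join(fail_tbl, by = "transcript_id") |>
    mutate(pass = is.na(.data$stage),
           reason = if_else(is.na(.data$stage), "lncrna_candidate",
                            paste0("failed_", .data$stage))) |>
    select("transcript_id", "pass", "reason")

  structure(
    list(survivors = alive, report = purrr::list_rbind(report),
         detail = detail, params = params),
    class = "lnc_cascade"
  )
}

#' @export
print.lnc_cascade <- function(x, ...) {
  cat("<lnc_cascade>\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}
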