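#' Target-site scoring parameters
#'
#' The declared surrogate penalty scheme for miRNA target prediction on
#' lncRNAs: mismatch 1.0, G:U wobble 0.5, indel 2.0 per position, with
#' positions 2-13 of the miRNA (5' numbering) doubled; a window is a hit
#' when its total penalty is at most `cutoff` (default 4.0). This scheme is
#' a documented convention of this package, not a reimplementation of any
#' external target-prediction tool.
#'
#' @param mismatch,wobble,indel Per-position costs.
#' @param core_start,core_end 1-based miRNA positions whose costs are
#'   multiplied by `core_mult`.
#' @param core_mult Core weighting factor.
#' @param cutoff Maximum penalty for a hit.
#' @return A `target_params` list.
#' @export
target_params <- function(mismatch = 1, wobble = 0.5, indel = 2,
                          core_start = 2L, core_end = 13L, core_mult = 2,
                          cutoff = 4) {
  structure(list(mismatch = mismatch, wobble = wobble, indel = indel,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end), core_mult = core_mult,
                 cutoff = cutoff),
            class = "target_params")
}

check_duplex_alphabet <- function(x, what) {
  if (any(grepl("[^ACGU]", as_rna(x)))) {
    abort(sprintf("%s may contain only A/C/G/U (or T).", what))
  }
}

#' Score one candidate target site
#'
#' Aligns a site window (given 5'->3' as it appears on the transcript)
#' against the miRNA read 5'->3' (so the site is reversed internally) and
#' returns the penalty under [target_params()]. Site length may differ
#' from the miRNA length by at most one; the best single-indel placement
#' is used for off-by-one lengths.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param site Site window, 5'->3'.
#' @param params A [target_params()].
#' @return The penalty (numeric scalar).
#' @examples
#' # a perfect reverse complement scores 0
#' score_target_site("UGACAGAAGAGAGUGAGCACA", "UGUGCUCACUCUCUUCUGUCA")
#' @export
score_target_site <- function(mirna, site, params = target_params()) {
  mirna <- as_rna(mirna)
  site <- as_rna(site)
  check_duplex_alphabet(c(mirna, site), "`mirna`/`site`")
  if (abs(nchar(site) - nchar(mirna)) > 1) {
    abort("site length must be within one of the miRNA length.")
  }
  cpp_score_site(mirna, site, params$mismatch, params$wobble, params$indel,
                 params$core_start, params$core_end, params$core_mult)
}

#' Find miRNA target sites on lncRNA transcripts
#'
#' Slides every miRNA over each transcript (and, for the antisense strand,
#' over its reverse complement), scoring windows of length L-1, L and L+1
#' under [target_params()]. Overlapping hits on the same transcript strand
#' are reduced greedily to the best-scoring, leftmost, non-overlapping set.
#' Antisense hits are reported in sense-transcript coordinates.
#'
#' @param mirnas Tibble `(mirna_id, sequence)` (RNA or DNA), or a named
#'   character vector.
#' @param transcripts Tibble `(transcript_id, sequence)` or a named
#'   character vector.
#' @param params A [target_params()].
#' @param strands Strands to scan: subset of `c("sense", "antisense")`.
#' @return A `lnc_hits` tibble: `mirna_id`, `transcript_id`, `start`,
#'   `end`, `strand`, `penalty`, `kind = "cleavage_target"`.
#' @export
find_target_sites <- function(mirnas, transcripts, params = target_params(),
                              strands = c("sense", "antisense")) {
  strands <- match.arg(strands, several.ok = TRUE)
  mirnas <- as_id_tbl(mirnas, "mirna_id")
  transcripts <- as_id_tbl(transcripts, "transcript_id")
  check_duplex_alphabet(mirnas$sequence, "`mirnas`")
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- as_rna(transcripts$sequence[ti])
    n <- nchar(tseq)
    tseq_as <- as_rna(revcomp(as_dna(tseq)))
    for (mi in seq_len(nrow(mirnas))) {
      mir <- as_rna(mirnas$sequence[mi])
      for (st in strands) {
        seq_scan <- if (st == "sense") tseq else tseq_as
        raw <- tibble::as_tibble(cpp_scan_targets(
          seq_scan, mir, params$mismatch, params$wobble, params$indel,
          params$core_start, params$core_end, params$core_mult,
          params$cutoff
        ))
        if (nrow(raw) == 0) next
        if (st == "antisense") {
          raw <- mutate(raw,
                        new_start = n - (.data$start + .data$width - 1L) + 1L,
                        start = .data$new_start) |> select(-"new_start")
        }
        raw <- mutate(raw, end = .data$start + .data$width - 1L)
        kept <- greedy_nonoverlap(raw)
        out[[length(out) + 1]] <- tibble::tibble(
          mirna_id = mirnas$mirna_id[mi],
          transcript_id = transcripts$transcript_id[ti],
          start = kept$start, end = kept$end, strand = st,
          penalty = kept$penalty, kind = "cleavage_target"
        )
      }
    }
  }
  hits <- if (length(out)) purrr::list_rbind(out) else tibble::tibble(
    mirna_id = character(), transcript_id = character(), start = integer(),
    end = integer(), strand = character(), penalty = numeric(),
    kind = character()
  )
  class(hits) <- c("lnc_hits", class(hits))
  hits
}

# best-score-first (ties: leftmost) selection of non-overlapping windows
greedy_nonoverlap <- function(tbl) {
  tbl <- arrange(tbl, .data$penalty, .data$start)
  kept <- logical(nrow(tbl))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    if (!any(occ_s <= tbl$end[i] & occ_e >= tbl$start[i])) {
      kept[i] <- TRUE
      occ_s <- c(occ_s, tbl$start[i]); occ_e <- c(occ_e, tbl$end[i])
    }
  }
  arrange(tbl[kept, ], .data$start)
}

as_id_tbl <- function(x, id_col) {
  if (is.data.frame(x)) return(x)
  tibble::tibble("{id_col}" := names(x), sequence = unname(x))
}

#' Detect endogenous target mimics (eTMs)
#'
#' Enumerates candidate sites of length `len(miRNA) + 3` on the sense
#' strand of each transcript (mimics act as transcripts; antisense search
#' available via `strands`) and evaluates the four eTM rules for each
#' allowed bulge placement (the 3-nt site insertion opposite the junction
#' between consecutive miRNA positions within 9-12, i.e. junctions 9/10,
#' 10/11 and 11/12, numbered from the miRNA 5' end):
#' 1. the bulge is only permitted there (single central bulge);
#' 2. the bulge is exactly 3 nt;
#' 3. miRNA positions 2-8 are perfectly Watson-Crick paired (G:U does not
#'    count as paired);
#' 4. outside the bulge, mismatches plus G:U pairs total at most
#'    `max_edits` (default 3) over all paired positions.
#'
#' @inheritParams find_target_sites
#' @param max_edits Rule-4 budget.
#' @param strands Strand(s) to scan; default sense only.
#' @return A `lnc_hits` tibble: `mirna_id`, `transcript_id`, `start`,
#'   `end`, `strand`, `junction`, `bulge_start`, `bulge_end`, `n_edits`,
#'   `n_gu`, `n_mismatch`, per-rule logical columns `rule1_single_bulge`,
#'   `rule2_bulge_3nt`, `rule3_seed_paired`, `rule4_edit_budget`, and
#'   `kind = "etm"`.
#' @export
detect_target_mimics <- function(mirnas, transcripts, max_edits = 3L,
                                 strands = "sense") {
  strands <- match.arg(strands, c("sense", "antisense"), several.ok = TRUE)
  mirnas <- as_id_tbl(mirnas, "mirna_id")
  transcripts <- as_id_tbl(transcripts, "transcript_id")
  check_duplex_alphabet(mirnas$sequence, "`mirnas`")
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- as_rna(transcripts$sequence[ti])
    n <- nchar(tseq)
    for (mi in seq_len(nrow(mirnas))) {
      mir <- as_rna(mirnas$sequence[mi])
      L <- nchar(mir)
      for (st in strands) {
        seq_scan <- if (st == "sense") tseq
                    else as_rna(revcomp(as_dna(tseq)))
        raw <- tibble::as_tibble(cpp_scan_etm(seq_scan, mir,
                                              as.integer(max_edits)))
        if (nrow(raw) == 0) next
        w <- L + 3L
        if (st == "antisense") {
          raw$start <- n - (raw$start + w - 1L) + 1L
        }
        out[[length(out) + 1]] <- tibble::tibble(
          mirna_id = mirnas$mirna_id[mi],
          transcript_id = transcripts$transcript_id[ti],
          start = raw$start, end = raw$start + w - 1L, strand = st,
          junction = raw$junction,
          bulge_start = raw$start + (L + 1L - raw$junction) - 1L,
          bulge_end = raw$start + (L + 3L - raw$junction) - 1L,
          n_edits = raw$n_edits, n_gu = raw$n_gu,
          n_mismatch = raw$n_mismatch,
          rule1_single_bulge = TRUE,
          rule2_bulge_3nt = TRUE,
          rule3_seed_paired = TRUE,
          rule4_edit_budget = raw$n_edits <= max_edits,
          kind = "etm"
        )
      }
    }
  }
  hits <- if (length(out)) purrr::list_rbind(out) else tibble::tibble(
    mirna_id = character(), transcript_id = character(), start = integer(),
    end = integer(), strand = character(), junction = integer(),
    bulge_start = integer(), bulge_end = integer(), n_edits = integer(),
    n_gu = integer(), n_mismatch = integer(),
    rule1_single_bulge = logical(), rule2_bulge_3nt = logical(),
    rule3_seed_paired = logical(), rule4_edit_budget = logical(),
    kind = character()
  )
  class(hits) <- c("lnc_hits", class(hits))
  hits
}

#' Predict miRNA-lncRNA interactions (targets and mimics)
#'
#' @inheritParams find_target_sites
#' @param mode `"both"`, `"targets"` or `"mimics"`.
#' @param max_edits eTM rule-4 budget.
#' @return Combined `lnc_hits` tibble.
#' @export
predict_mirna_interactions <- function(mirnas, transcripts,
                                       mode = c("both", "targets", "mimics"),
                                       params = target_params(),
                                       max_edits = 3L) {
  mode <- match.arg(mode)
  pieces <- list()
  if (mode %in% c("both", "targets")) {
    pieces$targets <- find_target_sites(mirnas, transcripts, params)
  }
  if (mode %in% c("both", "mimics")) {
    pieces$mimics <- detect_target_mimics(mirnas, transcripts, max_edits)
  }
  hits <- bind_rows(pieces)
  class(hits) <- unique(c("lnc_hits", class(hits)))
  hits
}

#' Render a miRNA/site duplex as aligned text
#'
#' Three rows: the site read 3'->5' (top), a pairing row (`|` Watson-Crick,
#' `o` G:U wobble, space mismatch), and the miRNA 5'->3' (bottom). eTM
#' bulges appear as a 3-nt insertion over gap dashes in the miRNA row.
#'
#' @param mirna,site Sequences (site 5'->3' as on the transcript).
#' @param junction For eTM sites, the bulge junction (9-11); NA for
#'   target sites of equal length.
#' @return Character vector of three lines.
#' @export
render_duplex <- function(mirna, site, junction = NA) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  r <- rev(strsplit(as_rna(site), "")[[1]])
  L <- length(m)
  if (!is.na(junction)) {
    stopifnot(length(r) == L + 3)
    top <- r
    bottom <- c(m[seq_len(junction)], rep("-", 3), m[(junction + 1):L])
    mir_at <- c(seq_len(junction), rep(NA, 3), (junction + 1):L)
  } else {
    stopifnot(length(r) == L)
    top <- r
    bottom <- m
    mir_at <- seq_len(L)
  }
  bond <- vapply(seq_along(top), function(i) {
    if (is.na(mir_at[i])) return(" ")
    pc <- pair_symbol(m[mir_at[i]], top[i])
    pc
  }, character(1))
  c(paste0("site 3'-", paste(top, collapse = ""), "-5'"),
    paste0("        ", paste(bond, collapse = ""), "   "),
    paste0("miR  5'-", paste(bottom, collapse = ""), "-3'"))
}

pair_symbol <- function(m, s) {
  wc <- rna_complement(m)
  if (s == wc) return("|")
  if ((m == "G" && s == "U") || (m == "U" && s == "G")) return("o")
  " "
}

#' Regional-amplification PCR cleavage-consistency ratio
#'
#' In RA-PCR, poly(T)-primed reverse transcription copies only the 3' side
#' of a miRNA-cleaved transcript, so an excess of 3'-region product over
#' the 5' and middle regions indicates cleavage. The ratio is
#' `abundance_3prime / max(abundance_5prime, abundance_middle)`; the site
#' is called cleavage-consistent when the ratio reaches `threshold`.
#'
#' @param five_prime,middle,three_prime Relative abundances (> 0).
#' @param threshold Consistency threshold (default 2).
#' @return Tibble `(ratio, cleavage_consistent)`.
#' @examples
#' ra_pcr_ratio(1, 1, 6.5)   # ratio 6.5, consistent
#' @export
ra_pcr_ratio <- function(five_prime, middle, three_prime, threshold = 2) {
  if (any(c(five_prime, middle, three_prime) <= 0)) {
    abort("all abundances must be > 0.")
  }
  ratio <- three_prime / pmax(five_prime, middle)
  tibble::tibble(ratio = ratio, cleavage_consistent = ratio >= threshold)
}
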