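rna_complement <- function(x) chartr("ACGU", "UGCA", x)

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Plant miRNA target and eTM sites into the simulated transcripts
#'
#' Generates mature miRNAs (19-24 nt) and edits lncRNA transcript
#' sequences so that planted sites exist with known coordinates:
#' cleavage-target sites are exact reverse complements of the miRNA
#' (penalty 0 for the downstream target scorer), and eTM sites are reverse
#' complements carrying exactly one 3-nt bulge opposite a junction between
#' consecutive miRNA positions within 9-12 plus 0-2 mismatch/G:U edits
#' outside the seed (miRNA positions 2-8 stay perfectly paired). Edits are
#' written through to the genome, so transcript sequences stay equal to
#' their spliced genomic sequence; consequently sites are only planted into
#' intergenic and intragenic lncRNAs, whose genomic footprint is free
#' sequence. Each planted site is re-validated against the cascade's
#' ORF/surrogate checks.
#'
#' @param sim A `lnc_sim` from [plant_lncrnas()].
#' @param config The same [sim_config()].
#' @return `sim` with `mirnas` (tibble: `mirna_id`, `sequence` in RNA
#'   alphabet) and `truth_sites` (tibble: `site_id`, `kind`, `mirna_id`,
#'   `transcript_id`, `start`, `end`, `junction`, `bulge_start`,
#'   `bulge_end`) added, and transcript/genome sequences updated.
#' @export
plant_mirna_sites <- function(sim, config) {
  stopifnot(inherits(sim, "lnc_sim"))
  config <- validate_sim_config(config)
  set.seed(stage_seed(config$seed, "mirna"))
  mirnas <- tibble::tibble(
    mirna_id = sprintf("miR%03d", seq_len(config$n_mirnas)),
    sequence = vapply(seq_len(config$n_mirnas),
                      function(i) random_rna(sample(19:24, 1)), character(1))
  )
  sim$mirnas <- mirnas
  sim$truth_sites <- tibble::tibble(
    site_id = character(), kind = character(), mirna_id = character(),
    transcript_id = character(), start = integer(), end = integer(),
    junction = integer(), bulge_start = integer(), bulge_end = integer()
  )
  n_sites <- config$n_planted_target_sites + config$n_planted_etm_sites
  if (n_sites == 0 || config$n_mirnas == 0) return(sim)

  max_len <- max(nchar(mirnas$sequence)) + 3L
  eligible <- sim$truth$transcript_id[
    sim$truth$category == "lncrna" &
      sim$truth$positional_class %in% c("intergenic", "intragenic")
  ]
  lens <- setNames(nchar(sim$transcripts$sequence),
                   sim$transcripts$transcript_id)
  eligible <- eligible[lens[eligible] >= max_len + 10L]
  if (length(eligible) < n_sites) {
    abort("not enough eligible lncRNAs to host the requested planted sites.")
  }
  hosts <- sample(eligible, n_sites)
  kinds <- rep(c("cleavage_target", "etm"),
               c(config$n_planted_target_sites, config$n_planted_etm_sites))

  for (i in seq_len(n_sites)) {
    mi <- sample.int(nrow(mirnas), 1)
    mir <- mirnas$sequence[mi]
    if (kinds[i] == "cleavage_target") {
      site <- revcomp(as_dna(mir))
      meta <- list(junction = NA_integer_, bulge_off = NA_integer_)
    } else {
      junction <- sample(9:11, 1)
      built <- make_etm_site(mir, junction, n_edits = sample(0:2, 1))
      site <- as_dna(built$site)
      meta <- list(junction = junction, bulge_off = built$bulge_offset)
    }
    planted <- plant_site_in_transcript(sim, hosts[i], site)
    sim <- planted$sim
    sim$truth_sites <- bind_rows(sim$truth_sites, tibble::tibble(
      site_id = sprintf("site%03d", i),
      kind = kinds[i],
      mirna_id = mirnas$mirna_id[mi],
      transcript_id = hosts[i],
      start = planted$start,
      end = planted$start + nchar(site) - 1L,
      junction = meta$junction,
      bulge_start = if (is.na(meta$bulge_off)) NA_integer_ else
        planted$start + meta$bulge_off - 1L,
      bulge_end = if (is.na(meta$bulge_off)) NA_integer_ else
        planted$start + meta$bulge_off + 1L
    ))
  }
  sim
}

# Build an eTM site (RNA, 5'->3') for a miRNA with the 3-nt bulge opposite
# the junction between miRNA positions `junction` and `junction + 1`
# (junction in 9..11) and `n_edits` mismatch/G:U edits outside the seed.
# Returns the site and the 1-based offset of the bulge within the site.
make_etm_site <- function(mirna, junction, n_edits = 0) {
  m <- strsplit(as_rna(mirna), "", fixed = TRUE)[[1]]
  L <- length(m)
  stopifnot(junction %in% 9:11, L >= 19, L <= 24)
  r <- rna_complement(m)                     # reversed site, paired row
  editable <- setdiff(seq_len(L), 2:8)
  if (n_edits > 0) {
    for (i in sample(editable, n_edits)) {
      r[i] <- edit_base(m[i])
    }
  }
  # bulge of 3 nt inserted after pairing position `junction`; avoid bases
  # that would pair with the flanking miRNA positions (keeps the planted
  # placement unambiguous in most cases)
  bulge <- vapply(1:3, function(k) {
    sample(setdiff(RNA_BASES, rna_complement(m[min(junction + 1, L)])), 1)
  }, character(1))
  r_full <- c(r[seq_len(junction)], bulge, r[(junction + 1):L])
  site <- paste(rev(r_full), collapse = "")
  # bulge occupies reversed-site indices junction+1..junction+3, i.e.
  # site positions (L+3) - (junction+3) + 1 .. (L+3) - (junction+1) + 1
  list(site = site, bulge_offset = L + 1L - junction)
}

# A base that neither Watson-Crick pairs nor G:U wobbles with `m`.
edit_base <- function(m, allow_gu = TRUE) {
  wc <- rna_complement(m)
  gu_partner <- switch(m, G = "U", U = "G", NA_character_)
  if (allow_gu && !is.na(gu_partner) && runif(1) < 0.5) return(gu_partner)
  cand <- setdiff(RNA_BASES, c(wc, gu_partner))
  sample(cand, 1)
}

# Overwrite a window of a transcript with `site` (DNA), writing through to
# the genome. The window must lie within a single exon; the position is
# redrawn until the edited transcript still passes the noncoding checks.
plant_site_in_transcript <- function(sim, transcript_id, site,
                                     max_tries = 40) {
  tx <- sim$transcripts[sim$transcripts$transcript_id == transcript_id, ]
  stopifnot(nrow(tx) == 1)
  len <- nchar(tx$sequence)
  w <- nchar(site)
  used <- filter(sim$truth_sites, .data$transcript_id == !!transcript_id)
  for (try in seq_len(max_tries)) {
    s <- sample.int(len - w - 4L, 1) + 2L
    e <- s + w - 1L
    if (nrow(used) > 0 && any(used$start <= e & used$end >= s)) next
    gmap <- map_transcript_window(tx$exons[[1]], tx$strand, s, e)
    if (is.null(gmap)) next
    new_seq <- tx$sequence
    substr(new_seq, s, e) <- site
    if (!noncoding_ok(new_seq, sim$hexamer_model)) next
    content <- if (tx$strand == "+") site else revcomp(site)
    sim$genome$chromosomes[[tx$chrom]] <- write_genome(
      sim$genome$chromosomes[[tx$chrom]], gmap$start, content
    )
    idx <- which(sim$transcripts$transcript_id == transcript_id)
    sim$transcripts$sequence[idx] <- new_seq
    return(list(sim = sim, start = s))
  }
  abort(sprintf("could not plant a %d-nt site in %s.", w, transcript_id))
}

# Genomic interval of transcript window [s, e]; NULL unless the window
# falls inside a single exon.
map_transcript_window <- function(exons, strand, s, e) {
  widths <- exons$end - exons$start + 1L
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  cum <- cumsum(widths[ord])
  before <- c(0L, head(cum, -1))
  k <- which(s > before & e <= cum)
  if (length(k) != 1) return(NULL)
  ex <- ord[k]
  off_s <- s - before[k] - 1L
  off_e <- e - before[k] - 1L
  if (strand == "+") {
    list(start = exons$start[ex] + off_s, end = exons$start[ex] + off_e)
  } else {
    list(start = exons$end[ex] - off_e, end = exons$end[ex] - off_s)
  }
}
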