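#' Plant lncRNAs, decoys and expression effects into a synthetic genome
#'
#' Places lncRNA transcripts so that their *true* positional class matches
#' the configured proportions exactly (largest-remainder apportionment):
#' intergenic lncRNAs in gaps free of any gene, intragenic lncRNAs wholly
#' inside gene introns, and antisense lncRNAs overlapping a coding exon on
#' the opposite strand. Sequences are engineered to pass the identification
#' cascade: length 201-1,000 nt for ~96% of lncRNAs (the rest up to
#' 4,026 nt), 1-2 exons for >= 96%, longest six-frame ORF < 100 aa, and a
#' non-positive surrogate coding score. Decoy transcripts that *should* be
#' removed are planted as well: copies of housekeeping-ncRNA and
#' miRNA-precursor exclusion entries, and transcripts expressed in only one
#' genotype. Planted expression effects (`true_log2fc`, on the
#' log2(WT/MT) scale) are assigned here so the count simulator can consume
#' them.
#'
#' @param genome A `lnc_genome` from [generate_genome()].
#' @param config The same [sim_config()].
#' @return A `lnc_sim` list: updated `genome`, `transcripts` tibble
#'   (`transcript_id`, `chrom`, `strand`, `start`, `end`, `exons`,
#'   `sequence`), `truth` tibble (`transcript_id`, `category`, `is_coding`,
#'   `positional_class`, `true_log2fc`, `present_genotype`),
#'   `exclusion_sets` (named list of named character vectors), the trained
#'   `hexamer_model`, and `config`.
#' @export
plant_lncrnas <- function(genome, config) {
  stopifnot(inherits(genome, "lnc_genome"))
  config <- validate_sim_config(config)
  set.seed(stage_seed(config$seed, "lncrna"))
  genes <- genome$genes
  chroms <- genome$chromosomes
  model <- if (nrow(genes) > 0) train_hexamer_model(genes$sequence) else NULL

  props <- config$class_proportions
  names(props) <- c("intergenic", "intragenic", "antisense")
  n_class <- apportion(config$n_lncrnas, props)
  if ((n_class[["intragenic"]] > 0 || n_class[["antisense"]] > 0) &&
      nrow(genes) == 0) {
    abort("intragenic/antisense lncRNAs require coding genes in the annotation.")
  }

  # trackers: lnc spans (per chrom) to avoid collisions; gene spans and
  # exons are fixed obstacles
  lnc_spans <- stats::setNames(
    lapply(names(chroms), function(x) exon_tbl(integer(), integer())),
    names(chroms)
  )
  gene_spans <- split(exon_tbl(genes$start, genes$end), genes$chrom)
  all_exons <- if (nrow(genes) > 0) {
    tidyr::unnest(select(genes, "chrom", "exons"), "exons")
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  }

  placed <- list()
  add_placed <- function(row) {
    placed[[length(placed) + 1]] <<- row
    lnc_spans[[row$chrom]] <<-
      bind_rows(lnc_spans[[row$chrom]], exon_tbl(row$start, row$end))
  }

  # --- intergenic (also used for decoys) ------------------------------
  place_intergenic <- function(len, n_exons, seq = NULL) {
    intron_w <- if (n_exons > 1) sample(60:400, n_exons - 1, replace = TRUE)
                else integer()
    span <- len + sum(intron_w)
    occ <- lapply(names(chroms), function(cn) {
      bind_rows(gene_spans[[cn]], lnc_spans[[cn]])
    })
    names(occ) <- names(chroms)
    pos <- sample_free_position(span, occ,
                               nchar(chroms), margin = 25L)
    strand <- sample(c("+", "-"), 1)
    chunks_len <- as.integer(
      nchar(split_sequence(strrep("A", len), n_exons, min_chunk = 40L))
    )
    seq <- seq %||% make_noncoding_seq(len, model)
    chunks <- substring(seq, cumsum(c(1, head(chunks_len, -1))),
                        cumsum(chunks_len))
    genomic_chunks <- if (strand == "+") chunks else rev(revcomp(chunks))
    starts <- integer(n_exons); ends <- integer(n_exons)
    p <- pos$start
    for (j in seq_len(n_exons)) {
      starts[j] <- p
      ends[j] <- p + nchar(genomic_chunks[j]) - 1L
      chroms[[pos$chrom]] <<-
        write_genome(chroms[[pos$chrom]], p, genomic_chunks[j])
      p <- ends[j] + 1L
      if (j < n_exons) p <- p + intron_w[j]
    }
    list(chrom = pos$chrom, strand = strand, start = starts[1],
         end = ends[n_exons], exons = exon_tbl(starts, ends),
         sequence = seq)
  }

  # --- intragenic: wholly inside an intron ----------------------------
  introns <- gene_introns(genes)
  place_intragenic <- function(len) {
    # free segments: introns minus already-planted lncRNAs, with margins
    segs <- purrr::pmap(introns, function(gene_id, chrom, start, end) {
      ir <- IRanges::IRanges(start + 10L, end - 10L)
      occ <- lnc_spans[[chrom]]
      if (nrow(occ) > 0) {
        ir <- IRanges::setdiff(
          ir, IRanges::IRanges(occ$start - 5L, occ$end + 5L)
        )
      }
      if (length(ir) == 0) return(NULL)
      tibble::tibble(gene_id = gene_id, chrom = chrom,
                     start = IRanges::start(ir), end = IRanges::end(ir))
    }) |> purrr::list_rbind()
    if (is.null(segs) || nrow(segs) == 0) {
      abort("infeasible packing: no intron can host an intragenic lncRNA.",
            class = "lncorange_packing_error")
    }
    widths <- segs$end - segs$start + 1L
    # shrink overly long draws to what the introns can actually hold
    len <- min(len, max(widths))
    if (len < 201L) {
      abort("infeasible packing: introns too crowded for intragenic lncRNAs.",
            class = "lncorange_packing_error")
    }
    ok <- which(widths >= len)
    k <- if (length(ok) == 1) ok else sample(ok, 1, prob = widths[ok] - len + 1)
    s <- segs$start[k] + sample.int(widths[k] - len + 1L, 1) - 1L
    e <- s + len - 1L
    strand <- sample(c("+", "-"), 1)
    seq <- make_noncoding_seq(len, model)
    content <- if (strand == "+") seq else revcomp(seq)
    chroms[[segs$chrom[k]]] <<-
      write_genome(chroms[[segs$chrom[k]]], s, content)
    list(chrom = segs$chrom[k], strand = strand, start = s,
         end = e, exons = exon_tbl(s, e),
         sequence = seq, host_gene = segs$gene_id[k])
  }

  # --- antisense: single exon overlapping a coding exon, opposite strand
  place_antisense <- function(len) {
    cand <- all_exons_for_antisense(genes)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      ex <- cand[k, ]
      ov <- min(60L, ex$end - ex$start + 1L)
      for (side in sample(c("up", "down"))) {
        if (side == "up") {
          e <- ex$start + ov - 1L
          s <- e - len + 1L
          free_lo <- s; free_hi <- ex$start - 1L
        } else {
          s <- ex$end - ov + 1L
          e <- s + len - 1L
          free_lo <- ex$end + 1L; free_hi <- e
        }
        if (s < 25L || e > nchar(chroms[[ex$chrom]]) - 25L) next
        blockers <- bind_rows(
          filter(all_exons, .data$chrom == ex$chrom) |> select(-"chrom"),
          lnc_spans[[ex$chrom]]
        )
        if (free_hi >= free_lo &&
            overlaps_any(free_lo, free_hi, blockers)) next
        if (overlaps_any(s, e, lnc_spans[[ex$chrom]])) next
        strand <- if (ex$strand == "+") "-" else "+"
        # regenerate the free (non-overlap) part until the composed
        # transcript passes the ORF/surrogate checks
        for (try in 1:60) {
          if (free_hi >= free_lo) {
            chroms[[ex$chrom]] <<- write_genome(
              chroms[[ex$chrom]], free_lo,
              random_dna(free_hi - free_lo + 1L)
            )
          }
          seq <- spliced_sequence(chroms[[ex$chrom]], exon_tbl(s, e), strand)
          if (noncoding_ok(seq, model)) {
            return(list(chrom = ex$chrom, strand = strand, start = s,
                        end = e, exons = exon_tbl(s, e), sequence = seq,
                        host_gene = ex$gene_id))
          }
          if (free_hi < free_lo) break
        }
      }
    }
    abort("infeasible packing: could not place an antisense lncRNA.",
          class = "lncorange_packing_error")
  }

  # --- plant the three classes ----------------------------------------
  for (cls in names(n_class)) {
    for (i in seq_len(n_class[[cls]])) {
      len <- sample_lnc_length()
      n_ex <- if (cls == "intergenic") sample_lnc_exons(len) else 1L
      row <- switch(cls,
        intergenic = place_intergenic(len, n_ex),
        intragenic = place_intragenic(len),
        antisense = place_antisense(len)
      )
      row$category <- "lncrna"
      row$positional_class <- cls
      add_placed(row)
    }
  }

  # --- screen decoys and single-genotype decoys -----------------------
  set.seed(stage_seed(config$seed, "screen"))
  exclusion_sets <- list(
    coding = setNames(genes$sequence, genes$transcript_id),
    housekeeping = named_random_set("hkRNA", 6, 250:400),
    mirna_precursor = named_random_set("preMIR", 6, 220:380)
  )
  set.seed(stage_seed(config$seed, "decoy"))
  n_single <- round(config$single_genotype_fraction * config$n_lncrnas)
  plant_decoy <- function(seq, category) {
    row <- place_intergenic(nchar(seq), 1L, seq = seq)
    row$category <- category
    row$positional_class <- "intergenic"
    add_placed(row)
  }
  for (i in seq_len(config$n_housekeeping_decoys)) {
    src <- exclusion_sets$housekeeping[[
      (i - 1) %% length(exclusion_sets$housekeeping) + 1]]
    plant_decoy(mutate_copy(src, rate = 0.02, model = model),
                "decoy_housekeeping")
  }
  for (i in seq_len(config$n_precursor_decoys)) {
    src <- exclusion_sets$mirna_precursor[[
      (i - 1) %% length(exclusion_sets$mirna_precursor) + 1]]
    plant_decoy(mutate_copy(src, rate = 0.02, model = model),
                "decoy_precursor")
  }
  for (i in seq_len(n_single)) {
    row <- place_intergenic(sample_lnc_length(), 1L)
    row$category <- "decoy_single_genotype"
    row$positional_class <- "intergenic"
    row$present_genotype <- if (i %% 2 == 0) "MT" else "WT"
    add_placed(row)
  }

  # --- assemble the transcript set (coding + planted), shuffled ids ---
  lnc_tbl <- purrr::map(placed, function(r) {
    tibble::tibble(
      chrom = r$chrom, strand = r$strand, start = r$start, end = r$end,
      exons = list(r$exons), sequence = r$sequence, category = r$category,
      positional_class = r$positional_class,
      present_genotype = r$present_genotype %||% NA_character_
    )
  }) |> purrr::list_rbind()
  coding_tbl <- if (nrow(genes) > 0) {
    genes |>
      select("chrom", "strand", "start", "end", "exons", "sequence") |>
      mutate(category = "coding", positional_class = NA_character_,
             present_genotype = NA_character_)
  } else {
    lnc_tbl[0, ]
  }
  all_tbl <- bind_rows(coding_tbl, lnc_tbl)
  all_tbl <- all_tbl[sample.int(nrow(all_tbl)), , drop = FALSE]
  all_tbl$transcript_id <- sprintf("TCONS_%05d", seq_len(nrow(all_tbl)))

  # --- planted DE effects ---------------------------------------------
  is_lnc <- all_tbl$category == "lncrna"
  tau <- rep(0, nrow(all_tbl))
  n_de <- round(config$de_fraction * sum(is_lnc))
  if (n_de > 0) {
    de_idx <- sample(which(is_lnc), n_de)
    tau[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$planted_log2fc
  }
  tau[all_tbl$category == "decoy_single_genotype"] <- NA_real_

  truth <- tibble::tibble(
    transcript_id = all_tbl$transcript_id,
    category = all_tbl$category,
    is_coding = all_tbl$category == "coding",
    positional_class = all_tbl$positional_class,
    true_log2fc = tau,
    present_genotype = all_tbl$present_genotype
  )
  transcripts <- select(all_tbl, "transcript_id", "chrom", "strand",
                        "start", "end", "exons", "sequence")
  genome$chromosomes <- chroms
  structure(
    list(genome = genome, genes = genes, transcripts = transcripts,
         truth = truth, exclusion_sets = exclusion_sets,
         hexamer_model = model, config = config),
    class = "lnc_sim"
  )
}

# Largest-remainder apportionment of n into named proportions.
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.list(base)
}

# Length mixture: ~95.8% in 201-1,000 nt (concentrated at 200-400),
# the rest up to 4,026 nt.
sample_lnc_length <- function() {
  bin <- sample(5, 1, prob = c(0.47, 0.25, 0.15, 0.088, 0.042))
  switch(bin,
    sample(201:400, 1), sample(401:600, 1), sample(601:800, 1),
    sample(801:1000, 1), sample(1001:4026, 1)
  )
}

# >= 96% with 1-2 exons.
sample_lnc_exons <- function(len) {
  n <- sample(1:3, 1, prob = c(0.80, 0.17, 0.03))
  min(n, max(1L, len %/% 80L))
}

noncoding_ok <- function(seq, model) {
  orf_aa <- scan_orfs(seq)$longest_orf_aa
  if (orf_aa >= 100) return(FALSE)
  if (!is.null(model) &&
      surrogate_coding_score(orf_aa, hexamer_score(seq, model)) > 0) {
    return(FALSE)
  }
  TRUE
}

make_noncoding_seq <- function(len, model, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (noncoding_ok(s, model)) return(s)
  }
  abort("could not generate a cascade-passing noncoding sequence.")
}

gene_introns <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  purrr::pmap(genes, function(gene_id, chrom, exons, ...) {
    if (nrow(exons) < 2) return(NULL)
    tibble::tibble(
      gene_id = gene_id, chrom = chrom,
      start = exons$end[-nrow(exons)] + 1L,
      end = exons$start[-1] - 1L
    )
  }) |> purrr::list_rbind()
}

all_exons_for_antisense <- function(genes) {
  genes |>
    select("gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons") |>
    filter(.data$end - .data$start + 1L >= 30L)
}

overlaps_any <- function(start, end, tbl) {
  nrow(tbl) > 0 && any(tbl$start <= end & tbl$end >= start)
}

# Sample a free genomic interval of width `span` across chromosomes.
sample_free_position <- function(span, occupied_by_chrom, chrom_lens,
                                 margin = 25L) {
  free <- purrr::imap(occupied_by_chrom, function(occ, cn) {
    ir <- IRanges::IRanges(start = 1, end = chrom_lens[[cn]])
    if (nrow(occ) > 0) {
      ir <- IRanges::setdiff(
        ir, IRanges::IRanges(pmax(1L, occ$start - margin),
                             pmin(chrom_lens[[cn]], occ$end + margin))
      )
    }
    tibble::tibble(chrom = cn, start = IRanges::start(ir),
                   end = IRanges::end(ir))
  }) |> purrr::list_rbind() |>
    filter(.data$end - .data$start + 1L >= span + 2L * margin)
  if (nrow(free) == 0) {
    abort("infeasible packing: no free interval large enough.",
          class = "lncorange_packing_error")
  }
  w <- free$end - free$start + 1L - span - 2L * margin + 1L
  k <- sample.int(nrow(free), 1, prob = w)
  s <- free$start[k] + margin + sample.int(w[k], 1) - 1L
  list(chrom = free$chrom[k], start = s)
}

# Near-copy of an exclusion entry (default 2% substitutions) that still
# passes the ORF/surrogate checks.
mutate_copy <- function(seq, rate = 0.02, model = NULL, max_tries = 50) {
  n <- nchar(seq)
  for (i in seq_len(max_tries)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    k <- max(1L, round(rate * n))
    pos <- sample.int(n, k)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1))
    out <- paste(ch, collapse = "")
    if (noncoding_ok(out, model)) return(out)
  }
  abort("could not generate a decoy copy passing the noncoding checks.")
}

named_random_set <- function(prefix, n, len_range) {
  setNames(
    vapply(seq_len(n), function(i) random_dna(sample(len_range, 1)),
           character(1)),
    sprintf("%s%02d", prefix, seq_len(n))
  )
}

#' @export
print.lnc_sim <- function(x, ...) {
  n_cat <- table(x$truth$category)
  cat("<lnc_sim>\n  transcripts:",
      paste(sprintf("%s=%d", names(n_cat), n_cat), collapse = ", "), "\n")
  if (!is.null(x$mirnas)) {
    cat(sprintf("  %d miRNAs, %d planted sites\n", nrow(x$mirnas),
                nrow(x$truth_sites)))
  }
  if (!is.null(x$counts)) {
    cat(sprintf("  counts: %d samples\n", nrow(x$counts$samples)))
  }
  invisible(x)
}
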