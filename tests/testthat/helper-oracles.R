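# Independent oracles used to cross-check the package implementations.
# These are deliberately written as naive enumerations, separate from the
# code paths they verify.

# Exhaustive six-frame ORF scan: try every ATG on both strands, walk
# codon by codon to the first in-frame stop. N codons invalidate an ORF.
oracle_longest_orf <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    i <- 1L
    while (i + 5L <= n) {
      if (substring(s, i, i + 2) == "ATG") {
        j <- i + 3L
        while (j + 2L <= n) {
          cod <- substring(s, j, j + 2)
          if (grepl("N", cod, fixed = TRUE)) break
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, (j - i) %/% 3)
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 1L
    }
  }
  best
}

# Naive all-pairs interval-overlap classification with the documented
# precedence (antisense > intragenic > intergenic; partial span overlap
# counts as intragenic).
oracle_classify <- function(lncrnas, genes) {
  vapply(seq_len(nrow(lncrnas)), function(i) {
    lx <- lncrnas[i, ]
    lex <- lx$exons[[1]]
    antisense <- FALSE
    within <- FALSE
    touched <- FALSE
    for (g in seq_len(nrow(genes))) {
      gn <- genes[g, ]
      if (gn$chrom != lx$chrom) next
      gex <- gn$exons[[1]]
      for (a in seq_len(nrow(lex))) {
        for (b in seq_len(nrow(gex))) {
          if (lex$start[a] <= gex$end[b] && lex$end[a] >= gex$start[b] &&
              lx$strand != gn$strand) {
            antisense <- TRUE
          }
        }
      }
      if (lx$start >= gn$start && lx$end <= gn$end) within <- TRUE
      if (lx$start <= gn$end && lx$end >= gn$start) touched <- TRUE
    }
    if (antisense) "antisense"
    else if (within || touched) "intragenic"
    else "intergenic"
  }, character(1))
}

rna_pair_code <- function(m, s) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (s == wc[[m]]) return(2L)
  if ((m == "G" && s == "U") || (m == "U" && s == "G")) return(1L)
  0L
}

# Exhaustive eTM enumeration: every window of length L+3, every bulge
# junction 9/10, 10/11, 11/12; rules checked literally on the pairing.
oracle_etm <- function(tseq, mir, max_edits = 3) {
  tseq <- chartr("Tt", "Uu", toupper(tseq))
  mir <- chartr("Tt", "Uu", toupper(mir))
  m <- strsplit(mir, "")[[1]]
  L <- length(m)
  W <- L + 3L
  n <- nchar(tseq)
  hits <- list()
  if (n >= W) {
    for (s in 1:(n - W + 1L)) {
      win <- substring(tseq, s, s + W - 1L)
      r <- rev(strsplit(win, "")[[1]])
      for (j in 9:11) {
        codes <- vapply(seq_len(L), function(i) {
          sb <- if (i <= j) r[i] else r[i + 3L]
          rna_pair_code(m[i], sb)
        }, integer(1))
        seed_ok <- all(codes[2:8] == 2L)
        edits <- sum(codes[-(2:8)] != 2L)
        if (seed_ok && edits <= max_edits) {
          hits[[length(hits) + 1]] <- data.frame(start = s, junction = j,
                                                 n_edits = edits)
        }
      }
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(start = integer(), junction = integer(),
                  n_edits = integer())
}

# Exhaustive target-window scoring in plain R (independent of the C++
# scanner): all windows of length L-1, L, L+1, all indel placements.
oracle_target_penalty <- function(mir, site, params = target_params()) {
  mir <- strsplit(chartr("Tt", "Uu", toupper(mir)), "")[[1]]
  r <- rev(strsplit(chartr("Tt", "Uu", toupper(site)), "")[[1]])
  L <- length(mir)
  wt <- function(pos) {
    if (pos >= params$core_start && pos <= params$core_end) params$core_mult
    else 1
  }
  cost <- function(i, s) {
    pc <- rna_pair_code(mir[i], s)
    (if (pc == 2) 0 else if (pc == 1) params$wobble else params$mismatch) *
      wt(i)
  }
  W <- length(r)
  if (W == L) {
    sum(vapply(1:L, function(i) cost(i, r[i]), numeric(1)))
  } else if (W == L + 1) {
    min(vapply(1:(L + 1), function(g) {
      params$indel * wt(min(g, L)) +
        sum(vapply(1:L, function(i) cost(i, if (i < g) r[i] else r[i + 1]),
                   numeric(1)))
    }, numeric(1)))
  } else if (W == L - 1) {
    min(vapply(1:L, function(g) {
      params$indel * wt(g) +
        sum(vapply(setdiff(1:L, g), function(i) {
          cost(i, if (i < g) r[i] else r[i - 1])
        }, numeric(1)))
    }, numeric(1)))
  } else {
    stop("bad site length")
  }
}

oracle_scan_targets <- function(tseq, mir, params = target_params()) {
  n <- nchar(tseq)
  L <- nchar(mir)
  out <- list()
  for (w in (L - 1):(L + 1)) {
    if (w > n) next
    for (s in 1:(n - w + 1L)) {
      p <- oracle_target_penalty(mir, substring(tseq, s, s + w - 1L), params)
      if (p <= params$cutoff) {
        out[[length(out) + 1]] <- data.frame(start = s, width = w,
                                             penalty = p)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), width = integer(), penalty = numeric())
}

# Closed-form Welch statistic (for checking de_test(var_equal = FALSE)).
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
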