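# Degenerate motif scanning, enrichment statistics, and harvesting of PWMs
# from first-layer convolution activations of a trained model.

.check_pattern <- function(pattern) {
  p <- toupper(pattern)
  if (!nzchar(p)) stop("empty motif pattern")
  if (!grepl("^[ACGTN]+$", p))
    stop("pattern must be over {A,C,G,T,N}")
  p
}

#' Count occurrences of a degenerate motif in a sequence
#'
#' \code{N} matches any base. Overlapping matches are counted; with
#' \code{both_strands} the reverse-complement pattern is also scanned, and a
#' position matching both the pattern and its reverse complement (possible
#' only for self-complementary patterns) is counted once.
#'
#' @param seq DNA string (A,C,G,T; case-insensitive).
#' @param motif Pattern string over \code{{A,C,G,T,N}}.
#' @param both_strands Count reverse-complement matches too.
#' @return Non-negative integer occurrence count.
#' @examples
#' scan_count("CCTCCCTAACCAC", "CCTCCCTNNCCAC")  # 1
#' @export
scan_count <- function(seq, motif, both_strands = TRUE) {
  s <- .check_dna(seq, allow_n = TRUE)
  p <- .check_pattern(motif)
  if (nchar(s) < nchar(p)) return(0L)
  hits <- function(pat) {
    rx <- paste0("(?=", gsub("N", ".", pat, fixed = TRUE), ")")
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  fwd <- hits(p)
  if (!both_strands) return(length(fwd))
  rcp <- rc_seq(p)
  length(union(fwd, hits(rcp)))
}

#' Occurrence counts of a motif over a labelled dataset
#'
#' Total occurrence counts (summed over sequences, both strands by default)
#' in the label-1 ("hot") and label-0 ("cold") classes.
#'
#' @param dataset An \code{rcnet_dataset} (label 1 = hot).
#' @param motif Pattern over \code{{A,C,G,T,N}}.
#' @param both_strands Count both strands.
#' @param split Optional tag recorded in the result.
#' @return A list of class \code{rcnet_counts}: motif, hot_count,
#'   cold_count, n_hot_seqs, n_cold_seqs, split.
#' @export
count_dataset <- function(dataset, motif, both_strands = TRUE,
                          split = "full") {
  stopifnot(inherits(dataset, "rcnet_dataset"))
  cnt <- vapply(dataset$sequences, scan_count, integer(1), motif = motif,
                both_strands = both_strands, USE.NAMES = FALSE)
  count_table(motif,
              hot_count = sum(cnt[dataset$labels == 1L]),
              cold_count = sum(cnt[dataset$labels == 0L]),
              n_hot_seqs = sum(dataset$labels == 1L),
              n_cold_seqs = sum(dataset$labels == 0L),
              split = split)
}

#' Construct a motif count table directly
#'
#' Useful for published count tables where only the totals are available.
#'
#' @param motif Pattern string.
#' @param hot_count,cold_count Occurrence counts per class.
#' @param n_hot_seqs,n_cold_seqs Sequence totals per class.
#' @param split Split tag.
#' @return An \code{rcnet_counts} list.
#' @export
count_table <- function(motif, hot_count, cold_count,
                        n_hot_seqs = NA_integer_, n_cold_seqs = NA_integer_,
                        split = "full") {
  if (hot_count < 0 || cold_count < 0) stop("counts must be non-negative")
  structure(list(motif = motif, hot_count = as.numeric(hot_count),
                 cold_count = as.numeric(cold_count),
                 n_hot_seqs = n_hot_seqs, n_cold_seqs = n_cold_seqs,
                 split = split), class = "rcnet_counts")
}

#' Motif enrichment statistics
#'
#' The enrichment ratio is the plain ratio of hot to cold occurrence counts,
#' the convention that reproduces published hot/cold enrichment columns;
#' a classical 2x2 odds ratio (on occurrence vs sequence-total margins) is
#' available with \code{classical_or = TRUE}. The p-value is a two-sided
#' exact binomial test of \code{hot_count} successes in \code{hot_count +
#' cold_count} trials against the null proportion \code{n_hot_seqs /
#' (n_hot_seqs + n_cold_seqs)} (0.5 when sequence totals are unknown),
#' Bonferroni-corrected by \code{n_tests}.
#'
#' @param table An \code{rcnet_counts}.
#' @param n_tests Number of motifs tested (Bonferroni factor).
#' @param classical_or Report the 2x2 odds ratio instead of the count ratio.
#' @return A list of class \code{rcnet_enrichment}: ratio, p_raw,
#'   p_bonferroni.
#' @export
enrich <- function(table, n_tests = 1L, classical_or = FALSE) {
  stopifnot(inherits(table, "rcnet_counts"))
  hc <- table$hot_count; cc <- table$cold_count
  if (hc + cc == 0) stop("zero total count")
  ratio <- if (classical_or) {
    if (is.na(table$n_hot_seqs) || is.na(table$n_cold_seqs))
      stop("classical odds ratio needs sequence totals")
    (hc * (table$n_cold_seqs - cc)) / (cc * (table$n_hot_seqs - hc))
  } else if (cc == 0) Inf else hc / cc
  p_null <- if (is.na(table$n_hot_seqs) || is.na(table$n_cold_seqs)) 0.5 else
    table$n_hot_seqs / (table$n_hot_seqs + table$n_cold_seqs)
  p_raw <- stats::binom.test(round(hc), round(hc + cc), p = p_null)$p.value
  structure(list(motif = table$motif, ratio = ratio, p_raw = p_raw,
                 p_bonferroni = min(1, n_tests * p_raw),
                 n_tests = as.integer(n_tests)),
            class = "rcnet_enrichment")
}

#' @export
print.rcnet_enrichment <- function(x, ...) {
  cat(sprintf("%s  ratio %.2f  p %.3g (Bonferroni %.3g over %d tests)\n",
              x$motif, x$ratio, x$p_raw, x$p_bonferroni, x$n_tests))
  invisible(x)
}

#' Per-column information content of a PWM
#'
#' \code{2 + sum_b p_b log2 p_b} bits per column under a uniform background;
#' 0 for a uniform column, 2 for a point mass.
#'
#' @param p An \code{rcnet_pwm}.
#' @return Numeric vector of per-column bits in \code{[0, 2]}.
#' @export
information_content <- function(p) {
  apply(p$probs, 2L, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
}

#' Degenerate consensus of a PWM
#'
#' Each column is rendered as its dominant base when informative (IC at
#' least \code{ic_threshold} bits and dominant probability at least
#' \code{base_prob_threshold}), otherwise as \code{N}.
#'
#' @param p An \code{rcnet_pwm}.
#' @param ic_threshold Minimum column information content (bits).
#' @param base_prob_threshold Minimum dominant base probability.
#' @return A pattern string over \code{{A,C,G,T,N}}.
#' @export
pwm_to_consensus <- function(p, ic_threshold = 0.5,
                             base_prob_threshold = 0.75) {
  ic <- information_content(p)
  out <- vapply(seq_len(ncol(p$probs)), function(j) {
    col <- p$probs[, j]
    if (ic[j] >= ic_threshold && max(col) >= base_prob_threshold)
      DNA_BASES[which.max(col)] else "N"
  }, character(1))
  paste(out, collapse = "")
}

#' Harvest PWMs from first-layer filter activations
#'
#' For each first-layer filter (one representative per RC-tied pair in an
#' equivariant model): activations are computed for every sequence, the
#' maximal activation and its position recorded, and the top sequences
#' retained (the smaller of \code{top_k} and the set above the
#' \code{activation_quantile} of per-sequence maxima). The length-f_l
#' subsequence under each retained maximum is extracted -
#' reverse-complemented when the tied partner filter produced the larger
#' activation - and the stacked subsequences are turned into a PWM with
#' pseudocount 1.
#'
#' @param model A trained \code{rcnet_model}.
#' @param sequences Character vector of equal-length sequences.
#' @param top_k Maximum number of contributing subsequences per filter.
#' @param activation_quantile Quantile of per-sequence maxima above which
#'   sequences contribute.
#' @return List of \code{rcnet_harvest} objects (one per representative
#'   filter): pwm, support, filter, mean_activation.
#' @export
harvest_motifs <- function(model, sequences, top_k = 500L,
                           activation_quantile = 0.99) {
  cfg <- model$config
  bank <- .bank(model)
  n_f <- dim(bank$W)[3]
  f_l <- cfg$f_l
  reps <- if (cfg$equivariant) seq_len(n_f %/% 2L) else seq_len(n_f)
  nseq <- length(sequences)
  # activation of every filter at every position, per sequence
  best_val <- matrix(-Inf, nseq, n_f)
  best_pos <- matrix(1L, nseq, n_f)
  for (s in seq_len(nseq)) {
    A <- conv1d_valid(one_hot_encode(sequences[s]), bank$W, bank$b,
                      activation = cfg$activation)
    best_pos[s, ] <- max.col(A, ties.method = "first")
    best_val[s, ] <- A[cbind(seq_len(n_f), best_pos[s, ])]
  }
  out <- list()
  for (i in reps) {
    partner <- if (cfg$equivariant) n_f + 1L - i else i
    use_partner <- cfg$equivariant & (best_val[, partner] > best_val[, i])
    val <- ifelse(use_partner, best_val[, partner], best_val[, i])
    pos <- ifelse(use_partner, best_pos[, partner], best_pos[, i])
    thr <- stats::quantile(val, activation_quantile)
    keep <- which(val >= thr)
    if (length(keep) > top_k)
      keep <- keep[order(val[keep], decreasing = TRUE)[seq_len(top_k)]]
    if (length(keep) == 0L) {
      message("filter ", i, ": no sequence passed the activation threshold")
      next
    }
    counts <- matrix(1, 4L, f_l, dimnames = list(DNA_BASES, NULL))
    for (s in keep) {
      sub <- substr(sequences[s], pos[s], pos[s] + f_l - 1L)
      if (use_partner[s]) sub <- rc_seq(sub)
      idx <- match(strsplit(sub, "")[[1]], DNA_BASES)
      counts[cbind(idx, seq_len(f_l))] <- counts[cbind(idx, seq_len(f_l))] + 1
    }
    out[[length(out) + 1L]] <- structure(list(
      pwm = pwm(sweep(counts, 2L, colSums(counts), "/"),
                name = paste0("filter", i)),
      support = length(keep), filter = i,
      mean_activation = mean(val[keep])), class = "rcnet_harvest")
  }
  out
}

#' Best alignment correlation between a harvested and a reference PWM
#'
#' Slides the shorter PWM along the longer one (both strands) and, at each
#' offset, computes the mean column-wise Pearson correlation over reference
#' columns whose information content is at least \code{ic_min}. Returns the
#' best value with its offset and strand.
#'
#' @param query,reference \code{rcnet_pwm} objects.
#' @param ic_min Minimum reference-column IC (bits) entering the mean.
#' @return List (correlation, offset, strand).
#' @export
pwm_match_correlation <- function(query, reference, ic_min = 0.5) {
  score <- function(qm, rm) {
    ic <- apply(rm, 2L, function(col) {
      nz <- col[col > 0]; 2 + sum(nz * log2(nz))
    })
    use <- which(ic >= ic_min)
    if (length(use) == 0L) use <- seq_len(ncol(rm))
    mean(vapply(use, function(j) {
      if (stats::sd(qm[, j]) == 0 || stats::sd(rm[, j]) == 0) return(0)
      stats::cor(qm[, j], rm[, j])
    }, numeric(1)))
  }
  q <- query$probs; r <- reference$probs
  swap <- ncol(q) < ncol(r)
  long <- if (swap) r else q
  short <- if (swap) q else r
  best <- list(correlation = -Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    sh <- if (strand == "+") short else rc_hidden(short)
    for (off in 0:(ncol(long) - ncol(sh))) {
      win <- long[, (off + 1L):(off + ncol(sh)), drop = FALSE]
      cc <- if (swap) score(sh, win) else score(win, sh)
      if (cc > best$correlation)
        best <- list(correlation = cc, offset = off, strand = strand)
    }
  }
  best
}

#' Write an enrichment report TSV
#'
#' One row per motif: counts, ratio and Bonferroni-corrected p-value.
#'
#' @param tables List of \code{rcnet_counts}.
#' @param path Output path.
#' @param n_tests Bonferroni factor (defaults to the number of motifs).
#' @return The report data frame, invisibly.
#' @export
write_enrichment_report <- function(tables, path,
                                    n_tests = length(tables)) {
  rows <- lapply(tables, function(tb) {
    e <- enrich(tb, n_tests = n_tests)
    data.frame(motif = tb$motif, hot_count = tb$hot_count,
               cold_count = tb$cold_count, ratio = e$ratio,
               p_raw = e$p_raw, p_bonferroni = e$p_bonferroni,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
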