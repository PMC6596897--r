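# Recombination hotspot segmentation: a two-state hidden Markov model with
# exponential emission densities over windowed recombination rates (cM/Mb),
# fitted by Viterbi training (hard EM), plus extraction of centred 1 kb
# hotspot sequences and GC-matched coldspot controls.

RATE_FLOOR <- 1e-6  # cM/Mb; zero rates are floored before likelihood evaluation

#' Two-state HMM parameters
#'
#' State 1 is "hot", state 2 "not hot". Emissions are exponential densities
#' parameterized by their means (cM/Mb); identifiability is fixed by the
#' convention \code{mean_hot > mean_cold}.
#'
#' @param mean_hot,mean_cold Exponential emission means, \code{mean_hot >
#'   mean_cold > 0}.
#' @param transitions 2x2 row-stochastic transition matrix (rows: from hot,
#'   from cold).
#' @param initial Initial distribution over (hot, cold).
#' @return An object of class \code{rcnet_hmm2}.
#' @export
hmm2_params <- function(mean_hot, mean_cold,
                        transitions = matrix(c(0.9, 0.1, 0.1, 0.9), 2L,
                                             byrow = TRUE),
                        initial = c(0.5, 0.5)) {
  if (mean_hot <= 0 || mean_cold <= 0) stop("emission means must be > 0")
  if (mean_hot <= mean_cold) stop("mean_hot must exceed mean_cold")
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  structure(list(mean_hot = mean_hot, mean_cold = mean_cold,
                 transitions = transitions, initial = initial),
            class = "rcnet_hmm2")
}

#' Rate track container
#'
#' @param chrom Chromosome name per window.
#' @param start,end 0-based half-open window coordinates (BED convention).
#' @param rate Recombination rate in cM/Mb, \code{>= 0}.
#' @return A data frame of class \code{rcnet_ratetrack}, sorted and checked
#'   for non-overlap within each chromosome.
#' @export
rate_track <- function(chrom, start, end, rate) {
  if (any(rate < 0)) stop("rates must be non-negative")
  if (any(end <= start)) stop("windows must have positive width")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping windows on ", ch)
  }
  rownames(df) <- NULL
  class(df) <- c("rcnet_ratetrack", "data.frame")
  df
}

#' Read / write a 4-column rate track TSV
#'
#' Columns: chrom, start, end, rate (cM/Mb); BED-style 0-based half-open.
#'
#' @param path File path.
#' @return \code{read_rate_track}: an \code{rcnet_ratetrack}.
#' @export
read_rate_track <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "rate"),
                          stringsAsFactors = FALSE)
  rate_track(df$chrom, df$start, df$end, df$rate)
}

#' @rdname read_rate_track
#' @param track An \code{rcnet_ratetrack}.
#' @export
write_rate_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "rate")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.emission_ll <- function(rates, params) {
  r <- pmax(rates, RATE_FLOOR)
  cbind(hot = stats::dexp(r, rate = 1 / params$mean_hot, log = TRUE),
        cold = stats::dexp(r, rate = 1 / params$mean_cold, log = TRUE))
}

#' Viterbi decoding of a rate track
#'
#' Most probable hot/not-hot state path under the two-state exponential
#' model, computed in log space. Rates are floored at 1e-6 cM/Mb before
#' likelihood evaluation. Chromosomes are decoded independently, each
#' starting from the initial distribution.
#'
#' @param track An \code{rcnet_ratetrack}.
#' @param params An \code{rcnet_hmm2}.
#' @return Integer vector (1 = hot, 2 = not hot) per window, with a
#'   \code{loglik} attribute: the joint log-likelihood of (path, data).
#' @export
viterbi <- function(track, params) {
  if (nrow(track) == 0L) stop("empty track")
  path <- integer(nrow(track))
  total_ll <- 0
  logA <- log(params$transitions)
  logpi <- log(params$initial)
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    ll <- .emission_ll(track$rate[idx], params)
    n <- length(idx)
    delta <- matrix(-Inf, n, 2L)
    psi <- matrix(0L, n, 2L)
    delta[1L, ] <- logpi + ll[1L, ]
    if (n > 1L) for (t in 2:n) {
      for (j in 1:2) {
        cand <- delta[t - 1L, ] + logA[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- cand[psi[t, j]] + ll[t, j]
      }
    }
    p <- integer(n)
    p[n] <- which.max(delta[n, ])
    if (n > 1L) for (t in (n - 1L):1L) p[t] <- psi[t + 1L, p[t + 1L]]
    path[idx] <- p
    total_ll <- total_ll + max(delta[n, ])
  }
  attr(path, "loglik") <- total_ll
  path
}

# joint log-likelihood of a given (path, data) pair
.path_loglik <- function(track, params, path) {
  ll <- 0
  logA <- log(params$transitions)
  logpi <- log(params$initial)
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    em <- .emission_ll(track$rate[idx], params)
    p <- path[idx]
    ll <- ll + logpi[p[1L]] + sum(em[cbind(seq_along(idx), p)])
    if (length(idx) > 1L)
      ll <- ll + sum(logA[cbind(p[-length(p)], p[-1L])])
  }
  ll
}

#' Viterbi training (hard EM) of the two-state model
#'
#' Alternates Viterbi decoding with re-estimation: each state's mean becomes
#' the sample mean of its assigned (floored) rates, and transitions are
#' re-estimated from path transition counts with add-one smoothing. Stops
#' when the decoded path is unchanged or the parameter change falls below
#' \code{tol}. The \code{mean_hot > mean_cold} labelling is enforced by
#' swapping states if needed. A state decoding zero windows keeps its
#' current parameters for that iteration (reported via a message).
#'
#' @param track An \code{rcnet_ratetrack}.
#' @param init Initial \code{rcnet_hmm2}.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the maximum absolute parameter change.
#' @return The fitted \code{rcnet_hmm2}, with attributes \code{iterations}
#'   and \code{path} (final decoding).
#' @export
viterbi_train <- function(track, init, max_iter = 50L, tol = 1e-6) {
  params <- init
  old_path <- NULL
  for (it in seq_len(max_iter)) {
    path <- viterbi(track, params)
    r <- pmax(track$rate, RATE_FLOOR)
    means <- c(params$mean_hot, params$mean_cold)
    for (s in 1:2) {
      if (any(path == s)) means[s] <- mean(r[path == s])
      else message("state ", s, " received no windows; parameters frozen")
    }
    if (means[1] < means[2]) {     # enforce labelling convention
      means <- rev(means)
      path <- 3L - path
    }
    counts <- matrix(1, 2L, 2L)    # add-one smoothing
    for (ch in unique(track$chrom)) {
      p <- path[track$chrom == ch]
      if (length(p) > 1L)
        for (t in seq_len(length(p) - 1L))
          counts[p[t], p[t + 1L]] <- counts[p[t], p[t + 1L]] + 1
    }
    trans <- counts / rowSums(counts)
    delta <- max(abs(c(means[1] - params$mean_hot,
                       means[2] - params$mean_cold,
                       trans - params$transitions)))
    params <- hmm2_params(means[1], means[2], transitions = trans,
                          initial = params$initial)
    if (!is.null(old_path) && identical(path, old_path)) break
    if (delta < tol) break
    old_path <- path
  }
  attr(params, "iterations") <- it
  attr(params, "path") <- viterbi(track, params)
  params
}

#' Merge decoded hot windows into hotspot intervals
#'
#' Maximal runs of hot-state windows are merged per chromosome into
#' intervals with bp lengths and rate summaries.
#'
#' @param path Integer state path from \code{\link{viterbi}} (1 = hot).
#' @param track The decoded \code{rcnet_ratetrack}.
#' @return Data frame (chrom, start, end, length_bp, mean_rate).
#' @export
call_hotspots <- function(path, track) {
  out <- NULL
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    hot <- path[idx] == 1L
    if (!any(hot)) next
    rr <- rle(hot)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    for (k in which(rr$values)) {
      w <- idx[starts[k]:ends[k]]
      out <- rbind(out, data.frame(
        chrom = ch, start = track$start[w[1L]],
        end = track$end[w[length(w)]],
        length_bp = track$end[w[length(w)]] - track$start[w[1L]],
        mean_rate = mean(track$rate[w]), stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(chrom = character(), start = integer(),
                      end = integer(), length_bp = integer(),
                      mean_rate = numeric())
}

#' Extract centred fixed-length sequences from intervals
#'
#' Intervals longer than \code{max_len} are discarded (hotspots much longer
#' than ~4 kb are poorly localized); for the rest a window of \code{out_len}
#' bp centred at \code{floor((start + end) / 2)} is extracted. Windows that
#' run off the contig or contain \code{N} are dropped with a warning.
#'
#' @param intervals Data frame with chrom, start, end (0-based half-open).
#' @param genome Named character vector of contig sequences (or a path to a
#'   FASTA file).
#' @param max_len Maximum interval length retained (default 4000).
#' @param out_len Extracted window length (default 1000).
#' @return Data frame (chrom, start, end, seq) of extracted windows.
#' @export
extract_center <- function(intervals, genome, max_len = 4000L,
                           out_len = 1000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  keep <- intervals$end - intervals$start <= max_len
  intervals <- intervals[keep, , drop = FALSE]
  half <- out_len %/% 2L
  out <- NULL
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    if (!ch %in% names(genome)) stop("contig ", ch, " not in genome")
    center <- (intervals$start[i] + intervals$end[i]) %/% 2L
    s0 <- center - half; e0 <- s0 + out_len
    if (s0 < 0L || e0 > nchar(genome[[ch]])) {
      warning("window for interval ", i, " extends past contig end; dropped")
      next
    }
    sq <- toupper(substr(genome[[ch]], s0 + 1L, e0))
    if (grepl("N", sq, fixed = TRUE)) next
    out <- rbind(out, data.frame(chrom = ch, start = s0, end = e0, seq = sq,
                                 stringsAsFactors = FALSE))
  }
  out %||% data.frame(chrom = character(), start = integer(),
                      end = integer(), seq = character())
}

# mean rate of track windows overlapping [s0, e0) on chrom, overlap-weighted
.window_rate <- function(track, chrom, s0, e0) {
  sub <- track[track$chrom == chrom & track$end > s0 & track$start < e0, ,
               drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  w <- pmin(sub$end, e0) - pmax(sub$start, s0)
  sum(sub$rate * w) / sum(w)
}

#' Find a GC-matched coldspot window for a hotspot
#'
#' Greedy search: candidate \code{out_len} bp windows are scanned outward
#' from the hotspot window in 1 kb steps, alternating sides, out to
#' \code{search_radius}. The first candidate that (i) matches the hotspot's
#' GC content within \code{gc_tol} (absolute difference of fractions by
#' default; relative with \code{relative_gc}), (ii) has mean track rate
#' below \code{rate_max} cM/Mb, (iii) contains no N, and (iv) overlaps no
#' hot interval nor any window in \code{exclude} is returned; \code{NULL}
#' if the radius is exhausted.
#'
#' @param hot_window One row (chrom, start, end, seq) from
#'   \code{\link{extract_center}}.
#' @param genome Named character vector of contig sequences.
#' @param track An \code{rcnet_ratetrack}.
#' @param hot_intervals Data frame of hot intervals to avoid.
#' @param exclude Data frame (chrom, start, end) of already-claimed windows.
#' @param search_radius Maximum distance searched (bp).
#' @param gc_tol GC tolerance (fraction).
#' @param rate_max Maximum mean rate of an acceptable coldspot (cM/Mb).
#' @param relative_gc Interpret \code{gc_tol} relative to the hotspot GC.
#' @return A list (chrom, start, end, seq, gc, rate) or \code{NULL}.
#' @export
match_coldspot <- function(hot_window, genome, track, hot_intervals = NULL,
                           exclude = NULL, search_radius = 300000L,
                           gc_tol = 0.10, rate_max = 0.5,
                           relative_gc = FALSE) {
  ch <- hot_window$chrom
  len <- hot_window$end - hot_window$start
  gseq <- genome[[ch]]
  glen <- nchar(gseq)
  gc_hot <- gc_content(hot_window$seq)
  tol <- if (relative_gc) gc_tol * gc_hot else gc_tol
  overlaps <- function(s0, e0, df)
    !is.null(df) && nrow(df) > 0L &&
      any(df$chrom == ch & df$end > s0 & df$start < e0)
  for (d in seq(1000L, search_radius, by = 1000L)) {
    for (sgn in c(1L, -1L)) {
      s0 <- hot_window$start + sgn * d
      e0 <- s0 + len
      if (s0 < 0L || e0 > glen) next
      if (overlaps(s0, e0, hot_intervals) || overlaps(s0, e0, exclude)) next
      sq <- toupper(substr(gseq, s0 + 1L, e0))
      if (grepl("N", sq, fixed = TRUE)) next
      gc <- gc_content(sq)
      if (abs(gc - gc_hot) > tol) next
      rate <- .window_rate(track, ch, s0, e0)
      if (is.na(rate) || rate >= rate_max) next
      return(list(chrom = ch, start = s0, end = e0, seq = sq,
                  gc = gc, rate = rate))
    }
  }
  NULL
}

#' Simulate a rate track from known HMM parameters
#'
#' Draws a Markov state path and per-window rates from each state's
#' exponential distribution; the true path is returned for parameter
#' recovery tests.
#'
#' @param params An \code{rcnet_hmm2}.
#' @param n_windows Number of windows.
#' @param window_bp Window size in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return List with \code{track} (an \code{rcnet_ratetrack}) and
#'   \code{path} (true states, 1 = hot).
#' @export
simulate_rate_track <- function(params, n_windows, window_bp = 1000L,
                                seed = 1L, chrom = "chrSim") {
  set.seed(seed)
  path <- integer(n_windows)
  path[1L] <- sample(1:2, 1L, prob = params$initial)
  for (t in seq_len(n_windows - 1L))
    path[t + 1L] <- sample(1:2, 1L, prob = params$transitions[path[t], ])
  means <- c(params$mean_hot, params$mean_cold)
  rates <- stats::rexp(n_windows, rate = 1 / means[path])
  starts <- (seq_len(n_windows) - 1L) * window_bp
  list(track = rate_track(chrom, starts, starts + window_bp, rates),
       path = path)
}
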