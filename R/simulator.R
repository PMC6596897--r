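# PWM motif-injection simulator: labelled regulatory-sequence datasets with
# a known ground truth, mimicking a two-binding-protein regulatory network.

#' Position weight matrix
#'
#' @param probs Numeric \code{[4, L]} matrix, rows A, C, G, T; columns must
#'   sum to 1 (within 1e-9) with non-negative entries.
#' @param name Motif name.
#' @return An object of class \code{rcnet_pwm}.
#' @export
pwm <- function(probs, name = "pwm") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("a PWM has 4 rows (A, C, G, T)")
  if (any(probs < 0)) stop("PWM entries must be non-negative")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  rownames(probs) <- DNA_BASES
  structure(list(probs = probs, name = name), class = "rcnet_pwm")
}

#' @export
print.rcnet_pwm <- function(x, ...) {
  cat("rcnet_pwm", x$name, "length", ncol(x$probs), "consensus",
      pwm_to_consensus(x), "\n")
  invisible(x)
}

#' Reverse complement of a PWM
#'
#' Reverses the columns and swaps complementary base rows.
#'
#' @param p An \code{rcnet_pwm}.
#' @return The reverse-complement PWM.
#' @export
rc_pwm <- function(p) {
  pwm(rc_hidden(p$probs), name = paste0(p$name, "_rc"))
}

#' Read a JASPAR PFM text file
#'
#' Expects a header line \code{>ID NAME} followed by four rows like
#' \code{A  [ 4  19  0 ... ]} (brackets optional). Counts are normalized
#' per column into probabilities.
#'
#' @param path Path to a JASPAR-format PFM file.
#' @return An \code{rcnet_pwm}.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L || hdr != 1L) stop("expected a single '>' header line")
  name <- trimws(sub("^>\\s*", "", lines[1]))
  rows <- lines[-1]
  if (length(rows) != 4L) stop("expected 4 count rows (A, C, G, T)")
  parse_row <- function(r) {
    base <- sub("^\\s*([ACGT]).*", "\\1", r)
    nums <- gsub("[][]", " ", sub("^\\s*[ACGT]", "", r))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (anyNA(vals)) stop("malformed count row: ", r)
    list(base = base, vals = vals)
  }
  parsed <- lapply(rows, parse_row)
  bases <- vapply(parsed, `[[`, character(1), "base")
  if (!setequal(bases, DNA_BASES)) stop("rows must cover A, C, G, T")
  lens <- vapply(parsed, function(p) length(p$vals), integer(1))
  if (length(unique(lens)) != 1L) stop("unequal row lengths")
  counts <- do.call(rbind, lapply(parsed, `[[`, "vals"))[match(DNA_BASES, bases), , drop = FALSE]
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total PFM column")
  pwm(sweep(counts, 2L, tot, "/"), name = name)
}

#' Write a PWM in JASPAR PFM format
#'
#' @param p An \code{rcnet_pwm}.
#' @param path Output path.
#' @param counts_scale Probabilities are written as counts scaled by this
#'   total per column.
#' @return \code{path}, invisibly.
#' @export
write_jaspar_pfm <- function(p, path, counts_scale = 1) {
  m <- p$probs * counts_scale
  lines <- c(paste0(">", p$name),
             vapply(seq_len(4L), function(i)
               sprintf("%s  [ %s ]", DNA_BASES[i],
                       paste(format(m[i, ], trim = TRUE, digits = 15),
                             collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Sample a motif instance from a PWM
#'
#' Position j of the returned string is drawn from column j.
#'
#' @param p An \code{rcnet_pwm}.
#' @return A DNA string of the PWM's length.
#' @export
sample_motif <- function(p) {
  paste(apply(p$probs, 2L, function(col)
    sample(DNA_BASES, 1L, prob = col)), collapse = "")
}

#' Inject a motif instance into a background sequence
#'
#' Replaces the substring starting at the 0-based \code{position} (BED-style
#' offset) with the motif, or with its reverse complement when
#' \code{rc_flag} is TRUE. Sequence length is unchanged.
#'
#' @param seq Background sequence.
#' @param motif Motif instance to plant.
#' @param position 0-based start offset; \code{position + nchar(motif)} must
#'   not exceed \code{nchar(seq)}.
#' @param rc_flag Plant the reverse complement strand.
#' @return The modified sequence.
#' @examples
#' inject("AAAA", "CG", 1, FALSE)  # "ACGA"
#' @export
inject <- function(seq, motif, position, rc_flag = FALSE) {
  s <- .check_dna(seq); m <- .check_dna(motif)
  lm <- nchar(m)
  if (position < 0L || position + lm > nchar(s))
    stop("injection position out of range")
  if (rc_flag) m <- rc_seq(m)
  paste0(substr(s, 1L, position), m,
         substr(s, position + lm + 1L, nchar(s)))
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the bundled two-motif
#' regulatory simulation: 40 000 sequences of length 1000, a balanced
#' Bernoulli(0.5) response, and per-motif injection probability 40% for
#' label-1 sequences versus 20% for label-0 sequences, on a uniform
#' i.i.d. background.
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Sequence length (>= the longest PWM).
#' @param p_inject_pos Per-PWM injection probability given label 1.
#' @param p_inject_neg Per-PWM injection probability given label 0.
#' @param label_prob P(label = 1).
#' @param background Base probabilities (A, C, G, T) of the background.
#' @return A list of class \code{rcnet_simconfig}.
#' @export
sim_config <- function(n_sequences = 40000L, seq_length = 1000L,
                       p_inject_pos = 0.4, p_inject_neg = 0.2,
                       label_prob = 0.5,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(n_sequences >= 1L, seq_length >= 1L,
            p_inject_pos >= 0, p_inject_pos <= 1,
            p_inject_neg >= 0, p_inject_neg <= 1,
            label_prob >= 0, label_prob <= 1,
            length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-9)
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 p_inject_pos = p_inject_pos, p_inject_neg = p_inject_neg,
                 label_prob = label_prob, background = background),
            class = "rcnet_simconfig")
}

#' Simulate a labelled two-motif dataset
#'
#' For every sequence: a 0/1 label is drawn first; a background sequence is
#' drawn i.i.d. from the background composition; then each PWM is injected
#' independently with probability \code{p_inject_pos} (label 1) or
#' \code{p_inject_neg} (label 0). Every injected instance is sampled from
#' its PWM, reverse-complemented with probability 1/2 and placed at a
#' uniform random valid position. Injections may overlap (the later one
#' overwrites); both are logged.
#'
#' @param config An \code{rcnet_simconfig}.
#' @param pwms List of \code{rcnet_pwm} objects (canonically two).
#' @param seed Integer seed; a fixed seed gives a bit-identical dataset.
#' @return An \code{rcnet_dataset} with an \code{injection_log} attribute:
#'   a data frame (seq_id, pwm, position (0-based), strand, instance).
#' @export
simulate_dataset <- function(config, pwms, seed = 1L) {
  stopifnot(inherits(config, "rcnet_simconfig"))
  if (inherits(pwms, "rcnet_pwm")) pwms <- list(pwms)
  lens <- vapply(pwms, function(p) ncol(p$probs), integer(1))
  if (any(lens > config$seq_length))
    stop("seq_length shorter than a PWM")
  set.seed(seed)
  n <- config$n_sequences; L <- config$seq_length
  labels <- stats::rbinom(n, 1L, config$label_prob)
  seqs <- character(n)
  cap <- max(16L, ceiling(1.2 * n * length(pwms) *
                            max(config$p_inject_pos, config$p_inject_neg)))
  log_seq <- integer(cap); log_pwm <- character(cap)
  log_pos <- integer(cap); log_str <- character(cap); log_ins <- character(cap)
  nlog <- 0L
  pwm_names <- vapply(pwms, `[[`, character(1), "name")
  for (s in seq_len(n)) {
    bg <- sample(DNA_BASES, L, replace = TRUE, prob = config$background)
    seq_s <- paste(bg, collapse = "")
    p_inj <- if (labels[s] == 1L) config$p_inject_pos else config$p_inject_neg
    for (k in seq_along(pwms)) {
      if (stats::runif(1) < p_inj) {
        inst <- sample_motif(pwms[[k]])
        rc_flag <- stats::runif(1) < 0.5
        pos <- sample.int(L - lens[k] + 1L, 1L) - 1L   # 0-based
        seq_s <- inject(seq_s, inst, pos, rc_flag)
        nlog <- nlog + 1L
        if (nlog > length(log_seq)) {  # grow
          log_seq <- c(log_seq, integer(cap)); log_pwm <- c(log_pwm, character(cap))
          log_pos <- c(log_pos, integer(cap)); log_str <- c(log_str, character(cap))
          log_ins <- c(log_ins, character(cap))
        }
        log_seq[nlog] <- s; log_pwm[nlog] <- pwm_names[k]
        log_pos[nlog] <- pos; log_str[nlog] <- if (rc_flag) "-" else "+"
        log_ins[nlog] <- inst
      }
    }
    seqs[s] <- seq_s
  }
  ds <- labeled_dataset(seqs, labels, ids = paste0("seq", seq_len(n)))
  keep <- seq_len(nlog)
  attr(ds, "injection_log") <- data.frame(
    seq_id = paste0("seq", log_seq[keep]), pwm = log_pwm[keep],
    position = log_pos[keep], strand = log_str[keep],
    instance = log_ins[keep], stringsAsFactors = FALSE)
  ds
}

#' Bundled toy PWMs
#'
#' Two synthetic motifs used by tests and examples in place of external
#' database matrices: a sharp (near point-mass) 10-mer and a degenerate
#' 8-mer. The JASPAR reader loads real matrices when users supply them.
#'
#' @param sharpness Probability mass on the consensus base of the sharp
#'   motif's columns.
#' @return Named list with elements \code{sharp10} and \code{degen8}.
#' @export
toy_pwms <- function(sharpness = 0.97) {
  off <- (1 - sharpness) / 3
  cons <- strsplit("ACGGTAGCAT", "")[[1]]
  sharp <- vapply(cons, function(b) {
    col <- rep(off, 4L); col[match(b, DNA_BASES)] <- sharpness; col
  }, numeric(4L))
  degen <- cbind(
    c(0.55, 0.15, 0.15, 0.15),
    c(0.10, 0.60, 0.15, 0.15),
    c(0.25, 0.25, 0.25, 0.25),
    c(0.15, 0.15, 0.55, 0.15),
    c(0.15, 0.55, 0.15, 0.15),
    c(0.25, 0.25, 0.25, 0.25),
    c(0.15, 0.15, 0.15, 0.55),
    c(0.55, 0.15, 0.15, 0.15))
  list(sharp10 = pwm(sharp, name = "sharp10"),
       degen8 = pwm(degen, name = "degen8"))
}

#' Write a simulated dataset to disk
#'
#' FASTA of sequences, a two-column TSV of (id, label), and the injection
#' log as a TSV.
#'
#' @param data An \code{rcnet_dataset}.
#' @param prefix Output path prefix; writes \code{<prefix>.fasta},
#'   \code{<prefix>_labels.tsv} and (when present)
#'   \code{<prefix>_injections.tsv}.
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(data, prefix) {
  fa <- paste0(prefix, ".fasta")
  write_fasta(stats::setNames(data$sequences, data$ids), fa)
  lab <- paste0(prefix, "_labels.tsv")
  utils::write.table(data.frame(id = data$ids, label = data$labels),
                     lab, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(fa, lab)
  il <- attr(data, "injection_log")
  if (!is.null(il) && nrow(il) > 0L) {
    inj <- paste0(prefix, "_injections.tsv")
    utils::write.table(il, inj, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, inj)
  }
  invisible(out)
}

#' Read a dataset written by \code{write_dataset}
#'
#' @param fasta Path to the FASTA file.
#' @param labels Path to the (id, label) TSV.
#' @return An \code{rcnet_dataset}.
#' @export
read_dataset <- function(fasta, labels) {
  seqs <- read_fasta(fasta)
  lab <- utils::read.table(labels, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  m <- match(names(seqs), lab$id)
  if (anyNA(m)) stop("label file is missing ids present in the FASTA")
  labeled_dataset(unname(seqs), lab$label[m], ids = names(seqs))
}
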