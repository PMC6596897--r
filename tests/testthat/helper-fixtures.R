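# Shared fixtures: random sequences, tiny datasets, toy genomes.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small simulated dataset split into train/test halves
sim_fixture <- function(n = 400, len = 100, p_pos = 0.8, p_neg = 0.1,
                        seed = 7, sharpness = 0.97) {
  pw <- toy_pwms(sharpness = sharpness)
  ds <- simulate_dataset(
    sim_config(n_sequences = n, seq_length = len,
               p_inject_pos = p_pos, p_inject_neg = p_neg),
    unname(pw), seed = seed)
  half <- n %/% 2
  list(pwms = pw,
       train = labeled_dataset(ds$sequences[1:half], ds$labels[1:half]),
       test = labeled_dataset(ds$sequences[(half + 1):n],
                              ds$labels[(half + 1):n]),
       full = ds)
}

# a toy single-contig genome with a known hot region
toy_genome <- function(len = 20000, seed = 3) {
  set.seed(seed)
  stats::setNames(random_dna(len), "chrT")
}

# brute-force Viterbi oracle: enumerate all 2^n state paths
brute_force_viterbi <- function(rates, params) {
  n <- length(rates)
  r <- pmax(rates, 1e-6)
  em <- cbind(stats::dexp(r, 1 / params$mean_hot, log = TRUE),
              stats::dexp(r, 1 / params$mean_cold, log = TRUE))
  logA <- log(params$transitions)
  logpi <- log(params$initial)
  best_ll <- -Inf; best_path <- NULL
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[seq_len(n)] + 1L
    ll <- logpi[path[1]] + sum(em[cbind(seq_len(n), path)])
    if (n > 1) ll <- ll + sum(logA[cbind(path[-n], path[-1])])
    if (ll > best_ll) { best_ll <- ll; best_path <- path }
  }
  list(path = best_path, loglik = best_ll)
}

# brute-force degenerate motif counter (independent of scan_count's regex)
brute_force_scan <- function(seq, motif, both_strands = TRUE) {
  match_at <- function(s, p, i) {
    sub <- substr(s, i, i + nchar(p) - 1L)
    all(mapply(function(a, b) b == "N" || a == b,
               strsplit(sub, "")[[1]], strsplit(p, "")[[1]]))
  }
  L <- nchar(seq); lp <- nchar(motif)
  if (L < lp) return(0L)
  n <- 0L
  rcm <- rc_seq(motif)
  for (i in seq_len(L - lp + 1L)) {
    hit <- match_at(seq, motif, i)
    if (both_strands) hit <- hit || match_at(seq, rcm, i)
    n <- n + hit
  }
  as.integer(n)
}
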