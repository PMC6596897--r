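test_that("viterbi decodes obvious tracks correctly", {
  par <- hmm2_params(10, 0.5)
  # all-zero (floored) rates decode entirely not-hot
  tr <- rate_track("c", seq(0, 9000, 1000), seq(1000, 10000, 1000), rep(0, 10))
  expect_true(all(viterbi(tr, par) == 2L))
  # a single window at the hot mean decodes hot
  tr1 <- rate_track("c", 0, 1000, 10)
  expect_equal(as.integer(viterbi(tr1, par)), 1L)
  expect_error(viterbi(tr1[0, ], par), "empty")
})

test_that("viterbi agrees with brute-force path enumeration", {
  set.seed(60)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    mh <- runif(1, 2, 20); mc <- runif(1, 0.05, 1)
    a <- runif(1, 0.6, 0.99); b <- runif(1, 0.6, 0.99)
    par <- hmm2_params(mh, mc,
                       transitions = matrix(c(a, 1 - a, 1 - b, b), 2,
                                            byrow = TRUE),
                       initial = c(0.4, 0.6))
    rates <- rexp(n, 1 / sample(c(mh, mc), n, replace = TRUE))
    tr <- rate_track("c", (0:(n - 1)) * 1000, (1:n) * 1000, rates)
    got <- viterbi(tr, par)
    oracle <- brute_force_viterbi(rates, par)
    expect_equal(attr(got, "loglik"), oracle$loglik, tolerance = 1e-9)
    expect_equal(as.integer(got), oracle$path)
  }
})

test_that("viterbi training recovers simulated parameters", {
  true <- hmm2_params(10.5, 0.5,
                      transitions = matrix(c(0.99, 0.01, 0.01, 0.99), 2,
                                           byrow = TRUE))
  sim <- simulate_rate_track(true, 1e4, seed = 61)
  fit <- viterbi_train(sim$track, hmm2_params(5, 1))
  expect_lt(abs(fit$mean_hot - 10.5) / 10.5, 0.10)
  expect_lt(abs(fit$mean_cold - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit$transitions[1, 1] - 0.99), 0.02)
  expect_lt(abs(fit$transitions[2, 2] - 0.99), 0.02)
  # decoded path mostly matches the truth
  expect_gt(mean(attr(fit, "path") == sim$path), 0.95)
})

test_that("viterbi training is a fixed point at the truth and handles one-state data", {
  true <- hmm2_params(10.5, 0.5,
                      transitions = matrix(c(0.99, 0.01, 0.01, 0.99), 2,
                                           byrow = TRUE))
  sim <- simulate_rate_track(true, 5e3, seed = 62)
  fit <- viterbi_train(sim$track, true, max_iter = 1)
  expect_lt(abs(fit$mean_hot - true$mean_hot) / true$mean_hot, 0.05)
  expect_lt(abs(fit$mean_cold - true$mean_cold) / true$mean_cold, 0.05)
  # single-state track: constant path, one mean equals the sample mean
  one <- hmm2_params(8, 0.1, transitions = matrix(c(1, 0, 1, 0), 2,
                                                  byrow = TRUE),
                     initial = c(1, 0))
  sim1 <- simulate_rate_track(one, 500, seed = 63)
  expect_true(all(sim1$path == 1L))
  fit1 <- suppressMessages(viterbi_train(sim1$track, hmm2_params(8, 0.1)))
  path1 <- attr(fit1, "path")
  expect_equal(length(unique(path1)), 1L)
  expect_equal(fit1$mean_hot, mean(pmax(sim1$track$rate, 1e-6)),
               tolerance = 1e-6)
})

test_that("viterbi training does not decrease the joint path likelihood", {
  set.seed(64)
  true <- hmm2_params(12, 0.4,
                      transitions = matrix(c(0.95, 0.05, 0.02, 0.98), 2,
                                           byrow = TRUE))
  sim <- simulate_rate_track(true, 2000, seed = 65)
  params <- hmm2_params(3, 1.5)
  prev <- -Inf
  for (it in 1:8) {
    params <- viterbi_train(sim$track, params, max_iter = 1)
    ll <- attr(viterbi(sim$track, params), "loglik")
    expect_gte(ll, prev - 1e-8)
    prev <- ll
  }
})

test_that("call_hotspots merges runs of hot windows", {
  tr <- rate_track("c", (0:5) * 1000, (1:6) * 1000, c(9, 9, 0, 0, 9, 0))
  hs <- call_hotspots(c(1L, 1L, 2L, 2L, 1L, 2L), tr)
  expect_equal(nrow(hs), 2)
  expect_equal(hs$start, c(0, 4000))
  expect_equal(hs$length_bp, c(2000, 1000))
  expect_equal(nrow(call_hotspots(rep(2L, 6), tr)), 0)
  # alternating states: one interval per hot window
  alt <- call_hotspots(rep(c(1L, 2L), 3), tr)
  expect_equal(nrow(alt), 3)
  expect_true(all(alt$length_bp == 1000))
})

test_that("extract_center applies the length filter and centre window", {
  genome <- toy_genome(12000)
  iv <- data.frame(chrom = "chrT",
                   start = c(1000, 2000, 5000),
                   end = c(6001, 4000, 5100))  # 5001 bp interval dropped
  out <- extract_center(iv, genome, max_len = 4000, out_len = 1000)
  expect_equal(nrow(out), 2)
  expect_true(all(nchar(out$seq) == 1000))
  # a 2000 bp interval yields exactly its middle 1000 bp
  expect_equal(out$start[1], 2500)
  expect_identical(out$seq[1], substr(genome[["chrT"]], 2501, 3500))
  expect_false(any(grepl("N", out$seq)))
  # windows containing N are dropped
  gN <- genome
  substr(gN[["chrT"]], 3000, 3000) <- "N"
  outN <- extract_center(iv[2, ], gN, out_len = 1000)
  expect_equal(nrow(outN), 0)
  # windows running off the contig are dropped with a warning
  expect_warning(extract_center(data.frame(chrom = "chrT", start = 0,
                                           end = 400), genome),
                 "contig end")
})

test_that("match_coldspot returns the nearest window satisfying all constraints", {
  set.seed(66)
  genome <- toy_genome(30000, seed = 67)
  # zero-rate track everywhere: rate constraint trivially satisfied
  tr <- rate_track("chrT", seq(0, 29000, 1000), seq(1000, 30000, 1000),
                   rep(0, 30))
  hot_iv <- data.frame(chrom = "chrT", start = 10000, end = 11000)
  hw <- extract_center(hot_iv, genome, out_len = 1000)
  cs <- match_coldspot(hw[1, ], genome, tr, hot_intervals = hot_iv,
                       gc_tol = 1.0)
  expect_false(is.null(cs))
  expect_equal(cs$end - cs$start, 1000)
  expect_lt(cs$rate, 0.5)
  expect_lt(abs(cs$gc - gc_content(hw$seq[1])), 1.0)
  # no overlap with the hot interval
  expect_true(cs$end <= hot_iv$start || cs$start >= hot_iv$end)
  # all candidates too hot: no coldspot
  hot_tr <- rate_track("chrT", seq(0, 29000, 1000), seq(1000, 30000, 1000),
                       rep(5, 30))
  expect_null(match_coldspot(hw[1, ], genome, hot_tr,
                             hot_intervals = hot_iv, gc_tol = 1.0))
  # impossible rate ceiling: no coldspot
  expect_null(match_coldspot(hw[1, ], genome, tr, hot_intervals = hot_iv,
                             gc_tol = 1.0, rate_max = 0))
})

test_that("coldspots never overlap hot intervals over random toy genomes", {
  set.seed(68)
  for (rep in 1:25) {
    genome <- stats::setNames(random_dna(8000), "chrT")
    tr <- rate_track("chrT", seq(0, 7000, 1000), seq(1000, 8000, 1000),
                     runif(8, 0, 0.4))
    s0 <- sample(seq(1000, 6000, 500), 1)
    hot_iv <- data.frame(chrom = "chrT", start = s0, end = s0 + 1000)
    hw <- extract_center(hot_iv, genome, out_len = 1000)
    cs <- match_coldspot(hw[1, ], genome, tr, hot_intervals = hot_iv,
                         search_radius = 8000, gc_tol = 0.10)
    if (!is.null(cs)) {
      expect_true(cs$end <= hot_iv$start || cs$start >= hot_iv$end)
      expect_lte(abs(cs$gc - gc_content(hw$seq[1])), 0.10)
      expect_lt(cs$rate, 0.5)
    }
  }
})

test_that("relative GC tolerance is supported", {
  genome <- toy_genome(20000, seed = 69)
  tr <- rate_track("chrT", seq(0, 19000, 1000), seq(1000, 20000, 1000),
                   rep(0, 20))
  hot_iv <- data.frame(chrom = "chrT", start = 9000, end = 10000)
  hw <- extract_center(hot_iv, genome, out_len = 1000)
  cs_rel <- match_coldspot(hw[1, ], genome, tr, hot_intervals = hot_iv,
                           gc_tol = 0.10, relative_gc = TRUE)
  if (!is.null(cs_rel)) {
    gc_hot <- gc_content(hw$seq[1])
    expect_lte(abs(cs_rel$gc - gc_hot), 0.10 * gc_hot)
  }
})

test_that("simulate_rate_track honours parameters and seeds", {
  par <- hmm2_params(10, 0.5,
                     transitions = matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                     initial = c(1, 0))
  sim <- simulate_rate_track(par, 200, seed = 70)
  expect_true(all(sim$path == 1L))  # absorbing hot state
  # empirical hot mean within 3 SE
  par2 <- hmm2_params(10, 0.5)
  sim2 <- simulate_rate_track(par2, 3000, seed = 71)
  hot_rates <- sim2$track$rate[sim2$path == 1L]
  se <- 10 / sqrt(length(hot_rates))
  expect_lt(abs(mean(hot_rates) - 10), 3 * se)
  sim3 <- simulate_rate_track(par2, 3000, seed = 71)
  expect_identical(sim2$track$rate, sim3$track$rate)
})

test_that("rate track disk round trip", {
  tr <- rate_track(c("c1", "c1", "c2"), c(0, 1000, 0), c(1000, 2000, 500),
                   c(0.5, 9.25, 0))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_rate_track(tr, tmp)
  back <- read_rate_track(tmp)
  expect_equal(back$rate, tr$rate)
  expect_equal(back$start, tr$start)
  expect_error(rate_track("c", c(0, 500), c(1000, 1500), c(1, 1)),
               "overlapping")
  expect_error(rate_track("c", 0, 1000, -1), "non-negative")
})
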