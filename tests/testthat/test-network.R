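small_cfg <- function(...) {
  args <- utils::modifyList(list(n_f = 8L, f_l = 6L, epochs = 3L,
                                 batch_size = 32L), list(...))
  do.call(network_config, args)
}

test_that("build_model applies the custom output initialization", {
  m <- build_model(small_cfg(), seed = 4)
  expect_true(all(m$Wd == 1))
  expect_equal(m$bd, c(1, -1))
  m2 <- build_model(small_cfg(), seed = 4)
  expect_identical(m$W, m2$W)
  expect_error(network_config(n_f = 7L), "even")
})

test_that("forward produces a probability pair and exact RC invariance", {
  set.seed(20)
  m <- build_model(small_cfg(), seed = 9)
  for (i in 1:20) {
    s <- random_dna(60)
    p <- forward(m, s)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(forward(m, rc_seq(s))), unname(p), tolerance = 1e-6)
  }
})

test_that("a non-equivariant model generally breaks RC invariance", {
  m <- build_model(small_cfg(equivariant = FALSE), seed = 2)
  set.seed(21)
  # a fresh model has identical dense rows (scores differ by a constant), so
  # perturb them to expose the asymmetric convolution features
  m$Wd <- m$Wd + matrix(rnorm(length(m$Wd)), nrow = 2)
  gaps <- vapply(1:20, function(i) {
    s <- random_dna(60)
    abs(forward(m, s)[2] - forward(m, rc_seq(s))[2])
  }, numeric(1))
  expect_gt(max(gaps), 1e-6)
})

test_that("training reduces loss, preserves weight ties, and learns a planted motif", {
  fx <- sim_fixture(n = 800, len = 150, p_pos = 1.0, p_neg = 0.0,
                    seed = 31, sharpness = 0.9999)
  cfg <- network_config(epochs = 30L)
  m <- train(build_model(cfg, seed = 1), fx$full, seed = 1)
  bank <- symmetrize(m$W, m$b)
  expect_true(is_tied_bank(bank$W, bank$b, exact = TRUE))
  lh <- attr(m, "loss_history")
  expect_lt(lh[length(lh)], lh[1])
  acc <- mean((predict_weight_avg(m, fx$full) > 0.5) == (fx$full$labels == 1))
  expect_gt(acc, 0.95)
})

test_that("zero learning rate leaves parameters unchanged", {
  fx <- sim_fixture(n = 64, len = 40, seed = 5)
  m0 <- build_model(small_cfg(), seed = 3)
  m1 <- train(m0, fx$train, epochs = 2, lr = 0, seed = 1)
  expect_identical(m0$W, m1$W)
  expect_identical(m0$Wd, m1$Wd)
})

test_that("gradients match finite differences on a tiny model", {
  # independent oracle for the hand-derived backward pass
  fx <- sim_fixture(n = 16, len = 30, seed = 8)
  for (eqv in c(TRUE, FALSE)) {
    cfg <- network_config(n_f = 4L, f_l = 3L, equivariant = eqv,
                          keep_p = 1, l2 = 0.01)
    m <- build_model(cfg, seed = 6)
    m$Wd <- m$Wd + matrix(rnorm(length(m$Wd), sd = 0.3), nrow = 2)
    Xb <- rcnets:::.onehot_batch(fx$train$sequences)
    y <- fx$train$labels
    loss_of <- function(model) {
      P <- rcnets:::.net_forward(model, Xb)
      -mean(log(P[cbind(y + 1L, seq_along(y))])) +
        cfg$l2 * (sum(model$W^2) + sum(model$Wd^2))
    }
    cc <- rcnets:::.net_forward(m, Xb, cache = TRUE)
    gr <- rcnets:::.net_backward(m, cc, y)
    eps <- 1e-6
    for (k in sample(length(m$W), 5)) {
      mp <- m; mp$W[k] <- mp$W[k] + eps
      mm <- m; mm$W[k] <- mm$W[k] - eps
      expect_equal(gr$dW[k], (loss_of(mp) - loss_of(mm)) / (2 * eps),
                   tolerance = 1e-4)
    }
    for (k in seq_along(m$Wd)) {
      mp <- m; mp$Wd[k] <- mp$Wd[k] + eps
      mm <- m; mm$Wd[k] <- mm$Wd[k] - eps
      expect_equal(gr$dWd[k], (loss_of(mp) - loss_of(mm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("predict_mc degenerates to forward at keep_p = 1 and is RC-symmetric", {
  fx <- sim_fixture(n = 40, len = 50, seed = 12)
  m1 <- build_model(small_cfg(keep_p = 1), seed = 2)
  expect_equal(predict_mc(m1, fx$test, K = 4, seed = 1),
               predict_weight_avg(m1, fx$test))
  m <- build_model(small_cfg(), seed = 2)
  s <- fx$test$sequences[1:10]
  p <- predict_mc(m, s, K = 16, seed = 5)
  prc <- predict_mc(m, vapply(s, rc_seq, character(1), USE.NAMES = FALSE),
                    K = 16, seed = 5)
  expect_equal(p, prc, tolerance = 1e-6)
})

test_that("predict_mc variance across mask seeds shrinks roughly as 1/K", {
  fx <- sim_fixture(n = 30, len = 50, seed = 13)
  m <- build_model(small_cfg(), seed = 4)
  s <- fx$test$sequences[1]
  var_at <- function(K) {
    stats::var(vapply(1:30, function(r) predict_mc(m, s, K = K, seed = r),
                      numeric(1)))
  }
  v1 <- var_at(1); v10 <- var_at(10); v100 <- var_at(100)
  expect_gt(v1, v10)
  expect_gt(v10, v100)
  expect_lt(v100, v1 / 10)  # ~1/K scaling, with slack
})

test_that("weight averaging differs from MC averaging on a dropout model", {
  fx <- sim_fixture(n = 60, len = 50, seed = 14)
  m <- train(build_model(small_cfg(), seed = 3), fx$train, seed = 3)
  pm <- predict_mc(m, fx$test, K = 8, seed = 2)
  pw <- predict_weight_avg(m, fx$test)
  expect_gt(max(abs(pm - pw)), 0)
  expect_true(all(pw >= 0 & pw <= 1))
})

test_that("augmentation doubles the dataset preserving labels", {
  fx <- sim_fixture(n = 20, len = 40, seed = 15)
  aug <- augment_dataset(fx$train)
  n <- length(fx$train$sequences)
  expect_length(aug$sequences, 2 * n)
  expect_identical(aug$labels, rep(fx$train$labels, 2))
  expect_identical(aug$sequences[n + 1],
                   rc_seq(fx$train$sequences[1]))
  expect_length(augment_dataset(aug)$sequences, 4 * n)
})

test_that("a non-equivariant model trained on augmented data is only approximately invariant", {
  fx <- sim_fixture(n = 200, len = 60, p_pos = 0.9, p_neg = 0.1, seed = 16)
  cfg <- small_cfg(equivariant = FALSE, epochs = 5L)
  m <- train(build_model(cfg, seed = 1), augment_dataset(fx$train), seed = 1)
  gaps <- vapply(fx$test$sequences[1:30], function(s)
    abs(forward(m, s)[2] - forward(m, rc_seq(s))[2]), numeric(1))
  expect_gt(max(gaps), 1e-6)  # not exactly invariant, unlike equivariant nets
})

test_that("auroc follows the midrank convention", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  s <- c(0.3, 0.7, 0.5, 0.6)
  y <- c(0, 1, 0, 1)
  expect_equal(auroc(s, y), 1 - auroc(-s, y))
  expect_error(auroc(c(0.5, 0.6), c(1, 1)), "both classes")
  # random scores, large n: close to 1/2
  set.seed(30)
  expect_lt(abs(auroc(runif(1e4), rbinom(1e4, 1, 0.5)) - 0.5), 0.02)
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- c(rnorm(50), rnorm(50, 1)); yy <- rep(0:1, each = 50)
  expect_equal(auroc(sc, yy),
               as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE))))
})

test_that("prediction_consistency emits one correlation per run pair", {
  runs <- lapply(1:3, function(i) c(0.1, 0.5, 0.9) + i / 100)
  pc <- prediction_consistency(runs)
  expect_equal(nrow(pc), 3)
  expect_equal(pc$correlation, rep(1, 3))
  ident <- replicate(5, c(0.2, 0.4, 0.8), simplify = FALSE)
  expect_equal(prediction_consistency(ident)$correlation, rep(1, 10))
  const <- list(c(1, 1, 1), c(0.2, 0.5, 0.8))
  expect_true(is.na(prediction_consistency(const)$correlation))
  expect_error(prediction_consistency(list(1:3)), "two runs")
})

test_that("model serialization round-trips bit-exactly", {
  fx <- sim_fixture(n = 64, len = 40, seed = 17)
  m <- train(build_model(small_cfg(), seed = 5), fx$train, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_identical(m2$W, m$W)
  expect_identical(m2$b, m$b)
  expect_identical(m2$Wd, m$Wd)
  expect_identical(m2$bd, m$bd)
  s <- fx$test$sequences[1]
  expect_identical(forward(m2, s), forward(m, s))
})

test_that("fixed seeds give bit-identical models and predictions", {
  fx <- sim_fixture(n = 64, len = 40, seed = 18)
  m1 <- train(build_model(small_cfg(), seed = 7), fx$train, seed = 7)
  m2 <- train(build_model(small_cfg(), seed = 7), fx$train, seed = 7)
  expect_identical(m1$W, m2$W)
  expect_identical(predict_mc(m1, fx$test, K = 4, seed = 9),
                   predict_mc(m2, fx$test, K = 4, seed = 9))
})
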