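# Trainable reverse-complement (RC) equivariant classifiers.
#
# The model family is a single convolutional block:
#   conv (tied weights if equivariant) -> [dropout] -> [RC orbit pool]
#     -> spatial max pool -> global spatial max -> dense(2) -> softmax
# which contains every construction of the layer algebra. Because a global
# spatial maximum follows the spatial pool, the pool may use a partial final
# window without changing the composite map (maxpool then global max equals
# global max), so arbitrary sequence lengths are accepted.
#
# Equivariance is enforced by reparameterization: only the free half of the
# filter bank is stored and the full tied bank is rebuilt on every forward
# pass, so the weight symmetry holds bitwise after every optimizer step.

#' Network configuration
#'
#' Declares the layer stack and training hyperparameters. The default is the
#' reference architecture used throughout the package: conv(n_f = 16,
#' f_l = 12, ELU), equivariant dropout (keep_p = 0.7), RC orbit max-pooling,
#' spatial max-pool (p_l = 8), global spatial max, dense(2) with the custom
#' output initialization, softmax.
#'
#' @param n_f Number of convolution filters (must be even).
#' @param f_l Filter length in bases.
#' @param activation Activation after the convolution: "elu", "relu",
#'   "srelu".
#' @param equivariant Tie the filter bank and pool over RC orbits so the
#'   classifier is exactly RC-symmetric.
#' @param bayesian Keep dropout active (Monte Carlo dropout) rather than
#'   training-only.
#' @param keep_p Dropout keep probability in (0, 1]; 1 disables dropout.
#' @param dropout_position "pre_orbit" (between conv and orbit pool) or
#'   "post_orbit".
#' @param orbit_mode RC orbit pooling reduction: "max", "sum" or "avg".
#' @param p_l Spatial pool width.
#' @param l2 L2 penalty coefficient on free convolution and dense weights
#'   (not biases).
#' @param mc_samples Default number K of Monte Carlo dropout samples.
#' @param lr Learning rate for mini-batch gradient descent.
#' @param momentum Heavy-ball momentum coefficient (0 = plain SGD).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @return An object of class \code{rcnet_config}.
#' @export
network_config <- function(n_f = 16L, f_l = 12L, activation = "elu",
                           equivariant = TRUE, bayesian = TRUE,
                           keep_p = 0.7, dropout_position = "pre_orbit",
                           orbit_mode = "max", p_l = 8L, l2 = 1e-4,
                           mc_samples = 16L, lr = 0.2, momentum = 0,
                           batch_size = 64L, epochs = 10L) {
  if (n_f %% 2L != 0L)
    stop("n_f must be even: RC weight tying pairs filters with their flips")
  if (keep_p <= 0 || keep_p > 1) stop("keep_p must be in (0, 1]")
  if (p_l < 1L) stop("p_l must be >= 1")
  if (l2 < 0) stop("l2 must be non-negative")
  if (mc_samples < 1L) stop("mc_samples must be >= 1")
  dropout_position <- match.arg(dropout_position, c("pre_orbit", "post_orbit"))
  orbit_mode <- match.arg(orbit_mode, c("max", "sum", "avg"))
  activation <- match.arg(activation, c("elu", "relu", "srelu"))
  layers <- list(
    list(kind = "conv", n_f = n_f, f_l = f_l, activation = activation,
         tied = equivariant))
  if (keep_p < 1 && dropout_position == "pre_orbit")
    layers <- c(layers, list(list(kind = "dropout", keep_p = keep_p,
                                  equivariant = equivariant)))
  if (equivariant)
    layers <- c(layers, list(list(kind = "rc_orbit_pool", mode = orbit_mode)))
  if (keep_p < 1 && dropout_position == "post_orbit")
    layers <- c(layers, list(list(kind = "dropout", keep_p = keep_p,
                                  equivariant = FALSE)))
  layers <- c(layers,
              list(list(kind = "spatial_pool", p_l = p_l),
                   list(kind = "global_max"),
                   list(kind = "dense", units = 2L),
                   list(kind = "softmax")))
  structure(list(n_f = as.integer(n_f), f_l = as.integer(f_l),
                 activation = activation, equivariant = isTRUE(equivariant),
                 bayesian = isTRUE(bayesian), keep_p = keep_p,
                 dropout_position = dropout_position, orbit_mode = orbit_mode,
                 p_l = as.integer(p_l), l2 = l2,
                 mc_samples = as.integer(mc_samples), lr = lr,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), layers = layers),
            class = "rcnet_config")
}

#' @export
print.rcnet_config <- function(x, ...) {
  cat("rcnet_config:",
      if (x$equivariant) "equivariant" else "non-equivariant",
      if (x$bayesian) "Bayesian (MC dropout)" else "deterministic", "\n")
  for (l in x$layers)
    cat("  -", l$kind,
        paste(sprintf("%s=%s", setdiff(names(l), "kind"),
                      unlist(l[setdiff(names(l), "kind")])), collapse = " "),
        "\n")
  invisible(x)
}

#' Build a fresh model
#'
#' Hidden convolution weights use a scaled normal initialization
#' (sd = sqrt(2 / (4 f_l))); the final dense layer uses the custom output
#' initialization: all weights exactly 1 and the two biases exactly (1, -1),
#' which empirically sits close to the optimum for two-class sequence
#' problems and speeds convergence. Equivariant configs allocate only the
#' free half of the filter bank.
#'
#' @param config An \code{rcnet_config}.
#' @param seed Integer seed; two builds with the same seed are
#'   parameter-identical.
#' @return An object of class \code{rcnet_model}.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "rcnet_config"))
  set.seed(seed)
  n_store <- if (config$equivariant) config$n_f %/% 2L else config$n_f
  sd0 <- sqrt(2 / (4 * config$f_l))
  W <- array(stats::rnorm(4L * config$f_l * n_store, sd = sd0),
             dim = c(4L, config$f_l, n_store))
  b <- numeric(n_store)
  h_dense <- if (config$equivariant) config$n_f %/% 2L else config$n_f
  Wd <- matrix(1, nrow = 2L, ncol = h_dense)
  bd <- c(1, -1)
  structure(list(W = W, b = b, Wd = Wd, bd = bd, config = config,
                 seed = as.integer(seed), trained_epochs = 0L),
            class = "rcnet_model")
}

# realized (possibly tied) filter bank
.bank <- function(model) {
  if (model$config$equivariant) symmetrize(model$W, model$b)
  else list(W = model$W, b = model$b)
}

# one-hot a character vector of equal-length sequences into [4, L, B]
.onehot_batch <- function(seqs) {
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("sequences must have equal length")
  B <- length(seqs)
  codes <- match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), DNA_BASES)
  if (anyNA(codes)) stop("sequences must contain only A, C, G, T")
  X <- array(0, dim = c(4L, L, B))
  pos <- rep(seq_len(L), times = B)
  bb <- rep(seq_len(B), each = L)
  X[cbind(codes, pos, bb)] <- 1
  X
}

# row indices mapping a flattened [4, L] sequence onto im2col order
.im2col_index <- function(L, f_l) {
  L1 <- L - f_l + 1L
  m <- rep(seq_len(4L), times = f_l)
  n <- rep(seq_len(f_l), each = 4L)
  base <- m + 4L * (n - 1L)                     # within-window offsets
  as.vector(outer(base, 4L * (seq_len(L1) - 1L), `+`))
}

# forward pass on a batch; returns probabilities and (optionally) the cache
# needed for backprop. mask: NULL or rcnet_mask on the dropout layer.
.net_forward <- function(model, Xb, mask = NULL, cache = FALSE) {
  cfg <- model$config
  d <- dim(Xb); L <- d[2]; B <- d[3]
  f_l <- cfg$f_l; n_f <- cfg$n_f
  L1 <- L - f_l + 1L
  if (L1 < 1L) stop("sequences shorter than the filter length")
  bank <- .bank(model)
  Wmat <- matrix(bank$W, nrow = 4L * f_l, ncol = n_f)
  ridx <- .im2col_index(L, f_l)
  Xmat <- matrix(Xb, nrow = 4L * L, ncol = B)
  Xc <- matrix(Xmat[ridx, , drop = FALSE], nrow = 4L * f_l, ncol = L1 * B)
  Z <- crossprod(Wmat, Xc) + bank$b                   # [n_f, L1*B]
  A <- activate(Z, cfg$activation)
  dim(A) <- c(n_f, L1, B)
  has_drop <- !is.null(mask)
  pre_drop <- has_drop && cfg$dropout_position == "pre_orbit"
  D <- A
  if (pre_drop) D <- D * as.vector(mask$eps) / mask$keep_p
  if (cfg$equivariant) {
    h <- n_f %/% 2L
    Dflip <- D[rev(seq_len(n_f)), rev(seq_len(L1)), , drop = FALSE]
    Atop <- D[seq_len(h), , , drop = FALSE]
    Abot <- Dflip[seq_len(h), , , drop = FALSE]
    O <- switch(cfg$orbit_mode,
                max = pmax(Atop, Abot),
                sum = Atop + Abot,
                avg = (Atop + Abot) / 2)
    h2 <- h
  } else {
    O <- D
    h2 <- n_f
  }
  if (has_drop && cfg$dropout_position == "post_orbit")
    O <- O * as.vector(mask$eps) / mask$keep_p
  # spatial pool (partial windows) followed by global max == global max
  Om <- matrix(aperm(O, c(2L, 1L, 3L)), nrow = L1)    # cols ordered (i, b)
  Om <- t(Om)                                         # [(h2*B), L1]
  jmax <- max.col(Om, ties.method = "first")
  g <- Om[cbind(seq_len(nrow(Om)), jmax)]
  G <- matrix(g, nrow = h2, ncol = B)
  S <- model$Wd %*% G + model$bd                      # [2, B]
  S <- sweep(S, 2L, apply(S, 2L, max))
  E <- exp(S)
  P <- sweep(E, 2L, colSums(E), "/")
  if (!cache) return(P)
  list(P = P, Xc = Xc, Z = Z, A = A, D = D, O = O, G = G, jmax = jmax,
       mask = mask, L1 = L1, B = B, h2 = h2)
}

# backward pass: gradients of mean cross-entropy (+ L2) wrt stored params
.net_backward <- function(model, cc, y) {
  cfg <- model$config
  n_f <- cfg$n_f; B <- cc$B; L1 <- cc$L1; h2 <- cc$h2
  Y <- rbind(1 - y, y)                                # row 2 = class 1
  dS <- (cc$P - Y) / B
  dWd <- unname(tcrossprod(dS, cc$G)) + 2 * cfg$l2 * model$Wd
  dbd <- unname(rowSums(dS))
  dG <- crossprod(model$Wd, dS)                       # [h2, B]
  dO <- array(0, dim = c(h2, L1, B))
  ib <- seq_len(h2 * B)                               # row order of Om: i fastest
  lin <- rep(seq_len(h2), B) +
    h2 * ((cc$jmax - 1L) + L1 * (rep(seq_len(B), each = h2) - 1L))
  dO[lin] <- as.vector(dG)[ib]
  mask <- cc$mask
  if (!is.null(mask) && cfg$dropout_position == "post_orbit")
    dO <- dO * as.vector(mask$eps) / mask$keep_p
  if (cfg$equivariant) {
    h <- n_f %/% 2L
    Dflip <- cc$D[rev(seq_len(n_f)), rev(seq_len(L1)), , drop = FALSE]
    Atop <- cc$D[seq_len(h), , , drop = FALSE]
    Abot <- Dflip[seq_len(h), , , drop = FALSE]
    if (cfg$orbit_mode == "max") {
      win <- Atop >= Abot
      dtop <- dO * win
      dbot <- dO * !win
    } else if (cfg$orbit_mode == "sum") {
      dtop <- dO; dbot <- dO
    } else {
      dtop <- dO / 2; dbot <- dO / 2
    }
    dD <- array(0, dim = c(n_f, L1, B))
    dD[seq_len(h), , ] <- dtop
    dD[seq(h + 1L, n_f), , ] <- dbot[rev(seq_len(h)), rev(seq_len(L1)), , drop = FALSE]
  } else {
    dD <- dO
  }
  if (!is.null(mask) && cfg$dropout_position == "pre_orbit")
    dD <- dD * as.vector(mask$eps) / mask$keep_p
  dZ <- dD
  dim(dZ) <- c(n_f, L1 * B)
  dZ <- dZ * .activate_grad(cc$Z, cfg$activation)
  dWmat <- tcrossprod(cc$Xc, dZ)                      # [4*f_l, n_f]
  db <- rowSums(dZ)
  dW <- array(dWmat, dim = c(4L, cfg$f_l, n_f))
  if (cfg$equivariant) {
    gr <- .symmetrize_grad(dW, db)
    dW <- gr$dW_free + 2 * cfg$l2 * model$W
    db <- gr$db_free
  } else {
    dW <- dW + 2 * cfg$l2 * model$W
  }
  list(dW = dW, db = db, dWd = dWd, dbd = dbd)
}

#' Forward pass on a single sequence
#'
#' Deterministic when \code{masks} is \code{NULL} (dropout layers act as the
#' identity). For an equivariant model the output is identical (to floating
#' point) for a sequence and its reverse complement.
#'
#' @param model An \code{rcnet_model}.
#' @param X A \code{[4, N]} one-hot matrix or a DNA string.
#' @param masks Optional list with one \code{rcnet_mask} for the dropout
#'   layer.
#' @return Named probability pair \code{c(p0, p1)} summing to 1.
#' @export
forward <- function(model, X, masks = NULL) {
  if (is.character(X)) X <- one_hot_encode(X)
  Xb <- array(X, dim = c(4L, ncol(X), 1L))
  mask <- if (is.null(masks)) NULL else masks[[1]]
  P <- .net_forward(model, Xb, mask = mask)
  stats::setNames(as.vector(P), c("p0", "p1"))
}

#' Labeled sequence dataset
#'
#' @param sequences Character vector of equal-length DNA sequences.
#' @param labels Integer 0/1 vector, one per sequence.
#' @param ids Optional sequence identifiers.
#' @param split Optional per-record split tag ("train"/"test").
#' @return An object of class \code{rcnet_dataset}.
#' @export
labeled_dataset <- function(sequences, labels, ids = NULL, split = NULL) {
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) stop("one label per sequence")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(nchar(sequences))) > 1L)
    stop("sequences must have equal length")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  structure(list(sequences = toupper(sequences), labels = labels,
                 ids = ids, split = split), class = "rcnet_dataset")
}

#' @export
print.rcnet_dataset <- function(x, ...) {
  cat("rcnet_dataset:", length(x$sequences), "sequences of length",
      nchar(x$sequences[1]), "|", sum(x$labels == 1L), "positive\n")
  invisible(x)
}

#' Reverse-complement data augmentation
#'
#' Appends the reverse complement of every sequence with its original label,
#' doubling the dataset. This is the classical alternative to architectural
#' equivariance: strand symmetry must then be learned rather than being
#' guaranteed.
#'
#' @param data An \code{rcnet_dataset}.
#' @return The augmented \code{rcnet_dataset} (2n records).
#' @export
augment_dataset <- function(data) {
  stopifnot(inherits(data, "rcnet_dataset"))
  rc <- vapply(data$sequences, rc_seq, character(1), USE.NAMES = FALSE)
  labeled_dataset(c(data$sequences, rc), c(data$labels, data$labels),
                  ids = c(data$ids, paste0(data$ids, "_rc")),
                  split = if (is.null(data$split)) NULL
                          else c(data$split, data$split))
}

#' Train a model by mini-batch gradient descent
#'
#' Minimizes mean softmax cross-entropy plus the L2 penalty on free
#' convolution and dense weights. When the config is Bayesian, a fresh
#' dropout mask (equivariant if configured) is sampled once per batch and
#' shared across the batch's examples. The weight symmetry of an equivariant
#' model holds bitwise after every update because only the free parameter
#' half is ever touched.
#'
#' @param model A fresh or previously trained \code{rcnet_model}.
#' @param data An \code{rcnet_dataset} used as the training split.
#' @param epochs,lr Optional overrides of the config values.
#' @param seed Seed for batch shuffling and mask sampling.
#' @param verbose Print per-epoch mean loss.
#' @return The trained model, with a \code{loss_history} attribute.
#' @export
train <- function(model, data, epochs = NULL, lr = NULL, seed = 1L,
                  verbose = FALSE) {
  stopifnot(inherits(model, "rcnet_model"), inherits(data, "rcnet_dataset"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  n <- length(data$sequences)
  if (n == 0L) stop("empty training set")
  set.seed(seed)
  Xall <- .onehot_batch(data$sequences)
  y <- data$labels
  bs <- min(cfg$batch_size, n)
  use_drop <- cfg$bayesian && cfg$keep_p < 1
  L1 <- dim(Xall)[2] - cfg$f_l + 1L
  mshape <- if (cfg$equivariant && cfg$dropout_position == "post_orbit")
    c(cfg$n_f %/% 2L, L1) else c(cfg$n_f, L1)
  vel <- list(dW = model$W * 0, db = model$b * 0,
              dWd = model$Wd * 0, dbd = model$bd * 0)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[seq.int(start, min(start + bs - 1L, n))]
      Xb <- Xall[, , idx, drop = FALSE]
      mask <- if (use_drop)
        sample_mask(mshape, cfg$keep_p,
                    equivariant = cfg$equivariant &&
                      cfg$dropout_position == "pre_orbit") else NULL
      cc <- .net_forward(model, Xb, mask = mask, cache = TRUE)
      pb <- cc$P[cbind(y[idx] + 1L, seq_along(idx))]
      loss <- -mean(log(pmax(pb, 1e-12)))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      gr <- .net_backward(model, cc, y[idx])
      for (p in names(vel)) vel[[p]] <- cfg$momentum * vel[[p]] + gr[[p]]
      model$W <- model$W - lr * vel$dW
      model$b <- model$b - lr * vel$db
      model$Wd <- model$Wd - lr * vel$dWd
      model$bd <- model$bd - lr * vel$dbd
    }
    losses[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d  mean loss %.4f", ep, losses[ep]))
  }
  model$trained_epochs <- model$trained_epochs + epochs
  attr(model, "loss_history") <- losses
  model
}

# chunked deterministic forward over many sequences
.predict_batched <- function(model, seqs, mask = NULL, chunk = 512L) {
  n <- length(seqs)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- seq.int(start, min(start + chunk - 1L, n))
    Xb <- .onehot_batch(seqs[idx])
    out[idx] <- .net_forward(model, Xb, mask = mask)[2L, ]
  }
  out
}

#' Monte Carlo dropout prediction
#'
#' Approximates the posterior predictive by averaging K stochastic forward
#' passes, each with its own dropout mask. All K masks are sampled up front
#' and shared across test sequences, so the predictive function is a fixed
#' deterministic function of the input; with equivariant masks it is exactly
#' RC-symmetric.
#'
#' @param model A trained \code{rcnet_model} (warns if not Bayesian).
#' @param data An \code{rcnet_dataset} or character vector of sequences.
#' @param K Number of Monte Carlo samples (>= 1).
#' @param seed Seed for mask sampling.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_mc <- function(model, data, K = NULL, seed = 1L) {
  cfg <- model$config
  K <- as.integer(K %||% cfg$mc_samples)
  if (K < 1L) stop("K must be >= 1")
  if (!cfg$bayesian)
    warning("model was not configured as Bayesian; MC dropout prediction ",
            "is averaging masks the model never trained with")
  seqs <- if (inherits(data, "rcnet_dataset")) data$sequences else data
  if (cfg$keep_p >= 1) return(.predict_batched(model, seqs))
  L1 <- nchar(seqs[1]) - cfg$f_l + 1L
  mshape <- if (cfg$equivariant && cfg$dropout_position == "post_orbit")
    c(cfg$n_f %/% 2L, L1) else c(cfg$n_f, L1)
  set.seed(seed)
  masks <- lapply(seq_len(K), function(k)
    sample_mask(mshape, cfg$keep_p,
                equivariant = cfg$equivariant &&
                  cfg$dropout_position == "pre_orbit"))
  acc <- numeric(length(seqs))
  for (m in masks) acc <- acc + .predict_batched(model, seqs, mask = m)
  acc / K
}

#' Weight-averaging (conventional dropout) prediction
#'
#' A single deterministic forward pass with no dropout masks: the test-time
#' behaviour of conventional dropout, provided for comparison against Monte
#' Carlo averaging.
#'
#' @param model An \code{rcnet_model}.
#' @param data An \code{rcnet_dataset} or character vector.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_weight_avg <- function(model, data) {
  seqs <- if (inherits(data, "rcnet_dataset")) data$sequences else data
  .predict_batched(model, seqs)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param predictions Numeric scores (higher = more class 1).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(predictions, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(predictions)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise prediction consistency between training runs
#'
#' Pearson correlation of hold-out predictions for every unordered pair of
#' runs; R runs give R(R-1)/2 correlations (50 runs give 1225). A constant
#' prediction vector makes the correlation undefined and is reported as NA
#' for the affected pairs.
#'
#' @param runs List (length >= 2) of equal-length prediction vectors.
#' @return Data frame with columns \code{run_a}, \code{run_b},
#'   \code{correlation}.
#' @export
prediction_consistency <- function(runs) {
  R <- length(runs)
  if (R < 2L) stop("need at least two runs")
  len <- unique(lengths(runs))
  if (length(len) != 1L) stop("prediction vectors must have equal length")
  pairs <- utils::combn(R, 2L)
  corr <- apply(pairs, 2L, function(p)
    suppressWarnings(stats::cor(runs[[p[1]]], runs[[p[2]]])))
  data.frame(run_a = pairs[1L, ], run_b = pairs[2L, ], correlation = corr)
}

#' Save / load a model as a JSON archive
#'
#' The archive stores the configuration and all parameter arrays at full
#' (17 significant digit) precision, so a save/load round trip is bit-exact.
#'
#' @param model An \code{rcnet_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", as.vector(x))  # exact double round trip
  obj <- list(
    config = unclass(model$config)[setdiff(names(model$config), "layers")],
    W = list(dim = dim(model$W), values = num(model$W)),
    b = num(model$b),
    Wd = list(dim = dim(model$Wd), values = num(model$Wd)),
    bd = num(model$bd),
    seed = model$seed, trained_epochs = model$trained_epochs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$config[
    intersect(names(obj$config), names(formals(network_config)))])
  structure(list(
    W = array(as.numeric(obj$W$values), dim = obj$W$dim),
    b = as.numeric(obj$b),
    Wd = matrix(as.numeric(obj$Wd$values), nrow = obj$Wd$dim[1],
                ncol = obj$Wd$dim[2]),
    bd = as.numeric(obj$bd),
    config = cfg, seed = as.integer(obj$seed),
    trained_epochs = as.integer(obj$trained_epochs)), class = "rcnet_model")
}

#' @export
print.rcnet_model <- function(x, ...) {
  cat("rcnet_model (", if (x$config$equivariant) "equivariant"
      else "non-equivariant", ", ",
      if (x$config$bayesian) "Bayesian" else "deterministic",
      "), trained ", x$trained_epochs, " epochs\n", sep = "")
  invisible(x)
}
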