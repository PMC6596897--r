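# Layer algebra for reverse-complement equivariant networks.
#
# Conventions (all documented against paper-style 1-based index formulas):
# a convolution bank is an array W[4, f_l, n_f] with channel m, filter
# position n, filter index i, plus a bias vector b[n_f]. The RC weight
# symmetry W[m,n,i] = W[5-m, f_l+1-n, n_f+1-i] (and b[i] = b[n_f+1-i]) makes
# the convolution equivariant: conv(rc_input(X)) == rc_hidden(conv(X)).

.flip_filter <- function(Wf) {
  # double flip of one [4, f_l] filter: channel axis and position axis
  Wf[rev(seq_len(nrow(Wf))), rev(seq_len(ncol(Wf))), drop = FALSE]
}

#' Expand free convolution parameters into a tied filter bank
#'
#' A bank of \code{n_f} filters with the RC weight symmetry has only
#' \code{n_f / 2} free filters: filter \code{n_f + 1 - i} is the
#' channel-and-position flip of filter \code{i}, and biases are mirrored.
#' Storing the free half and symmetrizing on every forward pass keeps the
#' weight tie exact after every gradient update, by construction.
#'
#' @param W_free Array \code{[4, f_l, n_f/2]} of free filters.
#' @param b_free Numeric vector of length \code{n_f/2} of free biases.
#' @return A list with the full tied \code{W} \code{[4, f_l, n_f]} and
#'   \code{b} \code{[n_f]}.
#' @export
symmetrize <- function(W_free, b_free) {
  d <- dim(W_free)
  if (length(d) != 3L || d[1] != 4L) stop("W_free must be [4, f_l, n_f/2]")
  h <- d[3]
  if (h < 1L) stop("need at least one free filter")
  if (length(b_free) != h) stop("b_free length must match free filter count")
  n_f <- 2L * h
  W <- array(0, dim = c(4L, d[2], n_f))
  W[, , seq_len(h)] <- W_free
  for (i in seq_len(h))
    W[, , n_f + 1L - i] <- .flip_filter(matrix(W_free[, , i], 4L, d[2]))
  b <- c(b_free, rev(b_free))
  list(W = W, b = b)
}

# gradient of symmetrize: fold a gradient on the full bank back onto the free half
.symmetrize_grad <- function(dW, db) {
  n_f <- dim(dW)[3]
  h <- n_f %/% 2L
  f_l <- dim(dW)[2]
  dWf <- dW[, , seq_len(h), drop = FALSE]
  for (i in seq_len(h)) {
    dWf[, , i] <- matrix(dWf[, , i], 4L, f_l) +
      .flip_filter(matrix(dW[, , n_f + 1L - i], 4L, f_l))
  }
  dbf <- db[seq_len(h)] + rev(db[seq(h + 1L, n_f)])
  list(dW_free = dWf, db_free = dbf)
}

#' Check the RC weight symmetry of a filter bank
#'
#' @param W Array \code{[4, f_l, n_f]}.
#' @param b Bias vector \code{[n_f]}.
#' @param exact If \code{TRUE}, require bitwise identity.
#' @return \code{TRUE} when \code{W[m,n,i] == W[5-m, f_l+1-n, n_f+1-i]} and
#'   \code{b[i] == b[n_f+1-i]} for all indices.
#' @export
is_tied_bank <- function(W, b, exact = TRUE) {
  n_f <- dim(W)[3]
  Wr <- W[rev(seq_len(4L)), rev(seq_len(dim(W)[2])), rev(seq_len(n_f)), drop = FALSE]
  wok <- if (exact) identical(as.numeric(W), as.numeric(Wr)) else
    isTRUE(all.equal(as.numeric(W), as.numeric(Wr)))
  bok <- if (exact) identical(as.numeric(b), as.numeric(rev(b))) else
    isTRUE(all.equal(as.numeric(b), as.numeric(rev(b))))
  wok && bok
}

#' Elementwise activation functions
#'
#' \code{relu(z) = max(0, z)}; \code{elu(z) = z} for \code{z > 0} and
#' \code{exp(z) - 1} otherwise; \code{srelu(z) = max(z, -1)}, the shifted
#' ReLU. ELU and SReLU avoid the hard sparsity of ReLU, which tends to stall
#' convergence on shallow genomic networks.
#'
#' @param T_ Numeric vector/matrix/array.
#' @param kind One of \code{"relu"}, \code{"elu"}, \code{"srelu"},
#'   \code{"identity"}.
#' @return Tensor of the same shape.
#' @export
activate <- function(T_, kind = c("elu", "relu", "srelu", "identity")) {
  kind <- match.arg(kind)
  switch(kind,
    relu = pmax(T_, 0),
    elu = ifelse(T_ > 0, T_, exp(pmin(T_, 0)) - 1),
    srelu = pmax(T_, -1),
    identity = T_
  )
}

# derivative of the activation given the pre-activation Z
.activate_grad <- function(Z, kind) {
  switch(kind,
    relu = (Z > 0) * 1,
    elu = ifelse(Z > 0, 1, exp(pmin(Z, 0))),
    srelu = (Z > -1) * 1,
    identity = array(1, dim = dim(Z) %||% length(Z))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Valid-padding 1D convolution over a one-hot (or hidden) tensor
#'
#' Computes \code{C(X)[i, j] = f(sum_{m,n} X[m, j+n-1] W[m, n, i] + b[i])}
#' with valid padding and stride 1, so a length-\code{N} input yields
#' \code{N - f_l + 1} output positions. When \code{W} carries the RC weight
#' symmetry, \code{conv1d_valid(rc_input(X))} equals
#' \code{rc_hidden(conv1d_valid(X))} up to floating-point summation order.
#'
#' @param X Input matrix \code{[C_in, N]}.
#' @param W Filter array \code{[C_in, f_l, n_f]}.
#' @param b Bias vector \code{[n_f]} (default zeros).
#' @param activation Activation kind (see \code{\link{activate}}).
#' @return Matrix \code{[n_f, N - f_l + 1]}.
#' @export
conv1d_valid <- function(X, W, b = NULL, activation = "identity") {
  d <- dim(W)
  c_in <- d[1]; f_l <- d[2]; n_f <- d[3]
  if (nrow(X) != c_in) stop("channel dimension mismatch")
  N <- ncol(X)
  if (N < f_l) stop("sequence shorter than filter")
  if (is.null(b)) b <- numeric(n_f)
  L1 <- N - f_l + 1L
  Wmat <- matrix(W, nrow = c_in * f_l, ncol = n_f)  # column i = filter i
  Xc <- .im2col(X, f_l)                             # [c_in*f_l, L1]
  Z <- crossprod(Wmat, Xc) + b                      # [n_f, L1]
  activate(Z, activation)
}

# im2col: column j stacks X[, j:(j+f_l-1)] in (channel, filter-position) order
.im2col <- function(X, f_l) {
  c_in <- nrow(X); N <- ncol(X); L1 <- N - f_l + 1L
  pos <- outer(seq_len(f_l), seq_len(L1) - 1L, `+`)      # [f_l, L1] column index
  ridx <- rep(seq_len(c_in), times = f_l * L1)
  cidx <- rep(as.vector(pos), each = c_in)
  matrix(X[cbind(ridx, cidx)], nrow = c_in * f_l, ncol = L1)
}

#' Non-overlapping spatial max-pooling
#'
#' \code{MP(X)[i, j] = max_k X[i, k]} over windows of width \code{p_l} with
#' stride equal to the pool width. With \code{p_l} dividing \code{L} this is
#' RC-equivariant; \code{partial = TRUE} allows a shorter final window, which
#' is safe (and used by the network) only downstream of RC orbit pooling,
#' where RC already acts as the identity.
#'
#' @param T_ Matrix \code{[C, L]}.
#' @param p_l Pool width (= stride), \code{>= 1}.
#' @param partial Allow a final window shorter than \code{p_l}.
#' @return Matrix \code{[C, ceiling(L / p_l)]} (or \code{L / p_l} windows).
#' @export
spatial_max_pool <- function(T_, p_l, partial = FALSE) {
  if (p_l < 1L) stop("p_l must be >= 1")
  L <- ncol(T_)
  if (!partial && L %% p_l != 0L)
    stop("pool width ", p_l, " does not divide spatial length ", L)
  nw <- as.integer(ceiling(L / p_l))
  out <- matrix(-Inf, nrow = nrow(T_), ncol = nw)
  for (j in seq_len(nw)) {
    cols <- seq.int((j - 1L) * p_l + 1L, min(j * p_l, L))
    out[, j] <- do.call(pmax, lapply(cols, function(k) T_[, k]))
  }
  out
}

#' Pooling over reverse-complement orbits of the filter axis
#'
#' Reduces each RC orbit \code{{(i, j), (C+1-i, L+1-j)}} with max, sum or
#' mean, keeping filter indices \code{1..C/2}:
#' \code{M(X)[i, j] = reduce(X[i, j], X[C+1-i, L+1-j])}. The output tensor is
#' half the size and RC acts on it as the identity, so any downstream layer
#' is automatically RC-invariant.
#'
#' @param T_ Matrix \code{[C, L]} with even \code{C}.
#' @param mode One of \code{"max"}, \code{"sum"}, \code{"avg"}.
#' @return Matrix \code{[C/2, L]}.
#' @export
rc_orbit_pool <- function(T_, mode = c("max", "sum", "avg")) {
  mode <- match.arg(mode)
  C <- nrow(T_)
  if (C %% 2L != 0L) stop("filter dimension must be even for RC orbit pooling")
  h <- C %/% 2L
  A <- T_[seq_len(h), , drop = FALSE]
  Bm <- rc_hidden(T_)[seq_len(h), , drop = FALSE]  # partner entries T[C+1-i, L+1-j]
  switch(mode,
    max = pmax(A, Bm),
    sum = A + Bm,
    avg = (A + Bm) / 2
  )
}

#' Sample a dropout mask
#'
#' Entries are Bernoulli(\code{keep_p}) indicators. In equivariant mode one
#' indicator is drawn per RC orbit \code{{(i, j), (C+1-i, L+1-j)}} and copied
#' to both members, so the mask satisfies \code{eps == rc_hidden(eps)}
#' exactly and dropout commutes with the RC action.
#'
#' @param shape Integer vector \code{c(C, L)}.
#' @param keep_p Keep probability in \code{(0, 1]} (the Bernoulli parameter:
#'   a unit is kept, not dropped, with this probability).
#' @param equivariant Draw one indicator per RC orbit.
#' @return A list of class \code{rcnet_mask} with elements \code{eps}
#'   (\code{[C, L]} 0/1 matrix) and \code{keep_p}.
#' @export
sample_mask <- function(shape, keep_p, equivariant = FALSE) {
  if (keep_p <= 0 || keep_p > 1) stop("keep_p must be in (0, 1]")
  C <- shape[1]; L <- shape[2]
  if (equivariant) {
    if (C %% 2L != 0L) stop("equivariant masks require an even filter dimension")
    h <- C %/% 2L
    top <- matrix(stats::rbinom(h * L, 1L, keep_p), nrow = h, ncol = L)
    # row C+1-i, column L+1-j copies the orbit representative at (i, j)
    eps <- rbind(top, top[rev(seq_len(h)), rev(seq_len(L)), drop = FALSE])
  } else {
    eps <- matrix(stats::rbinom(C * L, 1L, keep_p), nrow = C, ncol = L)
  }
  structure(list(eps = eps, keep_p = keep_p), class = "rcnet_mask")
}

#' Apply a dropout mask
#'
#' Elementwise product with the 0/1 mask, rescaled by \code{1 / keep_p}
#' (inverted-dropout convention) so that \code{keep_p = 1} is exactly the
#' identity and expected activations are scale-stable between training and
#' prediction passes.
#'
#' @param T_ Tensor matching the mask shape.
#' @param mask An \code{rcnet_mask} from \code{\link{sample_mask}}.
#' @return Masked, rescaled tensor.
#' @export
apply_dropout <- function(T_, mask) {
  if (!identical(dim(T_)[1:2], dim(mask$eps)[1:2]))
    stop("mask shape does not match tensor shape")
  T_ * mask$eps / mask$keep_p
}
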