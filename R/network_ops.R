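# Reference implementations of the network's building blocks, one instance at
# a time: 1D valid convolution, an LSTM cell, 2D valid convolution, and the
# CBAM channel/spatial attention gates. These define the semantics that the
# batched training engine (network_engine.R) reproduces; they are also the
# user-facing way to inspect individual layers.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' 1D convolution over a sequence of feature vectors
#'
#' `y[i, f] = act( sum_j W[j, , f] . X[i + j - 1, ] + b[f] )`, valid
#' convolution: the output has `nrow(X) - m + 1` positions for kernel
#' width `m`.
#'
#' @param X Numeric matrix, positions x features (a plain vector is treated
#'   as positions x 1).
#' @param W Kernel array `m x d x F` (or a matrix `m x d` for a single
#'   filter, or a length-m vector for scalar features).
#' @param b Bias, one per filter (recycled scalar allowed).
#' @param act Activation function applied elementwise (default [relu]).
#' @return Numeric matrix, `(nrow(X) - m + 1)` x F.
#' @export
#' @examples
#' conv1d_forward(c(1, 2, 3), c(1, 1), b = 0, act = identity) # 3, 5
conv1d_forward <- function(X, W, b = 0, act = relu) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(W)) W <- array(W, dim = c(length(W), 1L, 1L))
  if (is.matrix(W)) W <- array(W, dim = c(dim(W), 1L))
  m <- dim(W)[1]; d <- dim(W)[2]; nf <- dim(W)[3]
  if (d != ncol(X)) stop("kernel feature dimension does not match input", call. = FALSE)
  if (m > nrow(X)) stop("kernel width exceeds input length", call. = FALSE)
  b <- rep_len(b, nf)
  P <- nrow(X) - m + 1L
  out <- matrix(0, P, nf)
  for (f in seq_len(nf)) {
    for (i in seq_len(P)) {
      out[i, f] <- sum(W[, , f] * X[i:(i + m - 1L), , drop = FALSE]) + b[f]
    }
  }
  act(out)
}

#' Rectified linear activation
#' @param x Numeric input.
#' @return `pmax(x, 0)`.
#' @export
relu <- function(x) pmax(x, 0)

#' One LSTM cell step
#'
#' Implements the standard gated recurrence on the concatenated
#' `[h_prev, x]` input:
#' forget `f = sigmoid(W_f [h, x] + b_f)`, input `i`, output `o` analogously,
#' candidate `g = tanh(W_c [h, x] + b_c)`, cell `C = f * C_prev + i * g`,
#' hidden `h = o * tanh(C)`.
#'
#' @param x Input vector at this step.
#' @param h_prev,C_prev Previous hidden and cell state vectors (length H).
#' @param params List with matrices `W_f`, `W_i`, `W_o`, `W_c`
#'   (each `H x (H + length(x))`, acting on `c(h_prev, x)`) and bias vectors
#'   `b_f`, `b_i`, `b_o`, `b_c` (length H).
#' @return List of class `lstm_state`: gates `f`, `i`, `o` in (0,1),
#'   candidate `g` in (-1,1), cell `C`, hidden `h`.
#' @export
lstm_step <- function(x, h_prev, C_prev, params) {
  z <- c(h_prev, x)
  H <- length(h_prev)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) {
    Wm <- params[[nm]]
    if (!is.matrix(Wm) || nrow(Wm) != H || ncol(Wm) != length(z)) {
      stop(sprintf("%s must be %d x %d", nm, H, length(z)), call. = FALSE)
    }
  }
  f <- .sigmoid(drop(params$W_f %*% z) + params$b_f)
  i <- .sigmoid(drop(params$W_i %*% z) + params$b_i)
  o <- .sigmoid(drop(params$W_o %*% z) + params$b_o)
  g <- tanh(drop(params$W_c %*% z) + params$b_c)
  C <- f * C_prev + i * g
  h <- o * tanh(C)
  structure(list(f = f, i = i, o = o, g = g, C = C, h = h),
            class = "lstm_state")
}

#' 2D convolution of a matrix with a single kernel
#'
#' `y[i, j] = act( sum_{k,l} w[k, l] * x[i + k - 1, j + l - 1] + b )`,
#' valid convolution.
#'
#' @param x Input matrix.
#' @param w Kernel matrix (K x L), `K <= nrow(x)`, `L <= ncol(x)`.
#' @param b Scalar bias.
#' @param act Activation function (default [relu]).
#' @return Matrix of dimension `(nrow(x)-K+1) x (ncol(x)-L+1)`.
#' @export
conv2d_forward <- function(x, w, b = 0, act = relu) {
  K <- nrow(w); L <- ncol(w)
  if (K > nrow(x) || L > ncol(x)) {
    stop("kernel exceeds input dimensions", call. = FALSE)
  }
  P <- nrow(x) - K + 1L; Q <- ncol(x) - L + 1L
  out <- matrix(0, P, Q)
  for (i in seq_len(P)) for (j in seq_len(Q)) {
    out[i, j] <- sum(w * x[i:(i + K - 1L), j:(j + L - 1L)]) + b
  }
  act(out)
}

#' CBAM channel attention
#'
#' `Mc = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))` where the pools are
#' global over all spatial positions of each channel and the two pooled
#' vectors share one two-layer MLP (ReLU hidden).
#'
#' @param F Feature map array `channels x height x width`.
#' @param params List with `W1` (C x hidden), `b1`, `W2` (hidden x C), `b2`.
#'   `NULL` (default) uses an identity MLP, i.e. `Mc = sigmoid(avg + max)`.
#' @return Numeric vector of per-channel weights, each in (0, 1).
#' @export
cbam_channel_attention <- function(F, params = NULL) {
  stopifnot(length(dim(F)) == 3, all(dim(F) > 0))
  C <- dim(F)[1]
  avg <- apply(F, 1, mean)
  mx  <- apply(F, 1, max)
  mlp <- function(v) {
    if (is.null(params)) return(v)
    h <- relu(drop(v %*% params$W1) + params$b1)
    drop(h %*% params$W2) + params$b2
  }
  .sigmoid(mlp(avg) + mlp(mx))
}

#' CBAM spatial attention
#'
#' `Ms = sigmoid(Conv([AvgPool(F); MaxPool(F)]))`: the pools run across the
#' channel dimension, the two pooled maps are stacked as a 2-channel image
#' and convolved with a single kernel, zero-padded to preserve shape.
#'
#' @inheritParams cbam_channel_attention
#' @param params List with `w` (kernel array `k x k x 2`, k odd, default 7x7
#'   when omitted sizes come from the kernel itself) and scalar `b`.
#' @return Matrix `height x width` of weights, each in (0, 1).
#' @export
cbam_spatial_attention <- function(F, params) {
  stopifnot(length(dim(F)) == 3, all(dim(F) > 0))
  Hh <- dim(F)[2]; Ww <- dim(F)[3]
  avg <- apply(F, c(2, 3), mean)
  mx  <- apply(F, c(2, 3), max)
  w <- params$w
  if (is.matrix(w)) w <- array(rep(w, 2), dim = c(dim(w), 2L))
  k1 <- dim(w)[1]; k2 <- dim(w)[2]
  stopifnot(k1 %% 2 == 1, k2 %% 2 == 1)
  p1 <- (k1 - 1L) %/% 2L; p2 <- (k2 - 1L) %/% 2L
  padm <- function(m) {
    out <- matrix(0, Hh + 2 * p1, Ww + 2 * p2)
    out[p1 + seq_len(Hh), p2 + seq_len(Ww)] <- m
    out
  }
  pa <- padm(avg); pm <- padm(mx)
  out <- matrix(0, Hh, Ww)
  for (i in seq_len(Hh)) for (j in seq_len(Ww)) {
    out[i, j] <- sum(w[, , 1] * pa[i:(i + k1 - 1L), j:(j + k2 - 1L)]) +
                 sum(w[, , 2] * pm[i:(i + k1 - 1L), j:(j + k2 - 1L)]) +
                 params$b
  }
  .sigmoid(out)
}

#' Apply CBAM to a feature map
#'
#' Channel attention first (`F1 = Mc * F`, broadcast over positions), then
#' spatial attention on the reweighted map (`F2 = Ms(F1) * F1`, broadcast
#' over channels). Because both gates are sigmoids, the output is an
#' elementwise contraction of the input.
#'
#' @inheritParams cbam_channel_attention
#' @param params List with elements `channel` (see
#'   [cbam_channel_attention()]) and `spatial` (see
#'   [cbam_spatial_attention()]).
#' @return Array with the same dimensions as `F`.
#' @export
cbam_apply <- function(F, params) {
  Mc <- cbam_channel_attention(F, params$channel)
  F1 <- F * Mc # channel-first layout: dim 1 fastest, so Mc recycles per channel
  Ms <- cbam_spatial_attention(F1, params$spatial)
  F2 <- F1
  for (c in seq_len(dim(F)[1])) F2[c, , ] <- F1[c, , ] * Ms
  F2
}
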