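# Independent scalar-arithmetic oracles for the network equations and the
# ranking metrics. Everything here is written as plainly as possible (loops
# over scalars, exhaustive enumeration) and never calls the implementation
# it checks.

sigmoid_scalar <- function(x) 1 / (1 + exp(-x))

# y_i = act(sum_j W_j . X_{i+j} + b), one filter, scalar loops
oracle_conv1d <- function(X, W, b, act = function(z) max(z, 0)) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(W)) W <- matrix(W, ncol = 1)
  m <- nrow(W)
  out <- numeric(nrow(X) - m + 1)
  for (i in seq_along(out)) {
    acc <- b
    for (j in seq_len(m)) {
      for (d in seq_len(ncol(X))) acc <- acc + W[j, d] * X[i + j - 1, d]
    }
    out[i] <- act(acc)
  }
  out
}

oracle_conv2d <- function(x, w, b, act = function(z) max(z, 0)) {
  K <- nrow(w); L <- ncol(w)
  out <- matrix(0, nrow(x) - K + 1, ncol(x) - L + 1)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    acc <- b
    for (k in seq_len(K)) for (l in seq_len(L)) {
      acc <- acc + w[k, l] * x[i + k - 1, j + l - 1]
    }
    out[i, j] <- act(acc)
  }
  out
}

# One LSTM step evaluated element by element on c(h_prev, x)
oracle_lstm <- function(x, h_prev, C_prev, params) {
  z <- c(h_prev, x)
  H <- length(h_prev)
  gate <- function(W, b, squash) {
    out <- numeric(H)
    for (r in seq_len(H)) {
      acc <- b[r]
      for (c in seq_along(z)) acc <- acc + W[r, c] * z[c]
      out[r] <- squash(acc)
    }
    out
  }
  f <- gate(params$W_f, params$b_f, sigmoid_scalar)
  i <- gate(params$W_i, params$b_i, sigmoid_scalar)
  o <- gate(params$W_o, params$b_o, sigmoid_scalar)
  g <- gate(params$W_c, params$b_c, tanh)
  C <- f * C_prev + i * g
  list(f = f, i = i, o = o, g = g, C = C, h = o * tanh(C))
}

oracle_cbam_channel <- function(F, params = NULL) {
  C <- dim(F)[1]
  out <- numeric(C)
  mlp <- function(v) {
    if (is.null(params)) return(v)
    h <- pmax(as.vector(v %*% params$W1) + params$b1, 0)
    as.vector(h %*% params$W2) + params$b2
  }
  avg <- sapply(seq_len(C), function(c) mean(F[c, , ]))
  mx <- sapply(seq_len(C), function(c) max(F[c, , ]))
  sigmoid_scalar(mlp(avg) + mlp(mx))
}

oracle_cbam_spatial <- function(F, w, b) {
  Hh <- dim(F)[2]; Ww <- dim(F)[3]
  k1 <- dim(w)[1]; k2 <- dim(w)[2]
  p1 <- (k1 - 1) / 2; p2 <- (k2 - 1) / 2
  avg <- apply(F, c(2, 3), mean)
  mx <- apply(F, c(2, 3), max)
  out <- matrix(0, Hh, Ww)
  for (i in seq_len(Hh)) for (j in seq_len(Ww)) {
    acc <- b
    for (k in seq_len(k1)) for (l in seq_len(k2)) {
      ii <- i + k - 1 - p1; jj <- j + l - 1 - p2
      if (ii >= 1 && ii <= Hh && jj >= 1 && jj <= Ww) {
        acc <- acc + w[k, l, 1] * avg[ii, jj] + w[k, l, 2] * mx[ii, jj]
      }
    }
    out[i, j] <- sigmoid_scalar(acc)
  }
  out
}

# Exhaustive pairwise Mann-Whitney AUC
oracle_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg) {
    acc <- acc + (p > n) + 0.5 * (p == n)
  }
  acc / (length(pos) * length(neg))
}

# All-thresholds precision/recall step area, ties grouped
oracle_pr_auc <- function(labels, scores) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in th) {
    called <- scores >= t
    precision <- sum(labels[called] == 1) / sum(called)
    recall <- sum(labels[called] == 1) / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_top_k_ppv <- function(labels, scores, k) {
  m <- ceiling(k * length(labels))
  ord <- order(-scores)  # stable: ties keep input order
  mean(labels[ord[seq_len(m)]] == 1)
}

# Brute-force count of mutation windows of length L covering the altered
# region [p, alt_end] of a protein of length N
oracle_window_count <- function(N, p, L, alt_end = p) {
  n <- 0L
  for (s in seq_len(max(N - L + 1, 0))) {
    if (s <= alt_end && s + L - 1 >= p) n <- n + 1L
  }
  n
}

# A tiny pseudo-sequence table for unit tests
toy_pseudo <- function(alleles = c("A0101", "A0201", "B0702"), len = 6,
                       seed = 42) {
  set.seed(seed)
  stats::setNames(
    vapply(alleles, function(a)
      paste(sample(aa_alphabet, len, replace = TRUE), collapse = ""),
      character(1)),
    alleles)
}

# Deterministic stub scorer: hash-like but reproducible score per
# (peptide, allele) pair
stub_scorer <- function(seed = 1) {
  function(peptide, allele) {
    vapply(paste(peptide, allele), function(key) {
      set.seed(seed + sum(utf8ToInt(key)))
      stats::runif(1)
    }, numeric(1), USE.NAMES = FALSE)
  }
}
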