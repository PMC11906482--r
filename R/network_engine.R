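# Batched training engine for the hybrid network.
#
# Architecture (classification or regression head):
#   input: one-hot (T x 21) of middle-padded peptide + allele pseudo-sequence
#   branch A (always on): 2D conv (KxK, F2 filters, ReLU) on the T x 21
#     "image" -> 2x2 max pool -> CBAM (channel then spatial attention)
#     -> global average + max pooling per channel          (2*F2 features)
#   branch B (use_1dcnn_bilstm): 1D conv (width m, F1 filters, ReLU) over the
#     21-channel sequence -> BiLSTM, last hidden state of both directions
#                                                          (2*H features)
#   branch C (use_blosum): flattened BLOSUM62 encoding of the padded peptide
#     -> one dense ReLU layer                              (Db features)
#   fusion: concatenation -> dense ReLU -> linear output (sigmoid for
#   classification).
#
# All convolutions are implemented as im2col gathers + BLAS matrix products;
# the backward pass is hand-derived. Internal batched layouts are
# column-major with batch as the fastest dimension.

#' Network / training configuration
#'
#' Returns a validated configuration list. Defaults follow the published
#' training setup (AdamW, learning rate 1e-4, cosine-annealing schedule with
#' `t_max = 30`, 30 epochs, batch size 40000 for class I and 20000 for
#' class II); layer sizes are configurable since the architecture description
#' leaves them open. See [tiny_config()] for CPU desk-scale defaults.
#'
#' @param mode `"class1"` or `"class2"`; sets `max_pep_len` (14 / 21) and the
#'   default batch size.
#' @param task `"regression"` (IC50 score target, MSE loss) or
#'   `"classification"` (binary label, weighted cross-entropy).
#' @param use_cbam,use_1dcnn_bilstm,use_blosum Ablation toggles for the CBAM
#'   attention block, the 1D-CNN + BiLSTM branch, and the BLOSUM62 skip
#'   connection.
#' @param conv1d_filters,conv1d_width 1D convolution size.
#' @param conv1d_pool Temporal max-pool width (= stride) between the 1D
#'   convolution and the BiLSTM; 1 disables pooling.
#' @param conv2d_filters,conv2d_kernel 2D convolution size (square kernel).
#' @param conv2d_stride Stride of the 2D convolution in both image
#'   dimensions (1 = dense valid convolution; 2 halves the feature map and
#'   roughly quarters the compute).
#' @param lstm_hidden LSTM hidden units per direction.
#' @param cbam_reduction Channel-attention MLP reduction ratio.
#' @param cbam_spatial_kernel Spatial-attention convolution size (odd).
#' @param blosum_dense Width of the BLOSUM62 skip dense layer.
#' @param onehot_dense Width of the dense layer on the flattened one-hot
#'   pair encoding that is merged into the fusion vector alongside the
#'   branch outputs (position-resolved skip connection; this is what lets
#'   the head learn peptide-position x allele interactions).
#' @param mlp_hidden Width of the fusion hidden layer.
#' @param max_pep_len Padded peptide length; `NULL` = by mode.
#' @param learning_rate,epochs,t_max,batch_size,weight_decay AdamW / schedule
#'   settings.
#' @param seed Integer seed governing initialisation and batch order.
#' @return A list of class `model_config`.
#' @export
model_config <- function(mode = c("class1", "class2"),
                         task = c("classification", "regression"),
                         use_cbam = TRUE, use_1dcnn_bilstm = TRUE,
                         use_blosum = TRUE,
                         conv1d_filters = 64, conv1d_width = 3,
                         conv1d_pool = 1,
                         conv2d_filters = 32, conv2d_kernel = 3,
                         conv2d_stride = 1,
                         lstm_hidden = 64, cbam_reduction = 8,
                         cbam_spatial_kernel = 7, blosum_dense = 64,
                         onehot_dense = 64, mlp_hidden = 64,
                         max_pep_len = NULL,
                         learning_rate = 1e-4, epochs = 30, t_max = 30,
                         batch_size = NULL, weight_decay = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  task <- match.arg(task)
  if (is.null(max_pep_len)) max_pep_len <- if (mode == "class1") 14L else 21L
  if (is.null(batch_size)) batch_size <- if (mode == "class1") 40000L else 20000L
  cfg <- list(mode = mode, task = task,
              use_cbam = isTRUE(use_cbam),
              use_1dcnn_bilstm = isTRUE(use_1dcnn_bilstm),
              use_blosum = isTRUE(use_blosum),
              conv1d_filters = as.integer(conv1d_filters),
              conv1d_width = as.integer(conv1d_width),
              conv1d_pool = as.integer(conv1d_pool),
              conv2d_filters = as.integer(conv2d_filters),
              conv2d_kernel = as.integer(conv2d_kernel),
              conv2d_stride = as.integer(conv2d_stride),
              lstm_hidden = as.integer(lstm_hidden),
              cbam_reduction = as.integer(cbam_reduction),
              cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
              blosum_dense = as.integer(blosum_dense),
              onehot_dense = as.integer(onehot_dense),
              mlp_hidden = as.integer(mlp_hidden),
              max_pep_len = as.integer(max_pep_len),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              t_max = as.integer(t_max), batch_size = as.integer(batch_size),
              weight_decay = weight_decay, seed = as.integer(seed))
  sizes <- c(cfg$conv1d_filters, cfg$conv1d_width, cfg$conv2d_filters,
             cfg$conv2d_kernel, cfg$conv2d_stride, cfg$conv1d_pool,
             cfg$lstm_hidden,
             cfg$cbam_reduction,
             cfg$blosum_dense, cfg$onehot_dense, cfg$mlp_hidden,
             cfg$max_pep_len,
             cfg$epochs, cfg$t_max, cfg$batch_size)
  if (any(sizes <= 0)) stop("all sizes must be positive", call. = FALSE)
  if (cfg$cbam_spatial_kernel %% 2 == 0) {
    stop("cbam_spatial_kernel must be odd", call. = FALSE)
  }
  class(cfg) <- "model_config"
  cfg
}

#' Desk-scale configuration
#'
#' [model_config()] with small layer sizes, a larger learning rate, few
#' epochs and a small batch size, suitable for CPU-only runs on synthetic
#' data (tests, examples, the bundled pipelines).
#'
#' @param ... Overrides passed on to [model_config()].
#' @export
tiny_config <- function(...) {
  defaults <- list(conv1d_filters = 16, conv2d_filters = 8, lstm_hidden = 8,
                   cbam_reduction = 4, cbam_spatial_kernel = 3,
                   conv2d_stride = 2, conv1d_pool = 2,
                   blosum_dense = 12, onehot_dense = 32, mlp_hidden = 32,
                   learning_rate = 0.01, epochs = 6, t_max = 6,
                   batch_size = 256, weight_decay = 1e-4)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# Precomputed gather geometry for a given (T, A, config).
make_geometry <- function(config, pseudo_len) {
  A <- 21L
  T_len <- config$max_pep_len + as.integer(pseudo_len)
  m1 <- config$conv1d_width
  K <- config$conv2d_kernel
  if (m1 > T_len || K > T_len || K > A) {
    stop("convolution kernel exceeds input size", call. = FALSE)
  }
  P1 <- T_len - m1 + 1L
  # 2D conv on the T x A image (optionally strided), pos q = i + (j2-1)*H2
  st <- config$conv2d_stride
  H2 <- (T_len - K) %/% st + 1L
  W2 <- (A - K) %/% st + 1L
  P2 <- H2 * W2
  # 2x2 max pool
  Hp <- H2 %/% 2L
  Wp <- W2 %/% 2L
  if (Hp < 1L || Wp < 1L) stop("feature map too small for pooling", call. = FALSE)
  Pp <- Hp * Wp
  u <- rep(seq_len(Hp), Wp)
  v <- rep(seq_len(Wp), each = Hp)
  pool_s <- cbind((2L * u - 1L) + (2L * v - 2L) * H2,
                  (2L * u) + (2L * v - 2L) * H2,
                  (2L * u - 1L) + (2L * v - 1L) * H2,
                  (2L * u) + (2L * v - 1L) * H2)
  # CBAM spatial conv, 'same' padding on Hp x Wp grid with 2 channels
  ks <- config$cbam_spatial_kernel
  pd <- (ks - 1L) %/% 2L
  Hpad <- Hp + 2L * pd
  Wpad <- Wp + 2L * pd
  chan_off <- Hpad * Wpad
  interior <- as.vector(outer(pd + seq_len(Hp), (pd + seq_len(Wp) - 1L) * Hpad, "+"))
  ksq <- ks * ks
  sk <- rep(seq_len(ks), ks)
  sl <- rep(seq_len(ks), each = ks)
  spat <- matrix(0L, Pp, 2L * ksq)   # row q, col r -> padded flat index
  for (cix in 1:2) for (r in seq_len(ksq)) {
    spat[, (cix - 1L) * ksq + r] <-
      (u + sk[r] - 1L) + (v + sl[r] - 2L) * Hpad + (cix - 1L) * chan_off
  }
  list(A = A, T_len = T_len, P1 = P1,
       H2 = H2, W2 = W2, P2 = P2,
       Hp = Hp, Wp = Wp, Pp = Pp, pool_s = pool_s,
       ks = ks, pad_flat = 2L * chan_off, spat = spat, interior = interior,
       chan_off = chan_off)
}

.glorot <- function(nin, nout, n = nin * nout) {
  matrix(stats::rnorm(n, 0, sqrt(2 / (nin + nout))), nin, nout)
}

# Initialise all parameters for a config + pseudo-sequence length.
init_network <- function(config, pseudo_len, seed = config$seed) {
  set.seed(seed)
  geo <- make_geometry(config, pseudo_len)
  A <- geo$A
  F1 <- config$conv1d_filters
  F2 <- config$conv2d_filters
  H <- config$lstm_hidden
  K <- config$conv2d_kernel
  p <- list()
  p$conv2_W <- .glorot(K * K, F2)
  p$conv2_b <- numeric(F2)
  if (config$use_cbam) {
    rh <- max(1L, F2 %/% config$cbam_reduction)
    p$cbamc_W1 <- .glorot(F2, rh)
    p$cbamc_b1 <- numeric(rh)
    p$cbamc_W2 <- .glorot(rh, F2)
    p$cbamc_b2 <- numeric(F2)
    p$cbams_W <- .glorot(2L * geo$ks^2, 1L)
    p$cbams_b <- numeric(1L)
  }
  if (config$use_1dcnn_bilstm) {
    p$conv1_W <- .glorot(config$conv1d_width * A, F1)
    p$conv1_W[.pad_rows_1d(config$conv1d_width, A), ] <- 0
    p$conv1_b <- numeric(F1)
    for (dir in c("f", "b")) {
      p[[paste0("lstm", dir, "_Wx")]] <- .glorot(F1, 4L * H)
      p[[paste0("lstm", dir, "_Wh")]] <- .glorot(H, 4L * H)
      bias <- numeric(4L * H)
      bias[seq_len(H)] <- 1  # forget-gate bias: remember by default
      p[[paste0("lstm", dir, "_b")]] <- bias
    }
  }
  if (config$use_blosum) {
    p$blosum_W <- .glorot(config$max_pep_len * 20L, config$blosum_dense)
    p$blosum_b <- numeric(config$blosum_dense)
  }
  p$onehot_W <- .glorot(geo$T_len * A, config$onehot_dense)
  p$onehot_b <- numeric(config$onehot_dense)
  fusion <- 2L * F2 +
    (if (config$use_1dcnn_bilstm) 2L * H else 0L) +
    (if (config$use_blosum) config$blosum_dense else 0L) +
    config$onehot_dense
  p$mlp_W1 <- .glorot(fusion, config$mlp_hidden)
  p$mlp_b1 <- numeric(config$mlp_hidden)
  p$mlp_W2 <- .glorot(config$mlp_hidden, 1L)
  p$mlp_b2 <- numeric(1L)
  structure(list(params = p, config = config, geometry = geo,
                 pseudo_len = as.integer(pseudo_len), fusion_dim = fusion),
            class = "network_params")
}


.sig <- function(x) 1 / (1 + exp(-x))

# W1 rows corresponding to the padding channel: fixed at zero so that gather
# semantics match one-hot semantics (a padded position contributes nothing).
.pad_rows_1d <- function(m1, A = 21L) (seq_len(m1) - 1L) * A + A

# Dense one-hot matrix (B x T*A) from residue indices (pad index 21 -> zero
# row, so the 21st channel is never set).
.onehot_flat <- function(idx, A = 21L) {
  B <- nrow(idx)
  X <- matrix(0, B, ncol(idx) * A)
  sel <- which(idx != A)
  if (length(sel)) {
    b <- ((sel - 1L) %% B) + 1L
    t <- ((sel - 1L) %/% B) + 1L
    X[cbind(b, (t - 1L) * A + idx[sel])] <- 1
  }
  X
}

# Forward pass on a batch of residue-index rows. Both convolutions exploit
# the one-hot structure of the input: a valid convolution over a one-hot
# sequence is a sum of weight-matrix row gathers indexed by the residues, so
# no dense im2col matrix is ever built.
network_forward <- function(net, idx, blosum, keep_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  g <- net$geometry
  B <- nrow(idx)
  A <- g$A
  F2 <- cfg$conv2d_filters
  K <- cfg$conv2d_kernel
  Pp <- g$Pp
  cache <- list(B = B)

  ## --- 2D branch: conv (gather/scatter), ReLU, 2x2 max pool ---
  n2 <- B * g$P2
  Z2 <- matrix(0, n2, F2)
  for (f in seq_len(F2)) if (p$conv2_b[f] != 0) Z2[, f] <- p$conv2_b[f]
  rf_list <- vector("list", K * K)
  r <- 0L
  st <- cfg$conv2d_stride
  for (l in seq_len(K)) for (k in seq_len(K)) {
    r <- r + 1L
    av <- idx[, seq.int(k, by = st, length.out = g$H2), drop = FALSE]
    j0 <- av - l                                       # (image col - 1) of tap
    ok <- which(av != A & j0 >= 0L & j0 %% st == 0L & j0 %/% st < g$W2)
    if (length(ok)) {
      b <- ((ok - 1L) %% B) + 1L
      i2 <- ((ok - 1L) %/% B) + 1L
      rf <- b + (i2 + (j0[ok] %/% st) * g$H2 - 1L) * B  # row of Z2
      for (f in seq_len(F2)) {
        ii <- rf + (f - 1L) * n2
        Z2[ii] <- Z2[ii] + p$conv2_W[r, f]
      }
      rf_list[[r]] <- rf
    } else rf_list[[r]] <- integer(0)
  }
  mask2 <- Z2 > 0
  Fmap <- Z2 * mask2
  dim(Fmap) <- c(B, g$P2, F2)
  S <- g$pool_s
  M1 <- Fmap[, S[, 1], , drop = FALSE]; M2 <- Fmap[, S[, 2], , drop = FALSE]
  M3 <- Fmap[, S[, 3], , drop = FALSE]; M4 <- Fmap[, S[, 4], , drop = FALSE]
  W12 <- 1L + (M2 > M1); Y12 <- pmax(M1, M2)
  W34 <- 3L + (M4 > M3); Y34 <- pmax(M3, M4)
  Fp <- pmax(Y12, Y34)
  Wm <- W12; sel <- Y34 > Y12; Wm[sel] <- W34[sel]

  ## --- CBAM ---
  if (cfg$use_cbam) {
    avgc <- matrix(0, B, F2); maxc <- matrix(0, B, F2)
    imaxc <- matrix(0L, B, F2)
    for (cc in seq_len(F2)) {
      Fc <- matrix(Fp[, , cc], B, Pp)
      avgc[, cc] <- .rowMeans(Fc, B, Pp)
      im <- max.col(Fc, ties.method = "first")
      imaxc[, cc] <- im
      maxc[, cc] <- Fc[cbind(seq_len(B), im)]
    }
    za <- sweep(avgc %*% p$cbamc_W1, 2, p$cbamc_b1, "+"); ha <- za * (za > 0)
    zm <- sweep(maxc %*% p$cbamc_W1, 2, p$cbamc_b1, "+"); hm <- zm * (zm > 0)
    s <- sweep(ha %*% p$cbamc_W2, 2, p$cbamc_b2, "+") +
         sweep(hm %*% p$cbamc_W2, 2, p$cbamc_b2, "+")
    Mc <- .sig(s)                                                # B x F2
    F1p <- Fp
    for (cc in seq_len(F2)) F1p[, , cc] <- matrix(Fp[, , cc], B, Pp) * Mc[, cc]
    # spatial attention: channel-avg / channel-max maps -> 'same' conv
    avgs <- rowSums(F1p, dims = 2) / F2                          # B x Pp
    Msp <- matrix(F1p, B * Pp, F2)
    imaxs <- max.col(Msp, ties.method = "first")
    maxs <- matrix(Msp[cbind(seq_len(B * Pp), imaxs)], B, Pp)
    Cpad <- matrix(0, B, g$pad_flat)
    Cpad[, g$interior] <- avgs
    Cpad[, g$interior + g$chan_off] <- maxs
    Wsv <- as.vector(p$cbams_W)
    zs <- matrix(p$cbams_b, B, Pp)
    for (rr in seq_len(2L * g$ks^2)) {
      zs <- zs + Cpad[, g$spat[, rr], drop = FALSE] * Wsv[rr]
    }
    Ms <- .sig(zs)                                               # B x Pp
    F2p <- F1p * as.vector(Ms)   # recycles the B x Pp gate over channels
    if (keep_cache) {
      cache <- c(cache, list(avgc = avgc, imaxc = imaxc, za = za, zm = zm,
                             ha = ha, hm = hm, maxc = maxc, Mc = Mc,
                             F1p = F1p, imaxs = imaxs, Cpad = Cpad, Ms = Ms))
    }
  } else {
    F2p <- Fp
  }

  ## --- global average + max pooling per channel ---
  gavg <- matrix(0, B, F2); gmax <- matrix(0, B, F2)
  imaxg <- matrix(0L, B, F2)
  for (cc in seq_len(F2)) {
    Fc <- matrix(F2p[, , cc], B, Pp)
    gavg[, cc] <- .rowMeans(Fc, B, Pp)
    im <- max.col(Fc, ties.method = "first")
    imaxg[, cc] <- im
    gmax[, cc] <- Fc[cbind(seq_len(B), im)]
  }
  feats <- cbind(gavg, gmax)

  ## --- 1D-CNN + BiLSTM branch ---
  if (cfg$use_1dcnn_bilstm) {
    m1 <- cfg$conv1d_width
    F1 <- cfg$conv1d_filters
    Z1 <- matrix(rep(p$conv1_b, each = B * g$P1), B * g$P1, F1)
    vj <- vector("list", m1)
    for (j in seq_len(m1)) {
      vj[[j]] <- as.vector((j - 1L) * A + idx[, j:(j + g$P1 - 1L),
                                              drop = FALSE])
      Z1 <- Z1 + p$conv1_W[vj[[j]], , drop = FALSE]
    }
    mask1 <- Z1 > 0
    Y1 <- Z1 * mask1
    dim(Y1) <- c(B, g$P1, F1)
    # optional temporal max pool before the BiLSTM
    pw <- cfg$conv1d_pool
    if (pw > 1L) {
      Pl <- g$P1 %/% pw
      Yl <- Y1[, seq.int(1L, by = pw, length.out = Pl), , drop = FALSE]
      Wp1 <- array(1L, dim(Yl))
      for (o in 2:pw) {
        cand <- Y1[, seq.int(o, by = pw, length.out = Pl), , drop = FALSE]
        sel <- cand > Yl
        Yl[sel] <- cand[sel]
        Wp1[sel] <- o
      }
    } else {
      Pl <- g$P1
      Yl <- Y1
      Wp1 <- NULL
    }
    H <- cfg$lstm_hidden
    run_lstm <- function(Wx, Wh, bias, times) {
      P1 <- length(times)
      Fc <- array(0, c(B, H, P1)); Ic <- Fc; Oc <- Fc; Gc <- Fc
      Cc <- Fc; Hc <- Fc
      h <- matrix(0, B, H); C <- matrix(0, B, H)
      for (s in seq_along(times)) {
        xt <- Yl[, times[s], ]
        if (is.null(dim(xt))) xt <- matrix(xt, B)
        Z <- xt %*% Wx + h %*% Wh
        Z <- sweep(Z, 2, bias, "+")
        f <- .sig(Z[, seq_len(H), drop = FALSE])
        i <- .sig(Z[, H + seq_len(H), drop = FALSE])
        o <- .sig(Z[, 2L * H + seq_len(H), drop = FALSE])
        gg <- tanh(Z[, 3L * H + seq_len(H), drop = FALSE])
        C <- f * C + i * gg
        h <- o * tanh(C)
        Fc[, , s] <- f; Ic[, , s] <- i; Oc[, , s] <- o; Gc[, , s] <- gg
        Cc[, , s] <- C; Hc[, , s] <- h
      }
      list(f = Fc, i = Ic, o = Oc, g = Gc, C = Cc, h = Hc, last = h,
           times = times)
    }
    fwd <- run_lstm(p$lstmf_Wx, p$lstmf_Wh, p$lstmf_b, seq_len(Pl))
    bwd <- run_lstm(p$lstmb_Wx, p$lstmb_Wh, p$lstmb_b, rev(seq_len(Pl)))
    feats <- cbind(feats, fwd$last, bwd$last)
    if (keep_cache) {
      cache <- c(cache, list(vj = vj, mask1 = mask1, Yl = Yl, Wp1 = Wp1,
                             Pl = Pl, lstm_f = fwd, lstm_b = bwd))
    }
  }

  ## --- BLOSUM skip ---
  if (cfg$use_blosum) {
    zb <- sweep(blosum %*% p$blosum_W, 2, p$blosum_b, "+")
    hb <- zb * (zb > 0)
    feats <- cbind(feats, hb)
    if (keep_cache) cache <- c(cache, list(zb = zb, hb = hb, blosum_X = blosum))
  }

  ## --- one-hot pair skip ---
  X1h <- .onehot_flat(idx, A)
  zo <- sweep(X1h %*% p$onehot_W, 2, p$onehot_b, "+")
  ho <- zo * (zo > 0)
  feats <- cbind(feats, ho)
  if (keep_cache) cache <- c(cache, list(zo = zo, X1h = X1h))

  ## --- head ---
  z1h <- sweep(feats %*% p$mlp_W1, 2, p$mlp_b1, "+")
  h1 <- z1h * (z1h > 0)
  out <- drop(sweep(h1 %*% p$mlp_W2, 2, p$mlp_b2, "+"))
  if (cfg$task == "classification") out_act <- .sig(out) else out_act <- out

  if (!keep_cache) return(out_act)
  cache <- c(cache, list(rf_list = rf_list, mask2 = mask2, Fp = Fp,
                         Wm = Wm, pool_S = S, imaxg = imaxg,
                         feats = feats, h1 = h1, z1h = z1h, out = out,
                         out_act = out_act))
  list(out = out_act, logit = out, cache = cache)
}

# Backward pass: dout is dLoss/d(linear output) (length-B vector). Returns a
# gradient list with the same names and shapes as net$params.
network_backward <- function(net, cache, dout) {
  cfg <- net$config
  p <- net$params
  g <- net$geometry
  B <- cache$B
  F2 <- cfg$conv2d_filters
  Pp <- g$Pp
  gr <- list()
  dout <- matrix(dout, B, 1)

  ## head
  gr$mlp_W2 <- crossprod(cache$h1, dout)
  gr$mlp_b2 <- colSums(dout)
  dh1 <- dout %*% t(p$mlp_W2)
  dz1 <- dh1 * (cache$z1h > 0)
  gr$mlp_W1 <- crossprod(cache$feats, dz1)
  gr$mlp_b1 <- colSums(dz1)
  dfeats <- dz1 %*% t(p$mlp_W1)

  off <- 2L * F2
  d2d <- dfeats[, seq_len(off), drop = FALSE]
  if (cfg$use_1dcnn_bilstm) {
    H <- cfg$lstm_hidden
    dlstm <- dfeats[, off + seq_len(2L * H), drop = FALSE]
    off <- off + 2L * H
  }
  if (cfg$use_blosum) {
    db <- dfeats[, off + seq_len(cfg$blosum_dense), drop = FALSE]
    dzb <- db * (cache$zb > 0)
    gr$blosum_W <- crossprod(cache$blosum_X, dzb)
    gr$blosum_b <- colSums(dzb)
    off <- off + cfg$blosum_dense
  }
  do_ <- dfeats[, off + seq_len(cfg$onehot_dense), drop = FALSE]
  dzo <- do_ * (cache$zo > 0)
  gr$onehot_W <- crossprod(cache$X1h, dzo)
  gr$onehot_b <- colSums(dzo)

  ## global pooling backward
  dgavg <- d2d[, seq_len(F2), drop = FALSE]
  dgmax <- d2d[, F2 + seq_len(F2), drop = FALSE]
  dF2p <- array(0, c(B, Pp, F2))
  bseq <- seq_len(B)
  for (cc in seq_len(F2)) {
    dc <- matrix(dgavg[, cc] / Pp, B, Pp)
    dc[cbind(bseq, cache$imaxg[, cc])] <-
      dc[cbind(bseq, cache$imaxg[, cc])] + dgmax[, cc]
    dF2p[, , cc] <- dc
  }

  if (cfg$use_cbam) {
    F1p <- cache$F1p; Ms <- cache$Ms; Mc <- cache$Mc
    dMs <- rowSums(dF2p * F1p, dims = 2)
    dF1p <- dF2p * as.vector(Ms)
    dzs <- dMs * Ms * (1 - Ms)
    Wsv <- as.vector(p$cbams_W)
    dWs <- numeric(2L * g$ks^2)
    dCpad <- matrix(0, B, g$pad_flat)
    for (rr in seq_len(2L * g$ks^2)) {
      colsr <- g$spat[, rr]
      dWs[rr] <- sum(cache$Cpad[, colsr, drop = FALSE] * dzs)
      dCpad[, colsr] <- dCpad[, colsr] + dzs * Wsv[rr]
    }
    gr$cbams_W <- matrix(dWs, ncol = 1)
    gr$cbams_b <- sum(dzs)
    davgs <- dCpad[, g$interior, drop = FALSE]
    dmaxs <- dCpad[, g$interior + g$chan_off, drop = FALSE]
    for (cc in seq_len(F2)) dF1p[, , cc] <- matrix(dF1p[, , cc], B, Pp) + davgs / F2
    idxs <- seq_len(B * Pp) + (cache$imaxs - 1L) * B * Pp
    dF1p[idxs] <- dF1p[idxs] + as.vector(dmaxs)
    # channel attention backward
    dMc <- matrix(0, B, F2)
    dFp <- dF1p
    for (cc in seq_len(F2)) {
      dMc[, cc] <- rowSums(matrix(dF1p[, , cc] * cache$Fp[, , cc], B, Pp))
      dFp[, , cc] <- matrix(dF1p[, , cc], B, Pp) * Mc[, cc]
    }
    ds <- dMc * Mc * (1 - Mc)
    gr$cbamc_W2 <- crossprod(cache$ha, ds) + crossprod(cache$hm, ds)
    gr$cbamc_b2 <- 2 * colSums(ds)
    dha <- ds %*% t(p$cbamc_W2); dza <- dha * (cache$za > 0)
    dhm <- ds %*% t(p$cbamc_W2); dzm <- dhm * (cache$zm > 0)
    gr$cbamc_W1 <- crossprod(cache$avgc, dza) + crossprod(cache$maxc, dzm)
    gr$cbamc_b1 <- colSums(dza) + colSums(dzm)
    davgc <- dza %*% t(p$cbamc_W1)
    dmaxc <- dzm %*% t(p$cbamc_W1)
    for (cc in seq_len(F2)) {
      dc <- matrix(dFp[, , cc], B, Pp) + davgc[, cc] / Pp
      sel <- cbind(bseq, cache$imaxc[, cc])
      dc[sel] <- dc[sel] + dmaxc[, cc]
      dFp[, , cc] <- dc
    }
  } else {
    dFp <- dF2p
  }

  ## max-pool backward to the conv2 output
  S <- cache$pool_S
  qarr <- slice.index(cache$Wm, 2)
  s_chosen <- S[cbind(as.vector(qarr), as.vector(cache$Wm))]
  n_el <- B * Pp * F2
  barr <- ((seq_len(n_el) - 1L) %% B) + 1L
  carr <- ((seq_len(n_el) - 1L) %/% (B * Pp)) + 1L
  idxp <- barr + (s_chosen - 1L) * B + (carr - 1L) * B * g$P2
  n2 <- B * g$P2
  dZ2 <- numeric(n2 * F2)
  dZ2[idxp] <- as.vector(dFp) * cache$mask2[idxp]
  dim(dZ2) <- c(n2, F2)
  gr$conv2_b <- colSums(dZ2)
  dW2 <- matrix(0, cfg$conv2d_kernel^2, F2)
  for (r in seq_along(cache$rf_list)) {
    rf <- cache$rf_list[[r]]
    if (length(rf)) {
      for (f in seq_len(F2)) dW2[r, f] <- sum(dZ2[rf + (f - 1L) * n2])
    }
  }
  gr$conv2_W <- dW2

  ## BiLSTM + conv1 backward
  if (cfg$use_1dcnn_bilstm) {
    H <- cfg$lstm_hidden
    F1 <- cfg$conv1d_filters
    Pl <- cache$Pl
    dYl <- array(0, c(B, Pl, F1))
    back_lstm <- function(cacheL, Wx, Wh, dh_last) {
      P1 <- length(cacheL$times)
      dWx <- matrix(0, nrow(Wx), ncol(Wx))
      dWh <- matrix(0, H, 4L * H)
      dbias <- numeric(4L * H)
      dh <- dh_last
      dC <- matrix(0, B, H)
      for (s in rev(seq_len(P1))) {
        f <- matrix(cacheL$f[, , s], B); i <- matrix(cacheL$i[, , s], B)
        o <- matrix(cacheL$o[, , s], B); gg <- matrix(cacheL$g[, , s], B)
        C <- matrix(cacheL$C[, , s], B)
        tC <- tanh(C)
        do_ <- dh * tC
        dC <- dC + dh * o * (1 - tC^2)
        Cprev <- if (s > 1) matrix(cacheL$C[, , s - 1], B) else
          matrix(0, B, H)
        df <- dC * Cprev
        di <- dC * gg
        dg <- dC * i
        dZ <- cbind(df * f * (1 - f), di * i * (1 - i),
                    do_ * o * (1 - o), dg * (1 - gg^2))
        xt <- matrix(cache$Yl[, cacheL$times[s], ], B)
        hprev <- if (s > 1) matrix(cacheL$h[, , s - 1], B) else
          matrix(0, B, H)
        dWx <- dWx + crossprod(xt, dZ)
        dWh <- dWh + crossprod(hprev, dZ)
        dbias <- dbias + colSums(dZ)
        dYl[, cacheL$times[s], ] <<- dYl[, cacheL$times[s], ] + dZ %*% t(Wx)
        dh <- dZ %*% t(Wh)
        dC <- dC * f
      }
      list(Wx = dWx, Wh = dWh, b = dbias)
    }
    gf <- back_lstm(cache$lstm_f, p$lstmf_Wx, p$lstmf_Wh,
                    dlstm[, seq_len(H), drop = FALSE])
    gb <- back_lstm(cache$lstm_b, p$lstmb_Wx, p$lstmb_Wh,
                    dlstm[, H + seq_len(H), drop = FALSE])
    gr$lstmf_Wx <- gf$Wx; gr$lstmf_Wh <- gf$Wh; gr$lstmf_b <- gf$b
    gr$lstmb_Wx <- gb$Wx; gr$lstmb_Wh <- gb$Wh; gr$lstmb_b <- gb$b
    pw <- cfg$conv1d_pool
    if (pw > 1L) {
      n_el <- B * Pl * F1
      i_el <- seq_len(n_el)
      b <- ((i_el - 1L) %% B) + 1L
      q <- (((i_el - 1L) %/% B) %% Pl) + 1L
      f <- ((i_el - 1L) %/% (B * Pl)) + 1L
      t <- (q - 1L) * pw + as.vector(cache$Wp1)
      dY1 <- numeric(B * g$P1 * F1)
      dY1[b + (t - 1L) * B + (f - 1L) * B * g$P1] <- as.vector(dYl)
    } else {
      dY1 <- dYl
    }
    dZ1 <- matrix(dY1, B * g$P1, F1) * cache$mask1
    dW1 <- matrix(0, cfg$conv1d_width * g$A, F1)
    for (j in seq_len(cfg$conv1d_width)) {
      rs <- rowsum(dZ1, cache$vj[[j]])
      rows <- as.integer(rownames(rs))
      dW1[rows, ] <- dW1[rows, ] + rs
    }
    dW1[.pad_rows_1d(cfg$conv1d_width, g$A), ] <- 0
    gr$conv1_W <- dW1
    gr$conv1_b <- colSums(dZ1)
  }
  gr
}


# Loss and gradient w.r.t. the linear output.
.loss_grad <- function(net, logit, y, w = NULL) {
  B <- length(y)
  if (net$config$task == "regression") {
    r <- logit - y
    list(loss = mean(r^2), dout = 2 * r / B)
  } else {
    if (is.null(w)) w <- rep(1, B)
    pr <- .sig(logit)
    eps <- 1e-12
    loss <- -mean(w * (y * log(pr + eps) + (1 - y) * log(1 - pr + eps)))
    list(loss = loss, dout = w * (pr - y) / B)
  }
}

# Cosine-annealed learning rate at (0-based) epoch e.
cosine_lr <- function(lr0, epoch, t_max) {
  0.5 * lr0 * (1 + cos(pi * min(epoch, t_max) / t_max))
}

#' Train the network on encoded data
#'
#' AdamW with a cosine-annealing learning-rate schedule. Loss is
#' mean-squared error on the IC50-derived score for regression, weighted
#' binary cross-entropy for classification (class weights inversely
#' proportional to class counts). The returned parameters are those with the
#' minimum validation loss across epochs; validation data is optional (last
#' epoch is kept if absent).
#'
#' @param train List with `idx`, `blosum` (from the internal encoder) and `y`.
#' @param config A [model_config()].
#' @param val Optional validation list like `train`.
#' @param verbose Print per-epoch losses.
#' @return A `network_params` object with a `history` data.frame attached.
#' @keywords internal
train_network <- function(train, config, val = NULL, verbose = FALSE) {
  pseudo_len <- train$pseudo_len
  net <- init_network(config, pseudo_len, seed = config$seed)
  n <- nrow(train$idx)
  if (n < 1) stop("empty training set", call. = FALSE)
  w <- NULL
  if (config$task == "classification") {
    n1 <- sum(train$y == 1); n0 <- n - n1
    if (n1 == 0 || n0 == 0) {
      w_all <- rep(1, n)
    } else {
      w_all <- ifelse(train$y == 1, n / (2 * n1), n / (2 * n0))
    }
  }
  opt <- list(m = lapply(net$params, function(x) x * 0),
              v = lapply(net$params, function(x) x * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, params = net$params)
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config$learning_rate, epoch - 1L, config$t_max)
    ord <- sample.int(n)
    bs <- min(config$batch_size, n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0; ep_n <- 0
    for (st in starts) {
      rows <- ord[st:min(st + bs - 1L, n)]
      fb <- network_forward(net, train$idx[rows, , drop = FALSE],
                            train$blosum[rows, , drop = FALSE],
                            keep_cache = TRUE)
      lg <- .loss_grad(net, fb$logit, train$y[rows],
                       if (config$task == "classification") w_all[rows])
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                     epoch), call. = FALSE)
      }
      gr <- network_backward(net, fb$cache, lg$dout)
      opt$t <- opt$t + 1
      bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
      for (nm in names(gr)) {
        opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr[[nm]]
        opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr[[nm]]^2
        step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
        net$params[[nm]] <- net$params[[nm]] -
          lr * (step + config$weight_decay * net$params[[nm]])
      }
      ep_loss <- ep_loss + lg$loss * length(rows)
      ep_n <- ep_n + length(rows)
    }
    vl <- NA_real_
    if (!is.null(val) && nrow(val$idx) > 0) {
      pv <- predict_network(net, val)
      if (config$task == "regression") {
        vl <- mean((pv - val$y)^2)
      } else {
        eps2 <- 1e-12
        vl <- -mean(val$y * log(pv + eps2) + (1 - val$y) * log(1 - pv + eps2))
      }
      if (vl < best$loss) best <- list(loss = vl, params = net$params)
    } else {
      best <- list(loss = ep_loss / ep_n, params = net$params)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d lr %.2e train %.5f val %s", epoch, lr,
                      ep_loss / ep_n,
                      if (is.na(vl)) "-" else sprintf("%.5f", vl)))
    }
  }
  net$params <- best$params
  net$history <- history
  net
}

# Forward-only prediction on encoded data, chunked to bound memory.
predict_network <- function(net, enc, chunk = 4096L) {
  n <- nrow(enc$idx)
  out <- numeric(n)
  for (st in seq(1L, n, by = chunk)) {
    rows <- st:min(st + chunk - 1L, n)
    out[rows] <- network_forward(net, enc$idx[rows, , drop = FALSE],
                                 enc$blosum[rows, , drop = FALSE])
  }
  out
}
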