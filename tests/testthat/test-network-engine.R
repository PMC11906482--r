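# The batched training engine: gradient correctness, determinism,
# sensitivity, ablation shape contracts.

tiny_net_fixture <- function(seed = 3, task = "classification", ...) {
  cfg <- model_config(task = task, conv1d_filters = 5, conv2d_filters = 3,
                      lstm_hidden = 4, cbam_reduction = 2, blosum_dense = 6,
                      onehot_dense = 7, mlp_hidden = 7, max_pep_len = 10,
                      conv2d_stride = 2, cbam_spatial_kernel = 3,
                      conv1d_pool = 2, seed = seed, ...)
  net <- mhcbind:::init_network(cfg, pseudo_len = 8)
  set.seed(seed + 50)
  # move biases off the ReLU/pool tie points so the loss is differentiable
  # at the evaluation point
  for (nm in grep("_b$|_b1$|_b2$", names(net$params), value = TRUE)) {
    net$params[[nm]] <- net$params[[nm]] +
      stats::rnorm(length(net$params[[nm]]), 0, 0.3)
  }
  B <- 4
  idx <- matrix(sample(1:20, B * net$geometry$T_len, replace = TRUE),
                B, net$geometry$T_len)
  idx[1, 5:6] <- 21L
  blosum <- matrix(stats::rnorm(B * cfg$max_pep_len * 20), B)
  list(net = net, idx = idx, blosum = blosum, y = c(1, 0, 1, 0))
}

test_that("backpropagated gradients match finite differences", {
  fx <- tiny_net_fixture()
  net <- fx$net
  fb <- mhcbind:::network_forward(net, fx$idx, fx$blosum, keep_cache = TRUE)
  lg <- mhcbind:::.loss_grad(net, fb$logit, fx$y)
  gr <- mhcbind:::network_backward(net, fb$cache, lg$dout)
  lossfun <- function(n2) {
    p <- mhcbind:::network_forward(n2, fx$idx, fx$blosum)
    mhcbind:::.loss_grad(n2, log(p / (1 - p)), fx$y)$loss
  }
  eps <- 1e-6
  set.seed(99)
  for (nm in names(net$params)) {
    P <- net$params[[nm]]
    for (i in sample(length(P), min(length(P), 6))) {
      n2 <- net
      n2$params[[nm]][i] <- P[i] + eps
      lp <- lossfun(n2)
      n2$params[[nm]][i] <- P[i] - eps
      lm <- lossfun(n2)
      fd <- (lp - lm) / (2 * eps)
      an <- gr[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("forward pass is deterministic and bounded for classification", {
  fx <- tiny_net_fixture()
  o1 <- mhcbind:::network_forward(fx$net, fx$idx, fx$blosum)
  o2 <- mhcbind:::network_forward(fx$net, fx$idx, fx$blosum)
  expect_identical(o1, o2)
  expect_true(all(o1 > 0 & o1 < 1))
})

test_that("swapping two distinct residues changes the output", {
  fx <- tiny_net_fixture()
  idx2 <- fx$idx
  stopifnot(idx2[2, 1] != idx2[2, 3])
  idx2[2, c(1, 3)] <- idx2[2, c(3, 1)]
  o1 <- mhcbind:::network_forward(fx$net, fx$idx, fx$blosum)
  o2 <- mhcbind:::network_forward(fx$net, idx2, fx$blosum)
  expect_false(isTRUE(all.equal(o1[2], o2[2])))
  expect_equal(o1[-2], o2[-2])  # other rows untouched
})

test_that("ablation variants build, run, and change the fusion size", {
  dims <- integer(0)
  for (flags in list(list(), list(use_cbam = FALSE),
                     list(use_1dcnn_bilstm = FALSE),
                     list(use_blosum = FALSE))) {
    fx <- do.call(tiny_net_fixture, c(list(seed = 5), flags))
    out <- mhcbind:::network_forward(fx$net, fx$idx, fx$blosum)
    expect_length(out, 4L)
    expect_true(all(is.finite(out)))
    dims <- c(dims, fx$net$fusion_dim)
  }
  # the three ablations have three distinct fusion dimensionalities
  expect_equal(anyDuplicated(dims[-1]), 0L)
  # disabling a branch removes its parameters
  fx_nb <- tiny_net_fixture(seed = 5, use_blosum = FALSE)
  expect_false("blosum_W" %in% names(fx_nb$net$params))
})

test_that("batched engine agrees with the reference layer semantics", {
  # one sample, one 2D filter, stride 1: engine conv2d output equals
  # conv2d_forward on the one-hot image
  cfg <- model_config(task = "regression", conv1d_filters = 2,
                      conv2d_filters = 1, lstm_hidden = 2,
                      cbam_reduction = 1, use_cbam = FALSE,
                      use_1dcnn_bilstm = FALSE, use_blosum = FALSE,
                      blosum_dense = 2, onehot_dense = 2, mlp_hidden = 2,
                      max_pep_len = 10, conv2d_stride = 1, seed = 2)
  net <- mhcbind:::init_network(cfg, pseudo_len = 6)
  g <- net$geometry
  set.seed(4)
  pep <- paste(sample(aa_alphabet, 9, replace = TRUE), collapse = "")
  pseudo <- paste(sample(aa_alphabet, 6, replace = TRUE), collapse = "")
  pair <- build_pair_input(pep, pseudo, cfg$max_pep_len)
  idx <- matrix(mhcbind:::.residue_index(pair$pair_sequence), 1)
  fb <- mhcbind:::network_forward(net, idx, matrix(0, 1, 200),
                                  keep_cache = TRUE)
  # rebuild the engine's conv output from the cached ReLU mask and compare
  W <- matrix(net$params$conv2_W[, 1], cfg$conv2d_kernel, cfg$conv2d_kernel)
  ref <- conv2d_forward(pair$onehot_pair, W, net$params$conv2_b[1])
  eng <- matrix(fb$cache$Fp, g$Hp * g$Wp)  # pooled map, 1 channel
  # pool the reference the same way and compare
  pooled_ref <- matrix(0, g$Hp, g$Wp)
  for (u in seq_len(g$Hp)) for (v in seq_len(g$Wp)) {
    pooled_ref[u, v] <- max(ref[(2 * u - 1):(2 * u), (2 * v - 1):(2 * v)])
  }
  expect_equal(as.vector(eng), as.vector(pooled_ref), tolerance = 1e-12)
})

test_that("training reduces loss on a separable synthetic problem", {
  world <- make_world(2, seed = 21)
  ba <- sample_ba(world, 600, seed = 22)
  cfg <- tiny_config(task = "regression", seed = 23, epochs = 4, t_max = 4,
                     batch_size = 128)
  enc <- mhcbind:::encode_dataset(ba$peptide, ba$allele, world$pseudo,
                                  cfg$max_pep_len)
  enc$y <- ic50_to_score(ba$ic50_nM)
  net <- mhcbind:::train_network(enc, cfg)
  h <- net$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("regression on constant targets converges to the constant", {
  world <- make_world(1, seed = 31)
  ba <- sample_ba(world, 400, seed = 32)
  cfg <- tiny_config(task = "regression", seed = 33, epochs = 14, t_max = 14,
                     batch_size = 64)
  enc <- mhcbind:::encode_dataset(ba$peptide, ba$allele, world$pseudo,
                                  cfg$max_pep_len)
  enc$y <- rep(0.37, 400)
  net <- mhcbind:::train_network(enc, cfg)
  pred <- mhcbind:::predict_network(net, enc)
  expect_lt(max(abs(pred - 0.37)), 0.05)
})

test_that("cosine schedule anneals from lr to zero over t_max", {
  expect_equal(mhcbind:::cosine_lr(0.01, 0, 30), 0.01)
  expect_equal(mhcbind:::cosine_lr(0.01, 30, 30), 0)
  expect_equal(mhcbind:::cosine_lr(0.01, 15, 30), 0.005)
  lrs <- sapply(0:30, mhcbind:::cosine_lr, lr0 = 0.01, t_max = 30)
  expect_true(all(diff(lrs) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(conv1d_filters = 0), "positive")
  expect_error(model_config(cbam_spatial_kernel = 4), "odd")
  expect_error(mhcbind:::init_network(model_config(max_pep_len = 2, conv1d_width = 30),
                            pseudo_len = 4), "exceeds")
})
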