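# Architecture contracts: attention, encoders, fusion, classifier head.

ns <- asNamespace("nanocon")

small_cfg <- function(...) {
  nanocon_config(embed_dim = 8L, n_transformer_layers = 1L, n_heads = 2L,
                 signal_encoder_dims = c(8L, 8L), gru_hidden = 6L,
                 gru_dropout = 0, ...)
}

forward_batch <- function(cfg, B = 5L, seed = 10L) {
  set.seed(seed)
  vocab <- build_vocab()
  params <- ns$init_params(cfg, attr(vocab, "vocab_size"), seed = seed)
  tokens <- tokenize(simulate_motif(B, "mixed"), vocab)
  signal <- matrix(rnorm(B * 39), B, 39)
  fw <- ns$nanocon_forward(params, cfg, tokens, signal,
                           mask_cache = ns$block_mask(B))
  list(fw = fw, params = params, tokens = tokens, signal = signal,
       cfg = cfg, vocab = vocab)
}

test_that("self-attention rows are a softmax and degenerate to the mean", {
  set.seed(1)
  X <- matrix(rnorm(9 * 6), 9, 6)
  W <- list(q = matrix(rnorm(36), 6), k = matrix(rnorm(36), 6),
            v = matrix(rnorm(36), 6))
  a <- self_attention(X, W$q, W$k, W$v)
  expect_equal(rowSums(a$weights), rep(1, 9))
  # zero query/key projections make attention uniform: output is the
  # column-mean of V at every step
  a0 <- self_attention(X, W$q * 0, W$k * 0, W$v)
  expect_equal(a0$weights, matrix(1 / 9, 9, 9))
  V <- X %*% W$v
  expect_equal(a0$output, matrix(colMeans(V), 9, 6, byrow = TRUE))
  expect_error(self_attention(X, matrix(0, 5, 6), W$k, W$v), "conform")
})

test_that("self-attention equals a three-loop oracle on a tiny example", {
  set.seed(2)
  X <- matrix(rnorm(8), 2, 4)
  Wq <- matrix(rnorm(16), 4); Wk <- matrix(rnorm(16), 4); Wv <- matrix(rnorm(16), 4)
  got <- self_attention(X, Wq, Wk, Wv)$output
  # brute-force: explicit loops over steps and dimensions
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  expected <- matrix(0, 2, 4)
  for (i in 1:2) {
    scores <- numeric(2)
    for (j in 1:2) scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
    w <- exp(scores) / sum(exp(scores))
    for (d in 1:4) expected[i, d] <- sum(w * V[, d])
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("forward shapes: 9-step context, repr_dim = 2 * gru_hidden, probs sum to 1", {
  out <- forward_batch(small_cfg())
  B <- 5L
  expect_equal(dim(out$fw$repr$val), c(B, 12L))  # 2 * gru_hidden
  expect_equal(dim(out$fw$logits$val), c(B, 2L))
  probs <- ns$softmax_rows(out$fw$logits$val)
  expect_equal(rowSums(probs), rep(1, B))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("the classifier is monotone in its class-1 logit", {
  z <- matrix(c(0.3, -0.2, 1.1, 0.4), 2, 2)
  p <- ns$softmax_rows(z)[, 2]
  z_up <- z; z_up[, 2] <- z_up[, 2] + 1
  expect_true(all(ns$softmax_rows(z_up)[, 2] > p))
})

test_that("forward pass is deterministic and batch-order equivariant", {
  out1 <- forward_batch(small_cfg())
  out2 <- forward_batch(small_cfg())
  expect_identical(out1$fw$logits$val, out2$fw$logits$val)
  # permuting instances permutes outputs identically
  perm <- c(3L, 1L, 5L, 2L, 4L)
  fw_p <- ns$nanocon_forward(out1$params, out1$cfg, out1$tokens[perm, ],
                             out1$signal[perm, ], mask_cache = ns$block_mask(5L))
  expect_equal(fw_p$logits$val, out1$fw$logits$val[perm, ], tolerance = 1e-12)
  expect_equal(fw_p$repr$val, out1$fw$repr$val[perm, ], tolerance = 1e-12)
})

test_that("every ablation flag changes the branch it targets", {
  ms <- simulate_dataset(sim_config(n_instances = 6L, seed = 20L))
  base_sig <- ns$signal_matrix(ms)
  for (flag in c("mask_means", "mask_stds", "mask_lens")) {
    sig <- ns$signal_matrix(ms, flag)
    cols <- switch(flag, mask_means = 1:13, mask_stds = 14:26,
                   mask_lens = 27:39)
    expect_true(all(sig[, cols] == 0))
    expect_equal(sig[, -cols], base_sig[, -cols])
  }
  # architecture flags alter the forward output on the same weights/input
  base <- forward_batch(small_cfg())
  for (flag in c("mask_sequence", "no_gru")) {
    cfg <- small_cfg(ablation = flag)
    params <- ns$init_params(cfg, attr(base$vocab, "vocab_size"), seed = 10L)
    fw <- ns$nanocon_forward(params, cfg, base$tokens, base$signal,
                             mask_cache = ns$block_mask(5L))
    expect_false(isTRUE(all.equal(fw$logits$val, base$fw$logits$val)))
    expect_equal(nrow(fw$repr$val), 5L)
  }
})

test_that("mask_sequence zeroes the sequence branch contribution", {
  cfg <- small_cfg(ablation = "mask_sequence")
  out <- forward_batch(cfg)
  # with the sequence branch zeroed, changing the tokens changes nothing
  other_tokens <- tokenize(simulate_motif(5L, "CpG"), out$vocab)
  fw2 <- ns$nanocon_forward(out$params, cfg, other_tokens, out$signal,
                            mask_cache = ns$block_mask(5L))
  expect_identical(fw2$logits$val, out$fw$logits$val)
})

test_that("configuration invariants are validated", {
  expect_error(nanocon_config(embed_dim = 10L, n_heads = 4L), "divisible")
  expect_error(nanocon_config(gru_dropout = 1), "gru_dropout")
  expect_error(nanocon_config(ablation = "mask_everything"), "unknown ablation")
  expect_equal(nanocon_config(gru_hidden = 32L)$repr_dim, 64L)
})

test_that("signal encoder output dimension follows the last layer width", {
  cfg <- nanocon_config(embed_dim = 8L, n_transformer_layers = 1L,
                        n_heads = 2L, signal_encoder_dims = c(16L, 10L),
                        gru_hidden = 6L, gru_dropout = 0)
  vocab <- build_vocab()
  params <- ns$init_params(cfg, attr(vocab, "vocab_size"), seed = 1L)
  expect_equal(dim(params$sig_W2), c(16L, 10L))
  expect_equal(dim(params$gru_f_Wi), c(8L + 10L, 18L))
  # all-zero signal input gives a deterministic bias-path output
  tokens <- tokenize(simulate_motif(2L, "CpG"), vocab)
  sig0 <- matrix(0, 2L, 39L)
  fw1 <- ns$nanocon_forward(params, cfg, tokens, sig0, mask_cache = ns$block_mask(2L))
  fw2 <- ns$nanocon_forward(params, cfg, tokens, sig0, mask_cache = ns$block_mask(2L))
  expect_identical(fw1$logits$val, fw2$logits$val)
  expect_error(ns$nanocon_forward(params, cfg, tokens, sig0 + NA_real_,
                                  mask_cache = ns$block_mask(2L)), "non-finite")
})
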