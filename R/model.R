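# The feature-fusion network: Transformer over 5-mer tokens, FC encoder over
# signal statistics, per-step concatenation, Bi-GRU fusion, classifier head.

ABLATION_FLAGS <- c("mask_means", "mask_stds", "mask_lens", "mask_sequence",
                    "no_gru", "no_contrast")

#' Model hyperparameter configuration
#'
#' Assembles and validates the architecture hyperparameters. Defaults are
#' deliberately small: the network is trained on CPU and the 13-base/9-token
#' problem does not need large widths.
#'
#' @param embed_dim token embedding size (must be divisible by `n_heads`).
#' @param n_transformer_layers number of Transformer encoder layers.
#' @param n_heads attention heads per layer.
#' @param signal_encoder_dims widths of the fully-connected signal encoder
#'   layers applied to the concatenated 39 per-base statistics.
#' @param gru_hidden hidden width of each GRU direction; the fused
#'   representation has `2 * gru_hidden` dimensions.
#' @param gru_dropout dropout probability applied to the fused
#'   representation during training, in `[0, 1)`.
#' @param ablation character vector of ablation switches, a subset of
#'   `mask_means`, `mask_stds`, `mask_lens` (zero one signal track),
#'   `mask_sequence` (zero the sequence branch), `no_gru` (replace the
#'   Bi-GRU with a fully-connected fusion layer), `no_contrast` (train
#'   without the contrastive objective).
#' @return a `nanocon_config` list; `repr_dim` is derived as
#'   `2 * gru_hidden`.
#' @export
nanocon_config <- function(embed_dim = 64L, n_transformer_layers = 2L,
                           n_heads = 4L, signal_encoder_dims = c(64L, 64L),
                           gru_hidden = 64L, gru_dropout = 0.2,
                           ablation = character()) {
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  if (any(c(embed_dim, n_transformer_layers, n_heads, signal_encoder_dims,
            gru_hidden) < 1)) stop("all dimensions must be positive")
  if (gru_dropout < 0 || gru_dropout >= 1) stop("gru_dropout must be in [0, 1)")
  unknown <- setdiff(ablation, ABLATION_FLAGS)
  if (length(unknown))
    stop("unknown ablation flag: ", paste(unknown, collapse = ", "))
  structure(list(
    embed_dim = as.integer(embed_dim),
    n_transformer_layers = as.integer(n_transformer_layers),
    n_heads = as.integer(n_heads),
    signal_encoder_dims = as.integer(signal_encoder_dims),
    gru_hidden = as.integer(gru_hidden),
    gru_dropout = gru_dropout,
    repr_dim = 2L * as.integer(gru_hidden),
    ablation = ablation
  ), class = "nanocon_config")
}

#' @export
print.nanocon_config <- function(x, ...) {
  cat("<nanocon_config>\n")
  cat(sprintf("  transformer: %d layers, %d heads, embed %d\n",
              x$n_transformer_layers, x$n_heads, x$embed_dim))
  cat(sprintf("  signal encoder: 39 -> %s\n",
              paste(x$signal_encoder_dims, collapse = " -> ")))
  cat(sprintf("  fusion: %s (repr_dim %d), dropout %.2f\n",
              if ("no_gru" %in% x$ablation) "fully-connected" else "Bi-GRU",
              x$repr_dim, x$gru_dropout))
  if (length(x$ablation)) cat("  ablation:", paste(x$ablation, collapse = ", "), "\n")
  invisible(x)
}

xavier <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

zeros_row <- function(n) matrix(0, 1L, n)

# Initialize all trainable parameters for a configuration. Classifier
# parameters are prefixed "cls_"; everything else belongs to the encoder
# (the feature-fusion module) for the purposes of the freezing schedule.
init_params <- function(config, vocab_size, seed = 1L) {
  with_seed(seed, {
    d <- config$embed_dim
    p <- list(
      emb = matrix(stats::rnorm(vocab_size * d, 0, 0.05), vocab_size, d),
      pos = matrix(stats::rnorm(N_TOKENS * d, 0, 0.05), N_TOKENS, d)
    )
    dff <- 2L * d
    for (l in seq_len(config$n_transformer_layers)) {
      pre <- sprintf("L%d_", l)
      p[[paste0(pre, "Wq")]] <- xavier(d, d)
      p[[paste0(pre, "Wk")]] <- xavier(d, d)
      p[[paste0(pre, "Wv")]] <- xavier(d, d)
      p[[paste0(pre, "Wo")]] <- xavier(d, d)
      p[[paste0(pre, "bo")]] <- zeros_row(d)
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "ln1_b")]] <- zeros_row(d)
      p[[paste0(pre, "W1")]] <- xavier(d, dff)
      p[[paste0(pre, "b1")]] <- zeros_row(dff)
      p[[paste0(pre, "W2")]] <- xavier(dff, d)
      p[[paste0(pre, "b2")]] <- zeros_row(d)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "ln2_b")]] <- zeros_row(d)
    }
    dims <- c(3L * MOTIF_LEN, config$signal_encoder_dims)
    for (i in seq_along(config$signal_encoder_dims)) {
      p[[sprintf("sig_W%d", i)]] <- xavier(dims[i], dims[i + 1])
      p[[sprintf("sig_b%d", i)]] <- zeros_row(dims[i + 1])
    }
    sig_dim <- utils::tail(config$signal_encoder_dims, 1L)
    fuse_in <- d + sig_dim
    h <- config$gru_hidden
    if ("no_gru" %in% config$ablation) {
      p$fuse_W <- xavier(N_TOKENS * fuse_in, config$repr_dim)
      p$fuse_b <- zeros_row(config$repr_dim)
    } else {
      for (dir in c("f", "b")) {
        p[[sprintf("gru_%s_Wi", dir)]] <- xavier(fuse_in, 3L * h)
        p[[sprintf("gru_%s_Wh", dir)]] <- xavier(h, 3L * h)
        p[[sprintf("gru_%s_bi", dir)]] <- zeros_row(3L * h)
        p[[sprintf("gru_%s_bh", dir)]] <- zeros_row(3L * h)
      }
    }
    p$cls_W1 <- xavier(config$repr_dim, 64L)
    p$cls_b1 <- zeros_row(64L)
    p$cls_W2 <- xavier(64L, 2L)
    p$cls_b2 <- zeros_row(2L)
    p
  })
}

encoder_param_names <- function(params) {
  names(params)[!startsWith(names(params), "cls_")]
}

classifier_param_names <- function(params) {
  names(params)[startsWith(names(params), "cls_")]
}

#' Scaled dot-product self-attention
#'
#' The attention primitive of the Transformer encoder:
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` with `Q = X Wq`,
#' `K = X Wk`, `V = X Wv`. Exposed as a plain numeric function so the
#' mechanism can be inspected and verified independently of the network.
#'
#' @param X sequence matrix, one embedded token per row.
#' @param Wq,Wk,Wv projection matrices with `nrow = ncol(X)`.
#' @return list with `output` (attended sequence, same rows as `X`) and
#'   `weights` (the attention matrix; every row sums to 1).
#' @examples
#' X <- matrix(rnorm(8), 2, 4)
#' W <- diag(4)
#' a <- self_attention(X, W, W, W)
#' rowSums(a$weights)
#' @export
self_attention <- function(X, Wq, Wk, Wv) {
  if (ncol(X) != nrow(Wq) || ncol(X) != nrow(Wk) || ncol(X) != nrow(Wv))
    stop("projection matrices do not conform to X")
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1L, max)
  e <- exp(S)
  P <- e / rowSums(e)
  list(output = P %*% V, weights = P)
}

# Additive attention mask restricting each token to its own instance's
# 9-token block; cached per (batch size).
block_mask <- function(n_batch, steps = N_TOKENS, neg = -1e30) {
  blk <- matrix(neg, n_batch * steps, n_batch * steps)
  for (b in seq_len(n_batch)) {
    idx <- (b - 1L) * steps + seq_len(steps)
    blk[idx, idx] <- 0
  }
  blk
}

# Assemble the 39-column signal matrix from a methyl_set, applying ablation
# masks. Signal lengths enter on a log1p scale to tame their count nature.
signal_matrix <- function(x, ablation = character()) {
  means <- if ("mask_means" %in% ablation) x$means * 0 else x$means
  stds <- if ("mask_stds" %in% ablation) x$stds * 0 else x$stds
  lens <- if ("mask_lens" %in% ablation) x$lens * 0 else log1p(x$lens)
  cbind(means, stds, lens)
}

# Forward pass over one batch. `tokens` is a B x 9 matrix of 0-based token
# ids, `signal` a B x 39 matrix. Returns the tape plus representation and
# logit nodes; dropout_mask (B x repr_dim, pre-scaled) is applied when given.
nanocon_forward <- function(params, config, tokens, signal,
                            dropout_mask = NULL, mask_cache = NULL) {
  tape <- new_tape()
  B <- nrow(tokens)
  d <- config$embed_dim
  steps <- N_TOKENS
  abl <- config$ablation

  if ("mask_sequence" %in% abl) {
    ctx <- tp_const(tape, matrix(0, B * steps, d))
  } else {
    emb <- tp_param(tape, "emb", params$emb)
    pos <- tp_param(tape, "pos", params$pos)
    flat_ids <- as.integer(t(tokens)) + 1L      # instance-major, 1-based
    X <- tp_rows(tape, emb, flat_ids)
    X <- tp_add(tape, X, tp_rows(tape, pos, rep(seq_len(steps), B)))
    mask <- if (is.null(mask_cache)) block_mask(B) else mask_cache
    d_head <- d %/% config$n_heads
    for (l in seq_len(config$n_transformer_layers)) {
      pre <- sprintf("L%d_", l)
      P <- function(s) tp_param(tape, paste0(pre, s), params[[paste0(pre, s)]])
      Q <- tp_matmul(tape, X, P("Wq"))
      K <- tp_matmul(tape, X, P("Wk"))
      V <- tp_matmul(tape, X, P("Wv"))
      heads <- vector("list", config$n_heads)
      for (hh in seq_len(config$n_heads)) {
        jdx <- (hh - 1L) * d_head + seq_len(d_head)
        Qh <- tp_cols(tape, Q, jdx)
        Kh <- tp_cols(tape, K, jdx)
        Vh <- tp_cols(tape, V, jdx)
        S <- tp_affine(tape, tp_matmul_t(tape, Qh, Kh), 1 / sqrt(d_head))
        A <- tp_softmax_masked(tape, S, mask)
        heads[[hh]] <- tp_matmul(tape, A, Vh)
      }
      H <- heads[[1L]]
      for (hh in seq_len(config$n_heads)[-1L]) H <- tp_cbind2(tape, H, heads[[hh]])
      attn <- tp_add(tape, tp_matmul(tape, H, P("Wo")), P("bo"))
      X <- tp_layernorm(tape, tp_add(tape, X, attn), P("ln1_g"), P("ln1_b"))
      ff <- tp_relu(tape, tp_add(tape, tp_matmul(tape, X, P("W1")), P("b1")))
      ff <- tp_add(tape, tp_matmul(tape, ff, P("W2")), P("b2"))
      X <- tp_layernorm(tape, tp_add(tape, X, ff), P("ln2_g"), P("ln2_b"))
    }
    ctx <- X
  }

  if (any(!is.finite(signal))) stop("non-finite values in signal features")
  sig <- tp_const(tape, signal)
  for (i in seq_along(config$signal_encoder_dims)) {
    W <- tp_param(tape, sprintf("sig_W%d", i), params[[sprintf("sig_W%d", i)]])
    b <- tp_param(tape, sprintf("sig_b%d", i), params[[sprintf("sig_b%d", i)]])
    sig <- tp_relu(tape, tp_add(tape, tp_matmul(tape, sig, W), b))
  }

  # broadcast the signal vector onto each of the 9 sequence steps
  inst_idx <- rep(seq_len(B), each = steps)
  fused_in <- tp_cbind2(tape, ctx, tp_rows(tape, sig, inst_idx))

  if ("no_gru" %in% abl) {
    flat <- tp_flatten_steps(tape, fused_in, B, steps)
    W <- tp_param(tape, "fuse_W", params$fuse_W)
    b <- tp_param(tape, "fuse_b", params$fuse_b)
    repr <- tp_relu(tape, tp_add(tape, tp_matmul(tape, flat, W), b))
  } else {
    h <- config$gru_hidden
    run_dir <- function(dir, order) {
      Wi <- tp_param(tape, sprintf("gru_%s_Wi", dir), params[[sprintf("gru_%s_Wi", dir)]])
      Wh <- tp_param(tape, sprintf("gru_%s_Wh", dir), params[[sprintf("gru_%s_Wh", dir)]])
      bi <- tp_param(tape, sprintf("gru_%s_bi", dir), params[[sprintf("gru_%s_bi", dir)]])
      bh <- tp_param(tape, sprintf("gru_%s_bh", dir), params[[sprintf("gru_%s_bh", dir)]])
      XW <- tp_add(tape, tp_matmul(tape, fused_in, Wi), bi)
      hs <- tp_const(tape, matrix(0, B, h))
      for (t in order) {
        rows_t <- (seq_len(B) - 1L) * steps + t
        xw <- tp_rows(tape, XW, rows_t)
        hw <- tp_add(tape, tp_matmul(tape, hs, Wh), bh)
        zi <- seq_len(h); ri <- h + seq_len(h); ni <- 2L * h + seq_len(h)
        z <- tp_sigmoid(tape, tp_add(tape, tp_cols(tape, xw, zi), tp_cols(tape, hw, zi)))
        r <- tp_sigmoid(tape, tp_add(tape, tp_cols(tape, xw, ri), tp_cols(tape, hw, ri)))
        nn <- tp_tanh(tape, tp_add(tape, tp_cols(tape, xw, ni),
                                   tp_mul(tape, r, tp_cols(tape, hw, ni))))
        # h_t = (1 - z) * n + z * h_{t-1}
        hs <- tp_add(tape, nn, tp_mul(tape, z, tp_add(tape, hs, tp_affine(tape, nn, -1))))
      }
      hs
    }
    repr <- tp_cbind2(tape, run_dir("f", seq_len(steps)),
                      run_dir("b", rev(seq_len(steps))))
  }

  if (!is.null(dropout_mask)) repr <- tp_mul(tape, repr, tp_const(tape, dropout_mask))

  W1 <- tp_param(tape, "cls_W1", params$cls_W1)
  b1 <- tp_param(tape, "cls_b1", params$cls_b1)
  W2 <- tp_param(tape, "cls_W2", params$cls_W2)
  b2 <- tp_param(tape, "cls_b2", params$cls_b2)
  hidden <- tp_relu(tape, tp_add(tape, tp_matmul(tape, repr, W1), b1))
  logits <- tp_add(tape, tp_matmul(tape, hidden, W2), b2)

  list(tape = tape, repr = repr, logits = logits)
}

# Row-wise softmax (numeric helper, used to turn logits into probabilities).
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text JSON holding the weights, the configuration
#' and a vocabulary fingerprint; [predict.nanocon()] refuses a checkpoint
#' whose vocabulary hash differs from the tokenizer in use.
#'
#' @param object a fitted `nanocon` model.
#' @param path output (or input) file; `.gz` is honored.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `nanocon` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "nanocon"))
  payload <- list(
    params = lapply(object$params, function(m) list(dim = dim(m), x = as.numeric(m))),
    config = unclass(object$config),
    vocab_hash = object$vocab_hash,
    history = object$history,
    best_epoch = object$best_epoch,
    seed = object$seed
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::fromJSON(readLines(gzfile(path)), simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) matrix(p$x, p$dim[1], p$dim[2]))
  cfg <- payload$config
  config <- nanocon_config(embed_dim = cfg$embed_dim,
                           n_transformer_layers = cfg$n_transformer_layers,
                           n_heads = cfg$n_heads,
                           signal_encoder_dims = cfg$signal_encoder_dims,
                           gru_hidden = cfg$gru_hidden,
                           gru_dropout = cfg$gru_dropout,
                           ablation = as.character(unlist(cfg$ablation)))
  structure(list(params = params, config = config,
                 vocab_hash = payload$vocab_hash,
                 history = as.data.frame(payload$history),
                 best_epoch = payload$best_epoch, seed = payload$seed),
            class = "nanocon")
}
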