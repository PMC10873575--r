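# Model fitting with the alternating freezing schedule, prediction,
# representation export, ablation and cross-domain protocols.

make_batches <- function(idx, batch_size) {
  split(idx, ceiling(seq_along(idx) / batch_size))
}

prepare_inputs <- function(x, vocab, ablation) {
  tokens <- tokenize(x$info$motif, vocab)
  if (is.null(dim(tokens))) tokens <- matrix(tokens, 1L)
  list(tokens = tokens, signal = signal_matrix(x, ablation),
       labels = x$info$label)
}

#' Fit the contrastive hybrid methylation caller
#'
#' Trains the feature-fusion network with the two-phase alternating
#' schedule: in the *contrastive phase* the classifier head is frozen and
#' the encoder minimizes the combined loss
#' `alpha * L_contrastive + (1 - alpha) * L_CE`; in the *classification
#' phase* the encoder is frozen and the classifier head minimizes the
#' cross-entropy alone. Phases alternate per epoch (or per batch),
#' optimized with Adam under an exponential learning-rate decay. When a
#' validation set is supplied, the returned model carries the weights of
#' the epoch with the best validation AUPRC (the metric of interest under
#' class imbalance).
#'
#' @param train labeled [methyl_set] containing both classes.
#' @param validation optional labeled [methyl_set] used for model
#'   selection.
#' @param config a [nanocon_config()].
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param alpha weight of the contrastive term in the combined loss
#'   (default 0.8); ignored (treated as 0) under the `no_contrast`
#'   ablation.
#' @param margin contrastive margin (default 2).
#' @param freeze_schedule `"per_epoch"` (default) alternates the two phases
#'   between epochs, `"per_batch"` within each epoch.
#' @param seed integer seed controlling initialization, shuffling, pairing
#'   and dropout; fits are bit-reproducible given the seed.
#' @param verbose print per-epoch progress.
#' @return an object of class `nanocon` with elements `params`, `config`,
#'   `history` (per-epoch data.frame), `best_epoch`, `vocab_hash`, `seed`.
#' @seealso [predict.nanocon()], [evaluate()], [run_ablation()]
#' @export
nanocon <- function(train, validation = NULL, config = nanocon_config(),
                    epochs = 20L, batch_size = 64L, lr = 1e-3,
                    lr_decay = 0.95, alpha = 0.8, margin = 2,
                    freeze_schedule = c("per_epoch", "per_batch"),
                    seed = 1L, verbose = FALSE) {
  stopifnot(inherits(train, "methyl_set"), inherits(config, "nanocon_config"))
  freeze_schedule <- match.arg(freeze_schedule)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  labels <- train$info$label
  if (any(is.na(labels))) stop("training data contain unlabeled instances")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes (contrastive pairing is degenerate otherwise)")
  if ("no_contrast" %in% config$ablation) alpha <- 0

  vocab <- build_vocab()
  tr <- prepare_inputs(train, vocab, config$ablation)
  va <- if (!is.null(validation)) prepare_inputs(validation, vocab, config$ablation)
  n <- nrow(train$info)
  params <- init_params(config, attr(vocab, "vocab_size"), seed = seed)
  opt_enc <- adam_init(params[encoder_param_names(params)])
  opt_cls <- adam_init(params[classifier_param_names(params)])
  mask_cache <- new.env(parent = emptyenv())
  get_mask <- function(B) {
    key <- as.character(B)
    if (is.null(mask_cache[[key]])) mask_cache[[key]] <- block_mask(B)
    mask_cache[[key]]
  }

  history <- data.frame(epoch = integer(), phase = character(),
                        loss = numeric(), val_auprc = numeric(),
                        val_auroc = numeric())
  best <- list(auprc = -Inf, params = params, epoch = NA_integer_)

  with_seed(seed + 1L, {
    for (epoch in seq_len(epochs)) {
      lr_e <- lr * lr_decay^(epoch - 1L)
      epoch_phase <- if (epoch %% 2L == 1L) "contrastive" else "classification"
      batches <- make_batches(sample.int(n), batch_size)
      losses <- numeric(0)
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        B <- length(idx)
        phase <- if (freeze_schedule == "per_epoch") epoch_phase
          else if (bi %% 2L == 1L) "contrastive" else "classification"
        if (phase == "contrastive" && B < 2L) next
        keep_prob <- 1 - config$gru_dropout
        drop_mask <- if (config$gru_dropout > 0)
          matrix(stats::rbinom(B * config$repr_dim, 1L, keep_prob) / keep_prob,
                 B, config$repr_dim)
        fw <- nanocon_forward(params, config, tr$tokens[idx, , drop = FALSE],
                              tr$signal[idx, , drop = FALSE],
                              dropout_mask = drop_mask, mask_cache = get_mask(B))
        y <- tr$labels[idx]
        ce <- tp_softmax_ce(fw$tape, fw$logits, y)
        if (phase == "contrastive") {
          if (alpha > 0) {
            pr <- make_pairs(y, seed = sample.int(.Machine$integer.max, 1L))
            con <- tp_contrastive(fw$tape,
                                  tp_rows(fw$tape, fw$repr, pr$idx_a),
                                  tp_rows(fw$tape, fw$repr, pr$idx_b),
                                  pr$y, margin = margin)
            loss <- tp_axpy(fw$tape, con, ce, alpha, 1 - alpha)
          } else loss <- ce
          grads <- backward(fw$tape, loss)
          params <- adam_step(params, grads, opt_enc,
                              encoder_param_names(params), lr_e)
        } else {
          loss <- ce
          grads <- backward(fw$tape, loss)
          params <- adam_step(params, grads, opt_cls,
                              classifier_param_names(params), lr_e)
        }
        losses <- c(losses, loss$val)
      }
      val_auprc <- NA_real_; val_auroc <- NA_real_
      if (!is.null(va)) {
        p <- predict_prob(params, config, va, get_mask)
        rep_v <- confusion_and_metrics(p, va$labels)
        val_auprc <- rep_v$AUPRC; val_auroc <- rep_v$AUROC
        # >= so that among equal-AUPRC epochs the latest (whose classifier
        # head has seen the most training) is kept
        if (val_auprc >= best$auprc) {
          best$auprc <- val_auprc; best$params <- params; best$epoch <- epoch
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, phase = epoch_phase, loss = mean(losses),
        val_auprc = val_auprc, val_auroc = val_auroc))
      if (verbose)
        message(sprintf("epoch %3d [%s] loss %.4f val AUPRC %s", epoch,
                        epoch_phase, mean(losses),
                        ifelse(is.na(val_auprc), "-", sprintf("%.4f", val_auprc))))
    }
  })

  if (is.null(va)) { best$params <- params; best$epoch <- epochs }
  structure(list(params = best$params, config = config, history = history,
                 best_epoch = best$epoch, vocab_hash = vocab_hash(vocab),
                 seed = seed, alpha = alpha, margin = margin,
                 n_train = n),
            class = "nanocon")
}

# Batched probability predictions from raw parameter list (no dropout).
predict_prob <- function(params, config, inputs, get_mask, batch_size = 64L,
                         want_repr = FALSE) {
  n <- nrow(inputs$tokens)
  p <- numeric(n)
  reprs <- if (want_repr) matrix(0, n, config$repr_dim)
  for (idx in make_batches(seq_len(n), batch_size)) {
    fw <- nanocon_forward(params, config, inputs$tokens[idx, , drop = FALSE],
                          inputs$signal[idx, , drop = FALSE],
                          mask_cache = get_mask(length(idx)))
    p[idx] <- softmax_rows(fw$logits$val)[, 2L]
    if (want_repr) reprs[idx, ] <- fw$repr$val
  }
  if (want_repr) list(p = p, repr = reprs) else p
}

#' Predict methylation probabilities or representations
#'
#' @param object a fitted `nanocon` model.
#' @param newdata a [methyl_set].
#' @param type `"prob"` for `P(methylated)` per instance, `"class"` for the
#'   thresholded 0/1 call, `"repr"` for the fused representation matrix
#'   (one `repr_dim` row per instance, e.g. for t-SNE/UMAP visualization).
#' @param threshold probability cut for `type = "class"`.
#' @param batch_size prediction batch size.
#' @param vocab tokenizer vocabulary; must match the one the model was
#'   trained with.
#' @param ... ignored.
#' @return numeric vector (`prob`), integer vector (`class`) or matrix
#'   (`repr`).
#' @export
predict.nanocon <- function(object, newdata, type = c("prob", "class", "repr"),
                            threshold = 0.5, batch_size = 64L,
                            vocab = build_vocab(), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "methyl_set"))
  if (!identical(vocab_hash(vocab), object$vocab_hash))
    stop("tokenizer vocabulary does not match the model checkpoint")
  inputs <- prepare_inputs(newdata, vocab, object$config$ablation)
  mask_cache <- new.env(parent = emptyenv())
  get_mask <- function(B) {
    key <- as.character(B)
    if (is.null(mask_cache[[key]])) mask_cache[[key]] <- block_mask(B)
    mask_cache[[key]]
  }
  out <- predict_prob(object$params, object$config, inputs, get_mask,
                      batch_size = batch_size, want_repr = type == "repr")
  switch(type,
         prob = out,
         class = as.integer(out >= threshold),
         repr = out$repr)
}

#' Evaluate a fitted model on a labeled test set
#'
#' @param object a fitted `nanocon` model.
#' @param test labeled [methyl_set].
#' @param threshold probability cut for the confusion matrix.
#' @return a `metric_report` (see [confusion_and_metrics()]).
#' @export
evaluate <- function(object, test, threshold = 0.5) {
  p <- stats::predict(object, test)
  confusion_and_metrics(p, test$info$label, threshold = threshold)
}

#' Cross-domain evaluation
#'
#' Evaluates a frozen model trained on one domain (species, motif context,
#' simulator regime) on a test set from another, the protocol behind
#' cross-species and cross-context transfer matrices.
#'
#' @param object a `nanocon` model trained on domain A.
#' @param test_b labeled [methyl_set] from domain B (identical feature
#'   schema: 13-base motifs, three 13-long tracks).
#' @param threshold probability cut.
#' @return a `metric_report`.
#' @export
cross_domain_eval <- function(object, test_b, threshold = 0.5) {
  stopifnot(inherits(object, "nanocon"))
  if (!inherits(test_b, "methyl_set")) stop("test_b must be a methyl_set")
  evaluate(object, test_b, threshold = threshold)
}

#' Train and evaluate one ablation variant
#'
#' Re-trains the model with a single branch disabled, under otherwise
#' identical configuration, data and seed, and reports the full metric
#' suite on the test partition.
#'
#' @param splits list with `train`, `validation`, `test` (as from
#'   [split_dataset()]).
#' @param variant one of `mask_means`, `mask_stds`, `mask_lens`,
#'   `mask_sequence`, `no_gru`, `no_contrast`.
#' @param config base [nanocon_config()] (without the ablation flag).
#' @param ... further arguments passed to [nanocon()].
#' @return a `metric_report` with the fitted variant attached as attribute
#'   `"model"`.
#' @export
run_ablation <- function(splits, variant, config = nanocon_config(), ...) {
  if (length(variant) != 1L || !variant %in% ABLATION_FLAGS)
    stop("unknown ablation flag: ", paste(variant, collapse = ", "))
  cfg <- nanocon_config(embed_dim = config$embed_dim,
                        n_transformer_layers = config$n_transformer_layers,
                        n_heads = config$n_heads,
                        signal_encoder_dims = config$signal_encoder_dims,
                        gru_hidden = config$gru_hidden,
                        gru_dropout = config$gru_dropout,
                        ablation = union(config$ablation, variant))
  fit <- nanocon(splits$train, splits$validation, config = cfg, ...)
  rep <- evaluate(fit, splits$test)
  attr(rep, "model") <- fit
  rep
}

#' @export
print.nanocon <- function(x, ...) {
  cat("<nanocon> contrastive hybrid methylation caller\n")
  cat(sprintf("  trained on %d instances, %d epochs (best epoch %s)\n",
              x$n_train, nrow(x$history),
              ifelse(is.na(x$best_epoch), "last", x$best_epoch)))
  print(x$config)
  invisible(x)
}

#' @export
summary.nanocon <- function(object, ...) {
  h <- object$history
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(h, 5L), row.names = FALSE)
  if (any(!is.na(h$val_auprc)))
    cat(sprintf("Best validation AUPRC %.4f at epoch %d\n",
                max(h$val_auprc, na.rm = TRUE), object$best_epoch))
  np <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("Parameters: %d tensors, %d scalars\n", length(object$params), np))
  invisible(object)
}

#' @export
coef.nanocon <- function(object, ...) object$params

#' Plot training history
#'
#' Draws the per-epoch training loss and, when available, validation AUPRC.
#'
#' @param x a fitted `nanocon` model.
#' @param ... passed to [plot()].
#' @export
plot.nanocon <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (any(!is.na(h$val_auprc))) 2 else 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  if (any(!is.na(h$val_auprc)))
    plot(h$epoch, h$val_auprc, type = "b", xlab = "epoch",
         ylab = "validation AUPRC", main = "model selection", ...)
  invisible(x)
}
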