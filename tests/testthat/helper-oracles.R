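# Independent brute-force oracles and small fixture builders.

# Scalar-loop contrastive loss: one pair at a time, cosine written out.
oracle_contrastive <- function(a, b, y, margin = 2) {
  n <- nrow(a)
  total <- 0
  for (i in seq_len(n)) {
    xi <- a[i, ]; xj <- b[i, ]
    D <- sum(xi * xj) / (sqrt(sum(xi^2)) * sqrt(sum(xj^2)))
    total <- total + (1 - y[i]) * D^2 + y[i] * max(margin - D, 0)^2
  }
  total / (2 * n)
}

# Scalar-loop mean binary cross-entropy.
oracle_ce <- function(p, y, eps = 1e-7) {
  total <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    total <- total - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  total / length(p)
}

# O(n^2) pairwise AUROC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auroc <- function(p, labels) {
  pos <- p[labels == 1]; neg <- p[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Average precision by direct confusion counting at each distinct threshold.
oracle_ap <- function(p, labels) {
  thresholds <- sort(unique(p), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (t in thresholds) {
    tp <- sum(p >= t & labels == 1)
    fp <- sum(p >= t & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# A tiny hand-built methyl_set (n instances, alternating labels).
tiny_methyl_set <- function(n = 4L, motif = "ACGTAGCTTACGT") {
  methyl_set(chrom = "chr1", pos = seq_len(n) - 1L, strand = "+",
             read_id = sprintf("r%d", seq_len(n)),
             motif = rep(motif, n),
             means = matrix(seq_len(n * 13) / 10, n, 13),
             stds = matrix(0.5, n, 13),
             lens = matrix(5, n, 13),
             label = rep_len(c(1L, 0L), n))
}

# One small separable fit, trained once per test run and memoized; several
# test files probe it (prediction, checkpointing, cross-domain transfer).
shared_fit_cache <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(shared_fit_cache$fit)) {
    ms <- simulate_dataset(sim_config(n_instances = 600L, proportion = 0.25,
                                      delta = 3, noise_sigma = 1, seed = 1L))
    sp <- split_dataset(ms, seed = 1L)
    shared_fit_cache$splits <- sp
    shared_fit_cache$fit <- nanocon(sp$train, sp$validation, epochs = 4L,
                                    seed = 1L)
  }
  list(fit = shared_fit_cache$fit, splits = shared_fit_cache$splits)
}
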