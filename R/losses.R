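# Contrastive pairing and the training losses.

#' Pair a labeled batch for contrastive learning
#'
#' Randomly splits a batch into two equal halves (an odd leftover instance
#' is dropped) and pairs the i-th element of one half with the i-th of the
#' other. Each pair carries the indicator `y = 1` when both members share a
#' class and `y = 0` otherwise.
#'
#' @param labels vector of 0/1 labels, or a [methyl_set] whose labels are
#'   used.
#' @param seed integer seed; the same seed reproduces the same pairing.
#' @return list with integer index vectors `idx_a`, `idx_b` (into the
#'   batch), the same-class indicator `y`, and the pair count `n_pairs`.
#' @examples
#' make_pairs(c(1, 1, 0, 0), seed = 1)$n_pairs
#' @export
make_pairs <- function(labels, seed = 1L) {
  if (inherits(labels, "methyl_set")) labels <- labels$info$label
  n <- length(labels)
  if (n < 2L) stop("need at least 2 instances to form a contrastive pair")
  perm <- with_seed(seed, sample.int(n))
  m <- n %/% 2L
  idx_a <- perm[seq_len(m)]
  idx_b <- perm[m + seq_len(m)]
  list(idx_a = idx_a, idx_b = idx_b,
       y = as.integer(labels[idx_a] == labels[idx_b]), n_pairs = m)
}

#' Cosine similarity between representation vectors
#'
#' `D(x, y) = (x . y) / (|x| |y|)`, the similarity used as the "distance"
#' inside the contrastive loss.
#'
#' @param x,y numeric vectors of equal length, or matrices with one
#'   representation per row (compared row-wise).
#' @return similarity in `[-1, 1]` (a vector for matrix input).
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1)) # 0
#' @export
cosine_similarity <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
    if (any(nx == 0) || any(ny == 0)) stop("cosine similarity undefined for a zero vector")
    return(rowSums(x * y) / (nx * ny))
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Margin contrastive loss over paired representations
#'
#' For N pairs with same-class indicator `y` and pair similarity
#' `D = cosine_similarity(x_i, x_j)`:
#' `L = (1 / 2N) * sum((1 - y) * D^2 + y * max(margin - D, 0)^2)`.
#' Same-class pairs (`y = 1`) are pushed toward high similarity,
#' different-class pairs toward zero similarity. Note that with the default
#' margin of 2 and `D` bounded by 1, the same-class term is strictly
#' positive for every pair; the loss can therefore never reach zero on a
#' batch containing a same-class pair.
#'
#' @param reprs_a,reprs_b matrices of paired representations (one pair per
#'   row).
#' @param y 0/1 same-class indicators, one per pair.
#' @param margin similarity threshold (default 2).
#' @return the scalar loss (non-negative).
#' @examples
#' contrastive_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1), y = 1) # 0.5
#' @export
contrastive_loss <- function(reprs_a, reprs_b, y, margin = 2) {
  reprs_a <- rbind(reprs_a); reprs_b <- rbind(reprs_b)
  n <- nrow(reprs_a)
  if (n == 0L) stop("empty pair batch")
  if (nrow(reprs_b) != n || length(y) != n)
    stop("pair batch components have mismatched lengths")
  D <- cosine_similarity(reprs_a, reprs_b)
  sum((1 - y) * D^2 + y * pmax(margin - D, 0)^2) / (2 * n)
}

#' Mean binary cross-entropy
#'
#' `L = (1/N) * sum(-(y * log p + (1 - y) * log(1 - p)))`, with predicted
#' probabilities clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param p predicted probabilities of class 1.
#' @param y 0/1 labels.
#' @param eps clamp (default `1e-7`).
#' @return the scalar loss (non-negative).
#' @examples
#' cross_entropy_loss(0.5, 1) # log(2)
#' @export
cross_entropy_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  if (any(is.na(p)) || any(!is.finite(p))) stop("NaN or non-finite probability")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined training loss
#'
#' `L = alpha * L_contrastive + (1 - alpha) * L_CE`; `alpha = 0.8` weights
#' the representation objective over the classification objective.
#'
#' @param l_contrastive,l_ce the two component losses.
#' @param alpha weight in `[0, 1]`.
#' @return the weighted sum.
#' @export
combined_loss <- function(l_contrastive, l_ce, alpha = 0.8) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * l_contrastive + (1 - alpha) * l_ce
}
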