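# Synthetic nanopore-feature simulator: class-conditional current shifts
# around the central cytosine, motif-context structure, configurable
# imbalance. Gives every other module a testable ground truth.

BASES <- c("A", "C", "G", "T")
H_BASES <- c("A", "C", "T")

# Fixed per-base current levels (normalized, dimensionless). Arbitrary but
# documented values; purines above zero, pyrimidines below.
BASE_MU <- c(A = 0.5, C = -0.3, G = 0.3, T = -0.5)

#' Simulator configuration
#'
#' The generator draws per-base current means from
#' `Normal(mu(base) + label * delta * [|i - center| <= effect_width], noise_sigma)`
#' when `"means"` is an effect track, per-base standard deviations from
#' `|Normal(0, 0.5)| + 0.1` (plus `0.2 * delta` inside the window on
#' methylated instances when `"stds"` is an effect track), and per-base
#' signal lengths from `1 + Poisson(len_rate)` (with the rate raised by
#' `delta` inside the window when `"lens"` is an effect track).
#'
#' @param n_instances total instances to generate (>= 2).
#' @param proportion positives per negative (matching the imbalance regimes
#'   of real methylation datasets, roughly 0.02 to 1.85).
#' @param context motif context: `"CpG"`, `"CHG"`, `"CHH"` or `"mixed"`.
#' @param delta mean-current shift on methylated instances (in units of the
#'   normalized current).
#' @param effect_width half-width (in bases) of the affected window around
#'   the central cytosine, emulating the ~5-base pore footprint; in
#'   `[0, 6]`.
#' @param noise_sigma per-base current noise standard deviation (> 0).
#' @param len_rate mean extra signal points per base.
#' @param effect_tracks which tracks carry the class signal; subset of
#'   `c("means", "stds", "lens")`.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_instances = 4000L, proportion = 0.25,
                       context = "mixed", delta = 3, effect_width = 2L,
                       noise_sigma = 1, len_rate = 8,
                       effect_tracks = "means", seed = 1L) {
  if (n_instances < 2L) stop("n_instances must be >= 2")
  if (proportion <= 0) stop("proportion must be > 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (effect_width < 0L || effect_width > 6L) stop("effect_width must be in [0, 6]")
  if (!context %in% c("CpG", "CHG", "CHH", "mixed")) stop("unknown context")
  if (length(effect_tracks) && !all(effect_tracks %in% c("means", "stds", "lens")))
    stop("effect_tracks must be a subset of means/stds/lens")
  structure(list(n_instances = as.integer(n_instances), proportion = proportion,
                 context = context, delta = delta,
                 effect_width = as.integer(effect_width),
                 noise_sigma = noise_sigma, len_rate = len_rate,
                 effect_tracks = effect_tracks, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate 13-base motifs with a fixed cytosine context
#'
#' Bases are uniform over `{A,C,G,T}` except the constrained positions:
#' the center (position 7) is always `C`; `CpG` forces the next base to `G`;
#' `CHG` forces position 8 to `H` (A/C/T) and position 9 to `G`; `CHH`
#' forces positions 8 and 9 to `H`. `mixed` draws a context uniformly per
#' motif.
#'
#' @param n number of motifs.
#' @param context `"CpG"`, `"CHG"`, `"CHH"` or `"mixed"`.
#' @return character vector of 13-base motifs; the realized context of each
#'   motif is attached as attribute `"context"`.
#' @export
simulate_motif <- function(n, context = "mixed") {
  ctx <- if (context == "mixed")
    sample(c("CpG", "CHG", "CHH"), n, replace = TRUE) else rep(context, n)
  m <- matrix(sample(BASES, n * MOTIF_LEN, replace = TRUE), n, MOTIF_LEN)
  m[, MOTIF_CENTER] <- "C"
  p1 <- MOTIF_CENTER + 1L
  p2 <- MOTIF_CENTER + 2L
  cpg <- ctx == "CpG"; chg <- ctx == "CHG"; chh <- ctx == "CHH"
  m[cpg, p1] <- "G"
  if (any(chg)) {
    m[chg, p1] <- sample(H_BASES, sum(chg), replace = TRUE)
    m[chg, p2] <- "G"
  }
  if (any(chh)) {
    m[chh, p1] <- sample(H_BASES, sum(chh), replace = TRUE)
    m[chh, p2] <- sample(H_BASES, sum(chh), replace = TRUE)
  }
  structure(apply(m, 1L, paste, collapse = ""), context = ctx)
}

# Draw the three signal tracks for n instances with given labels.
simulate_tracks <- function(motifs, labels, config) {
  n <- length(motifs)
  base_mat <- matrix(BASE_MU[unlist(strsplit(motifs, ""))],
                     n, MOTIF_LEN, byrow = TRUE)
  window <- abs(seq_len(MOTIF_LEN) - MOTIF_CENTER) <= config$effect_width
  shift <- outer(as.numeric(labels), as.numeric(window)) * config$delta
  means <- base_mat +
    ("means" %in% config$effect_tracks) * shift +
    matrix(stats::rnorm(n * MOTIF_LEN, 0, config$noise_sigma), n, MOTIF_LEN)
  stds <- abs(matrix(stats::rnorm(n * MOTIF_LEN, 0, 0.5), n, MOTIF_LEN)) + 0.1 +
    ("stds" %in% config$effect_tracks) * 0.2 * shift
  len_rate <- config$len_rate + ("lens" %in% config$effect_tracks) * shift
  lens <- 1 + matrix(stats::rpois(n * MOTIF_LEN, lambda = as.numeric(len_rate)),
                     n, MOTIF_LEN)
  list(means = means, stds = stds, lens = lens)
}

#' Simulate a labeled methylation feature dataset
#'
#' Generates `n_instances` per-read feature records at the requested
#' positive:negative proportion (`n_pos = round(n * p / (1 + p))`), with
#' class-conditional signal shifts confined to `effect_tracks` inside the
#' window around the central cytosine. Identical configurations (including
#' the seed) produce identical datasets.
#'
#' @param config a [sim_config()].
#' @return a [methyl_set]; the generating configuration is attached as
#'   attribute `"manifest"` (a list with the config fields plus realized
#'   class counts).
#' @examples
#' ms <- simulate_dataset(sim_config(n_instances = 50, seed = 7))
#' table(ms$info$label)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_instances
  n_pos <- round(n * config$proportion / (1 + config$proportion))
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L)
    stop("requested proportion yields an empty class at this n")
  with_seed(config$seed, {
    labels <- sample(rep(c(1L, 0L), c(n_pos, n_neg)))
    motifs <- simulate_motif(n, config$context)
    tracks <- simulate_tracks(motifs, labels, config)
    ms <- methyl_set(
      chrom = "sim1", pos = seq_len(n) - 1L, strand = "+",
      read_id = sprintf("read%07d", seq_len(n)), motif = motifs,
      means = tracks$means, stds = tracks$stds, lens = tracks$lens,
      label = labels
    )
    attr(ms, "manifest") <- c(unclass(config),
                              list(n_positive = n_pos, n_negative = n_neg))
    ms
  })
}

#' Simulate a bisulfite cytosine report from site truth states
#'
#' Coverage is Poisson with the given mean (so some sites fall below any
#' coverage filter); methylated counts are binomial with success
#' probability 0.97 (methylated truth), 0.01 (unmethylated) or 0.5
#' (ambiguous).
#'
#' @param truth character vector over
#'   `c("methylated", "unmethylated", "ambiguous")`, one per site, or a
#'   data.frame with columns `chrom`, `pos`, `strand`, `truth`.
#' @param mean_coverage Poisson mean of per-site coverage.
#' @param seed integer RNG seed.
#' @return data.frame in [read_bisulfite_report()] layout.
#' @export
simulate_bisulfite_report <- function(truth, mean_coverage = 20, seed = 1L) {
  if (is.data.frame(truth)) {
    sites <- truth
  } else {
    sites <- data.frame(chrom = "sim1", pos = seq_along(truth) - 1L,
                        strand = "+", truth = truth, stringsAsFactors = FALSE)
  }
  if (!all(sites$truth %in% c("methylated", "unmethylated", "ambiguous")))
    stop("unknown truth state")
  with_seed(seed, {
    n <- nrow(sites)
    cov <- stats::rpois(n, mean_coverage)
    rate <- c(methylated = 0.97, unmethylated = 0.01, ambiguous = 0.5)[sites$truth]
    meth <- stats::rbinom(n, cov, rate)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               count_meth = meth, count_unmeth = cov - meth,
               context = sample(c("CpG", "CHG", "CHH"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
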