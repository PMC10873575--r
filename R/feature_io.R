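# Per-read feature records, bisulfite reports, ground-truth labeling, splits.

MOTIF_LEN <- 13L
MOTIF_CENTER <- 7L  # 1-based index of the candidate cytosine

#' Per-read methylation candidate instances
#'
#' A `methyl_set` holds per-read, per-site nanopore feature records: the
#' 13-base motif centered on a candidate cytosine together with three
#' 13-long per-base signal tracks (normalized current mean, current standard
#' deviation, number of raw signal points) and an optional binary label.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 0-based genomic coordinate of the central
#'   cytosine on the read strand.
#' @param strand character vector over `"+"`/`"-"`.
#' @param read_id character vector of read identifiers.
#' @param motif character vector of 13-base strings over `A,C,G,T,N`; the
#'   7th base (the center) must be `C` on the read strand.
#' @param means,stds,lens numeric matrices with one row per instance and 13
#'   columns: per-base signal means (dimensionless, normalized), per-base
#'   standard deviations (non-negative) and per-base signal lengths
#'   (positive integers).
#' @param label integer vector over `0`, `1`, `NA` (unlabeled).
#' @return An object of class `methyl_set`.
#' @examples
#' ms <- methyl_set(
#'   chrom = "chr1", pos = 100L, strand = "+", read_id = "r1",
#'   motif = "ACGTAGCTTACGT",
#'   means = matrix(0, 1, 13), stds = matrix(1, 1, 13),
#'   lens = matrix(5, 1, 13), label = 1L
#' )
#' nrow(ms)
#' @export
methyl_set <- function(chrom, pos, strand, read_id, motif,
                       means, stds, lens, label = NA_integer_) {
  n <- length(motif)
  means <- as_track_matrix(means, n, "means")
  stds <- as_track_matrix(stds, n, "stds")
  lens <- as_track_matrix(lens, n, "lens")
  info <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), read_id = as.character(read_id),
    motif = toupper(as.character(motif)),
    label = rep_len(as.integer(label), n),
    stringsAsFactors = FALSE
  )
  x <- structure(list(info = info, means = means, stds = stds, lens = lens),
                 class = "methyl_set")
  validate_methyl_set(x)
  x
}

as_track_matrix <- function(m, n, what) {
  m <- as.matrix(m)
  if (n == 1 && length(m) == MOTIF_LEN) m <- matrix(as.numeric(m), 1L)
  if (nrow(m) != n || ncol(m) != MOTIF_LEN)
    stop(sprintf("'%s' must be a %d x %d matrix", what, n, MOTIF_LEN))
  storage.mode(m) <- "double"
  m
}

validate_methyl_set <- function(x) {
  info <- x$info
  bad <- which(nchar(info$motif) != MOTIF_LEN)
  if (length(bad))
    stop("motif length != 13 at instance ", bad[1])
  centers <- substr(info$motif, MOTIF_CENTER, MOTIF_CENTER)
  bad <- which(centers != "C")
  if (length(bad))
    stop("central base is not 'C' at instance ", bad[1])
  if (any(grepl("[^ACGTN]", info$motif)))
    stop("motif contains characters outside {A,C,G,T,N}")
  if (any(!is.finite(x$means)))
    stop("non-finite values in means")
  if (any(x$stds < 0, na.rm = TRUE))
    stop("negative values in stds")
  if (any(x$lens < 1, na.rm = TRUE))
    stop("signal lengths must be >= 1")
  if (!all(info$label %in% c(0L, 1L, NA_integer_)))
    stop("labels must be 0, 1 or NA")
  if (!all(info$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(x)
}

#' @export
dim.methyl_set <- function(x) c(nrow(x$info), MOTIF_LEN)

#' Subset a methyl_set by instance index
#' @param x a `methyl_set`.
#' @param i integer or logical index over instances.
#' @param ... ignored.
#' @return the subsetted `methyl_set`.
#' @export
`[.methyl_set` <- function(x, i, ...) {
  structure(list(
    info = x$info[i, , drop = FALSE],
    means = x$means[i, , drop = FALSE],
    stds = x$stds[i, , drop = FALSE],
    lens = x$lens[i, , drop = FALSE]
  ), class = "methyl_set")
}

#' @export
print.methyl_set <- function(x, ...) {
  n <- nrow(x$info)
  lab <- x$info$label
  cat(sprintf("<methyl_set> %d instances (%d positive, %d negative, %d unlabeled)\n",
              n, sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
              sum(is.na(lab))))
  if (n > 0) {
    show <- utils::head(x$info, 4L)
    print(show, row.names = FALSE)
    if (n > 4L) cat("  ...\n")
  }
  invisible(x)
}

rbind_methyl_set <- function(...) {
  xs <- list(...)
  structure(list(
    info = do.call(rbind, lapply(xs, `[[`, "info")),
    means = do.call(rbind, lapply(xs, `[[`, "means")),
    stds = do.call(rbind, lapply(xs, `[[`, "stds")),
    lens = do.call(rbind, lapply(xs, `[[`, "lens"))
  ), class = "methyl_set")
}

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

label_token <- function(label) ifelse(is.na(label), ".", as.character(label))

FEATURE_COLS <- c("chrom", "pos", "strand", "read_id", "motif",
                  "means", "stds", "lens", "label")

#' Read a per-site feature table
#'
#' Parses a tab-separated feature file with columns `chrom`, `pos`, `strand`,
#' `read_id`, `motif`, `means`, `stds`, `lens`, `label`, where the three
#' signal tracks are comma-joined lists of 13 numbers and the label token is
#' `0`, `1` or `.` (unlabeled). Files ending in `.gz` are decompressed
#' transparently.
#'
#' @param path path to the (optionally gzipped) TSV file; a header line is
#'   optional and detected by its first field.
#' @param strict if `TRUE` (default) malformed rows abort with the offending
#'   line number; if `FALSE` they are skipped with a warning.
#' @return a [methyl_set].
#' @seealso [write_feature_file()]
#' @export
read_feature_file <- function(path, strict = TRUE) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) && startsWith(lines[1], "chrom")) lines <- lines[-1]
  lines_no <- seq_along(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]; lines_no <- lines_no[keep]
  if (!length(lines)) return(empty_methyl_set())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(FEATURE_COLS))
  parse_fail <- function(i, why) {
    msg <- sprintf("feature file %s: line %d: %s", path, lines_no[i], why)
    if (strict) stop(msg) else warning(msg)
  }
  if (length(bad)) {
    parse_fail(bad[1], sprintf("expected %d tab-separated fields, found %d",
                               length(FEATURE_COLS), nf[bad[1]]))
    keep2 <- nf == length(FEATURE_COLS)
    fields <- fields[keep2]; lines_no <- lines_no[keep2]
  }
  if (!length(fields)) return(empty_methyl_set())
  m <- do.call(rbind, fields)

  tracks <- lapply(6:8, function(j) strsplit(m[, j], ",", fixed = TRUE))
  track_len_ok <- lengths(tracks[[1]]) == MOTIF_LEN &
    lengths(tracks[[2]]) == MOTIF_LEN & lengths(tracks[[3]]) == MOTIF_LEN
  motif_ok <- nchar(m[, 5]) == MOTIF_LEN
  label_ok <- m[, 9] %in% c("0", "1", ".")
  ok <- track_len_ok & motif_ok & label_ok
  if (any(!ok)) {
    i <- which(!ok)[1]
    why <- if (!motif_ok[i]) "motif is not 13 bases" else
      if (!track_len_ok[i]) "signal track does not have 13 values" else
        sprintf("unknown label token '%s'", m[i, 9])
    parse_fail(i, why)
    m <- m[ok, , drop = FALSE]
    tracks <- lapply(tracks, `[`, ok)
    if (!nrow(m)) return(empty_methyl_set())
  }
  to_mat <- function(tr) matrix(as.numeric(unlist(tr)), ncol = MOTIF_LEN, byrow = TRUE)
  label <- rep(NA_integer_, nrow(m))
  known <- m[, 9] != "."
  label[known] <- as.integer(m[known, 9])
  methyl_set(chrom = m[, 1], pos = as.integer(m[, 2]), strand = m[, 3],
             read_id = m[, 4], motif = m[, 5],
             means = to_mat(tracks[[1]]), stds = to_mat(tracks[[2]]),
             lens = to_mat(tracks[[3]]), label = label)
}

empty_methyl_set <- function() {
  structure(list(
    info = data.frame(chrom = character(), pos = integer(), strand = character(),
                      read_id = character(), motif = character(), label = integer(),
                      stringsAsFactors = FALSE),
    means = matrix(numeric(), 0L, MOTIF_LEN),
    stds = matrix(numeric(), 0L, MOTIF_LEN),
    lens = matrix(numeric(), 0L, MOTIF_LEN)
  ), class = "methyl_set")
}

#' Write a per-site feature table
#'
#' Inverse of [read_feature_file()]; numbers are written with enough digits
#' that a read/write round trip is exact. A `.gz` suffix triggers gzip
#' compression.
#'
#' @param x a [methyl_set].
#' @param path output path.
#' @param header write a header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_feature_file <- function(x, path, header = TRUE) {
  join <- function(m) apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (header) writeLines(paste(FEATURE_COLS, collapse = "\t"), con)
  if (nrow(x$info) > 0) {
    rows <- paste(x$info$chrom, x$info$pos, x$info$strand, x$info$read_id,
                  x$info$motif, join(x$means), join(x$stds), join(x$lens),
                  label_token(x$info$label), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a bisulfite cytosine report
#'
#' Reads a Bismark-style cytosine report: tab-separated columns `chrom`,
#' `pos`, `strand`, `count_meth`, `count_unmeth`, `context` (one of
#' `CpG`/`CHG`/`CHH`). Gzip-transparent.
#'
#' @param path path to the report.
#' @return a data.frame with those six columns.
#' @export
read_bisulfite_report <- function(path) {
  df <- utils::read.table(gzfile(path), sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "strand",
                                        "count_meth", "count_unmeth", "context"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character"))
  if (any(df$count_meth < 0) || any(df$count_unmeth < 0))
    stop("negative counts in bisulfite report")
  df
}

#' @rdname read_bisulfite_report
#' @param records data.frame as returned by `read_bisulfite_report`.
#' @export
write_bisulfite_report <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Call per-site ground-truth labels from bisulfite counts
#'
#' Applies the bisulfite labeling rule: a site is *positive* (methylated)
#' when its coverage exceeds `min_coverage` and its methylation rate exceeds
#' `pos_rate`; *negative* when its methylation rate is exactly zero (and, by
#' default, the same coverage filter holds); anything else — including sites
#' with zero coverage, whose rate is undefined — is *excluded*. Both
#' thresholds are strict inequalities.
#'
#' @param records data.frame of per-site counts as from
#'   [read_bisulfite_report()].
#' @param min_coverage coverage must be strictly above this (default 5).
#' @param pos_rate methylation rate must be strictly above this for a
#'   positive call (default 0.9).
#' @param negative_coverage_filter also require the coverage filter for
#'   negative calls (default `TRUE`); with `FALSE` any covered site at 0%
#'   rate is negative.
#' @return data.frame with `chrom`, `pos`, `strand`, `status` (factor with
#'   levels positive/negative/excluded).
#' @examples
#' recs <- data.frame(chrom = "c", pos = 1:3, strand = "+",
#'                    count_meth = c(6L, 0L, 5L), count_unmeth = c(0L, 10L, 5L),
#'                    context = "CpG")
#' table(label_sites(recs)$status)
#' @export
label_sites <- function(records, min_coverage = 5L, pos_rate = 0.9,
                        negative_coverage_filter = TRUE) {
  cov <- records$count_meth + records$count_unmeth
  rate <- ifelse(cov > 0, records$count_meth / cov, NA_real_)
  covered <- cov > min_coverage
  pos <- covered & !is.na(rate) & rate > pos_rate
  neg <- !is.na(rate) & rate == 0
  if (negative_coverage_filter) neg <- neg & covered
  status <- factor(rep("excluded", nrow(records)),
                   levels = c("positive", "negative", "excluded"))
  status[pos] <- "positive"
  status[neg & !pos] <- "negative"
  data.frame(chrom = records$chrom, pos = records$pos, strand = records$strand,
             status = status, stringsAsFactors = FALSE)
}

#' Attach bisulfite ground-truth labels to instances
#'
#' Instances located at positive sites get label 1, at negative sites label
#' 0; instances at excluded or unmapped sites are dropped.
#'
#' @param x a [methyl_set].
#' @param site_labels data.frame from [label_sites()].
#' @param quiet suppress the per-class count message.
#' @return the labeled, filtered `methyl_set`; per-class counts are attached
#'   as attribute `"label_counts"`.
#' @export
attach_labels <- function(x, site_labels, quiet = FALSE) {
  key <- site_key(x$info$chrom, x$info$pos, x$info$strand)
  lkey <- site_key(site_labels$chrom, site_labels$pos, site_labels$strand)
  status <- as.character(site_labels$status)[match(key, lkey)]
  keep <- !is.na(status) & status != "excluded"
  out <- x[keep]
  out$info$label <- ifelse(status[keep] == "positive", 1L, 0L)
  counts <- c(positive = sum(out$info$label == 1L),
              negative = sum(out$info$label == 0L),
              dropped = sum(!keep))
  if (!quiet)
    message(sprintf("attach_labels: %d positive, %d negative, %d dropped",
                    counts[1], counts[2], counts[3]))
  attr(out, "label_counts") <- counts
  out
}

#' Deterministic train/validation/test split
#'
#' Shuffles instances with the given seed and partitions them by the ratio
#' (default 8:1:1). Validation and test sizes are floor allocations; the
#' remainder goes to the training partition.
#'
#' @param x a [methyl_set].
#' @param ratios positive length-3 numeric vector (train, validation, test).
#' @param seed integer RNG seed; the same seed always yields the same split.
#' @return list with elements `train`, `validation`, `test`, each a
#'   `methyl_set`; the three are disjoint and their union is `x`.
#' @export
split_dataset <- function(x, ratios = c(8, 1, 1), seed = 1L) {
  n <- nrow(x$info)
  if (n < 3L) stop("need at least 3 instances to split")
  if (length(ratios) != 3L || any(ratios <= 0)) stop("ratios must be 3 positive numbers")
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  list(train = x[perm[seq_len(n_train)]],
       validation = x[perm[n_train + seq_len(n_val)]],
       test = x[perm[n_train + n_val + seq_len(n_test)]])
}

#' Positive-to-negative class proportion
#'
#' The imbalance statistic reported for methylation datasets: the number of
#' methylated (label 1) instances divided by the number of unmethylated
#' (label 0) instances.
#'
#' @param x a [methyl_set], or a vector of 0/1 labels.
#' @return the ratio `n_positive / n_negative`.
#' @examples
#' class_proportion(c(1, 1, 0, 0, 0, 0)) # 0.5
#' @export
class_proportion <- function(x) {
  labels <- if (inherits(x, "methyl_set")) x$info$label else x
  n_pos <- sum(labels == 1L, na.rm = TRUE)
  n_neg <- sum(labels == 0L, na.rm = TRUE)
  if (n_neg == 0) stop("class_proportion undefined: no negative instances")
  n_pos / n_neg
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
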