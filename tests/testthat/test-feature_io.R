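# Feature table IO, bisulfite labeling, splitting.

feature_line <- function(motif = "ACGTACCTACGTA", label = "1",
                         means = paste(1:13 / 10, collapse = ",")) {
  paste("chr1", "42", "+", "readA", motif, means,
        paste(rep("0.5", 13), collapse = ","),
        paste(rep("7", 13), collapse = ","), label, sep = "\t")
}

test_that("a one-row feature file parses into a valid instance", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(feature_line(), f)
  ms <- read_feature_file(f)
  expect_s3_class(ms, "methyl_set")
  expect_equal(nrow(ms$info), 1L)
  expect_equal(ms$info$motif, "ACGTACCTACGTA")
  expect_equal(ms$info$label, 1L)
  expect_equal(as.numeric(ms$means), 1:13 / 10)
})

test_that("empty files yield empty sets and malformed rows are caught by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_equal(nrow(read_feature_file(f)$info), 0L)

  writeLines(c(feature_line(),
               feature_line(means = paste(1:12 / 10, collapse = ","))), f)
  expect_error(read_feature_file(f, strict = TRUE), "line 2")
  expect_warning(ms <- read_feature_file(f, strict = FALSE), "line 2")
  expect_equal(nrow(ms$info), 1L)

  writeLines(feature_line(label = "2"), f)
  expect_error(read_feature_file(f), "label")
})

test_that("write/read round trip is the identity, including gzip and NA labels", {
  ms <- simulate_dataset(sim_config(n_instances = 40L, seed = 11L))
  ms$info$label[3L] <- NA_integer_
  for (ext in c(".tsv", ".tsv.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_feature_file(ms, f)
    back <- read_feature_file(f)
    expect_equal(back$info, ms$info)
    expect_equal(back$means, ms$means)
    expect_equal(back$stds, ms$stds)
    expect_equal(back$lens, ms$lens)
  }
})

test_that("methyl_set invariants are enforced at construction", {
  expect_error(tiny_methyl_set(motif = "ACGTAGATTACGT"), "central base")
  expect_error(tiny_methyl_set(motif = "ACGTAGCTTACG"), "length")
  ms <- tiny_methyl_set()
  ms$lens[1, 1] <- 0
  expect_error(nanocon:::validate_methyl_set(ms), ">= 1")
  ms <- tiny_methyl_set()
  ms$stds[2, 5] <- -0.1
  expect_error(nanocon:::validate_methyl_set(ms), "negative")
})

test_that("labeling thresholds are strict and partition the sites", {
  recs <- data.frame(
    chrom = "c", pos = 1:6, strand = "+",
    count_meth = c(6L, 0L, 5L, 4L, 0L, 0L),
    count_unmeth = c(0L, 10L, 5L, 0L, 0L, 4L),
    context = "CpG")
  # coverage 6 rate 1 -> positive; coverage 10 rate 0 -> negative;
  # coverage 10 rate .5 -> excluded; coverage 4 rate 1 -> excluded;
  # coverage 0 -> excluded (no error); coverage 4 rate 0 -> excluded
  st <- label_sites(recs)
  expect_equal(as.character(st$status),
               c("positive", "negative", "excluded", "excluded", "excluded",
                 "excluded"))
  # every site gets exactly one status
  expect_false(any(is.na(st$status)))
  # order-independence and idempotence
  perm <- c(4, 2, 6, 1, 3, 5)
  st2 <- label_sites(recs[perm, ])
  expect_equal(as.character(st2$status), as.character(st$status)[perm])
  expect_equal(label_sites(recs), st)
  # without the negative coverage filter, low-coverage 0%-rate sites pass
  st3 <- label_sites(recs, negative_coverage_filter = FALSE)
  expect_equal(as.character(st3$status)[6], "negative")
})

test_that("boundary rates respect the strict inequalities", {
  recs <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                     count_meth = c(9L, 10L, 19L),
                     count_unmeth = c(1L, 0L, 1L), context = "CHH")
  st <- label_sites(recs)  # rates 0.90, 1.0, 0.95; coverages 10, 10, 20
  expect_equal(as.character(st$status), c("excluded", "positive", "positive"))
  # coverage exactly 5 fails "above 5"
  recs5 <- data.frame(chrom = "c", pos = 1L, strand = "+",
                      count_meth = 5L, count_unmeth = 0L, context = "CpG")
  expect_equal(as.character(label_sites(recs5)$status), "excluded")
})

test_that("attach_labels keeps instances from labeled sites only", {
  # six sites: 2 meet the positive rule, 1 the negative rule, 3 excluded
  recs <- data.frame(
    chrom = "c", pos = 0:5, strand = "+",
    count_meth = c(10L, 8L, 0L, 3L, 2L, 0L),
    count_unmeth = c(0L, 0L, 9L, 0L, 2L, 1L),
    context = "CpG")
  st <- label_sites(recs)
  expect_equal(sum(st$status == "positive"), 2L)
  expect_equal(sum(st$status == "negative"), 1L)
  ms <- simulate_dataset(sim_config(n_instances = 12L, seed = 2L))
  ms$info$chrom <- "c"
  ms$info$pos <- rep(0:5, each = 2L)  # two reads per site
  out <- attach_labels(ms, st, quiet = TRUE)
  expect_equal(nrow(out$info), 6L)
  expect_equal(sum(out$info$label == 1L), 4L)
  expect_equal(sum(out$info$label == 0L), 2L)
  expect_equal(unname(attr(out, "label_counts")["dropped"]), 6L)
  # empty label map drops everything
  empty <- attach_labels(ms, st[0, ], quiet = TRUE)
  expect_equal(nrow(empty$info), 0L)
})

test_that("split_dataset allocates by floor with remainder to train", {
  ms <- simulate_dataset(sim_config(n_instances = 10L, proportion = 1,
                                    seed = 3L))
  sp <- split_dataset(ms, seed = 5L)
  expect_equal(vapply(sp, function(s) nrow(s$info), integer(1)),
               c(train = 8L, validation = 1L, test = 1L))
  # disjoint partition covering the input
  ids <- sort(c(sp$train$info$read_id, sp$validation$info$read_id,
                sp$test$info$read_id))
  expect_equal(ids, sort(ms$info$read_id))
  # determinism
  sp2 <- split_dataset(ms, seed = 5L)
  expect_identical(sp$train$info, sp2$train$info)
  expect_error(split_dataset(ms[1:2]), "at least 3")
})

test_that("partition properties hold across seeds and sizes", {
  for (seed in c(2L, 9L, 31L)) {
    n <- 47L
    ms <- simulate_dataset(sim_config(n_instances = n, proportion = 0.5,
                                      seed = seed))
    sp <- split_dataset(ms, seed = seed)
    sizes <- vapply(sp, function(s) nrow(s$info), integer(1))
    expect_equal(sum(sizes), n)
    expect_equal(unname(sizes[2]), floor(n / 10))
    ids <- c(sp$train$info$read_id, sp$validation$info$read_id,
             sp$test$info$read_id)
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("class_proportion is the positive:negative ratio", {
  expect_equal(class_proportion(rep(c(1, 0), c(5, 5))), 1.0)
  expect_equal(class_proportion(tiny_methyl_set(6L)), 1.0)
  expect_error(class_proportion(rep(1, 5)), "no negative")
})

test_that("bisulfite report IO round-trips", {
  recs <- simulate_bisulfite_report(rep(c("methylated", "unmethylated"), 5L),
                                    seed = 4L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bisulfite_report(recs, f)
  expect_equal(read_bisulfite_report(f), recs)
})
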