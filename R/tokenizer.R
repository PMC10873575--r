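# 5-mer tokenization of the 13-base motif for the Transformer branch.

KMER_K <- 5L
N_TOKENS <- MOTIF_LEN - KMER_K + 1L  # 9 overlapping windows

#' Build the 5-mer vocabulary
#'
#' The vocabulary contains all 4^5 = 1024 DNA 5-mers over `{A,C,G,T}` in
#' lexicographic order with ids `0..1023`, followed by a single unknown
#' token (id 1024) to which any 5-mer containing `N` maps, and a pad token
#' (id 1025). Ids are a pure function of the alphabet, hence stable across
#' runs and machines.
#'
#' @return named integer vector mapping 5-mer string to id; the attributes
#'   `unk_id` and `pad_id` carry the special ids and `vocab_size` the total
#'   id count.
#' @examples
#' v <- build_vocab()
#' v[["AAAAA"]]; v[["TTTTT"]]
#' @export
build_vocab <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b5 = bases, b4 = bases, b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  kmers <- sort(paste0(grid$b1, grid$b2, grid$b3, grid$b4, grid$b5))
  ids <- stats::setNames(seq_along(kmers) - 1L, kmers)
  structure(ids, unk_id = length(kmers), pad_id = length(kmers) + 1L,
            vocab_size = length(kmers) + 2L)
}

#' Tokenize a 13-base motif into 9 overlapping 5-mer ids
#'
#' Slides a 5-base window with stride 1 over the motif: windows
#' `[1..5], [2..6], ..., [9..13]`. Any window containing a base outside
#' `{A,C,G,T}` maps to the unknown-token id.
#'
#' @param motif a 13-character string (or vector of them).
#' @param vocab vocabulary from [build_vocab()] (rebuilt if omitted).
#' @return for one motif, an integer vector of 9 token ids; for `n` motifs,
#'   an `n x 9` integer matrix.
#' @examples
#' tokenize("ACGTACCTACGTA")
#' @export
tokenize <- function(motif, vocab = build_vocab()) {
  if (any(nchar(motif) != MOTIF_LEN))
    stop("motif must be exactly 13 bases")
  unk <- attr(vocab, "unk_id")
  starts <- seq_len(N_TOKENS)
  ids <- vapply(starts, function(s) {
    kmer <- substr(motif, s, s + KMER_K - 1L)
    id <- unname(vocab[kmer])
    id[is.na(id)] <- unk
    id
  }, integer(length(motif)))
  if (length(motif) == 1L) as.integer(ids) else matrix(as.integer(ids), nrow = length(motif))
}

#' Save / load a vocabulary as a two-column text file
#'
#' @param vocab vocabulary from [build_vocab()].
#' @param path output (or input) path; columns are `kmer` and `id`,
#'   tab-separated, with the special tokens written as `<UNK>`/`<PAD>`.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` returns the
#'   vocabulary in [build_vocab()] form.
#' @export
write_vocab <- function(vocab, path) {
  df <- data.frame(kmer = c(names(vocab), "<UNK>", "<PAD>"),
                   id = c(unname(vocab), attr(vocab, "unk_id"), attr(vocab, "pad_id")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  special <- df$kmer %in% c("<UNK>", "<PAD>")
  ids <- stats::setNames(df$id[!special], df$kmer[!special])
  structure(ids,
            unk_id = df$id[df$kmer == "<UNK>"],
            pad_id = df$id[df$kmer == "<PAD>"],
            vocab_size = nrow(df))
}

# Stable fingerprint of a vocabulary, stored in checkpoints to detect
# tokenizer/model mismatches without shipping the whole table.
vocab_hash <- function(vocab) {
  s <- paste(names(vocab), unname(vocab), collapse = ";", sep = "=")
  as.character(sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2^31)
}
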