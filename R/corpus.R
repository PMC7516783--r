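#' Bag-of-words corpora
#'
#' A `ptm_corpus` is a bag-of-words container: a sparse `D x N` matrix of
#' nonnegative integer counts (documents in rows, vocabulary words in
#' columns), the vocabulary itself, and the per-document token totals
#' `Ld`.  All modeling functions in the package consume this container.
#'
#' `Ld` is always the *total* token count of document `d` (repeated
#' occurrences of a word each count), so the data likelihood is the
#' standard multinomial likelihood over token occurrences.
#'
#' @name ptm_corpus
#' @keywords internal
NULL

new_ptm_corpus <- function(counts, vocab) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  structure(
    list(
      counts = counts,
      vocab = as.character(vocab),
      doc_lengths = as.numeric(Matrix::rowSums(counts))
    ),
    class = "ptm_corpus"
  )
}

#' Build a corpus from tokenized documents
#'
#' Constructs the document-word count matrix from already-tokenized text.
#' The vocabulary is the sorted set of distinct tokens; entry `(d, n)` is
#' the multiplicity of word `n` in document `d`.  Documents that are empty
#' after tokenization are dropped with a warning.
#'
#' @param tokenized_docs A list of character vectors, one per document.
#' @return A `ptm_corpus` with fields `counts` (sparse `D x N` matrix),
#'   `vocab` (character vector of length `N`) and `doc_lengths` (numeric
#'   vector `Ld` of total token counts).
#' @examples
#' cc <- build_corpus(list(c("a", "b", "a"), c("b", "c")))
#' cc$vocab
#' as.matrix(cc$counts)
#' @export
build_corpus <- function(tokenized_docs) {
  if (!is.list(tokenized_docs) || length(tokenized_docs) == 0L)
    stop("`tokenized_docs` must be a non-empty list of character vectors")
  lens <- vapply(tokenized_docs, length, integer(1))
  if (all(lens == 0L))
    stop("all documents are empty after tokenization")
  if (any(lens == 0L)) {
    warning(sprintf("dropping %d empty document(s)", sum(lens == 0L)))
    tokenized_docs <- tokenized_docs[lens > 0L]
  }
  toks <- unlist(tokenized_docs, use.names = FALSE)
  toks <- as.character(toks)
  if (any(!nzchar(toks)))
    stop("empty-string tokens are not allowed")
  vocab <- sort(unique(toks))
  D <- length(tokenized_docs)
  doc_id <- rep.int(seq_len(D), vapply(tokenized_docs, length, integer(1)))
  word_id <- match(toks, vocab)
  counts <- Matrix::sparseMatrix(i = doc_id, j = word_id, x = 1,
                                 dims = c(D, length(vocab)))
  new_ptm_corpus(counts, vocab)
}

#' Validate a corpus
#'
#' Checks the container invariants: nonnegative integer counts, `Ld >= 1`
#' for every document, `doc_lengths` equal to the count-matrix row sums,
#' and unique non-empty vocabulary strings.  With
#' `require_coverage = TRUE` (the default, and always true for corpora
#' built by [build_corpus()]) every vocabulary word must occur in at least
#' one document; synthetic corpora drawn from a generative model may
#' legitimately leave rare vocabulary words unused and can be checked with
#' `require_coverage = FALSE`.
#'
#' @param corpus A `ptm_corpus`.
#' @param require_coverage Require every vocabulary word to occur at least
#'   once.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_corpus <- function(corpus, require_coverage = TRUE) {
  bad <- character(0)
  if (!inherits(corpus, "ptm_corpus"))
    return("not a ptm_corpus object")
  cnt <- corpus$counts
  if (length(corpus$vocab) != ncol(cnt))
    bad <- c(bad, "vocabulary length differs from number of count columns")
  if (any(cnt@x < 0))
    bad <- c(bad, "negative counts present")
  if (any(abs(cnt@x - round(cnt@x)) > 1e-9))
    bad <- c(bad, "non-integer counts present")
  rs <- as.numeric(Matrix::rowSums(cnt))
  if (any(rs < 1))
    bad <- c(bad, "document with zero tokens (Ld < 1)")
  if (max(abs(rs - corpus$doc_lengths)) > 1e-9)
    bad <- c(bad, "doc_lengths does not equal count row sums")
  if (anyDuplicated(corpus$vocab))
    bad <- c(bad, "duplicate vocabulary entries")
  if (any(!nzchar(corpus$vocab)))
    bad <- c(bad, "empty vocabulary strings")
  if (require_coverage && any(Matrix::colSums(cnt) == 0))
    bad <- c(bad, "vocabulary word occurring in no document")
  bad
}

#' Read and write corpora in sparse triplet format
#'
#' The on-disk format is plain text: the count file has a header line
#' `"D N NNZ"` followed by `NNZ` lines `"doc_index word_index count"`
#' (1-based indices); the vocabulary file has one word per line, `N` lines
#' in total.  `read_corpus(write_corpus(x))` reproduces `x` exactly.
#'
#' @param count_file,vocab_file Paths to the triplet count file and
#'   vocabulary file.
#' @param corpus A `ptm_corpus` to write.
#' @return `read_corpus` returns a `ptm_corpus`; `write_corpus` invisibly
#'   returns the paths written.
#' @export
read_corpus <- function(count_file, vocab_file) {
  lines <- readLines(count_file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty count file: ", count_file)
  hdr <- scan(text = lines[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 3L || any(hdr != round(hdr)) || any(hdr < 0))
    stop("malformed header (expected \"D N NNZ\") at line 1 of ", count_file)
  D <- hdr[1]; N <- hdr[2]; nnz <- hdr[3]
  body <- lines[-1]
  if (length(body) != nnz)
    stop(sprintf("header declares %d triplets but file has %d data lines",
                 nnz, length(body)))
  trip <- matrix(NA_real_, nrow = nnz, ncol = 3L)
  for (k in seq_along(body)) {
    v <- suppressWarnings(scan(text = body[k], what = numeric(), quiet = TRUE))
    if (length(v) != 3L || anyNA(v))
      stop(sprintf("malformed triplet at line %d of %s", k + 1L, count_file))
    trip[k, ] <- v
  }
  if (any(trip[, 3] < 0))
    stop(sprintf("negative count at line %d of %s",
                 which(trip[, 3] < 0)[1] + 1L, count_file))
  if (any(trip[, 1] < 1 | trip[, 1] > D | trip[, 2] < 1 | trip[, 2] > N))
    stop(sprintf("index out of declared range at line %d of %s",
                 which(trip[, 1] < 1 | trip[, 1] > D |
                       trip[, 2] < 1 | trip[, 2] > N)[1] + 1L, count_file))
  vocab <- readLines(vocab_file)
  if (length(vocab) != N)
    stop(sprintf("vocabulary has %d entries but header declares N = %d",
                 length(vocab), N))
  counts <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                                 dims = c(D, N))
  corpus <- new_ptm_corpus(counts, vocab)
  # a file may enumerate vocabulary wider than the observed words (e.g.
  # a corpus drawn from a generative model), so coverage is not required
  bad <- validate_corpus(corpus, require_coverage = FALSE)
  if (length(bad)) stop("invalid corpus in ", count_file, ": ",
                        paste(bad, collapse = "; "))
  corpus
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, count_file, vocab_file) {
  stopifnot(inherits(corpus, "ptm_corpus"))
  tr <- Matrix::mat2triplet(corpus$counts)
  keep <- tr$x != 0
  hdr <- sprintf("%d %d %d", nrow(corpus$counts), ncol(corpus$counts),
                 sum(keep))
  body <- sprintf("%d %d %g", tr$i[keep], tr$j[keep], tr$x[keep])
  writeLines(c(hdr, body), count_file)
  writeLines(corpus$vocab, vocab_file)
  invisible(c(count_file, vocab_file))
}

#' Per-document label sets
#'
#' Labels are held as a list with one integer vector of class ids per
#' document (possibly several ids per document for multi-label corpora)
#' plus the number of classes `C`.  The on-disk format is one
#' `"doc_index class_id"` pair per line (1-based), with repeated document
#' indices expressing multiple labels.
#'
#' @param labels A list of integer vectors, one per document.
#' @param num_classes Number of classes `C`; defaults to the largest id
#'   seen.
#' @return A `ptm_labels` object with fields `labels` and `num_classes`.
#' @export
make_labels <- function(labels, num_classes = NULL) {
  labels <- lapply(labels, function(x) as.integer(sort(unique(x))))
  if (any(vapply(labels, length, integer(1)) == 0L))
    stop("label sets must be non-empty for labeled documents")
  ids <- unlist(labels, use.names = FALSE)
  if (is.null(num_classes)) num_classes <- max(ids)
  if (any(ids < 1L | ids > num_classes))
    stop("class id outside 1..C")
  structure(list(labels = labels, num_classes = as.integer(num_classes)),
            class = "ptm_labels")
}

#' @rdname make_labels
#' @param file Path to a label file.
#' @param num_docs Number of documents the labels refer to.
#' @export
read_labels <- function(file, num_docs, num_classes = NULL) {
  tab <- utils::read.table(file, col.names = c("doc", "class"))
  if (any(tab$doc < 1 | tab$doc > num_docs))
    stop("document index outside 1..D in ", file)
  labs <- unname(split(tab$class, factor(tab$doc, levels = seq_len(num_docs))))
  if (any(vapply(labs, length, integer(1)) == 0L))
    stop("document without any label in ", file)
  make_labels(labs, num_classes)
}

#' @rdname make_labels
#' @param x A `ptm_labels` object.
#' @export
write_labels <- function(x, file) {
  stopifnot(inherits(x, "ptm_labels"))
  doc <- rep.int(seq_along(x$labels),
                 vapply(x$labels, length, integer(1)))
  writeLines(sprintf("%d %d", doc, unlist(x$labels, use.names = FALSE)), file)
  invisible(file)
}

#' @export
print.ptm_corpus <- function(x, ...) {
  cat(sprintf("ptm_corpus: %d documents, %d vocabulary words, %g tokens\n",
              nrow(x$counts), ncol(x$counts), sum(x$doc_lengths)))
  invisible(x)
}
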