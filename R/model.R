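#' Parsimonious topic model objects
#'
#' A `ptm_model` bundles the discrete model structure and the continuous
#' parameters of a parsimonious topic model over `M` topics, `D`
#' documents and `N` vocabulary words:
#'
#' * `v` (`M x D` binary): topic switches; `v[j, d] = 1` iff topic `j` is
#'   present in document `d`.  Every document has at least one active
#'   topic (`Md >= 1`).
#' * `u` (`M x N` binary): word switches; `u[j, n] = 1` iff word `n` has a
#'   topic-specific probability under topic `j`, otherwise the word uses
#'   the shared distribution `beta0`.
#' * `alpha` (`M x D`): document-topic proportions; each column sums to 1
#'   over the active topics, and `alpha[j, d] = 0` wherever `v[j, d] = 0`.
#' * `beta` (`M x N`): topic-specific word probabilities, stored as 0
#'   wherever `u[j, n] = 0` so stale values can never leak through switch
#'   flips.  Each topic satisfies the mixed pmf constraint
#'   `sum_n (u * beta + (1 - u) * beta0) = 1`.
#' * `beta0` (length `N`): the shared word distribution, a pmf over the
#'   vocabulary.
#'
#' @param M Number of topics.
#' @param v,u Binary switch matrices (`M x D`, `M x N`).
#' @param alpha,beta,beta0 Parameter arrays as described above.
#' @return An object of class `ptm_model`.
#' @export
ptm_model <- function(M, v, u, alpha, beta, beta0) {
  M <- as.integer(M)
  v <- as.matrix(v); u <- as.matrix(u)
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  beta0 <- as.numeric(beta0)
  stopifnot(nrow(v) == M, nrow(u) == M, nrow(alpha) == M, nrow(beta) == M,
            ncol(alpha) == ncol(v), ncol(beta) == ncol(u),
            length(beta0) == ncol(u))
  structure(list(M = M, v = v, u = u, alpha = alpha, beta = beta,
                 beta0 = beta0),
            class = "ptm_model")
}

#' Derived structure summaries
#'
#' `topic_doc_counts` returns `Md`, the number of topics active in each
#' document; `specific_word_counts` returns `Nj`, the number of
#' topic-specific words per topic; `effective_sizes` returns `Lbar_j`,
#' the total token count of the documents in which topic `j` is present
#' (the effective sample size that prices each `beta[j, n]` parameter in
#' the BIC).
#'
#' @param model A `ptm_model`.
#' @param corpus A `ptm_corpus` (needed for `effective_sizes`).
#' @return A numeric vector.
#' @export
topic_doc_counts <- function(model) colSums(model$v)

#' @rdname topic_doc_counts
#' @export
specific_word_counts <- function(model) rowSums(model$u)

#' @rdname topic_doc_counts
#' @export
effective_sizes <- function(model, corpus) {
  as.numeric(model$v %*% corpus$doc_lengths)
}

#' Per-topic emission probabilities
#'
#' `word_prob(model, j, n)` is `beta[j, n]` when the word switch is open
#' and `beta0[n]` when it is closed.  `emission_matrix` returns the full
#' `M x N` matrix of these mixed emission probabilities; each row is a
#' pmf over the vocabulary when the model is valid.
#'
#' @param model A `ptm_model`.
#' @param j,n Topic and word indices.
#' @export
word_prob <- function(model, j, n) {
  stopifnot(j >= 1, j <= model$M, n >= 1, n <= ncol(model$u))
  if (model$u[j, n] == 1) model$beta[j, n] else model$beta0[n]
}

#' @rdname word_prob
#' @export
emission_matrix <- function(model) {
  model$u * model$beta +
    (1 - model$u) * matrix(model$beta0, nrow = model$M,
                           ncol = length(model$beta0), byrow = TRUE)
}

#' Data log-likelihood
#'
#' Evaluates the incomplete-data log-likelihood of the corpus under the
#' model: each token of word `n` in document `d` contributes the log of
#' the mixture probability `sum_j alpha[j,d] * v[j,d] * word_prob(j, n)`.
#' The inner sum over topics is computed in linear space (`M` is small);
#' only the outer log is taken.  A mixture probability of exactly zero
#' for an observed word is a hard error, not `-Inf`.
#'
#' @param model A `ptm_model`.
#' @param corpus A `ptm_corpus` with matching vocabulary size.
#' @return The log-likelihood (a nonpositive scalar).
#' @export
log_likelihood <- function(model, corpus) {
  C <- as.matrix(corpus$counts)
  P <- crossprod(model$alpha, emission_matrix(model))  # D x N mixture probs
  obs <- which(C > 0)
  if (any(P[obs] <= 0)) {
    k <- obs[which(P[obs] <= 0)[1]]
    d <- (k - 1) %% nrow(C) + 1
    n <- (k - 1) %/% nrow(C) + 1
    stop(sprintf(paste0("zero mixture probability for observed word: ",
                        "document %d, word %d (\"%s\")"),
                 d, n, corpus$vocab[n]))
  }
  sum(C[obs] * log(P[obs]))
}

#' Validate a model
#'
#' Checks every structural and parametric invariant to tolerance `tol`:
#' binary switches, `Md >= 1`, the per-document proportion constraint,
#' the per-topic mixed pmf constraint, zero storage where switches are
#' closed, nonnegativity, and `sum(beta0) = 1`.
#'
#' @param model A `ptm_model`.
#' @param tol Numeric tolerance for the pmf constraints.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_model <- function(model, tol = 1e-9) {
  bad <- character(0)
  v <- model$v; u <- model$u
  if (!all(v %in% c(0, 1))) bad <- c(bad, "v is not binary")
  if (!all(u %in% c(0, 1))) bad <- c(bad, "u is not binary")
  Md <- colSums(v)
  if (any(Md < 1))
    bad <- c(bad, sprintf("document(s) with no active topic (Md = 0): %s",
                          paste(which(Md < 1), collapse = ",")))
  if (any(model$alpha < 0)) bad <- c(bad, "negative alpha")
  if (any(model$beta < 0)) bad <- c(bad, "negative beta")
  if (any(model$beta0 < 0)) bad <- c(bad, "negative beta0")
  if (any(abs(model$alpha[v == 0]) > 0))
    bad <- c(bad, "nonzero alpha where v = 0")
  if (any(abs(model$beta[u == 0]) > 0))
    bad <- c(bad, "nonzero beta where u = 0")
  a_sums <- colSums(model$alpha * v)
  off <- which(abs(a_sums - 1) > tol)
  if (length(off))
    bad <- c(bad, sprintf("topic proportions do not sum to 1 in document(s) %s",
                          paste(utils::head(off, 5), collapse = ",")))
  t_sums <- rowSums(u * model$beta) +
    as.numeric((1 - u) %*% model$beta0)
  off <- which(abs(t_sums - 1) > tol)
  if (length(off))
    bad <- c(bad, sprintf("topic emission pmf does not sum to 1 for topic(s) %s",
                          paste(off, collapse = ",")))
  if (abs(sum(model$beta0) - 1) > tol)
    bad <- c(bad, "beta0 does not sum to 1")
  bad
}

#' Permute topic labels
#'
#' Applies a permutation to the topic index of every structure and
#' parameter array.  Likelihood and BIC are invariant under this
#' relabeling.
#'
#' @param model A `ptm_model`.
#' @param perm An integer permutation of `1:M`; row `j` of the result is
#'   row `perm[j]` of the input.
#' @export
permute_topics <- function(model, perm) {
  stopifnot(length(perm) == model$M, all(sort(perm) == seq_len(model$M)))
  ptm_model(model$M, model$v[perm, , drop = FALSE],
            model$u[perm, , drop = FALSE],
            model$alpha[perm, , drop = FALSE],
            model$beta[perm, , drop = FALSE], model$beta0)
}

#' Serialize a model to JSON
#'
#' Writes the full model (dimensions, switches as sparse index lists,
#' open `beta` entries only, `alpha` and `beta0` dense) to a single JSON
#' file with a format version marker; `read_model` restores it exactly.
#'
#' @param model A `ptm_model`.
#' @param file Path to write/read.
#' @export
write_model <- function(model, file) {
  u_open <- which(model$u == 1)
  payload <- list(
    format = "parsitopic-model-1",
    M = model$M, D = ncol(model$v), N = ncol(model$u),
    v_open = which(model$v == 1),
    u_open = u_open,
    alpha = as.numeric(model$alpha),
    beta_open = as.numeric(model$beta[u_open]),
    beta0 = model$beta0
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(p$format, "parsitopic-model-1"))
    stop("unrecognized model file format: ", p$format)
  M <- p$M; D <- p$D; N <- p$N
  v <- matrix(0, M, D); v[p$v_open] <- 1
  u <- matrix(0, M, N); u[p$u_open] <- 1
  beta <- matrix(0, M, N); beta[p$u_open] <- p$beta_open
  ptm_model(M, v, u, matrix(p$alpha, M, D), beta, p$beta0)
}

#' @export
print.ptm_model <- function(x, ...) {
  Md <- colSums(x$v)
  cat(sprintf("ptm_model: M = %d topics, D = %d documents, N = %d words\n",
              x$M, ncol(x$v), ncol(x$u)))
  cat(sprintf("  mean topics per document: %.2f; topic-specific words per topic: %s\n",
              mean(Md), paste(rowSums(x$u), collapse = " ")))
  cat(sprintf("  all-closed (wholly uninformative) words: %.1f%%\n",
              100 * mean(colSums(x$u) == 0)))
  invisible(x)
}
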