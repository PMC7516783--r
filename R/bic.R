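#' Description-length cost of one word's switch column
#'
#' The customized BIC prices the parameters attached to word `n` by the
#' configuration of its switch column `u[, n]` across the `M` topics.
#' Three configuration classes exist:
#'
#' * all closed (the word is wholly uninformative): only the shared
#'   parameter `beta0[n]` is paid for, at effective sample size
#'   `sum_j Lbar_j`, giving `log(sum(Lbar) / 2 pi) / 2`.  There is a
#'   single such configuration, so its structure prior costs nothing —
#'   this is the specially cheap coding that drives model sparsity.
#' * all open: one topic-specific parameter per topic, each priced at its
#'   topic's effective sample size, `sum_j log(Lbar_j / 2 pi) / 2`; the
#'   shared parameter is unused and costs nothing.
#' * mixed: the shared parameter plus one parameter per open switch, plus
#'   `M log 2` to identify which of the `2^M` equally likely mixed
#'   configurations was chosen.
#'
#' The `"ablated"` scheme prices every column with the mixed-case formula
#' regardless of its configuration, removing the cheap all-closed coding;
#' it exists to quantify how much of the model's sparsity the coding
#' scheme itself induces.
#'
#' @param un Binary vector of length `M`: the switch column of one word.
#' @param Lbar Numeric vector of per-topic effective sample sizes
#'   `Lbar_j` (total token count of documents where topic `j` is active).
#' @param scheme `"modified"` (default) or `"ablated"`.
#' @return The scalar description-length cost (can be negative when
#'   effective sample sizes fall below `2 pi`).
#' @export
word_switch_cost <- function(un, Lbar, scheme = c("modified", "ablated")) {
  scheme <- match.arg(scheme)
  M <- length(un)
  stopifnot(length(Lbar) == M, all(un %in% c(0, 1)))
  if (any(un == 1 & Lbar <= 0))
    stop("open word switch on a topic with zero effective sample size")
  s <- sum(un)
  log_sum <- log(sum(Lbar) / (2 * pi))
  open_term <- if (s > 0) sum(log(Lbar[un == 1] / (2 * pi))) else 0
  if (scheme == "ablated")
    return(0.5 * log_sum + M * log(2) + 0.5 * open_term)
  if (s == 0) {
    0.5 * log_sum
  } else if (s == M) {
    0.5 * open_term
  } else {
    0.5 * log_sum + M * log(2) + 0.5 * open_term
  }
}

# Vectorized total word cost over all N columns; O(M + N).
word_cost_total <- function(u, Lbar, scheme = "modified") {
  M <- nrow(u)
  su <- colSums(u)
  Nj <- rowSums(u)
  if (any(Nj > 0 & Lbar <= 0))
    stop("open word switch on a topic with zero effective sample size")
  log_sum <- log(sum(Lbar) / (2 * pi))
  logL <- ifelse(Lbar > 0, log(Lbar / (2 * pi)), 0)  # guarded; unused if Nj=0
  open_term <- 0.5 * sum(Nj * logL)
  if (scheme == "ablated")
    return(0.5 * ncol(u) * log_sum + ncol(u) * M * log(2) + open_term)
  n_mixed <- sum(su > 0 & su < M)
  n_closed <- sum(su == 0)
  0.5 * (n_closed + n_mixed) * log_sum + n_mixed * M * log(2) + open_term
}

# Cost of choosing which Md of the M topics are present in each document.
topic_config_cost <- function(M, Md, prior = c("binomial", "power")) {
  prior <- match.arg(prior)
  if (prior == "binomial") sum(lchoose(M, Md)) else sum(Md) * log(M)
}

#' Customized BIC for a parsimonious topic model
#'
#' Computes the model-selection objective: the negative data
#' log-likelihood plus description-length penalties with per-parameter
#' effective sample sizes and structure-prior costs,
#' \deqn{D \log M + \sum_d \log\binom{M}{M_d}
#'   + \tfrac12 \sum_d (M_d - 1) \log(L_d / 2\pi)
#'   + \sum_n \mathrm{wordcost}(u_{\cdot n})
#'   - \log p(\mathcal{D} \mid H, \Theta).}
#' The per-document topic-configuration prior defaults to a uniform
#' distribution over the \eqn{\binom{M}{M_d}} size-\eqn{M_d} subsets; set
#' `topic_config_prior = "power"` for a uniform distribution over
#' \eqn{M^{M_d}} labeled configurations instead.
#'
#' During generalized EM the exact log-likelihood is replaced by the
#' expected complete-data log-likelihood; pass it via
#' `neg_loglik_override` to score that surrogate objective.
#'
#' @param model A valid `ptm_model`.
#' @param corpus A `ptm_corpus`.
#' @param neg_loglik_override Optional scalar replacing
#'   `-log_likelihood(model, corpus)`.
#' @param topic_config_prior `"binomial"` (default) or `"power"`.
#' @param word_cost_scheme `"modified"` (default) or `"ablated"`; see
#'   [word_switch_cost()].
#' @return An object of class `bic_breakdown`: a list with the additive
#'   terms `order_cost`, `topic_config_cost`, `alpha_cost`, `word_cost`,
#'   `neg_loglik`, and their sum `total`.
#' @export
ptm_bic <- function(model, corpus, neg_loglik_override = NULL,
                    topic_config_prior = c("binomial", "power"),
                    word_cost_scheme = c("modified", "ablated")) {
  topic_config_prior <- match.arg(topic_config_prior)
  word_cost_scheme <- match.arg(word_cost_scheme)
  D <- ncol(model$v)
  Md <- colSums(model$v)
  Ld <- corpus$doc_lengths
  Lbar <- effective_sizes(model, corpus)
  neg_ll <- if (is.null(neg_loglik_override)) {
    -log_likelihood(model, corpus)
  } else {
    as.numeric(neg_loglik_override)
  }
  out <- list(
    order_cost = D * log(model$M),
    topic_config_cost = topic_config_cost(model$M, Md, topic_config_prior),
    alpha_cost = 0.5 * sum((Md - 1) * log(Ld / (2 * pi))),
    word_cost = word_cost_total(model$u, Lbar, word_cost_scheme),
    neg_loglik = neg_ll
  )
  out$total <- out$order_cost + out$topic_config_cost + out$alpha_cost +
    out$word_cost + out$neg_loglik
  class(out) <- "bic_breakdown"
  out
}

#' Naive BIC
#'
#' The textbook criterion `K log(D) - 2 log L`, with every free parameter
#' priced at the same sample size `D` (the number of documents).  Free
#' parameters: `Md - 1` proportions per document, `Nj` topic-specific
#' word probabilities per topic, and `N - 1` shared probabilities.
#' Provided for comparison with the customized objective.
#'
#' @inheritParams ptm_bic
#' @return A scalar.
#' @export
naive_bic <- function(model, corpus) {
  D <- ncol(model$v)
  K <- sum(colSums(model$v) - 1) + sum(model$u) + (ncol(model$u) - 1)
  K * log(D) - 2 * log_likelihood(model, corpus)
}

#' @export
print.bic_breakdown <- function(x, ...) {
  cat("BIC breakdown:\n")
  for (f in c("order_cost", "topic_config_cost", "alpha_cost",
              "word_cost", "neg_loglik", "total"))
    cat(sprintf("  %-18s %14.4f\n", f, x[[f]]))
  invisible(x)
}
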