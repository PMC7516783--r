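# Shared fixtures and independent scalar oracles, built in code.

# Corpus with one document "a a b".
corpus_aab <- function() build_corpus(list(c("a", "a", "b")))

# Two-document corpus over three words.
corpus_ab_bc <- function() build_corpus(list(c("a", "b"), c("b", "c")))

# A valid model with given structure and M-step-consistent parameters:
# alpha uniform over active topics, beta spread over open words
# proportionally to beta0 (any such pmf satisfies the constraints).
make_valid_model <- function(v, u, beta0) {
  M <- nrow(v)
  alpha <- v / rep(colSums(v), each = M)
  beta <- matrix(0, M, ncol(u))
  for (j in seq_len(M)) {
    open <- u[j, ] == 1
    if (!any(open)) next
    sm <- sum(beta0[!open])
    w <- beta0[open]
    if (sum(w) <= 0) w <- rep(1, sum(open))
    beta[j, open] <- w * (1 - sm) / sum(w)
  }
  ptm_model(M, v, u, alpha, beta, beta0)
}

# Random valid model + corpus for property-style loops.  Parameters are
# drawn at M-step-consistent values via a real E/M pass so that every
# downstream operation sees a reachable state.
random_instance <- function(seed, D = 3, N = 5, M = 2) {
  withr::with_seed(seed, {
    C <- matrix(stats::rpois(D * N, 2) + 1, D, N)
    corpus <- parsitopic:::new_ptm_corpus(C, sprintf("w%d", seq_len(N)))
    v <- matrix(1, M, D)
    u <- matrix(stats::rbinom(M * N, 1, 0.5), M, N)
    beta0 <- init_beta0(corpus)
    model <- make_valid_model(v, u, beta0)
    alpha <- matrix(stats::rgamma(M * D, 1) + 0.05, M, D)
    model$alpha <- sweep(alpha, 2, colSums(alpha), "/")
    resp <- e_step(model, corpus)
    model$alpha <- update_alpha(resp, model, corpus)
    model$beta <- update_beta(resp, model, corpus, beta0, degenerate = "spread")
    list(corpus = corpus, model = model, resp = e_step(model, corpus))
  })
}

# --- independent scalar oracles (plain loops, no package internals) ----

# Expected complete-data log-likelihood by direct summation.
oracle_ecll <- function(model, corpus, resp) {
  C <- as.matrix(corpus$counts)
  tot <- 0
  for (d in seq_len(nrow(C))) for (n in seq_len(ncol(C))) {
    if (C[d, n] == 0) next
    for (j in seq_len(model$M)) {
      r <- resp$r[[j]][d, n]
      if (r <= 0) next
      wp <- if (model$u[j, n] == 1) model$beta[j, n] else model$beta0[n]
      tot <- tot + C[d, n] * r * (log(model$alpha[j, d]) + log(wp))
    }
  }
  tot
}

# Customized BIC by direct evaluation of each printed term.
oracle_bic_total <- function(model, corpus, neg_ll) {
  M <- model$M; D <- ncol(model$v)
  Md <- colSums(model$v)
  Ld <- corpus$doc_lengths
  Lbar <- as.numeric(model$v %*% Ld)
  tot <- D * log(M) + sum(lchoose(M, Md)) +
    0.5 * sum((Md - 1) * log(Ld / (2 * pi)))
  for (n in seq_len(ncol(model$u))) {
    s <- sum(model$u[, n])
    if (s == 0) {
      tot <- tot + 0.5 * log(sum(Lbar) / (2 * pi))
    } else if (s == M) {
      tot <- tot + 0.5 * sum(log(Lbar / (2 * pi)))
    } else {
      tot <- tot + 0.5 * log(sum(Lbar) / (2 * pi)) + M * log(2) +
        0.5 * sum(model$u[, n] * log(Lbar / (2 * pi)))
    }
  }
  tot + neg_ll
}

# Expected complete-data BIC of a model whose u-column n is replaced by
# uc, with every topic's beta re-normalized from the responsibilities
# (the quantity the joint word-switch update minimizes); Inf if the
# configuration is infeasible.
oracle_uswitch_score <- function(uc, n, model, corpus, resp) {
  m <- model
  m$u[, n] <- uc
  C <- as.matrix(corpus$counts)
  M <- m$M; N <- ncol(C)
  S <- matrix(0, M, N)
  for (j in seq_len(M)) for (d in seq_len(nrow(C))) for (w in seq_len(N))
    S[j, w] <- S[j, w] + C[d, w] * resp$r[[j]][d, w]
  Lbar <- as.numeric(m$v %*% corpus$doc_lengths)
  for (j in seq_len(M))
    if (uc[j] == 1 && (S[j, n] <= 0 || Lbar[j] < 1)) return(Inf)
  beta <- matrix(0, M, N)
  for (j in seq_len(M)) {
    open <- which(m$u[j, ] == 1)
    if (!length(open)) next
    B <- sum(S[j, open])
    if (B <= 0) return(Inf)
    beta[j, open] <- S[j, open] * (1 - sum(m$beta0[-open])) / B
  }
  m$beta <- beta
  oracle_bic_total(m, corpus, -oracle_ecll(m, corpus, resp))
}
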