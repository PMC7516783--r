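#' Synthetic corpus configuration
#'
#' Parameters of the generative process used for planted-structure
#' recovery benchmarks: per-document topic switches, per-document
#' proportions over the active topics, per-topic word switches with a
#' designated fraction of wholly uninformative (all-closed) noise words,
#' topic-specific word distributions scaled onto the mass left free by
#' the shared distribution, and document lengths drawn uniformly from
#' `doc_length_range`.
#'
#' The defaults define the package's reference recovery benchmark:
#' 200 documents of 80-120 tokens over a 300-word vocabulary with 4
#' topics, each topic active in half the documents, 15% of eligible
#' words topic-specific per topic, and half the vocabulary forced
#' uninformative under every topic.
#'
#' @param D,N,M_true Corpus and model dimensions.
#' @param doc_length_range Two integers; document lengths are uniform on
#'   this range (use equal values for fixed length).
#' @param p_topic_active Probability each topic is active in a document
#'   (re-drawn until at least one topic is active).
#' @param p_word_specific Probability an eligible (non-noise) word is
#'   topic-specific under a topic.
#' @param frac_noise_words Fraction of the vocabulary forced all-closed
#'   under every topic.
#' @param conc_alpha,conc_beta,conc_beta0 Dirichlet concentrations for
#'   the document-topic proportions, the topic-specific word
#'   distributions (low values give the sparse, few-dominant-words
#'   topics typical of text), and the shared distribution.
#' @param beta0_topical_boost Concentration multiplier applied to the
#'   shared-distribution weight of words that are topic-specific under
#'   at least one topic.  Because each topic's specific-word mass is
#'   pinned (by the emission pmf constraint) to the shared-model mass of
#'   those same words, topical words must be globally frequent for the
#'   planted topics to carry any signal; this mirrors real corpora,
#'   where topical vocabulary is frequent and the residual vocabulary is
#'   a long rare tail.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration including the seed.
#' @return A list of class `ptm_synth_config`.
#' @export
synth_config <- function(D = 200L, N = 300L, M_true = 4L,
                         doc_length_range = c(80L, 120L),
                         p_topic_active = 0.5, p_word_specific = 0.15,
                         frac_noise_words = 0.5,
                         conc_alpha = 1, conc_beta = 0.2, conc_beta0 = 1,
                         beta0_topical_boost = 20,
                         seed = 1L) {
  stopifnot(D >= 1, N >= 1, M_true >= 1,
            length(doc_length_range) == 2,
            doc_length_range[1] >= 1,
            doc_length_range[1] <= doc_length_range[2],
            p_topic_active >= 0, p_topic_active <= 1,
            p_word_specific >= 0, p_word_specific <= 1,
            frac_noise_words >= 0, frac_noise_words <= 1,
            conc_alpha > 0, conc_beta > 0, conc_beta0 > 0,
            beta0_topical_boost >= 1)
  structure(list(D = as.integer(D), N = as.integer(N),
                 M_true = as.integer(M_true),
                 doc_length_range = as.integer(doc_length_range),
                 p_topic_active = p_topic_active,
                 p_word_specific = p_word_specific,
                 frac_noise_words = frac_noise_words,
                 conc_alpha = conc_alpha, conc_beta = conc_beta,
                 conc_beta0 = conc_beta0,
                 beta0_topical_boost = beta0_topical_boost,
                 seed = as.integer(seed)),
            class = "ptm_synth_config")
}

rdirichlet1 <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc)
  if (sum(g) <= 0) g <- rep(1, n)   # numeric underflow at tiny concentrations
  g / sum(g)
}

#' Generate a corpus with planted structure
#'
#' Draws a ground-truth model from the configuration — noise-word
#' columns all closed, remaining word switches Bernoulli, `beta0`
#' Dirichlet over the vocabulary, each topic's specific-word
#' distribution Dirichlet scaled so the topic emission pmf sums to one,
#' topic switches Bernoulli with at least one active topic per document,
#' proportions Dirichlet over the active topics — and then samples each
#' document's tokens by the two-stage process (pick a topic from the
#' document's proportions, then a word from that topic's emission pmf).
#'
#' Rarely, a low-probability vocabulary word may receive zero tokens;
#' such corpora are valid for all downstream modeling (see
#' [validate_corpus()]).
#'
#' @param config A [synth_config()].
#' @return A list with `corpus` (a `ptm_corpus` with vocabulary
#'   `w1..wN`), `truth` (the generating `ptm_model`), and the echoed
#'   `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "ptm_synth_config"))
  M <- config$M_true; D <- config$D; N <- config$N
  withr::with_seed(config$seed, {
    n_noise <- floor(config$frac_noise_words * N)
    noise_words <- if (n_noise > 0) sample(N, n_noise) else integer(0)
    u <- matrix(stats::rbinom(M * N, 1, config$p_word_specific), M, N)
    u[, noise_words] <- 0
    topical <- colSums(u) > 0
    shape0 <- config$conc_beta0 *
      ifelse(topical, config$beta0_topical_boost, 1)
    g <- stats::rgamma(N, shape = shape0)
    beta0 <- g / sum(g)
    beta <- matrix(0, M, N)
    for (j in seq_len(M)) {
      open <- which(u[j, ] == 1)
      if (length(open) == 0) next
      free_mass <- 1 - sum(beta0[-open])
      if (free_mass <= 0)
        stop("infeasible config: shared mass >= 1 for topic ", j)
      beta[j, open] <- rdirichlet1(length(open), config$conc_beta) * free_mass
    }
    v <- matrix(0, M, D)
    for (d in seq_len(D)) {
      repeat {
        vd <- stats::rbinom(M, 1, config$p_topic_active)
        if (sum(vd) >= 1) break
      }
      v[, d] <- vd
    }
    alpha <- matrix(0, M, D)
    for (d in seq_len(D)) {
      act <- which(v[, d] == 1)
      alpha[act, d] <- rdirichlet1(length(act), config$conc_alpha)
    }
    truth <- ptm_model(M, v, u, alpha, beta, beta0)
    W <- emission_matrix(truth)
    Ld <- sample(seq(config$doc_length_range[1], config$doc_length_range[2]),
                 D, replace = TRUE)
    counts <- matrix(0, D, N)
    for (d in seq_len(D)) {
      per_topic <- stats::rmultinom(1, Ld[d], alpha[, d])[, 1]
      for (j in which(per_topic > 0))
        counts[d, ] <- counts[d, ] + stats::rmultinom(1, per_topic[j], W[j, ])[, 1]
    }
    corpus <- new_ptm_corpus(counts, sprintf("w%d", seq_len(N)))
    list(corpus = corpus, truth = truth, config = config)
  })
}

#' Match fitted topics to planted topics
#'
#' Pairs each true topic with a fitted topic by minimizing the total
#' variation distance between the topics' emission pmfs: exhaustively
#' over all permutations when both models have the same (small) number
#' of topics, greedily otherwise.
#'
#' @param truth,fitted `ptm_model` objects over the same vocabulary.
#' @return A list with `perm` (for each true topic, the index of its
#'   matched fitted topic; `NA` if unmatched) and `distances` (the
#'   per-pair total variation distances).
#' @export
match_topics <- function(truth, fitted) {
  Wt <- emission_matrix(truth)
  Wf <- emission_matrix(fitted)
  Mt <- nrow(Wt); Mf <- nrow(Wf)
  dist <- matrix(0, Mt, Mf)
  for (a in seq_len(Mt))
    for (b in seq_len(Mf))
      dist[a, b] <- 0.5 * sum(abs(Wt[a, ] - Wf[b, ]))
  if (Mt == Mf && Mt <= 8) {
    perms <- perms_of(Mt)
    costs <- vapply(perms, function(p) sum(dist[cbind(seq_len(Mt), p)]),
                    numeric(1))
    perm <- perms[[which.min(costs)]]
  } else {
    perm <- rep(NA_integer_, Mt)
    avail <- rep(TRUE, Mf)
    for (a in order(apply(dist, 1, min))) {
      if (!any(avail)) break
      b <- which(avail)[which.min(dist[a, avail])]
      perm[a] <- b
      avail[b] <- FALSE
    }
  }
  list(perm = perm,
       distances = ifelse(is.na(perm), NA_real_,
                          dist[cbind(seq_len(Mt), perm)]))
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- perms_of(k - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Structure-recovery metrics
#'
#' Compares a fitted model against the planted truth after topic
#' matching: word-switch precision/recall/F1 (per matched topic and
#' pooled over all matched pairs, treating an open switch as a
#' positive), detection of wholly uninformative words (a word counts as
#' detected iff its fitted switch column is all closed), topic-switch
#' F1, and mean L1 errors of the matched topic emission pmfs and of the
#' proportions.
#'
#' @param truth,fitted `ptm_model` objects.
#' @param matching Output of [match_topics()]; computed if missing.
#' @return A list of class `ptm_recovery` with fields `u_precision`,
#'   `u_recall`, `u_f1`, `u_f1_per_topic`, `all_closed_precision`,
#'   `all_closed_recall`, `v_f1`, `topic_pmf_l1`, `alpha_l1`.
#' @export
recovery_metrics <- function(truth, fitted, matching = match_topics(truth, fitted)) {
  perm <- matching$perm
  matched <- which(!is.na(perm))
  prf <- function(pred, act) {
    tp <- sum(pred & act)
    prec <- if (sum(pred) > 0) tp / sum(pred) else 1
    rec <- if (sum(act) > 0) tp / sum(act) else 1
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  ut <- truth$u[matched, , drop = FALSE] == 1
  uf <- fitted$u[perm[matched], , drop = FALSE] == 1
  pooled <- prf(uf, ut)
  per_topic <- vapply(seq_along(matched), function(i)
    prf(uf[i, ], ut[i, ])["f1"], numeric(1))
  closed_t <- colSums(truth$u) == 0
  closed_f <- colSums(fitted$u) == 0
  ac <- prf(closed_f, closed_t)
  vt <- truth$v[matched, , drop = FALSE] == 1
  vf <- fitted$v[perm[matched], , drop = FALSE] == 1
  vprf <- prf(vf, vt)
  Wt <- emission_matrix(truth)[matched, , drop = FALSE]
  Wf <- emission_matrix(fitted)[perm[matched], , drop = FALSE]
  pmf_l1 <- mean(rowSums(abs(Wt - Wf)))
  at <- truth$alpha[matched, , drop = FALSE]
  af <- fitted$alpha[perm[matched], , drop = FALSE]
  alpha_l1 <- mean(colSums(abs(at - af)))
  structure(list(
    u_precision = unname(pooled["precision"]),
    u_recall = unname(pooled["recall"]),
    u_f1 = unname(pooled["f1"]),
    u_f1_per_topic = per_topic,
    all_closed_precision = unname(ac["precision"]),
    all_closed_recall = unname(ac["recall"]),
    v_f1 = unname(vprf["f1"]),
    topic_pmf_l1 = pmf_l1,
    alpha_l1 = alpha_l1
  ), class = "ptm_recovery")
}

#' @export
print.ptm_recovery <- function(x, ...) {
  cat(sprintf("structure recovery: u F1 = %.3f (precision %.3f, recall %.3f)\n",
              x$u_f1, x$u_precision, x$u_recall))
  cat(sprintf("  all-closed word detection: precision %.3f, recall %.3f\n",
              x$all_closed_precision, x$all_closed_recall))
  cat(sprintf("  v F1 = %.3f; topic pmf L1 = %.4f; alpha L1 = %.4f\n",
              x$v_f1, x$topic_pmf_l1, x$alpha_l1))
  invisible(x)
}

#' Labels derived from planted structure
#'
#' Convenience labels for evaluating on synthetic corpora: `"single"`
#' labels each document with its dominant planted topic; `"multi"`
#' labels it with every active planted topic.
#'
#' @param truth The generating `ptm_model`.
#' @param type `"single"` or `"multi"`.
#' @return A `ptm_labels` with `M_true` classes.
#' @export
truth_labels <- function(truth, type = c("single", "multi")) {
  type <- match.arg(type)
  labs <- lapply(seq_len(ncol(truth$v)), function(d) {
    if (type == "single") which.max(truth$alpha[, d] * truth$v[, d])
    else which(truth$v[, d] == 1)
  })
  make_labels(labs, num_classes = truth$M)
}
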