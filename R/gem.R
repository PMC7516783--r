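#' Fitting configuration
#'
#' Collects the tunable knobs of the generalized EM fit.
#'
#' @param max_outer_iters Maximum number of outer E-step/M-step cycles.
#' @param max_switch_sweeps Maximum number of full passes over the word
#'   (or topic) switches inside one structure-update phase.
#' @param rel_tol Relative change of the expected-BIC objective between
#'   consecutive outer iterations below which the fit is declared
#'   converged.
#' @param seed Integer seed controlling the (only) stochastic ingredient
#'   of the fit, the symmetry-breaking initialization noise.
#' @param n_restarts Number of independently initialized runs of the
#'   whole cold-start procedure; the run with the lowest final true BIC
#'   is returned.  Restart `k` uses seed `seed + (k - 1) * 7919`.  The
#'   objective is highly non-convex, so a small number of restarts
#'   substantially reduces the risk of a poor basin; warm starts (an
#'   explicit `init`) are deterministic and never restarted.
#' @param init_scheme `"perturbed_global"` initializes every topic's word
#'   distribution as the global frequency pmf times topic-specific
#'   log-normal noise (re-normalized); `"uniform"` omits the noise (all
#'   topics identical, useful only for degenerate tests).
#' @param init_noise_sd Standard deviation of the log-normal perturbation.
#' @param n_burnin Cap on the plain EM iterations (parameter updates
#'   only, structure held fully open) run before structure search
#'   starts; the burn-in stops early once the log-likelihood change
#'   falls below `rel_tol`.  Structure decisions are thereby made
#'   against differentiated topics rather than the near-symmetric
#'   initialization, from which the description-length penalties would
#'   prune indiscriminately.
#' @param topic_config_prior Passed to [ptm_bic()].
#' @param word_cost_scheme Passed to [ptm_bic()]; `"ablated"` removes the
#'   cheap all-closed word coding.
#' @param check_invariants Record the maximum constraint violation after
#'   each phase in the trace.
#' @return A list of class `ptm_fit_config`.
#' @export
fit_config <- function(max_outer_iters = 50L, max_switch_sweeps = 20L,
                       rel_tol = 1e-6, seed = 1L, n_restarts = 3L,
                       init_scheme = c("perturbed_global", "uniform"),
                       init_noise_sd = 0.5, n_burnin = 100L,
                       topic_config_prior = c("binomial", "power"),
                       word_cost_scheme = c("modified", "ablated"),
                       check_invariants = TRUE) {
  stopifnot(max_outer_iters >= 1, max_switch_sweeps >= 1, rel_tol > 0,
            init_noise_sd >= 0, n_burnin >= 0, n_restarts >= 1)
  structure(list(
    max_outer_iters = as.integer(max_outer_iters),
    max_switch_sweeps = as.integer(max_switch_sweeps),
    rel_tol = rel_tol, seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    init_scheme = match.arg(init_scheme),
    init_noise_sd = init_noise_sd, n_burnin = as.integer(n_burnin),
    topic_config_prior = match.arg(topic_config_prior),
    word_cost_scheme = match.arg(word_cost_scheme),
    check_invariants = isTRUE(check_invariants)
  ), class = "ptm_fit_config")
}

#' Shared word distribution
#'
#' Global relative frequencies of the vocabulary: `beta0[n]` is the total
#' count of word `n` divided by the total token count.  Estimated once at
#' initialization and held fixed throughout fitting.
#'
#' @param corpus A `ptm_corpus`.
#' @return A pmf over the vocabulary.
#' @export
init_beta0 <- function(corpus) {
  tot <- Matrix::colSums(corpus$counts)
  as.numeric(tot / sum(tot))
}

#' E-step: posterior topic responsibilities
#'
#' For every document `d` and observed word `n`, the posterior
#' probability that topic `j` generated the tokens of that word,
#' `r(d,n,j) = alpha[j,d] v[j,d] wp(j,n) / sum_l alpha[l,d] v[l,d] wp(l,n)`
#' with `wp` the mixed emission probability.  All tokens of the same word
#' in a document share one responsibility vector.
#'
#' @param model A valid `ptm_model`.
#' @param corpus A `ptm_corpus`.
#' @return An object of class `ptm_resp`: a list whose element `r[[j]]`
#'   is the `D x N` matrix of responsibilities for topic `j` (zero
#'   wherever `v[j, d] = 0`; columns of unobserved words are zero).
#' @export
e_step <- function(model, corpus) {
  C <- as.matrix(corpus$counts)
  W <- emission_matrix(model)
  P <- crossprod(model$alpha, W)            # D x N mixture probabilities
  if (any(C > 0 & P <= 0)) {
    k <- which(C > 0 & P <= 0)[1]
    stop(sprintf("zero mixture probability for observed word: document %d, word %d",
                 (k - 1) %% nrow(C) + 1, (k - 1) %/% nrow(C) + 1))
  }
  Pf <- P
  Pf[P <= 0] <- 1                           # unobserved words only; r := 0
  r <- lapply(seq_len(model$M), function(j) {
    outer(model$alpha[j, ], W[j, ]) / Pf
  })
  structure(list(r = r, M = model$M), class = "ptm_resp")
}

# Responsibility-weighted counts: S[j, n] = sum_d C[d, n] r(d, n, j) and
# per-document weights Wa[j, d] = sum_n C[d, n] r(d, n, j).
resp_weights <- function(resp, C) {
  M <- resp$M
  S <- matrix(0, M, ncol(C))
  Wa <- matrix(0, M, nrow(C))
  for (j in seq_len(M)) {
    CR <- C * resp$r[[j]]
    S[j, ] <- colSums(CR)
    Wa[j, ] <- rowSums(CR)
  }
  list(S = S, Wa = Wa)
}

# x * log(y) with the convention 0 * log(0) = 0; errors if x > 0 pairs
# with y = 0.
xlogy_sum <- function(x, y, what) {
  pos <- x > 0
  if (any(y[pos] <= 0))
    stop("positive responsibility paired with zero ", what)
  sum(x[pos] * log(y[pos]))
}

#' Expected complete-data log-likelihood and expected BIC
#'
#' `expected_complete_loglik` evaluates
#' `E[Lc] = sum_{d,n} C[d,n] sum_j r(d,n,j) (log alpha[j,d] + log wp(j,n))`
#' under the given responsibilities; terms with zero responsibility
#' contribute zero.  `expected_complete_bic` substitutes `-E[Lc]` for the
#' exact negative log-likelihood in the customized BIC — the surrogate
#' objective that the generalized M-step descends.  By Jensen's
#' inequality `E[Lc] <= log p(D | H, Theta)`, so the expected BIC upper
#' bounds the true BIC.
#'
#' @param model A valid `ptm_model`.
#' @param corpus A `ptm_corpus`.
#' @param resp Responsibilities from [e_step()].
#' @param topic_config_prior,word_cost_scheme Passed to [ptm_bic()].
#' @return `expected_complete_loglik`: a scalar.
#'   `expected_complete_bic`: a `bic_breakdown`.
#' @export
expected_complete_loglik <- function(model, corpus, resp) {
  C <- as.matrix(corpus$counts)
  rw <- resp_weights(resp, C)
  alpha_term <- xlogy_sum(rw$Wa, model$alpha, "topic proportion")
  u <- model$u
  B0 <- matrix(model$beta0, nrow = model$M, ncol = ncol(u), byrow = TRUE)
  open_term <- xlogy_sum(rw$S * u, model$beta, "topic-specific word probability")
  closed_term <- xlogy_sum(rw$S * (1 - u), B0, "shared word probability")
  alpha_term + open_term + closed_term
}

#' @rdname expected_complete_loglik
#' @export
expected_complete_bic <- function(model, corpus, resp,
                                  topic_config_prior = "binomial",
                                  word_cost_scheme = "modified") {
  ptm_bic(model, corpus,
          neg_loglik_override = -expected_complete_loglik(model, corpus, resp),
          topic_config_prior = topic_config_prior,
          word_cost_scheme = word_cost_scheme)
}

#' Closed-form parameter updates
#'
#' `update_alpha` sets each document's topic proportions to its
#' responsibility-weighted token shares over the active topics;
#' `update_beta` sets each topic's specific word probabilities to the
#' responsibility-weighted counts of its open words, normalized (via the
#' Lagrange multiplier `mu_j`) so that the open mass equals one minus the
#' shared mass of the closed words.  Both are the exact maximizers of the
#' expected complete-data log-likelihood at fixed structure.
#'
#' @param resp Responsibilities from [e_step()].
#' @param model A `ptm_model` supplying the structure (`v`, `u`).
#' @param corpus A `ptm_corpus`.
#' @param beta0 The frozen shared distribution.
#' @param degenerate How to fill a topic whose open words carry zero
#'   responsibility mass: `"error"` (default) or `"spread"` (proportional
#'   to `beta0` over the open words — any pmf there is a maximizer, this
#'   is the deterministic tie-break used internally during fitting).
#' @return `update_alpha`: an `M x D` matrix. `update_beta`: an `M x N`
#'   matrix.
#' @export
update_alpha <- function(resp, model, corpus) {
  C <- as.matrix(corpus$counts)
  rw <- resp_weights(resp, C)
  num <- rw$Wa * model$v
  tot <- colSums(num)
  if (any(tot <= 0))
    stop("document with zero total responsibility mass: ",
         which(tot <= 0)[1])
  sweep(num, 2, tot, "/")
}

#' @rdname update_alpha
#' @export
update_beta <- function(resp, model, corpus, beta0 = model$beta0,
                        degenerate = c("error", "spread")) {
  degenerate <- match.arg(degenerate)
  C <- as.matrix(corpus$counts)
  S <- resp_weights(resp, C)$S
  beta_from_S(model$u, S, beta0, degenerate)
}

# Eq.-21/22 renormalization from responsibility-weighted counts.
beta_from_S <- function(u, S, beta0, degenerate = "error") {
  M <- nrow(u)
  beta <- matrix(0, M, ncol(u))
  shared <- as.numeric((1 - u) %*% beta0)
  open_mass <- 1 - shared
  num <- u * S
  B <- rowSums(num)
  for (j in seq_len(M)) {
    if (sum(u[j, ]) == 0) next                 # fully shared topic
    if (open_mass[j] <= 0)
      stop("shared mass >= 1 for topic ", j,
           ": inconsistent beta0/switch combination")
    if (B[j] > 0) {
      beta[j, ] <- num[j, ] * open_mass[j] / B[j]
    } else if (degenerate == "spread") {
      w <- u[j, ] * beta0
      if (sum(w) <= 0) w <- u[j, ]
      beta[j, ] <- w * open_mass[j] / sum(w)
    } else {
      stop("topic ", j, " has open word switches but zero responsibility ",
           "mass on its open words")
    }
  }
  beta
}

# ---------------------------------------------------------------------------
# Word-switch search.
#
# During a sweep the per-topic emission part of E[Lc] is tracked in O(1)
# per toggle through four sufficient statistics per topic:
#   A = sum_{open n} S log S,  B = sum_{open n} S,
#   sm = sum_{closed n} beta0, G = sum_{closed n} S log beta0,
# because with beta renormalized by Eqs. 21-22 the emission term equals
#   A + B (log(1 - sm) - log B) + G.
# ---------------------------------------------------------------------------

uswp_emission <- function(A, B, sm, G) {
  out <- A + G
  pos <- B > 0
  if (any(pos))
    out[pos] <- out[pos] + B[pos] * (log1p(-sm[pos]) - log(B[pos]))
  out
}

uswp_colcost <- function(b, log_sum, logL, M, scheme) {
  s <- sum(b)
  open_term <- if (s > 0) 0.5 * sum(b * logL) else 0
  if (scheme == "ablated") return(0.5 * log_sum + M * log(2) + open_term)
  if (s == 0) 0.5 * log_sum
  else if (s == M) open_term
  else 0.5 * log_sum + M * log(2) + open_term
}

# One full word-switch phase: sweeps over all words (descending corpus
# count) until no column changes or the sweep limit is hit.  Returns the
# new u, the materialized beta, and the flip count.
sweep_word_switches <- function(u, S, beta0, Lbar, word_order,
                                scheme = "modified", max_sweeps = 20L,
                                accept_tol = 1e-10) {
  M <- nrow(u)
  N <- ncol(u)
  slogs <- matrix(0, M, N)
  slogs[S > 0] <- (S * log(S))[S > 0]
  lb0 <- ifelse(beta0 > 0, log(beta0), 0)
  Gmat <- S * matrix(lb0, M, N, byrow = TRUE)
  A <- rowSums(slogs * u)
  B <- rowSums(S * u)
  sm <- as.numeric((1 - u) %*% beta0)
  G <- rowSums(Gmat * (1 - u))
  log_sum <- log(sum(Lbar) / (2 * pi))
  logL <- ifelse(Lbar > 0, log(Lbar / (2 * pi)), NA_real_)
  exhaustive <- 2^M <= 64
  if (exhaustive) {
    bits <- as.matrix(expand.grid(rep(list(c(0, 1)), M)))
    colnames(bits) <- NULL
    costs <- vapply(seq_len(nrow(bits)), function(i)
      uswp_colcost(bits[i, ], log_sum, logL, M, scheme), numeric(1))
  }
  nflips <- 0L
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (n in word_order) {
      s <- S[, n]; b0 <- beta0[n]; cur <- u[, n]
      slg <- slogs[, n]; g <- Gmat[, n]
      A0 <- A - cur * slg
      B0 <- B - cur * s
      sm0 <- sm - (1 - cur) * b0
      G0 <- G - (1 - cur) * g
      e_open <- uswp_emission(A0 + slg, B0 + s, sm0, G0)
      e_closed <- uswp_emission(A0, B0, sm0 + b0, G0 + g)
      feas_open <- (s > 0) & (Lbar >= 1)
      score_of <- function(b) {
        -sum(ifelse(b == 1, e_open, e_closed)) +
          uswp_colcost(b, log_sum, logL, M, scheme)
      }
      cur_score <- score_of(cur)
      if (exhaustive) {
        evec <- as.numeric(bits %*% e_open + (1 - bits) %*% e_closed)
        scores <- -evec + costs
        feasible <- as.numeric(bits %*% (!feas_open)) == 0
        scores[!feasible] <- Inf
        best_i <- which.min(scores)
        best <- bits[best_i, ]
        best_score <- scores[best_i]
      } else {
        cand <- list(rep(0, M))
        if (all(feas_open)) cand <- c(cand, list(rep(1, M)))
        gb <- cur
        repeat {                               # greedy per-topic refinement
          improved <- FALSE
          for (j in seq_len(M)) {
            alt <- gb; alt[j] <- 1 - alt[j]
            if (alt[j] == 1 && !feas_open[j]) next
            if (score_of(alt) < score_of(gb) - accept_tol) {
              gb <- alt; improved <- TRUE
            }
          }
          if (!improved) break
        }
        cand <- c(cand, list(gb))
        sc <- vapply(cand, score_of, numeric(1))
        best <- cand[[which.min(sc)]]
        best_score <- min(sc)
      }
      if (best_score < cur_score - accept_tol && any(best != cur)) {
        A <- A0 + best * slg
        B <- B0 + best * s
        sm <- sm0 + (1 - best) * b0
        G <- G0 + (1 - best) * g
        u[, n] <- best
        nflips <- nflips + sum(best != cur)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  beta <- beta_from_S(u, S, beta0, degenerate = "spread")
  list(u = u, beta = beta, nflips = nflips)
}

#' Joint update of one word's switch column
#'
#' Re-optimizes the switches `u[, n]` of a single word jointly across all
#' topics: candidate configurations (all closed, all open, and mixed —
#' exhaustively enumerated when `2^M <= 64`, otherwise by greedy
#' per-topic refinement) are scored by the expected complete-data BIC
#' with each affected topic's `beta` re-normalized through the
#' closed-form update, and the cheapest feasible configuration is
#' installed.  Candidates that would open a switch on a topic with zero
#' effective sample size, or with zero responsibility mass for the word,
#' are infeasible and skipped.  The incumbent is kept unless a candidate
#' is strictly cheaper (by more than `1e-10`).
#'
#' @param n Word index.
#' @param model A valid `ptm_model` whose `beta` is current for `resp`
#'   (i.e. parameter updates have been applied).
#' @param corpus A `ptm_corpus`.
#' @param resp Responsibilities from [e_step()].
#' @param word_cost_scheme See [word_switch_cost()].
#' @return A list with the updated `model` and `delta`, the (non-positive)
#'   change in expected BIC.
#' @export
update_word_switches_for_word <- function(n, model, corpus, resp,
                                          word_cost_scheme = "modified") {
  C <- as.matrix(corpus$counts)
  S <- resp_weights(resp, C)$S
  Lbar <- effective_sizes(model, corpus)
  before <- -uswp_total_emission(model$u, S, model$beta0) +
    word_cost_total(model$u, Lbar, word_cost_scheme)
  res <- sweep_word_switches(model$u, S, model$beta0, Lbar,
                             word_order = n, scheme = word_cost_scheme,
                             max_sweeps = 1L)
  after <- -uswp_total_emission(res$u, S, model$beta0) +
    word_cost_total(res$u, Lbar, word_cost_scheme)
  model$u <- res$u
  model$beta <- res$beta
  list(model = model, delta = after - before)
}

# Emission part of E[Lc] with beta at its Eq.-21/22 renormalized value.
uswp_total_emission <- function(u, S, beta0) {
  slogs <- matrix(0, nrow(u), ncol(u))
  slogs[S > 0] <- (S * log(S))[S > 0]
  lb0 <- ifelse(beta0 > 0, log(beta0), 0)
  Gmat <- S * matrix(lb0, nrow(u), ncol(u), byrow = TRUE)
  A <- rowSums(slogs * u)
  B <- rowSums(S * u)
  sm <- as.numeric((1 - u) %*% beta0)
  G <- rowSums(Gmat * (1 - u))
  sum(uswp_emission(A, B, sm, G))
}

# ---------------------------------------------------------------------------
# Topic-switch search.
# ---------------------------------------------------------------------------

#' Per-document topic switch updates
#'
#' Visits every `(topic, document)` switch in index order and tentatively
#' flips it.  Closing a topic re-normalizes the document's proportions
#' over the remaining active topics and projects the document's
#' responsibilities onto them (the projection of a posterior is exactly
#' the posterior of the re-scaled model); opening a topic gives it the
#' pseudo-proportion `1 / Md_new` before re-normalization (its
#' responsibilities stay zero until the next E-step).  A flip is
#' accepted only if the free-energy form of the expected BIC — the
#' expected complete-data BIC *minus the responsibility entropy*, the
#' tight upper bound on the true BIC — strictly decreases (by more than
#' `1e-10`).  The entropy term matters: without it, closing one of two
#' equally responsible topics would be credited a spurious gain of
#' exactly the responsibility entropy it removes, and the search would
#' collapse every document to a single topic.  Flips that would leave a
#' document with no active topic, strand open word switches on a topic
#' with zero effective sample size, or require projecting away a word's
#' entire responsibility mass are never proposed.  Sweeps repeat until
#' no flip is accepted or the sweep limit is reached.
#'
#' @param model A valid `ptm_model` with parameters current for `resp`.
#' @param corpus A `ptm_corpus`.
#' @param resp Responsibilities from [e_step()]; updated in the returned
#'   value when documents are re-projected.
#' @param config A [fit_config()].
#' @return A list with the updated `model`, updated `resp`, `delta` (the
#'   total non-positive expected-BIC change) and `nflips`.
#' @export
update_topic_switches <- function(model, corpus, resp, config = fit_config()) {
  C <- as.matrix(corpus$counts)
  M <- model$M; D <- nrow(C)
  Ld <- corpus$doc_lengths
  v <- model$v; alpha <- model$alpha
  Md <- colSums(v)
  Nj <- rowSums(model$u)
  Lbar <- as.numeric(v %*% Ld)
  prior <- config$topic_config_prior
  scheme <- config$word_cost_scheme
  su <- colSums(model$u)
  n_closed_mixed <- if (scheme == "ablated") ncol(model$u)
                    else sum(su == 0) + sum(su > 0 & su < M)
  # emission log-probabilities; finite wherever responsibilities are > 0
  E <- matrix(ifelse(model$beta0 > 0, log(model$beta0), -Inf),
              M, ncol(C), byrow = TRUE)
  E[model$u == 1] <- ifelse(model$beta[model$u == 1] > 0,
                            log(model$beta[model$u == 1]), -Inf)
  obs_list <- apply(C > 0, 1, which, simplify = FALSE)
  total_delta <- 0
  nflips <- 0L
  accept_tol <- 1e-10
  cfg_cost <- function(md) {
    if (prior == "binomial") lchoose(M, md) else md * log(M)
  }
  for (sweep_i in seq_len(config$max_switch_sweeps)) {
    changed <- FALSE
    for (d in seq_len(D)) {
      obs <- obs_list[[d]]
      cobs <- C[d, obs]
      Robs <- do.call(rbind, lapply(resp$r, function(m) m[d, obs]))
      Eobs <- E[, obs, drop = FALSE]
      # responsibility-weighted log-joint minus log-responsibility
      # (the per-(topic, word) integrand of E[Lc] + H)
      REL <- Robs * (Eobs - log(Robs))
      REL[Robs == 0] <- 0
      la <- ifelse(alpha[, d] > 0, log(alpha[, d]), 0)
      Wl <- as.numeric(Robs %*% cobs)
      cur_term <- sum(Wl * la) + sum(REL %*% cobs)
      for (j in seq_len(M)) {
        if (v[j, d] == 1) {
          if (Md[d] <= 1) next
          if (Nj[j] > 0 && Lbar[j] - Ld[d] < 1) next
          aj <- alpha[j, d]
          if (aj >= 1) next
          rj <- Robs[j, ]
          if (any(cobs > 0 & rj >= 1)) next      # whole mass on topic j
          t <- 1 / (1 - rj)
          ct <- cobs * t
          Wl2 <- as.numeric(Robs %*% ct)
          la2 <- ifelse(alpha[, d] > 0, log(alpha[, d] / (1 - aj)), 0)
          keep <- seq_len(M) != j
          new_term <- sum(Wl2[keep] * la2[keep]) +
            sum((REL %*% ct)[keep]) - sum(cobs * log(t))
          newLbar_j <- Lbar[j] - Ld[d]
          d_word <- 0.5 * n_closed_mixed *
            (log((sum(Lbar) - Ld[d]) / (2 * pi)) -
             log(sum(Lbar) / (2 * pi)))
          if (Nj[j] > 0)
            d_word <- d_word + 0.5 * Nj[j] *
              (log(newLbar_j / (2 * pi)) - log(Lbar[j] / (2 * pi)))
          dBIC <- -(new_term - cur_term) +
            (cfg_cost(Md[d] - 1) - cfg_cost(Md[d])) -
            0.5 * log(Ld[d] / (2 * pi)) + d_word
          if (dBIC < -accept_tol) {
            v[j, d] <- 0
            alpha[, d] <- ifelse(keep, alpha[, d] / (1 - aj), 0)
            for (l in seq_len(M))
              resp$r[[l]][d, obs] <- if (l == j) 0 else Robs[l, ] * t
            Lbar[j] <- newLbar_j
            Md[d] <- Md[d] - 1
            total_delta <- total_delta + dBIC
            nflips <- nflips + 1L
            changed <- TRUE
            Robs <- do.call(rbind, lapply(resp$r, function(m) m[d, obs]))
            REL <- Robs * (Eobs - log(Robs))
            REL[Robs == 0] <- 0
            la <- ifelse(alpha[, d] > 0, log(alpha[, d]), 0)
            Wl <- as.numeric(Robs %*% cobs)
            cur_term <- sum(Wl * la) + sum(REL %*% cobs)
          }
        } else {
          md2 <- Md[d] + 1
          denom <- 1 + 1 / md2
          d_word <- 0.5 * n_closed_mixed *
            (log((sum(Lbar) + Ld[d]) / (2 * pi)) -
             log(sum(Lbar) / (2 * pi)))
          if (Nj[j] > 0)
            d_word <- d_word + 0.5 * Nj[j] *
              (log((Lbar[j] + Ld[d]) / (2 * pi)) -
               ifelse(Lbar[j] > 0, log(Lbar[j] / (2 * pi)), 0))
          dBIC <- -(Ld[d] * log(1 / denom)) +
            (cfg_cost(md2) - cfg_cost(Md[d])) +
            0.5 * log(Ld[d] / (2 * pi)) + d_word
          if (dBIC < -accept_tol) {
            v[j, d] <- 1
            alpha[, d] <- alpha[, d] / denom
            alpha[j, d] <- (1 / md2) / denom
            Lbar[j] <- Lbar[j] + Ld[d]
            Md[d] <- md2
            total_delta <- total_delta + dBIC
            nflips <- nflips + 1L
            changed <- TRUE
            la <- ifelse(alpha[, d] > 0, log(alpha[, d]), 0)
            cur_term <- sum(Wl * la) + sum(REL %*% cobs)
          }
        }
      }
    }
    if (!changed) break
  }
  model$v <- v
  model$alpha <- alpha
  list(model = model, resp = resp, delta = total_delta, nflips = nflips)
}

# Responsibility entropy H = -sum_{d,n} C[d,n] sum_j r log r.  The
# variational identity log p(D) = E[Lc] + H (exact when r is the
# posterior) makes "expected BIC - H" a tight upper bound on the true
# BIC that every GEM phase descends.
resp_entropy <- function(resp, C) {
  H <- 0
  for (j in seq_len(resp$M)) {
    r <- resp$r[[j]]
    pos <- r > 0 & C > 0
    H <- H - sum(C[pos] * r[pos] * log(r[pos]))
  }
  H
}

# Numeric version of validate_model: largest constraint violation.
max_constraint_violation <- function(model) {
  a_sums <- colSums(model$alpha * model$v)
  t_sums <- rowSums(model$u * model$beta) +
    as.numeric((1 - model$u) %*% model$beta0)
  md_ok <- if (any(colSums(model$v) < 1)) 1 else 0
  stray <- max(0, abs(model$alpha[model$v == 0]),
               abs(model$beta[model$u == 0]))
  max(abs(a_sums - 1), abs(t_sums - 1), md_ok, stray)
}

# Repair a warm-start model so that every observed word has positive
# mixture probability in its documents.  Pruning can orphan a word: all
# of its responsibility mass lived on a removed topic, leaving open
# switches with zero probability in the surviving topics.  A word column
# with no surviving positive emission reverts to the shared model (its
# switches close, the topic pmfs re-scale onto the reduced open mass);
# a document whose active topics cannot emit an observed word gets the
# best emitting topic opened with the usual pseudo-proportion.
repair_init <- function(model, corpus) {
  C <- as.matrix(corpus$counts)
  W <- emission_matrix(model)
  # column repair: observed words no topic can emit
  dead <- which(Matrix::colSums(corpus$counts) > 0 & colSums(W > 0) == 0)
  for (n in dead) {
    for (j in which(model$u[, n] == 1)) {
      open <- model$u[j, ] == 1
      open_mass_old <- sum(model$beta[j, open])
      model$u[j, n] <- 0
      model$beta[j, n] <- 0
      open[n] <- FALSE
      open_mass_new <- open_mass_old - model$beta0[n]
      if (any(open) && open_mass_new > 0 && sum(model$beta[j, open]) > 0) {
        model$beta[j, open] <- model$beta[j, open] *
          open_mass_new / sum(model$beta[j, open])
      } else {
        model$u[j, ] <- 0
        model$beta[j, ] <- 0
      }
    }
  }
  W <- emission_matrix(model)
  P <- crossprod(model$alpha, W)
  bad <- which(C > 0 & P <= 0, arr.ind = TRUE)
  for (d in unique(bad[, 1])) {
    words <- bad[bad[, 1] == d, 2]
    for (n in words) {
      cand <- which(W[, n] > 0 & model$v[, d] == 0)
      if (!length(cand)) next                  # fixed by an earlier repair
      j <- cand[which.max(W[cand, n])]
      md2 <- sum(model$v[, d]) + 1
      model$v[j, d] <- 1
      model$alpha[, d] <- model$alpha[, d] / (1 + 1 / md2)
      model$alpha[j, d] <- (1 / md2) / (1 + 1 / md2)
      W <- emission_matrix(model)
    }
  }
  model
}

# Default initialization: richest structure (all switches open), uniform
# proportions, topic word pmfs = global frequencies times seeded
# log-normal noise.  Words absent from the corpus start all-closed (an
# open switch there is infeasible).
init_model <- function(corpus, M, config, beta0) {
  D <- nrow(corpus$counts); N <- ncol(corpus$counts)
  v <- matrix(1, M, D)
  seen <- as.numeric(Matrix::colSums(corpus$counts) > 0)
  u <- matrix(rep(seen, each = M), M, N)
  alpha <- matrix(1 / M, M, D)
  closed_mass <- as.numeric((1 - u) %*% beta0)   # zero-frequency words: 0 mass
  beta <- matrix(0, M, N)
  noise <- if (config$init_scheme == "perturbed_global" && config$init_noise_sd > 0) {
    withr::with_seed(config$seed,
                     matrix(exp(stats::rnorm(M * N, 0, config$init_noise_sd)),
                            M, N))
  } else {
    matrix(1, M, N)
  }
  raw <- u * noise * matrix(beta0, M, N, byrow = TRUE)
  rs <- rowSums(raw)
  for (j in seq_len(M))
    if (rs[j] > 0) beta[j, ] <- raw[j, ] * (1 - closed_mass[j]) / rs[j]
  ptm_model(M, v, u, alpha, beta, beta0)
}

#' Fit a parsimonious topic model at fixed order
#'
#' Runs the generalized EM algorithm: after a short parameter burn-in
#' with the structure held fully open, each outer iteration performs an
#' E-step, the closed-form parameter updates, a joint word-switch phase,
#' and a topic-switch phase, every move accepted only if it lowers the
#' expected complete-data BIC.  The shared distribution `beta0` is
#' estimated once from global frequencies and frozen.  Iteration stops
#' when the relative change of the objective falls below
#' `config$rel_tol` or at the iteration cap (recorded as
#' `converged = FALSE`, with a warning in the trace, not an error).
#'
#' @param corpus A `ptm_corpus`.
#' @param M Number of topics (`M >= 1`).
#' @param config A [fit_config()].
#' @param init Optional `ptm_model` used as a warm start (e.g. a pruned
#'   higher-order fit); its structure and parameters replace the default
#'   initialization, and the burn-in is skipped.
#' @return An object of class `ptm_fit`: a list with the fitted `model`,
#'   the per-iteration `trace`, the final true-BIC `bic` breakdown, and
#'   `converged`.  The trace records, after each phase (`obj_e`,
#'   `obj_p`, `obj_u`, `obj_v`), the descended objective — the expected
#'   complete-data BIC minus the responsibility entropy, i.e. the
#'   variational upper bound on the true BIC, which coincides with the
#'   true BIC at every E-step — plus flip counts and the maximum
#'   constraint violation.  The recorded sequence is non-increasing
#'   within and across outer iterations.
#' @export
fit_ptm <- function(corpus, M, config = fit_config(), init = NULL) {
  if (is.null(init) && config$n_restarts > 1L) {
    best <- NULL
    for (k in seq_len(config$n_restarts)) {
      cfg_k <- config
      cfg_k$seed <- config$seed + (k - 1L) * 7919L
      f <- fit_ptm_once(corpus, M, cfg_k, NULL)
      if (is.null(best) || f$bic$total < best$bic$total) best <- f
    }
    return(best)
  }
  fit_ptm_once(corpus, M, config, init)
}

fit_ptm_once <- function(corpus, M, config, init = NULL) {
  stopifnot(M >= 1)
  M <- as.integer(M)
  C <- as.matrix(corpus$counts)
  beta0 <- if (is.null(init)) init_beta0(corpus) else init$beta0
  model <- if (is.null(init)) init_model(corpus, M, config, beta0)
           else repair_init(init, corpus)
  stopifnot(model$M == M, ncol(model$v) == nrow(C), ncol(model$u) == ncol(C))
  word_order <- order(colSums(C), decreasing = TRUE)
  # objective from cached responsibility statistics (rw) and entropy (H)
  obj_cached <- function(m, rw, H) {
    u <- m$u
    B0 <- matrix(m$beta0, nrow = m$M, ncol = ncol(u), byrow = TRUE)
    ecll <- xlogy_sum(rw$Wa, m$alpha, "topic proportion") +
      xlogy_sum(rw$S * u, m$beta, "topic-specific word probability") +
      xlogy_sum(rw$S * (1 - u), B0, "shared word probability")
    ptm_bic(m, corpus, neg_loglik_override = -ecll,
            topic_config_prior = config$topic_config_prior,
            word_cost_scheme = config$word_cost_scheme)$total - H
  }
  n_burn <- if (is.null(init)) config$n_burnin else 0L
  prev_ll <- -Inf
  for (b in seq_len(n_burn)) {
    resp <- e_step(model, corpus)
    model$alpha <- update_alpha(resp, model, corpus)
    model$beta <- update_beta(resp, model, corpus, beta0,
                              degenerate = "spread")
    ll <- log_likelihood(model, corpus)
    if (is.finite(prev_ll) && abs(ll - prev_ll) <= config$rel_tol * abs(prev_ll))
      break
    prev_ll <- ll
  }
  trace <- vector("list", config$max_outer_iters)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(config$max_outer_iters)) {
    resp <- e_step(model, corpus)
    rw <- resp_weights(resp, C)
    H <- resp_entropy(resp, C)
    obj_e <- obj_cached(model, rw, H)
    num_a <- rw$Wa * model$v
    tot_a <- colSums(num_a)
    if (any(tot_a <= 0))
      stop("document with zero total responsibility mass: ",
           which(tot_a <= 0)[1])
    model$alpha <- sweep(num_a, 2, tot_a, "/")
    model$beta <- beta_from_S(model$u, rw$S, beta0, degenerate = "spread")
    obj_p <- obj_cached(model, rw, H)
    us <- sweep_word_switches(model$u, rw$S, beta0,
                              effective_sizes(model, corpus), word_order,
                              scheme = config$word_cost_scheme,
                              max_sweeps = config$max_switch_sweeps)
    model$u <- us$u
    model$beta <- us$beta
    obj_u <- obj_cached(model, rw, H)
    ts <- update_topic_switches(model, corpus, resp, config)
    model <- ts$model
    resp <- ts$resp
    rw <- resp_weights(resp, C)
    obj_v <- obj_cached(model, rw, resp_entropy(resp, C))
    viol <- if (config$check_invariants) max_constraint_violation(model) else NA_real_
    trace[[it]] <- data.frame(iter = it, obj_e = obj_e, obj_p = obj_p,
                              obj_u = obj_u, obj_v = obj_v,
                              u_flips = us$nflips, v_flips = ts$nflips,
                              max_violation = viol)
    if (is.finite(prev) &&
        abs(prev - obj_v) <= config$rel_tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- obj_v
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  if (!converged)
    attr(trace, "warning") <- "iteration cap reached before convergence"
  structure(list(model = model,
                 trace = trace,
                 bic = ptm_bic(model, corpus,
                               topic_config_prior = config$topic_config_prior,
                               word_cost_scheme = config$word_cost_scheme),
                 converged = converged,
                 config = config),
            class = "ptm_fit")
}

#' @export
print.ptm_fit <- function(x, ...) {
  cat(sprintf("ptm_fit: %s after %d outer iteration(s)\n",
              if (x$converged) "converged" else "iteration cap reached",
              nrow(x$trace)))
  print(x$model)
  cat(sprintf("  BIC = %.2f (neg. log-likelihood %.2f)\n",
              x$bic$total, x$bic$neg_loglik))
  invisible(x)
}
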