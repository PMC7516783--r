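#' Topic mass
#'
#' The expected token count attributed to each topic,
#' `mass(j) = sum_d Ld * alpha[j, d] * v[j, d]`.  Masses are nonnegative
#' and sum to the total token count of the corpus.  This is the quantity
#' used to decide which topics to remove during top-down order selection.
#'
#' @param model A `ptm_model`.
#' @param corpus A `ptm_corpus`.
#' @return A numeric vector of length `M`.
#' @export
topic_mass <- function(model, corpus) {
  as.numeric((model$alpha * model$v) %*% corpus$doc_lengths)
}

#' Remove the lowest-mass topics
#'
#' Deletes the `k` topics with the smallest mass (ties broken in favor of
#' the lower topic index) and re-normalizes every document's proportions
#' over its remaining active topics.  A document left with no active
#' topic has its highest-mass remaining topic re-opened with proportion
#' one.
#'
#' @param model A `ptm_model`.
#' @param corpus A `ptm_corpus`.
#' @param k Number of topics to remove (`k < M`).
#' @return A `ptm_model` with `M - k` topics.
#' @export
prune_topics <- function(model, corpus, k) {
  if (k >= model$M) stop("cannot remove ", k, " of ", model$M, " topics")
  if (k == 0) return(model)
  mass <- topic_mass(model, corpus)
  drop_idx <- order(mass, seq_along(mass))[seq_len(k)]
  keep <- setdiff(seq_len(model$M), drop_idx)
  v <- model$v[keep, , drop = FALSE]
  alpha <- model$alpha[keep, , drop = FALSE]
  kept_mass <- mass[keep]
  # rescue documents whose every active topic was pruned
  dead <- which(colSums(v) == 0)
  for (d in dead) {
    j <- which.max(kept_mass)
    v[j, d] <- 1
    alpha[, d] <- 0
    alpha[j, d] <- 1
  }
  tot <- colSums(alpha * v)
  alpha <- sweep(alpha, 2, tot, "/")
  ptm_model(model$M - k, v, model$u[keep, , drop = FALSE], alpha,
            model$beta[keep, , drop = FALSE], model$beta0)
}

#' Top-down model-order selection
#'
#' Fits the model at `Mmax` from a cold start, then repeatedly removes
#' the `delta` lowest-mass topics and refits, recording the true BIC at
#' each candidate order down to `Mmin` (the final step is clamped so
#' `Mmin` itself is always visited).  The selected order is the BIC
#' argmin over the sweep.
#'
#' Each candidate order below `Mmax` is fitted twice: warm-started from
#' the pruned previous model (the top-down continuation) and from a cold
#' start; the lower-BIC fit is kept and carried forward.  The discrete
#' switch structure can lock a poor pruning path in place, and the cold
#' companion fit guards the sweep against such basins.
#'
#' @param corpus A `ptm_corpus`.
#' @param Mmax,Mmin Largest and smallest candidate orders
#'   (`1 <= Mmin <= Mmax`).
#' @param delta Step size (`>= 1`); `delta = 1` visits every order.
#' @param config A [fit_config()].
#' @return An object of class `ptm_order_sweep`: a list with
#'   `candidates` (a data frame with one row per order: `M`, `bic`, the
#'   BIC terms, and the all-closed word fraction), `fits` (the per-order
#'   `ptm_fit` objects, named by order), `selected_order`, and
#'   `selected_fit`.
#' @export
select_order <- function(corpus, Mmax, Mmin = 1L, delta = 1L,
                         config = fit_config()) {
  stopifnot(Mmin >= 1, Mmin <= Mmax, delta >= 1)
  orders <- unique(c(seq(from = Mmax, to = Mmin, by = -delta), Mmin))
  fits <- vector("list", length(orders))
  names(fits) <- as.character(orders)
  rows <- vector("list", length(orders))
  prev_fit <- NULL
  for (i in seq_along(orders)) {
    M <- orders[i]
    fit <- fit_ptm(corpus, M, config)
    if (!is.null(prev_fit)) {
      init <- prune_topics(prev_fit$model, corpus, prev_fit$model$M - M)
      warm <- fit_ptm(corpus, M, config, init = init)
      if (warm$bic$total < fit$bic$total) fit <- warm
    }
    fits[[i]] <- fit
    b <- fit$bic
    rows[[i]] <- data.frame(
      M = M, bic = b$total, neg_loglik = b$neg_loglik,
      order_cost = b$order_cost, topic_config_cost = b$topic_config_cost,
      alpha_cost = b$alpha_cost, word_cost = b$word_cost,
      all_closed_fraction = mean(colSums(fit$model$u) == 0)
    )
    prev_fit <- fit
  }
  candidates <- do.call(rbind, rows)
  best <- which.min(candidates$bic)
  structure(list(candidates = candidates,
                 fits = fits,
                 selected_order = orders[best],
                 selected_fit = fits[[best]]),
            class = "ptm_order_sweep")
}

#' @export
print.ptm_order_sweep <- function(x, ...) {
  cat("Top-down model-order sweep:\n")
  print(x$candidates[, c("M", "bic", "neg_loglik", "all_closed_fraction")],
        row.names = FALSE)
  cat(sprintf("selected order: M = %d\n", x$selected_order))
  invisible(x)
}
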