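#' Document-completion split
#'
#' Splits each test document's token bag into an observed part and a
#' held-out part by seeded sampling without replacement.  For documents
#' with `Ld >= 2` both halves are guaranteed non-empty; a document with a
#' single token goes entirely to the observed half (and contributes
#' nothing to the held-out likelihood).
#'
#' @param corpus A `ptm_corpus` of test documents.
#' @param split_fraction Fraction of tokens assigned to the observed
#'   half.
#' @param seed Integer seed for the token sampling.
#' @return A list of class `ptm_heldout_split` with `observed` and
#'   `heldout` (`D x N` count matrices), `split_fraction` and `seed`.
#' @export
split_heldout <- function(corpus, split_fraction = 0.5, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  C <- as.matrix(corpus$counts)
  D <- nrow(C); N <- ncol(C)
  obs <- matrix(0, D, N)
  withr::with_seed(as.integer(seed), {
    for (d in seq_len(D)) {
      idx <- which(C[d, ] > 0)
      toks <- rep.int(idx, C[d, idx])
      Ld <- length(toks)
      n_obs <- if (Ld < 2) Ld else min(Ld - 1L, max(1L, round(split_fraction * Ld)))
      take <- sample(Ld, n_obs)
      obs[d, ] <- tabulate(toks[take], nbins = N)
    }
  })
  structure(list(observed = obs, heldout = C - obs,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "ptm_heldout_split")
}

#' Infer topic proportions for new documents
#'
#' With the trained structure frozen (`u`, `beta`, `beta0` fixed, and all
#' topics made available to each new document), alternates the
#' responsibility computation and the proportion update on the given
#' count matrix until the observed-data log-likelihood changes by less
#' than `rel_tol` (relative) or `max_iter` iterations are reached.
#' Documents with an empty observed part are skipped with a warning and
#' returned as `NA` columns.
#'
#' @param model A trained `ptm_model`.
#' @param observed_counts A `D_test x N` count matrix (e.g. the
#'   `observed` half of a [split_heldout()]).
#' @param rel_tol,max_iter Convergence controls.
#' @return An `M x D_test` matrix of proportions, each non-`NA` column
#'   summing to one.
#' @export
infer_test_proportions <- function(model, observed_counts,
                                   rel_tol = 1e-6, max_iter = 200L) {
  C <- as.matrix(observed_counts)
  D <- nrow(C)
  M <- model$M
  W <- emission_matrix(model)
  empty <- rowSums(C) == 0
  if (any(empty))
    warning(sprintf("%d document(s) with empty observed part skipped",
                    sum(empty)))
  alpha <- matrix(1 / M, M, D)
  use <- !empty
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    P <- crossprod(alpha, W)                  # D x N
    if (any(C > 0 & P <= 0)) {
      k <- which(C > 0 & P <= 0)[1]
      stop(sprintf("zero mixture probability for observed word: document %d, word %d",
                   (k - 1) %% D + 1, (k - 1) %/% D + 1))
    }
    obsm <- C > 0
    ll <- sum((C * log(ifelse(obsm, P, 1)))[obsm & use])
    Pf <- P; Pf[P <= 0] <- 1
    num <- matrix(0, M, D)
    for (j in seq_len(M))
      num[j, ] <- rowSums(C * (outer(alpha[j, ], W[j, ]) / Pf))
    tot <- colSums(num)
    alpha[, use & tot > 0] <- sweep(num[, use & tot > 0, drop = FALSE], 2,
                                    tot[use & tot > 0], "/")
    if (is.finite(prev_ll) && abs(ll - prev_ll) <= rel_tol * abs(prev_ll))
      break
    prev_ll <- ll
  }
  alpha[, empty] <- NA_real_
  alpha
}

#' Held-out document-completion log-likelihood
#'
#' Scores the held-out half of each test document under the proportions
#' inferred from its observed half: every held-out token of word `n`
#' contributes `log sum_j alpha[j, d] * (u[j,n] beta[j,n] + (1 - u[j,n])
#' beta0[n])`.  Documents whose proportions are `NA` (empty observed
#' half) are skipped.
#'
#' @param model A trained `ptm_model`.
#' @param test_alpha Proportions from [infer_test_proportions()].
#' @param heldout_counts The held-out `D_test x N` count matrix.
#' @return The total held-out log-likelihood (nonpositive).
#' @export
heldout_loglik <- function(model, test_alpha, heldout_counts) {
  C <- as.matrix(heldout_counts)
  ok <- !is.na(test_alpha[1, ])
  A <- test_alpha
  A[, !ok] <- 0
  P <- crossprod(A, emission_matrix(model))
  obs <- C > 0 & ok
  if (any(P[obs] <= 0)) {
    k <- which(obs & P <= 0)[1]
    stop(sprintf("zero mixture probability for held-out word: document %d, word %d",
                 (k - 1) %% nrow(C) + 1, (k - 1) %/% nrow(C) + 1))
  }
  sum(C[obs] * log(P[obs]))
}

#' Topic-to-class profiles
#'
#' Associates a class distribution with each topic by frequency counting
#' over the documents' ground-truth labels, weighted by topic
#' proportions: each occurrence of label `c` in document `d` contributes
#' `|Cd| * alpha[j, d] * v[j, d]` to `p_j(c)`, where `|Cd|` is the number
#' of labels of document `d`; rows are normalized.  A topic with zero
#' total weight receives a uniform profile with a warning.
#'
#' @param model A trained `ptm_model`.
#' @param labels A `ptm_labels` object aligned with the documents behind
#'   `alpha`.
#' @param alpha Proportions to weight by; defaults to the training
#'   proportions stored in the model.
#' @return An `M x C` matrix of class pmfs, one row per topic.
#' @export
topic_class_profiles <- function(model, labels, alpha = model$alpha) {
  stopifnot(inherits(labels, "ptm_labels"),
            length(labels$labels) == ncol(alpha))
  M <- nrow(alpha)
  Cc <- labels$num_classes
  av <- alpha * (alpha > 0)
  num <- matrix(0, M, Cc)
  for (d in seq_along(labels$labels)) {
    lab <- labels$labels[[d]]
    w <- length(lab) * av[, d]
    for (cl in lab) num[, cl] <- num[, cl] + w
  }
  tot <- rowSums(num)
  if (any(tot <= 0)) {
    warning("topic(s) with zero label weight given a uniform profile: ",
            paste(which(tot <= 0), collapse = ","))
    num[tot <= 0, ] <- 1
    tot <- rowSums(num)
  }
  num / tot
}

#' Multi-label precision/recall curve and its area
#'
#' Scores each class for each document as `sum_j alpha[j, d] p_j(c)` and
#' assigns the labels whose score exceeds a threshold `T`, sweeping `T`
#' over a grid.  The two ratios are computed exactly as defined for this
#' model family: `precision` = correctly discovered labels divided by
#' the total number of ground-truth labels, and `recall` = correctly
#' discovered labels divided by the total number of labels assigned by
#' the classifier (note these are swapped relative to the conventional
#' definitions; set `conventional_pr = TRUE` for the standard ones).  A
#' threshold assigning no labels has recall 1 by convention.  The AUC is
#' the trapezoidal area under the curve sorted by recall, anchored at
#' recall 0 with the precision of the lowest-recall point (so a curve
#' pinned at a single recall value integrates to its precision).
#'
#' @param model A trained `ptm_model`.
#' @param labels A `ptm_labels` for the scored documents.
#' @param profiles Topic-class profiles from [topic_class_profiles()]
#'   (learned on the training documents).
#' @param alpha Proportions of the scored documents (`M x D`).
#' @param thresholds Threshold grid; default 101 evenly spaced values in
#'   `[0, 1]`.
#' @param conventional_pr Use the conventional precision/recall
#'   definitions instead.
#' @return A list with `auc` and `curve` (a data frame with columns
#'   `threshold`, `precision`, `recall`).
#' @export
multilabel_pr_auc <- function(model, labels, profiles, alpha = model$alpha,
                              thresholds = seq(0, 1, length.out = 101),
                              conventional_pr = FALSE) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  stopifnot(length(labels$labels) == ncol(alpha))
  scores <- crossprod(alpha, profiles)         # D x C
  D <- nrow(scores)
  truth <- matrix(FALSE, D, labels$num_classes)
  for (d in seq_len(D)) truth[d, labels$labels[[d]]] <- TRUE
  n_truth <- sum(truth)
  curve <- lapply(sort(thresholds), function(T) {
    assigned <- scores > T
    correct <- sum(assigned & truth)
    n_assigned <- sum(assigned)
    prec <- correct / n_truth
    rec <- if (n_assigned == 0) 1 else correct / n_assigned
    if (conventional_pr) {
      tmp <- prec; prec <- rec; rec <- tmp
    }
    data.frame(threshold = T, precision = prec, recall = rec)
  })
  curve <- do.call(rbind, curve)
  o <- order(curve$recall, curve$precision)
  x <- curve$recall[o]; y <- curve$precision[o]
  if (x[1] > 0) {                       # anchor the curve at recall zero
    x <- c(0, x)
    y <- c(y[1], y)
  }
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Single-label clustering purity
#'
#' Hard-assigns each document to its dominant topic (`argmax_j alpha[j,d]
#' v[j,d]`, ties to the lower index), maps each topic to the most
#' frequent true class among its assigned documents, and returns the
#' fraction of documents whose topic's class matches their own.
#'
#' @param model A trained `ptm_model`.
#' @param labels A `ptm_labels` with exactly one label per document.
#' @param alpha Proportions of the scored documents; defaults to the
#'   training proportions.
#' @return The purity fraction in `[0, 1]`.
#' @export
single_label_purity <- function(model, labels, alpha = model$alpha) {
  stopifnot(length(labels$labels) == ncol(alpha))
  lab <- vapply(labels$labels, function(x) {
    if (length(x) != 1L) stop("single_label_purity requires one label per document")
    x
  }, integer(1))
  assign_topic <- apply(alpha, 2, which.max)
  correct <- 0L
  for (j in unique(assign_topic)) {
    docs <- which(assign_topic == j)
    tab <- tabulate(lab[docs], nbins = labels$num_classes)
    correct <- correct + max(tab)
  }
  correct / length(lab)
}
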