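test_that("held-out splits partition each document's tokens", {
  gen <- generate_corpus(synth_config(D = 15, N = 30, M_true = 2,
                                      doc_length_range = c(2L, 20L),
                                      seed = 4))
  sp <- split_heldout(gen$corpus, 0.5, seed = 9)
  C <- as.matrix(gen$corpus$counts)
  expect_equal(sp$observed + sp$heldout, C, ignore_attr = TRUE)
  Ld <- gen$corpus$doc_lengths
  expect_true(all(rowSums(sp$observed)[Ld >= 2] >= 1))
  expect_true(all(rowSums(sp$heldout)[Ld >= 2] >= 1))
  # seeded: identical split on repetition
  sp2 <- split_heldout(gen$corpus, 0.5, seed = 9)
  expect_equal(sp$observed, sp2$observed)
})

test_that("test-document proportions are a fixed point of their own update", {
  gen <- generate_corpus(synth_config(D = 20, N = 40, M_true = 2,
                                      doc_length_range = c(30L, 40L),
                                      seed = 6))
  fit <- fit_ptm(gen$corpus, 2, fit_config(seed = 3, n_restarts = 1))
  sp <- split_heldout(gen$corpus, 0.5, seed = 2)
  a1 <- infer_test_proportions(fit$model, sp$observed)
  expect_equal(colSums(a1), rep(1, ncol(a1)), tolerance = 1e-9)
  # at convergence the observed-data likelihood is stationary: running
  # far past the tolerance improves it only negligibly
  a2 <- infer_test_proportions(fit$model, sp$observed, max_iter = 2000L,
                               rel_tol = 1e-14)
  W <- emission_matrix(fit$model)
  ll_of <- function(a) {
    P <- crossprod(a, W)
    sum((sp$observed * log(P))[sp$observed > 0])
  }
  expect_lt(abs(ll_of(a1) - ll_of(a2)), 1e-3 * abs(ll_of(a2)))
  # single topic: proportions are identically one
  f1 <- fit_ptm(gen$corpus, 1, fit_config(seed = 3, n_restarts = 1))
  expect_equal(infer_test_proportions(f1$model, sp$observed),
               matrix(1, 1, 20), ignore_attr = TRUE)
})

test_that("held-out log-likelihood matches direct evaluation", {
  # fully-closed single-topic model scores held-out tokens by beta0
  cc <- build_corpus(list(c("a", "a", "b", "b"), c("a", "b", "b", "c")))
  m <- ptm_model(1, matrix(1, 1, 2), matrix(0, 1, 3), matrix(1, 1, 2),
                 matrix(0, 1, 3), init_beta0(cc))
  sp <- split_heldout(cc, 0.5, seed = 1)
  a <- infer_test_proportions(m, sp$observed)
  hl <- heldout_loglik(m, a, sp$heldout)
  expect_equal(hl, sum(sp$heldout %*% diag(log(init_beta0(cc)))),
               tolerance = 1e-10)
  expect_lte(hl, 0)
  # scalar oracle on a two-topic model
  inst <- random_instance(8, D = 3, N = 5, M = 2)
  ao <- matrix(c(0.3, 0.7, 0.5, 0.5, 0.9, 0.1), 2, 3)
  H <- matrix(c(1, 0, 2, 0, 1, 0, 0, 3, 0, 0, 1, 2, 0, 0, 1), 3, 5)
  W <- emission_matrix(inst$model)
  direct <- 0
  for (d in 1:3) for (n in 1:5) if (H[d, n] > 0)
    direct <- direct + H[d, n] * log(sum(ao[, d] * W[, n]))
  expect_equal(heldout_loglik(inst$model, ao, H), direct, tolerance = 1e-10)
  # permutation invariance
  pm <- permute_topics(inst$model, c(2L, 1L))
  expect_equal(heldout_loglik(pm, ao[c(2, 1), ], H), direct,
               tolerance = 1e-10)
})

test_that("topic-class profiles implement label-weighted frequency counting", {
  # single topic, uniform class c*: profile concentrates there
  labs <- make_labels(list(2L, 2L, 2L), num_classes = 3)
  alpha <- matrix(1, 1, 3)
  m <- ptm_model(1, matrix(1, 1, 3), matrix(0, 1, 2), alpha,
                 matrix(0, 1, 2), c(0.5, 0.5))
  p <- topic_class_profiles(m, labs)
  expect_equal(p[1, ], c(0, 1, 0))
  # two-document worked example against hand evaluation:
  # doc1 labels {1}, |Cd|=1; doc2 labels {1,2}, |Cd|=2
  labs2 <- make_labels(list(1L, c(1L, 2L)), num_classes = 2)
  a2 <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2)
  m2 <- ptm_model(2, matrix(1, 2, 2), matrix(0, 2, 2), a2,
                  matrix(0, 2, 2), c(0.5, 0.5))
  p2 <- topic_class_profiles(m2, labs2)
  # topic 1: class1 gets 1*0.8 + 2*0.4 = 1.6, class2 gets 2*0.4 = 0.8
  expect_equal(p2[1, ], c(1.6, 0.8) / 2.4, tolerance = 1e-12)
  # topic 2: class1 gets 1*0.2 + 2*0.6 = 1.4, class2 gets 2*0.6 = 1.2
  expect_equal(p2[2, ], c(1.4, 1.2) / 2.6, tolerance = 1e-12)
  expect_equal(rowSums(p2), c(1, 1), tolerance = 1e-12)
})

test_that("multi-label precision/recall follow the printed definitions", {
  # degenerate perfect classifier: one topic, one class
  labs <- make_labels(list(1L, 1L), num_classes = 1)
  m <- ptm_model(1, matrix(1, 1, 2), matrix(0, 1, 2), matrix(1, 1, 2),
                 matrix(0, 1, 2), c(0.5, 0.5))
  p <- topic_class_profiles(m, labs)
  res <- multilabel_pr_auc(m, labs, p, thresholds = seq(0, 0.99, by = 0.01))
  expect_equal(res$auc, 1, tolerance = 1e-12)
  expect_true(all(res$curve$precision == 1))
  # threshold above every score assigns nothing: printed precision is 0
  res2 <- multilabel_pr_auc(m, labs, p, thresholds = 2)
  expect_equal(res2$curve$precision, 0)
  expect_equal(res2$curve$recall, 1)      # 0/0 convention
  expect_error(multilabel_pr_auc(m, labs, p, thresholds = numeric(0)),
               "empty threshold grid")
  # small fixed table against an exhaustive hand count
  labs3 <- make_labels(list(1L, c(1L, 2L), 2L), num_classes = 2)
  a3 <- matrix(c(1, 0, 0.5, 0.5, 0, 1), 2, 3)
  m3 <- ptm_model(2, matrix(1, 2, 3), matrix(0, 2, 2), a3,
                  matrix(0, 2, 2), c(0.5, 0.5))
  prof <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  # scores: d1 (0.9, 0.1); d2 (0.55, 0.45); d3 (0.2, 0.8)
  res3 <- multilabel_pr_auc(m3, labs3, prof, alpha = a3, thresholds = 0.5)
  # assigned: d1 {1}, d2 {1}, d3 {2}; correct = 3; truth total = 4; assigned = 3
  expect_equal(res3$curve$precision, 3 / 4)
  expect_equal(res3$curve$recall, 3 / 3)
  # conventional flag swaps the two ratios
  res4 <- multilabel_pr_auc(m3, labs3, prof, alpha = a3, thresholds = 0.5,
                            conventional_pr = TRUE)
  expect_equal(res4$curve$precision, 1)
  expect_equal(res4$curve$recall, 3 / 4)
  # AUC is always within [0, 1]
  res5 <- multilabel_pr_auc(m3, labs3, prof, alpha = a3)
  expect_gte(res5$auc, 0); expect_lte(res5$auc, 1)
})

test_that("single-label purity counts dominant-topic majority agreement", {
  # topics perfectly aligned with classes
  a <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 2, 4)
  m <- ptm_model(2, matrix(1, 2, 4), matrix(0, 2, 2), a,
                 matrix(0, 2, 2), c(0.5, 0.5))
  labs <- make_labels(list(1L, 1L, 2L, 2L), num_classes = 2)
  expect_equal(single_label_purity(m, labs), 1)
  # one topic, two equal classes: majority bound of one half
  m1 <- ptm_model(1, matrix(1, 1, 4), matrix(0, 1, 2), matrix(1, 1, 4),
                  matrix(0, 1, 2), c(0.5, 0.5))
  expect_equal(single_label_purity(m1, labs), 0.5)
  # six-document toy assignment versus exhaustive evaluation
  a6 <- matrix(c(0.9, 0.1, 0.8, 0.2, 0.4, 0.6,
                 0.3, 0.7, 0.2, 0.8, 0.1, 0.9), 2, 6)
  m6 <- ptm_model(2, matrix(1, 2, 6), matrix(0, 2, 2), a6,
                  matrix(0, 2, 2), c(0.5, 0.5))
  labs6 <- make_labels(list(1L, 1L, 1L, 2L, 2L, 2L), num_classes = 2)
  # dominant topics: 1,1,2,2,2,2; topic1 -> class 1 (2/2),
  # topic2 -> class 2 (3/4); purity = (2 + 3) / 6
  expect_equal(single_label_purity(m6, labs6), 5 / 6)
})
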