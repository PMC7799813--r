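make_table <- function(n_pos, n_neg, feats) {
  feature_table(
    case_id = sprintf("c%02d", seq_len(n_pos + n_neg)),
    label = c(rep("mutant", n_pos), rep("wildtype", n_neg)),
    features = feats
  )
}

test_that("the Mann-Whitney filter reproduces exact and tied cases", {
  # complete separation at 5 vs 5: exact two-sided p = 2/252
  tb <- make_table(5, 5, data.frame(sep = c(6:10, 1:5), same = rep(2, 10)))
  d <- mann_whitney_filter(tb, details = TRUE)
  expect_equal(d$p_value[d$feature == "sep"], 2 / 252, tolerance = 1e-12)
  expect_equal(d$p_value[d$feature == "same"], 1)
  expect_equal(mann_whitney_filter(tb), "sep")
  # permutation invariance of the kept set
  perm <- sample(nrow(tb))
  expect_setequal(mann_whitney_filter(tb[perm, ]), mann_whitney_filter(tb))
  expect_error(mann_whitney_filter(tb[tb$label == "mutant", ]),
               class = "bettimap_param")
})

test_that("the normal-approximation path agrees with wilcox.test", {
  set.seed(40)
  for (i in 1:20) {
    x <- round(rnorm(30), 1) # rounding induces ties
    g <- rep(c(TRUE, FALSE), each = 15)
    p_pkg <- bettimap:::mw_u_pvalue(x, g)
    p_ref <- suppressWarnings(
      wilcox.test(x[g], x[!g], exact = FALSE, correct = TRUE)$p.value)
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
  # exact path against wilcox.test's exact p
  for (i in 1:10) {
    x <- sample(1:100, 12) # distinct -> tie-free
    g <- rep(c(TRUE, FALSE), each = 6)
    expect_equal(bettimap:::mw_u_pvalue(x, g),
                 wilcox.test(x[g], x[!g], exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("robustness index matches its closed form and properties", {
  expect_equal(robustness_index(0.5, 0.5), 1)
  expect_equal(robustness_index(1, 0), 0.5)
  expect_equal(robustness_index(1, 1), 2)
  expect_equal(robustness_index(0.9, 0.7), robustness_index(0.7, 0.9))
  # strictly increasing in each argument at fixed gap
  a <- seq(0.1, 0.8, by = 0.1)
  expect_true(all(diff(robustness_index(a, a + 0.1)) > 0))
  expect_error(robustness_index(1.2, 0.5), class = "bettimap_param")
})

test_that("cv_auc is perfect on a separable feature and respects label flips", {
  tb <- make_table(10, 10, data.frame(f = c(rnorm(10, 5), rnorm(10, -5))))
  cv <- cv_auc(tb, "f", seed = 1)
  expect_equal(cv$auc_train, 1)
  expect_equal(cv$auc_valid, 1)
  expect_equal(cv$ri, 2)
  # flipping the labels at fixed scores complements the AUC exactly
  set.seed(41)
  sc <- rnorm(24)
  pos24 <- rep(c(TRUE, FALSE), 12)
  expect_equal(bettimap:::auc_rank(sc, !pos24),
               1 - bettimap:::auc_rank(sc, pos24))
  # refitting with swapped class names leaves every fold AUC unchanged:
  # folds are relabeling-invariant, the SVM solution is sign-symmetric,
  # and complementing both scores and labels cancels in the AUC
  tb2 <- make_table(12, 12, data.frame(g = rnorm(24)))
  tb2_fl <- tb2
  tb2_fl$label <- ifelse(tb2$label == "mutant", "wildtype", "mutant")
  cv_a <- cv_auc(tb2, "g", seed = 3)
  cv_b <- cv_auc(tb2_fl, "g", seed = 3)
  expect_equal(cv_a$fold_aucs$auc_valid, cv_b$fold_aucs$auc_valid,
               tolerance = 1e-6)
  expect_error(cv_auc(make_table(3, 10, data.frame(h = rnorm(13))), "h"),
               class = "bettimap_param")
})

test_that("cv_auc is calibrated on label-independent noise", {
  aucs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    tb <- make_table(100, 100, data.frame(noise = rnorm(200)))
    cv_auc(tb, "noise", seed = s)$auc_valid
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("signature search recovers a planted informative feature", {
  set.seed(42)
  n <- 30
  feats <- as.data.frame(matrix(rnorm(2 * n * 50), 2 * n, 50))
  names(feats) <- sprintf("noise_%02d", 1:50)
  feats$informative <- c(rnorm(n, 1.6), rnorm(n, 0))
  tb <- make_table(n, n, feats)
  cand <- mann_whitney_filter(tb)
  expect_true("informative" %in% cand)
  sig <- search_signature(tb, cand, seed = 7)
  expect_true("informative" %in% sig$features)
  # dominance: the result is at least as good as every single candidate
  expect_gte(sig$ri, max(sig$ranking$ri) - 1e-12)
  # reproducibility
  sig2 <- search_signature(tb, cand, seed = 7)
  expect_identical(glance(sig), glance(sig2))
  # single candidate trivially returned
  one <- search_signature(tb, "informative", seed = 7)
  expect_equal(one$features, "informative")
  expect_error(search_signature(tb, character(0)),
               class = "bettimap_no_features")
})

test_that("signature tidiers expose the search trace", {
  set.seed(43)
  tb <- make_table(10, 10, data.frame(a = c(rnorm(10, 2), rnorm(10)),
                                      b = rnorm(20)))
  sig <- search_signature(tb, c("a", "b"), seed = 1)
  tr <- tidy(sig)
  expect_true(all(c("size", "features", "ri") %in% names(tr)))
  g <- glance(sig)
  expect_equal(g$ri, sig$ri)
})
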