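sep_table <- function(n = 12) {
  feature_table(
    case_id = sprintf("c%02d", seq_len(2 * n)),
    label = c(rep("mutant", n), rep("wildtype", n)),
    features = data.frame(f = c(rnorm(n, 6), rnorm(n, -6)))
  )
}

test_that("the SVM grid enumerates the declared configurations", {
  g <- svm_model_grid()
  expect_equal(nrow(g), 2346)
  expect_equal(sum(g$kernel == "linear"), 34)
  expect_equal(sum(g$kernel == "gaussian"), 34 * 34)
  expect_equal(sum(g$kernel == "sigmoid"), 34 * 34)
  expect_equal(range(g$cost), c(0.1, 10))
  expect_equal(sort(unique(g$cost)), 0.1 + 0.3 * (0:33))
  expect_true(all(is.na(g$gamma[g$kernel == "linear"])))
  expect_equal(sort(unique(g$gamma[g$kernel == "gaussian"])), 0.1 + 0.3 * (0:33))
})

test_that("grid search returns an in-grid optimum, deterministically", {
  set.seed(50)
  tb <- sep_table(10)
  small <- svm_model_grid()[c(1, 5, 40, 600, 1200, 2000), ]
  m1 <- grid_search_svm(tb, "f", seed = 2, grid = small)
  m2 <- grid_search_svm(tb, "f", seed = 2, grid = small)
  expect_equal(m1$ri, 2) # separable ceiling
  expect_true(any(small$kernel == m1$kernel & small$cost == m1$cost &
                    (is.na(small$gamma) == is.na(m1$gamma))))
  expect_identical(m1[c("kernel", "cost", "gamma", "ri")],
                   m2[c("kernel", "cost", "gamma", "ri")])
})

test_that("evaluation metrics are exact on separable data and self-consistent", {
  set.seed(51)
  tb <- sep_table(10)
  model <- fit_model(tb, "f")
  rep <- evaluate(model, tb, boot_b = 200, seed = 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$ci_low, 1)
  expect_equal(rep$ci_high, 1)
  # consistency of thresholded metrics with the stored scores, recomputed
  set.seed(52)
  tb2 <- feature_table(sprintf("c%d", 1:40),
                       rep(c("mutant", "wildtype"), 20),
                       data.frame(f = rnorm(40, rep(c(0.5, -0.5), 20))))
  r2 <- evaluate(fit_model(tb2, "f"), tb2, boot_b = 0)
  pred <- r2$scores > 0
  tp <- sum(pred & r2$labels); tn <- sum(!pred & !r2$labels)
  fp <- sum(pred & !r2$labels); fn <- sum(!pred & r2$labels)
  expect_equal(r2$accuracy, (tp + tn) / 40)
  expect_equal(r2$sensitivity, tp / (tp + fn))
  expect_equal(r2$specificity, tn / (tn + fp))
  expect_equal((tp + tn + fp + fn), 40L)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(53)
  s <- rnorm(30)
  pos <- rep(c(TRUE, FALSE), 15)
  a1 <- bettimap:::auc_rank(s, pos)
  a2 <- bettimap:::auc_rank(exp(2 * s) + 5, pos)
  expect_equal(a1, a2)
  skip_if_not_installed("pROC")
  a_ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(pos, s, quiet = TRUE))))
  expect_equal(a1, a_ref, tolerance = 1e-12)
})

test_that("bootstrap CIs behave on degenerate and null inputs", {
  pos <- rep(c(TRUE, FALSE), each = 10)
  sep <- c(rnorm(10, 10), rnorm(10, -10))
  expect_equal(bootstrap_ci(sep, pos, B = 200, seed = 1), c(1, 1))
  # same seed twice -> identical interval
  set.seed(54)
  s <- rnorm(20)
  expect_identical(bootstrap_ci(s, pos, B = 300, seed = 9),
                   bootstrap_ci(s, pos, B = 300, seed = 9))
  # null coverage: CI straddles 0.5 in at least 90% of outer draws
  hits <- vapply(1:20, function(k) {
    set.seed(500 + k)
    sc <- rnorm(50)
    p <- rep(c(TRUE, FALSE), 25)
    ci <- bootstrap_ci(sc, p, B = 400, seed = k)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("DeLong test matches pROC and is symmetric", {
  set.seed(55)
  pos <- rep(c(TRUE, FALSE), each = 30)
  sa <- rnorm(60, ifelse(pos, 0.8, 0))
  sb <- 0.6 * sa + rnorm(60, ifelse(pos, 0.3, 0))
  d <- delong_test(sa, sb, pos)
  expect_equal(delong_test(sb, sa, pos)$p_value, d$p_value, tolerance = 1e-12)
  expect_equal(delong_test(sa, sa, pos)$p_value, 1)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(pos, sa, quiet = TRUE)
  rb <- pROC::roc(pos, sb, quiet = TRUE)
  p_ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value
  expect_equal(d$p_value, p_ref, tolerance = 1e-9)
})

test_that("ICC grades raters per the cut-points and matches hand ANOVA", {
  # identical raters, cases differ -> ICC 1, excellent
  cases <- matrix(rep(1:6, 3), 6, 3)
  arr <- array(cases, c(6, 3, 1), dimnames = list(NULL, NULL, "f1"))
  rep1 <- icc_robustness(arr)
  expect_equal(rep1$icc, 1)
  expect_equal(attr(rep1, "category"), "excellent")
  # independent noise raters -> mean ICC near 0, poor
  mean_iccs <- vapply(1:20, function(k) {
    set.seed(600 + k)
    a <- array(rnorm(12 * 3), c(12, 3, 1), dimnames = list(NULL, NULL, "f"))
    attr(icc_robustness(a), "mean_icc")
  }, numeric(1))
  expect_lt(abs(mean(mean_iccs)), 0.15)
  expect_equal(bettimap:::icc_category(mean(mean_iccs)), "poor")
  # 6x3 worked matrix against an independent ANOVA mean-squares computation
  set.seed(56)
  m <- matrix(rnorm(18, rep(1:6, 3)), 6, 3)
  df <- data.frame(y = as.vector(m), case = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  aovt <- anova(stats::aov(y ~ case + rater, df))
  msr <- aovt["case", "Mean Sq"]; msc <- aovt["rater", "Mean Sq"]
  mse <- aovt["Residuals", "Mean Sq"]
  icc_ref <- (msr - mse) / (msr + 2 * mse + 3 * (msc - mse) / 6)
  expect_equal(bettimap:::icc_single(m), icc_ref, tolerance = 1e-10)
  # constant feature -> NA, excluded from the mean
  a2 <- array(c(m, matrix(5, 6, 3)), c(6, 3, 2),
              dimnames = list(NULL, NULL, c("f", "const")))
  r2 <- icc_robustness(a2)
  expect_true(is.na(r2$icc[r2$feature == "const"]))
  expect_equal(attr(r2, "mean_icc"), icc_ref, tolerance = 1e-10)
})

test_that("signature distance follows its closed form", {
  set.seed(57)
  a <- feature_table(sprintf("a%d", 1:20), rep(c("mutant", "wildtype"), 10),
                     data.frame(f = rnorm(20)))
  b <- a
  b$case_id <- sprintf("b%d", 1:20)
  expect_equal(signature_distance(a, b, "f"), 0)
  delta <- 1.7
  b2 <- b
  b2$f <- a$f + delta
  pooled_sd <- sd(c(a$f, b2$f))
  expect_equal(signature_distance(a, b2, "f"),
               abs(median(a$f) - median(b2$f)) / pooled_sd, tolerance = 1e-12)
  perm <- sample(20)
  expect_equal(signature_distance(a[perm, ], b2, "f"),
               signature_distance(a, b2, "f"))
})
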