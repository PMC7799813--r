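#' The SVM hyperparameter grid
#'
#' Kernels linear, gaussian and sigmoid with soft-margin parameter C on
#' `0.1, 0.4, ..., 10.0` (34 values); gaussian and sigmoid additionally
#' sweep gamma over the same 34 values. 34 + 34^2 + 34^2 = 2,346
#' configurations, ordered by kernel (linear < gaussian < sigmoid), then C,
#' then gamma — the row order doubles as the deterministic tie-break.
#'
#' @return Tibble with columns `kernel`, `cost`, `gamma` (NA for linear).
#' @examples
#' nrow(svm_model_grid())
#' @export
svm_model_grid <- function() {
  vals <- 0.1 + 0.3 * (0:33)
  dplyr::bind_rows(
    tibble(kernel = "linear", cost = vals, gamma = NA_real_),
    tidyr::expand_grid(kernel = "gaussian", cost = vals, gamma = vals),
    tidyr::expand_grid(kernel = "sigmoid", cost = vals, gamma = vals)
  )
}

#' Grid-search the SVM configuration maximizing the robustness index
#'
#' Evaluates every grid row with [cv_auc()] on the signature features and
#' returns the configuration with maximal RI; ties break to the earliest
#' row (kernel order linear < gaussian < sigmoid, then smaller C, then
#' smaller gamma).
#'
#' @param table A [feature_table()].
#' @param signature Character vector of signature features (or a
#'   `signature_result`).
#' @param seed Integer seed (fold assignment, shared across the grid).
#' @param grid The configuration tibble; defaults to [svm_model_grid()].
#' @return A `model_spec`: list with `kernel`, `cost`, `gamma`, the achieved
#'   `ri`/`auc_train`/`auc_valid`, and the full `results` tibble.
#' @export
grid_search_svm <- function(table, signature, seed = 1, grid = svm_model_grid()) {
  if (inherits(signature, "signature_result")) signature <- signature$features
  if (length(signature) == 0) stop_param("empty signature")
  table <- as_feature_table(table)
  res <- purrr::pmap_dfr(grid, function(kernel, cost, gamma) {
    cv <- cv_auc(table, signature, seed = seed, kernel = kernel, cost = cost,
                 gamma = if (is.na(gamma)) NULL else gamma)
    tibble(auc_train = cv$auc_train, auc_valid = cv$auc_valid, ri = cv$ri)
  })
  results <- dplyr::bind_cols(grid, res)
  k <- which.max(results$ri)
  structure(list(
    kernel = results$kernel[k], cost = results$cost[k], gamma = results$gamma[k],
    ri = results$ri[k], auc_train = results$auc_train[k],
    auc_valid = results$auc_valid[k], seed = seed, results = results
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$kernel, " kernel, C = ", x$cost,
      if (!is.na(x$gamma)) paste0(", gamma = ", x$gamma) else "",
      ", RI = ", round(x$ri, 3), "\n", sep = "")
  invisible(x)
}

#' Fit the final SVM on a feature table
#'
#' Z-scores the signature features on the whole table (statistics stored in
#' the model for later application) and fits the SVM given by `spec`.
#'
#' @param table A [feature_table()].
#' @param signature Feature names (or a `signature_result`).
#' @param spec A `model_spec` from [grid_search_svm()], or `NULL` for the
#'   signature-stage default (gaussian, C = 1, gamma = 1/N).
#' @return A `bn_model` usable with [evaluate()].
#' @export
fit_model <- function(table, signature, spec = NULL) {
  if (inherits(signature, "signature_result")) signature <- signature$features
  table <- as_feature_table(table)
  X <- as.matrix(table[signature])
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  kernel <- if (is.null(spec)) "gaussian" else spec$kernel
  cost <- if (is.null(spec)) 1 else spec$cost
  gamma <- if (is.null(spec) || is.na(spec$gamma)) NULL else spec$gamma
  fit <- fit_svm_raw(Z, label_flags(table), kernel, cost, gamma)
  structure(list(fit = fit, features = signature, center = mu, scale = sg,
                 kernel = kernel, cost = cost,
                 gamma = if (is.null(gamma)) 1 / ncol(Z) else gamma),
            class = "bn_model")
}

#' @rdname fit_model
#' @param model A `bn_model`.
#' @export
model_scores <- function(model, table) {
  table <- as_feature_table(table)
  X <- as.matrix(table[model$features])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  decision_scores(model$fit, Z)
}

#' Evaluate a fitted model on a labeled table
#'
#' AUC from the SVM decision scores with a 2000-replicate bootstrap
#' percentile CI, plus accuracy, sensitivity and specificity at the frozen
#' decision-score threshold 0 (positives = mutants).
#'
#' @param model A `bn_model` from [fit_model()].
#' @param table A [feature_table()] with both classes.
#' @param boot_b Bootstrap replicates for the AUC CI (default 2000; 0 skips
#'   the CI).
#' @param seed Integer seed for the bootstrap.
#' @return An `eval_report`: list with `auc`, `ci_low`, `ci_high`,
#'   `accuracy`, `sensitivity`, `specificity`, `n`, and the score/label
#'   vectors. Has [tidy()]/[glance()]/[autoplot()] methods.
#' @export
evaluate <- function(model, table, boot_b = 2000, seed = 1) {
  table <- as_feature_table(table)
  pos <- label_flags(table)
  if (!any(pos) || all(pos)) stop_degenerate("evaluation needs both classes")
  scores <- model_scores(model, table)
  pred <- scores > 0
  ci <- if (boot_b > 0) bootstrap_ci(scores, pos, B = boot_b, seed = seed)
        else c(NA_real_, NA_real_)
  structure(list(
    auc = auc_rank(scores, pos), ci_low = ci[1], ci_high = ci[2],
    accuracy = mean(pred == pos),
    sensitivity = mean(pred[pos]),
    specificity = mean(!pred[!pos]),
    n = length(pos), scores = scores, labels = pos
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n = ", x$n, "\n  AUC ", round(x$auc, 3),
      if (!is.na(x$ci_low)) paste0(" (95% CI ", round(x$ci_low, 3), "-",
                                   round(x$ci_high, 3), ")") else "",
      "\n  accuracy ", round(x$accuracy, 3),
      ", sensitivity ", round(x$sensitivity, 3),
      ", specificity ", round(x$specificity, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname evaluate
#' @param x,object An `eval_report`.
#' @param ... Unused.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, n = x$n)
}

#' @rdname evaluate
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("auc", "accuracy", "sensitivity", "specificity"),
         value = c(x$auc, x$accuracy, x$sensitivity, x$specificity))
}

#' @rdname evaluate
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(roc_points(object$scores, object$labels),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

roc_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  tibble(
    tpr = c(0, cumsum(pos[ord]) / sum(pos)),
    fpr = c(0, cumsum(!pos[ord]) / sum(!pos))
  )
}

#' Bootstrap percentile CI for an AUC
#'
#' Case-resampled percentile interval (2.5th/97.5th) over `B` replicates;
#' replicates that draw a single class are redrawn. Deterministic given the
#' seed.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical (TRUE = positive) or `"mutant"`/`"wildtype"`.
#' @param B Number of replicates (default 2000).
#' @param seed Integer seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, B = 2000, seed = 1) {
  pos <- if (is.logical(labels)) labels else labels == "mutant"
  n <- length(scores)
  if (n != length(pos) || !any(pos) || all(pos))
    stop_degenerate("bootstrap needs scores for both classes")
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (tries in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(pos[idx]) && !all(pos[idx])) break
      }
      auc_rank(scores[idx], pos[idx])
    }, numeric(1))
  })
  as.numeric(quantile(aucs, c(0.025, 0.975), names = FALSE))
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equal AUCs for two score vectors on the same cases,
#' via the DeLong structural-components estimator (midrank placement
#' values). Zero variance of the AUC difference (e.g. identical score
#' vectors) gives p = 1 by convention.
#'
#' @param scores_a,scores_b Numeric score vectors, same cases in the same
#'   order.
#' @param labels Logical (TRUE = positive) or `"mutant"`/`"wildtype"`.
#' @return List with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  pos <- if (is.logical(labels)) labels else labels == "mutant"
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos))
    stop_param("scores and labels must have equal length")
  if (!any(pos) || all(pos)) stop_degenerate("both classes required")
  comp <- function(s) {
    x <- s[pos]
    y <- s[!pos]
    # placement values by pairwise comparison (ties count 1/2)
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  m <- sum(pos)
  n <- sum(!pos)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_d) || var_d <= 0)
    return(list(p_value = 1, auc_a = a$auc, auc_b = b$auc, z = 0))
  z <- (a$auc - b$auc) / sqrt(var_d)
  list(p_value = min(1, 2 * pnorm(-abs(z))), auc_a = a$auc, auc_b = b$auc, z = z)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement.
icc_single <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop_param("ICC needs >= 2 cases and >= 2 raters")
  mu <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den == 0) return(NA_real_)
  (msr - mse) / den
}

icc_category <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good" else "excellent"
}

#' ICC-based robustness of signature features across raters
#'
#' For each feature, the intraclass correlation coefficient over a cases x
#' raters matrix — two-way random effects, absolute agreement, single
#' measurement — and the mean ICC over the signature, graded poor (< 0.5),
#' moderate (< 0.75), good (< 0.9) or excellent (>= 0.9). A feature
#' constant across all cells has an undefined ICC, is reported as `NA` and
#' excluded from the mean.
#'
#' @param rater_tables List of [feature_table()]s, one per rater, with
#'   cases in the same order, or a 3-D array cases x raters x features
#'   (with feature dimnames).
#' @param features Feature names to grade (default: all shared features).
#' @return An `icc_report`: tibble of per-feature ICCs plus attributes
#'   `mean_icc` and `category`; also accessible via [glance()].
#' @export
icc_robustness <- function(rater_tables, features = NULL) {
  if (is.array(rater_tables) && length(dim(rater_tables)) == 3) {
    arr <- rater_tables
    feats <- dimnames(arr)[[3]]
    if (is.null(feats)) feats <- paste0("f", seq_len(dim(arr)[3]))
  } else {
    if (length(rater_tables) < 2) stop_param("need >= 2 raters")
    feats <- feature_names(rater_tables[[1]])
    arr <- vapply(rater_tables, function(tb) as.matrix(as_feature_table(tb)[feats]),
                  matrix(0, nrow(rater_tables[[1]]), length(feats)))
    arr <- aperm(arr, c(1, 3, 2)) # cases x raters x features
    dimnames(arr)[[3]] <- feats
  }
  if (!is.null(features)) {
    arr <- arr[, , features, drop = FALSE]
    feats <- features
  }
  iccs <- vapply(seq_along(feats), function(i) icc_single(arr[, , i]), numeric(1))
  res <- tibble(feature = feats, icc = iccs,
                category = vapply(iccs, icc_category, character(1)))
  mean_icc <- if (all(is.na(iccs))) NA_real_ else mean(iccs, na.rm = TRUE)
  structure(res, mean_icc = mean_icc, category = icc_category(mean_icc),
            class = c("icc_report", class(res)))
}

#' @rdname icc_robustness
#' @param x An `icc_report`.
#' @param ... Unused.
#' @export
glance.icc_report <- function(x, ...) {
  tibble(mean_icc = attr(x, "mean_icc"), category = attr(x, "category"),
         n_features = nrow(x))
}

#' Euclidean distance between cohorts on a signature
#'
#' Both tables are z-scored with pooled statistics; the distance is the
#' Euclidean norm between the per-table median vectors of the signature
#' features.
#'
#' @param table_a,table_b [feature_table()]s sharing the signature columns.
#' @param signature Feature names (or a `signature_result`).
#' @return Non-negative scalar.
#' @export
signature_distance <- function(table_a, table_b, signature) {
  if (inherits(signature, "signature_result")) signature <- signature$features
  if (length(signature) == 0) stop_param("empty signature")
  A <- as.matrix(as_tibble(table_a)[signature])
  B <- as.matrix(as_tibble(table_b)[signature])
  pooled <- rbind(A, B)
  mu <- colMeans(pooled)
  sg <- apply(pooled, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  za <- sweep(sweep(A, 2, mu), 2, sg, "/")
  zb <- sweep(sweep(B, 2, mu), 2, sg, "/")
  sqrt(sum((apply(za, 2, median) - apply(zb, 2, median))^2))
}
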