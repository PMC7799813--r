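#' Assemble a feature table
#'
#' A feature table is a tibble with one row per case: a `case_id` column, a
#' `label` column with values `"mutant"` (positive class) / `"wildtype"`
#' (negative class), and numeric feature columns. All user-facing selection
#' and modeling functions take one of these as their first argument.
#'
#' @param case_id Character or integer vector of case identifiers.
#' @param label Character vector, `"mutant"` or `"wildtype"`.
#' @param features Matrix or data frame of named numeric features.
#' @param x A data frame to validate/coerce.
#' @return A tibble of class `tbl_df` validated for downstream use.
#' @export
feature_table <- function(case_id, label, features) {
  features <- as.data.frame(features, check.names = FALSE)
  tb <- dplyr::bind_cols(tibble(case_id = case_id, label = label), features)
  as_feature_table(tb)
}

#' @rdname feature_table
#' @export
as_feature_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("case_id", "label") %in% names(x)))
    stop_param("a feature table needs `case_id` and `label` columns")
  if (!all(x$label %in% c("mutant", "wildtype")))
    stop_param('labels must be "mutant" or "wildtype"')
  feat <- feature_names(x)
  if (length(feat) == 0) stop_param("no feature columns")
  fx <- as.matrix(x[feat])
  if (anyNA(fx) || any(!is.finite(fx)))
    stop_param("feature table contains missing or non-finite values")
  x
}

feature_names <- function(table) {
  setdiff(names(table), c("case_id", "label", "role"))
}

label_flags <- function(table) table$label == "mutant"

#' Mann-Whitney representative-feature filter
#'
#' Tests every feature for a location difference between mutants and
#' wildtypes with a two-sided Mann-Whitney U test and keeps features with
#' `p < alpha`. The exact null distribution is used when both groups have at
#' most 8 cases and there are no ties; otherwise the tie-corrected,
#' continuity-corrected normal approximation (a feature identical in both
#' groups has zero rank variance and gets p = 1). No multiplicity
#' correction is applied.
#'
#' @param table A [feature_table()] with both classes present.
#' @param alpha Significance threshold, default 0.05.
#' @param details If `TRUE`, return a tibble with per-feature p-values
#'   instead of the kept names.
#' @return Character vector of kept feature names (or a tibble when
#'   `details = TRUE`).
#' @export
mann_whitney_filter <- function(table, alpha = 0.05, details = FALSE) {
  table <- as_feature_table(table)
  pos <- label_flags(table)
  if (!any(pos) || all(pos)) stop_param("both classes must be present")
  feats <- feature_names(table)
  X <- as.matrix(table[feats])
  p <- apply(X, 2, mw_u_pvalue, pos = pos)
  res <- tibble(feature = feats, p_value = as.numeric(p),
                kept = as.numeric(p) < alpha)
  if (details) return(res)
  res$feature[res$kept]
}

# Two-sided Mann-Whitney p for one feature; exact via the U null
# distribution for small tie-free samples, tie-corrected normal otherwise.
mw_u_pvalue <- function(x, pos) {
  n1 <- sum(pos)
  n2 <- sum(!pos)
  r <- rank(x)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  ties <- table(x)
  has_ties <- any(ties > 1)
  if (n1 <= 8 && n2 <= 8 && !has_ties) {
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    return(min(1, p))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Robustness index of an AUC pair
#'
#' `RI = (a + b) / (1 + |a - b|)`: rewards a high total AUC and a small gap
#' between the two procedures (training vs validation, or validation vs
#' test). Symmetric in its arguments, increasing in each, with maximum 2 at
#' (1, 1).
#'
#' @param auc_a,auc_b AUCs in `[0, 1]` (vectorized).
#' @return Numeric RI in `[0, 2]`.
#' @examples
#' robustness_index(0.85, 0.81)
#' @export
robustness_index <- function(auc_a, auc_b) {
  if (any(!is.finite(auc_a)) || any(!is.finite(auc_b)) ||
      any(auc_a < 0 | auc_a > 1) || any(auc_b < 0 | auc_b > 1))
    stop_param("AUCs must lie in [0, 1]")
  (auc_a + auc_b) / (1 + abs(auc_a - auc_b))
}

# Midrank (Mann-Whitney) AUC of scores for the positive class.
auc_rank <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_degenerate("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment; deterministic in `seed`. A single
# label-independent permutation orders the cases and each class is dealt
# round-robin in that order, so the assignment is stratified yet invariant
# under relabeling the classes (swapping positive/negative leaves every
# case in its fold). Requires at least k cases of each class so every fold
# sees both classes.
make_folds <- function(pos, k = 5, seed = 1) {
  if (sum(pos) < k || sum(!pos) < k)
    stop_param(paste0("stratified ", k, "-fold CV needs >= ", k, " cases per class"))
  perm <- withr::with_seed(seed, sample.int(length(pos)))
  fold <- integer(length(pos))
  for (cl in c(TRUE, FALSE)) {
    idx <- perm[pos[perm] == cl]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_kernel_map <- c(linear = "linear", gaussian = "radial", sigmoid = "sigmoid")

fit_svm_raw <- function(X, y, kernel = "gaussian", cost = 1, gamma = NULL) {
  if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(X)
  yf <- factor(ifelse(y, "mutant", "wildtype"), levels = c("mutant", "wildtype"))
  e1071::svm(X, yf, type = "C-classification",
             kernel = svm_kernel_map[[kernel]], cost = cost, gamma = gamma,
             scale = FALSE)
}

decision_scores <- function(model, X) {
  pr <- attr(stats::predict(model, X, decision.values = TRUE), "decision.values")
  sgn <- if (startsWith(colnames(pr)[1], "mutant")) 1 else -1
  sgn * as.numeric(pr[, 1])
}

#' Cross-validated SVM AUCs for a feature set
#'
#' Stratified five-fold cross-validation of a Gaussian-kernel SVM with
#' `C = 1` and `gamma = 1/N` (N = number of features) by default. Features
#' are z-scored with training-fold statistics only; decision values are
#' used as ranking scores. `auc_train` averages the five AUCs computed on
#' the training folds, `auc_valid` the five validation-fold AUCs.
#'
#' @param table A [feature_table()].
#' @param features Character vector of feature columns to use.
#' @param seed Integer seed fixing the fold assignment.
#' @param folds Number of folds (default 5).
#' @param kernel,cost,gamma SVM parameters (`gamma = NULL` means `1/N`).
#' @return List with `auc_train`, `auc_valid`, `ri` and a per-fold tibble.
#' @export
cv_auc <- function(table, features, seed = 1, folds = 5,
                   kernel = "gaussian", cost = 1, gamma = NULL) {
  table <- as_feature_table(table)
  if (length(features) < 1) stop_param("need at least one feature")
  if (!all(features %in% names(table))) stop_param("unknown feature columns")
  pos <- label_flags(table)
  X <- as.matrix(table[features])
  fold <- make_folds(pos, folds, seed)
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
    m <- fit_svm_raw(Z[tr, , drop = FALSE], pos[tr], kernel, cost, gamma)
    tibble(
      fold = f,
      auc_train = auc_rank(decision_scores(m, Z[tr, , drop = FALSE]), pos[tr]),
      auc_valid = auc_rank(decision_scores(m, Z[!tr, , drop = FALSE]), pos[!tr])
    )
  })
  at <- mean(res$auc_train)
  av <- mean(res$auc_valid)
  list(auc_train = at, auc_valid = av, ri = robustness_index(at, av),
       fold_aucs = res)
}

#' Search a 1-4 feature signature maximizing the robustness index
#'
#' Stepwise forward search over the candidate features: each candidate is
#' scored alone by [cv_auc()] and ranked by RI; the `top_m` best (default
#' 25) stay in play. Starting from the best single feature, the set grows
#' one candidate at a time up to `max_size`, at each step adding the
#' candidate that maximizes the RI of the grown set. The returned signature
#' is the set (any size from 1 to `max_size`) with the globally maximal RI.
#' Deterministic given the seed; ties break to the earlier candidate.
#'
#' @param table A [feature_table()].
#' @param candidates Character vector of candidate features, typically from
#'   [mann_whitney_filter()]; an empty set is an error ("no representative
#'   features").
#' @param max_size Maximum signature size (default 4).
#' @param seed Integer seed (folds).
#' @param top_m Cap on the number of ranked candidates searched (default 25).
#' @return A `signature_result`: list with `features`, `ri`, `auc_train`,
#'   `auc_valid`, `size`, `seed`, the per-step `trace` and the ranked
#'   single-feature table `ranking`. Has [tidy()] and [glance()] methods.
#' @export
search_signature <- function(table, candidates, max_size = 4, seed = 1,
                             top_m = 25) {
  table <- as_feature_table(table)
  if (length(candidates) == 0)
    abort("no representative features to search", class = "bettimap_no_features")
  if (!all(candidates %in% names(table))) stop_param("unknown candidate features")
  single <- purrr::map_dfr(candidates, function(f) {
    cv <- cv_auc(table, f, seed = seed)
    tibble(feature = f, auc_train = cv$auc_train, auc_valid = cv$auc_valid,
           ri = cv$ri)
  })
  ranking <- single[order(-single$ri), ]
  pool <- head(ranking$feature, top_m)
  current <- pool[1]
  best_row <- ranking[1, ]
  trace <- tibble(size = 1L, features = paste(current, collapse = " + "),
                  auc_train = best_row$auc_train,
                  auc_valid = best_row$auc_valid, ri = best_row$ri)
  best <- list(features = current, auc_train = best_row$auc_train,
               auc_valid = best_row$auc_valid, ri = best_row$ri)
  while (length(current) < min(max_size, length(pool))) {
    remaining <- setdiff(pool, current)
    step <- purrr::map_dfr(remaining, function(f) {
      cv <- cv_auc(table, c(current, f), seed = seed)
      tibble(feature = f, auc_train = cv$auc_train,
             auc_valid = cv$auc_valid, ri = cv$ri)
    })
    k <- which.max(step$ri)
    current <- c(current, step$feature[k])
    trace <- dplyr::bind_rows(trace, tibble(
      size = length(current), features = paste(current, collapse = " + "),
      auc_train = step$auc_train[k], auc_valid = step$auc_valid[k],
      ri = step$ri[k]))
    if (step$ri[k] > best$ri) {
      best <- list(features = current, auc_train = step$auc_train[k],
                   auc_valid = step$auc_valid[k], ri = step$ri[k])
    }
  }
  structure(list(
    features = best$features, ri = best$ri, auc_train = best$auc_train,
    auc_valid = best$auc_valid, size = length(best$features), seed = seed,
    trace = trace, ranking = ranking
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result> ", x$size, " feature(s): ",
      paste(x$features, collapse = ", "), "\n  RI = ", round(x$ri, 3),
      " (AUC train ", round(x$auc_train, 3), ", valid ",
      round(x$auc_valid, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname search_signature
#' @param x A `signature_result`.
#' @param ... Unused.
#' @export
tidy.signature_result <- function(x, ...) x$trace

#' @rdname search_signature
#' @export
glance.signature_result <- function(x, ...) {
  tibble(size = x$size, features = paste(x$features, collapse = " + "),
         auc_train = x$auc_train, auc_valid = x$auc_valid, ri = x$ri,
         seed = x$seed)
}

#' @rdname search_signature
#' @param object A `signature_result`.
#' @export
autoplot.signature_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("auc_train", "auc_valid", "ri"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$size, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "signature size", y = NULL)
}

#' Serialize a signature search to JSON
#'
#' @param x A `signature_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(x, path) {
  jsonlite::write_json(list(
    features = x$features, ri = x$ri, auc_train = x$auc_train,
    auc_valid = x$auc_valid, seed = x$seed, trace = x$trace
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
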