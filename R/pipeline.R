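#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run: preprocessing (HU window,
#' bit depth, isotropic voxel), BN map geometry, which feature approaches to
#' extract (`bn`, `oi`, `wd`), the signature search caps and the seed. The
#' configuration hash is embedded in all written outputs so two runs with
#' equal hashes are byte-identical.
#'
#' @param window HU window preset name (see [quant_preset()]).
#' @param bits Bit depth q (5-8).
#' @param kernel,stride BN map geometry (see [bn_map_config()]).
#' @param iso_mm Isotropic voxel size in mm.
#' @param approaches Subset of `c("bn", "oi", "wd")`.
#' @param alpha Mann-Whitney threshold for representative features.
#' @param top_m,max_size Signature search caps.
#' @param tune If `TRUE`, run the full SVM grid search after the signature
#'   search; the default `FALSE` keeps the signature-stage SVM (C = 1,
#'   gamma = 1/N).
#' @param holdout_frac Fraction of the training cases set aside, stratified
#'   by class, as a validation partition that takes no part in feature
#'   filtering, signature search or model fitting (default 1/3). The
#'   pipeline reports its validation AUC on this partition, so the estimate
#'   is shielded from the optimism of the RI-maximizing search; 0 disables
#'   the holdout and reports the (optimistic) cross-validation AUC instead.
#' @param boot_b Bootstrap replicates for evaluation CIs.
#' @param texture A [texture_config()].
#' @param seed Integer seed for folds, holdout and bootstraps.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(window = "mediastinal", bits = 5, kernel = 7, stride = 2,
                       iso_mm = 0.77, approaches = c("bn", "oi", "wd"),
                       alpha = 0.05, top_m = 25, max_size = 4, tune = FALSE,
                       holdout_frac = 1 / 3, boot_b = 2000,
                       texture = texture_config(), seed = 1) {
  if (!all(approaches %in% c("bn", "oi", "wd")) || length(approaches) == 0)
    stop_param("`approaches` must be a non-empty subset of bn/oi/wd")
  if (holdout_frac < 0 || holdout_frac >= 1)
    stop_param("`holdout_frac` must be in [0, 1)")
  cfg <- list(window = window, bits = bits, kernel = kernel, stride = stride,
              iso_mm = iso_mm, approaches = approaches, alpha = alpha,
              top_m = top_m, max_size = max_size, tune = tune,
              holdout_frac = holdout_frac, boot_b = boot_b,
              texture = texture, seed = seed)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

case_list <- function(cases) {
  if (inherits(cases, "phantom_cohort")) return(cases$cases)
  cases
}

#' Extract feature tables for a set of cases
#'
#' Preprocesses every case ([preprocess_case()]) and extracts the feature
#' vector of each requested approach: BN (Betti-number maps), OI (original
#' image) and WD (wavelet decomposition). Unreadable or degenerate cases
#' are skipped with a warning; if every case fails, an error is raised.
#'
#' @param cases A `phantom_cohort`, or a list of
#'   `list(case_id, label, volume, mask)` entries.
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes one CSV per approach plus a
#'   JSON sidecar with the configuration.
#' @return Named list of [feature_table()]s (one per approach), with the
#'   config attached as attribute `config`.
#' @export
run_extract <- function(cases, config = run_config(), out_dir = NULL) {
  cases <- case_list(cases)
  qcfg <- quant_preset(config$window, config$bits)
  bcfg <- bn_map_config(config$kernel, config$stride)
  rows <- purrr::map(cases, function(cs) {
    tryCatch({
      qs <- preprocess_case(cs$volume, cs$mask, qcfg, config$iso_mm)
      out <- list(case_id = cs$case_id, label = cs$label)
      if ("bn" %in% config$approaches) {
        stack <- bn_maps(qs, bcfg)
        rg <- roi_on_map_grid(qs$roi, bcfg)
        if (!any(rg)) stop_degenerate("ROI empty on the map grid")
        out$bn <- extract_bn_features(stack, rg, config$texture)
      }
      if ("oi" %in% config$approaches)
        out$oi <- extract_oi_features(qs, config$texture)
      if ("wd" %in% config$approaches)
        out$wd <- extract_wd_features(qs, config$texture)
      out
    }, error = function(e) {
      warning("skipping case ", cs$case_id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stop_degenerate("all cases failed feature extraction")
  tables <- purrr::map(rlang::set_names(config$approaches), function(ap) {
    feature_table(
      case_id = purrr::map_chr(rows, "case_id"),
      label = purrr::map_chr(rows, "label"),
      features = do.call(rbind, purrr::map(rows, ap))
    )
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ap in names(tables))
      utils::write.csv(tables[[ap]], file.path(out_dir, paste0(ap, "_features.csv")),
                       row.names = FALSE)
    jsonlite::write_json(config[setdiff(names(config), "texture")],
                         file.path(out_dir, "extraction_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(tables, "config") <- config
  tables
}

train_eval_one <- function(table, config, roles) {
  train_tb <- if (is.null(roles)) table else table[roles == "train", ]
  test_tb <- if (is.null(roles) || !any(roles == "test")) NULL
             else table[roles == "test", ]
  valid_tb <- NULL
  if (config$holdout_frac > 0) {
    pos <- label_flags(train_tb)
    hold <- withr::with_seed(config$seed + 7L, {
      h <- logical(length(pos))
      for (cl in c(TRUE, FALSE)) {
        idx <- which(pos == cl)
        h[sample(idx, max(1L, round(length(idx) * config$holdout_frac)))] <- TRUE
      }
      h
    })
    valid_tb <- train_tb[hold, ]
    train_tb <- train_tb[!hold, ]
  }
  candidates <- mann_whitney_filter(train_tb, config$alpha)
  if (length(candidates) == 0)
    return(list(status = "no representative features"))
  sig <- search_signature(train_tb, candidates, max_size = config$max_size,
                          seed = config$seed, top_m = config$top_m)
  spec <- if (isTRUE(config$tune))
    grid_search_svm(train_tb, sig, seed = config$seed) else NULL
  model <- fit_model(train_tb, sig, spec)
  out <- list(status = "ok", signature = sig, model_spec = spec, model = model)
  if (!is.null(valid_tb)) {
    out$eval_valid <- evaluate(model, valid_tb, boot_b = config$boot_b,
                               seed = config$seed)
    out$auc_valid <- out$eval_valid$auc
  } else {
    out$auc_valid <- sig$auc_valid
  }
  if (!is.null(test_tb)) {
    out$eval_test <- evaluate(model, test_tb, boot_b = config$boot_b,
                              seed = config$seed)
    out$ri <- robustness_index(out$auc_valid, out$eval_test$auc)
  } else {
    out$ri <- robustness_index(sig$auc_train, out$auc_valid)
  }
  out
}

#' Train, select and evaluate all approaches
#'
#' For each extracted feature table: sets aside a stratified validation
#' holdout (see `holdout_frac` in [run_config()]), filters representative
#' features (Mann-Whitney) on the remaining training cases, searches the
#' RI-maximizing 1-4 feature signature, optionally grid-searches the SVM,
#' fits the final model, and evaluates it on the holdout (the reported
#' validation AUC) and, when a test partition is declared, on the test
#' cases. The winning approach is the one with the highest RI (validation
#' vs test when a test set exists, training vs validation otherwise). An
#' approach whose filter keeps nothing is reported with status "no
#' representative features".
#'
#' @param tables Named list of feature tables from [run_extract()].
#' @param config A [run_config()].
#' @param roles Optional character vector (one per case, `"train"` or
#'   `"test"`) declaring the split; `NULL` uses every case for
#'   training/validation.
#' @return A `pipeline_report`: per-approach results, `winner`, and the
#'   config.
#' @export
run_train_eval <- function(tables, config = run_config(), roles = NULL) {
  if (!is.null(roles)) {
    if (!all(roles %in% c("train", "test")))
      stop_param('`roles` entries must be "train" or "test"')
    if (length(roles) != nrow(tables[[1]]))
      stop_param("`roles` must have one entry per case")
  }
  approaches <- purrr::map(tables, train_eval_one, config = config, roles = roles)
  ris <- purrr::map_dbl(approaches, function(a) {
    if (identical(a$status, "ok")) a$ri else -Inf
  })
  winner <- if (all(!is.finite(ris))) NA_character_ else names(which.max(ris))
  structure(list(approaches = approaches, winner = winner, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> approaches:", paste(names(x$approaches), collapse = ", "),
      "\n")
  for (nm in names(x$approaches)) {
    a <- x$approaches[[nm]]
    if (identical(a$status, "ok")) {
      cat("  ", nm, ": RI ", round(a$ri, 3), ", signature [",
          paste(a$signature$features, collapse = ", "), "]\n", sep = "")
    } else {
      cat("  ", nm, ": ", a$status, "\n", sep = "")
    }
  }
  cat("  winner by RI:", x$winner, "\n")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes signatures, RIs, evaluation metrics, the winner, the seed and the
#' configuration hash.
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  enc <- purrr::map(report$approaches, function(a) {
    if (!identical(a$status, "ok")) return(list(status = a$status))
    out <- list(status = "ok", features = a$signature$features,
                ri = a$ri, auc_train = a$signature$auc_train,
                auc_valid = a$signature$auc_valid)
    if (!is.null(a$eval_test)) out$test <- glance(a$eval_test)
    out
  })
  jsonlite::write_json(list(
    approaches = enc, winner = report$winner,
    seed = report$config$seed, config_hash = report$config$hash
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a pipeline report JSON
#'
#' @param path Path written by [write_report_json()].
#' @return The parsed list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
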