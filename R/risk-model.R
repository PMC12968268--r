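# Report-level gradient-boosted classification of miscarriage from binary
# drug-exposure indicators, with cross-validated discrimination, Mann-Whitney
# AUC, SHAP attribution and gain-based importance.

#' Default booster hyperparameters
#'
#' Fixed, documented defaults favoring reproducibility over tuning: logistic
#' objective, depth 4, learning rate 0.1, 200 rounds, single thread, class
#' imbalance handled by `scale_pos_weight =` negatives/positives (computed on
#' each training set).
#'
#' @param nrounds Boosting rounds.
#' @return List with `params` (passed to the booster) and `nrounds`.
#' @export
default_booster_params <- function(nrounds = 200) {
  list(params = list(objective = "binary:logistic", max_depth = 4,
                     eta = 0.1, nthread = 1),
       nrounds = nrounds)
}

#' Most frequently reported drugs among cases
#'
#' Ranks primary-suspect drugs by their miscarriage case-report count (after
#' the cohort's exclusion list, which [filter_cohort()] already applied to
#' qualification); ties are broken lexicographically for determinism.
#'
#' @param cohort A `pv_cohort`.
#' @param k Number of drugs to select.
#' @return Character vector of up to `k` normalized drug names (all drugs,
#'   with a warning, when fewer exist).
#' @export
select_top_drugs <- function(cohort, k = 30) {
  stopifnot(inherits(cohort, "pv_cohort"), k >= 1)
  cases <- cohort$demo[is_case == TRUE, primaryid]
  ps <- unique(cohort$drug[role_cod == "PS", .(primaryid, drugname_norm)])
  flt <- attr(cohort, "filter")
  if (!is.null(flt)) ps <- ps[!drugname_norm %in% flt$drug_exclusions]
  cnt <- ps[primaryid %in% cases, .N, by = drugname_norm]
  setorder(cnt, -N, drugname_norm)
  if (nrow(cnt) < k) {
    warning(sprintf("only %d drugs available (< k = %d); returning all",
                    nrow(cnt), k))
    k <- nrow(cnt)
  }
  cnt$drugname_norm[seq_len(k)]
}

#' Build the report-level feature matrix
#'
#' Rows are deduplicated reports exposed (as primary suspect) to at least one
#' selected drug; columns are binary exposure indicators; the outcome flags
#' whether the report is a miscarriage case.
#'
#' @param cohort A `pv_cohort`.
#' @param drugs Selected (normalized) drug names.
#' @return Object of class `feature_matrix`: `x` (0/1 matrix), `y` (0/1
#'   outcome), `caseid` row keys; attribute `n_dropped` counts reports with
#'   no selected exposure.
#' @export
build_feature_matrix <- function(cohort, drugs) {
  stopifnot(inherits(cohort, "pv_cohort"), length(drugs) >= 1)
  drugs <- normalize_drug(drugs)
  ps <- unique(cohort$drug[role_cod == "PS" & drugname_norm %in% drugs,
                           .(primaryid, drugname_norm)])
  keep <- unique(ps$primaryid)
  if (!length(keep)) stop("no reports exposed to the selected drugs", call. = FALSE)
  demo <- cohort$demo[primaryid %in% keep, .(primaryid, caseid, is_case)]
  setorder(demo, primaryid)
  x <- matrix(0L, nrow(demo), length(drugs),
              dimnames = list(NULL, drugs))
  ri <- match(ps$primaryid, demo$primaryid)
  ci <- match(ps$drugname_norm, drugs)
  x[cbind(ri, ci)] <- 1L
  structure(list(x = x, y = as.integer(demo$is_case), caseid = demo$caseid),
            class = "feature_matrix",
            n_dropped = nrow(cohort$demo) - nrow(demo))
}

#' Mann-Whitney AUC
#'
#' Rank-sum estimator of the area under the ROC curve with half credit for
#' ties.
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 (or logical) outcomes.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_mw <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

train_booster <- function(x, y, booster = default_booster_params()) {
  spw <- sum(y == 0) / max(1, sum(y == 1))
  dm <- xgboost::xgb.DMatrix(x, label = y)
  bst <- xgboost::xgb.train(params = c(booster$params,
                                       list(scale_pos_weight = spw)),
                            data = dm, nrounds = booster$nrounds, verbose = 0)
  xgboost::xgb.attr(bst, "pv_features") <- paste(colnames(x), collapse = "|")
  bst
}

booster_features <- function(model) {
  f <- xgboost::xgb.attr(model, "pv_features")
  if (is.null(f)) return(NULL)
  strsplit(f, "|", fixed = TRUE)[[1]]
}

#' Cross-validated discrimination of the boosted risk model
#'
#' Seeded stratified fold assignment; per fold a gradient-boosted tree model
#' is trained on the remaining folds and scored on the held-out fold. AUC per
#' fold uses the in-package rank-sum estimator; pooled accuracy at the 0.5
#' threshold carries an exact binomial 95% interval. When a fold lacks both
#' outcome classes the folds are re-drawn once, then an error is raised.
#'
#' @param matrix A `feature_matrix`.
#' @param n_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param booster See [default_booster_params()].
#' @return List of class `fold_metrics`: `auc` per fold, `mean_auc`,
#'   `accuracy` with `accuracy_ci`, `folds` assignment vector.
#' @export
cross_validate <- function(matrix, n_folds = 5, seed = 7,
                           booster = default_booster_params()) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- matrix$y
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  fold <- stratified_folds(y, n_folds, seed)
  bad <- vapply(seq_len(n_folds), function(f)
    length(unique(y[fold == f])) < 2, TRUE)
  if (any(bad)) {
    fold <- stratified_folds(y, n_folds, seed + 1L)
    bad <- vapply(seq_len(n_folds), function(f)
      length(unique(y[fold == f])) < 2, TRUE)
    if (any(bad)) stop("a fold lacks both classes after re-draw", call. = FALSE)
  }
  aucs <- numeric(n_folds)
  pred <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    bst <- train_booster(matrix$x[tr, , drop = FALSE], y[tr], booster)
    p <- stats::predict(bst, xgboost::xgb.DMatrix(
      matrix$x[!tr, , drop = FALSE]))
    pred[!tr] <- p
    aucs[f] <- auc_mw(p, y[!tr])
  }
  acc_n <- sum((pred >= 0.5) == (y == 1))
  ci <- stats::binom.test(acc_n, length(y))$conf.int
  structure(list(auc = aucs, mean_auc = mean(aucs),
                 accuracy = acc_n / length(y),
                 accuracy_ci = as.numeric(ci), folds = fold,
                 predictions = pred),
            class = "fold_metrics")
}

#' Fit the risk model on the full matrix
#'
#' @param matrix A `feature_matrix`.
#' @param booster See [default_booster_params()].
#' @return A trained xgboost booster.
#' @export
fit_risk_model <- function(matrix, booster = default_booster_params()) {
  stopifnot(inherits(matrix, "feature_matrix"))
  train_booster(matrix$x, matrix$y, booster)
}

#' SHAP-based feature importance
#'
#' Per-feature mean absolute SHAP attribution (TreeSHAP, via the booster's
#' native contribution predictions), the mean signed attribution among
#' exposed rows (direction summary), and the descending importance rank.
#' Additivity is enforced: per-row attributions plus the base value must
#' reproduce the model margin within `tol`.
#'
#' @param model Trained booster from [fit_risk_model()].
#' @param matrix The `feature_matrix` the model was trained on.
#' @param tol Maximum permitted additivity deviation.
#' @param sample_rows Optional cap on the number of rows used for the global
#'   summary (TreeSHAP cost grows with rows x trees); when the matrix is
#'   larger, a seeded uniform subsample of this size is explained instead.
#'   `NULL` explains every row.
#' @param seed Subsampling seed (only used when `sample_rows` bites).
#' @return data.table: `feature`, `mean_abs_shap`, `mean_shap_exposed`,
#'   `rank`.
#' @export
shap_ranking <- function(model, matrix, tol = 1e-4, sample_rows = NULL,
                         seed = 1) {
  stopifnot(inherits(matrix, "feature_matrix"))
  feats <- colnames(matrix$x)
  trained <- booster_features(model)
  if (!is.null(trained) && !identical(trained, feats))
    stop("feature mismatch between model and matrix", call. = FALSE)
  x <- matrix$x
  if (!is.null(sample_rows) && nrow(x) > sample_rows) {
    idx <- with_seed(seed, sample.int(nrow(x), sample_rows))
    x <- x[idx, , drop = FALSE]
    matrix <- structure(list(x = x, y = matrix$y[idx],
                             caseid = matrix$caseid[idx]),
                        class = "feature_matrix")
  }
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- stats::predict(model, dm, predcontrib = TRUE)
  margin <- stats::predict(model, dm, outputmargin = TRUE)
  dev <- max(abs(rowSums(contrib) - margin))
  if (dev > tol)
    stop(sprintf("SHAP additivity violated: max deviation %.2e > %.0e",
                 dev, tol), call. = FALSE)
  sh <- contrib[, feats, drop = FALSE]
  mean_abs <- colMeans(abs(sh))
  mean_exposed <- vapply(feats, function(f) {
    rows <- matrix$x[, f] == 1
    if (any(rows)) mean(sh[rows, f]) else NA_real_
  }, 0)
  out <- data.table(feature = feats, mean_abs_shap = mean_abs,
                    mean_shap_exposed = mean_exposed)
  setorder(out, -mean_abs_shap, feature)
  out[, rank := .I]
  out[]
}

#' Gain-based feature importance
#'
#' Total split gain per feature from the booster, normalized to sum to 1;
#' unused features appear with gain 0.
#'
#' @param model Trained booster.
#' @param features Full feature set (ensures unused features are listed).
#' @return data.table: `feature`, `gain`, `rank`.
#' @export
gain_importance <- function(model, features = NULL) {
  tr <- xgboost::xgb.model.dt.tree(model = model)
  out <- tr[Feature != "Leaf", .(gain = sum(Gain)), by = .(feature = Feature)]
  features <- features %||% booster_features(model)
  if (!is.null(features)) {
    missing <- setdiff(features, out$feature)
    if (length(missing))
      out <- rbindlist(list(out, data.table(feature = missing, gain = 0)))
  }
  out[, gain := gain / sum(gain)]
  setorder(out, -gain, feature)
  out[, rank := .I]
  out[]
}
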