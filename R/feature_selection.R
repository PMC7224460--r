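#' Cross-validation configuration
#'
#' @param k_folds Number of folds (>= 2).
#' @param seeds Integer RNG seeds; each seed yields one repetition of the
#'   whole CV (default 1:5).
#' @param variant `"OUT"` (feature ranking fixed before fold splitting,
#'   the default) or `"IN"` (ranking re-estimated inside each training
#'   fold).
#' @param stratified Stratify fold assignment by class (default TRUE).
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_folds = 10, seeds = 1:5,
                      variant = c("OUT", "IN"), stratified = TRUE) {
  variant <- match.arg(variant)
  stopifnot(k_folds >= 2, length(seeds) >= 1)
  structure(list(k_folds = as.integer(k_folds), seeds = as.integer(seeds),
                 variant = variant, stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Stratified fold assignment: seeded shuffle within each class, then
# round-robin over folds. Re-draws with an incremented sub-seed until every
# fold contains both classes (when attainable).
make_folds <- function(y, k, seed, stratified = TRUE, max_redraw = 25L) {
  n <- length(y)
  k <- min(k, n)
  assign_once <- function(s) {
    set.seed(s)
    fold <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    fold
  }
  both_attainable <- min(table(factor(y, levels = c(0, 1)))) >= k
  fold <- assign_once(seed)
  if (both_attainable) {
    tries <- 0L
    while (tries < max_redraw &&
           any(vapply(seq_len(k), function(f)
             length(unique(y[fold != f])) < 2L, logical(1)))) {
      tries <- tries + 1L
      fold <- assign_once(seed + 10000L * tries)
    }
    if (tries > 0L)
      message("fold partition re-drawn ", tries, " time(s) for seed ", seed)
  }
  fold
}

#' Decision-tree predictor importance
#'
#' Fits a tree on all 12 features and computes, per feature, the sum of
#' split risk reductions across branch nodes divided by the total number of
#' branch nodes. Features never split on score exactly 0. The ranking
#' orders features by descending importance, ties broken by canonical
#' order.
#'
#' @param table Feature table with the 12 canonical columns and `label`.
#' @param impurity Impurity passed to [fit_cart()].
#' @param min_split,min_leaf Tree growth controls.
#' @return An `importance_result`: list with `importance` (named numeric)
#'   and `ranking` (character).
#' @export
estimate_importance <- function(table, impurity = "gini",
                                min_split = 10, min_leaf = 1) {
  feats <- feature_names()
  tree <- fit_cart(table, table$label, features = feats, impurity = impurity,
                   min_split = min_split, min_leaf = min_leaf)
  nb <- n_branch_nodes(tree)
  imp <- if (nb == 0L) stats::setNames(numeric(12), feats)
         else cart_risk_reduction(tree) / nb
  ranking <- feats[order(-imp, seq_along(feats))]
  structure(list(importance = imp, ranking = ranking, n_branch_nodes = nb,
                 tree = tree),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result>\n")
  print(data.frame(feature = x$ranking,
                   Imp = unname(x$importance[x$ranking])))
  invisible(x)
}

#' Cross-validated MSE profile over nested feature subsets
#'
#' For k = 1..12 features taken in ranked order, fits a decision tree under
#' stratified `k_folds`-fold CV once per seed and pools the test-fold
#' squared error of the 0/1 predictions (equal to the misclassification
#' rate). The OUT variant uses the supplied ranking for every fold; the IN
#' variant re-ranks within each training fold.
#'
#' @param table Feature table.
#' @param ranking Character vector covering all 12 features (from
#'   [estimate_importance()]); ignored per-fold under `variant = "IN"`.
#' @param cv A [cv_config()] (default 10-fold, seeds 1:5, OUT).
#' @param impurity,min_split,min_leaf Tree controls.
#' @return An `mse_profile` data frame: one row per feature count with one
#'   column per seed plus `mean_mse` and `sd_mse` (sample SD across seeds).
#' @export
cv_mse_profile <- function(table, ranking, cv = cv_config(),
                           impurity = "gini", min_split = 10, min_leaf = 1) {
  stopifnot(setequal(ranking, feature_names()))
  y <- table$label
  ks <- seq_along(ranking)
  res <- matrix(NA_real_, nrow = length(ks), ncol = length(cv$seeds),
                dimnames = list(NULL, paste0("seed_", cv$seeds)))
  for (s in seq_along(cv$seeds)) {
    fold <- make_folds(y, cv$k_folds, cv$seeds[s], cv$stratified)
    nf <- max(fold)
    # per-fold training rankings for the IN variant
    in_rankings <- if (cv$variant == "IN") {
      lapply(seq_len(nf), function(f)
        estimate_importance(table[fold != f, , drop = FALSE],
                            impurity = impurity, min_split = min_split,
                            min_leaf = min_leaf)$ranking)
    } else NULL
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      sq_err <- 0
      for (f in seq_len(nf)) {
        feats <- if (cv$variant == "IN") in_rankings[[f]][seq_len(k)]
                 else ranking[seq_len(k)]
        train <- table[fold != f, , drop = FALSE]
        test <- table[fold == f, , drop = FALSE]
        tree <- fit_cart(train, train$label, features = feats,
                         impurity = impurity, min_split = min_split,
                         min_leaf = min_leaf)
        pred <- predict(tree, test)
        sq_err <- sq_err + sum((pred - test$label)^2)
      }
      res[ki, s] <- sq_err / length(y)
    }
  }
  out <- data.frame(n_features = ks, res, check.names = FALSE)
  out$mean_mse <- rowMeans(res)
  out$sd_mse <- apply(res, 1, stats::sd)
  class(out) <- c("mse_profile", "data.frame")
  out
}

#' Select the optimal feature subset from an MSE profile
#'
#' Rule: let k_min minimize the mean CV MSE (first minimum); candidates are
#' all k whose mean MSE lies within one SD (the SD at k_min) of that
#' minimum; the smallest candidate wins. When a per-k performance table is
#' given (columns `n_features`, `SE`, and optionally `exT`), candidates
#' whose SE equals the best candidate SE are preferred, smallest k first —
#' fewer features means lower prediction latency, accepted at the price of
#' a small specificity loss.
#'
#' @param profile An `mse_profile` from [cv_mse_profile()].
#' @param ranking Feature ranking the profile was built on.
#' @param perf_by_k Optional data frame with per-k `SE` (and `exT`).
#' @return Character vector: the selected top-k features.
#' @export
select_optimal_set <- function(profile, ranking, perf_by_k = NULL) {
  mu <- profile$mean_mse
  sdv <- profile$sd_mse
  k_min <- which.min(mu)
  thresh <- mu[k_min] + sdv[k_min]
  cand <- profile$n_features[mu <= thresh]
  k_star <- min(cand)
  if (!is.null(perf_by_k) && all(c("n_features", "SE") %in% names(perf_by_k))) {
    pk <- perf_by_k[perf_by_k$n_features %in% cand, , drop = FALSE]
    if (nrow(pk) > 0L) {
      best_se <- max(pk$SE)
      k_star <- min(pk$n_features[pk$SE >= best_se - 1e-9])
    }
  }
  ranking[seq_len(k_star)]
}

#' Write an importance report (feature, Imp) as CSV
#' @param imp An `importance_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_importance_report <- function(imp, path) {
  utils::write.csv(
    data.frame(feature = imp$ranking, Imp = unname(imp$importance[imp$ranking])),
    path, row.names = FALSE)
  invisible(path)
}

#' Write an MSE-profile report as CSV
#' @param profile An `mse_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mse_profile_report <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
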