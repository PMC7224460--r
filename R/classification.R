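#' Classifier specification
#'
#' @param kind `"dt"` (decision tree), `"nb"` (Gaussian naive Bayes) or
#'   `"svm"` (support vector machine).
#' @param ... Kind-specific parameters. dt: `impurity`, `min_split`,
#'   `min_leaf`; nb: `var_floor_frac` (variance floor as a fraction of the
#'   pooled feature variance, default 1e-9); svm: `kernel` (default
#'   `"linear"`), `cost` (default 1), `standardize` (default FALSE).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("dt", "nb", "svm"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    dt = list(impurity = "gini", min_split = 10, min_leaf = 1),
    nb = list(var_floor_frac = 1e-9),
    svm = list(kernel = "linear", cost = 1, standardize = FALSE))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L)
    stop("invalid parameters for ", kind, ": ", paste(unknown, collapse = ", "))
  structure(list(kind = kind, params = utils::modifyList(defaults, params)),
            class = "classifier_spec")
}

#' Split a feature table into five 5-minute interval datasets
#'
#' Positive rows are binned by minutes before onset: interval r covers
#' `((r-1)*5, r*5]` minutes, r = 1..5; positives beyond 25 minutes (or at
#' exactly 0) are discarded with a message. Negatives are matched by
#' record-minute position: every normal-record row whose
#' `index_in_record` occurs among the interval's positives is included,
#' which balances each interval without reusing unrelated minutes.
#'
#' @param table Feature table with `label`, `minutes_before_onset` and
#'   `index_in_record` columns.
#' @return A list of up to five `interval_dataset` objects (list with
#'   `interval`, `rows`); empty intervals are skipped with a warning.
#' @export
build_interval_datasets <- function(table) {
  stopifnot(all(c("label", "minutes_before_onset") %in% names(table)))
  pos <- table[table$label == 1L, , drop = FALSE]
  neg <- table[table$label == 0L, , drop = FALSE]
  out_of_range <- pos$minutes_before_onset <= 0 | pos$minutes_before_onset > 25
  if (any(out_of_range))
    message(sum(out_of_range), " positive row(s) outside 0-25 minutes discarded")
  pos <- pos[!out_of_range, , drop = FALSE]
  interval_of <- ceiling(pos$minutes_before_onset / 5)
  datasets <- list()
  for (r in 1:5) {
    p <- pos[interval_of == r, , drop = FALSE]
    if (nrow(p) == 0L) {
      warning("interval ", r, " empty; skipped")
      next
    }
    n <- if ("index_in_record" %in% names(table))
      neg[neg$index_in_record %in% unique(p$index_in_record), , drop = FALSE]
    else neg
    rows <- rbind(p, n)
    datasets[[length(datasets) + 1L]] <-
      structure(list(interval = r, rows = rows), class = "interval_dataset")
  }
  datasets
}

#' Train a classifier
#'
#' @param spec A [classifier_spec()].
#' @param train_rows Feature table rows to train on (must contain `label`).
#' @param feature_subset Character vector of feature columns.
#' @return A `fitted_classifier` wrapping the kind-specific model.
#' @export
train_classifier <- function(spec, train_rows, feature_subset) {
  y <- train_rows$label
  x <- train_rows[, feature_subset, drop = FALSE]
  if (spec$kind %in% c("dt", "svm") && length(unique(y)) < 2L)
    stop(spec$kind, " requires both classes in the training data")
  model <- switch(spec$kind,
    dt = fit_cart(x, y, features = feature_subset,
                  impurity = spec$params$impurity,
                  min_split = spec$params$min_split,
                  min_leaf = spec$params$min_leaf),
    nb = fit_gaussian_nb(x, y, var_floor_frac = spec$params$var_floor_frac),
    svm = e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                     kernel = spec$params$kernel, cost = spec$params$cost,
                     scale = spec$params$standardize, type = "C-classification"))
  structure(list(kind = spec$kind, model = model, features = feature_subset),
            class = "fitted_classifier")
}

#' Predict with a fitted classifier
#'
#' @param object A `fitted_classifier`.
#' @param rows Feature table rows (must contain the model's features).
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.fitted_classifier <- function(object, rows, ...) {
  missing <- setdiff(object$features, names(rows))
  if (length(missing) > 0L)
    stop("missing features: ", paste(missing, collapse = ", "))
  x <- rows[, object$features, drop = FALSE]
  switch(object$kind,
    dt = predict(object$model, x),
    nb = predict_gaussian_nb(object$model, x),
    svm = as.integer(as.character(predict(object$model, as.matrix(x)))))
}

# Gaussian naive Bayes: per-class, per-feature normal likelihoods with a
# variance floor; class priors from training frequencies; posterior ties
# (including the single-class degenerate fit) resolve to label 0.
fit_gaussian_nb <- function(x, y, var_floor_frac = 1e-9) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  pooled_var <- apply(x, 2, stats::var)
  pooled_var[!is.finite(pooled_var) | pooled_var <= 0] <- 1
  floor_v <- var_floor_frac * pooled_var
  pars <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    v <- apply(xc, 2, function(col)
      if (length(col) > 1L) stats::var(col) else 0)
    flo <- v < floor_v | v == 0
    if (any(flo)) v[flo] <- floor_v[flo]
    list(mu = mu, var = v, prior = nrow(xc) / nrow(x))
  })
  names(pars) <- as.character(classes)
  structure(list(classes = classes, pars = pars), class = "gaussian_nb")
}

predict_gaussian_nb <- function(model, x) {
  x <- as.matrix(x)
  ll <- matrix(0, nrow = nrow(x), ncol = length(model$classes))
  for (ci in seq_along(model$classes)) {
    p <- model$pars[[as.character(model$classes[ci])]]
    acc <- rep(log(p$prior), nrow(x))
    for (j in seq_len(ncol(x)))
      acc <- acc + stats::dnorm(x[, j], p$mu[j], sqrt(p$var[j]), log = TRUE)
    ll[, ci] <- acc
  }
  if (length(model$classes) == 1L)
    return(rep.int(as.integer(model$classes), nrow(x)))
  # tie (equal posteriors) -> class 0, which sorts first
  as.integer(model$classes[max.col(ll, ties.method = "first")])
}

#' Repeated stratified cross-validation of one interval dataset
#'
#' Per seed: stratified `k_folds` partition, train on k-1 folds, predict
#' the held-out fold, and pool TP/FP/TN/FN over all test folds. The feature
#' subset is fixed before fold splitting (the OUT protocol). Intervals with
#' fewer positives than folds reduce k to the positive count.
#'
#' @param dataset An `interval_dataset` (or any feature table with
#'   `label`).
#' @param spec A [classifier_spec()].
#' @param feature_subset Feature columns to use.
#' @param cv A [cv_config()] (default 5-fold, seeds 1:5).
#' @return Data frame of pooled confusion counts, one row per seed:
#'   `seed`, `TP`, `FP`, `TN`, `FN`.
#' @export
run_cv <- function(dataset, spec, feature_subset, cv = cv_config(k_folds = 5)) {
  rows <- if (inherits(dataset, "interval_dataset")) dataset$rows else dataset
  y <- rows$label
  k <- cv$k_folds
  n_pos <- sum(y == 1L)
  if (n_pos < k) {
    message("interval has ", n_pos, " positives; folds reduced to ", n_pos)
    k <- max(2L, n_pos)
  }
  out <- data.frame(seed = cv$seeds, TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (s in seq_along(cv$seeds)) {
    fold <- make_folds(y, k, cv$seeds[s], cv$stratified)
    for (f in seq_len(max(fold))) {
      train <- rows[fold != f, , drop = FALSE]
      test <- rows[fold == f, , drop = FALSE]
      if (nrow(test) == 0L) next
      model <- train_classifier(spec, train, feature_subset)
      pred <- predict(model, test)
      out$TP[s] <- out$TP[s] + sum(pred == 1L & test$label == 1L)
      out$FP[s] <- out$FP[s] + sum(pred == 1L & test$label == 0L)
      out$TN[s] <- out$TN[s] + sum(pred == 0L & test$label == 0L)
      out$FN[s] <- out$FN[s] + sum(pred == 0L & test$label == 1L)
    }
  }
  out
}
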