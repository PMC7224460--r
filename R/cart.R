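#' Fit a binary CART decision tree
#'
#' Greedy binary classification tree on numeric features. Each branch node
#' stores the split feature, threshold and node risk (node weight times
#' impurity); leaves store the majority label (ties toward label 0). The
#' fit is fully deterministic: splits are found by exhaustive search and
#' ties in split gain are broken by lowest feature index, then lowest
#' threshold. No pruning is applied; growth stops at pure nodes, below
#' `min_split` rows, or when no split with positive gain and `min_leaf`
#' rows per child exists.
#'
#' @param x Data frame or matrix of numeric features.
#' @param y 0/1 labels.
#' @param features Character vector of feature columns to use (default all
#'   columns of `x`, in their canonical order).
#' @param impurity `"gini"` (default) or `"mse"` (variance of the 0/1
#'   labels, i.e. the squared-error risk the importance statistic is
#'   defined on; for binary labels the two orderings of splits coincide up
#'   to a factor of 2).
#' @param min_split Minimum rows in a node to attempt a split.
#' @param min_leaf Minimum rows in each child.
#' @return A `cart_tree`: list with a node table and fitting metadata.
#' @export
fit_cart <- function(x, y, features = NULL, impurity = c("gini", "mse"),
                     min_split = 10, min_leaf = 1) {
  impurity <- match.arg(impurity)
  x <- as.data.frame(x)
  if (is.null(features)) features <- names(x)
  missing <- setdiff(features, names(x))
  if (length(missing) > 0L)
    stop("features not in data: ", paste(missing, collapse = ", "))
  xm <- as.matrix(x[, features, drop = FALSE])
  storage.mode(xm) <- "double"
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(xm), length(y) >= 1L)
  N <- length(y)

  imp_fun <- switch(impurity,
    gini = function(n1, n) { p <- n1 / n; 2 * p * (1 - p) },
    mse  = function(n1, n) { p <- n1 / n; p * (1 - p) })

  nodes <- list()
  new_node <- function(rows) {
    n <- length(rows)
    n1 <- sum(y[rows])
    risk <- (n / N) * imp_fun(n1, n)
    list(rows = rows, n = n, n1 = n1, risk = risk,
         pred = if (n1 * 2L > n) 1L else 0L,   # tie -> 0
         is_leaf = TRUE, feature = NA_integer_, threshold = NA_real_,
         left = NA_integer_, right = NA_integer_)
  }

  best_split <- function(rows) {
    n <- length(rows)
    n1_tot <- sum(y[rows])
    if (n1_tot == 0L || n1_tot == n || n < min_split) return(NULL)
    parent_risk <- (n / N) * imp_fun(n1_tot, n)
    best <- NULL
    tol <- 1e-12
    for (j in seq_along(features)) {
      xj <- xm[rows, j]
      ord <- order(xj)
      xs <- xj[ord]
      ys <- y[rows][ord]
      cum1 <- cumsum(ys)
      i <- seq_len(n - 1L)
      cand <- i[xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf]
      if (length(cand) == 0L) next
      nl <- cand
      nr <- n - cand
      l_risk <- (nl / N) * imp_fun(cum1[cand], nl)
      r_risk <- (nr / N) * imp_fun(n1_tot - cum1[cand], nr)
      gain <- parent_risk - (l_risk + r_risk)
      gmax <- max(gain)
      if (gmax <= tol) next
      # lowest threshold among (numerically) tied maxima within the feature
      k <- cand[which(gain >= gmax - tol)[1L]]
      thr <- (xs[k] + xs[k + 1L]) / 2
      if (is.null(best) || gmax > best$gain + tol) {
        best <- list(feature = j, threshold = thr, gain = gmax)
      }
    }
    best
  }

  # iterative growth, depth-first, left before right (node ids stable)
  nodes[[1L]] <- new_node(seq_len(N))
  stack <- 1L
  while (length(stack) > 0L) {
    id <- stack[1L]
    stack <- stack[-1L]
    nd <- nodes[[id]]
    sp <- best_split(nd$rows)
    if (is.null(sp)) next
    go_left <- xm[nd$rows, sp$feature] <= sp$threshold
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[lid]] <- new_node(nd$rows[go_left])
    nodes[[rid]] <- new_node(nd$rows[!go_left])
    nd$is_leaf <- FALSE
    nd$feature <- sp$feature
    nd$threshold <- sp$threshold
    nd$left <- lid
    nd$right <- rid
    nodes[[id]] <- nd
    stack <- c(lid, rid, stack)
  }

  node_df <- data.frame(
    id = seq_along(nodes),
    is_leaf = vapply(nodes, `[[`, logical(1), "is_leaf"),
    feature = vapply(nodes, `[[`, integer(1), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
    left = vapply(nodes, `[[`, integer(1), "left"),
    right = vapply(nodes, `[[`, integer(1), "right"),
    n = vapply(nodes, `[[`, integer(1), "n"),
    n1 = vapply(nodes, `[[`, numeric(1), "n1"),
    risk = vapply(nodes, `[[`, numeric(1), "risk"),
    pred = vapply(nodes, `[[`, integer(1), "pred"))
  structure(list(nodes = node_df, features = features, impurity = impurity,
                 n_train = N, min_split = min_split, min_leaf = min_leaf),
            class = "cart_tree")
}

#' @export
print.cart_tree <- function(x, ...) {
  nb <- sum(!x$nodes$is_leaf)
  cat(sprintf("<cart_tree> %d nodes (%d branch), impurity %s, %d training rows\n",
              nrow(x$nodes), nb, x$impurity, x$n_train))
  invisible(x)
}

#' Predict labels with a CART tree
#'
#' @param object A `cart_tree`.
#' @param newdata Data frame containing the tree's feature columns.
#' @param ... Unused.
#' @return Integer 0/1 label vector, one per row of `newdata`.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L)
    stop("missing features in newdata: ", paste(missing, collapse = ", "))
  xm <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(xm) <- "double"
  nd <- object$nodes
  out <- integer(nrow(xm))
  # route row blocks down the tree (vectorized per node)
  stack <- list(list(id = 1L, rows = seq_len(nrow(xm))))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(top$rows) == 0L) next
    id <- top$id
    if (nd$is_leaf[id]) {
      out[top$rows] <- nd$pred[id]
    } else {
      go <- xm[top$rows, nd$feature[id]] <= nd$threshold[id]
      stack[[length(stack) + 1L]] <- list(id = nd$left[id],
                                          rows = top$rows[go])
      stack[[length(stack) + 1L]] <- list(id = nd$right[id],
                                          rows = top$rows[!go])
    }
  }
  out
}

#' Split-risk reduction per feature of a fitted tree
#'
#' For each branch node, the risk reduction is parent risk minus the sum of
#' its children's risks; reductions are summed per split feature.
#'
#' @param tree A `cart_tree`.
#' @return Named numeric vector over the tree's features (0 for features
#'   never split on).
#' @export
cart_risk_reduction <- function(tree) {
  nd <- tree$nodes
  out <- stats::setNames(numeric(length(tree$features)), tree$features)
  branch <- which(!nd$is_leaf)
  for (id in branch) {
    gain <- nd$risk[id] - nd$risk[nd$left[id]] - nd$risk[nd$right[id]]
    f <- tree$features[nd$feature[id]]
    out[f] <- out[f] + gain
  }
  out
}

#' Number of branch nodes of a fitted tree
#' @param tree A `cart_tree`.
#' @return Integer count.
#' @export
n_branch_nodes <- function(tree) sum(!tree$nodes$is_leaf)
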