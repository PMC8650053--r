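#' Bagged regression-tree ensemble
#'
#' A compact random-forest regressor used to rank climate variables:
#' CART-style regression trees (variance-reduction splits, midpoint cut
#' points, `mtry` variables sampled per node) grown on bootstrap samples,
#' with out-of-bag (OOB) error tracking. Written in-package because the
#' toolchain provides no forest implementation; deliberately minimal --
#' site-level climate tables have a few dozen rows.
#'
#' @param X numeric matrix or data.frame of predictors (rows = sites).
#' @param y numeric response (per-site mean performance).
#' @param ntree number of trees.
#' @param mtry variables sampled at each node (default `max(1, floor(p/3))`).
#' @param min_node minimum node size to attempt a split.
#' @param seed optional seed for the bootstrap/split stream.
#' @return object of class `rf_model`: `trees`, `inbag` (bootstrap index
#'   list), `impurity` (per-variable total decrease in node sum of squares,
#'   averaged over trees), `varnames`, and the training data.
#' @export
rf_fit <- function(X, y, ntree = 500, mtry = NULL, min_node = 2,
                   seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1)
  if (n < 2 * min_node)
    stop("fewer sites (", n, ") than the minimum leaf configuration allows")
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", ntree)
  inbag <- vector("list", ntree)
  impurity <- numeric(p)
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE)
    inbag[[b]] <- rows
    trees[[b]] <- .grow_tree(X, y, rows, mtry, min_node)
    impurity <- impurity + attr(trees[[b]], "impurity")
  }
  structure(list(trees = trees, inbag = inbag,
                 impurity = impurity / ntree,
                 varnames = colnames(X), X = X, y = y,
                 ntree = ntree, mtry = mtry, min_node = min_node),
            class = "rf_model")
}

# recursive CART growth; returns nested list, with the per-variable impurity
# decrease of this tree attached as an attribute at the root
.grow_tree <- function(X, y, rows, mtry, min_node) {
  p <- ncol(X)
  imp <- numeric(p)
  grow <- function(rows) {
    yy <- y[rows]
    if (length(rows) < 2 * min_node || stats::var(yy) == 0)
      return(list(leaf = TRUE, pred = mean(yy)))
    vars <- sample.int(p, min(mtry, p))
    best <- NULL
    sse_parent <- sum((yy - mean(yy))^2)
    for (v in vars) {
      xv <- X[rows, v]
      ux <- sort(unique(xv))
      if (length(ux) < 2) next
      cuts <- (ux[-1] + ux[-length(ux)]) / 2
      for (ct in cuts) {
        l <- xv <= ct
        if (sum(l) < min_node || sum(!l) < min_node) next
        yl <- yy[l]; yr <- yy[!l]
        sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
        if (is.null(best) || sse < best$sse)
          best <- list(v = v, cut = ct, sse = sse)
      }
    }
    if (is.null(best) || best$sse >= sse_parent)
      return(list(leaf = TRUE, pred = mean(yy)))
    imp[best$v] <<- imp[best$v] + (sse_parent - best$sse)
    l <- X[rows, best$v] <= best$cut
    list(leaf = FALSE, var = best$v, cut = best$cut,
         left = grow(rows[l]), right = grow(rows[!l]))
  }
  root <- grow(rows)
  attr(root, "impurity") <- imp
  root
}

.tree_predict <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  walk <- function(node, idx) {
    if (node$leaf) { out[idx] <<- node$pred; return(invisible()) }
    l <- X[idx, node$var] <= node$cut
    if (any(l)) walk(node$left, idx[l])
    if (any(!l)) walk(node$right, idx[!l])
  }
  walk(node, seq_len(n))
  out
}

#' @param object an `rf_model`.
#' @param newdata predictor matrix; defaults to the training data.
#' @param ... unused.
#' @rdname rf_fit
#' @export
predict.rf_model <- function(object, newdata = object$X, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees,
                  function(tr) .tree_predict(tr, newdata),
                  numeric(nrow(newdata)))
  rowMeans(preds)
}

#' Out-of-bag mean squared error
#'
#' Each observation is predicted by averaging only the trees whose bootstrap
#' sample excluded it. Supplying a modified `X` (e.g. one permuted column)
#' gives the permuted-OOB error used for permutation importance.
#'
#' @param forest an `rf_model`.
#' @param X predictor matrix aligned with the training rows.
#' @return mean squared OOB prediction error.
#' @export
rf_oob_mse <- function(forest, X = forest$X) {
  X <- as.matrix(X)
  n <- nrow(X)
  tot <- numeric(n); cnt <- integer(n)
  for (b in seq_along(forest$trees)) {
    oob <- setdiff(seq_len(n), forest$inbag[[b]])
    if (!length(oob)) next
    tot[oob] <- tot[oob] +
      .tree_predict(forest$trees[[b]], X[oob, , drop = FALSE])
    cnt[oob] <- cnt[oob] + 1L
  }
  has <- cnt > 0
  mean((forest$y[has] - tot[has] / cnt[has])^2)
}

#' Permutation (mean-decrease-in-accuracy) importance
#'
#' For each variable, one permutation of its column is drawn from the rng
#' stream (seeded by `seed` when given, so a manual re-permutation with the
#' same seed reproduces the score exactly) and the importance is the increase
#' in OOB mean squared error caused by the permutation.
#'
#' @param forest an `rf_model`.
#' @param seed optional seed for the permutation draws.
#' @return named numeric vector of MSE increases (one per variable).
#' @export
rf_importance <- function(forest, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- forest$X
  base <- rf_oob_mse(forest, X)
  p <- ncol(X)
  out <- numeric(p)
  for (v in seq_len(p)) {
    perm <- sample.int(nrow(X))
    Xp <- X
    Xp[, v] <- X[perm, v]
    out[v] <- rf_oob_mse(forest, Xp) - base
  }
  names(out) <- forest$varnames
  out
}
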