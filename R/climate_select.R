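#' Ensemble importance ranking of climate variables
#'
#' Runs the regression-tree ensemble `n_runs` times with distinct seeds
#' (`seed + run - 1`), recording both importance measures per run -- the mean
#' decrease in accuracy (permutation importance, OOB MSE increase) and the
#' mean decrease in node impurity -- and counting how often each variable
#' ranks in the top `top_k` by permutation importance (the recurrence count).
#'
#' @param climate climate table: a `site` column plus numeric variables.
#' @param response per-site mean performance, named by site or aligned with
#'   the climate rows.
#' @param n_runs number of ensemble runs.
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param top_k recurrence window (default 7, the number of variables kept
#'   in the motivating analysis).
#' @param ntree,min_node forest hyperparameters (500 trees, leaf size 2).
#' @return data.frame of class `importance_report`: per variable the mean
#'   MDA and impurity scores, sd of MDA across runs, and recurrence count;
#'   attribute `n_runs`.
#' @export
importance_ranking <- function(climate, response, n_runs = 20, seed = 1,
                               top_k = 7, ntree = 500, min_node = 2) {
  vars <- setdiff(names(climate), "site")
  stopifnot(length(vars) >= 2)
  if (nrow(climate) < 8) stop("need at least 8 sites for importance ranking")
  X <- as.matrix(climate[, vars])
  y <- if (!is.null(names(response))) response[climate$site] else response
  stopifnot(length(y) == nrow(X), !anyNA(y))
  top_k <- min(top_k, length(vars))
  mda <- imp <- matrix(0, n_runs, length(vars),
                       dimnames = list(NULL, vars))
  for (r in seq_len(n_runs)) {
    fr <- rf_fit(X, y, ntree = ntree, min_node = min_node,
                 seed = seed + r - 1)
    mda[r, ] <- rf_importance(fr, seed = seed + r - 1)
    imp[r, ] <- fr$impurity
  }
  # apply over runs gives a variables x runs matrix of top-k membership
  recurrence <- rowSums(apply(mda, 1, function(z)
    rank(-z, ties.method = "first") <= top_k))
  out <- data.frame(variable = vars,
                    mda = colMeans(mda),
                    mda_sd = apply(mda, 2, stats::sd),
                    impurity = colMeans(imp),
                    recurrence = recurrence,
                    row.names = NULL)
  out <- out[order(-out$recurrence, -out$mda), ]
  rownames(out) <- NULL
  attr(out, "n_runs") <- n_runs
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Group collinear climate variables
#'
#' Builds a graph with an edge between two variables when the absolute
#' Pearson correlation exceeds `threshold`, and returns its connected
#' components as collinearity blocks. Constant columns have undefined
#' correlations and are excluded with a warning.
#'
#' @param climate climate table (`site` column ignored).
#' @param variables which variables to consider (default all).
#' @param threshold correlation threshold (default 0.85).
#' @return list of class `collinearity_blocks`: `blocks` (list of character
#'   vectors, singletons included), `threshold`, `excluded`.
#' @export
collinearity_filter <- function(climate, variables = NULL, threshold = 0.85) {
  vars <- variables %||% setdiff(names(climate), "site")
  stopifnot(length(vars) >= 2)
  X <- as.matrix(climate[, vars])
  const <- apply(X, 2, function(z) stats::sd(z) == 0 || !is.finite(stats::sd(z)))
  if (any(const)) {
    warning("constant column(s) excluded (correlation undefined): ",
            paste(vars[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    vars <- vars[!const]
  }
  R <- abs(stats::cor(X))
  adj <- R > threshold
  diag(adj) <- FALSE
  # connected components by breadth-first search
  comp <- rep(NA_integer_, length(vars))
  k <- 0L
  for (i in seq_along(vars)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  blocks <- split(vars, comp)
  names(blocks) <- NULL
  structure(list(blocks = blocks, threshold = threshold,
                 excluded = if (any(const)) vars[const] else character(0)),
            class = "collinearity_blocks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nominate the climatic gradient variable
#'
#' Combines the importance report with the collinearity blocks: the block
#' containing the most recurring variable is selected and its representative
#' is the member with the highest recurrence count, ties broken by mean
#' decrease in accuracy. Also reports the OOB R-squared of an ensemble using
#' the representative alone (the single-gradient share of response
#' variability).
#'
#' @param report an [importance_ranking()] result.
#' @param blocks a [collinearity_filter()] result.
#' @param climate,response as in [importance_ranking()] (used for the
#'   single-variable ensemble R-squared; skipped when omitted).
#' @param seed seed for the single-variable ensemble.
#' @return list: `variable` (the representative), `block` (its members),
#'   `single_var_r2` (or NA).
#' @export
select_gradient_variable <- function(report, blocks, climate = NULL,
                                     response = NULL, seed = 1) {
  stopifnot(inherits(report, "importance_report"),
            inherits(blocks, "collinearity_blocks"))
  top <- report$variable[1]
  blk <- blocks$blocks[[which(vapply(blocks$blocks, function(b) top %in% b,
                                     TRUE))]]
  members <- report[report$variable %in% blk, ]
  members <- members[order(-members$recurrence, -members$mda), ]
  rep_var <- members$variable[1]
  r2 <- NA_real_
  if (!is.null(climate) && !is.null(response)) {
    y <- if (!is.null(names(response))) response[climate$site] else response
    fr <- rf_fit(as.matrix(climate[, rep_var, drop = FALSE]), y, seed = seed)
    r2 <- 1 - rf_oob_mse(fr) / stats::var(y) * (length(y) - 1) / length(y)
  }
  list(variable = rep_var, block = blk, single_var_r2 = r2)
}
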