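#' Quadratic response function
#'
#' Ordinary least squares of performance `v` on the climate value `c` and its
#' square: `v = b0 + b1 c + b2 c^2`. The regression is computed on centred
#' and scaled `c` for numerical stability and the coefficients are mapped
#' back to the original climate units, so the reported vertex
#' `c* = -b1 / (2 b2)`, `v* = b0 + b1 c* + b2 c*^2` is expressed in degC and
#' cm/year.
#'
#' @param c climate values (>= 3 distinct).
#' @param v performance values (same length).
#' @param level label stored on the curve (e.g. `"population"` or a family id).
#' @return object of class `response_curve`: `model`, `coef`, `vertex`
#'   (`c_star`, `v_star`; NA when the curvature is not concave), `r2`,
#'   `adj_r2`, `p_value` (overall F test), `n`, `k` (mean parameters),
#'   `rss`, `aic`, `level`.
#' @export
fit_quadratic <- function(c, v, level = "population") {
  ok <- stats::complete.cases(c, v)
  c <- c[ok]; v <- v[ok]
  if (length(unique(c)) < 3)
    stop("singular design: need >= 3 distinct climate values for a quadratic")
  mu <- mean(c); sdc <- stats::sd(c)
  if (sdc == 0) sdc <- 1
  z <- (c - mu) / sdc
  fit <- stats::lm(v ~ z + I(z^2))
  g <- stats::coef(fit)
  # back-transform: v = g0 + g1 (c-mu)/sd + g2 (c-mu)^2/sd^2
  b2 <- g[3] / sdc^2
  b1 <- g[2] / sdc - 2 * g[3] * mu / sdc^2
  b0 <- g[1] - g[2] * mu / sdc + g[3] * mu^2 / sdc^2
  beta <- stats::setNames(c(b0, b1, b2), c("b0", "b1", "b2"))
  .response_curve("quadratic", beta, c, v, stats::fitted(fit), k = 3,
                  level = level)
}

#' Linear response function
#'
#' @inheritParams fit_quadratic
#' @return a `response_curve` (no vertex).
#' @export
fit_linear <- function(c, v, level = "population") {
  ok <- stats::complete.cases(c, v)
  c <- c[ok]; v <- v[ok]
  if (length(unique(c)) < 2) stop("singular design: need >= 2 distinct climate values")
  fit <- stats::lm(v ~ c)
  beta <- stats::setNames(stats::coef(fit), c("b0", "b1"))
  .response_curve("linear", beta, c, v, stats::fitted(fit), k = 2,
                  level = level)
}

#' Gaussian response function
#'
#' Nonlinear least squares for `v = A exp(-(c - m)^2 / (2 s^2))`.
#' Initialization: a quadratic pre-fit supplies the mode (`m0` = vertex
#' abscissa clipped to the observed range, `A0` = vertex ordinate,
#' `s0 = sqrt(A0 / (-2 b2))` from the curvature at the peak); if the
#' quadratic is not concave, `m0` is the `c` of the maximum `v`, `A0` the
#' maximum `v` and `s0` the sd of `c`. Non-convergence is flagged by an
#' `AIC` of `+Inf` and `converged = FALSE` rather than an error.
#'
#' @inheritParams fit_quadratic
#' @return a `response_curve` with `coef` `(A, m, s)`; the vertex is `(m, A)`.
#' @export
fit_gaussian <- function(c, v, level = "population") {
  ok <- stats::complete.cases(c, v)
  c <- c[ok]; v <- v[ok]
  if (length(unique(c)) < 4)
    stop("need >= 4 distinct climate values for a Gaussian fit")
  if (max(v) <= 0) stop("Gaussian response needs a positive amplitude")
  q <- tryCatch(fit_quadratic(c, v), error = function(e) NULL)
  if (!is.null(q) && is.finite(q$vertex["c_star"]) && q$coef["b2"] < 0) {
    m0 <- min(max(q$vertex["c_star"], min(c)), max(c))
    A0 <- max(q$vertex["v_star"], max(v) / 2)
    s0 <- sqrt(A0 / (-2 * q$coef["b2"]))
  } else {
    m0 <- c[which.max(v)]; A0 <- max(v); s0 <- stats::sd(c)
  }
  dat <- data.frame(c = c, v = v)
  fit <- tryCatch(
    stats::nls(v ~ A * exp(-(c - m)^2 / (2 * s^2)), data = dat,
               start = list(A = A0, m = m0, s = s0),
               algorithm = "port",
               lower = c(A = 1e-8, m = -Inf, s = 1e-8),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- .response_curve("gaussian",
                           stats::setNames(c(A0, m0, s0), c("A", "m", "s")),
                           c, v, rep(mean(v), length(v)), k = 3, level = level)
    out$aic <- Inf
    out$converged <- FALSE
    return(out)
  }
  beta <- stats::setNames(stats::coef(fit), c("A", "m", "s"))
  out <- .response_curve("gaussian", beta, c, v, stats::fitted(fit), k = 3,
                         level = level)
  out$vertex <- c(c_star = unname(beta["m"]), v_star = unname(beta["A"]))
  out
}

.response_curve <- function(model, beta, c, v, fitted, k, level) {
  n <- length(v)
  rss <- sum((v - fitted)^2)
  tss <- sum((v - mean(v))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj <- if (n > k) 1 - (1 - r2) * (n - 1) / (n - k) else NA_real_
  # overall F test of the mean structure against the intercept-only model
  df1 <- k - 1; df2 <- n - k
  p <- if (df2 > 0 && rss > 0 && df1 > 0) {
    Fst <- ((tss - rss) / df1) / (rss / df2)
    stats::pf(Fst, df1, df2, lower.tail = FALSE)
  } else NA_real_
  vertex <- c(c_star = NA_real_, v_star = NA_real_)
  if (model == "quadratic" && beta["b2"] < 0) {
    cs <- -beta["b1"] / (2 * beta["b2"])
    vertex <- c(c_star = unname(cs),
                v_star = unname(beta["b0"] + beta["b1"] * cs + beta["b2"] * cs^2))
  }
  structure(list(model = model, coef = beta, vertex = vertex,
                 r2 = r2, adj_r2 = adj, p_value = p,
                 n = n, k = k, rss = rss,
                 aic = n * log(rss / n) + 2 * (k + 1),  # + n(1+log 2 pi), omitted
                 converged = TRUE, level = level,
                 data_sig = c(n, sum(c), sum(v))),
            class = "response_curve")
}

#' Predict from a response curve
#' @param object a `response_curve`.
#' @param newdata climate values.
#' @param ... unused.
#' @export
predict.response_curve <- function(object, newdata, ...) {
  b <- object$coef
  switch(object$model,
         linear = b["b0"] + b["b1"] * newdata,
         quadratic = b["b0"] + b["b1"] * newdata + b["b2"] * newdata^2,
         gaussian = b["A"] * exp(-(newdata - b["m"])^2 / (2 * b["s"]^2)))
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("%s response curve [%s], n = %d\n", x$model, x$level, x$n))
  print(signif(x$coef, 5))
  if (is.finite(x$vertex["c_star"]))
    cat(sprintf("vertex: c* = %.3f, v* = %.2f\n",
                x$vertex["c_star"], x$vertex["v_star"]))
  cat(sprintf("adj R2 = %.3f, p = %.3g, AIC = %.2f\n",
              x$adj_r2, x$p_value, x$aic))
  invisible(x)
}

#' Compare response-curve families by AIC
#'
#' `AIC = n log(RSS / n) + 2 (k + 1)` (the Gaussian-likelihood constant,
#' identical across models on the same data, is omitted). Curves must have
#' been fit on identical data. Ties within `tol` are broken toward the
#' simpler family in the order linear < quadratic < gaussian.
#'
#' @param curves list of `response_curve`s fit on the same data.
#' @param tol AIC difference treated as a tie (default 1e-8).
#' @return data.frame `model,k,aic,delta_aic,selected`, ordered by AIC with
#'   the documented tie-break.
#' @export
compare_models <- function(curves, tol = 1e-8) {
  stopifnot(length(curves) >= 2,
            all(vapply(curves, inherits, TRUE, "response_curve")))
  sig <- vapply(curves, function(x) x$data_sig, numeric(3))
  if (max(abs(sig - sig[, 1])) > 1e-8 * (1 + max(abs(sig[, 1]))))
    stop("curves were not fit on identical data")
  fam_order <- c(linear = 1, quadratic = 2, gaussian = 3)
  df <- data.frame(model = vapply(curves, function(x) x$model, ""),
                   k = vapply(curves, function(x) x$k, 0),
                   aic = vapply(curves, function(x) x$aic, 0))
  df <- df[order(df$aic, fam_order[df$model]), ]
  # tie-break: within tol of the minimum, prefer the simpler family
  near <- df$aic <= min(df$aic) + tol
  pick <- which(near)[which.min(fam_order[df$model[near]])]
  df$delta_aic <- df$aic - df$aic[pick]
  df$selected <- seq_len(nrow(df)) == pick
  rownames(df) <- NULL
  df
}

#' Population- and family-level response functions
#'
#' Fits one quadratic response curve pooling all individual PMAIs against
#' the site climate value, and one per half-sib family. Families with fewer
#' than `min_obs` observations are skipped with a warning. "Individual-level"
#' curves are realized at the half-sib family level: a per-tree curve is not
#' identifiable from a single observation per tree, whereas the maternal
#' family ties siblings together across sites.
#'
#' @param perf a (trimmed) [performance_table()].
#' @param climate climate table with a `site` column.
#' @param variable climate column to use as the gradient (default `"mtcm"`).
#' @param min_obs minimum observations per family curve.
#' @param site_means fit on per-site family means instead of individual PMAIs.
#' @return list of class `response_set`: `population` (a `response_curve`),
#'   `families` (named list of curves), `table` (one row per curve: level,
#'   N_b, coefficients, vertex, adj R2, p-value, AIC), `variable`.
#' @export
fit_all_levels <- function(perf, climate, variable = "mtcm", min_obs = 4,
                           site_means = FALSE) {
  stopifnot(variable %in% names(climate), "site" %in% names(climate))
  cvals <- stats::setNames(climate[[variable]], climate$site)
  missing_sites <- setdiff(unique(perf$site), climate$site)
  if (length(missing_sites))
    stop("sites absent from climate table: ",
         paste(missing_sites, collapse = ", "))
  cc <- cvals[perf$site]
  pop <- fit_quadratic(cc, perf$pmai, level = "population")
  fams <- split(seq_len(nrow(perf)), perf$family)
  curves <- list()
  skipped <- character(0)
  for (f in names(fams)) {
    i <- fams[[f]]
    ci <- cc[i]; vi <- perf$pmai[i]
    if (site_means) {
      vi <- tapply(vi, perf$site[i], mean)
      ci <- cvals[names(vi)]
    }
    if (length(vi) < min_obs || length(unique(ci)) < 3) {
      skipped <- c(skipped, f)
      next
    }
    curves[[f]] <- fit_quadratic(ci, vi, level = f)
  }
  if (length(skipped))
    warning("skipped family(ies) with too few observations: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(c(list(pop), curves), function(x)
    data.frame(level = x$level, N_b = x$n,
               b0 = unname(x$coef["b0"]), b1 = unname(x$coef["b1"]),
               b2 = unname(x$coef["b2"]),
               c_star = unname(x$vertex["c_star"]),
               v_star = unname(x$vertex["v_star"]),
               adj_r2 = x$adj_r2, p_value = x$p_value, aic = x$aic))
  structure(list(population = pop, families = curves,
                 table = do.call(rbind, rows), variable = variable),
            class = "response_set")
}

#' @rdname fit_all_levels
#' @param rs a `response_set`.
#' @param path output CSV path.
#' @export
write_curves <- function(rs, path) {
  utils::write.csv(rs$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
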