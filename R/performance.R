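#' Mean annual increment from height and stand age
#'
#' @param height tree height (cm), >= 0.
#' @param age stand age (years), > 0.
#' @return height / age (cm/year), vectorized.
#' @export
mai_from_height <- function(height, age) {
  if (any(age <= 0)) stop("stand age must be positive")
  if (any(height < 0, na.rm = TRUE)) stop("height must be non-negative")
  height / age
}

#' Predicted phenotypic performance for MAI
#'
#' `PMAI = overall mean + site effect + breeding value`, all in cm/year.
#'
#' @param overall_mean scalar or vector, cm/year.
#' @param site_effect site fixed-effect deviation, cm/year.
#' @param bv individual breeding value, cm/year.
#' @return the arithmetic sum.
#' @export
pmai <- function(overall_mean, site_effect, bv) {
  stopifnot(all(is.finite(overall_mean)), all(is.finite(site_effect)),
            all(is.finite(bv)))
  overall_mean + site_effect + bv
}

#' Per-individual performance table
#'
#' Combines the genetic evaluation with the phenotype table: for each
#' measured offspring its MAI, MAI breeding value, site effect, and PMAI.
#' The overall mean is the unweighted mean of the MAI site cell means and the
#' site effect is the cell mean minus that overall mean, so
#' `PMAI = cell mean + BV`. The half-sib family key is the maternal (seed)
#' parent -- the natural family unit of a seed-orchard progeny, and the one
#' always identified in the reconstructed pedigree.
#'
#' @param fit an [solve_mme()] result (first trait must be MAI).
#' @param phenotypes phenotype table with `id`, `site`, `height`, `age` (or a
#'   precomputed `mai` column).
#' @param ped the pedigree, used for the maternal family key.
#' @param mean_weights `"site"` (default, unweighted over site cell means) or
#'   `"record"` (cell means weighted by record counts).
#' @return data.frame of class `performance_table` with columns
#'   `individual,family,site,mai,bv,site_effect,pmai` and attribute
#'   `overall_mean`.
#' @export
performance_table <- function(fit, phenotypes, ped,
                              mean_weights = c("site", "record")) {
  stopifnot(inherits(fit, "am_fit"), inherits(ped, "pedigree"))
  mean_weights <- match.arg(mean_weights)
  s <- length(fit$sites)
  cell <- fit$b[seq_len(s)]              # MAI trait block
  names(cell) <- fit$sites
  wts <- if (mean_weights == "site") rep(1, s)
         else as.numeric(table(factor(phenotypes$site, levels = fit$sites)))
  overall <- sum(cell * wts) / sum(wts)
  site_eff <- cell - overall

  mai <- if ("mai" %in% names(phenotypes)) phenotypes$mai
         else mai_from_height(phenotypes$height, phenotypes$age)
  ids <- as.character(phenotypes$id)
  bv <- fit$a[ids, 1]
  fam <- ped$dam[match(ids, ped$id)]
  out <- data.frame(individual = ids,
                    family = fam,
                    site = as.character(phenotypes$site),
                    mai = mai,
                    bv = unname(bv),
                    site_effect = unname(site_eff[phenotypes$site]),
                    pmai = unname(pmai(overall, site_eff[phenotypes$site], bv)),
                    stringsAsFactors = FALSE)
  attr(out, "overall_mean") <- overall
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Trim families by site representation
#'
#' Retains only half-sib families whose offspring occur in at least
#' `min_sites` distinct sites, evening out family representation across the
#' climatic gradient. The operation is idempotent.
#'
#' @param perf a [performance_table()] (needs `family` and `site` columns).
#' @param min_sites minimum number of distinct sites (default 6).
#' @return the filtered table, same class and attributes.
#' @export
trim_families <- function(perf, min_sites = 6) {
  stopifnot(all(c("family", "site") %in% names(perf)))
  n_sites <- tapply(perf$site, perf$family, function(s) length(unique(s)))
  keep_fam <- names(n_sites)[n_sites >= min_sites]
  out <- perf[!is.na(perf$family) & perf$family %in% keep_fam, , drop = FALSE]
  if (nrow(out) == 0)
    stop("trimming at min_sites = ", min_sites, " removed all families")
  attr(out, "overall_mean") <- attr(perf, "overall_mean")
  class(out) <- class(perf)
  out
}

#' @rdname performance_table
#' @param perf a performance table.
#' @param path output CSV path.
#' @export
write_performance <- function(perf, path) {
  utils::write.csv(perf, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
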