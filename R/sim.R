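#' Simulation configuration for a clonal seed-orchard progeny trial
#'
#' The generator emulates a clonal seed orchard of grafted parents whose
#' open-pollinated offspring are planted across sites spanning a winter
#' temperature (MTCM) gradient. Defaults describe the stated world: 53
#' parents, 21 sites, ~8.4% pollen contamination, stand ages 25-37 years,
#' two genetically correlated traits (mean annual increment of height, and
#' wood density on a dimensionless scale) with narrow-sense heritabilities
#' 0.27 and 0.30 and additive genetic correlation 0.09, and a true
#' population-level quadratic response of MAI to MTCM peaking at
#' (-2.2 degC, 65 cm/year).
#'
#' @param n_parents number of orchard founder clones.
#' @param n_sites number of planting sites.
#' @param offspring_per_site offspring phenotyped per site (62 gives ~1300
#'   offspring over 21 sites, matching the genotyped subset of the trial the
#'   defaults emulate).
#' @param contamination_rate probability an offspring is sired by external
#'   (outside-orchard) pollen.
#' @param G0 2x2 additive genetic covariance matrix (MAI, density).
#' @param R0 2x2 residual covariance matrix.
#' @param beta true population response coefficients (b0, b1, b2) of MAI on
#'   MTCM; the default (40.8, -22, -5) has vertex -b1/(2 b2) = -2.2 degC and
#'   peak 65 cm/year.
#' @param mtcm_range range (degC) over which site MTCM values are spread.
#' @param ages stand ages (years) assigned to sites, recycled as needed.
#' @param density_mean,density_site_slope mean of the density trait and the
#'   slope of its (linear) true site effect on centred MTCM.
#' @param climate_noise_sd sd of the noise added to the winter-temperature
#'   variables derived from MTCM (0.35 keeps all pairwise correlations in the
#'   collinear block above 0.85).
#' @param n_decoys number of pure-noise precipitation-like decoy variables.
#' @param family_optimum_range optional length-2 range of true MAI-optimum
#'   MTCM values (degC). When set, each maternal family receives its own
#'   quadratic site response whose optimum is evenly spaced over the range
#'   (a genotype-by-environment variant emulating family-level curve
#'   spread); the default `NULL` keeps a single population curve (no GxE),
#'   matching the non-significant interaction of the emulated trial.
#' @param seed integer seed governing the single rng stream; draws occur in
#'   the documented order pedigree -> climate -> breeding values -> residuals.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 53,
                       n_sites = 21,
                       offspring_per_site = 62,
                       contamination_rate = 0.084,
                       G0 = matrix(c(6.3, 0.1237219, 0.1237219, 0.30), 2, 2),
                       R0 = matrix(c(17.0, 0.3449638, 0.3449638, 0.70), 2, 2),
                       beta = c(40.8, -22, -5),
                       mtcm_range = c(-4, 0),
                       ages = 25:37,
                       density_mean = 10,
                       density_site_slope = 0.3,
                       climate_noise_sd = 0.35,
                       n_decoys = 5,
                       family_optimum_range = NULL,
                       seed = 1L) {
  cfg <- list(n_parents = n_parents, n_sites = n_sites,
              offspring_per_site = offspring_per_site,
              contamination_rate = contamination_rate,
              G0 = G0, R0 = R0, beta = beta, mtcm_range = mtcm_range,
              ages = ages, density_mean = density_mean,
              density_site_slope = density_site_slope,
              climate_noise_sd = climate_noise_sd, n_decoys = n_decoys,
              family_optimum_range = family_optimum_range,
              seed = as.integer(seed))
  .check_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.check_sim_config <- function(cfg) {
  for (nm in c("G0", "R0")) {
    M <- cfg[[nm]]
    if (!isTRUE(all.equal(M, t(M))) ||
        min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(nm, " must be symmetric positive semi-definite")
  }
  if (cfg$contamination_rate < 0 || cfg$contamination_rate > 1)
    stop("contamination_rate must lie in [0, 1]")
  if (cfg$n_sites < 3)
    stop("need at least 3 sites for an identifiable quadratic response")
  invisible(TRUE)
}

.parent_ids <- function(n) sprintf("P%02d", seq_len(n))
.site_ids   <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate the reconstructed orchard pedigree
#'
#' Each offspring draws its dam uniformly from the orchard parents. With
#' probability `contamination_rate` its sire is external pollen: the emitted
#' (reconstructed) pedigree then records the sire as unknown and flags the
#' offspring as externally sired. Otherwise the sire is drawn uniformly from
#' the remaining parents (no selfing).
#'
#' Uses the current rng stream; call `set.seed()` first (or use
#' [simulate_dataset()], which seeds once for all stages).
#'
#' @param cfg a [sim_config()].
#' @param n_offspring total offspring; default `n_sites * offspring_per_site`.
#' @return a validated [validate_pedigree()] object in which offspring rows
#'   carry `external = TRUE` when sired from outside the orchard.
#' @export
simulate_pedigree <- function(cfg, n_offspring = cfg$n_sites * cfg$offspring_per_site) {
  par_ids <- .parent_ids(cfg$n_parents)
  dam <- par_ids[sample.int(cfg$n_parents, n_offspring, replace = TRUE)]
  ext <- stats::runif(n_offspring) < cfg$contamination_rate
  # uniform over the n-1 non-dam parents, by drawing an offset
  off <- sample.int(cfg$n_parents - 1L, n_offspring, replace = TRUE)
  sire_idx <- (match(dam, par_ids) + off - 1L) %% cfg$n_parents + 1L
  sire <- par_ids[sire_idx]
  sire[ext] <- NA_character_
  off_ids <- sprintf("O%05d", seq_len(n_offspring))
  validate_pedigree(
    id   = c(par_ids, off_ids),
    sire = c(rep(NA_character_, cfg$n_parents), sire),
    dam  = c(rep(NA_character_, cfg$n_parents), dam),
    external = c(rep(FALSE, cfg$n_parents), ext))
}

#' Simulate the per-site climate table
#'
#' Sites receive MTCM (mean temperature of the coldest month) values evenly
#' spread over `mtcm_range`. Six winter-temperature variables (altitude,
#' January/December minima, December mean, January/December maxima) are
#' affine transforms of MTCM plus Gaussian noise of sd `climate_noise_sd`
#' (scaled by each slope), forming a collinear block with pairwise
#' correlations above 0.85 at the default noise level. `n_decoys`
#' precipitation-like variables are pure noise.
#'
#' @param cfg a [sim_config()].
#' @return a data.frame with `site`, `mtcm`, the collinear block and decoys.
#' @export
simulate_climate <- function(cfg) {
  stopifnot(cfg$n_sites >= 3)
  ns <- cfg$n_sites
  mtcm <- seq(cfg$mtcm_range[1], cfg$mtcm_range[2], length.out = ns)
  sd0 <- cfg$climate_noise_sd
  deriv <- list(  # name = c(intercept, slope)
    altitude  = c(500, -120),
    tmin_jan  = c(-3.5, 1.1),
    tmin_dec  = c(-2.8, 1.0),
    tmean_dec = c(0.6, 0.9),
    tmax_jan  = c(3.2, 1.05),
    tmax_dec  = c(4.0, 0.95))
  out <- data.frame(site = .site_ids(ns), mtcm = mtcm)
  for (nm in names(deriv)) {
    ab <- deriv[[nm]]
    out[[nm]] <- ab[1] + ab[2] * mtcm + stats::rnorm(ns, 0, sd0 * abs(ab[2]))
  }
  if (cfg$n_decoys > 0) {
    for (k in seq_len(cfg$n_decoys)) {
      out[[sprintf("prec_%02d", k)]] <- stats::rnorm(ns, 800, 100)
    }
  }
  out
}

# one bivariate normal draw per row of n, via the Cholesky factor of Sigma
.rmvnorm2 <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sigma))
  Z <- matrix(stats::rnorm(n * nrow(Sigma)), n)
  Z %*% t(L)
}

#' Simulate phenotypes over a pedigree and climate table
#'
#' Founder breeding values are bivariate normal with covariance `G0`.
#' Offspring breeding values follow the additive inheritance rule
#' `0.5 (bv_sire + bv_dam)` plus a Mendelian deviation with covariance
#' `0.5 G0` (an unknown parent contributes 0 and inflates the Mendelian
#' covariance to `0.75 G0`). The true site effect on the MAI scale is the
#' configured quadratic in MTCM; density receives a linear site effect.
#' Phenotypes add an iid bivariate residual with covariance `R0`; height is
#' recorded as MAI x stand age.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param climate climate table from [simulate_climate()].
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_dataset`: `pedigree`, `phenotypes`
#'   (`id,site,age,height,density`), `climate`, `true_bv` (matrix, all
#'   pedigree individuals x 2 traits), `true_site_effects`, `config`.
#' @export
simulate_phenotypes <- function(ped, climate, cfg) {
  .check_sim_config(cfg)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  bv <- matrix(0, n, 2, dimnames = list(ped$id, c("mai", "density")))
  is_founder <- ped$founder
  bv[is_founder, ] <- .rmvnorm2(sum(is_founder), cfg$G0)
  non_f <- which(!is_founder)
  if (length(non_f)) {
    both <- !is.na(ped$sire[non_f]) & !is.na(ped$dam[non_f])
    ms <- matrix(0, length(non_f), 2)
    ms[both, ]  <- .rmvnorm2(sum(both), 0.5 * cfg$G0)
    ms[!both, ] <- .rmvnorm2(sum(!both), 0.75 * cfg$G0)
    for (k in seq_along(non_f)) {
      i <- non_f[k]
      pa <- c(ped$sire[i], ped$dam[i])
      pa <- pa[!is.na(pa)]
      mid <- if (length(pa)) colSums(bv[idx[pa], , drop = FALSE]) / 2 else c(0, 0)
      bv[i, ] <- mid + ms[k, ]
    }
  }

  off_ids <- ped$id[!is_founder]
  n_off <- length(off_ids)
  site_of <- rep(climate$site, length.out = n_off)
  ages <- rep(cfg$ages, length.out = cfg$n_sites)
  names(ages) <- climate$site
  c_j <- climate$mtcm
  mai_eff <- cfg$beta[1] + cfg$beta[2] * c_j + cfg$beta[3] * c_j^2
  dens_eff <- cfg$density_site_slope * (c_j - mean(c_j))
  names(mai_eff) <- names(dens_eff) <- climate$site

  # optional GxE: maternal families get their own optimum via a beta1 shift
  true_family_optima <- NULL
  gxe <- 0
  if (!is.null(cfg$family_optimum_range)) {
    par_ids <- ped$id[ped$founder & !ped$external]
    opt <- seq(cfg$family_optimum_range[1], cfg$family_optimum_range[2],
               length.out = length(par_ids))
    pop_opt <- -cfg$beta[2] / (2 * cfg$beta[3])
    d1 <- -2 * cfg$beta[3] * (opt - pop_opt)      # per-family beta1 shift
    names(d1) <- names(opt) <- par_ids
    dam_of <- ped$dam[match(off_ids, ped$id)]
    cs <- c_j[match(site_of, climate$site)]
    # centred so the family effect vanishes at the population optimum
    gxe <- d1[dam_of] * (cs - pop_opt)
    true_family_optima <- data.frame(family = par_ids, optimum = unname(opt))
  }

  e <- .rmvnorm2(n_off, cfg$R0)
  mai <- mai_eff[site_of] + gxe + bv[off_ids, "mai"] + e[, 1]
  dens <- cfg$density_mean + dens_eff[site_of] + bv[off_ids, "density"] + e[, 2]
  phen <- data.frame(id = off_ids,
                     site = site_of,
                     age = ages[site_of],
                     height = mai * ages[site_of],
                     density = dens,
                     row.names = NULL)
  structure(list(
    pedigree = ped,
    phenotypes = phen,
    climate = climate,
    true_bv = bv,
    true_site_effects = data.frame(site = climate$site, mai_effect = mai_eff,
                                   density_effect = dens_eff,
                                   row.names = NULL),
    true_family_optima = true_family_optima,
    config = cfg
  ), class = "synthetic_dataset")
}

#' One-call synthetic dataset
#'
#' Seeds the rng once from `cfg$seed` (or the `seed` argument) and runs
#' pedigree -> climate -> phenotypes in that order, so output is reproducible
#' byte-for-byte given the configuration.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return a `synthetic_dataset`, see [simulate_phenotypes()].
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  climate <- simulate_climate(cfg)
  simulate_phenotypes(ped, climate, cfg)
}

#' Write a synthetic dataset to disk
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, `climate.csv` and a
#' `truth.json` sidecar with the generating parameters, true breeding values
#' and true site effects, for parameter-recovery tests.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(ds$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(ds$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(config = ds$config[setdiff(names(ds$config), c("G0", "R0"))],
                G0 = ds$config$G0, R0 = ds$config$R0,
                true_site_effects = ds$true_site_effects,
                true_bv = data.frame(id = rownames(ds$true_bv), ds$true_bv))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
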