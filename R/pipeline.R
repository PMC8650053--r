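#' Pipeline run configuration
#'
#' Exactly one input mode must be supplied: either the three CSV paths
#' (pedigree, phenotypes, climate) for real data, or a [sim_config()] for
#' synthetic mode. All analysis thresholds live here with their
#' field-standard defaults: family trimming at 6 sites, collinearity at
#' |r| > 0.85, significance at alpha = 0.05, 20 ensemble runs.
#'
#' @param pedigree,phenotypes,climate CSV paths (real-data mode).
#' @param sim a [sim_config()] (synthetic mode).
#' @param seed run seed (overrides `sim$seed` in synthetic mode).
#' @param min_sites family-trimming threshold.
#' @param collinearity_threshold absolute-correlation threshold.
#' @param rf_runs importance-ranking ensemble runs.
#' @param alpha significance level for site contrasts.
#' @param gradient climate variable to force as the gradient (default: let
#'   [select_gradient_variable()] nominate one).
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(pedigree = NULL, phenotypes = NULL, climate = NULL,
                       sim = NULL, seed = 1L, min_sites = 6,
                       collinearity_threshold = 0.85, rf_runs = 20,
                       alpha = 0.05, gradient = NULL, out_dir = "orchardRF_run") {
  real <- !is.null(pedigree) || !is.null(phenotypes) || !is.null(climate)
  if (real && !is.null(sim))
    stop("supply either the three data paths or a sim config, not both")
  if (!real && is.null(sim))
    stop("supply either the three data paths or a sim config")
  if (real && (is.null(pedigree) || is.null(phenotypes) || is.null(climate)))
    stop("real-data mode needs all of pedigree, phenotypes and climate paths")
  structure(list(pedigree = pedigree, phenotypes = phenotypes,
                 climate = climate, sim = sim, seed = as.integer(seed),
                 min_sites = min_sites,
                 collinearity_threshold = collinearity_threshold,
                 rf_runs = rf_runs, alpha = alpha, gradient = gradient,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring the [run_config()] arguments; the `sim:` mapping, if
#' present, is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    for (nm in c("G0", "R0"))
      if (!is.null(sim_args[[nm]]))
        sim_args[[nm]] <- matrix(unlist(sim_args[[nm]]), 2, 2)
    if (isTRUE(sim_args)) sim_args <- list()
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(args, list(sim = sim)))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load) -> fit (bivariate animal model) ->
#' performance (PMAI + family trimming) -> select-climate (importance,
#' collinearity, gradient nomination) -> respfun (population and family
#' response curves). Writes `fit.json`, `perf.csv`, `importance.csv`,
#' `curves.csv`, `run.log` and `manifest.json` into `out_dir`. A stage error
#' aborts the run with the stage name and persists the partial manifest.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  cat("", file = logfile)
  logln <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...,
                                    "\n"), file = logfile, append = TRUE)
  manifest <- list(seed = cfg$seed, stages = list(), outputs = character(0))
  persist <- function() {
    cfg_plain <- unclass(cfg)
    cfg_plain$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
    manifest$config <- cfg_plain
    # hash the analytical configuration only: where outputs land is not
    # part of what was computed
    cfg_json <- jsonlite::toJSON(cfg_plain[setdiff(names(cfg_plain), "out_dir")],
                                 auto_unbox = TRUE, digits = NA, null = "null")
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest$config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }
  stage <- function(name, expr) {
    logln("stage ", name, " start")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logln("stage ", name, " FAILED: ", conditionMessage(e))
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      persist()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    # wall-clock goes to the log only, keeping the manifest byte-reproducible
    manifest$stages[[name]] <<- list(status = "ok")
    logln("stage ", name, " done in ", round(dt, 2), "s")
    res
  }
  emit <- function(fname) manifest$outputs <<- c(manifest$outputs, fname)

  dat <- stage("simulate", {
    if (!is.null(cfg$sim)) {
      ds <- simulate_dataset(cfg$sim, seed = cfg$seed)
      write_dataset(ds, cfg$out_dir)
      emit(c("pedigree.csv", "phenotypes.csv", "climate.csv", "truth.json"))
      list(ped = ds$pedigree, phen = ds$phenotypes,
           climate_loader = function() ds$climate)
    } else {
      for (p in c(cfg$pedigree, cfg$phenotypes))
        if (!file.exists(p)) stop("input file not found: ", p)
      # the climate table is first needed by select-climate; load it there
      list(ped = read_pedigree(cfg$pedigree),
           phen = utils::read.csv(cfg$phenotypes),
           climate_loader = function() {
             if (!file.exists(cfg$climate))
               stop("input file not found: ", cfg$climate)
             utils::read.csv(cfg$climate)
           })
    }
  })

  ev <- stage("fit", {
    phen <- dat$phen
    phen$mai <- mai_from_height(phen$height, phen$age)
    res <- fit_animal_model(phen, dat$ped)
    h2m <- heritability(res$vc, 1); h2d <- heritability(res$vc, 2)
    ra <- genetic_correlation(res$vc)
    contr <- site_contrasts(res$fit, trait = 1, alpha = cfg$alpha)
    fitj <- list(
      G0 = res$vc$G0, R0 = res$vc$R0, loglik = res$vc$loglik,
      converged = res$vc$converged,
      h2 = list(mai = h2m, density = h2d), ra = ra,
      b = as.list(res$fit$b),
      breeding_values = data.frame(id = rownames(res$fit$a), res$fit$a,
                                   se_mai = res$fit$a_se[, 1],
                                   se_density = res$fit$a_se[, 2]),
      site_contrast_fraction_significant = attr(contr, "fraction_significant"),
      trace = res$vc$trace)
    jsonlite::write_json(fitj, file.path(cfg$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("fit.json")
    c(res, list(phen = phen))
  })

  perf <- stage("performance", {
    pt <- performance_table(ev$fit, ev$phen, dat$ped)
    pt <- trim_families(pt, min_sites = cfg$min_sites)
    write_performance(pt, file.path(cfg$out_dir, "perf.csv"))
    emit("perf.csv")
    pt
  })

  sel <- stage("select-climate", {
    climate_full <- dat$climate_loader()
    site_pmai <- tapply(perf$pmai, perf$site, mean)
    climate <- climate_full[climate_full$site %in% names(site_pmai), ]
    rep_ <- importance_ranking(climate, site_pmai, n_runs = cfg$rf_runs,
                               seed = cfg$seed)
    blocks <- collinearity_filter(climate,
                                  threshold = cfg$collinearity_threshold)
    gv <- select_gradient_variable(rep_, blocks, climate, site_pmai,
                                   seed = cfg$seed)
    utils::write.csv(rep_, file.path(cfg$out_dir, "importance.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("importance.csv")
    list(report = rep_, blocks = blocks, gradient = gv,
         climate = climate_full)
  })

  stage("respfun", {
    variable <- cfg$gradient %||% sel$gradient$variable
    rs <- fit_all_levels(perf, sel$climate, variable = variable,
                         min_obs = 4)
    write_curves(rs, file.path(cfg$out_dir, "curves.csv"))
    emit("curves.csv")
    rs
  })

  manifest$gradient_variable <- cfg$gradient %||% sel$gradient$variable
  out <- persist()
  logln("pipeline complete")
  invisible(out)
}
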