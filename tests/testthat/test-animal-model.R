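test_that("build_design lays out trait-by-site cells and handles missingness", {
  ped <- validate_pedigree(sprintf("i%d", 1:6), rep(NA, 6), rep(NA, 6))
  phen <- data.frame(id = sprintf("i%d", 1:6),
                     site = rep(c("a", "b"), 3),
                     mai = rnorm(6), density = c(rnorm(5), NA))
  amd <- build_design(phen, ped)
  expect_equal(ncol(amd$X), 4)
  expect_equal(qr(amd$X)$rank, 4)
  expect_equal(nrow(amd$records), 11)       # one density record dropped
  expect_false(amd$complete)
  expect_equal(sum(amd$records$trait == 2), 5)

  expect_error(build_design(phen, ped, traits = "absent"), "lack column")
  phen_bad <- phen; phen_bad$id[1] <- "ghost"
  expect_error(build_design(phen_bad, ped), "absent from pedigree")
  phen_cell <- phen; phen_cell$density[phen_cell$site == "b"] <- NA
  expect_error(build_design(phen_cell, ped), "zero records")
})

test_that("REML equals the closed-form ANOVA estimator on a balanced
           one-way layout with A = I", {
  set.seed(7)
  ng <- 12; k <- 4
  id <- rep(sprintf("G%02d", 1:ng), each = 2 * k)
  site <- rep(rep(c("s1", "s2"), each = k), ng)
  u <- rep(rnorm(ng, 0, 2), each = 2 * k)
  y <- 10 + (site == "s2") * 3 + u + rnorm(length(id), 0, 3)
  ped <- validate_pedigree(sprintf("G%02d", 1:ng), rep(NA, ng), rep(NA, ng))
  amd <- build_design(data.frame(id = id, site = site, mai = y), ped,
                      traits = "mai")
  A <- diag(ng); dimnames(A) <- list(ped$id, ped$id)
  vc <- reml_fit(amd, A)
  av <- stats::anova(stats::lm(y ~ site + id))
  msg <- av["id", "Mean Sq"]; mse <- av["Residuals", "Mean Sq"]
  expect_equal(vc$G0[1, 1], (msg - mse) / (2 * k), tolerance = 1e-6)
  expect_equal(vc$R0[1, 1], mse, tolerance = 1e-6)
})

test_that("REML optimum agrees with a brute-force likelihood grid", {
  set.seed(31)
  dat <- halfsib_dataset(ns = 12, noff = 5, sites = 2,
                         sigma_a = 2, sigma_e = 3)
  amd <- build_design(dat$phen, dat$ped, traits = "mai")
  A <- numerator_relationship_matrix(dat$ped)
  vc <- reml_fit(amd, A)
  # independent restricted-likelihood evaluation over a 100 x 100 grid
  rec <- amd$records
  Arr <- A[rec$id, rec$id]
  n <- nrow(rec)
  grid_a <- seq(0.05, 12, length.out = 100)
  grid_e <- seq(0.05, 12, length.out = 100)
  ll <- matrix(NA_real_, 100, 100)
  for (i in seq_along(grid_a)) for (j in seq_along(grid_e))
    ll[i, j] <- direct_logRL(rec$y, amd$X,
                             grid_a[i] * Arr + grid_e[j] * diag(n))
  best <- which(ll == max(ll), arr.ind = TRUE)
  res_a <- diff(grid_a[1:2]); res_e <- diff(grid_e[1:2])
  expect_lt(abs(vc$G0[1, 1] - grid_a[best[1]]), res_a)
  expect_lt(abs(vc$R0[1, 1] - grid_e[best[2]]), res_e)
  # and the package likelihood at the optimum beats every grid point
  expect_gte(vc$loglik, max(ll) - 1e-6)
})

test_that("restricted likelihood is invariant to the fixed-effect basis", {
  set.seed(13)
  dat <- halfsib_dataset(ns = 8, noff = 4, sites = 3)
  amd <- build_design(dat$phen, dat$ped, traits = "mai")
  A <- numerator_relationship_matrix(dat$ped)
  rec <- amd$records
  eng1 <- orchardRF:::.dense_engine(rec, amd$X, A[rec$id, rec$id], 1)
  Tm <- matrix(c(1, 1, 0, 0, 1, 0, 2, -1, 1), 3, 3)  # invertible reparam
  eng2 <- orchardRF:::.dense_engine(rec, amd$X %*% Tm, A[rec$id, rec$id], 1)
  for (theta in list(c(2, 4), c(0.5, 1), c(6, 1.5)))
    expect_equal(eng1(theta)$ll, eng2(theta)$ll, tolerance = 1e-8)
})

test_that("bivariate code with one trait all-missing reduces to univariate", {
  set.seed(17)
  dat <- halfsib_dataset(ns = 10, noff = 5, sites = 2)
  phen <- dat$phen
  phen$density <- NA_real_
  A <- numerator_relationship_matrix(dat$ped)
  expect_message(amd2 <- build_design(phen, dat$ped,
                                      traits = c("mai", "density")),
                 "dropping trait")
  amd1 <- build_design(dat$phen, dat$ped, traits = "mai")
  vc2 <- reml_fit(amd2, A)
  vc1 <- reml_fit(amd1, A)
  expect_equal(vc2$G0[1, 1], vc1$G0[1, 1], tolerance = 1e-6)
  expect_equal(vc2$R0[1, 1], vc1$R0[1, 1], tolerance = 1e-6)
  expect_equal(vc2$loglik, vc1$loglik, tolerance = 1e-6)
})

test_that("unidentifiable structure is flagged", {
  ids <- sprintf("u%d", 1:20)
  ped <- validate_pedigree(ids, rep(NA, 20), rep(NA, 20))
  A <- diag(20); dimnames(A) <- list(ids, ids)
  phen <- data.frame(id = ids, site = rep(c("a", "b"), 10), mai = rnorm(20))
  amd <- build_design(phen, ped, traits = "mai")
  expect_warning(try(reml_fit(amd, A, control = list(max_iter = 30)),
                     silent = TRUE),
                 "not separable")
})

test_that("MME solution equals direct GLS/BLUP with full covariance
           inversion (bivariate, missing data)", {
  set.seed(23)
  cfg <- sim_config(n_parents = 6, n_sites = 3, offspring_per_site = 8)
  ds <- simulate_dataset(cfg)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  phen$density[c(3, 11)] <- NA            # exercise the missing-data path
  amd <- build_design(phen, ds$pedigree)
  A <- numerator_relationship_matrix(ds$pedigree)
  G0 <- cfg$G0; R0 <- cfg$R0
  vc <- make_vc(amd, A, G0, R0)
  fit <- solve_mme(amd, A, vc)

  # oracle: build Z into the trait-major (trait, individual) block vector,
  # V = Z (G0 x A) Z' + R, invert everything directly
  rec <- amd$records
  q <- nrow(A)
  Z <- matrix(0, nrow(rec), 2 * q)
  Z[cbind(seq_len(nrow(rec)),
          (rec$trait - 1L) * q + match(rec$id, rownames(A)))] <- 1
  Rmat <- matrix(0, nrow(rec), nrow(rec))
  for (r in seq_len(nrow(rec))) for (s in seq_len(nrow(rec)))
    Rmat[r, s] <- R0[rec$trait[r], rec$trait[s]] *
      (rec$id[r] == rec$id[s]) *
      (rec$trait[r] == rec$trait[s] | rec$id[r] == rec$id[s])
  # same-record same-trait or same-individual cross-trait
  or <- direct_gls_blup(rec$y, amd$X, Z, A, G0, Rmat)
  expect_equal(unname(fit$b), unname(or$b), tolerance = 1e-8)
  expect_equal(unname(c(fit$a)), unname(or$a), tolerance = 1e-8)
  expect_equal(unname(c(fit$a_se)), unname(sqrt(pmax(or$pev, 0))),
               tolerance = 1e-8)
  expect_equal(unname(fit$b_cov), unname(or$b_cov), tolerance = 1e-8)
})

test_that("constant phenotypes within sites give zero breeding values and
           cell-mean fixed effects", {
  ped <- validate_pedigree(c("s1", "s2", sprintf("o%d", 1:8)),
                           c(NA, NA, rep(c("s1", "s2"), 4)),
                           rep(NA, 10))
  phen <- data.frame(id = sprintf("o%d", 1:8),
                     site = rep(c("a", "b"), each = 4),
                     mai = rep(c(5, 9), each = 4))
  amd <- build_design(phen, ped, traits = "mai")
  A <- numerator_relationship_matrix(ped)
  vc <- make_vc(amd, A, matrix(2), matrix(3))
  fit <- solve_mme(amd, A, vc)
  expect_equal(max(abs(fit$a)), 0, tolerance = 1e-10)
  expect_equal(unname(fit$b), c(5, 9), tolerance = 1e-10)
})

test_that("MME residual identity holds at the solution", {
  set.seed(29)
  dat <- halfsib_dataset(ns = 8, noff = 6, sites = 2)
  amd <- build_design(dat$phen, dat$ped, traits = "mai")
  A <- numerator_relationship_matrix(dat$ped)
  # identity holds at any PD components; fixed values keep it well away from
  # the variance boundary a tiny instance can drive REML to
  vc <- make_vc(amd, A, matrix(2), matrix(4))
  fit <- solve_mme(amd, A, vc)
  rec <- amd$records
  q <- nrow(A)
  Z <- matrix(0, nrow(rec), q)
  Z[cbind(seq_len(nrow(rec)), match(rec$id, rownames(A)))] <- 1
  e <- rec$y - amd$X %*% fit$b - Z %*% fit$a[, 1]
  lhs <- t(Z) %*% e / vc$R0[1, 1]
  rhs <- solve(vc$G0[1, 1] * A) %*% fit$a[, 1]
  expect_equal(unname(drop(lhs)), unname(drop(rhs)), tolerance = 1e-6)
})

test_that("BLUP is calibrated: true-on-estimated regression slope near 1", {
  cfg <- sim_config(n_parents = 30, n_sites = 8, offspring_per_site = 40)
  ds <- simulate_dataset(cfg, seed = 37)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  res <- fit_animal_model(phen, ds$pedigree)
  off <- ds$pedigree$id[!ds$pedigree$founder]
  sl <- stats::lm(ds$true_bv[off, "mai"] ~ res$fit$a[off, 1])
  ci <- stats::confint(sl)[2, ]
  expect_gt(ci[2], 1); expect_lt(ci[1], 1)
  expect_equal(unname(stats::coef(sl)[2]), 1, tolerance = 0.15)
})

test_that("heritability is the variance ratio with a delta-method SE that
           matches a parametric bootstrap", {
  vc0 <- structure(list(G0 = matrix(27), R0 = matrix(73),
                        theta = c(27, 73), theta_cov = diag(2), nt = 1,
                        traits = "mai"), class = "am_vc")
  expect_equal(unname(heritability(vc0, 1)["h2"]), 0.27)
  vc1 <- structure(list(G0 = matrix(0), R0 = matrix(10),
                        theta = c(0, 10), theta_cov = diag(2), nt = 1,
                        traits = "mai"), class = "am_vc")
  expect_equal(unname(heritability(vc1, 1)["h2"]), 0)
  vcbad <- structure(list(G0 = matrix(0), R0 = matrix(0),
                          theta = c(0, 0), theta_cov = diag(2), nt = 1,
                          traits = "mai"), class = "am_vc")
  expect_error(heritability(vcbad, 1), "zero phenotypic variance")

  # bootstrap comparison on a well-identified half-sib design
  set.seed(41)
  dat <- halfsib_dataset(ns = 40, noff = 10, sites = 2,
                         sigma_a = sqrt(3), sigma_e = sqrt(7))
  amd <- build_design(dat$phen, dat$ped, traits = "mai")
  A <- numerator_relationship_matrix(dat$ped)
  vc <- reml_fit(amd, A)
  h <- heritability(vc, 1)
  ids <- dat$phen$id
  Arr <- A[ids, ids]
  L <- t(chol(vc$G0[1, 1] * Arr + vc$R0[1, 1] * diag(length(ids))))
  mu <- tapply(dat$phen$mai, dat$phen$site, mean)
  h2b <- replicate(200, {
    yb <- mu[dat$phen$site] + drop(L %*% rnorm(length(ids)))
    phb <- dat$phen; phb$mai <- yb
    vb <- reml_fit(build_design(phb, dat$ped, traits = "mai"), A)
    unname(heritability(vb, 1)["h2"])
  })
  # within 10% of the bootstrap SD, plus a 3-SE Monte-Carlo allowance for
  # the 200-replicate SD estimate itself
  mc <- 3 * stats::sd(h2b) / sqrt(2 * 199)
  expect_lt(abs(unname(h["se"]) - stats::sd(h2b)),
            0.1 * stats::sd(h2b) + mc)
})

test_that("genetic correlation and its boundary behaviour", {
  vc <- structure(list(G0 = matrix(c(4, 1.8, 1.8, 9), 2, 2),
                       R0 = diag(2), theta = c(4, 1.8, 9, 1, 0, 1),
                       theta_cov = diag(6), nt = 2,
                       traits = c("a", "b")), class = "am_vc")
  expect_equal(unname(genetic_correlation(vc)["ra"]), 0.3)
  vc$G0 <- matrix(c(4, 0, 0, 9), 2, 2); vc$theta <- c(4, 0, 9, 1, 0, 1)
  expect_equal(unname(genetic_correlation(vc)["ra"]), 0)
  vc$G0 <- matrix(c(0, 0, 0, 9), 2, 2)
  expect_error(genetic_correlation(vc), "boundary")
})

test_that("site contrasts enumerate all pairs and are null for identical
           sites", {
  ped <- validate_pedigree(c("p1", "p2", sprintf("o%d", 1:12)),
                           c(NA, NA, rep(c("p1", "p2"), 6)),
                           rep(NA, 14))
  y0 <- c(4.2, 5.1, 6.3, 3.9)
  phen <- data.frame(id = sprintf("o%d", 1:12),
                     site = rep(c("a", "b", "c"), each = 4),
                     mai = rep(y0, 3))            # identical records per site
  amd <- build_design(phen, ped, traits = "mai")
  A <- numerator_relationship_matrix(ped)
  vc <- make_vc(amd, A, matrix(1), matrix(2))
  fit <- solve_mme(amd, A, vc)
  ct <- site_contrasts(fit)
  expect_equal(nrow(ct), 3)                       # k(k-1)/2 with k = 3
  expect_equal(max(abs(ct$diff)), 0, tolerance = 1e-9)
  expect_true(all(ct$p > 0.999))
})

test_that("site-contrast type-I error is calibrated under the null", {
  # 200 small half-sib replicates with all true site effects equal; the
  # pooled fraction of p < 0.05 must sit inside a 99% binomial band (the
  # band conservatively uses the number of replicates, not the correlated
  # per-replicate contrast count)
  set.seed(53)
  fracs <- replicate(200, {
    dat <- halfsib_dataset(ns = 10, noff = 8, sites = 4,
                           sigma_a = 1.5, sigma_e = 3)
    amd <- build_design(dat$phen, dat$ped, traits = "mai")
    A <- numerator_relationship_matrix(dat$ped)
    vc <- tryCatch(reml_fit(amd, A), error = function(e) NULL,
                   warning = function(w) suppressWarnings(reml_fit(amd, A)))
    if (is.null(vc)) return(NA_real_)
    attr(site_contrasts(solve_mme(amd, A, vc)), "fraction_significant")
  })
  frac <- mean(fracs, na.rm = TRUE)
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / 200)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("GxE diagnostic detects an injected family-by-site interaction
           and stays quiet without one", {
  set.seed(59)
  cfg <- sim_config(n_parents = 8, n_sites = 5, offspring_per_site = 16)
  ds <- simulate_dataset(cfg, seed = 59)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  g0 <- gxe_diagnostic(phen, ds$pedigree)
  expect_gt(g0$p_value, 0.01)            # generator has no interaction

  # inject a strong family-by-site effect
  fam <- ds$pedigree$dam[match(phen$id, ds$pedigree$id)]
  key <- paste(fam, phen$site)
  bump <- stats::setNames(rnorm(length(unique(key)), 0, 6), unique(key))
  phen$mai <- phen$mai + bump[key]
  g1 <- gxe_diagnostic(phen, ds$pedigree)
  expect_lt(g1$p_value, 0.001)
  expect_gt(g1$sigma2_fs, 1)
})
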