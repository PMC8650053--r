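test_that("quadratic fit interpolates noiseless data and locates the vertex", {
  c <- seq(-4, 0, length.out = 9)
  v <- 40.8 - 22 * c - 5 * c^2
  q <- fit_quadratic(c, v)
  expect_equal(unname(q$coef), c(40.8, -22, -5), tolerance = 1e-9)
  expect_equal(unname(q$vertex["c_star"]), -2.2, tolerance = 1e-9)
  expect_equal(unname(q$vertex["v_star"]), 65, tolerance = 1e-9)
  expect_equal(q$r2, 1)

  flat <- fit_quadratic(c, rep(5, 9))
  expect_equal(unname(flat$coef[2:3]), c(0, 0), tolerance = 1e-12)
  expect_equal(flat$r2, 0)

  expect_error(fit_quadratic(c(1, 1, 2), rnorm(3)), "singular design")
})

test_that("quadratic coefficients match the normal-equations oracle", {
  set.seed(71)
  for (i in 1:5) {
    c <- rnorm(30, -2, 1.2)
    v <- 50 + 3 * c - 2 * c^2 + rnorm(30, 0, 4)
    q <- fit_quadratic(c, v)
    Xm <- cbind(1, c, c^2)
    beta <- solve(crossprod(Xm), crossprod(Xm, v))
    expect_equal(unname(q$coef), unname(drop(beta)), tolerance = 1e-8)
    # adjusted R2 definition
    rss <- sum((v - Xm %*% beta)^2); tss <- sum((v - mean(v))^2)
    expect_equal(q$adj_r2, 1 - (1 - (1 - rss / tss)) * 29 / 27,
                 tolerance = 1e-10)
  }
})

test_that("vertex is invariant to affine rescaling of the climate axis", {
  set.seed(73)
  c <- runif(25, -4, 0)
  v <- 60 - 10 * (c + 2.2)^2 + rnorm(25, 0, 2)
  q1 <- fit_quadratic(c, v)
  a <- 3.7; b <- 12.1                     # c' = a c + b
  q2 <- fit_quadratic(a * c + b, v)
  expect_equal(unname((q2$vertex["c_star"] - b) / a),
               unname(q1$vertex["c_star"]), tolerance = 1e-8)
  expect_equal(unname(q2$vertex["v_star"]), unname(q1$vertex["v_star"]),
               tolerance = 1e-8)
  # concave fit: no observed-range prediction exceeds the vertex ordinate
  expect_lte(max(predict(q1, seq(min(c), max(c), length.out = 200))),
             unname(q1$vertex["v_star"]) + 1e-10)
})

test_that("linear data yield a zero-residual linear fit and a flat quadratic
           curvature", {
  c <- seq(-4, 0, length.out = 12)
  v <- 7 + 2 * c
  l <- fit_linear(c, v)
  expect_equal(l$rss, 0, tolerance = 1e-18)
  q <- fit_quadratic(c, v)
  expect_equal(unname(q$coef["b2"]), 0, tolerance = 1e-9)
})

test_that("Gaussian fit recovers noiseless parameters and matches the
           quadratic under small curvature", {
  c <- seq(-4, 0, length.out = 15)
  v <- 62 * exp(-(c + 2.1)^2 / (2 * 1.4^2))
  g <- fit_gaussian(c, v)
  expect_equal(unname(g$coef), c(62, -2.1, 1.4), tolerance = 1e-6)
  expect_equal(unname(g$vertex), c(-2.1, 62), tolerance = 1e-6)

  # wide Gaussian over a short range is locally quadratic: AIC within 2
  set.seed(79)
  c2 <- runif(60, -2.7, -1.7)
  v2 <- 65 * exp(-(c2 + 2.2)^2 / (2 * 4^2)) + rnorm(60, 0, 1)
  q2 <- fit_quadratic(c2, v2); g2 <- fit_gaussian(c2, v2)
  expect_true(g2$converged)
  expect_lt(abs(q2$aic - g2$aic), 2)
})

test_that("model comparison uses the documented AIC and tie-breaks", {
  set.seed(83)
  c <- runif(40, -4, 0)
  v <- 50 - 8 * (c + 2)^2 + rnorm(40, 0, 3)   # strongly curved
  l <- fit_linear(c, v); q <- fit_quadratic(c, v)
  cmp <- compare_models(list(l, q))
  expect_equal(cmp$model[cmp$selected], "quadratic")
  expect_equal(q$aic, q$n * log(q$rss / q$n) + 2 * 4)

  # exact tie: simpler family wins (documented order)
  g <- fit_gaussian(c, v)
  g$aic <- q$aic
  tie <- compare_models(list(g, q))
  expect_equal(tie$model[tie$selected], "quadratic")

  expect_error(compare_models(list(l, fit_quadratic(c, v + 1))),
               "identical data")
})

test_that("a pure-noise regressor raises AIC by ~ (2 - chi-square) and is
           rarely selected", {
  set.seed(89)
  daic <- replicate(200, {
    c <- runif(200, -4, 0)                  # large n: asymptotic regime
    v <- 10 + 2 * c + rnorm(200)            # truth is linear
    fit_quadratic(c, v)$aic - fit_linear(c, v)$aic
  })
  # E[delta AIC] = 2 - E[chi2_1] = 1 (asymptotically); 3 MC SEs of slack
  expect_lt(abs(mean(daic) - 1), 3 * stats::sd(daic) / sqrt(200))
  expect_lt(mean(daic < 0), 0.3)            # selected ~ P(chi2_1 > 2) = 0.157
})

test_that("population and family curves recover the generating response", {
  cfg <- sim_config()
  ds <- simulate_dataset(cfg, seed = 97)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  res <- fit_animal_model(phen, ds$pedigree)
  pt <- trim_families(performance_table(res$fit, phen, ds$pedigree))
  rs <- fit_all_levels(pt, ds$climate, "mtcm")

  expect_equal(unname(rs$population$vertex["c_star"]), -2.2, tolerance = 0.1)
  expect_lt(abs(rs$population$vertex["v_star"] - 65), 2)

  # per-family N_b equals the family row count
  tab <- rs$table[rs$table$level != "population", ]
  cnt <- table(pt$family)
  expect_equal(tab$N_b, as.integer(cnt[tab$level]))

  # family curves, N_b-weighted, average to approximately the population
  # curve over the observed gradient
  grid <- seq(-3.5, -0.5, length.out = 7)
  fam_pred <- vapply(rs$families, predict, numeric(7), newdata = grid)
  wts <- tab$N_b[match(names(rs$families), tab$level)]
  avg <- drop(fam_pred %*% wts / sum(wts))
  expect_equal(avg, unname(predict(rs$population, grid)), tolerance = 0.05)
})

test_that("degenerate genetics collapse family curves onto the population
           curve", {
  cfg <- sim_config(n_parents = 10, n_sites = 8, offspring_per_site = 60,
                    G0 = matrix(0, 2, 2))
  ds <- simulate_dataset(cfg, seed = 101)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  res <- suppressWarnings(fit_animal_model(phen, ds$pedigree))
  pt <- trim_families(performance_table(res$fit, phen, ds$pedigree),
                      min_sites = 6)
  rs <- fit_all_levels(pt, ds$climate, "mtcm")
  grid <- seq(-3.5, -0.5, length.out = 5)
  pop <- predict(rs$population, grid)
  for (f in rs$families)
    expect_equal(predict(f, grid), pop, tolerance = 0.05)
})

test_that("family optima recover their generated ranking under GxE", {
  cfg <- sim_config(family_optimum_range = c(-2.4, -1.6))
  ds <- simulate_dataset(cfg, seed = 21)
  phen <- ds$phenotypes
  phen$mai <- phen$height / phen$age
  res <- fit_animal_model(phen, ds$pedigree)
  pt <- trim_families(performance_table(res$fit, phen, ds$pedigree))
  rs <- fit_all_levels(pt, ds$climate, "mtcm")
  est <- rs$table[rs$table$level != "population", c("level", "c_star")]
  m <- merge(est, ds$true_family_optima, by.x = "level", by.y = "family")
  expect_gt(stats::cor(m$c_star, m$optimum, method = "spearman"), 0.8)
})

test_that("families with too few observations are skipped with a warning", {
  set.seed(103)
  perf <- data.frame(individual = sprintf("i%d", 1:23),
                     family = c(rep("big", 20), rep("tiny", 3)),
                     site = c(rep_len(sprintf("s%d", 1:8), 20), "s1", "s2", "s3"),
                     pmai = rnorm(23, 60, 3))
  climate <- data.frame(site = sprintf("s%d", 1:8),
                        mtcm = seq(-4, 0, length.out = 8))
  expect_warning(rs <- fit_all_levels(perf, climate, "mtcm", min_obs = 4),
                 "tiny")
  expect_named(rs$families, "big")
})
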