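# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: kinship by gene dropping, restricted
# likelihood by direct dense algebra, GLS/BLUP by whole-covariance inversion.

# Monte-Carlo kinship by gene dropping. Unknown parents become phantom
# founders (one per missing parent), matching the relationship-matrix
# convention. Returns 2*kinship estimates and their Monte-Carlo SEs.
gene_drop_kinship <- function(ped, nrep = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  M1 <- matrix(0L, nrep, n)
  M2 <- matrix(0L, nrep, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    for (side in 1:2) {
      p <- if (side == 1) si[i] else di[i]
      if (p == 0L) {
        # phantom founder: two fixed alleles, one transmitted at random
        a1 <- next_allele + 1L; a2 <- next_allele + 2L
        next_allele <- next_allele + 2L
        pick <- stats::runif(nrep) < 0.5
        val <- ifelse(pick, a1, a2)
      } else {
        pick <- stats::runif(nrep) < 0.5
        val <- ifelse(pick, M1[, p], M2[, p])
      }
      if (side == 1) M1[, i] <- val else M2[, i] <- val
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      k <- 0.5 * (1 + (M1[, i] == M2[, i]))
    } else {
      k <- 0.25 * ((M1[, i] == M1[, j]) + (M1[, i] == M2[, j]) +
                   (M2[, i] == M1[, j]) + (M2[, i] == M2[, j]))
    }
    est[i, j] <- est[j, i] <- 2 * mean(k)
    se[i, j] <- se[j, i] <- 2 * stats::sd(k) / sqrt(nrep)
  }
  list(a = est, se = se)
}

# random multi-generation pedigree for property tests
random_pedigree <- function(n_founders = 10, n_per_gen = 20, gens = 2,
                            p_unknown_sire = 0.1) {
  id <- sprintf("F%02d", seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  pool <- id
  cnt <- 0L
  for (g in seq_len(gens)) {
    for (k in seq_len(n_per_gen)) {
      cnt <- cnt + 1L
      nid <- sprintf("I%03d", cnt)
      pr <- sample(pool, 2)
      s <- if (stats::runif(1) < p_unknown_sire) NA_character_ else pr[1]
      id <- c(id, nid); sire <- c(sire, s); dam <- c(dam, pr[2])
    }
    pool <- utils::tail(id, n_per_gen)
  }
  validate_pedigree(id, sire, dam)
}

# restricted log-likelihood by direct dense algebra (up to the same constant
# the package drops): -0.5 (log|V| + log|X'V^-1 X| + y'Py)
direct_logRL <- function(y, X, V) {
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  b <- solve(C, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  py <- Vi %*% r
  -0.5 * (determinant(V)$modulus + determinant(C)$modulus + sum(y * py))
}

# direct GLS / BLUP via full joint covariance of y
direct_gls_blup <- function(y, X, Z, A, G0, R0_blocks) {
  G <- kronecker(G0, A)      # trait-major over individuals
  V <- Z %*% G %*% t(Z) + R0_blocks
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  b <- solve(C, t(X) %*% Vi %*% y)
  py <- Vi %*% (y - X %*% b)
  P <- Vi - Vi %*% X %*% solve(C, t(X) %*% Vi)
  a <- G %*% t(Z) %*% py
  pev <- diag(G - G %*% t(Z) %*% P %*% Z %*% G)
  list(b = drop(b), a = drop(a), pev = pev, b_cov = solve(C))
}

# am_vc at fixed (not estimated) variance components, for MME-only tests
make_vc <- function(amd, A, G0, R0) {
  nt <- length(amd$traits)
  theta <- if (nt == 1) c(G0[1, 1], R0[1, 1])
           else c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
  rec <- amd$records
  eng <- orchardRF:::.dense_engine(rec, amd$X, A[rec$id, rec$id], nt)
  ev <- eng(theta)
  structure(list(G0 = G0, R0 = R0, loglik = ev$ll, theta = theta,
                 theta_cov = diag(length(theta)), converged = TRUE,
                 boundary = FALSE, traits = amd$traits, nt = nt,
                 cache = list(path = "dense", aux = ev$aux)),
            class = "am_vc")
}

# small half-sib design used by several animal-model tests: ns sires with
# noff offspring each (dams unknown), offspring spread over sites
halfsib_dataset <- function(ns = 20, noff = 8, sites = 4,
                            sigma_a = 2, sigma_e = 4, site_effects = NULL,
                            mu = 50) {
  sires <- sprintf("S%02d", seq_len(ns))
  off <- sprintf("O%03d", seq_len(ns * noff))
  ped <- validate_pedigree(c(sires, off),
                           c(rep(NA, ns), rep(sires, each = noff)),
                           rep(NA, ns + ns * noff))
  site <- rep_len(sprintf("st%d", seq_len(sites)), length(off))
  if (is.null(site_effects)) site_effects <- rep(0, sites)
  u_s <- stats::rnorm(ns, 0, sigma_a)
  u_o <- 0.5 * rep(u_s, each = noff) +
    stats::rnorm(length(off), 0, sqrt(0.75) * sigma_a)
  y <- mu + site_effects[as.integer(factor(site))] + u_o +
    stats::rnorm(length(off), 0, sigma_e)
  list(ped = ped,
       phen = data.frame(id = off, site = site, mai = y),
       true_bv = u_o)
}
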