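# Independent oracles and small fixtures used across the suite. Everything
# here deliberately takes the dense / brute-force route, never the package's
# MME-based implementations.

# small trial configuration used wherever study-scale sizes are not the point
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_parents = 6, n_families = 4,
                   family_sizes = c(6, 8, 10, 12), n_progeny = 36,
                   n_markers = 400, n_sites = 3, ramets_range = c(4, 6))
  do.call(sim_config, utils::modifyList(defaults, args))
}

# ten-individual pedigree with inbreeding, used for the gene-dropping check
ten_pedigree <- function() {
  as_pedigree(data.frame(
    id   = c("F1", "F2", "F3", "F4", "O1", "O2", "O3", "O4", "O5", "O6"),
    sire = c(NA, NA, NA, NA, "F1", "F1", "F3", "O1", "O1", "O4"),
    dam  = c(NA, NA, NA, NA, "F2", "F2", "F4", "O3", "O2", "O5")))
}

# Monte-Carlo IBD sharing: drop unique founder allele labels down the
# pedigree nrep times; A_jk = 2 * kinship = mean shared-allele count / 2,
# A_jj = 1 + P(the two alleles of j are IBD).
gene_drop_A <- function(ped, nrep = 1e5) {
  id <- ped$id
  n <- length(id)
  si <- match(ped$sire, id); di <- match(ped$dam, id)
  a1 <- matrix(0L, nrep, n); a2 <- matrix(0L, nrep, n)
  lab <- 0L
  for (j in seq_len(n)) {
    if (is.na(si[j])) {
      a1[, j] <- lab + 1L; a2[, j] <- lab + 2L; lab <- lab + 2L
    } else {
      pick <- stats::rbinom(nrep, 1L, 0.5) == 1L
      a1[, j] <- ifelse(pick, a1[, si[j]], a2[, si[j]])
      pick <- stats::rbinom(nrep, 1L, 0.5) == 1L
      a2[, j] <- ifelse(pick, a1[, di[j]], a2[, di[j]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  SE <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    x <- if (j == k) 1 + (a1[, j] == a2[, j])
         else ((a1[, j] == a1[, k]) + (a1[, j] == a2[, k]) +
               (a2[, j] == a1[, k]) + (a2[, j] == a2[, k])) / 2
    A[j, k] <- mean(x)
    SE[j, k] <- stats::sd(x) / sqrt(nrep)
  }
  list(A = A, SE = SE)
}

# design matrices exactly as the package builds them (site contrasts, clone
# incidence on the K labels) -- shared by the dense oracles below
dense_design <- function(pheno, K) {
  site <- droplevels(factor(pheno$site_id))
  X <- if (nlevels(site) > 1L) stats::model.matrix(~site) else
    matrix(1, nrow(pheno), 1L)
  Zc <- outer(pheno$clone_id, rownames(K), `==`) * 1
  list(X = X, Zc = Zc, y = as.numeric(pheno$volume))
}

# brute-force joint GLS/BLUP through the full n x n covariance matrix
oracle_blup <- function(pheno, K, sigma2_a, sigma2_e) {
  d <- dense_design(pheno, K)
  V <- d$Zc %*% K %*% t(d$Zc) * sigma2_a + diag(sigma2_e, nrow(d$X))
  Vi <- solve(V)
  b <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% d$y)
  u <- sigma2_a * K %*% t(d$Zc) %*% Vi %*% (d$y - d$X %*% b)
  list(b = drop(b), u = stats::setNames(drop(u), rownames(K)))
}

# dense -2 restricted log-likelihood (up to the usual constant)
oracle_neg2_reml <- function(pheno, K, sigma2_a, sigma2_e) {
  d <- dense_design(pheno, K)
  V <- d$Zc %*% K %*% t(d$Zc) * sigma2_a + diag(sigma2_e, nrow(d$X))
  Vi <- solve(V)
  XtViX <- t(d$X) %*% Vi %*% d$X
  b <- solve(XtViX, t(d$X) %*% Vi %*% d$y)
  r <- d$y - d$X %*% b
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r)
}

# dense REML estimates by direct 2-parameter optimization
oracle_reml <- function(pheno, K, start = c(1, 1)) {
  f <- function(lp) oracle_neg2_reml(pheno, K, exp(lp[1]), exp(lp[2]))
  o <- stats::optim(log(start), f, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  stats::setNames(exp(o$par), c("sigma2_a", "sigma2_e"))
}

# gene-content prediction via the equivalent GLS route (not the MME):
# mean by GLS under V = A_oo + lambda I, then u = A[, o] V^{-1} (y - mu)
oracle_gene_content <- function(y, A, h2 = 0.99) {
  o <- which(!is.na(y))
  lambda <- (1 - h2) / h2
  V <- A[o, o, drop = FALSE] + diag(lambda, length(o))
  Vi <- solve(V)
  one <- rep(1, length(o))
  mu <- drop(t(one) %*% Vi %*% y[o]) / drop(t(one) %*% Vi %*% one)
  drop(mu + A[, o, drop = FALSE] %*% Vi %*% (y[o] - mu))
}
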