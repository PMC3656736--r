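test_that("REML matches lme4 when the relationship is identity", {
  skip_if_not_installed("lme4")
  sim <- simulate_trial(small_cfg(), seed = 41)
  cl <- names(sim$families)
  I <- diag(1, length(cl)); dimnames(I) <- list(cl, cl)
  vc <- fit_reml(sim$pheno, I)
  m <- lme4::lmer(volume ~ site_id + (1 | clone_id), data = sim$pheno,
                  REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(vc$sigma2_a, v[1], tolerance = 1e-5)
  expect_equal(vc$sigma2_e, v[2], tolerance = 1e-5)
})

test_that("REML matches a dense restricted-likelihood oracle under K = A", {
  sim <- simulate_trial(small_cfg(n_markers = 200), seed = 42)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  vc <- fit_reml(sim$pheno, A)
  dense <- oracle_reml(sim$pheno, A, start = c(vc$sigma2_a, vc$sigma2_e) * 1.6)
  expect_equal(vc$sigma2_a, unname(dense["sigma2_a"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_e, unname(dense["sigma2_e"]), tolerance = 1e-4)
  # and our optimum is no worse than any nearby point on the dense surface
  at <- function(s2a, s2e) oracle_neg2_reml(sim$pheno, A, s2a, s2e)
  base <- at(vc$sigma2_a, vc$sigma2_e)
  for (f in c(0.9, 1.1)) {
    expect_gte(at(vc$sigma2_a * f, vc$sigma2_e), base - 1e-6)
    expect_gte(at(vc$sigma2_a, vc$sigma2_e * f), base - 1e-6)
  }
})

test_that("REML reduces to the balanced one-way ANOVA estimators", {
  set.seed(43)
  q <- 30; n <- 6
  u <- rnorm(q, 0, sqrt(2))
  ph <- data.frame(tree_id = seq_len(q * n),
                   clone_id = rep(sprintf("C%02d", 1:q), each = n),
                   site_id = "S1",
                   volume = 5 + rep(u, each = n) + rnorm(q * n, 0, 1))
  I <- diag(1, q); dimnames(I) <- list(unique(ph$clone_id), unique(ph$clone_id))
  vc <- fit_reml(ph, I)
  ybar <- tapply(ph$volume, ph$clone_id, mean)
  msb <- n * stats::var(ybar)
  msw <- sum((ph$volume - ybar[ph$clone_id])^2) / (q * (n - 1))
  expect_equal(vc$sigma2_e, msw, tolerance = 1e-6)
  expect_equal(vc$sigma2_a, (msb - msw) / n, tolerance = 1e-6)
})

test_that("degenerate responses drive components to the boundary", {
  ph <- data.frame(tree_id = 1:40,
                   clone_id = rep(sprintf("C%d", 1:10), 4),
                   site_id = rep(c("S1", "S2"), each = 20),
                   volume = rep(c(1, 5), each = 20))  # y = Xb exactly
  I <- diag(1, 10); dimnames(I) <- list(sprintf("C%d", 1:10), sprintf("C%d", 1:10))
  expect_warning(expect_warning(vc <- fit_reml(ph, I), "boundary|clamped"),
                 "boundary|edge|clamped")
  expect_lt(vc$sigma2_a, 1e-6)
  expect_lt(vc$sigma2_e, 1e-6)
})

test_that("BLUP with identity K is shrunken clone-mean deviation", {
  set.seed(44)
  q <- 12; n <- 5
  ph <- data.frame(tree_id = seq_len(q * n),
                   clone_id = rep(sprintf("C%02d", 1:q), each = n),
                   site_id = "S1",
                   volume = rnorm(q * n, 10, 2))
  I <- diag(1, q); dimnames(I) <- list(sprintf("C%02d", 1:q), sprintf("C%02d", 1:q))
  vc <- structure(list(sigma2_a = 1, sigma2_e = 3, lambda = 3), class = "varcomp")
  fit <- solve_blup(ph, I, vc)
  ybar <- tapply(ph$volume, ph$clone_id, mean)
  shrink <- n / (n + vc$lambda)
  # balanced intercept-only: u_i = shrink * (ybar_i - GLS mean)
  mu <- fit$fixef[["(Intercept)"]]
  expect_equal(fit$bv$value, as.vector(shrink * (ybar - mu)), tolerance = 1e-8)
})

test_that("BLUP matches the brute-force joint GLS oracle, including PEV facts", {
  sim <- simulate_trial(small_cfg(), seed = 45)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  vc <- fit_reml(sim$pheno, A)
  fit <- solve_blup(sim$pheno, A, vc)
  orc <- oracle_blup(sim$pheno, A, vc$sigma2_a, vc$sigma2_e)
  expect_equal(fit$bv$value, unname(orc$u), tolerance = 1e-8)
  expect_equal(unname(fit$fixef), unname(orc$b), tolerance = 1e-8)
  expect_true(all(fit$bv$se >= 0))
  expect_true(all(fit$bv$accuracy >= 0 & fit$bv$accuracy <= 1))
})

test_that("unphenotyped full sibs get the mid-parent value under A", {
  sim <- simulate_trial(small_cfg(), seed = 46)
  A_all <- amatrix(sim$ped)                 # parents included
  fam <- sim$families
  val <- names(fam)[fam == "F1"][1:3]       # withhold three sibs
  ph <- sim$pheno[!sim$pheno$clone_id %in% val, ]
  vc <- fit_reml(ph, A_all)
  fit <- solve_blup(ph, A_all, vc, method = "EBV2")
  u <- stats::setNames(fit$bv$value, fit$bv$clone_id)
  # identical predictions for all withheld sibs
  expect_lt(max(u[val]) - min(u[val]), 1e-10)
  # and exactly the mid-parent value
  par <- sim$ped[sim$ped$id == val[1], c("sire", "dam")]
  expect_equal(unname(u[val[1]]),
               unname((u[[par$sire]] + u[[par$dam]]) / 2), tolerance = 1e-10)
})

test_that("infinite shrinkage sends all predictions to zero", {
  sim <- simulate_trial(small_cfg(), seed = 47)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  vc <- structure(list(sigma2_a = 1e-9, sigma2_e = 1, lambda = 1e9),
                  class = "varcomp")
  fit <- solve_blup(sim$pheno, A, vc)
  expect_lt(max(abs(fit$bv$value)), 1e-5)
})

test_that("selection-index and MME GBLUP coincide", {
  sim <- simulate_trial(small_cfg(), seed = 48)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  G <- make_invertible(gmatrix_frequency(
    impute_major_homozygote(filter_markers(sim$geno)$geno)), A)
  vc <- fit_reml(sim$pheno, G)
  si <- gblup_selection_index(sim$pheno, G, vc)
  mm <- gblup_mme(sim$pheno, G, vc)
  expect_lt(max(abs(si$bv$value - mm$bv$value)), 1e-8)
  # two identical genotypes, one phenotyped: both get the same prediction
  G2 <- matrix(1, 2, 2, dimnames = list(c("ca", "cb"), c("ca", "cb")))
  G2 <- G2 + diag(1e-8, 2)
  ph2 <- data.frame(tree_id = c("t1", "t2", "t3"), clone_id = "ca",
                    site_id = "S1", volume = c(3.0, 3.4, 2.9))
  vc2 <- structure(list(sigma2_a = 1, sigma2_e = 2, lambda = 2),
                   class = "varcomp")
  fit2 <- gblup_selection_index(ph2, G2, vc2)
  expect_equal(fit2$bv$value[1], fit2$bv$value[2], tolerance = 1e-6)
})

test_that("adding ramets never increases a clone's PEV", {
  sim <- simulate_trial(small_cfg(), seed = 49)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  vc <- fit_reml(sim$pheno, A)
  target <- cl[5]
  pev0 <- solve_blup(sim$pheno, A, vc)$bv
  pev0 <- pev0$se[pev0$clone_id == target]^2
  extra <- sim$pheno[sim$pheno$clone_id == target, ][1:2, ]
  extra$tree_id <- paste0(extra$tree_id, "x")
  fit1 <- solve_blup(rbind(sim$pheno, extra), A, vc)$bv
  pev1 <- fit1$se[fit1$clone_id == target]^2
  expect_lte(pev1, pev0 + 1e-12)
})

test_that("accuracy follows the reliability relation", {
  expect_equal(accuracy_from_se(0, 0, 1), 1)
  expect_equal(accuracy_from_se(1, 0, 1), 0)
  expect_equal(accuracy_from_se(sqrt(0.5), 0, 1), sqrt(0.5))
  expect_equal(accuracy_from_se(sqrt(1.5), 0.5, 1), 0)     # SE^2 = (1+f)s2a
  expect_warning(r <- accuracy_from_se(2, 0, 1), "accuracy set to 0")
  expect_equal(r, 0)
  expect_error(accuracy_from_se(1, 0, 0), "positive")
  expect_error(accuracy_from_se(-1, 0, 1), "non-negative")
})

test_that("noise-free data recovers true breeding values", {
  cfg <- small_cfg(h2 = 0.999, ramets_range = c(6, 6))
  sim <- simulate_trial(cfg, seed = 50)
  fit <- compute_ebv1(sim$pheno)
  tbv <- sim$truth$tbv[fit$bv$clone_id]
  expect_gt(stats::cor(fit$bv$value, tbv), 0.999)
})
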