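toy_geno <- function() {
  # 4 markers: informative / monomorphic / 20% missing / informative
  matrix(c(0, 1, 2, 1, 0,
           0, 0, 0, 0, 0,
           1, NA, 2, 1, 0,
           2, 2, 1, 0, 1),
         nrow = 5,
         dimnames = list(sprintf("C%d", 1:5), sprintf("M%d", 1:4)))
}

test_that("marker summaries and filtering match hand counts", {
  g <- toy_geno()
  rep <- summarize_markers(g, max_missing = 0.15)
  expect_equal(rep$missing, c(0, 0, 0.2, 0))
  expect_equal(rep$monomorphic, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(rep$high_missing, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(rep, "n_informative"), 2)
  fl <- filter_markers(g)
  expect_equal(colnames(fl$geno), c("M1", "M4"))
  # a fraction like 25/165 = 0.1515... exceeds the 15% threshold
  g2 <- matrix(rbinom(165 * 2, 2, 0.4), 165, 2,
               dimnames = list(sprintf("C%03d", 1:165), c("A", "B")))
  g2[sample(165, 25), "B"] <- NA
  r2 <- summarize_markers(g2)
  expect_equal(r2$missing[2], 25 / 165)
  expect_true(r2$high_missing[2])
  # max_missing = 1 removes only monomorphic columns
  fl3 <- filter_markers(toy_geno(), max_missing = 1)
  expect_equal(ncol(fl3$geno), 3)
  # filtering is idempotent
  fl4 <- filter_markers(fl$geno)
  expect_equal(fl4$geno, fl$geno)
  expect_equal(attr(fl4$report, "n_informative"), ncol(fl$geno))
})

test_that("filtering recodes survivors to minor-allele dosage", {
  g <- matrix(c(2, 2, 1, 1, 0, 2), 3, 2,
              dimnames = list(c("C1", "C2", "C3"), c("M1", "M2")))
  out <- filter_markers(g)$geno
  expect_true(all(colMeans(out) / 2 <= 0.5))
  expect_equal(unname(out[, "M1"]), c(0, 0, 1))  # flipped: freq was 5/6
  expect_equal(unname(out[, "M2"]), c(1, 0, 2))  # tie at 0.5 left as coded
})

test_that("missing_fraction counts masked cells", {
  expect_equal(missing_fraction(toy_geno()), 1 / 20)
  expect_equal(missing_fraction(matrix(1, 2, 2)), 0)
})

test_that("stochastic imputation preserves genotype-class frequencies", {
  # one locus with class probabilities (.25, .5, .25) and many missing draws
  obs <- rep(c(0, 1, 2), times = c(25, 50, 25))
  g <- matrix(c(obs, rep(NA, 10000)), ncol = 1,
              dimnames = list(NULL, "L1"))
  rownames(g) <- sprintf("C%05d", seq_len(nrow(g)))
  imp <- impute_stochastic_frequency(g, seed = 1)
  expect_true(all(imp %in% 0:2))
  counts <- table(factor(imp[-(1:100), 1], levels = 0:2))
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  # observed cells untouched, degenerate locus imputes its only class
  expect_equal(imp[1:100, 1], g[1:100, 1])
  g2 <- matrix(c(1, 1, 1, NA), 4, 1, dimnames = list(NULL, "L"))
  rownames(g2) <- sprintf("C%d", 1:4)
  expect_equal(impute_stochastic_frequency(g2)[4, 1], 1)
  # byte-identical under a fixed seed
  expect_identical(impute_stochastic_frequency(g, seed = 7),
                   impute_stochastic_frequency(g, seed = 7))
  # expected allele frequency unchanged: paired over replicate imputations
  obs_freq <- mean(obs) / 2
  imp_freq <- replicate(200, mean(impute_stochastic_frequency(g, seed = NULL)[, 1]) / 2)
  expect_gt(stats::t.test(imp_freq, mu = obs_freq)$p.value, 0.01)
})

test_that("major-homozygote imputation zero-fills and only that", {
  g <- toy_geno()
  imp <- impute_major_homozygote(g)
  expect_equal(imp[is.na(g)], 0)
  expect_equal(imp[!is.na(g)], g[!is.na(g)])
  expect_identical(impute_major_homozygote(imp), imp)
})

test_that("gene-content imputation matches the GLS oracle", {
  # three individuals: two full sibs and one unrelated, sib 2 missing
  A <- matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  y <- c(2, NA, 0)
  g <- matrix(y, 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  imp <- impute_gene_content(g, A, variant = "truncated")
  expect_equal(unname(imp["b", 1]),
               unname(pmax(pmin(oracle_gene_content(y, A), 2), 0)["b"]),
               tolerance = 1e-8)
  # the prediction leans toward the observed sib, not the plain mean
  expect_gt(imp["b", 1], 1)

  # individual unrelated to everyone -> prediction is the GLS locus mean
  A2 <- diag(3); dimnames(A2) <- dimnames(A)
  g2 <- matrix(c(0, 2, NA), 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  imp2 <- impute_gene_content(g2, A2, variant = "truncated")
  expect_equal(unname(imp2["c", 1]), 1, tolerance = 1e-6)

  # monomorphic-zero locus with one missing -> prediction 0
  g3 <- matrix(c(0, 0, NA), 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  expect_equal(unname(impute_gene_content(g3, A, "truncated")["c", 1]), 0,
               tolerance = 1e-6)

  # clone pair (A_jk = 1): prediction approaches the observed twin's value
  A3 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
               dimnames = dimnames(A))
  g4 <- matrix(c(2, NA, 0), 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  imp4 <- suppressMessages(impute_gene_content(g4, A3, "truncated"))
  expect_lt(abs(imp4["b", 1] - 2), 0.1)
})

test_that("gene-content variants keep values in range and observed cells fixed", {
  sim <- simulate_trial(small_cfg(), seed = 21)
  cl <- names(sim$families)
  A <- amatrix(sim$ped)[cl, cl]
  g <- filter_markers(sim$geno)$geno
  for (v in c("scaled", "truncated")) {
    imp <- impute_gene_content(g, A, variant = v)
    expect_false(anyNA(imp))
    expect_true(all(imp >= 0 & imp <= 2))
    expect_equal(imp[!is.na(g)], g[!is.na(g)])
  }
})

test_that("all imputation methods agree on a complete matrix", {
  sim <- simulate_trial(small_cfg(missing_rate = 0), seed = 22)
  g <- filter_markers(sim$geno)$geno
  A <- amatrix(sim$ped)[rownames(g), rownames(g)]
  expect_identical(impute_major_homozygote(g), g)
  expect_identical(impute_stochastic_frequency(g, seed = 1), g)
  expect_identical(impute_gene_content(g, A, "truncated"), g)
})
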