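#' Reliability-based accuracy of a predicted breeding value
#'
#' \deqn{r = \sqrt{1 - SE^2 / ((1 + f)\,\sigma^2_a)}}
#' where `SE` is the prediction standard error (square root of the
#' prediction-error variance), `f` the inbreeding coefficient of the
#' individual (from the diagonal of the relationship matrix used in the fit),
#' and `sigma2_a` the additive variance. Numerical overshoot
#' (`SE^2 > (1+f) sigma2_a`) is clamped to accuracy 0 with a warning.
#'
#' @param se prediction standard error(s), `>= 0`.
#' @param f inbreeding coefficient(s), recycled.
#' @param sigma2_a additive genetic variance, `> 0`.
#' @return Accuracy in `[0, 1]`, vectorized over `se`.
#' @examples
#' accuracy_from_se(0, 0, 1)               # 1
#' accuracy_from_se(sqrt(0.5), 0, 1)       # sqrt(0.5)
#' @export
accuracy_from_se <- function(se, f = 0, sigma2_a) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  if (any(se < 0)) stop("se must be non-negative")
  rel <- 1 - se^2 / ((1 + f) * sigma2_a)
  if (any(rel < -1e-8))
    warning("SE^2 exceeds (1 + f) * sigma2_a for some clones; accuracy set to 0")
  sqrt(pmin(1, pmax(0, rel)))
}

.new_blup_fit <- function(clone_levels, u, se, f, vc, fixef, method) {
  bv <- data.frame(clone_id = clone_levels, method = method,
                   value = unname(u), se = unname(se),
                   accuracy = accuracy_from_se(se, f, vc$sigma2_a),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(bv = bv, fixef = fixef, vc = vc, method = method),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d clones, mean SE %.4g, mean accuracy %.3f\n",
              x$method, nrow(x$bv), mean(x$bv$se), mean(x$bv$accuracy)))
  invisible(x)
}

#' BLUP of clone breeding values from the mixed-model equations
#'
#' Solves Henderson's mixed-model equations for the clone-level model
#' `y = Xb + Zu + e` with `Var(u) = K sigma2_a`: the pedigree matrix `A`
#' yields traditional ABLUP, a genomic matrix `G` yields GBLUP, and the
#' identity yields phenotype-only (no-relationship) predictions. Clones
#' present in `K` without phenotype records are predicted through their
#' relationships (with `K = A`, unphenotyped full sibs all receive the
#' mid-parent value). Prediction-error variances come from the random-effect
#' block of the inverse coefficient matrix; accuracies use
#' [accuracy_from_se()] with `f = diag(K) - 1`.
#'
#' @param pheno phenotype table (`clone_id`, `site_id`, `volume`).
#' @param K labeled relationship matrix; its row order defines the output
#'   order.
#' @param vc variance components from [fit_reml()], or `NULL` to estimate
#'   them first.
#' @param method label stored with the predictions (e.g. `"EBV1"`, `"EBV2"`,
#'   `"GEBVb"`).
#' @return A `blup_fit`: `bv` data frame (`clone_id`, `method`, `value`,
#'   `se`, `accuracy`), fixed-effect estimates, and the variance components.
#' @export
solve_blup <- function(pheno, K, vc = NULL, method = "EBV") {
  .check_square_labeled(K, "K")
  if (is.null(vc)) vc <- fit_reml(pheno, K)
  d <- .mm_design(pheno, rownames(K))
  parts <- .mm_parts(d)
  Kinv <- .chol_inv_checked(K)$inv
  ms <- .mm_solve(parts, Kinv, vc$lambda)
  Minv <- chol2inv(ms$R)
  u <- ms$sol[parts$p + seq_len(parts$q)]
  pev <- vc$sigma2_e * diag(Minv)[parts$p + seq_len(parts$q)]
  se <- sqrt(pmax(pev, 0))
  b <- ms$sol[seq_len(parts$p)]
  names(b) <- colnames(d$X)
  names(u) <- rownames(K)
  fit <- .new_blup_fit(rownames(K), u, se, diag(K) - 1, vc, b, method)
  fit$design <- list(p = parts$p, q = parts$q)
  fit
}

#' GBLUP by the selection-index equations on adjusted clone means
#'
#' Estimates fixed effects from the tree-level mixed-model equations, adjusts
#' records to `y - X b_hat`, averages them per clone, and predicts genetic
#' merit as \deqn{\hat u = G\,[G + R\lambda]^{-1} (\bar y_{adj})}
#' with `lambda = sigma2_e / sigma2_a` and `R = diag(1 / n_i)` reflecting the
#' ramet count behind each clone mean. Clones without phenotypes are
#' predicted through the index weights on their relatives. With fixed effects
#' taken from the same generalized-least-squares fit, these predictions are
#' algebraically identical to the mixed-model-equation form of GBLUP.
#' Prediction-error variances use the index identity
#' `PEV = sigma2_a * diag(G - G [G + R lambda]^{-1} G)` (fixed effects
#' treated as known).
#'
#' @param pheno phenotype table.
#' @param G genomic relationship matrix (must be invertible in combination
#'   with `R lambda`).
#' @param vc variance components ([fit_reml()] with `K = G`), or `NULL`.
#' @param method prediction label, default `"GEBVa"`.
#' @return A `blup_fit` over all clones in `G`.
#' @export
gblup_selection_index <- function(pheno, G, vc = NULL, method = "GEBVa") {
  .check_square_labeled(G, "G")
  if (is.null(vc)) vc <- fit_reml(pheno, G)
  d <- .mm_design(pheno, rownames(G))
  parts <- .mm_parts(d)
  ms <- .mm_solve(parts, .chol_inv_checked(G)$inv, vc$lambda)
  b <- ms$sol[seq_len(parts$p)]
  adj <- d$y - drop(d$X %*% b)
  obs <- which(parts$nii > 0L)
  ybar <- rowsum(adj, group = d$clone)[, 1L]
  ybar <- ybar / parts$nii[obs]   # rowsum keeps only observed clone rows
  S <- G[obs, obs, drop = FALSE] +
    vc$lambda * diag(1 / parts$nii[obs], length(obs))
  Sinv_y <- solve(S, ybar)
  u <- drop(G[, obs, drop = FALSE] %*% Sinv_y)
  TT <- solve(S, t(G[, obs, drop = FALSE]))
  pev <- vc$sigma2_a * (diag(G) - rowSums(G[, obs, drop = FALSE] * t(TT)))
  se <- sqrt(pmax(pev, 0))
  names(b) <- colnames(d$X)
  .new_blup_fit(rownames(G), u, se, diag(G) - 1, vc, b, method)
}

#' GBLUP through the mixed-model equations
#'
#' The mixed-model-equation form
#' \deqn{\hat u = [R^{-1} + G^{-1}\lambda]^{-1} R^{-1} (y - X\hat b)}
#' solved jointly with the fixed effects on tree-level records; requires
#' `G` to be invertible (blend with `A` if it is not) and is the efficient
#' route when `G^{-1}` is available. Identical to [solve_blup()] with
#' `K = G`; provided as the genomic entry point with its own default label.
#'
#' @param pheno phenotype table.
#' @param G invertible genomic relationship matrix.
#' @param vc variance components, or `NULL` to estimate.
#' @param method prediction label, default `"GEBVb"`.
#' @return A `blup_fit` over all clones in `G`.
#' @export
gblup_mme <- function(pheno, G, vc = NULL, method = "GEBVb") {
  solve_blup(pheno, G, vc = vc, method = method)
}
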