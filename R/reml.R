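# Clone-level linear mixed model -----------------------------------------
#
#   y = X b + Z u + e,   Var(u) = K s2a,  Var(e) = I s2e
#
# y are tree-level records, X holds site fixed effects (intercept + site
# contrasts), Z maps trees to clones, and K is a relationship matrix (A, G,
# or identity). Everything below works off the mixed-model equations
#
#   [ X'X        X'Z        ] [b]   [X'y]
#   [ Z'X   Z'Z + lambda K^-1] [u] = [Z'y],     lambda = s2e / s2a,
#
# whose coefficient matrix is only (n_sites + n_clones) square regardless of
# the number of trees.

.mm_design <- function(pheno, clone_levels) {
  need <- c("clone_id", "site_id", "volume")
  if (!all(need %in% names(pheno)))
    stop("phenotypes must have columns: ", paste(need, collapse = ", "))
  if (nrow(pheno) < 2L) stop("need at least two phenotype records")
  site <- droplevels(factor(pheno$site_id))
  X <- if (nlevels(site) > 1L)
    stats::model.matrix(~site)
  else matrix(1, nrow(pheno), 1L, dimnames = list(NULL, "(Intercept)"))
  cl <- factor(pheno$clone_id, levels = clone_levels)
  if (anyNA(cl))
    stop("phenotyped clones absent from relationship matrix: ",
         paste(unique(pheno$clone_id[is.na(cl)]), collapse = ", "))
  list(X = X, clone = as.integer(cl), y = as.numeric(pheno$volume),
       n = nrow(pheno), p = ncol(X), q = length(clone_levels),
       clone_levels = clone_levels)
}

.mm_parts <- function(d) {
  sm <- rowsum(cbind(d$X, d$y), group = d$clone)
  idx <- as.integer(rownames(sm))
  ZtX <- matrix(0, d$q, d$p)
  ZtX[idx, ] <- sm[, seq_len(d$p), drop = FALSE]
  Zty <- numeric(d$q)
  Zty[idx] <- sm[, d$p + 1L]
  list(XtX = crossprod(d$X), Xty = drop(crossprod(d$X, d$y)),
       ZtX = ZtX, Zty = Zty, nii = tabulate(d$clone, d$q),
       yty = sum(d$y^2), n = d$n, p = d$p, q = d$q)
}

# solve the MME at a given lambda; returns solutions, Cholesky log-det,
# and the residual quadratic form y'Py * s2e = y'y - [b u]'rhs
.mm_solve <- function(parts, Kinv, lambda) {
  p <- parts$p; q <- parts$q
  M <- matrix(0, p + q, p + q)
  M[seq_len(p), seq_len(p)] <- parts$XtX
  M[seq_len(p), p + seq_len(q)] <- t(parts$ZtX)
  M[p + seq_len(q), seq_len(p)] <- parts$ZtX
  M[p + seq_len(q), p + seq_len(q)] <- lambda * Kinv
  dg <- p + seq_len(q)
  M[cbind(dg, dg)] <- M[cbind(dg, dg)] + parts$nii
  rhs <- c(parts$Xty, parts$Zty)
  R <- chol(M)
  sol <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  list(sol = sol, R = R, ldM = 2 * sum(log(diag(R))), rhs = rhs,
       quad = parts$yty - sum(sol * rhs))
}

# invert a relationship matrix, refusing near-singular input (a
# sample-frequency G is exactly singular and must be blended/bent first)
.chol_inv_checked <- function(K) {
  cK <- tryCatch(chol(K), error = function(e)
    stop("K is not positive definite; consider blend_with_A()", call. = FALSE))
  d <- diag(cK)
  if (min(d)^2 < 1e-10 * max(d)^2)
    stop("K is numerically singular; consider blend_with_A()", call. = FALSE)
  list(inv = chol2inv(cK), logdet = 2 * sum(log(d)))
}

# -2 * restricted log-likelihood profiled over s2e, up to a constant:
#   (n-p) (log s2e_hat + 1) - q log lambda + log|K| + log|M(lambda)|
.reml_profile <- function(log_lambda, parts, Kinv, ldK) {
  lambda <- exp(log_lambda)
  ms <- .mm_solve(parts, Kinv, lambda)
  s2e <- max(ms$quad, 1e-300) / (parts$n - parts$p)
  (parts$n - parts$p) * (log(s2e) + 1) - parts$q * log(lambda) + ldK + ms$ldM
}

#' REML variance components for the clone-level mixed model
#'
#' Fits `y = Xb + Zu + e` with `Var(u) = K sigma2_a`, `Var(e) = I sigma2_e`,
#' where `X` carries site fixed effects and `Z` maps trees to clones, by
#' restricted maximum likelihood. The restricted likelihood is profiled down
#' to the single ratio `lambda = sigma2_e / sigma2_a` (the residual variance
#' has a closed form at each `lambda` through the mixed-model equations) and
#' maximized by Brent search on `log(lambda)`, which is deterministic and
#' cannot step outside the positive cone.
#'
#' @param pheno phenotype table (`clone_id`, `site_id`, `volume`).
#' @param K labeled relationship matrix covering all phenotyped clones
#'   (clones present in `K` but unphenotyped are carried and predicted
#'   downstream).
#' @param lambda_interval search interval for `lambda`.
#' @param tol convergence tolerance on `log(lambda)`.
#' @return A `varcomp` list: `sigma2_a`, `sigma2_e`, `lambda`, `neg2ll`
#'   (profiled, up to a constant), and `boundary` flag.
#' @examples
#' sim <- simulate_trial(sim_config(family_sizes = c(10, 10), n_parents = 4,
#'                                  n_families = 2, n_markers = 200,
#'                                  n_sites = 2, ramets_range = c(4, 6)),
#'                       seed = 7)
#' A <- amatrix(sim$ped)
#' cl <- names(sim$families)
#' fit_reml(sim$pheno, A[cl, cl])
#' @export
fit_reml <- function(pheno, K, lambda_interval = c(1e-6, 1e6), tol = 1e-9) {
  .check_square_labeled(K, "K")
  d <- .mm_design(pheno, rownames(K))
  parts <- .mm_parts(d)
  kc <- .chol_inv_checked(K)
  Kinv <- kc$inv
  ldK <- kc$logdet
  opt <- stats::optimize(.reml_profile, interval = log(lambda_interval),
                         parts = parts, Kinv = Kinv, ldK = ldK, tol = tol)
  lambda <- exp(opt$minimum)
  ms <- .mm_solve(parts, Kinv, lambda)
  s2e <- ms$quad / (parts$n - parts$p)
  boundary <- FALSE
  floor_ <- 1e-10
  if (!is.finite(s2e) || s2e < floor_) {
    warning("residual variance at boundary; clamped to ", floor_)
    s2e <- floor_; boundary <- TRUE
  }
  s2a <- s2e / lambda
  if (s2a < floor_) {
    warning("additive variance at boundary; clamped to ", floor_)
    s2a <- floor_; boundary <- TRUE
  }
  edge <- abs(opt$minimum - log(lambda_interval)) < 1e-3
  if (any(edge) && !boundary)
    warning("lambda estimate at search-interval edge (",
            signif(lambda, 4), "); a variance component is near zero")
  structure(list(sigma2_a = s2a, sigma2_e = s2e, lambda = s2e / s2a,
                 neg2ll = opt$objective, boundary = boundary || any(edge)),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_a = %.5g, sigma2_e = %.5g (lambda = %.5g)\n",
              x$sigma2_a, x$sigma2_e, x$lambda))
  invisible(x)
}

#' Marker-level variance implied by the additive variance
#'
#' `sigma2_m = sigma2_a / (2 sum(p (1 - p)))`, the per-marker effect variance
#' consistent with the allele-frequency scaling of the genomic relationship
#' matrix.
#'
#' @param sigma2_a additive genetic variance.
#' @param freqs per-locus allele frequencies.
#' @return Scalar marker variance.
#' @export
marker_variance <- function(sigma2_a, freqs) sigma2_a / (2 * sum(freqs * (1 - freqs)))
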