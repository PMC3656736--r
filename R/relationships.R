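#' Realized genomic relationship matrix, allele-frequency method
#'
#' Centers each marker column at twice its allele frequency,
#' \eqn{Z = M - 2p}, and scales the cross-product by twice the summed marker
#' heterozygosity: \deqn{G = Z Z^\top / \left(2 \sum_i p_i (1 - p_i)\right).}
#' This scaling makes \eqn{G} analogous to the pedigree numerator relationship
#' matrix, so that \eqn{Var(u) = G \sigma^2_a}. Frequencies default to the
#' genotyped sample; base-population frequencies can be supplied instead (they
#' are the theoretically preferred choice when available).
#'
#' @param geno complete (imputed) clones x markers dosage matrix.
#' @param freqs optional per-locus allele frequencies of the coded allele;
#'   defaults to sample frequencies `colMeans(geno) / 2`.
#' @return Symmetric labeled matrix, attribute `flavor = "G_freq"` and
#'   `freq_source` either `"sample"` or `"supplied"`.
#' @export
gmatrix_frequency <- function(geno, freqs = NULL) {
  if (anyNA(geno)) stop("genotype matrix has missing values; impute first")
  supplied <- !is.null(freqs)
  p <- freqs %||% (colMeans(geno) / 2)
  if (length(p) != ncol(geno)) stop("freqs must have one entry per marker")
  if (any(p <= 0 | p >= 1))
    stop("monomorphic locus (allele frequency 0 or 1); filter markers first")
  Z <- sweep(geno, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  attr(G, "flavor") <- "G_freq"
  attr(G, "freq_source") <- if (supplied) "supplied" else "sample"
  G
}

#' Realized genomic relationship matrix, regression method
#'
#' Codes markers as \eqn{M - 1} (values -1, 0, 1 for the two homozygotes and
#' the heterozygote) and regresses the observed similarity matrix
#' \eqn{MM^\top} on the pedigree expectation:
#' \deqn{MM^\top = g_0 \mathbf{1}\mathbf{1}^\top + g_1 A + E,}
#' solving the 2x2 normal equations over all \eqn{n^2} cell pairs (diagonals
#' included). The genomic matrix is then
#' \eqn{G = (MM^\top - \hat g_0 \mathbf{1}\mathbf{1}^\top)/\hat g_1}, whose
#' expectation is \eqn{A} plus a constant; no allele frequencies are needed,
#' the intercept absorbing mean homozygosity.
#'
#' @param geno complete clones x markers dosage matrix.
#' @param A numerator relationship matrix covering (at least) the genotyped
#'   clones.
#' @return Symmetric labeled matrix with attributes `flavor = "G_reg"` and
#'   `regression = c(g0, g1)`. Errors if the fitted slope is not positive;
#'   warns when markers do not outnumber individuals (G likely singular).
#' @export
gmatrix_regression <- function(geno, A) {
  if (anyNA(geno)) stop("genotype matrix has missing values; impute first")
  .check_square_labeled(A, "A")
  ids <- rownames(geno)
  if (is.null(ids) || !all(ids %in% rownames(A)))
    stop("A must cover all genotyped clones")
  if (ncol(geno) <= nrow(geno))
    warning("markers (", ncol(geno), ") do not exceed individuals (",
            nrow(geno), "); G may be singular")
  A <- A[ids, ids]
  W <- tcrossprod(geno - 1)
  fit <- .fit_g_regression(W, A)
  G <- (W - fit[["g0"]]) / fit[["g1"]]
  attr(G, "flavor") <- "G_reg"
  attr(G, "regression") <- fit
  G
}

# least squares of vec(W) on (1, vec(A)) via the 2x2 normal equations
.fit_g_regression <- function(W, A) {
  n2 <- length(A)
  sA <- sum(A); sAA <- sum(A * A)
  sW <- sum(W); sWA <- sum(W * A)
  coefs <- solve(matrix(c(n2, sA, sA, sAA), 2L), c(sW, sWA))
  g <- c(g0 = coefs[1L], g1 = coefs[2L])
  if (g[["g1"]] <= 0)
    stop("regression slope g1 <= 0; markers carry no usable relationship signal")
  g
}

#' Genomic inbreeding coefficients
#'
#' The genomic inbreeding coefficient of individual \eqn{j} is
#' \eqn{G_{jj} - 1}.
#'
#' @param G genomic relationship matrix.
#' @return Named numeric vector.
#' @export
genomic_inbreeding <- function(G) diag(G) - 1

#' Normalize a relationship matrix to correlation form
#'
#' Divides each element \eqn{G_{jk}} by \eqn{\sqrt{G_{jj} G_{kk}}}, giving a
#' unit diagonal.
#'
#' @param G relationship matrix with strictly positive diagonal.
#' @return Normalized matrix (same labels and flavor).
#' @export
normalize_relationships <- function(G) {
  d <- diag(G)
  if (any(d <= 0)) stop("cannot normalize: non-positive diagonal element")
  out <- G / sqrt(outer(d, d))
  attr(out, "flavor") <- attr(G, "flavor")
  out
}
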