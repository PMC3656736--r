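`%||%` <- function(a, b) if (is.null(a)) b else a

# guess tab vs comma from the first line
.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!length(l1)) stop("empty file: ", path)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else "\t"
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

.check_square_labeled <- function(K, what = "relationship matrix") {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop(what, " must be a square matrix")
  if (is.null(rownames(K)) || is.null(colnames(K)))
    stop(what, " must have row and column labels")
  if (max(abs(K - t(K))) > 1e-8 * (1 + max(abs(K))))
    stop(what, " is not symmetric")
  invisible(K)
}

#' Blend a genomic relationship matrix with the pedigree matrix
#'
#' Returns \eqn{(1-w)\,G + w\,A}. A small weight on \eqn{A} removes
#' singularities that arise when markers are limited or individuals share
#' identical genotypes, while leaving the realized relationships essentially
#' unchanged.
#'
#' @param G genomic relationship matrix.
#' @param A numerator relationship matrix on the same individuals (any order;
#'   matched by labels).
#' @param w blending weight in `[0, 1]`; default 0.01.
#' @return Blended matrix with `G`'s labels and flavor.
#' @export
blend_with_A <- function(G, A, w = 0.01) {
  .check_square_labeled(G, "G")
  .check_square_labeled(A, "A")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  ids <- rownames(G)
  if (!all(ids %in% rownames(A)))
    stop("A is missing individuals present in G")
  out <- (1 - w) * G + w * A[ids, ids]
  attr(out, "flavor") <- attr(G, "flavor")
  attr(out, "blend_weight") <- w
  out
}

#' Repair a relationship matrix so it can be inverted
#'
#' Accepts the matrix unchanged when it is well conditioned; otherwise blends
#' it lightly with `A` ([blend_with_A()]), and as a last resort bends the
#' eigenvalues (raising small or negative ones to a floor of `1e-4` times the
#' largest). One of these repairs is routinely needed before REML or GBLUP:
#' a genomic matrix built with sample allele frequencies is always exactly
#' singular (centered marker columns sum to zero, so `G %*% 1 = 0`), and the
#' regression-method G can be indefinite when markers are few relative to
#' individuals.
#'
#' @param K relationship matrix to repair.
#' @param A optional pedigree matrix used for blending.
#' @param w blending weight passed to [blend_with_A()].
#' @param min_rcond smallest acceptable eigenvalue ratio.
#' @return A positive-definite matrix with `K`'s labels and flavor.
#' @export
make_invertible <- function(K, A = NULL, w = 0.01, min_rcond = 1e-8) {
  well <- function(M) {
    e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    e[length(e)] > min_rcond * e[1L]
  }
  if (well(K)) return(K)
  if (!is.null(A)) {
    K2 <- blend_with_A(K, A, w)
    if (well(K2)) return(K2)
    K <- K2
  }
  e <- eigen(K, symmetric = TRUE)
  floor_ <- 1e-4 * max(e$values)
  message("bending relationship matrix: ", sum(e$values < floor_),
          " eigenvalues raised to ", signif(floor_, 3))
  out <- e$vectors %*% (pmax(e$values, floor_) * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(K)
  attr(out, "flavor") <- attr(K, "flavor")
  out
}
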