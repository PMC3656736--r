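#' Per-marker summary statistics
#'
#' Computes, over non-missing calls only: allele frequency of the coded
#' allele, minor-allele frequency, missing fraction, and flags. A marker is
#' monomorphic when its observed allele frequency is 0 or 1 (all individuals
#' carry the same homozygote), including the degenerate all-missing case.
#'
#' @param geno clones x markers dosage matrix (`NA` = missing).
#' @param max_missing missing-fraction threshold used for the high-missing
#'   flag and report totals (default 0.15).
#' @return Data frame (one row per marker: `marker_id`, `freq`, `maf`,
#'   `missing`, `monomorphic`, `high_missing`) with totals in attributes
#'   `n_monomorphic`, `n_high_missing`, `n_informative`. Monomorphic markers
#'   are excluded from the high-missing count, matching the filter order.
#' @export
summarize_markers <- function(geno, max_missing = 0.15) {
  n_obs <- colSums(!is.na(geno))
  freq <- ifelse(n_obs > 0, colMeans(geno, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(freq, 1 - freq)
  miss <- colMeans(is.na(geno))
  mono <- n_obs == 0 | (!is.na(freq) & (freq == 0 | freq == 1))
  high <- !mono & miss > max_missing
  rep <- data.frame(marker_id = colnames(geno) %||% seq_len(ncol(geno)),
                    freq = freq, maf = maf, missing = miss,
                    monomorphic = mono, high_missing = high,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(rep, "max_missing") <- max_missing
  attr(rep, "n_monomorphic") <- sum(mono)
  attr(rep, "n_high_missing") <- sum(high)
  attr(rep, "n_informative") <- ncol(geno) - sum(mono) - sum(high)
  class(rep) <- c("marker_report", "data.frame")
  rep
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Marker report:", nrow(x), "markers\n")
  cat("  monomorphic :", attr(x, "n_monomorphic"), "\n")
  cat("  missing >", attr(x, "max_missing"), ":",
      attr(x, "n_high_missing"), "\n")
  cat("  informative :", attr(x, "n_informative"), "\n")
  invisible(x)
}

#' Filter markers to the informative set
#'
#' Drops monomorphic markers first, then markers whose missing fraction
#' exceeds `max_missing` (strictly), and recodes the survivors to minor-allele
#' dosage (columns with coded-allele frequency above 0.5 are flipped to
#' `2 - dosage`; ties at 0.5 are left as coded in the input).
#'
#' @param geno clones x markers dosage matrix.
#' @param max_missing missing-fraction threshold (default 0.15).
#' @return List with `geno` (filtered, minor-allele coded) and `report`
#'   (the [summarize_markers()] report of the input).
#' @export
filter_markers <- function(geno, max_missing = 0.15) {
  rep <- summarize_markers(geno, max_missing)
  keep <- !rep$monomorphic & !rep$high_missing
  if (!any(keep)) stop("no informative markers remain after filtering")
  out <- geno[, keep, drop = FALSE]
  out <- recode_minor(out)
  list(geno = out, report = rep)
}

#' Recode dosages to count the minor allele
#'
#' @param geno dosage matrix.
#' @return Matrix in which every column has observed allele frequency <= 0.5.
#' @export
recode_minor <- function(geno) {
  freq <- colMeans(geno, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  geno[, flip] <- 2 - geno[, flip, drop = FALSE]
  geno
}

#' Overall missing-call fraction
#' @param geno dosage matrix.
#' @return Proportion of `NA` cells.
#' @export
missing_fraction <- function(geno) mean(is.na(geno))

#' Stochastic imputation from observed genotype-class frequencies
#'
#' Each missing call is drawn from the empirical distribution of the genotype
#' classes (0/1/2 copies of the minor allele) observed at the same locus
#' across all families, so that on average imputation leaves the genotype
#' frequencies unchanged.
#'
#' @param geno dosage matrix with integer observed calls.
#' @param seed integer seed.
#' @return Completed categorical dosage matrix.
#' @export
impute_stochastic_frequency <- function(geno, seed = 1) {
  .with_seed(seed, {
    for (l in which(colSums(is.na(geno)) > 0)) {
      obs <- geno[!is.na(geno[, l]), l]
      if (!length(obs))
        stop("locus ", colnames(geno)[l], " has no observed genotypes")
      miss <- is.na(geno[, l])
      geno[miss, l] <- sample(obs, sum(miss), replace = TRUE)
    }
    geno
  })
}

#' Impute missing calls as the major homozygote
#'
#' Under minor-allele dosage coding the major homozygote carries zero copies
#' of the minor allele, so every missing call becomes 0.
#'
#' @param geno minor-allele dosage matrix.
#' @return Completed matrix with former `NA` cells set to 0.
#' @export
impute_major_homozygote <- function(geno) {
  geno[is.na(geno)] <- 0
  geno
}

#' Gene-content imputation through the relationship matrix
#'
#' Treats the observed gene content at each locus as the response in a mixed
#' model with an overall mean and a random individual effect whose covariance
#' is proportional to the additive relationship matrix `A`: because relatives
#' share alleles identical by descent, the covariance between their genotypes
#' is proportional to their additive relationship. The mixed-model solutions
#' are continuous predicted genotypes for every individual, centered near the
#' locus mean gene content. Predictions can fall outside the feasible `[0, 2]`
#' range, so two post-processing variants are offered:
#' \describe{
#'   \item{`scaled`}{per locus, the solution vector is standardized and mapped
#'     back to the observed scale as
#'     `1 + (x - mean(x)) / sd(x) * sd(observed dosages)`;}
#'   \item{`truncated`}{raw solutions are clipped to `[0, 2]`.}
#' }
#' Only missing cells are replaced; observed calls are never touched.
#'
#' @param geno dosage matrix.
#' @param A additive relationship matrix covering all rows of `geno`.
#' @param variant `"scaled"` or `"truncated"`.
#' @param h2_gene_content heritability of gene content; gene content is
#'   (nearly) fully heritable, so the variance ratio uses 0.99 by default.
#' @return Completed matrix with continuous imputed entries in `[0, 2]`
#'   (truncated) or mean/SD-standardized values (scaled, clipped to `[0, 2]`
#'   only where standardization overshoots the feasible range).
#' @export
impute_gene_content <- function(geno, A, variant = c("scaled", "truncated"),
                                h2_gene_content = 0.99) {
  variant <- match.arg(variant)
  .check_square_labeled(A, "A")
  ids <- rownames(geno)
  if (is.null(ids) || !all(ids %in% rownames(A)))
    stop("A must cover all genotyped individuals")
  A <- A[ids, ids]
  n <- length(ids)
  lambda <- (1 - h2_gene_content) / h2_gene_content
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) {
    message("relationship matrix near-singular; adding a small ridge")
    chol2inv(chol(A + diag(1e-6, n)))
  })
  for (l in which(colSums(is.na(geno)) > 0)) {
    y <- geno[, l]
    obs <- !is.na(y)
    if (!any(obs))
      stop("locus ", colnames(geno)[l], " has no observed genotypes")
    w <- as.numeric(obs)
    yo <- ifelse(obs, y, 0)
    # MME: fixed overall mean + random individual effect with Var = A * s2u
    C <- rbind(c(sum(w), w),
               cbind(w, diag(w) + lambda * Ainv))
    rhs <- c(sum(yo), yo)
    sol <- tryCatch(solve(C, rhs), error = function(e)
      solve(C + diag(1e-8, n + 1L), rhs))
    pred <- sol[1L] + sol[-1L]          # predicted gene content, everyone
    fill <- switch(variant,
      truncated = pmin(2, pmax(0, pred)),
      scaled = {
        s_pred <- stats::sd(pred)
        s_obs <- stats::sd(y[obs])
        x <- if (s_pred > 0 && s_obs > 0)
          1 + (pred - mean(pred)) / s_pred * s_obs
        else pred
        pmin(2, pmax(0, x))
      })
    geno[!obs, l] <- fill[!obs]
  }
  geno
}

#' Compare imputation methods by downstream GBLUP accuracy
#'
#' Runs the full genomic evaluation once per imputation method: impute the
#' masked matrix, build the allele-frequency genomic relationship matrix, fit
#' the clone-level mixed model by REML (or reuse supplied variance
#' components), and report the mean reliability-based accuracy
#' `sqrt(1 - SE^2 / ((1 + f) sigma2_a))` of the genomic breeding values
#' across clones.
#'
#' @param pheno phenotype table (tree_id, clone_id, site_id, volume).
#' @param geno masked dosage matrix (clones x markers).
#' @param A additive relationship matrix (needed by the gene-content methods).
#' @param methods subset of `"stochastic"`, `"major_homozygote"`,
#'   `"gene_content_scaled"`, `"gene_content_truncated"`.
#' @param vc optional variance components reused across methods; `NULL`
#'   re-estimates by REML per method.
#' @param seed seed for the stochastic method.
#' @return Data frame `method`, `mean_accuracy`, `mean_se`.
#' @export
imputation_accuracy_comparison <- function(pheno, geno, A,
                                           methods = c("stochastic",
                                                       "major_homozygote",
                                                       "gene_content_scaled",
                                                       "gene_content_truncated"),
                                           vc = NULL, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  res <- lapply(methods, function(mth) {
    imp <- switch(mth,
      stochastic = impute_stochastic_frequency(geno, seed = seed),
      major_homozygote = impute_major_homozygote(geno),
      gene_content_scaled = impute_gene_content(geno, A, "scaled"),
      gene_content_truncated = impute_gene_content(geno, A, "truncated"))
    G <- gmatrix_frequency(imp)
    G <- make_invertible(G, A)
    fit <- gblup_mme(pheno, G, vc = vc)
    data.frame(method = mth,
               mean_accuracy = mean(fit$bv$accuracy),
               mean_se = mean(fit$bv$se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
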