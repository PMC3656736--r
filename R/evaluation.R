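#' Phenotype-only breeding values (EBV1)
#'
#' BLUP with an identity relationship matrix over clones: predictions use
#' only the clonal replication (ramets) of each genotype, with no pedigree
#' information, so family structure cannot bias them. With ample clonal
#' replication these serve as the reference standard ("true" breeding
#' values) against which cross-validated predictions are correlated.
#'
#' @param pheno phenotype table.
#' @param vc variance components, or `NULL` to estimate by REML under the
#'   identity relationship.
#' @return A `blup_fit` labeled `EBV1` over all phenotyped clones.
#' @export
compute_ebv1 <- function(pheno, vc = NULL) {
  clones <- sort(unique(pheno$clone_id))
  I <- diag(1, length(clones))
  dimnames(I) <- list(clones, clones)
  solve_blup(pheno, I, vc = vc, method = "EBV1")
}

#' Pedigree breeding values with validation phenotypes withheld (EBV2)
#'
#' Traditional ABLUP in which every phenotype record of the validation clones
#' is removed before fitting; their predictions come purely through the
#' numerator relationship matrix. Unphenotyped full sibs therefore all
#' receive the mid-parent value: the pedigree cannot see Mendelian sampling.
#'
#' @param pheno phenotype table.
#' @param A numerator relationship matrix covering all clones to predict.
#' @param validation character vector of clone ids whose phenotypes are
#'   withheld (may be empty).
#' @param vc variance components, or `NULL` to estimate on the training
#'   records.
#' @return A `blup_fit` labeled `EBV2` over all clones in `A`.
#' @export
compute_ebv2 <- function(pheno, A, validation = character(), vc = NULL) {
  train <- pheno[!pheno$clone_id %in% validation, , drop = FALSE]
  solve_blup(train, A, vc = vc, method = "EBV2")
}

#' Genomic breeding values with validation phenotypes withheld (GEBV)
#'
#' GBLUP with the validation clones' records removed; predictions for them
#' flow through the realized genomic relationships, which capture Mendelian
#' sampling and so separate full sibs even without phenotypes. Either solver
#' path can be paired with either G matrix; conventionally the
#' allele-frequency G is run through the selection-index path (`GEBVa`) and
#' the regression G through the mixed-model-equation path (`GEBVb`).
#'
#' @param pheno phenotype table.
#' @param G genomic relationship matrix.
#' @param validation clone ids whose phenotypes are withheld.
#' @param method `"selection_index"` or `"mme"`.
#' @param vc variance components, or `NULL` to estimate on training records.
#' @param label prediction label; defaults to `GEBVa` for the
#'   selection-index path and `GEBVb` for the MME path.
#' @return A `blup_fit` over all clones in `G`.
#' @export
compute_gebv <- function(pheno, G, validation = character(),
                         method = c("selection_index", "mme"),
                         vc = NULL, label = NULL) {
  method <- match.arg(method)
  train <- pheno[!pheno$clone_id %in% validation, , drop = FALSE]
  if (method == "selection_index")
    gblup_selection_index(train, G, vc = vc, label %||% "GEBVa")
  else
    gblup_mme(train, G, vc = vc, label %||% "GEBVb")
}

#' Build cross-validation partitions
#'
#' Splits clones into training and validation sets, either within each
#' full-sib family (the stated validation fraction sampled from every family
#' independently) or at random from the whole population. The `train90`
#' scenario holds out ~10% of clones, `train50` ~50%. Per-family counts are
#' rounded half-up with at least one clone on each side whenever the family
#' has two or more members. Replicates redraw partitions with seeds
#' `seed + replicate`.
#'
#' @param families named character vector mapping clone id -> family id.
#' @param scenario `"train90"` or `"train50"`.
#' @param stratification `"within_family"` or `"random"`.
#' @param n_replicates number of independent partitions (default 6).
#' @param seed base integer seed.
#' @return A `cv_scheme`: list with the settings and `replicates`, each a
#'   list of `training` and `validation` clone-id vectors.
#' @export
make_cv_scheme <- function(families, scenario = c("train90", "train50"),
                           stratification = c("within_family", "random"),
                           n_replicates = 6, seed = 1) {
  scenario <- match.arg(scenario)
  stratification <- match.arg(stratification)
  frac_val <- if (scenario == "train90") 0.10 else 0.50
  clones <- names(families)
  if (is.null(clones)) stop("families must be a named vector (clone -> family)")
  reps <- lapply(seq_len(n_replicates), function(r) {
    .with_seed(seed + r, {
      val <- if (stratification == "within_family") {
        unlist(lapply(split(clones, families), function(cl) {
          k <- floor(frac_val * length(cl) + 0.5)
          if (length(cl) >= 2L) k <- min(max(k, 1L), length(cl) - 1L)
          else k <- 0L
          if (k > 0L) sample(cl, k) else character()
        }), use.names = FALSE)
      } else {
        sample(clones, floor(frac_val * length(clones) + 0.5))
      }
      if (!length(val) || length(val) == length(clones))
        stop("degenerate partition: validation fraction leaves no training or no validation clones")
      list(training = setdiff(clones, val), validation = sort(val))
    })
  })
  structure(list(scenario = scenario, stratification = stratification,
                 n_replicates = n_replicates, seed = seed,
                 replicates = reps),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  nv <- lengths(lapply(x$replicates, `[[`, "validation"))
  cat(sprintf("CV scheme %s / %s: %d replicates, %s validation clones\n",
              x$scenario, x$stratification, x$n_replicates,
              paste(unique(nv), collapse = "/")))
  invisible(x)
}

#' Run the cross-validation comparison of genomic and pedigree predictions
#'
#' For each replicate partition: variance components are re-estimated on the
#' training records for each relationship matrix, EBV2 (pedigree, validation
#' phenotypes withheld) and GEBVa / GEBVb (genomic, same withholding) are
#' computed, and the validation-clone predictions are correlated
#' (product-moment) with the full-data phenotype-only standard EBV1 and with
#' EBV2. Mean prediction SEs per method are averaged over the validation
#' clones and replicates.
#'
#' @param pheno phenotype table for all clones.
#' @param A numerator relationship matrix.
#' @param G_freq allele-frequency genomic relationship matrix (GEBVa path).
#' @param G_reg regression genomic relationship matrix (GEBVb path).
#' @param scheme a [make_cv_scheme()] partition set.
#' @param reestimate_vc re-fit REML per training set (default `TRUE`); if
#'   `FALSE`, `vc` must supply components reused everywhere.
#' @param vc optional fixed variance components (used when
#'   `reestimate_vc = FALSE`, and always for EBV1).
#' @return A `cv_report`: `replicates` (per-replicate correlations and mean
#'   SEs), `summary` (replicate means), plus the full-data `ebv1` fit.
#' @export
run_cross_validation <- function(pheno, A, G_freq, G_reg, scheme,
                                 reestimate_vc = TRUE, vc = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  ebv1 <- compute_ebv1(pheno, vc = vc)
  ref1 <- stats::setNames(ebv1$bv$value, ebv1$bv$clone_id)
  rows <- lapply(seq_along(scheme$replicates), function(r) {
    part <- scheme$replicates[[r]]
    val <- part$validation
    if (length(val) < 3L) {
      warning("replicate ", r, " has fewer than 3 validation clones; skipped")
      return(NULL)
    }
    train_ph <- pheno[!pheno$clone_id %in% val, , drop = FALSE]
    vcA <- if (reestimate_vc) fit_reml(train_ph, A) else vc
    vcGa <- if (reestimate_vc) fit_reml(train_ph, G_freq) else vc
    vcGb <- if (reestimate_vc) fit_reml(train_ph, G_reg) else vc
    ebv2 <- compute_ebv2(pheno, A, val, vc = vcA)
    geba <- compute_gebv(pheno, G_freq, val, "selection_index", vc = vcGa)
    gebb <- compute_gebv(pheno, G_reg, val, "mme", vc = vcGb)
    pick <- function(fit) stats::setNames(fit$bv$value, fit$bv$clone_id)[val]
    pse <- function(fit) mean(fit$bv$se[fit$bv$clone_id %in% val])
    e2 <- pick(ebv2); ga <- pick(geba); gb <- pick(gebb); e1 <- ref1[val]
    data.frame(replicate = r,
               n_validation = length(val),
               r_GEBVa_EBV1 = stats::cor(ga, e1),
               r_GEBVb_EBV1 = stats::cor(gb, e1),
               r_GEBVa_EBV2 = stats::cor(ga, e2),
               r_GEBVb_EBV2 = stats::cor(gb, e2),
               se_EBV2 = pse(ebv2), se_GEBVa = pse(geba), se_GEBVb = pse(gebb))
  })
  reps <- do.call(rbind, rows)
  if (is.null(reps) || !nrow(reps)) stop("no usable cross-validation replicates")
  summ <- colMeans(reps[, setdiff(names(reps), "replicate"), drop = FALSE])
  structure(list(scenario = scheme$scenario,
                 stratification = scheme$stratification,
                 replicates = reps, summary = summ, ebv1 = ebv1),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %s), %d replicates:\n",
              x$scenario, x$stratification, nrow(x$replicates)))
  print(round(x$summary, 3))
  invisible(x)
}

#' Paired prediction table for scatter plots
#'
#' Merges two breeding-value sets by clone and reports their product-moment
#' correlation, for external plotting of e.g. pedigree vs genomic
#' predictions, optionally keyed by full-sib family.
#'
#' @param bv_x,bv_y `blup_fit` objects or their `$bv` data frames.
#' @param families optional named vector clone -> family added as a column.
#' @return Data frame `clone_id`, `family`, `x`, `y` with attribute `r` (the
#'   correlation) and the two method labels.
#' @export
scatter_pairs <- function(bv_x, bv_y, families = NULL) {
  bx <- if (inherits(bv_x, "blup_fit")) bv_x$bv else bv_x
  by <- if (inherits(bv_y, "blup_fit")) bv_y$bv else bv_y
  m <- merge(bx[, c("clone_id", "value")], by[, c("clone_id", "value")],
             by = "clone_id", suffixes = c("_x", "_y"))
  out <- data.frame(clone_id = m$clone_id,
                    family = if (is.null(families)) NA_character_
                             else unname(families[m$clone_id]),
                    x = m$value_x, y = m$value_y,
                    stringsAsFactors = FALSE)
  attr(out, "r") <- stats::cor(out$x, out$y)
  attr(out, "methods") <- c(x = bx$method[1], y = by$method[1])
  out
}
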