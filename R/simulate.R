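#' Simulation settings for a clonally replicated full-sib trial
#'
#' The defaults emulate the design of a cloned loblolly pine progeny test:
#' 13 parents crossed into 9 full-sib families (several sharing a parent),
#' family sizes between 3 and 37 progeny summing to 165 clones, 3461
#' informative unlinked SNP loci, clones field-tested with 16-50 ramets spread
#' over 16 sites (~6250 trees), and 1.2% missing genotype calls. Raw-marker
#' mode additionally plants 1700 monomorphic and 218 high-missingness loci so
#' that the 5379 -> 3461 marker filtering pathway can be exercised.
#'
#' `h2` is the individual-tree (single-ramet) narrow-sense heritability; the
#' residual variance is derived as `sigma2_a * (1 - h2) / h2` (the default
#' pairing `sigma2_a = 1`, `h2 = 0.25` gives `sigma2_e = 3`, typical of a
#' growth trait of low heritability).
#'
#' @param n_parents number of founder parents.
#' @param n_families number of full-sib crosses.
#' @param family_sizes integer vector of progeny counts per family; `NULL`
#'   spreads `n_progeny` as evenly as the range allows.
#' @param n_progeny total cloned progeny (used when `family_sizes` is `NULL`).
#' @param share_parents if `TRUE`, some crosses share a common parent.
#' @param n_markers number of informative SNP loci.
#' @param maf_range founder minor-allele frequency range (uniform draw).
#' @param n_sites number of test sites (fixed effects).
#' @param ramets_range range of ramets per clone (uniform integer draw),
#'   allocated as evenly as possible across sites.
#' @param sigma2_a additive genetic variance of the simulated trait.
#' @param h2 individual-tree heritability target in (0, 1).
#' @param site_sd standard deviation of fixed site effects.
#' @param missing_rate fraction of genotype calls masked at random.
#' @param n_monomorphic,n_high_missing raw-mode counts of planted monomorphic
#'   and high-missingness loci.
#' @param high_missing_rate_range per-locus missing fraction range used for
#'   planted high-missingness loci (must exceed the QC threshold 0.15).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_parents = 13, n_families = 9,
                       family_sizes = c(3, 8, 12, 15, 18, 20, 25, 27, 37),
                       n_progeny = 165, share_parents = TRUE,
                       n_markers = 3461, maf_range = c(0.05, 0.5),
                       n_sites = 16, ramets_range = c(16, 50),
                       sigma2_a = 1, h2 = 0.25, site_sd = 1,
                       missing_rate = 0.012,
                       n_monomorphic = 1700, n_high_missing = 218,
                       high_missing_rate_range = c(0.16, 0.40)) {
  if (is.null(family_sizes)) {
    base <- rep(n_progeny %/% n_families, n_families)
    extra <- n_progeny - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    family_sizes <- base
  }
  if (length(family_sizes) != n_families)
    stop("family_sizes must have length n_families")
  cfg <- list(n_parents = n_parents, n_families = n_families,
              family_sizes = as.integer(family_sizes),
              share_parents = share_parents,
              n_markers = n_markers, maf_range = maf_range,
              n_sites = n_sites, ramets_range = as.integer(ramets_range),
              sigma2_a = sigma2_a, h2 = h2, site_sd = site_sd,
              missing_rate = missing_rate,
              n_monomorphic = n_monomorphic, n_high_missing = n_high_missing,
              high_missing_rate_range = high_missing_rate_range)
  stopifnot(n_parents >= 2, n_families >= 1, all(cfg$family_sizes > 0),
            n_markers >= 1, n_sites >= 1,
            ramets_range[1] >= 1, ramets_range[2] >= ramets_range[1],
            sigma2_a > 0, h2 > 0, h2 < 1,
            missing_rate >= 0, missing_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-parent full-sib mating pedigree
#'
#' Parents are founders; each family is a full-sib cross between two parents.
#' With `share_parents = TRUE` (default) some crosses reuse a parent, so that
#' families are genetically connected, as in structured breeding populations.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A pedigree with an extra `family` column (`NA` for founders).
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = 1) {
  .with_seed(seed, {
    np <- cfg$n_parents; nf <- cfg$n_families
    if (!cfg$share_parents && 2L * nf > np)
      stop("need at least 2*n_families parents for disjoint crosses")
    pairs <- .mating_pairs(np, nf, cfg$share_parents)
    parents <- sprintf("P%02d", seq_len(np))
    n_off <- sum(cfg$family_sizes)
    off <- sprintf("C%03d", seq_len(n_off))
    fam <- rep(sprintf("F%d", seq_len(nf)), cfg$family_sizes)
    sire <- parents[pairs[rep(seq_len(nf), cfg$family_sizes), 1L]]
    dam  <- parents[pairs[rep(seq_len(nf), cfg$family_sizes), 2L]]
    df <- data.frame(
      id = c(parents, off),
      sire = c(rep(NA_character_, np), sire),
      dam  = c(rep(NA_character_, np), dam),
      family = c(rep(NA_character_, np), fam),
      stringsAsFactors = FALSE)
    as_pedigree(df)
  })
}

# cross pairs: disjoint single-pair matings first, then crosses reusing
# already-used parents so families share a common male or female parent
.mating_pairs <- function(np, nf, share) {
  if (!share) return(cbind(seq(1, 2 * nf, by = 2), seq(2, 2 * nf, by = 2)))
  n_disjoint <- min(nf, np %/% 2L)
  pairs <- cbind(seq_len(n_disjoint) * 2L - 1L, seq_len(n_disjoint) * 2L)
  extra <- nf - n_disjoint
  spare <- setdiff(seq_len(np), as.vector(pairs))
  k <- 0L
  while (extra > 0L) {
    k <- k + 1L
    p1 <- pairs[(k - 1L) %% n_disjoint + 1L, 1L]
    p2 <- if (length(spare)) spare[1L] else pairs[k %% n_disjoint + 1L, 2L]
    spare <- setdiff(spare, p2)
    pairs <- rbind(pairs, c(p1, p2))
    extra <- extra - 1L
  }
  if (nrow(pairs) > nf) pairs <- pairs[seq_len(nf), , drop = FALSE]
  # guarantee at least one shared parent when asked for
  if (anyDuplicated(as.vector(pairs)) == 0L && nf >= 2L)
    pairs[nf, 1L] <- pairs[1L, 1L]
  pairs
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' Founder genotypes are drawn `Binomial(2, p_i)` per locus with founder minor
#' allele frequencies uniform on `cfg$maf_range`; every offspring receives one
#' allele from each parent by fair Mendelian sampling. Loci are unlinked (no
#' linkage map), so marker covariances between relatives arise solely from
#' pedigree structure, matching populations where linkage disequilibrium is
#' low.
#'
#' @param ped a pedigree.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return Dosage matrix (all pedigree individuals x markers) with founder
#'   minor-allele frequencies in attribute `founder_maf`.
#' @export
simulate_genotypes <- function(ped, cfg = sim_config(), seed = 1) {
  .with_seed(seed, {
    id <- ped$id
    n <- length(id); m <- cfg$n_markers
    si <- match(ped$sire, id); di <- match(ped$dam, id)
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    G <- matrix(NA_real_, n, m, dimnames = list(id, sprintf("M%05d", seq_len(m))))
    gamete <- function(g) (g == 2) + (g == 1) * stats::rbinom(length(g), 1L, 0.5)
    for (j in seq_len(n)) {
      G[j, ] <- if (is.na(si[j]) || is.na(di[j]))
        stats::rbinom(m, 2L, p)
      else
        gamete(G[si[j], ]) + gamete(G[di[j], ])
    }
    attr(G, "founder_maf") <- p
    G
  })
}

#' Simulate clonally replicated phenotypes under an additive marker model
#'
#' Marker effects are drawn i.i.d. normal with variance
#' `sigma2_a / (2 * sum(p * (1 - p)))` so that true breeding values
#' `TBV_j = sum_i (z_ij - 2 p_i) a_i` (centered dosages) have additive
#' variance `sigma2_a` in the founder population. Each tree record is
#' `site effect + TBV(clone) + N(0, sigma2_e)` with
#' `sigma2_e = sigma2_a (1 - h2) / h2`; site effects are fixed, drawn once.
#'
#' @param ped pedigree with a `family` column for progeny.
#' @param geno dosage matrix from [simulate_genotypes()] (must carry
#'   `founder_maf`).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `pheno` (tree_id, clone_id, site_id, volume) and `truth`
#'   (true breeding values, marker effects, variance components, site
#'   effects).
#' @export
simulate_phenotypes <- function(ped, geno, cfg = sim_config(), seed = 1) {
  .with_seed(seed, {
    p <- attr(geno, "founder_maf")
    if (is.null(p)) stop("geno must carry founder_maf (see simulate_genotypes)")
    clones <- ped$id[!is.na(ped$family)]
    if (!length(clones)) clones <- ped$id  # founder-only designs
    Zc <- sweep(geno[clones, , drop = FALSE], 2, 2 * p)
    sigma2_e <- cfg$sigma2_a * (1 - cfg$h2) / cfg$h2
    a <- stats::rnorm(ncol(geno), 0, sqrt(cfg$sigma2_a / (2 * sum(p * (1 - p)))))
    tbv <- drop(Zc %*% a)
    names(tbv) <- clones
    site_eff <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
    names(site_eff) <- sprintf("S%02d", seq_len(cfg$n_sites))
    nr <- sample(seq(cfg$ramets_range[1], cfg$ramets_range[2]),
                 length(clones), replace = TRUE)
    rows <- vector("list", length(clones))
    for (j in seq_along(clones)) {
      sites <- rep(sample(cfg$n_sites), length.out = nr[j])
      rows[[j]] <- data.frame(
        clone_id = clones[j],
        site_id = names(site_eff)[sites],
        volume = site_eff[sites] + tbv[j] +
          stats::rnorm(nr[j], 0, sqrt(sigma2_e)),
        stringsAsFactors = FALSE)
    }
    pheno <- do.call(rbind, rows)
    pheno <- data.frame(tree_id = sprintf("T%05d", seq_len(nrow(pheno))),
                        pheno, stringsAsFactors = FALSE)
    rownames(pheno) <- NULL
    list(pheno = pheno,
         truth = list(tbv = tbv, marker_effects = a,
                      sigma2_a = cfg$sigma2_a, sigma2_e = sigma2_e,
                      site_effects = site_eff))
  })
}

#' Mask genotype calls at random
#'
#' @param geno dosage matrix.
#' @param rate fraction of cells set to `NA`, in `[0, 1)`.
#' @param seed integer seed.
#' @return The matrix with `NA` in the masked cells (attributes preserved).
#' @export
mask_genotypes <- function(geno, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(geno)
  .with_seed(seed, {
    idx <- which(stats::runif(length(geno)) < rate)
    geno[idx] <- NA_real_
    geno
  })
}

#' Plant raw (uninformative) marker columns for QC testing
#'
#' Appends `n_monomorphic` constant homozygous loci and `n_high_missing`
#' polymorphic loci whose missing fraction exceeds the QC threshold, then
#' shuffles column order, reproducing the raw marker panel structure in which
#' only a subset of assayed loci is informative.
#'
#' @param geno informative dosage matrix (clones x markers).
#' @param cfg a [sim_config()] (uses `n_monomorphic`, `n_high_missing`,
#'   `maf_range`, `high_missing_rate_range`).
#' @param seed integer seed.
#' @return Dosage matrix with `ncol(geno) + n_monomorphic + n_high_missing`
#'   columns.
#' @export
add_raw_markers <- function(geno, cfg = sim_config(), seed = 1) {
  .with_seed(seed, {
    n <- nrow(geno)
    mono <- matrix(rep(sample(c(0, 2), cfg$n_monomorphic, replace = TRUE,
                              prob = c(0.8, 0.2)), each = n),
                   n, cfg$n_monomorphic,
                   dimnames = list(rownames(geno),
                                   sprintf("MONO%05d", seq_len(cfg$n_monomorphic))))
    hm <- matrix(NA_real_, n, cfg$n_high_missing,
                 dimnames = list(rownames(geno),
                                 sprintf("HIMI%05d", seq_len(cfg$n_high_missing))))
    for (l in seq_len(cfg$n_high_missing)) {
      repeat {
        p <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
        g <- stats::rbinom(n, 2L, p)
        fr <- stats::runif(1, cfg$high_missing_rate_range[1],
                           cfg$high_missing_rate_range[2])
        n_miss <- max(ceiling(fr * n), floor(0.15 * n) + 1L)
        g[sample(n, n_miss)] <- NA_real_
        af <- mean(g, na.rm = TRUE) / 2
        if (af > 0 && af < 1) break  # must stay polymorphic among observed
      }
      hm[, l] <- g
    }
    out <- cbind(geno, mono, hm)
    out <- out[, sample(ncol(out)), drop = FALSE]
    attr(out, "founder_maf") <- NULL
    out
  })
}

#' Simulate a complete clonal progeny-trial dataset
#'
#' One call produces everything the evaluation pipeline consumes: pedigree,
#' true and masked genotype matrices for the cloned progeny, the clonally
#' replicated phenotype table, and the simulation truth.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (sub-stages use offsets of it).
#' @param raw_markers also generate the raw marker panel (informative +
#'   planted monomorphic and high-missingness loci) as `geno_raw`.
#' @return List: `ped`, `geno` (masked, clones only), `geno_true` (complete),
#'   `geno_raw` (optional), `pheno`, `truth`, `founder_maf`, `families`
#'   (named vector clone -> family).
#' @export
simulate_trial <- function(cfg = sim_config(), seed = 1, raw_markers = FALSE) {
  ped <- simulate_pedigree(cfg, seed)
  g_all <- simulate_genotypes(ped, cfg, seed + 1L)
  ph <- simulate_phenotypes(ped, g_all, cfg, seed + 2L)
  clones <- ped$id[!is.na(ped$family)]
  geno_true <- g_all[clones, , drop = FALSE]
  attr(geno_true, "founder_maf") <- attr(g_all, "founder_maf")
  geno <- mask_genotypes(geno_true, cfg$missing_rate, seed + 3L)
  fams <- ped$family[!is.na(ped$family)]
  names(fams) <- clones
  out <- list(ped = ped, geno = geno, geno_true = geno_true,
              pheno = ph$pheno, truth = ph$truth,
              founder_maf = attr(g_all, "founder_maf"), families = fams)
  if (raw_markers)
    out$geno_raw <- add_raw_markers(geno, cfg, seed + 4L)
  out
}
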