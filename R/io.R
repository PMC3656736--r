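#' Read a genotype matrix
#'
#' Reads a delimited matrix of minor-allele dosages. The file has marker ids in
#' the header and individual (clone) ids in the first column by default; set
#' `orientation = "markers_in_rows"` for the transposed layout. Cells must be
#' 0, 1, 2 or `NA` unless `allow_continuous = TRUE` (for re-reading imputed
#' matrices, any value in `[0, 2]` is then accepted).
#'
#' @param path path to the genotype file.
#' @param sep field separator; auto-detected by default.
#' @param orientation `"clones_in_rows"` (default) or `"markers_in_rows"`.
#' @param allow_continuous accept non-integer dosages in `[0, 2]`.
#' @return Numeric matrix, clones in rows, markers in columns, `NA` marking
#'   missing genotypes.
#' @export
read_genotypes <- function(path, sep = NULL,
                           orientation = c("clones_in_rows", "markers_in_rows"),
                           allow_continuous = FALSE) {
  orientation <- match.arg(orientation)
  sep <- sep %||% .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  if (orientation == "markers_in_rows") M <- t(M)
  ok <- if (allow_continuous) is.na(M) | (M >= 0 & M <= 2)
        else is.na(M) | M == 0 | M == 1 | M == 2
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid genotype value %s at row '%s', column '%s'",
                 format(M[bad[1, 1], bad[1, 2]]),
                 rownames(M)[bad[1, 1]], colnames(M)[bad[1, 2]]))
  }
  M
}

#' Write a genotype matrix
#'
#' @param geno clones x markers dosage matrix.
#' @param path output path (tab-separated, clone ids in the first column).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(clone_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects delimited text with columns `tree_id`, `clone_id`, `site_id`,
#' `volume` (header required, extra columns kept). Each row is one ramet
#' (a physical tree) of a clone.
#'
#' @param path path to the phenotype file.
#' @param sep field separator; auto-detected by default.
#' @param pedigree optional pedigree; clones absent from it trigger a warning
#'   and are dropped unless `keep_unknown_clones = TRUE`.
#' @param keep_unknown_clones keep rows whose clone is not in `pedigree`.
#' @return Data frame with at least the four standard columns.
#' @export
read_phenotypes <- function(path, sep = NULL, pedigree = NULL,
                            keep_unknown_clones = FALSE) {
  sep <- sep %||% .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("tree_id", "clone_id", "site_id", "volume")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("phenotype file has no data rows: ", path)
  df$tree_id <- as.character(df$tree_id)
  df$clone_id <- as.character(df$clone_id)
  df$site_id <- as.character(df$site_id)
  df$volume <- as.numeric(df$volume)
  if (!is.null(pedigree)) {
    unknown <- setdiff(unique(df$clone_id), pedigree$id)
    if (length(unknown)) {
      warning("clones not in pedigree: ", paste(unknown, collapse = ", "))
      if (!keep_unknown_clones) df <- df[!df$clone_id %in% unknown, , drop = FALSE]
    }
  }
  df
}

#' Write a phenotype table
#' @param pheno phenotype data frame.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled relationship matrix
#'
#' Relationship matrices are stored as tab-separated text with individual ids
#' both as header and as first column.
#'
#' @param path file path.
#' @return `read_relationship_matrix`: symmetric labeled matrix.
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  K <- as.matrix(df)
  storage.mode(K) <- "double"
  .check_square_labeled(K)
  K
}

#' @rdname read_relationship_matrix
#' @param K labeled symmetric matrix.
#' @export
write_relationship_matrix <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a breeding-value table
#'
#' @param bv a `blup_fit` object or its `$bv` data frame.
#' @param path output path (tab-separated: clone_id, method, value, se,
#'   accuracy).
#' @return `path`, invisibly.
#' @export
write_breeding_values <- function(bv, path) {
  if (inherits(bv, "blup_fit")) bv <- bv$bv
  utils::write.table(bv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
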