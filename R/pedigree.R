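#' Coerce a data frame to a validated pedigree
#'
#' A pedigree is a three-column table (`id`, `sire`, `dam`) of parent-offspring
#' trios. Unknown parents are coded `NA` (readers also accept `"0"` or empty
#' strings). The returned pedigree is topologically sorted so that every parent
#' precedes its offspring; founders (both parents unknown) come first. Any extra
#' columns (e.g. a `family` label) are carried along.
#'
#' @param df data frame whose first three columns are individual, sire and dam
#'   identifiers (character or coercible to character).
#' @return A `pedigree` object: a data frame with columns `id`, `sire`, `dam`
#'   (plus any extra input columns), sorted parents-before-offspring.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("O1", "P1", "P2"),
#'                               sire = c("P1", NA, NA),
#'                               dam  = c("P2", NA, NA)))
#' ped$id  # founders first
#' @export
as_pedigree <- function(df) {
  if (ncol(df) < 3L)
    stop("pedigree needs at least 3 columns (id, sire, dam)")
  names(df)[1:3] <- c("id", "sire", "dam")
  for (cl in c("id", "sire", "dam")) {
    v <- as.character(df[[cl]])
    v[!is.na(v) & (v == "0" | trimws(v) == "")] <- NA_character_
    df[[cl]] <- v
  }
  if (anyNA(df$id)) stop("missing individual id in pedigree")
  if (anyDuplicated(df$id))
    stop("duplicate pedigree id: ", df$id[duplicated(df$id)][1L])
  known <- df$id
  orphan_parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), known)
  if (length(orphan_parents)) {
    # parents that never appear as individuals are added as founders
    add <- df[rep(NA_integer_, length(orphan_parents)), , drop = FALSE]
    add$id <- orphan_parents
    df <- rbind(add, df)
    rownames(df) <- NULL
  }
  ord <- .ped_topo_order(df$id, df$sire, df$dam)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn's algorithm; errors on a cycle naming an individual on it.
.ped_topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  placed <- logical(n)
  parent_ok <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  ord <- integer(0)
  repeat {
    ready <- which(!placed & parent_ok(si) & parent_ok(di))
    if (!length(ready)) break
    # founders first, then stable input order
    ready <- ready[order(!(is.na(si[ready]) & is.na(di[ready])), ready)]
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    bad <- id[which(!placed)[1L]]
    stop("pedigree cycle detected involving individual '", bad, "'")
  }
  ord
}

#' Read a pedigree file
#'
#' Expects delimited text with a header and three columns: individual, sire,
#' dam. Unknown parents may be coded `"0"`, empty, or `NA`. Tab and comma
#' delimiters are auto-detected.
#'
#' @param path path to the pedigree file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A [as_pedigree()] pedigree, topologically sorted.
#' @export
read_pedigree <- function(path, sep = NULL) {
  sep <- sep %||% .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped a pedigree.
#' @param path output path; tab-separated with header, unknown parents as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the expected additive relationship matrix \eqn{A} by the recursive
#' tabular method: for individual \eqn{j} with parents \eqn{s} and \eqn{d},
#' \eqn{A_{jj} = 1 + \tfrac12 A_{sd}} and \eqn{A_{jk} = \tfrac12 (A_{ks} +
#' A_{kd})} for any earlier individual \eqn{k}; unknown parents contribute 0.
#' The diagonal is \eqn{1 + f} where \eqn{f} is the inbreeding coefficient.
#'
#' @param ped a pedigree (topologically sorted; [as_pedigree()] guarantees
#'   this).
#' @return Symmetric numeric matrix with individual ids as dimnames and
#'   attribute `flavor = "A"`.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("P1", "P2", "O1", "O2"),
#'                               sire = c(NA, NA, "P1", "P1"),
#'                               dam  = c(NA, NA, "P2", "P2")))
#' amatrix(ped)["O1", "O2"]  # full sibs: 0.5
#' @export
amatrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  id <- ped$id
  n <- length(id)
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE))
    stop("pedigree is not sorted parents-before-offspring")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      k <- seq_len(j - 1L)
      as_ <- if (is.na(s)) 0 else A[k, s]
      ad_ <- if (is.na(d)) 0 else A[k, d]
      ajk <- 0.5 * (as_ + ad_)
      A[k, j] <- ajk
      A[j, k] <- ajk
    }
    A[j, j] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  attr(A, "flavor") <- "A"
  A
}

#' Pedigree inbreeding coefficients
#'
#' @param ped a pedigree.
#' @return Named vector `diag(A) - 1`.
#' @export
pedigree_inbreeding <- function(ped) {
  A <- amatrix(ped)
  diag(A) - 1
}
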