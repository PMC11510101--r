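#' Pedigree relationship matrix (A) by the tabular method
#'
#' Builds the numerator relationship matrix recursively in topological
#' order: \eqn{a_{ii} = 1 + \tfrac12 a_{sd}} and
#' \eqn{a_{ij} = \tfrac12 (a_{js} + a_{jd})}, with unknown parents
#' contributing zero.  The diagonal is \eqn{1 + F_i} where \eqn{F_i} is the
#' inbreeding coefficient.
#'
#' @param ped pedigree accepted by [validate_pedigree()].
#' @return symmetric matrix with animal ids as dimnames and
#'   `attr(, "kind") == "A"`.
#' @export
build_A <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    prev <- seq_len(i - 1L)
    if (i > 1L) {
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[prev, s]
      if (!is.na(d)) row <- row + 0.5 * A[prev, d]
      A[prev, i] <- row
      A[i, prev] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  structure(A, kind = "A")
}

#' Pedigree relationship submatrix of the genotyped animals (A22)
#'
#' @param A matrix from [build_A()].
#' @param genotyped_ids character vector of animal ids, a subset of
#'   `rownames(A)`.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  miss <- setdiff(genotyped_ids, rownames(A))
  if (length(miss))
    stop("ids not in A: ", paste(utils::head(miss, 5L), collapse = ", "))
  structure(A[genotyped_ids, genotyped_ids, drop = FALSE], kind = "A22")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = ZZ' / (2 \sum_i p_i (1 - p_i))} where Z holds dosages centred by
#' twice the allele frequency.  Frequencies default to those observed among
#' the genotyped animals; monomorphic markers are excluded with a warning.
#' An optional blend \eqn{(1-w) G + w A_{22}} guards against singular G.
#'
#' @param geno matrix of dosages in \{0,1,2\}, animals in rows (rownames are
#'   ids), markers in columns.
#' @param blend_weight fraction `w` of `A22` blended into G (default 0, the
#'   plain VanRaden matrix).
#' @param A22 pedigree submatrix, required when `blend_weight > 0`.
#' @param allele_freqs optional per-marker frequencies of the counted allele.
#' @export
build_G <- function(geno, blend_weight = 0, A22 = NULL, allele_freqs = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  if (any(is.na(geno)) || !all(geno %in% 0:2))
    stop("dosages must be 0, 1 or 2 with no missing values")
  p <- if (is.null(allele_freqs)) colMeans(geno) / 2 else allele_freqs
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all markers are monomorphic")
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded")
    geno <- geno[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  if (blend_weight > 0) {
    if (is.null(A22)) stop("A22 required for blending")
    A22 <- A22[rownames(G), rownames(G)]
    G <- (1 - blend_weight) * G + blend_weight * A22
  }
  structure(G, kind = if (blend_weight > 0) "G_blended" else "G")
}

#' Inverse of the single-step hybrid relationship matrix (H)
#'
#' \eqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
#' \end{pmatrix}}, the genotyped block being indexed by `genotyped_ids`
#' within the ordering of `A_inv`.
#'
#' @param A_inv inverse of the full pedigree relationship matrix.
#' @param A22_inv inverse of the genotyped-animal submatrix of A.
#' @param G_inv inverse of the genomic relationship matrix.
#' @param genotyped_ids ids of the genotyped animals.
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  H_inv <- A_inv
  if (length(genotyped_ids)) {
    stopifnot(all(genotyped_ids %in% rownames(A_inv)))
    stopifnot(identical(dim(G_inv), dim(A22_inv)))
    G_inv <- G_inv[genotyped_ids, genotyped_ids]
    A22_inv <- A22_inv[genotyped_ids, genotyped_ids]
    H_inv[genotyped_ids, genotyped_ids] <-
      H_inv[genotyped_ids, genotyped_ids] + (G_inv - A22_inv)
  }
  structure((H_inv + t(H_inv)) / 2, kind = "H_inv")
}

#' Assemble H-inverse from pedigree, genotypes and ids
#'
#' Convenience wrapper: builds A, A22 and G, inverts them and applies
#' [build_H_inverse()].  Returns the pieces alongside H-inverse (and H
#' itself, needed as a covariance structure by the REML fitter).
#'
#' @inheritParams build_A
#' @inheritParams build_G
#' @param geno dosage matrix for the genotyped animals (rownames are ids).
#' @return list with elements `A`, `A22`, `G`, `H_inv`, `H`.
#' @export
build_H <- function(ped, geno, blend_weight = 0) {
  A <- build_A(ped)
  gids <- rownames(geno)
  A22 <- extract_A22(A, gids)
  G <- build_G(geno, blend_weight = blend_weight, A22 = A22)
  G_inv <- tryCatch(solve_sym(G), error = function(e)
    stop("G is singular; use blend_weight > 0 (got: ", conditionMessage(e), ")"))
  H_inv <- build_H_inverse(solve_sym(A), solve_sym(A22), G_inv, gids)
  H <- solve_sym(H_inv)
  dimnames(H) <- dimnames(A)
  list(A = A, A22 = A22, G = G, H_inv = H_inv,
       H = structure(H, kind = "H"))
}

#' Invert a symmetric positive definite matrix via Cholesky
#'
#' @param M symmetric positive definite matrix.
#' @export
solve_sym <- function(M) {
  out <- chol2inv(chol((M + t(M)) / 2))
  dimnames(out) <- dimnames(M)
  out
}
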