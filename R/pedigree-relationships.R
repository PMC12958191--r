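# Pedigree relationship machinery: tabular A, inbreeding, Henderson's
# rules for the sparse A-inverse, and the genotyped submatrix A22.
# Everything here assumes desk scale (a few thousand animals), where the
# dense tabular recursion is exact and fast.

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive (tabular) computation of A. Exact; O(n^2) memory, so
#' intended for pedigrees up to a few thousand animals.
#'
#' @param pedigree An `apy_pedigree` (parents precede offspring).
#' @return Dense symmetric matrix A with dimnames = animal ids.
#' @export
pedigree_A <- function(pedigree) {
  stopifnot(inherits(pedigree, "apy_pedigree"))
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$animal)
  di <- match(pedigree$dam, pedigree$animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si[i])) row <- row + 0.5 * A[si[i], j]
      if (!is.na(di[i])) row <- row + 0.5 * A[di[i], j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * A[si[i], di[i]] else 0
  }
  dimnames(A) <- list(pedigree$animal, pedigree$animal)
  A
}

#' Inbreeding coefficients from the pedigree
#'
#' @param pedigree An `apy_pedigree`.
#' @param A Optional precomputed tabular A (from [pedigree_A()]).
#' @return Named numeric vector F per animal (founders: 0).
#' @export
inbreeding_coefficients <- function(pedigree, A = NULL) {
  if (is.null(A)) A <- pedigree_A(pedigree)
  f <- diag(A) - 1
  names(f) <- pedigree$animal
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly by Henderson's parent-contribution
#' rules, with Mendelian sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one parent) or 1 (founders), using exact
#' tabular-method inbreeding.
#'
#' @param pedigree An `apy_pedigree`.
#' @param genotyped_ids Optional ids of genotyped animals; if given, the
#'   tabular A22 submatrix is computed and stored alongside.
#' @param A Optional precomputed tabular A, reused for inbreeding/A22.
#' @return Object of class `numerator_relationship`: list with sparse
#'   symmetric `A_inverse` (dimnames = animal ids), `inbreeding`, `ids`,
#'   and optionally `A22` + `genotyped_ids`.
#' @export
build_A_inverse <- function(pedigree, genotyped_ids = NULL, A = NULL) {
  stopifnot(inherits(pedigree, "apy_pedigree"))
  if (is.null(A)) A <- pedigree_A(pedigree)
  f <- diag(A) - 1
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$animal)
  di <- match(pedigree$dam, pedigree$animal)
  fs <- ifelse(is.na(si), 0, f[ifelse(is.na(si), 1L, si)])
  fd <- ifelse(is.na(di), 0, f[ifelse(is.na(di), 1L, di)])
  both <- !is.na(si) & !is.na(di)
  one <- xor(is.na(si), is.na(di))
  d <- rep(1, n)
  d[both] <- 0.5 - 0.25 * (fs[both] + fd[both])
  d[one] <- 0.75 - 0.25 * (fs + fd)[one]   # the known parent's F
  alpha <- 1 / d

  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # vectorized triplet assembly
  add(seq_len(n), seq_len(n), alpha)
  ks <- which(!is.na(si)); kd <- which(!is.na(di)); kb <- which(both)
  add(ks, si[ks], -alpha[ks] / 2); add(si[ks], ks, -alpha[ks] / 2)
  add(si[ks], si[ks], alpha[ks] / 4)
  add(kd, di[kd], -alpha[kd] / 2); add(di[kd], kd, -alpha[kd] / 2)
  add(di[kd], di[kd], alpha[kd] / 4)
  add(si[kb], di[kb], alpha[kb] / 4); add(di[kb], si[kb], alpha[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$animal, pedigree$animal))
  Ainv <- Matrix::forceSymmetric(Ainv)
  names(f) <- pedigree$animal
  out <- list(A_inverse = Ainv, inbreeding = f, ids = pedigree$animal)
  if (!is.null(genotyped_ids)) {
    out$A22 <- extract_A22(A, pedigree, genotyped_ids)
    out$genotyped_ids <- genotyped_ids
  }
  structure(out, class = "numerator_relationship")
}

extract_A22 <- function(A, pedigree, genotyped_ids) {
  idx <- match(genotyped_ids, pedigree$animal)
  if (anyNA(idx)) {
    stop("genotyped id not in pedigree: ", genotyped_ids[is.na(idx)][1], call. = FALSE)
  }
  A[idx, idx, drop = FALSE]
}

#' Pedigree relationships among the genotyped animals (A22)
#'
#' @param pedigree An `apy_pedigree`.
#' @param genotyped_ids Animal ids, in the genotype-set row order.
#' @param A Optional precomputed tabular A.
#' @return Dense symmetric matrix, dimnames = `genotyped_ids`.
#' @export
build_A22 <- function(pedigree, genotyped_ids, A = NULL) {
  stopifnot(inherits(pedigree, "apy_pedigree"))
  if (is.null(A)) A <- pedigree_A(pedigree)
  extract_A22(A, pedigree, genotyped_ids)
}
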