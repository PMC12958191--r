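#' Gene-content container
#'
#' Stores the n x m gene-content matrix `Z` (minor-allele counts 0/1/2,
#' possibly fractional after missing-value imputation) together with the
#' animal ids and the observed allele frequencies `p_j = colMeans(Z)/2`.
#'
#' @param ids Ordered animal ids (unique), length n.
#' @param Z Numeric n x m matrix with entries in [0, 2].
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(ids, Z) {
  Z <- as.matrix(Z)
  if (length(ids) != nrow(Z)) stop("length(ids) must equal nrow(Z)", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate animal ids in genotype set", call. = FALSE)
  if (nrow(Z) < 1 || ncol(Z) < 1) stop("genotype matrix must be non-empty", call. = FALSE)
  if (any(Z < 0 | Z > 2)) stop("gene content must lie in [0, 2]", call. = FALSE)
  rownames(Z) <- ids
  structure(
    list(ids = ids, Z = Z, allele_freq = colMeans(Z) / 2),
    class = "genotype_set"
  )
}

#' Restrict a genotype set to a subset of animals
#'
#' Allele frequencies are recomputed from the subset so that the
#' invariant `colMeans(Z) == 2 * allele_freq` always holds.
#'
#' @param genotypes A `genotype_set`.
#' @param ids Animal ids to keep, in the desired row order.
#' @return A `genotype_set` over `ids`.
#' @export
genotype_subset <- function(genotypes, ids) {
  stopifnot(inherits(genotypes, "genotype_set"))
  idx <- match(ids, genotypes$ids)
  if (anyNA(idx)) stop("unknown animal id: ", ids[is.na(idx)][1], call. = FALSE)
  genotype_set(ids = ids, Z = genotypes$Z[idx, , drop = FALSE])
}

#' @exportS3Method base::print
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d animals x %d SNPs, mean MAF %.3f\n",
              nrow(x$Z), ncol(x$Z), mean(pmin(x$allele_freq, 1 - x$allele_freq))))
  invisible(x)
}
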