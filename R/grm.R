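#' Genomic relationship matrix (VanRaden method 1, blended with A22)
#'
#' `G0 = W W' / (2 * sum p_j (1 - p_j))` with `W = Z - 2P` centered at
#' the observed allele frequencies; the returned matrix is
#' `alpha * G0 + (1 - alpha) * A22`, which keeps G positive definite and
#' on the pedigree scale. Monomorphic loci (p in {0, 1}) carry no
#' information and would not contribute to the scaling denominator, so
#' they are dropped with a warning.
#'
#' @param genotypes A [genotype_set()] over the genotyped animals.
#' @param A22 Pedigree relationships among the same animals, same order;
#'   required unless `alpha = 1`.
#' @param alpha Blending weight on the genomic component, in (0, 1];
#'   default 0.95.
#' @return Object of class `grm`: list with dense symmetric `G`, `ids`,
#'   `alpha`, and `n_dropped_loci`.
#' @export
build_grm <- function(genotypes, A22 = NULL, alpha = 0.95) {
  stopifnot(inherits(genotypes, "genotype_set"))
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]", call. = FALSE)
  p <- genotypes$allele_freq
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all loci are monomorphic; G is undefined", call. = FALSE)
  if (any(mono)) {
    warning(sum(mono), " monomorphic loci dropped before building G", call. = FALSE)
  }
  Z <- genotypes$Z[, !mono, drop = FALSE]
  p <- p[!mono]
  W <- sweep(Z, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G0 <- tcrossprod(W) / denom
  if (alpha < 1) {
    if (is.null(A22)) stop("`A22` is required when alpha < 1", call. = FALSE)
    A22 <- as.matrix(A22)
    stopifnot(all(dim(A22) == dim(G0)))
    G <- alpha * G0 + (1 - alpha) * A22
  } else {
    G <- G0
  }
  dimnames(G) <- list(genotypes$ids, genotypes$ids)
  structure(list(G = G, ids = genotypes$ids, alpha = alpha,
                 n_dropped_loci = sum(mono)),
            class = "grm")
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d genotyped animals, alpha = %.2f, mean diag = %.3f\n",
              length(x$ids), x$alpha, mean(diag(x$G))))
  invisible(x)
}

#' Diagonal of G by animal id
#' @param grm A `grm`.
#' @param ids Animal ids (default all).
#' @return Named numeric vector of g_ii.
#' @export
grm_diag <- function(grm, ids = grm$ids) {
  idx <- match(ids, grm$ids)
  if (anyNA(idx)) stop("unknown animal id: ", ids[is.na(idx)][1], call. = FALSE)
  stats::setNames(diag(grm$G)[idx], ids)
}

#' Core size from the spectrum of the gene-content matrix
#'
#' Singular value decomposition of the centered gene-content matrix W;
#' since `G0` is proportional to `W W'`, the squared singular values are
#' (up to scaling) the eigenvalues of the GRM. Returns the smallest
#' number of leading eigenvalues whose cumulative share of the total
#' variance reaches `threshold`.
#'
#' @param genotypes A [genotype_set()].
#' @param threshold Fraction of genetic variance to capture, in (0, 1];
#'   0.98-0.99 are the conventional choices.
#' @return Integer core size.
#' @export
choose_core_size <- function(genotypes, threshold = 0.99) {
  stopifnot(inherits(genotypes, "genotype_set"))
  if (!(threshold > 0 && threshold <= 1)) stop("`threshold` must be in (0, 1]", call. = FALSE)
  W <- sweep(genotypes$Z, 2, 2 * genotypes$allele_freq)
  d2 <- svd(W, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) stop("gene-content matrix has no variance", call. = FALSE)
  if (threshold >= 1) {
    # numerical rank
    return(sum(d2 > max(d2) * max(dim(W)) * .Machine$double.eps))
  }
  as.integer(which(cumsum(d2) / tot >= threshold)[1])
}

#' Nested random core partitions
#'
#' The largest core is drawn uniformly at random from the genotyped
#' animals; each smaller core is drawn uniformly from the next larger
#' one, so every animal of the smallest core belongs to all larger
#' cores.
#'
#' @param genotyped_ids All genotyped animal ids.
#' @param sizes Strictly descending vector of core sizes, max <= n.
#' @param seed Integer seed.
#' @return List of `core_partition` objects, one per size (largest
#'   first), each with sorted `core_ids`, `noncore_ids` and a
#'   `scenario_label` of the form `"c<size>"`.
#' @export
select_nested_cores <- function(genotyped_ids, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(sizes) > 1 && any(diff(sizes) >= 0)) {
    stop("`sizes` must be strictly descending", call. = FALSE)
  }
  if (any(sizes < 1L)) stop("core sizes must be >= 1", call. = FALSE)
  if (max(sizes) > length(genotyped_ids)) {
    stop("largest core exceeds the number of genotyped animals", call. = FALSE)
  }
  set.seed(seed)
  out <- vector("list", length(sizes))
  pool <- genotyped_ids
  for (k in seq_along(sizes)) {
    core <- sort(sample(pool, sizes[k]))
    out[[k]] <- core_partition(core, genotyped_ids)
    pool <- core
  }
  out
}

#' Core/noncore partition of the genotyped animals
#' @param core_ids Core animal ids (subset of `genotyped_ids`).
#' @param genotyped_ids All genotyped ids.
#' @param scenario_label Text label; default `"c<n_core>"`.
#' @return Object of class `core_partition`.
#' @export
core_partition <- function(core_ids, genotyped_ids,
                           scenario_label = paste0("c", length(core_ids))) {
  core_ids <- sort(core_ids)
  if (length(core_ids) < 1) stop("core must contain at least one animal", call. = FALSE)
  if (!all(core_ids %in% genotyped_ids)) stop("core ids must be genotyped", call. = FALSE)
  structure(list(core_ids = core_ids,
                 noncore_ids = sort(setdiff(genotyped_ids, core_ids)),
                 scenario_label = scenario_label),
            class = "core_partition")
}
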