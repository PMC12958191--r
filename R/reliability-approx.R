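# Reliability approximation for genotyped animals from the APY inverse
# plus a diagonal weight vector, with propagation to nongenotyped
# animals through pseudo-observations.
#
# Operational pipeline:
#   1. pedigree-only reliabilities -> effective record contributions
#      d_i = lambda * rel / (1 - rel)  (reverse reliability);
#   2. K = lambda * G_APY^{-1} + D inverted by block-sparse (Schur
#      complement) techniques; only diag(K^{-1}) is needed;
#   3. genomic reliabilities rel^G_i = 1 - lambda [K^{-1}]_ii / g_ii;
#   4. the genomic gain re-enters the pedigree system as pseudo-record
#      weights, and final reliabilities for all animals come from the
#      updated system.

#' Effective record contributions from reliabilities (reverse reliability)
#'
#' Inverts the single-animal reliability formula `rel = d / (d + lambda)`:
#' `d = lambda * rel / (1 - rel)`, the number of effective own records
#' (in residual-variance units) that would reproduce `rel` in isolation.
#'
#' @param rel Reliabilities in [0, 1] (named vector).
#' @param params A [model_params()].
#' @param cap Reliabilities are capped at `1 - cap` before reversal so
#'   that weights stay finite. Default 1e-6.
#' @return Named nonnegative weight vector, class `weight_vector`.
#' @export
reverse_reliability_weights <- function(rel, params, cap = 1e-6) {
  stopifnot(inherits(params, "model_params"))
  if (any(rel < 0 | rel > 1, na.rm = TRUE) || anyNA(rel)) {
    stop("reliabilities must lie in [0, 1]", call. = FALSE)
  }
  r <- pmin(rel, 1 - cap)
  d <- params$lambda * r / (1 - r)
  structure(d, class = "weight_vector")
}

# internal: K blocks in core-then-noncore order
.k_blocks <- function(apy, weights, params) {
  nc <- length(apy$partition$core_ids)
  nn <- length(apy$partition$noncore_ids)
  w <- unclass(weights)
  if (!is.null(names(w))) {
    idx <- match(apy$ids, names(w))
    if (anyNA(idx)) stop("weights missing for some genotyped animals", call. = FALSE)
    w <- w[idx]
  } else if (length(w) == length(apy$ids)) {
    # unnamed: assumed in the GRM (orig_ids) order
    w <- w[match(apy$ids, apy$orig_ids)]
  } else {
    stop("weights must be named or match the genotyped set in GRM order", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  lam <- params$lambda
  Minv <- if (nn) 1 / apy$Mnn else numeric(0)
  Kcc <- lam * apy$Gcc_inv
  if (nn) {
    Um <- sweep(apy$U, 2, Minv, `*`)
    Kcc <- Kcc + lam * tcrossprod(Um, apy$U)
    Kcn <- -lam * Um
  } else {
    Kcn <- matrix(0, nc, 0)
  }
  diag(Kcc) <- diag(Kcc) + w[seq_len(nc)]
  Knn <- lam * Minv + if (nn) w[nc + seq_len(nn)] else numeric(0)
  list(Kcc = Kcc, Kcn = Kcn, Knn = Knn, nc = nc, nn = nn)
}

#' Diagonal of the inverse of K = lambda G_APY^{-1} + D by block-sparse
#' inversion
#'
#' Exploits the APY pattern of K (dense core block, dense cross block,
#' diagonal noncore block). Step A, the first expensive product, forms
#' the Schur complement `S = K_cc - K_cn K_nn^{-1} K_nc` (cost
#' proportional to n_c^2 n_n); S is densely inverted; step B forms
#' `V = S^{-1} K_cn` and yields the noncore diagonal
#' `1/K_nn,ii + (K_cn col i)' (V col i) / K_nn,ii^2`. With a
#' [sketch_config()], the step-A product over the noncore dimension is
#' replaced by [randomized_matmul()] and step B consumes the sketched
#' factor.
#'
#' @param apy An [build_apy_inverse()] result.
#' @param weights A [reverse_reliability_weights()] vector (named by
#'   animal, or unnamed in GRM order).
#' @param params A [model_params()].
#' @param sketch Optional [sketch_config()].
#' @return Named diagonal of `K^{-1}` in the GRM id order.
#' @export
apy_block_diag_inverse <- function(apy, weights, params, sketch = NULL) {
  stopifnot(inherits(apy, "apy_inverse"))
  kb <- .k_blocks(apy, weights, params)
  if (any(kb$Knn <= 0)) stop("noncore diagonal of K must be positive", call. = FALSE)
  if (kb$nn) {
    A <- sweep(kb$Kcn, 2, kb$Knn, `/`)               # K_cn K_nn^{-1}
    P <- if (is.null(sketch)) {
      tcrossprod(A, kb$Kcn)                          # step A, exact
    } else {
      randomized_matmul(A, t(kb$Kcn), sketch)        # step A, sketched
    }
    S <- kb$Kcc - (P + t(P)) / 2                     # symmetrize
  } else {
    S <- kb$Kcc
  }
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    Sinv <- tryCatch(solve(S), error = function(e) {
      stop("Schur complement of K is numerically singular", call. = FALSE)
    })
  }
  d_core <- diag(Sinv)
  if (kb$nn) {
    V <- Sinv %*% kb$Kcn                             # step B
    d_non <- 1 / kb$Knn + colSums(kb$Kcn * V) / kb$Knn^2
    d <- c(d_core, d_non)
  } else {
    d <- d_core
  }
  names(d) <- apy$ids
  d[match(apy$orig_ids, apy$ids)]
}

#' Genomic reliabilities of the genotyped animals
#'
#' `rel^G_i = 1 - lambda * [K^{-1}]_ii / g_ii`, clipped to [0, 1]: the
#' reliability of a genotyped-only evaluation in which each animal's
#' non-genomic information enters as `d_i` pseudo-records. `[K^{-1}]_ii`
#' is `PEV_i / sigma_e2`, so the denominator fixes the base-variance
#' convention: the GBLUP default is the animal's own genomic variance
#' `g_ii`; pass `denominator = 1 + F` to put the genomic step on the
#' same pedigree scale as the exact reliabilities (the convention the
#' experiment pipeline uses throughout, so that pseudo-record algebra
#' across the pedigree and genomic stages is internally coherent).
#'
#' @param apy An [build_apy_inverse()] result.
#' @param grm_diag Named `g_ii` per genotyped animal (see [grm_diag()]).
#' @param weights,params,sketch As in [apy_block_diag_inverse()].
#' @param denominator Optional named base-variance vector replacing
#'   `grm_diag` in the reliability denominator (e.g. `1 + F`).
#' @return Named reliabilities in GRM order.
#' @export
genomic_reliabilities <- function(apy, grm_diag, weights, params, sketch = NULL,
                                  denominator = NULL) {
  g <- grm_diag[as.character(apy$orig_ids)]
  if (anyNA(g)) stop("GRM diagonal missing for some genotyped animals", call. = FALSE)
  if (any(g <= 0)) stop("GRM diagonal must be positive", call. = FALSE)
  if (!is.null(denominator)) {
    g <- if (is.null(names(denominator))) denominator else
      denominator[as.character(apy$orig_ids)]
    if (anyNA(g) || any(g <= 0)) stop("invalid reliability denominator", call. = FALSE)
  }
  dK <- apy_block_diag_inverse(apy, weights, params, sketch)
  rel <- 1 - params$lambda * dK / g
  pmin(pmax(rel, 0), 1)
}

#' Pedigree-pooling counterpart of the genomic reliabilities
#'
#' Pools the same pseudo-record weights through the pedigree
#' relationships among genotyped animals instead of the genomic ones:
#' the diagonal of `(lambda A22^{-1} + D)^{-1}` converted to
#' reliabilities exactly as in [genomic_reliabilities()]. This is the
#' pedigree-implied share of the genomic-step information; subtracting
#' it from the genomic pooling isolates what genotypes add beyond
#' pedigree, the same cancellation that `tau G^{-1} - omega A22^{-1}`
#' performs inside the H-inverse.
#'
#' @param A22 Dense pedigree relationships among the genotyped animals
#'   (row order = id order of `weights`).
#' @param weights A [reverse_reliability_weights()] vector, named by
#'   animal id.
#' @param params A [model_params()].
#' @param denominator Base-variance vector (e.g. `1 + F` or
#'   `diag(A22)`), named or in `A22` order.
#' @return Named reliabilities in `A22` order.
#' @export
pedigree_pooling_reliabilities <- function(A22, weights, params,
                                           denominator = diag(as.matrix(A22))) {
  A22 <- as.matrix(A22)
  ids <- rownames(A22)
  if (is.null(ids)) stop("A22 must carry animal ids as dimnames", call. = FALSE)
  w <- unclass(weights)
  w <- if (is.null(names(w))) w else w[ids]
  if (length(w) != nrow(A22) || anyNA(w)) {
    stop("weights must cover the A22 animals", call. = FALSE)
  }
  den <- if (is.null(names(denominator))) denominator else denominator[ids]
  if (anyNA(den) || any(den <= 0)) stop("invalid reliability denominator", call. = FALSE)
  KA <- params$lambda * chol2inv(chol(A22))
  diag(KA) <- diag(KA) + w
  dKA <- diag(chol2inv(chol(KA)))
  rel <- 1 - params$lambda * dKA / den
  stats::setNames(pmin(pmax(rel, 0), 1), ids)
}

#' Propagate genomic information to all animals via pseudo-observations
#'
#' Converts the genomic gain of each genotyped animal into an extra
#' pseudo-record weight `Delta_i = max(0, d^G_i - d^B_i)` -- reverse
#' reliabilities of the genomic-pooling estimate and of a baseline that
#' represents the pedigree-implied share of the same information (the
#' subtraction avoids double counting) -- adds `Delta` to the animal
#' diagonal of the pedigree-only coefficient matrix, and recomputes
#' reliabilities for every animal from the updated system's inverse
#' diagonal.
#'
#' By default the baseline is the [pedigree_pooling_reliabilities()]
#' counterpart of the genomic step (recommended: the two poolings share
#' their weights, so everything the pedigree already delivers cancels).
#' Passing `baseline_rel = NULL` falls back to subtracting the
#' animal's own pedigree reliability, a simpler rule that overstates
#' the gain whenever relatives' information reaches the animal through
#' both A22 and G.
#'
#' @param pedigree_rel `reliability_table` of pedigree-only (exact)
#'   reliabilities for all animals.
#' @param genomic_rel Named genomic reliabilities of the genotyped
#'   animals (from [genomic_reliabilities()]).
#' @param params A [model_params()].
#' @param pedigree_system The pedigree-only [assemble_mme()] system the
#'   reliabilities came from.
#' @param inbreeding Named pedigree inbreeding coefficients.
#' @param baseline_rel Named baseline reliabilities for the genotyped
#'   animals, on the same denominator convention as `genomic_rel`;
#'   `NULL` uses the animal's pedigree-only reliability.
#' @param scenario_label Text tag.
#' @param used_sketch Logical flag recorded in the result.
#' @return Object of class `approx_result`: list with
#'   `genomic_reliability`, `final_reliability` (a `reliability_table`
#'   over all animals, flavor `"approximated"`), `scenario_label`,
#'   `used_sketch`.
#' @export
propagate_to_pedigree <- function(pedigree_rel, genomic_rel, params,
                                  pedigree_system, inbreeding,
                                  baseline_rel = NULL,
                                  scenario_label = "approx",
                                  used_sketch = FALSE) {
  stopifnot(inherits(pedigree_system, "mme_system"))
  gids <- names(genomic_rel)
  relP_all <- stats::setNames(pedigree_rel$reliability, pedigree_rel$animal)
  relP <- relP_all[gids]
  if (anyNA(relP)) {
    stop("pedigree reliability missing for animal ",
         gids[is.na(relP)][1], call. = FALSE)
  }
  relB <- if (is.null(baseline_rel)) relP else baseline_rel[gids]
  if (anyNA(relB)) stop("baseline reliability missing for some animals", call. = FALSE)
  dG <- unclass(reverse_reliability_weights(genomic_rel, params))
  dP <- unclass(reverse_reliability_weights(relB, params))
  delta <- pmax(0, dG - dP)
  C2 <- pedigree_system$C
  rows <- pedigree_system$animal_index[match(gids, pedigree_system$animal_ids)]
  if (anyNA(rows)) stop("genotyped animal missing from the pedigree system", call. = FALSE)
  dg <- Matrix::diag(C2)
  dg[rows] <- dg[rows] + delta
  Matrix::diag(C2) <- dg
  f <- inbreeding[as.character(pedigree_system$animal_ids)]
  if (anyNA(f)) stop("inbreeding missing for some animals", call. = FALSE)
  dinv <- diag_of_inverse(C2)[pedigree_system$animal_index]
  pev <- pmax(params$sigma_e2 * dinv, 0)
  rel <- pmin(pmax(1 - pev / (params$sigma_a2 * (1 + f)), 0), 1)
  structure(
    list(
      genomic_reliability = genomic_rel,
      final_reliability = reliability_table(pedigree_system$animal_ids, pev, rel,
                                            "approximated", scenario_label),
      scenario_label = scenario_label,
      used_sketch = used_sketch
    ),
    class = "approx_result"
  )
}

#' Randomized-sketch configuration
#'
#' @param k Number of sampled inner columns (random projections),
#'   `1 <= k <= n_n`.
#' @param scheme Sampling scheme; only uniform column sampling without
#'   replacement is provided (it is exact at `k = n_n`).
#' @param seed Integer seed.
#' @return Object of class `sketch_config`.
#' @export
sketch_config <- function(k, scheme = "column_sampling_uniform", seed = 1L) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  structure(list(k = k, scheme = scheme, seed = as.integer(seed)),
            class = "sketch_config")
}

#' Randomized matrix multiplication by uniform column sampling
#'
#' Approximates `A %*% B` (inner dimension n) by sampling `k` inner
#' indices uniformly without replacement and rescaling by `n / k`:
#' an unbiased estimator that is exact at `k = n`. The cost drops from
#' O(p n q) to O(p k q).
#'
#' @param A p x n matrix.
#' @param B n x q matrix.
#' @param sketch A [sketch_config()] with `k <= n`.
#' @return p x q matrix estimate of `A %*% B`.
#' @export
randomized_matmul <- function(A, B, sketch) {
  stopifnot(inherits(sketch, "sketch_config"))
  n <- ncol(A)
  if (nrow(B) != n) stop("inner dimensions do not match", call. = FALSE)
  if (sketch$k > n) stop("`k` must not exceed the inner dimension", call. = FALSE)
  set.seed(sketch$seed)
  idx <- sample.int(n, sketch$k)
  (n / sketch$k) * (A[, idx, drop = FALSE] %*% B[idx, , drop = FALSE])
}
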