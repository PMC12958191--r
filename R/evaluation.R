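# Single-trait ssGBLUP machinery: H-inverse, Henderson's mixed model
# equations, sparse solve, and exact reliabilities from the diagonal of
# the inverse of the coefficient matrix.

#' Variance components for the single-trait animal model
#'
#' Derives `sigma_a2 = h2 * sigma_total`, `sigma_e2 = (1 - h2) *
#' sigma_total` and the variance ratio `lambda = sigma_e2 / sigma_a2`.
#'
#' @param heritability h2 in (0, 1).
#' @param sigma_total Total phenotypic variance (default 1).
#' @param tau Scale on G-inverse in H-inverse (default 1).
#' @param omega Scale on A22-inverse in H-inverse (default 1).
#' @return Object of class `model_params`.
#' @export
model_params <- function(heritability, sigma_total = 1, tau = 1, omega = 1) {
  if (!(heritability > 0 && heritability < 1)) {
    stop("`heritability` must be in (0, 1)", call. = FALSE)
  }
  sigma_a2 <- heritability * sigma_total
  sigma_e2 <- (1 - heritability) * sigma_total
  structure(list(heritability = heritability, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2, lambda = sigma_e2 / sigma_a2,
                 tau = tau, omega = omega),
            class = "model_params")
}

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' `H^{-1} = A^{-1}` plus `tau * G^{-1} - omega * A22^{-1}` scattered
#' into the genotyped block. With `G = A22` and `tau = omega = 1` the
#' genomic terms cancel and pedigree BLUP is recovered exactly.
#'
#' @param numrel A [build_A_inverse()] result carrying `A22` for
#'   `genotyped_ids` (or pass `A22` explicitly).
#' @param g_inverse Either a dense G-inverse matrix over the genotyped
#'   animals (in `genotyped_ids` order) or an [build_apy_inverse()]
#'   object, whose assembled sparse blocks are used.
#' @param genotyped_ids Genotyped animal ids; if `NULL`, no genomic term
#'   is added and `H^{-1} = A^{-1}`.
#' @param params A [model_params()] (for `tau`, `omega`).
#' @param A22 Optional explicit A22 (overrides `numrel$A22`).
#' @return Sparse symmetric H-inverse with animal-id dimnames.
#' @export
build_H_inverse <- function(numrel, g_inverse = NULL, genotyped_ids = NULL,
                            params = model_params(0.3), A22 = NULL) {
  stopifnot(inherits(numrel, "numerator_relationship"))
  Hinv <- numrel$A_inverse
  if (is.null(genotyped_ids) || length(genotyped_ids) == 0) return(Hinv)
  idx <- match(genotyped_ids, numrel$ids)
  if (anyNA(idx)) {
    stop("genotyped id not in pedigree: ", genotyped_ids[is.na(idx)][1], call. = FALSE)
  }
  if (is.null(A22)) A22 <- numrel$A22
  if (is.null(A22)) stop("A22 is required (build_A_inverse(..., genotyped_ids=))", call. = FALSE)
  A22 <- as.matrix(A22)
  if (!is.null(rownames(A22)) && !identical(rownames(A22), as.character(genotyped_ids))) {
    stop("A22 row order must match `genotyped_ids`", call. = FALSE)
  }
  if (inherits(g_inverse, "apy_inverse")) {
    if (!identical(g_inverse$orig_ids, genotyped_ids)) {
      stop("APY inverse was built over a different genotyped set", call. = FALSE)
    }
    Ginv <- as.matrix(apy_assemble(g_inverse, order = "original"))
  } else {
    Ginv <- as.matrix(g_inverse)
  }
  stopifnot(all(dim(Ginv) == length(genotyped_ids)))
  delta <- params$tau * Ginv - params$omega * chol2inv(chol(A22))
  Hinv <- as(Hinv, "CsparseMatrix")
  Hinv[idx, idx] <- Hinv[idx, idx] + delta
  Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
}

#' Assemble Henderson's mixed model equations
#'
#' Single-trait animal model `y = X b + W u + e` with `Var(u) =
#' sigma_a2 * H`, `Var(e) = sigma_e2 * I`:
#' `[[X'X, X'W], [W'X, W'W + lambda H^{-1}]] (b, u) = (X'y, W'y)`.
#' Equations exist for every animal, phenotyped or not.
#'
#' @param phenotypes A `phenotype_set` or a data frame with columns
#'   `animal`, `value` (optional `group` for the categorical fixed
#'   effect).
#' @param fixed `"intercept"` (default), `"group"` (one categorical
#'   effect from the `group` column, full dummy coding), `"none"`, or a
#'   numeric design matrix with one row per record.
#' @param H_inverse Sparse relationship inverse with animal-id dimnames
#'   (from [build_H_inverse()] or `numrel$A_inverse`).
#' @param params A [model_params()].
#' @return Object of class `mme_system`: list with sparse `C`, `rhs`,
#'   `animal_ids`, `animal_index` (equation rows of the animals),
#'   `n_fixed`, `params`, `n_records`.
#' @export
assemble_mme <- function(phenotypes, fixed = "intercept", H_inverse, params) {
  stopifnot(inherits(params, "model_params"))
  rec <- if (inherits(phenotypes, "phenotype_set")) phenotypes$records else phenotypes
  animal_ids <- rownames(H_inverse)
  if (is.null(animal_ids)) stop("H_inverse must carry animal ids as dimnames", call. = FALSE)
  n_anim <- length(animal_ids)
  n_rec <- nrow(rec)
  j <- match(as.character(rec$animal), animal_ids)
  if (anyNA(j)) {
    stop("phenotype record for unknown animal: ", rec$animal[is.na(j)][1], call. = FALSE)
  }
  if (anyDuplicated(j)) {
    stop("animal ", rec$animal[duplicated(j)][1],
         " has more than one record (single-record model)", call. = FALSE)
  }
  y <- rec$value
  X <- NULL
  if (is.matrix(fixed)) {
    stopifnot(nrow(fixed) == n_rec)
    X <- fixed
  } else if (identical(fixed, "intercept")) {
    X <- matrix(1, n_rec, 1, dimnames = list(NULL, "mu"))
  } else if (identical(fixed, "group")) {
    if (is.null(rec$group)) stop("`group` column required for fixed = \"group\"", call. = FALSE)
    g <- factor(rec$group)
    X <- stats::model.matrix(~ g - 1)
    colnames(X) <- paste0("group", levels(g))
  } else if (!identical(fixed, "none")) {
    stop("unknown `fixed` specification", call. = FALSE)
  }
  n_fixed <- if (is.null(X)) 0L else ncol(X)
  Wm <- Matrix::sparseMatrix(i = seq_len(n_rec), j = j, x = 1,
                             dims = c(n_rec, n_anim))
  WtW <- Matrix::crossprod(Wm)
  lamH <- params$lambda * as(H_inverse, "CsparseMatrix")
  if (n_fixed > 0) {
    X <- Matrix::Matrix(X, sparse = FALSE)
    XtX <- Matrix::crossprod(X)
    XtW <- Matrix::crossprod(X, Wm)
    C <- rbind(cbind(XtX, XtW), cbind(Matrix::t(XtW), WtW + lamH))
    rhs <- c(as.numeric(Matrix::crossprod(X, y)), as.numeric(Matrix::crossprod(Wm, y)))
  } else {
    C <- WtW + lamH
    rhs <- as.numeric(Matrix::crossprod(Wm, y))
  }
  structure(
    list(C = as(C, "CsparseMatrix"), rhs = rhs, animal_ids = animal_ids,
         animal_index = n_fixed + seq_len(n_anim), n_fixed = n_fixed,
         params = params, n_records = n_rec),
    class = "mme_system"
  )
}

#' Solve the mixed model equations
#'
#' Sparse Cholesky solve; falls back to a Moore-Penrose generalized
#' inverse (with a warning) when the fixed-effect block is rank
#' deficient, in which case the fixed-effect solution is one member of
#' the solution set while `u` is invariant.
#'
#' @param system An [assemble_mme()] result.
#' @return List with `fixed` and named `u` (breeding values).
#' @export
solve_mme <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  sol <- tryCatch(as.numeric(Matrix::solve(system$C, system$rhs)),
                  error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) {
    warning("coefficient matrix is singular; using a generalized inverse",
            call. = FALSE)
    sol <- as.numeric(MASS::ginv(as.matrix(system$C)) %*% system$rhs)
  }
  res <- as.numeric(system$C %*% sol) - system$rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(system$rhs^2)), 1e-300)
  if (is.finite(rel) && rel > 1e-8 && sum(system$rhs^2) > 0) {
    stop(sprintf("MME solve did not converge (relative residual %.2e)", rel),
         call. = FALSE)
  }
  u <- sol[system$animal_index]
  names(u) <- system$animal_ids
  list(fixed = if (system$n_fixed) sol[seq_len(system$n_fixed)] else numeric(0),
       u = u)
}

# diagonal of the inverse of a symmetric PSD coefficient matrix.
# Dense Cholesky at desk scale; generalized inverse if rank deficient.
diag_of_inverse <- function(C, max_dense = 20000L) {
  n <- nrow(C)
  if (n > max_dense) {
    stop("system too large for exact dense inversion (", n, " equations)",
         call. = FALSE)
  }
  M <- as.matrix(C)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    warning("coefficient matrix is rank deficient; PEV from a generalized inverse",
            call. = FALSE)
    return(diag(MASS::ginv(M)))
  }
  diag(chol2inv(ch))
}

#' Exact reliabilities from the inverse of the MME coefficient matrix
#'
#' `PEV_i = sigma_e2 * [C^{-1}]_ii` over the animal equations, and
#' `reliability_i = 1 - PEV_i / (sigma_a2 * (1 + F_i))`, clipped to
#' [0, 1].
#'
#' @param system An [assemble_mme()] result.
#' @param params A [model_params()].
#' @param inbreeding Named vector of pedigree inbreeding coefficients
#'   covering every animal in the system.
#' @param scenario_label Text tag carried into the output table.
#' @return A `reliability_table` data frame: `animal`, `PEV`,
#'   `reliability`, `flavor = "exact"`, `scenario`.
#' @export
exact_reliabilities <- function(system, params = system$params, inbreeding,
                                scenario_label = "exact") {
  stopifnot(inherits(system, "mme_system"))
  f <- inbreeding[as.character(system$animal_ids)]
  if (anyNA(f)) stop("inbreeding missing for some animals", call. = FALSE)
  dinv <- diag_of_inverse(system$C)[system$animal_index]
  pev <- params$sigma_e2 * dinv
  if (any(pev < -1e-8)) {
    stop("negative prediction error variance; the system is mis-assembled",
         call. = FALSE)
  }
  pev <- pmax(pev, 0)
  rel <- 1 - pev / (params$sigma_a2 * (1 + f))
  rel <- pmin(pmax(rel, 0), 1)
  reliability_table(system$animal_ids, pev, rel, "exact", scenario_label)
}

reliability_table <- function(animal, PEV, reliability, flavor, scenario) {
  structure(
    data.frame(animal = animal, PEV = as.numeric(PEV),
               reliability = as.numeric(reliability),
               flavor = flavor, scenario = scenario, row.names = NULL),
    class = c("reliability_table", "data.frame")
  )
}
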