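# APY sparse inverse of the genomic relationship matrix.
#
# Noncore breeding values are modeled conditionally on the core:
#   u_n = G_nc G_cc^{-1} u_c + eps,   Var(eps) = M_nn (diagonal),
# which gives the familiar block inverse with a *diagonal*
# noncore-noncore block:
#   G_APY^{-1} = [ G_cc^{-1} + U M^{-1} U'   -U M^{-1} ]
#                [ -M^{-1} U'                 M^{-1}   ],  U = G_cc^{-1} G_cn.
# Storage and factorization cost are quadratic in n_c and linear in n_n.

#' Build the APY inverse of a GRM for a core/noncore partition
#'
#' @param grm A [build_grm()] result (positive definite on the core).
#' @param partition A [core_partition()].
#' @param rcond_cap Reciprocal-condition cap for the core block; a
#'   cheaper-than-exact Cholesky-based estimate below this value raises
#'   an error rather than silently corrupting `M_nn`.
#' @param mnn_tol Positivity tolerance for the conditional variances.
#' @return Object of class `apy_inverse`: list with `partition`, dense
#'   `Gcc`, `Gcn`, diagonal `Mnn` (named by noncore id), `Gcc_inv`,
#'   `U = Gcc^{-1} Gcn`, and `ids` (core then noncore) plus
#'   `orig_ids` (the GRM order).
#' @export
build_apy_inverse <- function(grm, partition, rcond_cap = 1e-12, mnn_tol = 1e-10) {
  stopifnot(inherits(grm, "grm"), inherits(partition, "core_partition"))
  ci <- match(partition$core_ids, grm$ids)
  ni <- match(partition$noncore_ids, grm$ids)
  if (anyNA(ci) || anyNA(ni)) stop("partition ids must all be in the GRM", call. = FALSE)
  Gcc <- grm$G[ci, ci, drop = FALSE]
  R <- tryCatch(chol(Gcc), error = function(e) {
    stop("core block of G is not positive definite; choose a different or larger core",
         call. = FALSE)
  })
  rc <- (min(diag(R)) / max(diag(R)))^2
  if (rc < rcond_cap) {
    stop(sprintf(paste0("core block of G is numerically singular ",
                        "(rcond estimate %.1e); choose a different or larger core"), rc),
         call. = FALSE)
  }
  if (length(ni)) {
    Gcn <- grm$G[ci, ni, drop = FALSE]
    tmp <- forwardsolve(t(R), Gcn)                    # R^{-T} G_cn
    Mnn <- diag(grm$G)[ni] - colSums(tmp^2)
    names(Mnn) <- partition$noncore_ids
    if (any(Mnn <= mnn_tol)) {
      bad <- partition$noncore_ids[Mnn <= mnn_tol][1]
      stop("conditional variance M_nn is not positive for animal ", bad,
           "; G is not positive definite for this core", call. = FALSE)
    }
    U <- backsolve(R, tmp)                            # G_cc^{-1} G_cn
  } else {
    Gcn <- matrix(0, length(ci), 0)
    Mnn <- numeric(0)
    U <- matrix(0, length(ci), 0)
  }
  structure(
    list(partition = partition, Gcc = Gcc, Gcn = Gcn, Mnn = Mnn,
         Gcc_inv = chol2inv(R), U = U,
         ids = c(partition$core_ids, partition$noncore_ids),
         orig_ids = grm$ids),
    class = "apy_inverse"
  )
}

#' @exportS3Method base::print
print.apy_inverse <- function(x, ...) {
  nc <- length(x$partition$core_ids); nn <- length(x$partition$noncore_ids)
  cat(sprintf("apy_inverse: %d core / %d noncore (noncore:core = %.1f)\n",
              nc, nn, nn / nc))
  invisible(x)
}

#' Assemble the APY inverse as a sparse matrix
#'
#' Structural nonzeros: `n_c^2 + 2 n_c n_n + n_n` (dense core block, two
#' cross blocks, diagonal noncore block).
#'
#' @param apy An `apy_inverse`.
#' @param order `"original"` (GRM id order, the default) or
#'   `"core_first"`.
#' @return Sparse symmetric matrix (dgCMatrix) with id dimnames.
#' @export
apy_assemble <- function(apy, order = c("original", "core_first")) {
  order <- match.arg(order)
  nc <- length(apy$partition$core_ids)
  nn <- length(apy$partition$noncore_ids)
  Minv <- if (nn) 1 / apy$Mnn else numeric(0)
  Bcc <- apy$Gcc_inv
  if (nn) {
    Um <- sweep(apy$U, 2, Minv, `*`)                  # U M^{-1}
    Bcc <- Bcc + tcrossprod(Um, apy$U)                # + U M^{-1} U'
    Bcn <- -Um
  }
  ii <- rep(seq_len(nc), times = nc)
  jj <- rep(seq_len(nc), each = nc)
  xx <- as.vector(Bcc)
  if (nn) {
    ci <- rep(seq_len(nc), times = nn)
    nj <- rep(nc + seq_len(nn), each = nc)
    ii <- c(ii, ci, nj, nc + seq_len(nn))
    jj <- c(jj, nj, ci, nc + seq_len(nn))
    xx <- c(xx, as.vector(Bcn), as.vector(Bcn), Minv)
  }
  ids <- apy$ids
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nc + nn, nc + nn),
                            dimnames = list(ids, ids))
  if (order == "original") {
    perm <- match(apy$orig_ids, ids)
    M <- M[perm, perm, drop = FALSE]
  }
  M
}
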