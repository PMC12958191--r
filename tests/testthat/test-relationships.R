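test_that("A-inverse follows Henderson's rules on canonical pedigrees", {
  # founders only: identity
  ped <- make_pedigree(1:3, c(0, 0, 0), c(0, 0, 0))
  nr <- build_A_inverse(ped)
  expect_equal(as.matrix(nr$A_inverse), diag(3), ignore_attr = TRUE)

  # trio: closed-form inverse of tabular A
  nr <- build_A_inverse(trio_pedigree())
  expected <- matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3)
  expect_equal(as.matrix(nr$A_inverse), expected, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("A-inverse inverts tabular A on random pedigrees with inbreeding", {
  sp <- small_population(seed = 13)
  A <- pedigree_A(sp$ped)
  nr <- build_A_inverse(sp$ped, A = A)
  expect_lt(max(abs(A %*% as.matrix(nr$A_inverse) - diag(nrow(A)))), 1e-8)
})

test_that("inbreeding: full-sib mating offspring has F = 0.25", {
  ped <- make_pedigree(1:5, c(0, 0, 1, 1, 3), c(0, 0, 2, 2, 4))
  f <- inbreeding_coefficients(ped)
  expect_equal(unname(f[as.character(1:4)]), rep(0, 4))
  expect_equal(unname(f[["5"]]), 0.25)
})

test_that("A22 equals the corresponding block of tabular A", {
  sp <- small_population(seed = 17)
  A <- pedigree_A(sp$ped)
  ids <- sort(sample(sp$ped$animal, 10))
  A22 <- build_A22(sp$ped, ids, A = A)
  expect_equal(A22, A[as.character(ids), as.character(ids)])
  # all animals: A22 = A; unrelated founders: identity
  expect_equal(build_A22(sp$ped, sp$ped$animal, A = A), A)
  ped2 <- make_pedigree(1:2, c(0, 0), c(0, 0))
  expect_equal(build_A22(ped2, 1:2), diag(2), ignore_attr = TRUE)
  expect_error(build_A22(sp$ped, c(1, 999999)), "not in pedigree")
})

test_that("GRM follows the centered cross-product recipe", {
  # hand example: 2 animals, 2 loci, alpha = 1
  gs <- genotype_set(1:2, matrix(c(0, 2, 2, 0), 2, 2))
  g <- build_grm(gs, alpha = 1)
  expect_equal(gs$allele_freq, c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(g$G, matrix(c(2, -2, -2, 2), 2, 2), ignore_attr = TRUE)

  # identical heterozygous animals: W = 0, G = (1-alpha) A22
  gs <- genotype_set(1:3, matrix(1, 3, 4))
  A22 <- diag(3); dimnames(A22) <- list(1:3, 1:3)
  g <- build_grm(gs, A22 = A22, alpha = 0.9)
  expect_equal(g$G, 0.1 * A22, ignore_attr = TRUE)
  # a monomorphic locus is dropped with a warning and changes nothing
  gs2 <- genotype_set(1:3, cbind(matrix(1, 3, 4), c(0, 0, 0)))
  expect_warning(g2 <- build_grm(gs2, A22 = A22, alpha = 0.9), "1 monomorphic")
  expect_equal(g2$G, 0.1 * A22, ignore_attr = TRUE)
  expect_error(
    suppressWarnings(build_grm(genotype_set(1:2, matrix(c(0, 0, 2, 2), 2)), alpha = 1)),
    "monomorphic")
})

test_that("mean GRM diagonal tracks 1 + mean inbreeding", {
  sp <- small_population(seed = 23, founders = 200, generations = 3,
                         m = 500, gfrac = 1)
  gs <- genotype_subset(sp$gen, sp$gids)
  g <- build_grm(gs, alpha = 1)
  f <- inbreeding_coefficients(sp$ped)
  expect_lt(abs(mean(diag(g$G)) - (1 + mean(f))), 0.05)
})

test_that("core sizing follows the cumulative spectrum", {
  # construct W with prescribed singular values proportional to (2, 1, 1)
  # via orthogonal factors; variance shares are then (4/6, 5/6, 6/6)
  # cumulative variance shares 4/6, 5/6, 6/6: threshold 0.98 -> 3, 0.80 -> 2
  set.seed(101)
  d <- 0.3 * c(2, 1, 1)
  # left factors orthonormal and orthogonal to the ones vector, so the
  # constructed matrix is already column-centered and keeps its spectrum
  U <- qr.Q(qr(cbind(1, matrix(rnorm(12), 4))))[, 2:4]
  V <- qr.Q(qr(matrix(rnorm(16), 4)))[, 1:3]
  Wc <- U %*% diag(d) %*% t(V)
  stopifnot(max(abs(colMeans(Wc))) < 1e-14, max(abs(Wc)) < 1)
  Z <- sweep(Wc, 2, 1, `+`)                  # column means exactly 1 => p = 0.5
  gs <- genotype_set(1:4, Z)
  expect_equal(choose_core_size(gs, 0.98), 3L)
  expect_equal(choose_core_size(gs, 0.80), 2L)
  expect_equal(choose_core_size(gs, 0.50), 1L)
  # monotone in threshold
  ks <- vapply(c(0.3, 0.5, 0.8, 0.95, 1), function(t) choose_core_size(gs, t), 1L)
  expect_true(all(diff(ks) >= 0))
})

test_that("core sizing handles rank-1 and degenerate input", {
  W <- 0.3 * outer(c(1, -1, 0.5), c(1, 2, 1, 0.5))
  Z <- sweep(W, 2, 1, `+`)
  stopifnot(all(Z >= 0 & Z <= 2))
  gs <- genotype_set(1:3, Z)
  expect_equal(choose_core_size(gs, 0.5), 1L)
  expect_equal(choose_core_size(gs, 0.999), 1L)
  expect_error(choose_core_size(genotype_set(1:2, matrix(1, 2, 2)), 0.9),
               "no variance")
})

test_that("nested cores are nested, sized, and seed-deterministic", {
  ids <- 1:6
  parts <- select_nested_cores(ids, c(3, 2, 1), seed = 5)
  expect_equal(lengths(lapply(parts, `[[`, "core_ids")), c(3, 2, 1))
  expect_true(all(parts[[2]]$core_ids %in% parts[[1]]$core_ids))
  expect_true(all(parts[[3]]$core_ids %in% parts[[2]]$core_ids))
  expect_identical(parts, select_nested_cores(ids, c(3, 2, 1), seed = 5))
  # full-core partition
  p <- select_nested_cores(ids, 6, seed = 1)[[1]]
  expect_setequal(p$core_ids, ids)
  expect_length(p$noncore_ids, 0)
  expect_error(select_nested_cores(ids, c(2, 3)), "descending")
  expect_error(select_nested_cores(ids, 7), "exceeds")
})

test_that("APY inverse is exact for canonical cases", {
  # full core: equals dense inverse
  g <- structure(list(G = matrix(c(1, .5, .5, 1), 2, dimnames = list(1:2, 1:2)),
                      ids = 1:2, alpha = 1, n_dropped_loci = 0L), class = "grm")
  apy <- build_apy_inverse(g, core_partition(1:2, 1:2))
  expect_equal(as.matrix(apy_assemble(apy)),
               matrix(c(4/3, -2/3, -2/3, 4/3), 2), ignore_attr = TRUE,
               tolerance = 1e-12)

  # identity G: inverse is identity for any partition, Mnn all 1
  gI <- structure(list(G = diag(3), ids = 1:3, alpha = 1, n_dropped_loci = 0L),
                  class = "grm")
  dimnames(gI$G) <- list(1:3, 1:3)
  apy <- build_apy_inverse(gI, core_partition(2, 1:3))
  expect_equal(unname(apy$Mnn), c(1, 1))
  expect_equal(as.matrix(apy_assemble(apy)), diag(3), ignore_attr = TRUE)

  # 3x3 worked example, core = {1}
  G3 <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, dimnames = list(1:3, 1:3))
  g3 <- structure(list(G = G3, ids = 1:3, alpha = 1, n_dropped_loci = 0L),
                  class = "grm")
  apy <- build_apy_inverse(g3, core_partition(1, 1:3))
  expect_equal(unname(apy$Mnn), c(0.75, 0.9375))
  G_apy <- matrix(c(1, .5, .25, .5, 1, .125, .25, .125, 1), 3)
  expect_equal(as.matrix(apy_assemble(apy)), solve(G_apy), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("assembled APY inverse inverts the dense oracle G_APY", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:120, 1)
    g <- make_pd_grm(n, seed = seed)
    nc <- sample(seq(2, n - 1), 1)
    part <- core_partition(sort(sample(g$ids, nc)), g$ids)
    apy <- build_apy_inverse(g, part)
    # independent dense oracle
    ci <- match(part$core_ids, g$ids); ni <- match(part$noncore_ids, g$ids)
    Gcc <- g$G[ci, ci, drop = FALSE]; Gcn <- g$G[ci, ni, drop = FALSE]
    Mnn <- diag(g$G)[ni] - diag(t(Gcn) %*% solve(Gcc) %*% Gcn)
    G_apy <- rbind(cbind(Gcc, Gcn),
                   cbind(t(Gcn), t(Gcn) %*% solve(Gcc) %*% Gcn +
                           diag(Mnn, nrow = length(Mnn))))
    M <- as.matrix(apy_assemble(apy, order = "core_first"))
    expect_lt(max(abs(M %*% G_apy - diag(n))), 1e-8)
  }
})

test_that("APY inverse has the expected sparsity pattern", {
  g <- make_pd_grm(60, seed = 7)
  part <- core_partition(sort(sample(g$ids, 15)), g$ids)
  M <- apy_assemble(build_apy_inverse(g, part))
  nc <- 15; nn <- 45
  expect_equal(Matrix::nnzero(M), nc^2 + 2 * nc * nn + nn)
  # noncore-noncore block exactly diagonal
  Mc <- as.matrix(M)[as.character(part$noncore_ids), as.character(part$noncore_ids)]
  expect_true(all(Mc[upper.tri(Mc)] == 0) && all(Mc[lower.tri(Mc)] == 0))
})

test_that("APY construction rejects degenerate cores", {
  g <- make_pd_grm(10, seed = 3)
  g$G[1, 1] <- 0   # not PD
  expect_error(build_apy_inverse(g, core_partition(1:3, g$ids)),
               "positive definite")
})
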