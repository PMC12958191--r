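test_that("H-inverse reduces to A-inverse when the genomic term cancels", {
  sp <- small_population(seed = 31)
  A <- pedigree_A(sp$ped)
  nr <- build_A_inverse(sp$ped, genotyped_ids = sp$gids, A = A)
  pm <- model_params(0.3)
  # G = A22, tau = omega = 1 -> exact cancellation
  Hinv <- build_H_inverse(nr, chol2inv(chol(nr$A22)), sp$gids, pm)
  expect_lt(max(abs(as.matrix(Hinv) - as.matrix(nr$A_inverse))), 1e-8)
  # no genotyped animals -> A-inverse unchanged
  expect_identical(build_H_inverse(nr, NULL, NULL, pm), nr$A_inverse)
})

test_that("H-inverse matches the dense joint-density oracle", {
  # small instance: H from the block formula, then invert densely
  sp <- small_population(seed = 37, founders = 10, generations = 1, m = 80,
                         gfrac = 0.4)
  A <- pedigree_A(sp$ped)
  nr <- build_A_inverse(sp$ped, genotyped_ids = sp$gids, A = A)
  gs <- genotype_subset(sp$gen, sp$gids)
  g <- suppressWarnings(build_grm(gs, A22 = nr$A22, alpha = 0.95))
  pm <- model_params(0.3)
  Hinv <- build_H_inverse(nr, solve(g$G), sp$gids, pm)
  # oracle: H = A except genotyped block replaced per the standard identity
  # H22 = G + A21 A11^{-1} (A12 ... ) -- equivalently H^{-1} built densely
  gi <- match(sp$gids, sp$ped$animal)
  Ainv <- solve(A)
  Horacle_inv <- Ainv
  Horacle_inv[gi, gi] <- Horacle_inv[gi, gi] + solve(g$G) - solve(nr$A22)
  expect_lt(max(abs(as.matrix(Hinv) - Horacle_inv)), 1e-8)
  # and the implied H has the genotyped block structure of the joint density
  H <- solve(as.matrix(Hinv))
  A11 <- A[-gi, -gi]; A12 <- A[-gi, gi]
  H12 <- A12 %*% solve(nr$A22) %*% g$G
  expect_lt(max(abs(H[-gi, gi] - H12)), 1e-6)
  expect_lt(max(abs(H[gi, gi] - g$G)), 1e-6)
})

test_that("MME assembly matches hand computation", {
  pm <- model_params(0.3)   # lambda = 7/3
  # one animal, one record, no fixed effects
  ped <- make_pedigree(1, 0, 0)
  nr <- build_A_inverse(ped)
  phe <- data.frame(animal = 1, value = 2.5)
  sys <- assemble_mme(phe, fixed = "none", H_inverse = nr$A_inverse, params = pm)
  expect_equal(as.matrix(sys$C), matrix(1 + pm$lambda), ignore_attr = TRUE)
  expect_equal(sys$rhs, 2.5)
  # solution: u = y/(1 + lambda)
  sol <- solve_mme(sys)
  expect_equal(unname(sol$u), 2.5 / (1 + pm$lambda))

  # no phenotypes: animal block is lambda * H^{-1}, u = 0
  ped3 <- trio_pedigree()
  nr3 <- build_A_inverse(ped3)
  sys0 <- assemble_mme(data.frame(animal = integer(0), value = numeric(0)),
                       fixed = "none", H_inverse = nr3$A_inverse, params = pm)
  expect_equal(as.matrix(sys0$C), pm$lambda * as.matrix(nr3$A_inverse),
               ignore_attr = TRUE)
  expect_equal(unname(solve_mme(sys0)$u), rep(0, 3))

  # 5-animal worked instance with intercept: brute-force assembly
  ped5 <- make_pedigree(1:5, c(0, 0, 1, 1, 0), c(0, 0, 2, 2, 0))
  nr5 <- build_A_inverse(ped5)
  phe5 <- data.frame(animal = c(1, 3, 4), value = c(1, 2, 3))
  sys5 <- assemble_mme(phe5, fixed = "intercept", H_inverse = nr5$A_inverse,
                       params = pm)
  X <- matrix(1, 3, 1)
  W <- matrix(0, 3, 5); W[1, 1] <- W[2, 3] <- W[3, 4] <- 1
  Cb <- rbind(cbind(crossprod(X), crossprod(X, W)),
              cbind(crossprod(W, X), crossprod(W) + pm$lambda * as.matrix(nr5$A_inverse)))
  expect_equal(as.matrix(sys5$C), Cb, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sys5$rhs, c(6, 1, 0, 2, 3, 0))
  expect_error(assemble_mme(data.frame(animal = 99, value = 1), "none",
                            nr5$A_inverse, pm), "unknown animal")
})

test_that("sparse MME solve equals the dense solve", {
  sp <- small_population(seed = 41, founders = 20, generations = 2, m = 60)
  nr <- build_A_inverse(sp$ped)
  pm <- model_params(0.25)
  sys <- assemble_mme(sp$phe, "intercept", nr$A_inverse, pm)
  sol <- solve_mme(sys)
  dense <- solve(as.matrix(sys$C), sys$rhs)
  expect_equal(unname(sol$u), unname(dense[sys$animal_index]), tolerance = 1e-8)
})

test_that("exact reliabilities reproduce closed forms and the dense oracle", {
  for (h2 in c(0.042, 0.30)) {
    pm <- model_params(h2)
    ped <- make_pedigree(1, 0, 0)
    nr <- build_A_inverse(ped)
    sys <- assemble_mme(data.frame(animal = 1, value = 1), "none",
                        nr$A_inverse, pm)
    rel <- exact_reliabilities(sys, pm, nr$inbreeding)
    # single animal, one record, no relatives: reliability = h2
    expect_equal(rel$reliability, h2, tolerance = 1e-10)
    expect_equal(rel$PEV, pm$sigma_e2 / (1 + pm$lambda), tolerance = 1e-10)
  }
  # animal with no record and no relatives: reliability 0
  ped2 <- make_pedigree(1:2, 0, 0)
  nr2 <- build_A_inverse(ped2)
  pm <- model_params(0.3)
  sys2 <- assemble_mme(data.frame(animal = 1, value = 1), "none",
                       nr2$A_inverse, pm)
  rel2 <- exact_reliabilities(sys2, pm, nr2$inbreeding)
  expect_equal(rel2$reliability[rel2$animal == "2"], 0)

  # 30-animal pedigree: equals explicit dense inversion of C
  sp <- small_population(seed = 43, founders = 10, generations = 2, m = 50)
  nr <- build_A_inverse(sp$ped)
  sys <- assemble_mme(sp$phe, "intercept", nr$A_inverse, pm)
  rel <- exact_reliabilities(sys, pm, nr$inbreeding)
  Cinv <- solve(as.matrix(sys$C))
  pev <- pm$sigma_e2 * diag(Cinv)[sys$animal_index]
  f <- nr$inbreeding[as.character(sys$animal_ids)]
  expect_equal(rel$PEV, unname(pev), tolerance = 1e-9)
  expect_equal(rel$reliability,
               unname(pmin(pmax(1 - pev / (pm$sigma_a2 * (1 + f)), 0), 1)),
               tolerance = 1e-9)
  expect_true(all(rel$reliability >= 0 & rel$reliability <= 1))
})

test_that("adding a record never decreases an animal's exact reliability", {
  sp <- small_population(seed = 47, founders = 14, generations = 2, m = 40)
  nr <- build_A_inverse(sp$ped)
  pm <- model_params(0.3)
  rec <- sp$phe$records
  unrec <- setdiff(sp$ped$animal, rec$animal)
  sys1 <- assemble_mme(rec, "intercept", nr$A_inverse, pm)
  r1 <- rel_named(exact_reliabilities(sys1, pm, nr$inbreeding))
  for (a in unrec[seq_len(min(3, length(unrec)))]) {
    rec2 <- rbind(rec, data.frame(animal = a, value = 1, group = 1))
    sys2 <- assemble_mme(rec2, "intercept", nr$A_inverse, pm)
    r2 <- rel_named(exact_reliabilities(sys2, pm, nr$inbreeding))
    expect_gte(r2[[as.character(a)]], r1[[as.character(a)]] - 1e-10)
  }
})

test_that("ssGBLUP with G = A22 equals pedigree BLUP", {
  sp <- small_population(seed = 53, founders = 10, generations = 2, m = 60,
                         gfrac = 0.4)
  A <- pedigree_A(sp$ped)
  nr <- build_A_inverse(sp$ped, genotyped_ids = sp$gids, A = A)
  pm <- model_params(0.3)
  Hinv <- build_H_inverse(nr, chol2inv(chol(nr$A22)), sp$gids, pm)
  sysH <- assemble_mme(sp$phe, "intercept", Hinv, pm)
  sysA <- assemble_mme(sp$phe, "intercept", nr$A_inverse, pm)
  rH <- exact_reliabilities(sysH, pm, nr$inbreeding)
  rA <- exact_reliabilities(sysA, pm, nr$inbreeding)
  expect_lt(max(abs(rH$reliability - rA$reliability)), 1e-8)
})
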