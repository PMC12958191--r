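# Shared fixture builders. Everything is generated in code; no files.

# pedigree from a plain data frame (animal/sire/dam, 0 = unknown)
make_pedigree <- function(animal, sire, dam) {
  apycore:::new_pedigree(data.frame(animal = as.integer(animal),
                                    sire = as.integer(sire),
                                    dam = as.integer(dam)))
}

# trio: two unrelated founders and one offspring
trio_pedigree <- function() make_pedigree(1:3, c(0, 0, 1), c(0, 0, 2))

# random positive-definite "GRM" with unit-scale diagonal (Wishart-like)
make_pd_grm <- function(n, seed = 1, m = 2L * n) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  G <- tcrossprod(X) / m
  ids <- seq_len(n)
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, ids = ids, alpha = 1, n_dropped_loci = 0L), class = "grm")
}

# small simulated population shared by several tests
small_population <- function(seed = 11, h2 = 0.3, mode = "continuous",
                             founders = 40, generations = 3, m = 150,
                             gfrac = 0.5) {
  cfg <- sim_config(n_founders = founders, n_generations = generations,
                    m_snps = m, genotyped_fraction = gfrac,
                    heritability = h2, trait_mode = mode, seed = seed)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  phe <- simulate_phenotypes(ped, gen, cfg)
  gids <- select_genotyped(ped, cfg)
  list(cfg = cfg, ped = ped, gen = gen, phe = phe, gids = gids)
}

rel_named <- function(tab) stats::setNames(tab$reliability, tab$animal)
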