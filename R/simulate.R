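# Synthetic population generator: pedigree, gene-dropped genotypes,
# additive animal-model phenotypes.  Distinct deterministic seed offsets
# per stage so that e.g. regenerating phenotypes does not shift the
# pedigree stream.
.seed_offset <- c(pedigree = 0L, genotypes = 1L, phenotypes = 2L, genotyped = 3L)

.sim_seed <- function(config, stage) {
  config$seed + .seed_offset[[stage]]
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders have unknown parents (sentinel 0). Each subsequent
#' generation is produced by randomly pairing the animals of the
#' previous generation; every pair yields `offspring_per_dam` offspring.
#' Animal ids are consecutive integers in birth order, so every parent
#' precedes its offspring.
#'
#' @param config A [sim_config()].
#' @return An object of class `apy_pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` (0 = unknown) and `generation`, ordered by
#'   birth.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "pedigree"))
  animal <- seq_len(config$n_founders)
  sire <- dam <- rep(0L, config$n_founders)
  generation <- rep(0L, config$n_founders)
  prev <- animal
  next_id <- config$n_founders + 1L
  for (g in seq_len(config$n_generations)) {
    if (length(prev) < 2L) break
    perm <- sample(prev)
    n_pair <- length(prev) %/% 2L
    sires <- perm[seq_len(n_pair)]
    dams <- perm[n_pair + seq_len(n_pair)]
    n_off <- n_pair * config$offspring_per_dam
    off_ids <- seq.int(next_id, length.out = n_off)
    animal <- c(animal, off_ids)
    sire <- c(sire, rep(sires, each = config$offspring_per_dam))
    dam <- c(dam, rep(dams, each = config$offspring_per_dam))
    generation <- c(generation, rep(g, n_off))
    prev <- off_ids
    next_id <- next_id + n_off
  }
  new_pedigree(data.frame(animal = as.integer(animal), sire = as.integer(sire),
                          dam = as.integer(dam), generation = as.integer(generation)))
}

new_pedigree <- function(df) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  if (is.null(df$generation)) df$generation <- NA_integer_
  validate_pedigree(df)
  structure(df, class = c("apy_pedigree", "data.frame"))
}

validate_pedigree <- function(df) {
  if (nrow(df) == 0) stop("empty pedigree", call. = FALSE)
  if (anyDuplicated(df$animal)) {
    stop("duplicate animal id: ", df$animal[duplicated(df$animal)][1], call. = FALSE)
  }
  for (col in c("sire", "dam")) {
    p <- df[[col]]
    known <- p != 0L
    if (any(p[known] == df$animal[known])) {
      bad <- df$animal[known][p[known] == df$animal[known]][1]
      stop("animal ", bad, " is recorded as its own parent", call. = FALSE)
    }
    idx <- match(p[known], df$animal)
    if (anyNA(idx)) {
      stop("parent id ", p[known][is.na(idx)][1], " has no pedigree entry", call. = FALSE)
    }
    if (any(idx >= which(known))) {
      bad <- df$animal[known][idx >= which(known)][1]
      stop("parent of animal ", bad,
           " does not precede it; sort the pedigree in birth order", call. = FALSE)
    }
  }
  invisible(df)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder allele counts at locus j are Binomial(2, p_j) with p_j drawn
#' uniformly from `maf_range`. Each offspring receives one allele from
#' each parent, sampled from the parent's gene content (Mendelian gene
#' dropping); an unknown parent contributes a founder-frequency draw.
#'
#' @param pedigree An `apy_pedigree`.
#' @param config A [sim_config()].
#' @return A [genotype_set()] covering every animal in the pedigree.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(pedigree, "apy_pedigree"), inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "genotypes"))
  n <- nrow(pedigree)
  m <- config$m_snps
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  Z <- matrix(0L, n, m)
  si <- match(pedigree$sire, pedigree$animal)  # NA for unknown
  di <- match(pedigree$dam, pedigree$animal)
  for (i in seq_len(n)) {
    a1 <- if (is.na(si[i])) stats::rbinom(m, 1L, p0) else stats::rbinom(m, 1L, Z[si[i], ] / 2)
    a2 <- if (is.na(di[i])) stats::rbinom(m, 1L, p0) else stats::rbinom(m, 1L, Z[di[i], ] / 2)
    Z[i, ] <- a1 + a2
  }
  rownames(Z) <- pedigree$animal
  genotype_set(ids = pedigree$animal, Z = Z)
}

#' Simulate phenotypes under the additive animal model
#'
#' True breeding values are `u = W a` with `W` the column-centered gene
#' content matrix and i.i.d. normal SNP effects rescaled so that the
#' realized additive variance equals `h2` of a unit total variance.
#' Records are `y = mu + fixed + u + e` with residual variance `1 - h2`,
#' for a random `record_fraction` of animals. In `binary_1_2` mode the
#' liability is thresholded at the normal quantile giving
#' `binary_incidence` and coded 1 (unaffected) / 2 (affected); the coded
#' values are analyzed with the linear model downstream.
#'
#' @param pedigree An `apy_pedigree`.
#' @param genotypes A [genotype_set()] covering all pedigree animals.
#' @param config A [sim_config()].
#' @return An object of class `phenotype_set`: list with `records`
#'   (data frame `animal`, `value`, `group`), `tbv` (named vector of true
#'   breeding values for all animals) and `mu`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  stopifnot(inherits(pedigree, "apy_pedigree"), inherits(genotypes, "genotype_set"),
            inherits(config, "sim_config"))
  if (!(config$heritability > 0 && config$heritability < 1)) {
    stop("heritability must be in (0, 1)", call. = FALSE)
  }
  set.seed(.sim_seed(config, "phenotypes"))
  h2 <- config$heritability
  Z <- genotypes$Z[as.character(pedigree$animal), , drop = FALSE]
  W <- sweep(Z, 2, 2 * genotypes$allele_freq)
  a <- stats::rnorm(ncol(W))
  u <- drop(W %*% a)
  v <- stats::var(u)
  if (v <= 0) stop("no genetic variance in the simulated genotypes", call. = FALSE)
  u <- u * sqrt(h2 / v)
  n <- nrow(pedigree)
  e <- stats::rnorm(n, 0, sqrt(1 - h2))
  group <- if (config$n_fixed_levels > 1L) {
    sample.int(config$n_fixed_levels, n, replace = TRUE)
  } else {
    rep(1L, n)
  }
  group_eff <- if (config$n_fixed_levels > 1L) stats::rnorm(config$n_fixed_levels) else 0
  mu <- 0
  y <- mu + group_eff[group] + u + e
  if (config$trait_mode == "binary_1_2") {
    thr <- stats::qnorm(1 - config$binary_incidence, mean = mu, sd = 1)
    y <- ifelse(y > thr, 2, 1)
  }
  n_rec <- max(1L, floor(config$record_fraction * n))
  rec_idx <- sort(sample.int(n, n_rec))
  names(u) <- pedigree$animal
  structure(
    list(
      records = data.frame(animal = pedigree$animal[rec_idx],
                           value = y[rec_idx],
                           group = group[rec_idx]),
      tbv = u,
      mu = mu
    ),
    class = "phenotype_set"
  )
}

#' Select the genotyped subset of a pedigree
#'
#' Draws `floor(genotyped_fraction * n)` animals (minimum 1) uniformly
#' at random; the returned ids are sorted in birth order so downstream
#' matrices have a fixed row order.
#'
#' @param pedigree An `apy_pedigree`.
#' @param config A [sim_config()].
#' @return Integer vector of genotyped animal ids, ascending.
#' @export
select_genotyped <- function(pedigree, config) {
  stopifnot(inherits(pedigree, "apy_pedigree"), inherits(config, "sim_config"))
  n <- nrow(pedigree)
  n_g <- max(1L, floor(config$genotyped_fraction * n))
  if (n_g < 1L) stop("genotyped fraction selects no animals", call. = FALSE)
  set.seed(.sim_seed(config, "genotyped"))
  sort(sample(pedigree$animal, n_g))
}
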