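#' Simulation configuration for the synthetic dairy population
#'
#' Bundles every knob of the synthetic-data generator: pedigree shape,
#' SNP panel, trait architecture and the seed. The defaults emulate a
#' lowly heritable binary health trait (coded 1 = healthy, 2 = affected)
#' evaluated with a linear animal model, i.e. the kind of calf disease
#' trait for which large-scale reliability approximation matters, at a
#' desk scale where exact dense oracles are still computable.
#'
#' @param n_founders Number of unrelated founder animals (>= 2).
#' @param n_generations Number of discrete generations bred by random
#'   mating after the founders (0 = founders only).
#' @param offspring_per_dam Offspring produced by each mated pair per
#'   generation. With the default of 2 the population size stays
#'   approximately constant across generations.
#' @param genotyped_fraction Fraction of all animals that end up with
#'   genotypes, in (0, 1].
#' @param m_snps Number of biallelic SNP markers.
#' @param maf_range Length-2 numeric, lower/upper bound of the uniform
#'   distribution founder allele frequencies are drawn from, in (0, 0.5].
#' @param heritability Narrow-sense heritability of the trait, in (0, 1).
#'   Default 0.042, a typical value for a binary calf health trait; 0.30
#'   is the usual "moderate heritability" sensitivity setting.
#' @param trait_mode `"binary_1_2"` (liability thresholded and coded
#'   1/2) or `"continuous"`.
#' @param binary_incidence Target incidence of code 2 in binary mode.
#' @param record_fraction Fraction of animals with a phenotype record
#'   (single-record animal model; the rest contribute only relationships).
#' @param n_fixed_levels Number of levels of one categorical fixed
#'   effect (1 = overall mean only).
#' @param seed Integer seed; identical configurations reproduce
#'   bit-identical populations.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 20, n_generations = 2, m_snps = 50, seed = 42)
#' ped <- simulate_pedigree(cfg)
sim_config <- function(n_founders = 400,
                       n_generations = 4,
                       offspring_per_dam = 2,
                       genotyped_fraction = 0.4,
                       m_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       heritability = 0.042,
                       trait_mode = c("binary_1_2", "continuous"),
                       binary_incidence = 0.2,
                       record_fraction = 0.6,
                       n_fixed_levels = 1,
                       seed = 1L) {
  trait_mode <- match.arg(trait_mode)
  stopifnot(
    is.numeric(n_founders), length(n_founders) == 1, n_founders >= 2,
    is.numeric(n_generations), n_generations >= 0,
    is.numeric(offspring_per_dam), offspring_per_dam >= 1,
    is.numeric(m_snps), m_snps >= 1,
    length(maf_range) == 2
  )
  if (!(genotyped_fraction > 0 && genotyped_fraction <= 1)) {
    stop("`genotyped_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!(heritability > 0 && heritability < 1)) {
    stop("`heritability` must be in (0, 1)", call. = FALSE)
  }
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2])) {
    stop("`maf_range` must satisfy 0 < lower <= upper <= 0.5", call. = FALSE)
  }
  if (!(binary_incidence > 0 && binary_incidence < 1)) {
    stop("`binary_incidence` must be in (0, 1)", call. = FALSE)
  }
  if (!(record_fraction > 0 && record_fraction <= 1)) {
    stop("`record_fraction` must be in (0, 1]", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > .Machine$integer.max - 10L) {
    stop("`seed` must be a finite 32-bit integer", call. = FALSE)
  }
  structure(
    list(
      n_founders = as.integer(n_founders),
      n_generations = as.integer(n_generations),
      offspring_per_dam = as.integer(offspring_per_dam),
      genotyped_fraction = genotyped_fraction,
      m_snps = as.integer(m_snps),
      maf_range = as.numeric(maf_range),
      heritability = heritability,
      trait_mode = trait_mode,
      binary_incidence = binary_incidence,
      record_fraction = record_fraction,
      n_fixed_levels = as.integer(n_fixed_levels),
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  pedigree : %d founders, %d generations, %d offspring/pair\n",
              x$n_founders, x$n_generations, x$offspring_per_dam))
  cat(sprintf("  genome   : %d SNPs, founder MAF ~ U(%.2f, %.2f)\n",
              x$m_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  trait    : %s, h2 = %.3f%s\n", x$trait_mode, x$heritability,
              if (x$trait_mode == "binary_1_2")
                sprintf(", incidence %.2f", x$binary_incidence) else ""))
  cat(sprintf("  genotyped fraction %.2f, record fraction %.2f, seed %d\n",
              x$genotyped_fraction, x$record_fraction, x$seed))
  invisible(x)
}
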