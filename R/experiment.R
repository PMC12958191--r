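# Core-reduction experiment: nested cores, benchmark vs reduced
# scenarios, N-/F-/R-core classification, comparison statistics and
# progeny stratification.

#' Classify genotyped animals by core membership
#'
#' For a (benchmark core, reduced core) pair: `R_core` = animals
#' retained in the reduced core, `F_core` = formerly core (in the
#' benchmark core but dropped), `N_core` = never core (noncore in every
#' scenario, since cores are nested).
#'
#' @param benchmark_core Benchmark core ids.
#' @param reduced_core Reduced core ids (must be nested in the benchmark
#'   core, nonempty).
#' @param genotyped_ids All genotyped ids.
#' @return Named factor over `genotyped_ids` with levels
#'   `R_core`, `F_core`, `N_core`.
#' @export
classify_groups <- function(benchmark_core, reduced_core, genotyped_ids) {
  if (length(reduced_core) < 1) stop("reduced core must be nonempty", call. = FALSE)
  if (!all(reduced_core %in% benchmark_core)) {
    stop("reduced core is not nested in the benchmark core", call. = FALSE)
  }
  if (!all(benchmark_core %in% genotyped_ids)) {
    stop("benchmark core must be genotyped", call. = FALSE)
  }
  g <- ifelse(genotyped_ids %in% reduced_core, "R_core",
              ifelse(genotyped_ids %in% benchmark_core, "F_core", "N_core"))
  stats::setNames(factor(g, levels = c("R_core", "F_core", "N_core")), genotyped_ids)
}

#' Comparison statistics between benchmark and candidate reliabilities
#'
#' Per animal group: mean difference `MD = mean(benchmark - candidate)`,
#' Pearson correlation, and intercept/slope of the ordinary
#' least-squares regression of the benchmark reliability (response) on
#' the candidate reliability (predictor). A zero-variance candidate
#' within a group is flagged `degenerate` with correlation and
#' regression coefficients reported as NA rather than propagated NaNs.
#'
#' @param benchmark,candidate `reliability_table`s or named numeric
#'   vectors over (at least) the genotyped animals.
#' @param labels A [classify_groups()] factor.
#' @return Data frame: `group`, `n`, `correlation`, `intercept`,
#'   `slope`, `MD`, `degenerate`.
#' @export
compare_reliabilities <- function(benchmark, candidate, labels) {
  as_vec <- function(x) {
    if (inherits(x, "reliability_table") || is.data.frame(x)) {
      stats::setNames(x$reliability, x$animal)
    } else x
  }
  b <- as_vec(benchmark); cn <- as_vec(candidate)
  ids <- names(labels)
  b <- b[ids]; cn <- cn[ids]
  if (anyNA(b) || anyNA(cn)) stop("reliability missing for some animals", call. = FALSE)
  out <- lapply(levels(labels), function(gr) {
    sel <- labels == gr
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(group = gr, n = 0L, correlation = NA_real_,
                        intercept = NA_real_, slope = NA_real_, MD = NA_real_,
                        degenerate = FALSE))
    }
    bb <- b[sel]; cc <- cn[sel]
    md <- mean(bb - cc)
    if (n < 2 || stats::var(cc) <= .Machine$double.eps) {
      return(data.frame(group = gr, n = n, correlation = NA_real_,
                        intercept = NA_real_, slope = NA_real_, MD = md,
                        degenerate = TRUE))
    }
    slope <- stats::cov(bb, cc) / stats::var(cc)
    intercept <- mean(bb) - slope * mean(cc)
    r <- if (stats::var(bb) <= .Machine$double.eps) NA_real_ else stats::cor(bb, cc)
    data.frame(group = gr, n = n, correlation = r, intercept = intercept,
               slope = slope, MD = md, degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Noncore-to-core ratio
#'
#' @param n_genotyped Number of genotyped animals.
#' @param n_core Core size (>= 1).
#' @return `(n_genotyped - n_core) / n_core` (full precision; tables
#'   round to one decimal).
#' @export
noncore_core_ratio <- function(n_genotyped, n_core) {
  if (n_core < 1) stop("`n_core` must be >= 1", call. = FALSE)
  if (n_core > n_genotyped) stop("`n_core` exceeds `n_genotyped`", call. = FALSE)
  (n_genotyped - n_core) / n_core
}

#' Benchmark core size from an eigenvalue count
#'
#' Rounds the number of eigenvalues explaining the target variance up
#' to the nearest multiple of `step` (default 5000), the conventional
#' round-up-to-5k rule for choosing a practical core size.
#'
#' @param n_eigen Eigenvalue count (e.g. the 99% count).
#' @param step Rounding step.
#' @return Integer core size.
#' @export
benchmark_core_size <- function(n_eigen, step = 5000) {
  if (n_eigen < 1) stop("`n_eigen` must be >= 1", call. = FALSE)
  as.integer(ceiling(n_eigen / step) * step)
}

#' Stratify reliability differences by progeny count and record status
#'
#' @param deltas Named vector of reliability differences
#'   (benchmark - candidate) per genotyped animal.
#' @param pedigree An `apy_pedigree` (progeny counted as appearances as
#'   sire or dam).
#' @param phenotypes A `phenotype_set` or data frame with an `animal`
#'   column (record status).
#' @param bins Increasing numeric breaks for progeny counts, e.g.
#'   `c(0, 1, 3, Inf)` for 0, 1-2, and 3+ progeny.
#' @return Data frame: `progeny_bin`, `has_record`, `n`, `mean_MD`
#'   (NA when the stratum is empty).
#' @export
stratify_by_progeny <- function(deltas, pedigree, phenotypes,
                                bins = c(0, 1, 3, Inf)) {
  stopifnot(inherits(pedigree, "apy_pedigree"))
  rec <- if (inherits(phenotypes, "phenotype_set")) phenotypes$records else phenotypes
  ids <- names(deltas)
  parents <- c(pedigree$sire, pedigree$dam)
  prog <- table(factor(parents[parents != 0], levels = pedigree$animal))
  np <- as.integer(prog[as.character(ids)])
  np[is.na(np)] <- 0L
  has_rec <- ids %in% as.character(rec$animal)
  bin <- cut(np, breaks = bins, right = FALSE, include.lowest = TRUE)
  grid <- expand.grid(progeny_bin = levels(bin), has_record = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- !is.na(bin) & as.character(bin) == grid$progeny_bin[i] &
      has_rec == grid$has_record[i]
    data.frame(progeny_bin = grid$progeny_bin[i], has_record = grid$has_record[i],
               n = sum(sel), mean_MD = if (any(sel)) mean(deltas[sel]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Configuration of the core-reduction experiment
#'
#' @param sim A [sim_config()] describing the synthetic population.
#' @param tau,omega H-inverse scaling factors.
#' @param blend_alpha GRM blending weight passed to [build_grm()].
#' @param eigen_threshold Variance fraction for the benchmark core size.
#' @param core_fractions Descending fractions of the eigen-based
#'   benchmark core defining the nested schedule; the first entry (1)
#'   is the benchmark itself.
#' @param replicates Number of replicate populations.
#' @param seeds Optional explicit replicate seeds (default
#'   `sim$seed + 0:(replicates-1)`).
#' @param sketch Optional [sketch_config()] applied to the expensive
#'   products of the approximation.
#' @param compute_exact Also compute exact MME reliabilities (the
#'   reduced-dataset benchmark path) and exact-vs-approximated tables.
#' @param progeny_bins Breaks for [stratify_by_progeny()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              tau = 1, omega = 1, blend_alpha = 0.95,
                              eigen_threshold = 0.99,
                              core_fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                              replicates = 5, seeds = NULL,
                              sketch = NULL, compute_exact = TRUE,
                              progeny_bins = c(0, 1, 3, Inf)) {
  stopifnot(inherits(sim, "sim_config"))
  if (is.null(seeds)) seeds <- sim$seed + seq_len(replicates) - 1L
  if (length(seeds) != replicates) stop("need one seed per replicate", call. = FALSE)
  if (any(diff(core_fractions) >= 0) && length(core_fractions) > 1) {
    stop("`core_fractions` must be strictly descending", call. = FALSE)
  }
  structure(list(sim = sim, tau = tau, omega = omega, blend_alpha = blend_alpha,
                 eigen_threshold = eigen_threshold,
                 core_fractions = core_fractions, replicates = as.integer(replicates),
                 seeds = as.integer(seeds), sketch = sketch,
                 compute_exact = isTRUE(compute_exact),
                 progeny_bins = progeny_bins),
            class = "experiment_config")
}

# one replicate of the full pipeline
run_replicate <- function(config, seed) {
  sim <- config$sim
  sim$seed <- as.integer(seed)
  ped <- simulate_pedigree(sim)
  geno_all <- simulate_genotypes(ped, sim)
  phen <- simulate_phenotypes(ped, geno_all, sim)
  gids <- select_genotyped(ped, sim)

  A <- pedigree_A(ped)
  numrel <- build_A_inverse(ped, genotyped_ids = gids, A = A)
  gset <- genotype_subset(geno_all, gids)
  grm <- build_grm(gset, A22 = numrel$A22, alpha = config$blend_alpha)
  params <- model_params(sim$heritability, tau = config$tau, omega = config$omega)

  k_eigen <- choose_core_size(gset, config$eigen_threshold)
  sizes <- unique(pmax(1L, as.integer(round(k_eigen * config$core_fractions))))
  partitions <- select_nested_cores(gids, sizes, seed = seed)

  fixed <- if (sim$n_fixed_levels > 1L) "group" else "intercept"
  ped_system <- assemble_mme(phen, fixed = fixed, H_inverse = numrel$A_inverse,
                             params = params)
  relP <- exact_reliabilities(ped_system, params, numrel$inbreeding, "pedigree")
  relP_g <- stats::setNames(relP$reliability, relP$animal)[as.character(gids)]
  weights <- reverse_reliability_weights(relP_g, params)
  names(weights) <- gids
  gdiag <- grm_diag(grm)
  # consistent pedigree-scale denominator for both pooling steps
  denom <- stats::setNames(1 + numrel$inbreeding[as.character(gids)], gids)
  relA22 <- pedigree_pooling_reliabilities(numrel$A22, weights, params,
                                           denominator = denom)

  approx <- lapply(partitions, function(part) {
    apy <- build_apy_inverse(grm, part)
    relG <- genomic_reliabilities(apy, gdiag, weights, params,
                                  sketch = config$sketch, denominator = denom)
    propagate_to_pedigree(relP, relG, params, ped_system, numrel$inbreeding,
                          baseline_rel = relA22,
                          scenario_label = part$scenario_label,
                          used_sketch = !is.null(config$sketch))
  })
  names(approx) <- vapply(partitions, `[[`, "", "scenario_label")

  exact <- NULL
  if (config$compute_exact) {
    apy_bench <- build_apy_inverse(grm, partitions[[1]])
    Hinv <- build_H_inverse(numrel, apy_bench, gids, params)
    sys_g <- assemble_mme(phen, fixed = fixed, H_inverse = Hinv, params = params)
    exact <- exact_reliabilities(sys_g, params, numrel$inbreeding,
                                 partitions[[1]]$scenario_label)
  }

  list(pedigree = ped, phenotypes = phen, genotyped_ids = gids,
       k_eigen = k_eigen, sizes = sizes, partitions = partitions,
       pedigree_rel = relP, approx = approx, exact = exact, params = params)
}

rel_vec <- function(tab, ids) {
  stats::setNames(tab$reliability, tab$animal)[as.character(ids)]
}

#' Run the core-reduction experiment
#'
#' Per replicate: simulate a population, build relationship matrices,
#' pick the benchmark core size from the GRM spectrum, approximate
#' reliabilities with the benchmark core and with each nested smaller
#' core, classify genotyped animals into R-/F-/N-core groups, and
#' compute comparison statistics of the benchmark approximation against
#' each reduction (and, optionally, of exact MME reliabilities against
#' every approximation). Reliability differences at the smallest core
#' are additionally stratified by progeny count and record status.
#'
#' @param config An [experiment_config()].
#' @return Object of class `experiment_report`: list with
#'   `stats_vs_benchmark`, `stats_vs_exact` (or NULL), `fidelity`
#'   (per-replicate correlation of the benchmark approximation with the
#'   exact reliabilities over genotyped animals), `ratios`, `strata`,
#'   `core_sizes`, `failed` (replicates that aborted, with the cause)
#'   and a `config` echo.
#' @export
run_core_reduction_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  stats_bench <- list(); stats_exact <- list(); strata <- list()
  fidelity <- list(); ratios <- list(); core_sizes <- list(); failed <- list()
  for (r in seq_len(config$replicates)) {
    seed <- config$seeds[r]
    res <- tryCatch(run_replicate(config, seed), error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- data.frame(replicate = r, seed = seed,
                                                  error = conditionMessage(res))
      next
    }
    gids <- res$genotyped_ids
    bench_label <- res$partitions[[1]]$scenario_label
    bench <- rel_vec(res$approx[[1]]$final_reliability, gids)
    core_sizes[[r]] <- data.frame(replicate = r, seed = seed,
                                  k_eigen = res$k_eigen,
                                  scenario = names(res$approx),
                                  core_size = res$sizes)
    for (k in seq_along(res$partitions)) {
      part <- res$partitions[[k]]
      lab <- part$scenario_label
      ratios[[length(ratios) + 1L]] <- data.frame(
        replicate = r, scenario = lab, scenario_rank = k,
        noncore_core_ratio = noncore_core_ratio(length(gids), length(part$core_ids)))
      labels <- classify_groups(res$partitions[[1]]$core_ids, part$core_ids, gids)
      if (k > 1) {
        cand <- rel_vec(res$approx[[k]]$final_reliability, gids)
        st <- compare_reliabilities(bench, cand, labels)
        st <- cbind(replicate = r, scenario = lab, scenario_rank = k, st)
        stats_bench[[length(stats_bench) + 1L]] <- st
      }
      if (!is.null(res$exact)) {
        ex <- rel_vec(res$exact, gids)
        cand <- rel_vec(res$approx[[k]]$final_reliability, gids)
        st <- compare_reliabilities(ex, cand, labels)
        st <- cbind(replicate = r, scenario = lab, scenario_rank = k, st)
        stats_exact[[length(stats_exact) + 1L]] <- st
        if (k == 1) {
          fidelity[[length(fidelity) + 1L]] <- data.frame(
            replicate = r, seed = seed,
            correlation_genotyped = stats::cor(ex, cand),
            correlation_all = stats::cor(rel_vec(res$exact, res$pedigree$animal),
                                         rel_vec(res$approx[[1]]$final_reliability,
                                                 res$pedigree$animal)))
        }
      }
    }
    smallest <- length(res$partitions)
    if (smallest > 1) {
      cand <- rel_vec(res$approx[[smallest]]$final_reliability, gids)
      deltas <- bench - cand
      st <- stratify_by_progeny(deltas, res$pedigree, res$phenotypes,
                                bins = config$progeny_bins)
      strata[[length(strata) + 1L]] <- cbind(replicate = r, st)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(
    list(stats_vs_benchmark = bind(stats_bench),
         stats_vs_exact = bind(stats_exact),
         fidelity = bind(fidelity),
         ratios = bind(ratios),
         strata = bind(strata),
         core_sizes = bind(core_sizes),
         failed = bind(failed),
         config = config),
    class = "experiment_report"
  )
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat("Core-reduction experiment report\n")
  cs <- x$core_sizes
  if (!is.null(cs)) {
    cat(sprintf("  replicates: %d (failed: %d); core schedule (replicate 1): %s\n",
                length(unique(cs$replicate)),
                if (is.null(x$failed)) 0L else nrow(x$failed),
                paste(cs$core_size[cs$replicate == cs$replicate[1]], collapse = ", ")))
  }
  if (!is.null(x$fidelity)) {
    cat(sprintf("  benchmark approximation vs exact: mean r = %.3f (genotyped)\n",
                mean(x$fidelity$correlation_genotyped)))
  }
  if (!is.null(x$stats_vs_benchmark)) {
    agg <- stats::aggregate(MD ~ scenario + group, x$stats_vs_benchmark, mean)
    cat("  mean MD (benchmark - candidate) by scenario and group:\n")
    print(utils::head(agg[order(agg$scenario, agg$group), ], 20), row.names = FALSE)
  }
  invisible(x)
}
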