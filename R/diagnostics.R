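# Monte Carlo diagnostics of double-pedigree identifiability and power.

# one simulated replicate: population, phenotypes, full (A+C) and reduced
# (A-only) fits.  Per-replicate seeds are counter-derived from the master
# seed so any scenario/replicate can be reproduced in isolation.
simulateAndFit <- function(spec, vc, masterSeed, scenarioIdx, rep,
                           nStarts = 1L, fitReduced = TRUE,
                           fitFull = TRUE) {
  spec@seed <- childSeed(masterSeed, scenarioIdx, rep, 1L)
  pop <- applyCrossFostering(makeDesign(spec), spec)
  phen <- simulatePhenotypes(pop, vc,
                             seed = childSeed(masterSeed, scenarioIdx, rep, 2L))
  A <- additiveMatrix(popPedigree(pop))
  C <- culturalRelatednessMatrix(popCulturalPedigree(pop))
  fixed <- if (spec@nEnvironments > 1L) "environment" else character(0)
  full <- if (fitFull)
    fitAnimalModel(phen, random = list(A = A, C = C), fixed = fixed,
                   nStarts = nStarts,
                   seed = childSeed(masterSeed, scenarioIdx, rep, 3L))
  else NULL
  reduced <- if (fitReduced)
    fitAnimalModel(phen, random = list(A = A), fixed = fixed,
                   nStarts = 1L,
                   seed = childSeed(masterSeed, scenarioIdx, rep, 4L))
  else NULL
  ov <- pedigreeOverlap(A, subsetMatrix(C, ids(A)),
                        cped = popCulturalPedigree(pop))
  list(pop = pop, phen = phen, full = full, reduced = reduced, overlap = ov)
}

#' Monte Carlo power analysis of double-pedigree designs
#'
#' For each design in the grid, simulates `R` populations and phenotype
#' sets under the given variance components, fits the full (A + C) and the
#' reduced (A only) animal model, and aggregates: mean estimate, bias and
#' RMSE of the genetic and cultural components, the rejection rate of the
#' boundary-corrected LRT for the cultural component at level `alpha`, the
#' A-C overlap correlation, and the across-replicate correlation of the
#' two estimates (strongly negative on a confounded design).  Failed fits
#' are counted in `failures` and excluded from the moment summaries rather
#' than silently dropped.  Deterministic given `seed`.
#'
#' @param specs a [DesignSpec] or list of them (the scenario grid).
#' @param vc true [VarianceComponents] used for simulation.
#' @param R replicates per scenario (at least 2).
#' @param alpha LRT level.
#' @param seed master seed; per-replicate seeds are counter-derived.
#' @param nStarts optimizer starts per full fit.
#' @param scenarioIndices integer labels used in seed derivation and the
#'   `scenario` column; defaults to positions in `specs`.  Keeping a
#'   scenario's label fixed makes a partial re-run reproduce exactly the
#'   same replicates for it.
#' @return data.frame with one row per scenario.
#' @export
powerAnalysis <- function(specs, vc, R = 20L, alpha = 0.05, seed = 1L,
                          nStarts = 1L, scenarioIndices = NULL) {
  if (is(specs, "DesignSpec")) specs <- list(specs)
  if (R < 2L) stopf("R must be >= 2")
  if (is.null(scenarioIndices)) scenarioIndices <- seq_along(specs)
  s2 <- sigma2(vc)
  rows <- lapply(seq_along(specs), function(si) {
    s <- scenarioIndices[si]
    spec <- specs[[si]]
    estA <- estC <- pval <- ovr <- rep(NA_real_, R)
    nUsed <- NA_integer_
    fail <- 0L
    for (r in seq_len(R)) {
      res <- tryCatch(
        simulateAndFit(spec, vc, seed, s, r, nStarts = nStarts),
        error = function(e) NULL)
      if (is.null(res) || !isConverged(res$full)) { fail <- fail + 1L; next }
      est <- varianceEstimates(res$full)
      estA[r] <- est[["A"]]; estC[r] <- est[["C"]]
      pval[r] <- lrtComponent(res$full, res$reduced)$p_corrected
      ovr[r] <- res$overlap$r_offdiag
      nUsed <- res$full@nUsed
    }
    ok <- !is.na(estA)
    data.frame(
      scenario = s, swapFraction = spec@swapFraction, n = nUsed,
      sigma2_A_true = s2[["A"]], sigma2_C_true = s2[["C"]],
      mean_sigma2A = mean(estA[ok]), bias_A = mean(estA[ok]) - s2[["A"]],
      rmse_A = sqrt(mean((estA[ok] - s2[["A"]])^2)),
      mean_sigma2C = mean(estC[ok]), bias_C = mean(estC[ok]) - s2[["C"]],
      rmse_C = sqrt(mean((estC[ok] - s2[["C"]])^2)),
      rejection_rate = mean(pval[ok] < alpha),
      cor_AC_estimates = if (sum(ok) > 2 && stats::sd(estA[ok]) > 0 &&
                             stats::sd(estC[ok]) > 0)
        stats::cor(estA[ok], estC[ok]) else NA_real_,
      overlap_r = mean(ovr[ok]),
      replicates = R, failures = fail, seed = seed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Misattribution of cultural variance to genes
#'
#' Fits the genetic-only animal model to data that contain cultural
#' variance, once on the unmanipulated design (`swapFraction = 0`, where
#' the cultural pedigree shadows the genetic one and the A term absorbs
#' the cultural variance) and once on the manipulated design (the
#' `swapFraction` of `spec`, at least 0.5 recommended).  Reports the mean
#' genetic-only estimate under each design; the drop from the first to the
#' second is the part of "heritability" that was actually culture.
#'
#' @param spec a [DesignSpec] (its `swapFraction` is the manipulated
#'   scenario).
#' @param vc true [VarianceComponents] (typically with a cultural
#'   component).
#' @param R replicates per scenario.
#' @param seed master seed.
#' @return data.frame with one row per scenario (`swap0`, `swapped`) and
#'   the mean/sd of the genetic-only variance estimate.
#' @export
misattributionExperiment <- function(spec, vc, R = 20L, seed = 1L) {
  scen <- list(swap0 = { s <- spec; s@swapFraction <- 0; s },
               swapped = spec)
  rows <- lapply(seq_along(scen), function(s) {
    sp <- scen[[s]]
    estA <- rep(NA_real_, R)
    fail <- 0L
    for (r in seq_len(R)) {
      res <- tryCatch(
        simulateAndFit(sp, vc, seed, s, r, fitFull = FALSE),
        error = function(e) NULL)
      if (is.null(res)) { fail <- fail + 1L; next }
      estA[r] <- varianceEstimates(res$reduced)[["A"]]
    }
    ok <- !is.na(estA)
    data.frame(scenario = names(scen)[s], swapFraction = sp@swapFraction,
               mean_sigma2A_genetic_only = mean(estA[ok]),
               sd_sigma2A = stats::sd(estA[ok]),
               sigma2_A_true = sigma2(vc)[["A"]],
               sigma2_C_true = sigma2(vc)[["C"]],
               replicates = R, failures = fail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
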