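# Independent oracles used to check the package's fast paths.

# Random multigeneration pedigree with occasional inbred loops: parents are
# drawn from any earlier generation, so ancestors can recur on both sides.
randomPedigree <- function(n, nFounders = max(4L, n %/% 5L), seed = 1L,
                           pLoop = 0.3) {
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (k in (nFounders + 1L):n) {
    upper <- k - 1L
    lower <- if (runif(1) < pLoop) 1L else max(1L, upper - nFounders)
    pool <- lower:upper
    pick <- sample(pool, 2L, replace = FALSE)
    sire[k] <- id[pick[1]]
    dam[k] <- id[pick[2]]
  }
  geneticPedigree(id, sire, dam)
}

# Gene-dropping Monte Carlo estimate of the coancestry Theta_ij: founders
# get unique allele labels, every drop transmits one random allele per
# parent, and Theta is the match probability of randomly drawn alleles.
geneDropKinship <- function(ped, i, j, nDrop = 1e6, seed = 1L) {
  set.seed(seed)
  id <- ids(ped)
  pos <- seq_along(id); names(pos) <- id
  si <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  di <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  n <- length(id)
  a1 <- matrix(0L, nDrop, n)
  a2 <- matrix(0L, nDrop, n)
  nextAllele <- 1L
  for (k in seq_len(n)) {
    if (si[k] == 0L) {
      a1[, k] <- nextAllele; nextAllele <- nextAllele + 1L
    } else {
      pick <- runif(nDrop) < 0.5
      a1[, k] <- ifelse(pick, a1[, si[k]], a2[, si[k]])
    }
    if (di[k] == 0L) {
      a2[, k] <- nextAllele; nextAllele <- nextAllele + 1L
    } else {
      pick <- runif(nDrop) < 0.5
      a2[, k] <- ifelse(pick, a1[, di[k]], a2[, di[k]])
    }
  }
  ii <- pos[i]; jj <- pos[j]
  per <- ((a1[, ii] == a1[, jj]) + (a1[, ii] == a2[, jj]) +
          (a2[, ii] == a1[, jj]) + (a2[, ii] == a2[, jj])) / 4
  list(theta = mean(per), se = stats::sd(per) / sqrt(nDrop))
}

# Brute-force dense REML log-likelihood forming the projection P explicitly.
denseREMLOracle <- function(y, X, Klist, sigma2) {
  n <- length(y)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Klist)) V <- V + sigma2[k] * Klist[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  p <- qr(X)$rank
  -0.5 * ((n - p) * log(2 * pi) +
          as.numeric(determinant(V, logarithm = TRUE)$modulus) +
          as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
          drop(t(y) %*% P %*% y))
}

# random symmetric positive-definite covariance structure with unit-scale
# diagonal, for REML oracle problems
randomPSD <- function(n, seed) {
  set.seed(seed)
  M <- crossprod(matrix(rnorm(n * n), n)) / n
  M / mean(diag(M))
}

# small cross-fostered population + A and C, shared by several tests
smallCrossFosteredPop <- function(seed = 5L, swap = 0.5, nFam = 4L,
                                  brood = 4L, nEnv = 1L) {
  spec <- designSpec(nCultures = 2L, nEnvironments = nEnv,
                     nFamiliesPerCell = nFam, broodSize = brood,
                     swapFraction = swap, seed = seed)
  pop <- applyCrossFostering(makeDesign(spec), spec)
  A <- additiveMatrix(popPedigree(pop))
  C <- subsetMatrix(culturalRelatednessMatrix(popCulturalPedigree(pop)),
                    ids(A))
  list(spec = spec, pop = pop, A = A, C = C)
}

# read a delimited output file with '#' provenance lines, type-converted
readDelimitedTest <- function(path) {
  df <- dualped:::readDelimited(path)
  df[] <- lapply(df, utils::type.convert, as.is = TRUE)
  df
}
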