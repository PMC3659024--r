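# minimal hand-built fit objects for the pure-arithmetic contracts
fakeFit <- function(loglik, terms, hash = "h", fixed = character(0),
                    est = NULL) {
  q <- length(terms) + 1L
  if (is.null(est)) est <- setNames(rep(0.5, q), c(terms, "R"))
  new("AnimalModelFit", estimates = est,
      fixedEstimates = c("(Intercept)" = 0), loglik = loglik,
      aic = -2 * loglik + 2 * q, se = setNames(rep(NA_real_, q), names(est)),
      vcov = matrix(NA_real_, q, q), converged = TRUE, nUsed = 10L,
      dataHash = hash, terms = terms, fixedTerms = fixed,
      warnings = character(0))
}

test_that("restricted loglik matches the iid closed form and is translation invariant", {
  set.seed(1)
  y <- rnorm(25, mean = 3)
  X <- matrix(1, 25, 1)
  s <- 1.7
  n <- 25
  ss <- sum((y - mean(y))^2)
  closed <- -0.5 * ((n - 1) * log(2 * pi) + n * log(s) + log(n / s) + ss / s)
  expect_equal(restrictedLoglik(y, X, list(), c(R = s)), closed,
               tolerance = 1e-12)
  # adding a constant changes nothing when the intercept is in X
  expect_equal(restrictedLoglik(y + 100, X, list(), c(R = s)),
               restrictedLoglik(y, X, list(), c(R = s)), tolerance = 1e-9)
  expect_error(restrictedLoglik(y, cbind(X, X), list(), c(R = s)), "singular")
})

test_that("restricted loglik agrees with the dense-projection oracle", {
  for (case in 1:20) {
    set.seed(300 + case)
    n <- sample(10:30, 1)
    q <- sample(0:3, 1)
    X <- cbind(1, matrix(rnorm(n * sample(0:2, 1)), n))
    Klist <- lapply(seq_len(q), function(k) randomPSD(n, 300 + 10 * case + k))
    s2 <- c(runif(q, 0.1, 2), runif(1, 0.3, 2))
    y <- rnorm(n)
    ours <- restrictedLoglik(y, X, Klist, s2)
    oracle <- denseREMLOracle(y, X, Klist, s2)
    expect_equal(ours, unname(oracle), tolerance = 1e-8)
  }
})

test_that("intercept-only REML fit recovers the n-1 sample variance", {
  set.seed(5)
  y <- rnorm(80, 2, 1.3)
  fit <- fitAnimalModel(data.frame(id = paste0("i", 1:80), y = y))
  expect_true(isConverged(fit))
  expect_equal(unname(varianceEstimates(fit)[["R"]]), var(y),
               tolerance = 1e-6)
  expect_equal(unname(fixedEstimates(fit)[["(Intercept)"]]), mean(y),
               tolerance = 1e-6)
  expect_equal(modelAIC(fit), -2 * restrictedLogLik(fit) + 2)
})

test_that("a null genetic component is estimated at the boundary", {
  s <- smallCrossFosteredPop(seed = 13, swap = 0.5, nFam = 10, brood = 6)
  est <- vapply(1:4, function(r) {
    ph <- simulatePhenotypes(s$pop, varianceComponents(R = 1), seed = r)
    varianceEstimates(fitAnimalModel(ph, random = list(A = s$A), seed = r))
  }, numeric(2))
  expect_lt(mean(est["A", ]), 0.05)
  expect_lt(abs(mean(est["R", ]) - 1), 0.15)
})

test_that("variance components are recovered on a cross-fostered design", {
  s <- smallCrossFosteredPop(seed = 17, swap = 0.5, nFam = 12, brood = 6,
                             nEnv = 2)
  vc <- varianceComponents(A = 0.4, C = 0.3, R = 0.3)
  est <- vapply(1:5, function(r) {
    ph <- simulatePhenotypes(s$pop, vc, seed = 600 + r,
                             fixed = c(e1 = 0, e2 = 1))
    fit <- fitAnimalModel(ph, random = list(A = s$A, C = s$C),
                          fixed = "environment", seed = r, nStarts = 2)
    varianceEstimates(fit)[c("A", "C", "R")]
  }, numeric(3))
  m <- rowMeans(est)
  expect_lt(abs(m[["A"]] - 0.4), 0.12)
  expect_lt(abs(m[["C"]] - 0.3), 0.12)
  expect_lt(abs(m[["R"]] - 0.3), 0.12)
})

test_that("grouping-factor random terms absorb shared-brood variance", {
  s <- smallCrossFosteredPop(seed = 23, swap = 0.5, nFam = 12, brood = 6)
  vc <- varianceComponents(CB = 0.6, R = 0.4)
  est <- vapply(1:4, function(r) {
    ph <- simulatePhenotypes(s$pop, vc, seed = 30 + r)
    varianceEstimates(fitAnimalModel(ph, random = list(brood = "brood"),
                                     seed = r))
  }, numeric(2))
  expect_lt(abs(mean(est["brood", ]) - 0.6), 0.2)
  expect_lt(abs(mean(est["R", ]) - 0.4), 0.1)
})

test_that("fit is invariant under joint relabeling of the records", {
  s <- smallCrossFosteredPop(seed = 29, swap = 0.5, nFam = 6, brood = 4)
  ph <- simulatePhenotypes(s$pop, varianceComponents(A = 0.5, R = 0.5),
                           seed = 4)
  fit1 <- fitAnimalModel(ph, random = list(A = s$A), seed = 1)
  set.seed(9)
  perm <- sample(nrow(ph))
  fit2 <- fitAnimalModel(ph[perm, ], random = list(A = s$A), seed = 1)
  expect_equal(varianceEstimates(fit1), varianceEstimates(fit2),
               tolerance = 1e-6)
  expect_equal(restrictedLogLik(fit1), restrictedLogLik(fit2),
               tolerance = 1e-6)
})

test_that("heritability ratios: arithmetic, degenerate case, scale invariance", {
  fit <- fakeFit(-10, c("A", "C"),
                 est = c(A = 0.4, C = 0.3, R = 0.3))
  h <- heritabilities(fit)
  expect_equal(h$ratio[h$component == "A"], 0.4)
  expect_equal(h$ratio[h$component == "C"], 0.3)
  expect_equal(sum(h$ratio), 1)
  # all-residual data: both inherited components at the boundary
  s <- smallCrossFosteredPop(seed = 37, swap = 0.5, nFam = 8, brood = 4)
  h0 <- vapply(1:4, function(r) {
    ph <- simulatePhenotypes(s$pop, varianceComponents(R = 1), seed = 60 + r)
    f0 <- fitAnimalModel(ph, random = list(A = s$A, C = s$C), seed = r)
    h <- heritabilities(f0)
    c(A = h$ratio[h$component == "A"], C = h$ratio[h$component == "C"])
  }, numeric(2))
  expect_lt(mean(h0["A", ]), 0.12)
  expect_lt(mean(h0["C", ]), 0.12)
  ph <- simulatePhenotypes(s$pop, varianceComponents(R = 1), seed = 6)
  # rescaling the trait rescales variances but not ratios
  ph2 <- ph; ph2$y <- 3 * ph2$y
  fa <- fitAnimalModel(ph, random = list(A = s$A), seed = 1)
  fb <- fitAnimalModel(ph2, random = list(A = s$A), seed = 1)
  expect_equal(varianceEstimates(fb), 9 * varianceEstimates(fa),
               tolerance = 1e-4)
  expect_equal(heritabilities(fb)$ratio, heritabilities(fa)$ratio,
               tolerance = 1e-5)
})

test_that("boundary-corrected LRT: mixture arithmetic and guards", {
  full <- fakeFit(-100, c("A", "C"))
  red <- fakeFit(-100, "A")
  out <- lrtComponent(full, red)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_corrected, 0.5)
  expect_equal(out$dropped, "C")
  # statistic 2.706 sits at the corrected 5% point
  red2 <- fakeFit(-100 - 2.706 / 2, "A")
  out2 <- lrtComponent(full, red2)
  expect_equal(out2$statistic, 2.706)
  expect_equal(out2$p_corrected, 0.05, tolerance = 1e-3)
  expect_equal(out2$p_naive, 2 * out2$p_corrected)
  # guards: different data, non-nested terms
  expect_error(lrtComponent(full, fakeFit(-99, "A", hash = "other")),
               "identical data")
  expect_error(lrtComponent(full, fakeFit(-99, c("A", "C"))), "exactly one")
  expect_error(lrtComponent(fakeFit(-99, "A", fixed = "env"), red),
               "fixed effects")
})

test_that("AIC comparison ranks, penalizes, and refuses incomparable fits", {
  single <- compareModels(list(m = fakeFit(-50, "A")))
  expect_equal(single$dAIC, 0)
  two <- compareModels(list(small = fakeFit(-50, "A"),
                            big = fakeFit(-50, c("A", "C"))))
  expect_equal(two$model[1], "small")     # equal loglik: fewer parameters win
  expect_equal(two$dAIC[two$model == "big"], 2)
  expect_equal(two$rank, 1:2)
  expect_error(compareModels(list(fakeFit(-1, "A"),
                                  fakeFit(-1, "A", hash = "x"))),
               "identical data")
  expect_error(compareModels(list(fakeFit(-1, "A"),
                                  fakeFit(-1, "A", fixed = "env"))),
               "refused")
})

test_that("gene-by-culture Hadamard structure has unit diagonal and stays PSD", {
  s <- smallCrossFosteredPop(seed = 41, swap = 0.5, nFam = 5, brood = 4)
  A <- s$A; C <- s$C
  G <- gxcInteractionMatrix(A, C)
  expect_equal(unname(diag(as.matrix(G))), rep(1, nIndividuals(A)))
  ev <- eigen(as.matrix(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  # identity culture structure: no off-diagonal interaction left
  I <- relationshipMatrix(diag(nIndividuals(A)), ids(A))
  GI <- as.matrix(gxcInteractionMatrix(A, I))
  expect_equal(unname(GI), diag(nIndividuals(A)))
  # all-ones culture structure returns A itself (non-inbred diagonal)
  ones <- relationshipMatrix(matrix(1, nIndividuals(A), nIndividuals(A)),
                             ids(A))
  expect_equal(as.matrix(gxcInteractionMatrix(A, ones)), as.matrix(A))
  expect_error(gxcInteractionMatrix(A, relationshipMatrix(diag(2), c("a", "b"))),
               "same ids")
})

test_that("collinear A and C structures attach a ridge warning to the fit", {
  s0 <- smallCrossFosteredPop(seed = 43, swap = 0, nFam = 8, brood = 4)
  ph <- simulatePhenotypes(s0$pop, varianceComponents(A = 0.5, R = 0.5),
                           seed = 8)
  fit <- fitAnimalModel(ph, random = list(A = s0$A, C = s0$C), seed = 8)
  expect_match(fit@warnings, "collinear", all = FALSE)
})
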