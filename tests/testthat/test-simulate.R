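test_that("factorial design produces the expected counts", {
  spec <- designSpec(nCultures = 1, nEnvironments = 1, nFamiliesPerCell = 1,
                     broodSize = 2, seed = 1)
  pop <- makeDesign(spec)
  expect_equal(nIndividuals(pop), 4L)  # 2 parents + 2 offspring
  expect_equal(length(founders(popPedigree(pop))), 2L)
  spec2 <- designSpec(nCultures = 2, nEnvironments = 2, nFamiliesPerCell = 2,
                      broodSize = 2, seed = 1)
  pop2 <- makeDesign(spec2)
  broods <- popBrood(pop2)
  expect_equal(length(unique(na.omit(broods))), 8L)   # 2*2*2 broods
  expect_equal(sum(!is.na(broods)), 16L)              # 16 offspring
  expect_error(designSpec(broodSize = 1), "broodSize")
  expect_error(designSpec(swapFraction = 0.8, controlSwapFraction = 0.5),
               "<= 1")
})

test_that("designs and cross-fostering are deterministic given the seed", {
  spec <- designSpec(2, 1, 3, 4, swapFraction = 0.5,
                     controlSwapFraction = 0.25, seed = 11)
  p1 <- applyCrossFostering(makeDesign(spec), spec)
  p2 <- applyCrossFostering(makeDesign(spec), spec)
  expect_identical(dualped:::popTable(p1), dualped:::popTable(p2))
  spec3 <- spec; spec3@seed <- 12L
  p3 <- applyCrossFostering(makeDesign(spec3), spec3)
  expect_false(identical(dualped:::popTable(p1), dualped:::popTable(p3)))
})

test_that("reciprocal swapping conserves totals, brood sizes, and controls", {
  spec <- designSpec(2, 2, 4, 6, swapFraction = 0.5,
                     controlSwapFraction = 1 / 6, seed = 21)
  before <- makeDesign(spec)
  after <- applyCrossFostering(before, spec)
  expect_equal(nIndividuals(after), nIndividuals(before))
  expect_setequal(ids(after), ids(before))
  sizes <- function(p) table(popBrood(p))
  expect_equal(sizes(after), sizes(before))
  man <- popManipulated(after)
  off <- !is.na(popBrood(after))
  # per brood: 3 cross-swapped, 1 control-swapped, 2 natal
  perBrood <- table(popBrood(after)[off], man[off])
  expect_true(all(perBrood[, "cross_swap"] == 3))
  expect_true(all(perBrood[, "control_swap"] == 1))
  expect_true(all(perBrood[, "none"] == 2))
  # control swaps stay in their culture; cross swaps change culture
  cf <- popCulturalPedigree(after)@crossFostered
  names(cf) <- popCulturalPedigree(after)@id
  expect_true(all(cf[names(man)[man == "cross_swap"]]))
  expect_true(all(cf[names(man)[man == "control_swap"]]))
})

test_that("half of each two-offspring brood is fostered out at swap 0.5", {
  spec <- designSpec(2, 1, 4, 2, swapFraction = 0.5, seed = 31)
  pop <- applyCrossFostering(makeDesign(spec), spec)
  man <- popManipulated(pop)[!is.na(popBrood(pop))]
  perBrood <- table(popBrood(pop)[!is.na(popBrood(pop))], man)
  expect_true(all(perBrood[, "cross_swap"] == 1))
  expect_true(all(perBrood[, "none"] == 1))
})

test_that("a single culture cannot be cross-fostered across cultures", {
  spec <- designSpec(1, 1, 4, 4, swapFraction = 0.5, seed = 1)
  expect_error(applyCrossFostering(makeDesign(spec), spec),
               "no partner brood in a different culture")
})

test_that("without swaps the cultural pedigree shadows the genetic one", {
  spec <- designSpec(2, 2, 3, 4, swapFraction = 0, seed = 41)
  pop <- applyCrossFostering(makeDesign(spec), spec)
  expect_false(any(popCulturalPedigree(pop)@crossFostered))
  A <- additiveMatrix(popPedigree(pop))
  C <- subsetMatrix(culturalRelatednessMatrix(popCulturalPedigree(pop)),
                    ids(A))
  expect_equal(as.matrix(C), as.matrix(A), tolerance = 0)
})

test_that("multigeneration designs breed new pairs within rearing cells", {
  spec <- designSpec(2, 1, 3, 6, nGenerations = 2, swapFraction = 0.5,
                     seed = 51)
  pop <- applyCrossFostering(makeDesign(spec), spec)
  # 2 cells * (2 founders + 6 + 6 offspring) per family
  expect_equal(nIndividuals(pop), 2 * 3 * 2 + 2 * 3 * 6 * 2)
  gen <- attr(pop, "generation")
  ped <- popPedigree(pop)
  g2 <- ids(pop)[gen[ids(pop)] == 2]
  parentsOfG2 <- unique(c(ped@sire[match(g2, ped@id)],
                          ped@dam[match(g2, ped@id)]))
  expect_true(all(gen[parentsOfG2] == 1))
})

test_that("zero-variance phenotypes are exactly the mean plus fixed effects", {
  s <- smallCrossFosteredPop(seed = 3, swap = 0.5, nEnv = 2)
  vc0 <- varianceComponents()
  ph <- simulatePhenotypes(s$pop, vc0, mu = 5, seed = 1)
  expect_equal(ph$y, rep(5, nrow(ph)))
  ph2 <- simulatePhenotypes(s$pop, vc0, mu = 5,
                            fixed = c(e1 = 0, e2 = 1.5), seed = 1)
  expect_equal(ph2$y, 5 + 1.5 * (ph2$environment == "e2"))
  # manipulation-effect hook shifts exactly the swapped individuals
  ph3 <- simulatePhenotypes(s$pop, vc0, seed = 1, manipulationEffect = 2)
  expect_equal(ph3$y, 2 * (ph3$manipulated != "none"))
})

test_that("residual-only simulation matches its variance at n = 10000", {
  spec <- designSpec(1, 1, 2500, 2, seed = 61)
  pop <- makeDesign(spec)
  ph <- simulatePhenotypes(pop, varianceComponents(R = 1), seed = 7)
  expect_equal(nrow(ph), 10000L)
  # chi-square bound: sd(sample var) ~ sqrt(2/n) ~ 0.014
  expect_lt(abs(var(ph$y) - 1), 0.05)
})

test_that("replicate draws reproduce the full-sib genetic covariance", {
  spec <- designSpec(1, 1, 2, 2, seed = 71)
  pop <- makeDesign(spec)
  sibs <- ids(pop)[!is.na(popBrood(pop))][1:2]
  vc <- varianceComponents(A = 1)
  ys <- vapply(seq_len(2000), function(r) {
    ph <- simulatePhenotypes(pop, vc, seed = 1000 + r)
    ph$y[match(sibs, ph$id)]
  }, numeric(2))
  cv <- cov(t(ys))[1, 2]
  # cov(full sibs) = 0.5 sigma2_A; SE of a covariance at R = 2000
  se <- sqrt((1 * 1 + 0.5^2) / 2000)
  expect_lt(abs(cv - 0.5), 3 * se)
})

test_that("simulated covariance matches the model covariance entrywise", {
  s <- smallCrossFosteredPop(seed = 81, swap = 0.5, nFam = 3, brood = 3)
  vc <- varianceComponents(A = 0.5, C = 0.4, M = 0.3, CB = 0.3, R = 0.5)
  pop <- s$pop
  id <- ids(pop)
  n <- length(id)
  dam <- popRearingDam(pop)[id]
  brood <- popBrood(pop)[id]
  ZM <- outer(dam, dam, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
  ZB <- outer(brood, brood, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
  Sigma <- 0.5 * as.matrix(s$A) + 0.4 * as.matrix(s$C) +
    0.3 * ZM + 0.3 * ZB + 0.5 * diag(n)
  R <- 4000
  Y <- vapply(seq_len(R), function(r)
    simulatePhenotypes(pop, vc, seed = 5000 + r)$y, numeric(n))
  Shat <- tcrossprod(Y - rowMeans(Y)) / (R - 1)
  # worst-case MC standard error for entries of a covariance at R = 4000
  semax <- sqrt((max(diag(Sigma))^2 + max(abs(Sigma))^2) / R)
  expect_lt(max(abs(Shat - Sigma)), 6 * semax)
})

test_that("phenotype draws are reproducible and seed-sensitive", {
  s <- smallCrossFosteredPop(seed = 91, swap = 0.5)
  vc <- varianceComponents(A = 0.4, C = 0.3, R = 0.3)
  expect_identical(simulatePhenotypes(s$pop, vc, seed = 5),
                   simulatePhenotypes(s$pop, vc, seed = 5))
  expect_false(identical(simulatePhenotypes(s$pop, vc, seed = 5)$y,
                         simulatePhenotypes(s$pop, vc, seed = 6)$y))
})
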