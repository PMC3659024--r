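#' Construct a cross-fostering design specification
#'
#' @param nCultures,nEnvironments,nFamiliesPerCell number of cultures,
#'   environments, and breeding pairs per culture x environment cell.
#' @param broodSize offspring per pair per generation (at least 2, so that
#'   unmanipulated siblings remain as within-brood controls).
#' @param nGenerations number of offspring generations.
#' @param swapFraction share of each brood cross-fostered reciprocally into
#'   a brood of a *different* culture.
#' @param controlSwapFraction share of each brood swapped *within* the same
#'   culture, controlling for the manipulation itself.
#' @param seed integer seed recorded with the design.
#' @return a [DesignSpec].
#' @examples
#' designSpec(nCultures = 2, nEnvironments = 2, nFamiliesPerCell = 25,
#'            broodSize = 8, swapFraction = 0.5, seed = 1)
#' @export
designSpec <- function(nCultures = 2L, nEnvironments = 1L,
                       nFamiliesPerCell = 2L, broodSize = 2L,
                       nGenerations = 1L, swapFraction = 0,
                       controlSwapFraction = 0, seed = 1L) {
  new("DesignSpec", nCultures = as.integer(nCultures),
      nEnvironments = as.integer(nEnvironments),
      nFamiliesPerCell = as.integer(nFamiliesPerCell),
      broodSize = as.integer(broodSize),
      nGenerations = as.integer(nGenerations),
      swapFraction = swapFraction,
      controlSwapFraction = controlSwapFraction,
      seed = as.integer(seed))
}

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf(
    "DesignSpec: %d culture(s) x %d environment(s) x %d family(ies)/cell,\n",
    object@nCultures, object@nEnvironments, object@nFamiliesPerCell))
  cat(sprintf("  brood %d, %d generation(s), swap %.2f, control swap %.2f, seed %d\n",
    object@broodSize, object@nGenerations, object@swapFraction,
    object@controlSwapFraction, object@seed))
  invisible(object)
})

#' @describeIn ids member ids of a population.
#' @export
setMethod("ids", "Population", function(x) x@ped@id)

#' @describeIn nIndividuals population size.
#' @export
setMethod("nIndividuals", "Population", function(x) length(x@ped@id))

#' @describeIn cultures rearing-culture label per individual.
#' @export
setMethod("cultures", "Population", function(x) cultures(x@cped))

#' Population accessors
#'
#' @param pop a [Population].
#' @return `popPedigree`/`popCulturalPedigree` return the genetic and
#'   cultural pedigrees; the others return named character vectors keyed by
#'   individual id.
#' @name population-accessors
NULL

#' @rdname population-accessors
#' @export
popPedigree <- function(pop) pop@ped

#' @rdname population-accessors
#' @export
popCulturalPedigree <- function(pop) pop@cped

#' @rdname population-accessors
#' @export
popBrood <- function(pop) pop@brood

#' @rdname population-accessors
#' @export
popRearingDam <- function(pop) pop@damOf

#' @rdname population-accessors
#' @export
popEnvironment <- function(pop) pop@environment

#' @rdname population-accessors
#' @export
popManipulated <- function(pop) pop@manipulated

setMethod("show", "Population", function(object) {
  cat("Population of", length(object@ped@id), "individuals (",
      sum(object@manipulated == "cross_swap"), "cross-fostered,",
      sum(object@manipulated == "control_swap"), "control-swapped )\n")
  show(object@spec)
  invisible(object)
})

# internal flat representation used while building / fostering
popTable <- function(pop) {
  id <- pop@ped@id
  data.frame(
    id = id, sire = pop@ped@sire, dam = pop@ped@dam,
    sex = if (length(pop@ped@sex)) pop@ped@sex else rep("U", length(id)),
    rsire = stats::setNames(pop@cped@rearingSire, pop@cped@id)[id],
    rdam = stats::setNames(pop@cped@rearingDam, pop@cped@id)[id],
    culture = stats::setNames(pop@cped@culture, pop@cped@id)[id],
    brood = unname(pop@brood[id]), damOf = unname(pop@damOf[id]),
    environment = unname(pop@environment[id]),
    manipulated = unname(pop@manipulated[id]),
    generation = if (is.null(attr(pop, "generation"))) NA_integer_
                 else unname(attr(pop, "generation")[id]),
    stringsAsFactors = FALSE, row.names = NULL)
}

popFromTable <- function(tb, spec, generation) {
  ped <- geneticPedigree(tb$id, tb$sire, tb$dam, sex = tb$sex)
  cped <- culturalPedigree(tb$id, tb$rsire, tb$rdam, tb$culture, ped = ped)
  pop <- new("Population", ped = ped, cped = cped,
             brood = stats::setNames(tb$brood, tb$id),
             damOf = stats::setNames(tb$damOf, tb$id),
             environment = stats::setNames(tb$environment, tb$id),
             manipulated = stats::setNames(tb$manipulated, tb$id),
             spec = spec)
  attr(pop, "generation") <- stats::setNames(generation, tb$id)
  pop
}

#' Generate a factorial cross-fostering population (natal rearing)
#'
#' Places one monogamous founder pair in every culture x environment x
#' family cell and lets each pair produce `broodSize` offspring per
#' generation; with more than one generation, new pairs are drawn within
#' each cell from the previous generation's offspring (one male and one
#' female from different broods whenever possible).  All rearing is natal:
#' cross-fostering is applied afterwards by [applyCrossFostering()].
#' Deterministic given `spec@seed`.
#'
#' @param spec a [DesignSpec].
#' @return a [Population] with intact natal rearing.
#' @export
makeDesign <- function(spec) {
  validObject(spec)
  nc <- spec@nCultures; ne <- spec@nEnvironments; nf <- spec@nFamiliesPerCell
  if (nc * ne * nf < 1L) stopf("design has no cells")
  b <- spec@broodSize
  withSeed(childSeed(spec@seed, 1L), {
    cells <- expand.grid(culture = paste0("c", seq_len(nc)),
                         environment = paste0("e", seq_len(ne)),
                         family = seq_len(nf), stringsAsFactors = FALSE)
    base <- sprintf("G0-%s%s-F%d", cells$culture, cells$environment,
                    cells$family)
    tb <- data.frame(
      id = c(paste0(base, "S"), paste0(base, "D")),
      sire = NA_character_, dam = NA_character_,
      sex = rep(c("M", "F"), each = nrow(cells)),
      rsire = NA_character_, rdam = NA_character_,
      culture = rep(cells$culture, 2L), brood = NA_character_,
      damOf = NA_character_, environment = rep(cells$environment, 2L),
      manipulated = "none", generation = 0L, stringsAsFactors = FALSE)
    pairs <- data.frame(sire = paste0(base, "S"), dam = paste0(base, "D"),
                        culture = cells$culture,
                        environment = cells$environment,
                        family = cells$family, stringsAsFactors = FALSE)
    for (g in seq_len(spec@nGenerations)) {
      np <- nrow(pairs)
      brood <- sprintf("G%d-%s%s-F%d", g, pairs$culture, pairs$environment,
                       pairs$family)
      o <- rep(seq_len(b), np)
      k <- rep(seq_len(np), each = b)
      off <- data.frame(
        id = sprintf("%s-O%d", brood[k], o),
        sire = pairs$sire[k], dam = pairs$dam[k],
        sex = ifelse(o %% 2L == 1L, "M", "F"),
        rsire = pairs$sire[k], rdam = pairs$dam[k],
        culture = pairs$culture[k], brood = brood[k],
        damOf = pairs$dam[k], environment = pairs$environment[k],
        manipulated = "none", generation = g, stringsAsFactors = FALSE)
      tb <- rbind(tb, off)
      if (g < spec@nGenerations) pairs <- nextPairs(off, nf)
    }
  })
  popFromTable(tb, spec, stats::setNames(tb$generation, tb$id))
}

# draw nf new breeding pairs per culture x environment cell from the given
# offspring generation, avoiding full-sib pairs when a reshuffle can
nextPairs <- function(off, nf) {
  out <- list()
  for (cell in split(off, paste(off$culture, off$environment))) {
    males <- cell[cell$sex == "M", ]
    females <- cell[cell$sex == "F", ]
    if (nrow(males) < nf || nrow(females) < nf)
      stopf("cell %s/%s has too few offspring to form %d pairs",
            cell$culture[1], cell$environment[1], nf)
    for (try in 1:20) {
      mi <- males[sample(nrow(males), nf), ]
      fi <- females[sample(nrow(females), nf), ]
      if (!any(mi$brood == fi$brood)) break
    }
    out[[length(out) + 1L]] <- data.frame(
      sire = mi$id, dam = fi$id, culture = cell$culture[1],
      environment = cell$environment[1], family = seq_len(nf),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

roundHalfAway <- function(x) floor(x + 0.5)

#' Apply partial cross-fostering to a population
#'
#' For every brood, `round(swapFraction * broodSize)` offspring are
#' exchanged reciprocally with a partner brood in a *different* culture and
#' `round(controlSwapFraction * broodSize)` with a partner brood in the
#' *same* culture (the manipulation control).  Reciprocal exchange
#' conserves brood sizes and the total population.  Swapped offspring take
#' the rearing parents, brood, culture and environment of the foster brood;
#' at least one natal offspring is retained per brood whenever
#' `swapFraction < 1`.  Generations are processed in order, and each
#' brood's location (culture, environment) is re-derived from where its dam
#' was reared, so culture propagates along rearing lines across
#' generations.  Deterministic given `spec@seed`.
#'
#' @param pop a [Population] with intact natal rearing (from [makeDesign()]).
#' @param spec a [DesignSpec]; its swap fractions drive the manipulation.
#' @return a [Population] with updated rearing links, culture labels and
#'   `manipulated` flags.
#' @export
applyCrossFostering <- function(pop, spec = pop@spec) {
  tb <- popTable(pop)
  if (any(tb$manipulated != "none"))
    stopf("population has already been cross-fostered")
  b <- spec@broodSize
  kCross <- min(roundHalfAway(spec@swapFraction * b),
                if (spec@swapFraction < 1) b - 1L else b)
  kCtrl <- min(roundHalfAway(spec@controlSwapFraction * b), b - kCross)
  gens <- sort(unique(tb$generation[!is.na(tb$brood)]))
  withSeed(childSeed(spec@seed, 2L), {
    for (g in gens) {
      # brood location follows the dam's current rearing culture/environment
      idx <- which(tb$generation == g & !is.na(tb$brood))
      damRow <- match(tb$damOf[idx], tb$id)
      tb$culture[idx] <- tb$culture[damRow]
      tb$environment[idx] <- tb$environment[damRow]
      broods <- unique(tb$brood[idx])
      bcult <- tb$culture[match(broods, tb$brood)]
      if (kCross > 0L) {
        if (length(unique(bcult)) < 2L)
          stopf(paste("no partner brood in a different culture available;",
                      "increase nCultures or lower swapFraction"))
        pairsX <- pairBroods(broods, bcult, different = TRUE)
        for (p in seq_len(nrow(pairsX)))
          tb <- swapOffspring(tb, pairsX$a[p], pairsX$b[p], kCross,
                              "cross_swap")
      }
      if (kCtrl > 0L) {
        perCult <- split(broods, bcult)
        if (any(lengths(perCult) < 2L))
          stopf(paste("no partner brood in the same culture available;",
                      "increase nFamiliesPerCell or lower",
                      "controlSwapFraction"))
        pairsC <- do.call(rbind, lapply(perCult, function(bs)
          pairBroods(bs, rep("x", length(bs)), different = FALSE)))
        for (p in seq_len(nrow(pairsC)))
          tb <- swapOffspring(tb, pairsC$a[p], pairsC$b[p], kCtrl,
                              "control_swap")
      }
    }
  })
  popFromTable(tb, spec, stats::setNames(tb$generation, tb$id))
}

# randomly pair broods, each with a partner of a different (or any) culture;
# leftovers are dropped from swapping (never an error when a partner exists
# for at least one pairing arrangement of equal-sized culture pools)
pairBroods <- function(broods, cult, different) {
  ord <- sample(length(broods))
  broods <- broods[ord]; cult <- cult[ord]
  a <- character(0); bb <- character(0)
  free <- rep(TRUE, length(broods))
  for (i in seq_along(broods)) {
    if (!free[i]) next
    j <- which(free & seq_along(broods) > i &
               (if (different) cult != cult[i] else TRUE))
    if (!length(j)) next
    j <- j[1]
    a <- c(a, broods[i]); bb <- c(bb, broods[j])
    free[c(i, j)] <- FALSE
  }
  if (!length(a) && length(broods) > 1L)
    stopf("could not pair broods for swapping")
  data.frame(a = a, b = bb, stringsAsFactors = FALSE)
}

# reciprocally exchange k not-yet-manipulated offspring between broods A/B
swapOffspring <- function(tb, broodA, broodB, k, flag) {
  ia <- which(tb$brood == broodA & tb$manipulated == "none")
  ib <- which(tb$brood == broodB & tb$manipulated == "none")
  k <- min(k, length(ia), length(ib))
  if (k < 1L) return(tb)
  sa <- ia[sample(length(ia), k)]
  sb <- ib[sample(length(ib), k)]
  fosterOf <- function(rows) {
    r1 <- rows[1]
    list(rsire = tb$rsire[r1], rdam = tb$rdam[r1], culture = tb$culture[r1],
         environment = tb$environment[r1], brood = tb$brood[r1],
         damOf = tb$damOf[r1])
  }
  fa <- fosterOf(ia); fb <- fosterOf(ib)
  place <- function(tb, rows, f, flag) {
    tb$rsire[rows] <- f$rsire; tb$rdam[rows] <- f$rdam
    tb$culture[rows] <- f$culture; tb$environment[rows] <- f$environment
    tb$brood[rows] <- f$brood; tb$damOf[rows] <- f$damOf
    tb$manipulated[rows] <- flag
    tb
  }
  tb <- place(tb, sa, fb, flag)
  place(tb, sb, fa, flag)
}

#' Simulate phenotypes under the expanded animal model
#'
#' Draws \eqn{y_i = \mu + \beta_{envt(i)} + a_i + c_i + m_{dam(i)} +
#' cb_{brood(i)} + e_i}: the vector of breeding values `a` is multivariate
#' normal with covariance \eqn{\sigma^2_A A} (via Cholesky of A), the
#' cultural values `c` have covariance \eqn{\sigma^2_C C} (recursion-form C
#' from the rearing links), maternal and common-brood effects are i.i.d.
#' normal per rearing dam and per rearing brood, the environment enters as
#' a fixed effect by default (or as an i.i.d. random effect with variance
#' `ENVT` when `envRandom = TRUE`), and the residual is i.i.d. with
#' variance `R`.  Drawing jointly through the Cholesky factor makes
#' `cov(y)` exact, which keeps parameter-recovery experiments sharp.
#' Deterministic given `seed`.
#'
#' @param pop a [Population].
#' @param vc a [VarianceComponents].
#' @param fixed named numeric vector mapping environment labels to fixed
#'   effects (default: all zero).
#' @param mu population mean.
#' @param seed integer seed.
#' @param envRandom simulate the environment as a random effect with
#'   variance `sigma2(vc)["ENVT"]` instead of a fixed effect.
#' @param maternal which dam receives the maternal effect: the `"rearing"`
#'   dam (default: the dam that provides care) or the `"genetic"` dam.
#' @param manipulationEffect additive shift applied to every manipulated
#'   (swapped) individual; default 0.
#' @return data.frame with columns id, y, environment, dam, brood, culture,
#'   manipulated.
#' @export
simulatePhenotypes <- function(pop, vc, fixed = NULL, mu = 0, seed = 1L,
                               envRandom = FALSE,
                               maternal = c("rearing", "genetic"),
                               manipulationEffect = 0) {
  maternal <- match.arg(maternal)
  s2 <- sigma2(vc)
  id <- pop@ped@id
  n <- length(id)
  A <- if (s2[["A"]] > 0) as.matrix(additiveMatrix(pop@ped))
  C <- if (s2[["C"]] > 0)
    as.matrix(subsetMatrix(culturalRelatednessMatrix(pop@cped), id))
  damVec <- if (maternal == "rearing") pop@damOf[id]
            else stats::setNames(pop@ped@dam, id)[id]
  broodVec <- pop@brood[id]
  envVec <- pop@environment[id]
  withSeed(seed, {
    y <- rep(mu, n)
    if (s2[["A"]] > 0)
      y <- y + sqrt(s2[["A"]]) * drop(crossprod(cholPSD(A)$R, stats::rnorm(n)))
    if (s2[["C"]] > 0)
      y <- y + sqrt(s2[["C"]]) * drop(crossprod(cholPSD(C)$R, stats::rnorm(n)))
    y <- y + groupEffect(damVec, s2[["M"]]) +
      groupEffect(broodVec, s2[["CB"]])
    if (envRandom) {
      y <- y + groupEffect(envVec, s2[["ENVT"]])
    } else if (!is.null(fixed)) {
      y <- y + ifelse(envVec %in% names(fixed), fixed[envVec], 0)
    }
    if (manipulationEffect != 0)
      y <- y + manipulationEffect * (pop@manipulated[id] != "none")
    if (s2[["R"]] > 0) y <- y + stats::rnorm(n, sd = sqrt(s2[["R"]]))
  })
  data.frame(id = id, y = y, environment = unname(envVec),
             dam = unname(damVec), brood = unname(broodVec),
             culture = unname(cultures(pop)[id]),
             manipulated = unname(pop@manipulated[id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# i.i.d. group effects: one N(0, s2) draw per group level, NA group -> 0
groupEffect <- function(g, s2) {
  if (s2 <= 0) return(numeric(length(g)))
  lev <- unique(stats::na.omit(g))
  eff <- stats::setNames(stats::rnorm(length(lev), sd = sqrt(s2)), lev)
  ifelse(is.na(g), 0, eff[g])
}
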