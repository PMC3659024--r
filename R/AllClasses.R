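#' @import methods
NULL

UNKNOWN_TOKENS <- c("0", "", "NA")

#' Genetic pedigree
#'
#' Genealogical links (sire, dam) for a set of individuals, stored
#' parent-first: every named parent precedes all of its offspring.  Unknown
#' parents are `NA` and are treated as unique, unrelated, non-inbred
#' founders by all downstream computations.
#'
#' @slot id character vector of unique, non-empty individual identifiers.
#' @slot sire,dam character vectors aligned with `id`; `NA` means unknown.
#' @slot sex optional character vector (`"M"`, `"F"`, `"U"`) aligned with `id`.
#'
#' @seealso [geneticPedigree()], [additiveMatrix()], [kinshipCoefficient()]
#' @export
setClass("GeneticPedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character"),
  prototype(sex = character(0))
)

setValidity("GeneticPedigree", function(object) {
  id <- object@id; sire <- object@sire; dam <- object@dam
  msgs <- character(0)
  if (length(sire) != length(id) || length(dam) != length(id))
    msgs <- c(msgs, "id, sire and dam must have equal length")
  if (anyNA(id) || any(!nzchar(id)))
    msgs <- c(msgs, "ids must be non-empty and non-NA")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicated id(s): ", paste(dup, collapse = ", ")))
  if (length(msgs)) return(msgs)
  self <- which(id == sire | id == dam)
  if (length(self))
    msgs <- c(msgs, paste0("self-parentage for id(s): ",
                           paste(id[self], collapse = ", ")))
  both <- which(!is.na(sire) & !is.na(dam) & sire == dam)
  if (length(both))
    msgs <- c(msgs, paste0("sire and dam identical for offspring: ",
                           paste(id[both], collapse = ", ")))
  undeclared <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(undeclared))
    msgs <- c(msgs, paste0("parent(s) never declared as members: ",
                           paste(undeclared, collapse = ", ")))
  # parent-first storage implies acyclicity
  pos <- seq_along(id); names(pos) <- id
  bad <- which((!is.na(sire) & pos[sire] >= pos) |
               (!is.na(dam)  & pos[dam]  >= pos))
  if (length(bad))
    msgs <- c(msgs, "pedigree is not stored parent-first (possible cycle)")
  if (length(object@sex) && length(object@sex) != length(id))
    msgs <- c(msgs, "sex must be empty or aligned with id")
  if (length(msgs)) msgs else TRUE
})

#' Cultural pedigree
#'
#' Transgenerational rearing links and culture labels for the same universe
#' of individuals as a [GeneticPedigree].  `rearingSire`/`rearingDam` name
#' the pair that raised each individual (who need not be the genetic
#' parents); `culture` is the label of the culture the individual was reared
#' in; `crossFostered` flags individuals whose rearing parents differ from
#' their genetic parents.
#'
#' @slot id,rearingSire,rearingDam character vectors, `NA` = unknown.
#' @slot culture character vector of culture labels aligned with `id`.
#' @slot crossFostered logical vector aligned with `id`.
#'
#' @seealso [culturalPedigree()], [culturalRelatednessMatrix()],
#'   [cultureIdentityMatrix()]
#' @export
setClass("CulturalPedigree",
  representation(id = "character", rearingSire = "character",
                 rearingDam = "character", culture = "character",
                 crossFostered = "logical")
)

setValidity("CulturalPedigree", function(object) {
  id <- object@id; rs <- object@rearingSire; rd <- object@rearingDam
  msgs <- character(0)
  if (length(rs) != length(id) || length(rd) != length(id) ||
      length(object@culture) != length(id) ||
      length(object@crossFostered) != length(id))
    msgs <- c(msgs, "all slots must be aligned with id")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(id))
    msgs <- c(msgs, "duplicated ids")
  if (anyNA(object@culture) || any(!nzchar(object@culture)))
    msgs <- c(msgs, paste0("missing culture label for id(s): ",
      paste(id[is.na(object@culture) | !nzchar(object@culture)],
            collapse = ", ")))
  undeclared <- setdiff(stats::na.omit(c(rs, rd)), id)
  if (length(undeclared))
    msgs <- c(msgs, paste0("rearing parent(s) never declared: ",
                           paste(undeclared, collapse = ", ")))
  if (length(msgs)) return(msgs)
  pos <- seq_along(id); names(pos) <- id
  bad <- which((!is.na(rs) & pos[rs] >= pos) | (!is.na(rd) & pos[rd] >= pos))
  if (length(bad))
    msgs <- c(msgs, "rearing links not stored parent-first (possible cycle)")
  if (length(msgs)) msgs else TRUE
})

#' Relationship matrix
#'
#' A symmetric individual-by-individual covariance-structure matrix
#' (dimensionless), such as the additive genetic relationship matrix A, a
#' cultural relationship matrix C, or a Hadamard interaction matrix.
#' Positive semidefiniteness is not enforced at construction (it is a
#' property of the generating algorithms); [stabilizePSD()] adds an explicit
#' diagonal offset when a Cholesky factorization fails.
#'
#' @slot ids ordered character vector of individual ids.
#' @slot values numeric matrix with `ids` as both dimnames.
#'
#' @seealso [relationshipMatrix()], [additiveMatrix()], [pedigreeOverlap()]
#' @export
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix")
)

setValidity("RelationshipMatrix", function(object) {
  v <- object@values; ids <- object@ids
  msgs <- character(0)
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) != length(ids)) msgs <- c(msgs, "ids must match matrix dimension")
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated ids")
  if (length(msgs)) return(msgs)
  if (nrow(v) && max(abs(v - t(v))) > 1e-8)
    msgs <- c(msgs, "matrix is not symmetric within 1e-8")
  if (length(msgs)) msgs else TRUE
})

#' Variance components of the expanded animal model
#'
#' Named nonnegative variances on the trait scale: additive genetic (`A`),
#' additive cultural (`C`), maternal (`M`), common brood (`CB`),
#' environmental (`ENVT`) and residual (`R`).  The total phenotypic variance
#' is their sum.
#'
#' @slot sigma2 named numeric vector with names
#'   `c("A","C","M","CB","ENVT","R")`, all `>= 0`.
#'
#' @seealso [varianceComponents()], [simulatePhenotypes()], [heritabilities()]
#' @export
setClass("VarianceComponents", representation(sigma2 = "numeric"))

VC_NAMES <- c("A", "C", "M", "CB", "ENVT", "R")

setValidity("VarianceComponents", function(object) {
  s <- object@sigma2
  if (!identical(names(s), VC_NAMES))
    return(paste0("sigma2 must be named ", paste(VC_NAMES, collapse = ", ")))
  if (anyNA(s) || any(s < 0)) return("all variances must be nonnegative")
  TRUE
})

#' Cross-fostering design specification
#'
#' Describes a factorial partial cross-fostering experiment: founder pairs
#' are placed in every culture x environment x family cell, each pair
#' produces a brood per generation, and a share of every brood is exchanged
#' reciprocally with a brood in a different culture (`swapFraction`) or
#' within the same culture as a manipulation control
#' (`controlSwapFraction`).
#'
#' @slot nCultures,nEnvironments,nFamiliesPerCell,broodSize,nGenerations
#'   positive integers; `broodSize >= 2` so that unmanipulated siblings
#'   remain available as controls.
#' @slot swapFraction,controlSwapFraction numeric in `[0, 1]`, summing to
#'   at most 1.
#' @slot seed integer seed recorded with the design.
#'
#' @seealso [designSpec()], [makeDesign()], [applyCrossFostering()]
#' @export
setClass("DesignSpec",
  representation(nCultures = "integer", nEnvironments = "integer",
                 nFamiliesPerCell = "integer", broodSize = "integer",
                 nGenerations = "integer", swapFraction = "numeric",
                 controlSwapFraction = "numeric", seed = "integer")
)

setValidity("DesignSpec", function(object) {
  msgs <- character(0)
  for (sl in c("nCultures", "nEnvironments", "nFamiliesPerCell",
               "nGenerations"))
    if (slot(object, sl) < 1L)
      msgs <- c(msgs, paste0(sl, " must be >= 1"))
  if (object@broodSize < 2L)
    msgs <- c(msgs, "broodSize must be >= 2 (siblings are needed as controls)")
  sf <- object@swapFraction; cf <- object@controlSwapFraction
  if (sf < 0 || sf > 1 || cf < 0 || cf > 1)
    msgs <- c(msgs, "swap fractions must lie in [0, 1]")
  if (sf + cf > 1)
    msgs <- c(msgs, "swapFraction + controlSwapFraction must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Simulated population under a cross-fostering design
#'
#' Joint container for the genetic pedigree, the cultural (rearing)
#' pedigree, and the per-individual design bookkeeping of a simulated
#' population: rearing brood label, rearing dam, environment, and the
#' manipulation status (`"none"`, `"control_swap"` or `"cross_swap"`).
#'
#' @slot ped a [GeneticPedigree].
#' @slot cped a [CulturalPedigree] over the same individuals.
#' @slot brood,damOf,environment,manipulated named character vectors keyed
#'   by individual id (`brood`/`damOf` are `NA` for founders).
#' @slot spec the [DesignSpec] the population was generated from.
#'
#' @seealso [makeDesign()], [applyCrossFostering()], [simulatePhenotypes()]
#' @export
setClass("Population",
  representation(ped = "GeneticPedigree", cped = "CulturalPedigree",
                 brood = "character", damOf = "character",
                 environment = "character", manipulated = "character",
                 spec = "DesignSpec")
)

setValidity("Population", function(object) {
  id <- object@ped@id
  msgs <- character(0)
  if (!identical(sort(id), sort(object@cped@id)))
    msgs <- c(msgs, "genetic and cultural pedigrees cover different individuals")
  for (sl in c("brood", "damOf", "environment", "manipulated"))
    if (!identical(sort(names(slot(object, sl))), sort(id)))
      msgs <- c(msgs, paste0(sl, " must be named by every individual id"))
  if (length(msgs)) return(msgs)
  nonf <- id[!is.na(object@ped@sire) | !is.na(object@ped@dam)]
  if (anyNA(object@brood[nonf]) || anyNA(object@damOf[nonf]))
    msgs <- c(msgs, "every non-founder needs a brood and a dam")
  bad <- setdiff(unique(object@manipulated),
                 c("none", "control_swap", "cross_swap"))
  if (length(bad))
    msgs <- c(msgs, paste0("invalid manipulated status: ",
                           paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Animal model REML fit
#'
#' Result of [fitAnimalModel()]: restricted-maximum-likelihood estimates of
#' the variance components attached to each random term (plus the residual),
#' generalized-least-squares fixed-effect estimates at the optimum, the
#' restricted log-likelihood, AIC (counting estimated variance parameters
#' only, the REML convention), and standard errors from the observed
#' information when it is invertible.
#'
#' @slot estimates named numeric vector of variance estimates (includes
#'   `"R"`, the residual).
#' @slot fixedEstimates named numeric vector of fixed-effect coefficients.
#' @slot loglik restricted log-likelihood, including its
#'   `-(n-p)/2 log(2*pi)` constant (see [restrictedLoglik()]).
#' @slot aic `-2 loglik + 2 * (number of estimated variance parameters)`.
#' @slot se named numeric vector of standard errors (`NA` where the
#'   information matrix was not invertible or an estimate sits on the
#'   zero boundary).
#' @slot vcov covariance matrix of the variance estimates (may contain NA).
#' @slot converged logical convergence flag.
#' @slot nUsed number of phenotype records used.
#' @slot dataHash md5 hash of (y, X) identifying the data for comparability
#'   guards in [compareModels()] and [lrtComponent()].
#' @slot terms character vector of random-term names (excluding residual).
#' @slot fixedTerms character vector naming the fixed-effect columns.
#' @slot warnings character vector of fit diagnostics (e.g. an A-C
#'   collinearity ridge warning).
#'
#' @seealso [fitAnimalModel()], [heritabilities()], [lrtComponent()],
#'   [compareModels()]
#' @export
setClass("AnimalModelFit",
  representation(estimates = "numeric", fixedEstimates = "numeric",
                 loglik = "numeric", aic = "numeric", se = "numeric",
                 vcov = "matrix", converged = "logical", nUsed = "integer",
                 dataHash = "character", terms = "character",
                 fixedTerms = "character", warnings = "character")
)
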