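#' Construct variance components
#'
#' Named nonnegative variances of the expanded animal model: additive
#' genetic (`A`), additive cultural (`C`), maternal (`M`), common brood
#' (`CB`), environmental (`ENVT`) and residual (`R`); the total phenotypic
#' variance is their sum.
#'
#' @param A,C,M,CB,ENVT,R nonnegative variances (trait-variance units).
#' @return a [VarianceComponents].
#' @examples
#' varianceComponents(A = 0.4, C = 0.3, R = 0.3)
#' @export
varianceComponents <- function(A = 0, C = 0, M = 0, CB = 0, ENVT = 0, R = 0) {
  new("VarianceComponents",
      sigma2 = c(A = A, C = C, M = M, CB = CB, ENVT = ENVT, R = R))
}

#' Variances of a VarianceComponents object
#' @param vc a [VarianceComponents].
#' @return named numeric vector.
#' @export
sigma2 <- function(vc) vc@sigma2

#' Total phenotypic variance (sum of all components)
#' @param vc a [VarianceComponents].
#' @return numeric scalar.
#' @export
totalVariance <- function(vc) sum(vc@sigma2)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (sigma2_P =", format(totalVariance(object)), ")\n")
  print(object@sigma2)
  invisible(object)
})
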