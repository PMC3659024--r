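#' Construct a cultural pedigree
#'
#' Rearing links and culture labels.  When a [GeneticPedigree] is supplied,
#' the `crossFostered` flag is derived by comparing the rearing pair with
#' the genetic pair; otherwise it can be given explicitly (default: all
#' `FALSE`).  Rearing links are validated and ordered parent-first exactly
#' like genetic links.
#'
#' @param id character vector of individual ids.
#' @param rearingSire,rearingDam character vectors of rearing-parent ids
#'   (`NA`, `"0"`, `""` or `"NA"` = unknown).
#' @param culture character vector of culture labels (required, non-empty).
#' @param ped optional [GeneticPedigree] used to derive `crossFostered`.
#' @param crossFostered optional logical vector (ignored when `ped` given).
#' @return a [CulturalPedigree].
#' @export
culturalPedigree <- function(id, rearingSire, rearingDam, culture,
                             ped = NULL, crossFostered = NULL) {
  id <- as.character(id)
  rs <- normalizeUnknown(as.character(rearingSire))
  rd <- normalizeUnknown(as.character(rearingDam))
  culture <- as.character(culture)
  miss <- which(is.na(culture) | !nzchar(culture))
  if (length(miss))
    stopf("missing culture label for id(s): %s",
          paste(id[miss], collapse = ", "))
  undeclared <- setdiff(stats::na.omit(c(rs, rd)), id)
  if (length(undeclared))
    stopf("rearing parent(s) never declared: %s",
          paste(undeclared, collapse = ", "))
  ord <- topoOrder(id, rs, rd)
  id <- id[ord]; rs <- rs[ord]; rd <- rd[ord]; culture <- culture[ord]
  if (!is.null(ped)) {
    if (!setequal(ped@id, id))
      stopf("genetic and cultural pedigrees cover different individuals")
    gs <- stats::setNames(ped@sire, ped@id)[id]
    gd <- stats::setNames(ped@dam, ped@id)[id]
    same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
    cf <- !(same(rs, gs) & same(rd, gd))
  } else if (!is.null(crossFostered)) {
    cf <- as.logical(crossFostered)[ord]
  } else {
    cf <- rep(FALSE, length(id))
  }
  new("CulturalPedigree", id = id, rearingSire = rs, rearingDam = rd,
      culture = culture, crossFostered = cf)
}

#' Read a cultural pedigree file
#'
#' Delimited text with header columns `id`, `rearing_sire`, `rearing_dam`,
#' `culture` (extra columns ignored).
#'
#' @param path input path.
#' @param ped optional [GeneticPedigree] to derive the cross-fostering flag.
#' @return a [CulturalPedigree].
#' @export
readCulturalPedigree <- function(path, ped = NULL) {
  df <- readDelimited(path)
  need <- c("id", "rearing_sire", "rearing_dam", "culture")
  lack <- setdiff(need, names(df))
  if (length(lack))
    stopf("cultural pedigree file %s lacks column(s): %s",
          path, paste(lack, collapse = ", "))
  culturalPedigree(df$id, df$rearing_sire, df$rearing_dam, df$culture,
                   ped = ped)
}

#' Write a cultural pedigree file
#' @param cped a [CulturalPedigree].
#' @param path output path.
#' @param sep field separator.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeCulturalPedigree <- function(cped, path, sep = ",",
                                  header = character(0)) {
  df <- data.frame(
    id = cped@id,
    rearing_sire = ifelse(is.na(cped@rearingSire), "0", cped@rearingSire),
    rearing_dam = ifelse(is.na(cped@rearingDam), "0", cped@rearingDam),
    culture = cped@culture,
    cross_fostered = cped@crossFostered,
    stringsAsFactors = FALSE)
  writeDelimited(df, path, sep = sep, header = header)
}

#' @describeIn founders ids with both rearing parents unknown.
#' @export
setMethod("founders", "CulturalPedigree", function(ped)
  ped@id[is.na(ped@rearingSire) & is.na(ped@rearingDam)])

#' @describeIn nIndividuals members of a cultural pedigree.
#' @export
setMethod("nIndividuals", "CulturalPedigree", function(x) length(x@id))

#' @describeIn ids member ids of a cultural pedigree.
#' @export
setMethod("ids", "CulturalPedigree", function(x) x@id)

#' @describeIn cultures culture label per individual (named by id).
#' @export
setMethod("cultures", "CulturalPedigree", function(x)
  stats::setNames(x@culture, x@id))

#' Culture labels
#' @param x a [CulturalPedigree] or [Population].
#' @return named character vector of culture labels.
#' @rdname cultures
#' @name cultures
NULL

setMethod("show", "CulturalPedigree", function(object) {
  cat("CulturalPedigree with", length(object@id), "individuals,",
      length(unique(object@culture)), "culture(s),",
      sum(object@crossFostered), "cross-fostered\n")
  invisible(object)
})

#' Culture-identity relationship matrix (form 1)
#'
#' The simplest cultural covariance structure: \eqn{C_{ij} = 1} when i and j
#' were reared in the same culture (including \eqn{i = j}), else 0.  Block
#' diagonal after sorting individuals by culture.
#'
#' @param cped a [CulturalPedigree].
#' @return a [RelationshipMatrix].
#' @export
setMethod("cultureIdentityMatrix", "CulturalPedigree", function(cped) {
  same <- outer(cped@culture, cped@culture, "==") * 1
  relationshipMatrix(same, cped@id)
})

#' Social-contact relationship matrix (forms 2 and 3)
#'
#' Accumulates pairwise contact weights into a raw matrix
#' \eqn{S_{ij} = \sum w \cdot \mathrm{inertia}(class)}, symmetrizes it as
#' \eqn{(S + S^T)/2}, scales by the largest entry so values are relative,
#' and sets the diagonal to 1.  With the default inertia of 1 for every
#' relation class this is the plain social-encounter matrix (form 2);
#' supplying class-specific inertia weights (e.g. grandparent, competitor,
#' helper) gives the transgenerational weighted form (form 3).
#'
#' @param records data.frame with columns `i`, `j`, `weight` and optionally
#'   `class`; weights are nonnegative counts or durations.
#' @param ids character vector fixing the individuals and their order.
#' @param inertia named numeric vector mapping relation classes to
#'   nonnegative multipliers; classes absent from it default to 1.
#' @return a [RelationshipMatrix] with unit diagonal.
#' @export
contactMatrix <- function(records, ids, inertia = numeric(0)) {
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(records)) {
    bad <- setdiff(unique(c(records$i, records$j)), ids)
    if (length(bad))
      stopf("contact record id(s) absent from ids: %s",
            paste(bad, collapse = ", "))
    if (any(records$i == records$j))
      stopf("contact records must have i != j")
    w <- as.numeric(records$weight)
    if (any(w < 0)) stopf("contact weights must be nonnegative")
    if (any(inertia < 0)) stopf("inertia weights must be nonnegative")
    cls <- if ("class" %in% names(records)) as.character(records$class)
           else rep("", nrow(records))
    mult <- ifelse(cls %in% names(inertia), inertia[cls], 1)
    for (k in seq_along(w)) {
      S[records$i[k], records$j[k]] <- S[records$i[k], records$j[k]] +
        w[k] * mult[k]
    }
  }
  S <- (S + t(S)) / 2
  mx <- max(S)
  if (mx > 0) S <- S / mx
  diag(S) <- 1
  relationshipMatrix(S, ids)
}

#' Cultural relationship matrix from rearing links (recursion form)
#'
#' Builds C by the same tabular coancestry recursion as [additiveMatrix()],
#' substituting rearing parents for genetic parents: \eqn{c_{ij}} is a
#' coefficient of "cultural coancestry" through chains of rearing.  Founder
#' individuals are culturally unrelated even within one culture — the
#' culture-level sharing is the job of [cultureIdentityMatrix()], which
#' keeps the two forms non-redundant.  Consequently, when every individual
#' is reared by its genetic parents, C equals A entrywise: the confounding
#' of unmanipulated populations.
#'
#' @param cped a [CulturalPedigree].
#' @param ... unused.
#' @return a [RelationshipMatrix] over `ids(cped)`.
#' @export
setMethod("culturalRelatednessMatrix", "CulturalPedigree", function(cped, ...) {
  C <- tabularRelationship(parentIndices(cped@id, cped@rearingSire),
                           parentIndices(cped@id, cped@rearingDam))
  relationshipMatrix(C, cped@id)
})

#' Overlap diagnostics between A and C
#'
#' In an unmanipulated population the genetic and cultural pedigrees carry
#' the same links, so A and C are practically identical and the two
#' variance components cannot be separated.  This reports how far apart the
#' two matrices actually are: the Pearson correlation of the strictly
#' lower-triangular entries (`NA` with a flag when either triangle is
#' constant, to avoid a 0/0), the Frobenius distance, and — when the two
#' pedigrees are supplied — the fraction of individuals whose rearing
#' parents differ from their genetic parents.
#'
#' @param A,C [RelationshipMatrix] objects over the same ids in the same
#'   order.
#' @param ped optional [GeneticPedigree] and
#' @param cped optional [CulturalPedigree], used only for the
#'   cross-fostered fraction.
#' @return list with `r_offdiag`, `r_defined` (FALSE when a triangle is
#'   constant), `frobenius_distance`, and `fraction_cross_fostered` (`NA`
#'   when pedigrees are not supplied).
#' @export
pedigreeOverlap <- function(A, C, ped = NULL, cped = NULL) {
  if (!identical(A@ids, C@ids))
    stopf("A and C must be over the same ids in the same order")
  a <- A@values[lower.tri(A@values)]
  c_ <- C@values[lower.tri(C@values)]
  defined <- stats::sd(a) > 0 && stats::sd(c_) > 0
  r <- if (defined) stats::cor(a, c_) else NA_real_
  frac <- NA_real_
  if (!is.null(cped)) {
    if (!is.null(ped)) {
      cped <- culturalPedigree(cped@id, cped@rearingSire, cped@rearingDam,
                               cped@culture, ped = ped)
    }
    frac <- mean(cped@crossFostered)
  }
  list(r_offdiag = r, r_defined = defined,
       frobenius_distance = sqrt(sum((A@values - C@values)^2)),
       fraction_cross_fostered = frac)
}
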