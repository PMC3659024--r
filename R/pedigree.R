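#' Construct a genetic pedigree
#'
#' Validates parentage records and stores them parent-first.  Ordering is a
#' layered Kahn topological sort with ties broken by input order, so the
#' result is deterministic and independent of whether the input already
#' lists parents before offspring.  A cycle (an individual that is its own
#' ancestor) is an error that names one offending cycle.
#'
#' @param id character vector of individual ids.
#' @param sire,dam character vectors of parent ids; `NA` (or any of the
#'   tokens `"0"`, `""`, `"NA"`) means unknown.
#' @param sex optional character vector (`"M"`, `"F"`, `"U"`).
#' @param missingParents what to do when a parent is referenced but never
#'   declared as a member: `"insert"` (default) adds it as a founder with a
#'   warning, `"error"` aborts.
#'
#' @return a [GeneticPedigree].
#' @examples
#' ped <- geneticPedigree(id = c("o", "s", "d"),
#'                        sire = c("s", NA, NA), dam = c("d", NA, NA))
#' founders(ped)
#' @export
geneticPedigree <- function(id, sire, dam, sex = NULL,
                            missingParents = c("insert", "error")) {
  missingParents <- match.arg(missingParents)
  id <- as.character(id)
  sire <- normalizeUnknown(as.character(sire))
  dam <- normalizeUnknown(as.character(dam))
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stopf("duplicate id(s) in pedigree: %s", paste(dup, collapse = ", "))
  undeclared <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(undeclared)) {
    if (missingParents == "error")
      stopf("parent(s) referenced but never declared: %s",
            paste(undeclared, collapse = ", "))
    warning("inserting undeclared parent(s) as founders: ",
            paste(undeclared, collapse = ", "), call. = FALSE)
    id <- c(id, undeclared)
    sire <- c(sire, rep(NA_character_, length(undeclared)))
    dam <- c(dam, rep(NA_character_, length(undeclared)))
    if (!is.null(sex)) sex <- c(as.character(sex), rep("U", length(undeclared)))
  }
  ord <- topoOrder(id, sire, dam)
  new("GeneticPedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      sex = if (is.null(sex)) character(0) else as.character(sex)[ord])
}

normalizeUnknown <- function(x, tokens = UNKNOWN_TOKENS) {
  x[x %in% tokens] <- NA_character_
  x
}

# Layered Kahn topological sort over parent links; within a layer the input
# order is preserved.  Errors with one explicit cycle if no ordering exists.
topoOrder <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  self <- which(si == pos | di == pos)
  if (length(self))
    stopf("self-parentage for id(s): %s", paste(id[self], collapse = ", "))
  placed <- logical(n)
  out <- integer(0)
  while (length(out) < n) {
    ready <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) {
      cyc <- findCycle(id, si, di, which(!placed)[1])
      stopf("pedigree contains a cycle: %s", paste(cyc, collapse = " -> "))
    }
    placed[ready] <- TRUE
    out <- c(out, ready)
  }
  out
}

findCycle <- function(id, si, di, start) {
  seen <- integer(0)
  k <- start
  repeat {
    if (k %in% seen) {
      cyc <- seen[which(seen == k):length(seen)]
      return(id[c(cyc, k)])
    }
    seen <- c(seen, k)
    k <- if (si[k] > 0L) si[k] else di[k]
    if (k == 0L) return(id[seen]) # defensive; should not happen
  }
}

#' Read a pedigree file
#'
#' Delimited text (comma or tab, autodetected), header row required, with
#' columns mappable to id, sire and dam; extra columns are ignored.  Unknown
#' parents may be encoded as `"0"`, the empty string, or `"NA"`.
#'
#' @param path path to the file.
#' @param dialect named list mapping the roles `id`, `sire`, `dam` (and
#'   optionally `sex`) to column names in the file, plus an optional
#'   `unknown` character vector of tokens meaning "unknown parent".
#' @param missingParents passed to [geneticPedigree()].
#' @return a [GeneticPedigree].
#' @export
readPedigree <- function(path,
                         dialect = list(id = "id", sire = "sire", dam = "dam"),
                         missingParents = c("insert", "error")) {
  df <- readDelimited(path)
  for (role in c("id", "sire", "dam")) {
    col <- dialect[[role]] %||% role
    if (!col %in% names(df))
      stopf("pedigree file %s lacks a '%s' column (looked for '%s')",
            path, role, col)
  }
  unknown <- dialect$unknown %||% UNKNOWN_TOKENS
  sexcol <- dialect$sex %||% "sex"
  geneticPedigree(
    id = df[[dialect$id %||% "id"]],
    sire = normalizeUnknown(df[[dialect$sire %||% "sire"]], unknown),
    dam = normalizeUnknown(df[[dialect$dam %||% "dam"]], unknown),
    sex = if (sexcol %in% names(df)) df[[sexcol]] else NULL,
    missingParents = missingParents)
}

#' Write a pedigree file
#'
#' @param ped a [GeneticPedigree].
#' @param path output path.
#' @param sep field separator (default comma).
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments before the column header.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path, sep = ",", header = character(0)) {
  df <- data.frame(id = ped@id,
                   sire = ifelse(is.na(ped@sire), "0", ped@sire),
                   dam = ifelse(is.na(ped@dam), "0", ped@dam),
                   stringsAsFactors = FALSE)
  if (length(ped@sex)) df$sex <- ped@sex
  writeDelimited(df, path, sep = sep, header = header)
}

#' @describeIn founders ids of individuals with both parents unknown.
#' @export
setMethod("founders", "GeneticPedigree", function(ped)
  ped@id[is.na(ped@sire) & is.na(ped@dam)])

#' Founders of a pedigree
#'
#' @param ped a [GeneticPedigree] or [CulturalPedigree].
#' @return character vector of founder ids.
#' @rdname founders
#' @name founders
NULL

#' @describeIn nIndividuals number of members of a genetic pedigree.
#' @export
setMethod("nIndividuals", "GeneticPedigree", function(x) length(x@id))

#' Number of individuals
#' @param x a pedigree or population object.
#' @return integer count.
#' @rdname nIndividuals
#' @name nIndividuals
NULL

#' @describeIn ids member ids of a genetic pedigree (parent-first order).
#' @export
setMethod("ids", "GeneticPedigree", function(x) x@id)

#' Ordered ids
#' @param x a pedigree, population or relationship matrix.
#' @return character vector of ids.
#' @rdname ids
#' @name ids
NULL

setMethod("show", "GeneticPedigree", function(object) {
  cat("GeneticPedigree with", length(object@id), "individuals (",
      length(founders(object)), "founders )\n")
  utils::str(utils::head(data.frame(id = object@id, sire = object@sire,
                                    dam = object@dam), 6), give.attr = FALSE)
  invisible(object)
})

# Shared tabular-method engine: one O(n^2) pass over a parent-first ordering.
# si/di are parent indices (0 = unknown).  Returns the dense relationship
# matrix with diag 1 + F.
tabularRelationship <- function(si, di) {
  n <- length(si)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  A
}

parentIndices <- function(id, parent) {
  pos <- seq_along(id); names(pos) <- id
  ifelse(is.na(parent), 0L, pos[parent])
}

#' Additive genetic relationship matrix A
#'
#' Builds A with entries \eqn{A_{ij} = 2\Theta_{ij}} (twice the coefficient
#' of coancestry) by the single-pass tabular method over the parent-first
#' ordering.  Diagonal entries equal \eqn{1 + F_i} where \eqn{F_i} is the
#' inbreeding coefficient.  Unknown parents contribute as unique unrelated,
#' non-inbred founders.
#'
#' @param ped a [GeneticPedigree].
#' @param ... unused.
#' @return a [RelationshipMatrix] over `ids(ped)`.
#' @examples
#' ped <- geneticPedigree(c("o","s","d"), c("s",NA,NA), c("d",NA,NA))
#' as.matrix(additiveMatrix(ped))
#' @export
setMethod("additiveMatrix", "GeneticPedigree", function(ped, ...) {
  A <- tabularRelationship(parentIndices(ped@id, ped@sire),
                           parentIndices(ped@id, ped@dam))
  relationshipMatrix(A, ped@id)
})

#' Coefficient of coancestry (kinship)
#'
#' \eqn{\Theta_{ij}} is the probability that an allele drawn at random from
#' individual i is identical by descent to one drawn at random from j.
#' Computed by the classical recursion
#' \eqn{\Theta_{ii} = (1 + F_i)/2},
#' \eqn{\Theta_{ij} = (\Theta_{i,sire(j)} + \Theta_{i,dam(j)})/2}
#' (recursing on whichever of the pair appears later in the parent-first
#' ordering), with unknown parents contributing 0.  This pairwise recursion
#' is an independent (slower) route to the same quantity as
#' [additiveMatrix()], which uses the tabular method; `additiveMatrix`
#' doubles it: \eqn{A_{ij} = 2\Theta_{ij}}.
#'
#' @param ped a [GeneticPedigree].
#' @param i,j character vectors of member ids (recycled to equal length);
#'   a memoization cache is shared across all pairs of one call.
#' @return numeric vector of coancestry coefficients.
#' @export
kinshipCoefficient <- function(ped, i, j) {
  id <- ped@id
  pos <- seq_along(id); names(pos) <- id
  bad <- setdiff(unique(c(i, j)), id)
  if (length(bad))
    stopf("unknown id(s): %s", paste(bad, collapse = ", "))
  si <- parentIndices(id, ped@sire)
  di <- parentIndices(id, ped@dam)
  cache <- new.env(parent = emptyenv(), size = 4L * length(id))
  theta <- function(a, b) {
    if (a > b) { t <- a; a <- b; b <- t }
    key <- paste0(a, "|", b)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == 0L || b == 0L) {
      0
    } else if (a == b) {
      0.5 * (1 + theta(si[a], di[a]))
    } else {
      # b is never an ancestor of a because a < b in parent-first order
      0.5 * (theta(a, si[b]) + theta(a, di[b]))
    }
    cache[[key]] <- val
    val
  }
  pr <- cbind(pos[i], pos[j])
  vapply(seq_len(nrow(pr)), function(k) theta(pr[k, 1], pr[k, 2]), numeric(1))
}

#' Inbreeding coefficients
#'
#' \eqn{F_i = \Theta_{sire(i), dam(i)}}, the coancestry of the parents; 0
#' when either parent is unknown.  Computed from the tabular relationship
#' matrix (`F_i = A_{sire,dam}/2`), so `diag(A) == 1 + F` holds exactly.
#'
#' @param ped a [GeneticPedigree].
#' @return named numeric vector of `F_i` in `[0, 1)` over `ids(ped)`.
#' @export
setMethod("inbreeding", "GeneticPedigree", function(ped) {
  A <- as.matrix(additiveMatrix(ped))
  stats::setNames(diag(A) - 1, ped@id)
})
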